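# The four freshwater-invasion scenarios as parameterized model presets.
#
# Nine populations: a deep landlocked clade (DT, PY, NY), five recently
# landlocked lakes (LA, CH, TH, HZ, GY) and the anadromous population
# (SH), which also carries the ancestral lineage A.
#
#   model1: every freshwater population splits directly from the
#           anadromous population at one time T1.
#   model2: a single invasion founds a common freshwater ancestor at T1
#           which radiates into all eight lakes at T2.
#   model3: two independent invasions: the deep clade invades at T1 and
#           radiates at T2; the recent clade invades at T3 and radiates
#           at T4.
#   model4: model3 plus directed migration between adjacent populations
#           (14 adjacent pairs, 28 rates).
#
# The documented parameterization gives d = 10 / 11 / 13 / 41 free
# parameters: 9 current sizes plus 1 / 2 / 4 times (ancestral populations
# inherit the anadromous size N_SH), model4 adding the 28 rates. The true
# sizes, times and generation time behind the published calendar estimates
# were never published; preset defaults are placeholders chosen so that a
# full-scale simulated dataset reproduces the qualitative structure (deep
# vs shallow invasion, adjacency gene flow) and the observed SNP density
# (about 4.6 SNPs per variable locus).

POPS9 <- c("DT", "PY", "NY", "LA", "CH", "TH", "HZ", "GY", "SH")
DEEP_CLADE <- c("DT", "PY", "NY")
RECENT_CLADE <- c("LA", "CH", "TH", "HZ", "GY")

# 14 adjacent pairs (hydrological adjacency; the exact set is configurable)
ADJACENT_PAIRS <- matrix(c(
  "DT", "PY",  "PY", "NY",  "NY", "TH",  "SH", "CH",  "SH", "TH",
  "SH", "DT",  "SH", "PY",  "SH", "NY",  "SH", "GY",  "CH", "TH",
  "HZ", "GY",  "HZ", "SH",  "LA", "CH",  "LA", "TH"),
  ncol = 2, byrow = TRUE)

#' Default diploid sample sizes of the emulated nine-population survey
#' @return named integer vector (138 individuals over 9 populations).
#' @export
default_sample_sizes <- function() {
  c(DT = 18L, PY = 21L, NY = 19L, LA = 9L, CH = 19L, TH = 21L,
    HZ = 10L, GY = 8L, SH = 13L)
}

# Default "true" parameters of the presets (haploid gene copies;
# generations). Calibrated once so that a full-scale model3 dataset at the
# default sample sizes averages about 4.6 SNPs per variable region.
preset_defaults <- function() {
  sizes <- c(DT = 6120, PY = 5440, NY = 6120, LA = 6120, CH = 7480,
             TH = 8160, HZ = 6800, GY = 6460, SH = 20400)
  times <- c(T1 = 170000, T2 = 2500, T3 = 1100, T4 = 1050)
  mig <- setNames(rep(2e-5, nrow(ADJACENT_PAIRS) * 2),
                  paste0("m_",
                         c(ADJACENT_PAIRS[, 1], ADJACENT_PAIRS[, 2]), "_",
                         c(ADJACENT_PAIRS[, 2], ADJACENT_PAIRS[, 1])))
  list(sizes = sizes, times = times, mig = mig)
}

#' Build one of the four invasion models
#'
#' @param name `"model1"` ... `"model4"`.
#' @param sizes named haploid sizes per population (defaults are the
#'   calibrated placeholders).
#' @param times named vector with the divergence times used by the model
#'   (`T1` and, depending on the model, `T2`, `T3`, `T4`), generations.
#' @param mig named directed migration rates `m_<from>_<to>` for model4.
#' @param pops population subset (canonical order kept); reduced models
#'   (e.g. 4 populations for desk-scale fitting) keep the same topology
#'   with the surviving clade members.
#' @param ... further arguments to [demographic_model()] (mu, n_regions,
#'   region_length, generation_time).
#' @return a `DemographicModel`.
#' @export
preset_model <- function(name = c("model1", "model2", "model3", "model4"),
                         sizes = NULL, times = NULL, mig = NULL,
                         pops = POPS9, ...) {
  name <- match.arg(name)
  def <- preset_defaults()
  sz <- def$sizes; sz[names(sizes)] <- sizes
  tm <- def$times; tm[names(times)] <- times
  mg <- def$mig; mg[names(mig)] <- mig
  pops <- POPS9[POPS9 %in% pops]
  assert_that("SH" %in% pops, "presets require the anadromous population SH")
  # a radiation cannot postdate its invasion: clamp so any parameter draw
  # (e.g. an optimizer or ABC prior proposal) yields a valid model
  tm["T2"] <- min(tm["T2"], 0.99 * tm["T1"])
  tm["T4"] <- min(tm["T4"], 0.99 * tm["T3"])
  deep <- intersect(DEEP_CLADE, pops)
  recent <- intersect(RECENT_CLADE, pops)
  fresh <- c(deep, recent)
  assert_that(length(fresh) >= 1, "presets need at least one freshwater population")
  N_SH <- unname(sz["SH"])

  ev <- list()
  add <- function(e) ev[[length(ev) + 1]] <<- e

  if (name == "model1") {
    for (p in fresh) add(event_fusion(tm["T1"], p, "SH"))
  } else if (name == "model2") {
    carrier <- fresh[1]
    for (p in fresh[-1]) add(event_fusion(tm["T2"], p, carrier))
    add(event_size_change(tm["T2"], carrier, N_SH))
    add(event_fusion(tm["T1"], carrier, "SH"))
  } else {  # model3 / model4 topology
    if (length(deep) > 0) {
      dc <- deep[1]
      for (p in deep[-1]) add(event_fusion(tm["T2"], p, dc))
      add(event_size_change(tm["T2"], dc, N_SH))
      add(event_fusion(tm["T1"], dc, "SH"))
    }
    if (length(recent) > 0) {
      rc <- recent[1]
      for (p in recent[-1]) add(event_fusion(tm["T4"], p, rc))
      add(event_size_change(tm["T4"], rc, N_SH))
      add(event_fusion(tm["T3"], rc, "SH"))
    }
  }

  migration <- NULL
  if (name == "model4") {
    P <- length(pops)
    migration <- matrix(0, P, P, dimnames = list(pops, pops))
    for (r in seq_len(nrow(ADJACENT_PAIRS))) {
      a <- ADJACENT_PAIRS[r, 1]; b <- ADJACENT_PAIRS[r, 2]
      if (a %in% pops && b %in% pops) {
        migration[a, b] <- mg[paste0("m_", a, "_", b)]
        migration[b, a] <- mg[paste0("m_", b, "_", a)]
      }
    }
  }

  demographic_model(pops, unname(sz[pops]), events = ev,
                    migration = migration, ...)
}

#' Parameter-vector builder for a preset
#'
#' Returns `function(par)` mapping a named parameter vector (any subset
#' of `N_<pop>`, `T1`..`T4`, `m_<from>_<to>`; unnamed entries keep preset
#' defaults) to a `DemographicModel`, for use with [fit_model()].
#'
#' @inheritParams preset_model
#' @return a builder function with attribute `model_id`.
#' @export
preset_builder <- function(name, pops = POPS9, ...) {
  force(name); force(pops)
  dots <- list(...)
  f <- function(par) {
    nm <- names(par)
    sizes <- par[startsWith(nm, "N_")]
    names(sizes) <- sub("^N_", "", names(sizes))
    times <- par[nm %in% c("T1", "T2", "T3", "T4")]
    mig <- par[startsWith(nm, "m_")]
    do.call(preset_model, c(list(name = name, sizes = sizes, times = times,
                                 mig = mig, pops = pops), dots))
  }
  attr(f, "model_id") <- name
  f
}

#' Free parameters of a preset's documented parameterization
#'
#' @inheritParams preset_model
#' @return character vector of free parameter names; its length is the
#'   `d` used in AIC (10, 11, 13, 41 for the full nine-population models).
#' @export
preset_free_params <- function(name = c("model1", "model2", "model3", "model4"),
                               pops = POPS9) {
  name <- match.arg(name)
  pops <- POPS9[POPS9 %in% pops]
  deep <- intersect(DEEP_CLADE, pops)
  recent <- intersect(RECENT_CLADE, pops)
  sizes <- paste0("N_", pops)
  times <- switch(name,
    model1 = "T1",
    model2 = c("T1", "T2"),
    c(if (length(deep) > 0) c("T1", if (length(deep) > 1) "T2"),
      if (length(recent) > 0) c("T3", if (length(recent) > 1) "T4")))
  mig <- character(0)
  if (name == "model4") {
    keep <- ADJACENT_PAIRS[, 1] %in% pops & ADJACENT_PAIRS[, 2] %in% pops
    ap <- ADJACENT_PAIRS[keep, , drop = FALSE]
    mig <- paste0("m_", c(ap[, 1], ap[, 2]), "_", c(ap[, 2], ap[, 1]))
  }
  c(sizes, times, mig)
}
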