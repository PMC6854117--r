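# Demographic models for the structured coalescent.
#
# Conventions: time runs backward in generations; sizes are haploid gene
# copies (use `diploid_size = TRUE` to supply diploid N, which is doubled);
# migration is backward: mig[i, j] is the per-generation probability that a
# lineage sampled in population i traces its ancestry to population j.

#' Construct a demographic model
#'
#' @param pop_names ordered population labels.
#' @param sizes effective sizes per population (haploid gene copies unless
#'   `diploid_size = TRUE`).
#' @param events list of events from [event_fusion()], [event_size_change()]
#'   or [event_migration_change()], in any order (sorted by time; ties are
#'   applied in listed order).
#' @param migration optional square backward migration matrix (zero
#'   off-diagonals by default).
#' @param mu mutation rate per site per generation.
#' @param n_regions,region_length number and length (bp) of the independent
#'   non-recombining regions the locus set emulates.
#' @param generation_time generation time in years, used only to express
#'   times in calendar units.
#' @param diploid_size if `TRUE`, `sizes` (and event sizes) are diploid and
#'   are doubled internally (logged).
#' @return object of class `DemographicModel`.
#' @export
demographic_model <- function(pop_names, sizes, events = list(),
                              migration = NULL,
                              mu = 2.5e-8, n_regions = 2869L,
                              region_length = 214L,
                              generation_time = 3,
                              diploid_size = FALSE) {
  P <- length(pop_names)
  assert_that(length(sizes) == P, "need one size per population")
  assert_that(all(sizes > 0), "all population sizes must be positive")
  if (diploid_size) {
    fw_log("interpreting sizes as diploid N; doubling to haploid gene copies")
    sizes <- 2 * sizes
    events <- lapply(events, function(e) {
      if (e$kind == "size_change") e$size <- 2 * e$size
      e
    })
  }
  if (is.null(migration)) migration <- matrix(0, P, P)
  migration <- as.matrix(migration)
  assert_that(nrow(migration) == P && ncol(migration) == P,
              "migration matrix must be %d x %d", P, P)
  diag(migration) <- 0
  assert_that(all(migration >= 0), "migration rates must be non-negative")

  times <- vapply(events, `[[`, numeric(1), "time")
  events <- events[order(times)]
  times <- sort(times)
  assert_that(all(diff(times) >= 0) && all(times > 0),
              "event times must be positive and non-decreasing")

  model <- structure(list(pop_names = as.character(pop_names),
                          sizes = as.numeric(sizes),
                          events = events, migration = migration,
                          mu = mu, n_regions = as.integer(n_regions),
                          region_length = as.integer(region_length),
                          generation_time = generation_time),
                     class = "DemographicModel")
  validate_model(model)
  model
}

#' @rdname demographic_model
#' @param time event time (generations before present).
#' @param source,sink population labels: at `time`, all lineages of
#'   `source` move into `sink` (a population fusion, looking backward).
#' @export
event_fusion <- function(time, source, sink)
  list(time = time, kind = "fusion", source = source, sink = sink)

#' @rdname demographic_model
#' @param pop population whose size changes at `time`.
#' @param size the new size (same units as `sizes`).
#' @export
event_size_change <- function(time, pop, size)
  list(time = time, kind = "size_change", pop = pop, size = size)

#' @rdname demographic_model
#' @param matrix replacement backward migration matrix from `time` on.
#' @export
event_migration_change <- function(time, matrix)
  list(time = time, kind = "migration_change", matrix = matrix)

# A model must let every pair of lineages eventually coalesce: either the
# fusions funnel all populations into one terminal ancestor, or the
# populations remaining at the end of the event list communicate by
# migration.
validate_model <- function(model) {
  P <- length(model$pop_names)
  active <- rep(TRUE, P)
  mig <- model$migration
  for (e in model$events) {
    if (e$kind == "fusion") {
      is <- match(e$source, model$pop_names)
      it <- match(e$sink, model$pop_names)
      assert_that(!is.na(is) && !is.na(it), "fusion names unknown population")
      assert_that(active[is] && active[it],
                  "fusion involves an already-merged population: %s -> %s",
                  e$source, e$sink)
      active[is] <- FALSE
      mig[is, ] <- 0; mig[, is] <- 0
    } else if (e$kind == "size_change") {
      ip <- match(e$pop, model$pop_names)
      assert_that(!is.na(ip), "size change names unknown population: %s", e$pop)
      assert_that(e$size > 0, "sizes must remain positive")
    } else if (e$kind == "migration_change") {
      m <- as.matrix(e$matrix)
      assert_that(all(dim(m) == P), "migration_change matrix must be %d x %d", P)
      mig <- m
      mig[!active, ] <- 0; mig[, !active] <- 0
    } else stop_fw("unknown event kind: %s", e$kind)
  }
  if (sum(active) > 1) {
    # remaining populations must be connected through migration
    adj <- (mig + t(mig))[active, active, drop = FALSE] > 0
    reach <- rep(FALSE, nrow(adj)); reach[1] <- TRUE
    repeat {
      nxt <- reach | as.vector(adj %*% reach > 0)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    assert_that(all(reach),
                "model never fully coalesces: %d populations remain after the last event with no connecting migration",
                sum(active))
  }
  invisible(TRUE)
}

#' @export
print.DemographicModel <- function(x, ...) {
  cat(sprintf("DemographicModel: %d populations (%s), %d events, mu=%g, %d x %d bp regions\n",
              length(x$pop_names), paste(x$pop_names, collapse = ", "),
              length(x$events), x$mu, x$n_regions, x$region_length))
  invisible(x)
}

#' Convert generations to calendar years
#' @param model a `DemographicModel`.
#' @param generations times in generations before present.
#' @return times in years before present.
#' @export
generations_to_years <- function(model, generations)
  generations * model$generation_time

# flatten a model into the representation the C++ engine consumes
flatten_model <- function(model) {
  P <- length(model$pop_names)
  ev <- model$events
  n_ev <- length(ev)
  kind_code <- c(fusion = 0L, size_change = 1L, migration_change = 2L)
  ev_time <- vapply(ev, `[[`, numeric(1), "time")
  ev_kind <- vapply(ev, function(e) kind_code[[e$kind]], integer(1))
  ev_a <- integer(n_ev); ev_b <- integer(n_ev); ev_size <- numeric(n_ev)
  ev_mig <- vector("list", max(n_ev, 1))
  for (i in seq_len(n_ev)) {
    e <- ev[[i]]
    if (e$kind == "fusion") {
      ev_a[i] <- match(e$source, model$pop_names) - 1L
      ev_b[i] <- match(e$sink, model$pop_names) - 1L
    } else if (e$kind == "size_change") {
      ev_a[i] <- match(e$pop, model$pop_names) - 1L
      ev_size[i] <- e$size
    } else {
      ev_mig[[i]] <- as.matrix(e$matrix)
    }
  }
  list(n_pops = P, sizes = model$sizes, migration = model$migration,
       ev_time = ev_time, ev_kind = ev_kind, ev_a = ev_a, ev_b = ev_b,
       ev_size = ev_size, ev_mig = ev_mig)
}

#' Symmetric finite-island model
#'
#' Convenience constructor: `n_demes` exchangeable demes of `N` haploid
#' copies, each lineage migrating at total backward rate `m` with a
#' uniformly chosen destination.
#'
#' @param n_demes number of demes.
#' @param N haploid deme size.
#' @param m total per-lineage backward migration rate per generation.
#' @param ... passed to [demographic_model()].
#' @return a `DemographicModel`.
#' @export
island_model <- function(n_demes, N, m, ...) {
  mig <- matrix(m / (n_demes - 1), n_demes, n_demes)
  diag(mig) <- 0
  demographic_model(paste0("deme", seq_len(n_demes)),
                    sizes = rep(N, n_demes), migration = mig, ...)
}

#' Read or write a model configuration file
#'
#' Models are stored as JSON (a strict subset of YAML) with blocks
#' `populations` (names and sizes), `events`, `migration`, and `mutation`
#' (`mu`, `n_regions`, `region_length`, `generation_time`).
#'
#' @param path file path.
#' @return `read_model_config` returns a `DemographicModel`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (blk in c("populations", "mutation"))
    if (is.null(cfg[[blk]])) stop_fw("model config %s: missing block '%s'", path, blk)
  ev <- lapply(seq_len(NROW(cfg$events)), function(i) {
    e <- if (is.data.frame(cfg$events)) as.list(cfg$events[i, ]) else cfg$events[[i]]
    switch(e$kind,
           fusion = event_fusion(e$time, e$source, e$sink),
           size_change = event_size_change(e$time, e$pop, e$size),
           migration_change = event_migration_change(e$time, e$matrix),
           stop_fw("model config %s: unknown event kind '%s'", path, e$kind))
  })
  demographic_model(cfg$populations$name, cfg$populations$size,
                    events = ev,
                    migration = cfg$migration,
                    mu = cfg$mutation$mu,
                    n_regions = cfg$mutation$n_regions,
                    region_length = cfg$mutation$region_length,
                    generation_time = cfg$mutation$generation_time %||% 3)
}

#' @rdname read_model_config
#' @param model a `DemographicModel`.
#' @export
write_model_config <- function(model, path) {
  ev <- lapply(model$events, function(e) e)
  cfg <- list(populations = data.frame(name = model$pop_names,
                                       size = model$sizes),
              events = ev,
              migration = model$migration,
              mutation = list(mu = model$mu, n_regions = model$n_regions,
                              region_length = model$region_length,
                              generation_time = model$generation_time))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
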