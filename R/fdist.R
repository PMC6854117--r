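# FDIST-style outlier detection: an island-model coalescent null of Fst
# conditioned on heterozygosity, per-locus p-values via an
# He-rank-window, and disruptive/balancing classification.

# He and per-locus Weir-Cockerham theta from a dosage matrix + labels.
# Uses exactly the same variance-component code as pairwise_fst, so the
# two agree bit for bit on identical input.
locus_he_fst <- function(dos, groups) {
  comp <- wc_abc(dos, groups)
  theta <- with(comp, ifelse(a + b + c == 0, NA_real_, a / (a + b + c)))
  he <- with(comp, 2 * pbar * (1 - pbar) * n_total / (n_total - 1))
  data.frame(locus = comp$locus, He = he, Fst = theta)
}

#' Observed per-locus (He, Fst) table
#'
#' @param gm a `GenotypeMatrix`.
#' @param pm a `PopulationMap`.
#' @param pops the populations entering the comparison (e.g. the
#'   anadromous population against one resident group).
#' @return data.frame with `locus_id`, `He` (pooled expected
#'   heterozygosity) and `Fst` (per-locus Weir-Cockerham theta);
#'   uninformative loci are dropped.
#' @export
observed_locus_stats <- function(gm, pm, pops) {
  validate_popmap(pm, gm)
  cols <- unlist(lapply(pops, function(p) pop_columns(gm, pm, p)))
  lab <- rep(pops, vapply(pops, function(p) length(pop_columns(gm, pm, p)),
                          integer(1)))
  st <- locus_he_fst(gm$geno[, cols, drop = FALSE], lab)
  ok <- !is.na(st$Fst)
  data.frame(locus_id = gm$locus_id[st$locus[ok]],
             He = st$He[ok], Fst = st$Fst[ok])
}

#' Simulate the FDIST island-model null
#'
#' Simulates single-SNP loci under a finite island model (by default 100
#' demes per comparison group) with the per-lineage migration rate tuned
#' by bisection so that the trimmed-mean simulated Fst matches the
#' observed mean Fst to within `tol`. Each locus receives exactly one
#' mutation (branch-length weighted), so simulated heterozygosities span
#' the admissible range (0, 1). Haploid copies are paired into
#' pseudo-diploids so that the same Weir-Cockerham estimator as
#' [pairwise_fst()] applies.
#'
#' @param target_mean_fst observed multi-population mean Fst in (0, 1).
#' @param sample_sizes haploid copies per sampled deme (even numbers);
#'   one sampled deme per population in the comparison.
#' @param n_demes island size (classic setting: 100 demes).
#' @param n_sims null loci to return (classic setting: 20000).
#' @param seed integer seed.
#' @param N haploid deme size (the null depends on the product `Nm`, which
#'   the tuning controls; `N` itself only sets the time scale).
#' @param trim trim fraction per tail for the tuning criterion.
#' @param tol tuning tolerance on the trimmed mean (default 0.002).
#' @param n_tune loci per tuning evaluation.
#' @param max_iter bisection iteration cap.
#' @return data.frame of null `(He, Fst)` pairs with attributes
#'   `migration_rate` and `achieved_mean_fst`.
#' @export
simulate_fdist_null <- function(target_mean_fst, sample_sizes,
                                n_demes = 100L, n_sims = 20000L, seed = 1L,
                                N = 1000, trim = 0.05, tol = 0.002,
                                n_tune = 5000L, max_iter = 50L) {
  assert_that(target_mean_fst > 0 && target_mean_fst < 1,
              "target_mean_fst must lie strictly between 0 and 1")
  assert_that(all(sample_sizes %% 2 == 0),
              "sample_sizes are haploid copies and must be even (diploid pairing)")
  g <- length(sample_sizes)
  lab <- rep(paste0("deme", seq_len(g)), sample_sizes / 2)

  eval_stats <- function(m, n_loci, s) {
    sim <- sim_island_loci_cpp(n_demes, as.integer(sample_sizes), m, N,
                               as.integer(n_loci), as.numeric(s))
    island_stats(sim, sample_sizes, lab)
  }
  tmean <- function(st) mean(st$Fst, trim = trim, na.rm = TRUE)

  # island-model starting guess: Fst ~ 1 / (1 + 2Nm d/(d-1)). The bracket
  # is grown adaptively from the guess: simulation cost scales with N*m,
  # so blind evaluation at a huge upper migration rate must be avoided.
  m0 <- (1 / target_mean_fst - 1) * (n_demes - 1) / (2 * N * n_demes)
  s_tune <- derive_seed(seed, 777)
  s_final <- derive_seed(seed, 778)
  iter <- 1L
  f0 <- tmean(eval_stats(m0, n_tune, s_tune))
  if (f0 > target_mean_fst) {  # too much structure: raise migration
    lo <- m0; hi <- m0
    repeat {
      hi <- hi * 4
      iter <- iter + 1L
      if (tmean(eval_stats(hi, n_tune, s_tune)) < target_mean_fst) break
      lo <- hi
      if (iter >= max_iter %/% 2)
        stop_fw("failed to bracket target Fst %.3f from above", target_mean_fst)
    }
  } else {                     # too little structure: lower migration
    hi <- m0; lo <- m0
    repeat {
      lo <- lo / 4
      iter <- iter + 1L
      if (tmean(eval_stats(lo, n_tune, s_tune)) > target_mean_fst) break
      hi <- lo
      if (iter >= max_iter %/% 2)
        stop_fw("failed to bracket target Fst %.3f from below", target_mean_fst)
    }
  }
  # stage 1: coarse bisection on a tuning batch
  m <- sqrt(lo * hi)
  repeat {
    fm <- tmean(eval_stats(m, n_tune, s_tune))
    iter <- iter + 1L
    if (abs(fm - target_mean_fst) <= tol || iter >= max_iter %/% 2) break
    if (fm > target_mean_fst) lo <- m else hi <- m
    m <- sqrt(lo * hi)
  }
  # stage 2: refine against the full final simulation so the returned set
  # itself meets the tuning criterion
  st <- eval_stats(m, n_sims, s_final)
  fm <- tmean(st)
  while (abs(fm - target_mean_fst) > tol && iter < max_iter) {
    if (fm > target_mean_fst) lo <- m else hi <- m
    m <- sqrt(lo * hi)
    st <- eval_stats(m, n_sims, s_final)
    fm <- tmean(st)
    iter <- iter + 1L
  }
  if (abs(fm - target_mean_fst) > tol)
    stop_fw("migration tuning failed to reach target %.3f within %d iterations (got %.3f)",
            target_mean_fst, max_iter, fm)
  out <- st[!is.na(st$Fst), c("He", "Fst")]
  attr(out, "migration_rate") <- m
  attr(out, "achieved_mean_fst") <- mean(st$Fst, trim = trim, na.rm = TRUE)
  out
}

# loci x copies 0/1 matrix -> per-locus He / Fst after diploid pairing
island_stats <- function(haps, sample_sizes, lab) {
  odd <- seq(1, ncol(haps), by = 2)
  dos <- haps[, odd, drop = FALSE] + haps[, odd + 1, drop = FALSE]
  locus_he_fst(dos, lab)
}

#' Per-locus p-values conditioned on heterozygosity
#'
#' For each observed locus, the null loci whose He values are nearest
#' (the `window` fraction of the null set by He distance) form the
#' conditional distribution; the upper-tail p-value is
#' `(1 + #\{null Fst >= observed\}) / (1 + window size)`, and a lower-tail
#' analogue is kept for the balancing test.
#'
#' @param observed data.frame from [observed_locus_stats()].
#' @param null_pairs data.frame from [simulate_fdist_null()] (>= 1000
#'   rows).
#' @param window He-window fraction of the null set (default 0.1).
#' @param seed seed for the randomized tie ranks.
#' @details Two adaptations keep self-null p-values exactly uniform for
#'   single-SNP statistics, which are discrete: (i) when at least
#'   `min_exact` null loci share the observed locus's exact He value (He
#'   of a SNP is a function of the discrete pooled allele count), the
#'   conditional distribution is that exact class rather than the He-rank
#'   window, removing the between-class mixing a window straddles;
#'   (ii) the observed locus receives a uniformly random rank among its
#'   Fst ties (seeded). Both are no-ops for continuous statistics.
#' @return `OutlierRecord` data.frame: `locus_id`, `He`, `Fst`,
#'   `p_value` (upper tail), `p_lower`, `classification` (`NA` until
#'   [classify_outliers()]).
#' @export
locus_pvalues <- function(observed, null_pairs, window = 0.1, seed = 1L,
                          min_exact = 50L) {
  n_null <- nrow(null_pairs)
  assert_that(n_null >= 1000, "need at least 1000 null pairs")
  w <- ceiling(window * n_null)
  ord <- order(null_pairs$He)
  he_s <- null_pairs$He[ord]
  fst_s <- null_pairs$Fst[ord]
  n_obs <- nrow(observed)
  p_up <- p_lo <- numeric(n_obs)
  set.seed(as.integer(derive_seed(seed, 31)))
  for (i in seq_len(n_obs)) {
    e_lo <- findInterval(observed$He[i] - 1e-12, he_s)
    e_hi <- findInterval(observed$He[i] + 1e-12, he_s)
    if (e_hi - e_lo >= min_exact) {
      win <- fst_s[(e_lo + 1):e_hi]
    } else {
      pos <- findInterval(observed$He[i], he_s)
      lo <- pos; hi <- pos + 1
      # expand to the w null points nearest in He
      while (hi - lo - 1 < w) {
        d_lo <- if (lo >= 1) observed$He[i] - he_s[lo] else Inf
        d_hi <- if (hi <= n_null) he_s[hi] - observed$He[i] else Inf
        if (d_lo <= d_hi) lo <- lo - 1 else hi <- hi + 1
      }
      win <- fst_s[(lo + 1):(hi - 1)]
    }
    nw <- length(win)
    n_gt <- sum(win > observed$Fst[i])
    n_lt <- sum(win < observed$Fst[i])
    ties <- nw - n_gt - n_lt
    u <- if (ties > 0) sample.int(ties + 1L, 1L) - 1L else 0L
    p_up[i] <- (1 + n_gt + u) / (1 + nw)
    p_lo[i] <- (1 + n_lt + (ties - u)) / (1 + nw)
  }
  data.frame(locus_id = observed$locus_id, He = observed$He,
             Fst = observed$Fst, p_value = p_up, p_lower = p_lo,
             classification = NA_character_)
}

#' Classify outlier loci
#'
#' A locus is `disruptive` when its Fst exceeds the conditional
#' `upper_q` quantile of the null (upper-tail `p_value <= 1 - upper_q`),
#' `balancing` when it falls below the conditional `lower_q` quantile,
#' and `neutral` otherwise.
#'
#' @param records data.frame from [locus_pvalues()].
#' @param upper_q,lower_q conditional quantile thresholds (defaults 0.95
#'   and 0.05).
#' @return the records with `classification` filled in; a `counts`
#'   attribute tabulates the classes.
#' @export
classify_outliers <- function(records, upper_q = 0.95, lower_q = 0.05) {
  if (nrow(records) == 0) {
    attr(records, "counts") <- c(disruptive = 0L, balancing = 0L, neutral = 0L)
    return(records)
  }
  cls <- rep("neutral", nrow(records))
  cls[records$p_lower <= lower_q] <- "balancing"
  cls[records$p_value <= 1 - upper_q] <- "disruptive"
  records$classification <- cls
  attr(records, "counts") <- c(disruptive = sum(cls == "disruptive"),
                               balancing = sum(cls == "balancing"),
                               neutral = sum(cls == "neutral"))
  records
}
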