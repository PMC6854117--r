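# Descriptive population-genetic statistics: nucleotide diversity,
# Weir & Cockerham (1984) Fst with permutation significance, and PCA.

# Per-locus Weir-Cockerham variance components a, b, c for the populations
# given by `groups` (a factor over the columns of the dosage matrix).
# Returns a data.frame with one row per usable locus. Loci where any
# population has no called genotypes, or where nc = 0, are dropped.
wc_abc <- function(dos, groups) {
  groups <- as.factor(groups)
  pops <- levels(groups)
  r <- length(pops)
  S <- nrow(dos)
  n_m <- p_m <- h_m <- matrix(0, S, r)
  for (j in seq_len(r)) {
    sub <- dos[, groups == pops[j], drop = FALSE]
    n_m[, j] <- rowSums(!is.na(sub))
    p_m[, j] <- rowSums(sub, na.rm = TRUE) / (2 * n_m[, j])
    h_m[, j] <- rowSums(sub == 1L, na.rm = TRUE) / n_m[, j]
  }
  ok <- rowSums(n_m >= 1) == r & rowSums(n_m) > r  # nbar > 1
  n_m <- n_m[ok, , drop = FALSE]
  p_m <- p_m[ok, , drop = FALSE]
  h_m <- h_m[ok, , drop = FALSE]

  nbar <- rowMeans(n_m)
  nsum <- r * nbar
  nc <- (nsum - rowSums(n_m^2) / nsum) / (r - 1)
  pbar <- rowSums(n_m * p_m) / nsum
  s2 <- rowSums(n_m * (p_m - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_m * h_m) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a) & is.finite(b) & is.finite(cc) & nc > 0
  data.frame(locus = which(ok)[keep], a = a[keep], b = b[keep], c = cc[keep],
             pbar = pbar[keep], n_total = 2 * rowSums(n_m)[keep])
}

# multi-locus ratio-of-sums theta
wc_theta <- function(comp) {
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) return(NA_real_)
  sum(comp$a) / denom
}

#' Pairwise Weir-Cockerham Fst with permutation tests
#'
#' Multi-locus theta (ratio of summed variance components) for every
#' population pair, with p-values from permuting individuals between the
#' two populations: `p = (#\{theta_perm >= theta_obs\} + 1) / (n_perm + 1)`.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pm a `PopulationMap`; every population needs >= 2 individuals.
#' @param n_perm permutations per pair (0 skips testing).
#' @param seed integer seed for the permutations.
#' @return an `FstMatrix`: list with symmetric `fst` and `p_value`
#'   matrices.
#' @export
pairwise_fst <- function(gm, pm, n_perm = 1000L, seed = 1L) {
  validate_popmap(pm, gm)
  pops <- unique(pm$population)
  assert_that(length(pops) >= 2, "need at least two populations")
  sizes <- vapply(pops, function(p) length(pop_columns(gm, pm, p)), integer(1))
  small <- pops[sizes < 2]
  if (length(small) > 0)
    stop_fw("population(s) with fewer than 2 individuals: %s",
            paste(small, collapse = ", "))

  K <- length(pops)
  fst <- matrix(0, K, K, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ci <- pop_columns(gm, pm, pops[i]); cj <- pop_columns(gm, pm, pops[j])
    dos <- gm$geno[, c(ci, cj), drop = FALSE]
    lab <- rep(c("A", "B"), c(length(ci), length(cj)))
    obs <- wc_theta(wc_abc(dos, lab))
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      set.seed(as.integer(derive_seed(seed, i * K + j)))
      hits <- 0L
      for (b in seq_len(n_perm)) {
        tp <- wc_theta(wc_abc(dos, sample(lab)))
        if (!is.na(tp) && tp >= obs) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(fst = fst, p_value = pv, n_perm = n_perm),
            class = "FstMatrix")
}

#' @export
print.FstMatrix <- function(x, ...) {
  cat("Pairwise Weir-Cockerham Fst:\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Per-population nucleotide diversity
#'
#' Unbiased per-site diversity `2*p*q*n/(n-1)` summed over sites and
#' divided by the total sequence length surveyed. Missing genotypes are
#' handled per site (complete allele copies only); sites with fewer than
#' two called copies contribute nothing.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pm a `PopulationMap`.
#' @param region_length length in bp of each region present in `gm`
#'   (single number recycled, or named by region id). When `NULL`, Pi is
#'   reported per variant site instead of per bp.
#' @return named numeric vector of Pi per population.
#' @export
nucleotide_diversity <- function(gm, pm, region_length = NULL) {
  validate_popmap(pm, gm)
  pops <- unique(pm$population)
  regs <- unique(gm$region_id)
  if (is.null(region_length)) {
    total_len <- n_sites(gm)
  } else if (is.null(names(region_length))) {
    total_len <- length(regs) * region_length[1]
  } else {
    missing_reg <- setdiff(regs, names(region_length))
    assert_that(length(missing_reg) == 0, "no length supplied for region(s): %s",
                paste(head(missing_reg, 5), collapse = ", "))
    total_len <- sum(region_length[regs])
  }
  out <- vapply(pops, function(p) {
    sub <- gm$geno[, pop_columns(gm, pm, p), drop = FALSE]
    n <- 2 * rowSums(!is.na(sub))
    d <- rowSums(sub, na.rm = TRUE)
    ok <- n >= 2
    p_hat <- d[ok] / n[ok]
    sum(2 * p_hat * (1 - p_hat) * n[ok] / (n[ok] - 1)) / total_len
  }, numeric(1))
  setNames(out, pops)
}

#' PCA of genotype dosages
#'
#' Eigen-decomposition of the covariance of mean-imputed, centered dosages
#' (individuals as observations). Missing genotypes are imputed with the
#' per-site mean. Component signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param gm a `GenotypeMatrix` with >= 2 individuals and >= 1 variant.
#' @param scale. divide each site by its standard deviation (default
#'   `FALSE`: raw dosage covariance).
#' @return list with `scores` (individuals x components), `explained`
#'   (variance fractions, summing to at most 1) and `sdev`.
#' @export
pca_coordinates <- function(gm, scale. = FALSE) {
  assert_that(n_individuals(gm) >= 2 && n_sites(gm) >= 1,
              "PCA needs at least 2 individuals and 1 variant")
  X <- t(gm$geno)
  mns <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mns[j]
  if (scale.) {
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  for (k in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[top, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  rownames(pc$x) <- gm$individual_ids
  list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}
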