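# Hierarchical (three-level) analysis of molecular variance.
#
# Individuals nested in populations nested in groups. Distances between
# individuals are allele-mismatch counts over their genotypes (the L1
# distance between dosage vectors); with missing data the count is
# rescaled to the full locus set, which is what `dist(method =
# "manhattan")` does natively. These mismatch counts play the role of
# squared distances in the sums-of-squares decomposition.

amova_ssd <- function(D2, blocks) {
  # sum over blocks of (sum_{i<j in block} d2_ij) / n_block
  f <- as.factor(blocks)
  B <- rowsum(t(rowsum(D2, f)), f)       # block-sum matrix (symmetric)
  sum(diag(as.matrix(B)) / (2 * tabulate(f)))
}

amova_components <- function(D2, pop_of_ind, group_of_pop) {
  pops <- names(group_of_pop)
  grp_of_ind <- unname(group_of_pop[pop_of_ind])
  N <- length(pop_of_ind)
  n_p <- table(factor(pop_of_ind, levels = pops))
  P <- sum(n_p > 0)
  groups <- unique(unname(group_of_pop))
  G <- length(groups)
  n_g <- vapply(groups, function(g) sum(n_p[group_of_pop[pops] == g]),
                numeric(1))

  ssd_total <- amova_ssd(D2, rep("all", N))
  ssd_wg <- amova_ssd(D2, grp_of_ind)
  ssd_wp <- amova_ssd(D2, pop_of_ind)
  ss_ag <- ssd_total - ssd_wg
  ss_ap <- ssd_wg - ssd_wp

  sum_np2_by_g <- vapply(groups, function(g) {
    idx <- group_of_pop[pops] == g
    sum(n_p[idx]^2) / sum(n_p[idx])
  }, numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / (P - G)
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)

  sigma_c <- ssd_wp / (N - P)
  sigma_b <- (ss_ap / (P - G) - sigma_c) / n1
  sigma_a <- (ss_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within_pops = ssd_wp),
       df = c(G - 1, P - G, N - P),
       sigma = c(among_groups = sigma_a, among_pops = sigma_b,
                 within_pops = sigma_c))
}

#' Percentage decomposition of AMOVA variance components
#'
#' Negative components are clamped to zero for the percentage display
#' (Arlequin-compatible); the raw components are reported as computed.
#'
#' @param components numeric vector of the three variance components
#'   (among groups, among populations within groups, within populations).
#' @return percentages summing to 100.
#' @export
amova_percentages <- function(components) {
  cl <- pmax(components, 0)
  100 * cl / sum(cl)
}

#' Three-level AMOVA with permutation tests
#'
#' Partitions genetic variance among groups, among populations within
#' groups, and within populations, with permutation p-values: among-group
#' significance permutes whole populations among groups; among-population
#' significance permutes individuals among populations within their group;
#' the within-population component is tested by permuting individuals
#' among all populations (lower tail: structure shrinks the within
#' component).
#'
#' @param gm a `GenotypeMatrix`.
#' @param pm a `PopulationMap`.
#' @param grouping named character vector mapping population label to
#'   group label.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return an `AmovaResult`: sums of squares, degrees of freedom, variance
#'   components, percentages and p-values.
#' @export
amova <- function(gm, pm, grouping, n_perm = 10000L, seed = 1L) {
  validate_popmap(pm, gm)
  pops <- unique(pm$population)
  missing_pop <- setdiff(pops, names(grouping))
  assert_that(length(missing_pop) == 0, "no group assigned to population(s): %s",
              paste(missing_pop, collapse = ", "))
  grouping <- grouping[pops]
  assert_that(length(unique(grouping)) >= 2, "need at least two groups")
  assert_that(length(pops) > length(unique(grouping)),
              "need more populations than groups for a three-level AMOVA")

  ord <- match(gm$individual_ids, pm$individual)
  pop_of_ind <- pm$population[ord]
  D2 <- as.matrix(dist(t(gm$geno), method = "manhattan"))
  D2[is.na(D2)] <- 0  # pairs with no shared loci carry no information

  obs <- amova_components(D2, pop_of_ind, grouping)
  pcts <- amova_percentages(obs$sigma)

  p <- c(NA_real_, NA_real_, NA_real_)
  if (n_perm > 0) {
    set.seed(as.integer(derive_seed(seed, 97)))
    hits <- c(0L, 0L, 0L)
    groups_of_pops <- grouping
    for (b in seq_len(n_perm)) {
      # (a) permute populations among groups
      ga <- setNames(sample(unname(groups_of_pops)), names(groups_of_pops))
      sa <- amova_components(D2, pop_of_ind, ga)$sigma[1]
      if (sa >= obs$sigma[1]) hits[1] <- hits[1] + 1L
      # (b) permute individuals among populations within groups
      pb <- pop_of_ind
      for (g in unique(unname(grouping))) {
        in_g <- grouping[pop_of_ind] == g
        pb[in_g] <- sample(pop_of_ind[in_g])
      }
      sb <- amova_components(D2, pb, grouping)$sigma[2]
      if (sb >= obs$sigma[2]) hits[2] <- hits[2] + 1L
      # (c) permute individuals among all populations
      sc <- amova_components(D2, sample(pop_of_ind), grouping)$sigma[3]
      if (sc <= obs$sigma[3]) hits[3] <- hits[3] + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }

  structure(list(ss = obs$ss, df = obs$df, sigma = obs$sigma,
                 percentage = pcts, p_value = setNames(p, names(obs$sigma)),
                 n_perm = n_perm),
            class = "AmovaResult")
}

#' @export
print.AmovaResult <- function(x, ...) {
  tab <- data.frame(df = x$df, `Sum of squares` = round(x$ss, 2),
                    `Variance component` = round(x$sigma, 4),
                    `Percentage` = round(x$percentage, 2),
                    `P` = signif(x$p_value, 3), check.names = FALSE)
  rownames(tab) <- c("Among groups", "Among populations within groups",
                     "Within populations")
  print(tab)
  invisible(x)
}
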