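# popgen_stats: diversity, Weir-Cockerham Fst, AMOVA, PCA

test_that("pairwise Fst: fixed differences give exactly 1; duplicated population gives ~0", {
  geno <- cbind(matrix(0L, 20, 4), matrix(2L, 20, 4))
  gm <- toy_gm(geno)
  pm <- population_map(paste0("ind", 1:8), rep(c("A", "B"), each = 4))
  f <- pairwise_fst(gm, pm, n_perm = 199, seed = 1)
  expect_identical(f$fst[1, 2], 1)
  # only label permutations that re-create the two pure groups can tie the
  # observed value, so p is small but not 1/(n+1): P(pure split) = 2/C(8,4)
  expect_lt(f$p_value[1, 2], 0.06)

  # one population duplicated under two labels: theta is zero or slightly
  # negative (the estimator's finite-sample bias), never positive signal
  set.seed(2)
  base <- matrix(sample(0:2, 30 * 6, replace = TRUE), 30, 6)
  gm2 <- toy_gm(cbind(base, base))
  pm2 <- population_map(paste0("ind", 1:12), rep(c("X", "Y"), each = 6))
  f2 <- pairwise_fst(gm2, pm2, n_perm = 99, seed = 3)
  expect_lt(f2$fst[1, 2], 0.02)
  expect_gt(f2$fst[1, 2], -0.3)
  expect_gt(f2$p_value[1, 2], 0.05)
})

test_that("multi-locus theta equals the independent textbook oracle to 1e-10", {
  set.seed(4)
  for (rep in 1:5) {
    dos <- matrix(sample(c(0L, 1L, 2L, NA), 2 * 8, replace = TRUE,
                         prob = c(4, 3, 3, 1)), 2, 8)
    if (all(is.na(dos)) || sd(dos, na.rm = TRUE) == 0) next
    pops <- rep(c("A", "B"), each = 4)
    ours <- fwinvade:::wc_theta(fwinvade:::wc_abc(dos, pops))
    oracle <- wc_oracle(dos, pops)
    if (is.na(ours) || is.na(oracle)) {
      expect_equal(is.na(ours), is.na(oracle))
    } else {
      expect_equal(ours, oracle, tolerance = 1e-10)
    }
  }
})

test_that("Fst is invariant to individual order and allele relabeling", {
  set.seed(5)
  dos <- matrix(sample(0:2, 40 * 10, replace = TRUE), 40, 10)
  pops <- rep(c("A", "B"), each = 5)
  t0 <- fwinvade:::wc_theta(fwinvade:::wc_abc(dos, pops))
  perm <- sample(10)
  t1 <- fwinvade:::wc_theta(fwinvade:::wc_abc(dos[, perm], pops[perm]))
  t2 <- fwinvade:::wc_theta(fwinvade:::wc_abc(2L - dos, pops))
  expect_equal(t0, t1, tolerance = 1e-12)
  expect_equal(t0, t2, tolerance = 1e-12)
})

test_that("pairwise_fst validates population sizes", {
  gm <- toy_gm(matrix(0:2, 3, 3))
  pm <- population_map(paste0("ind", 1:3), c("A", "A", "B"))
  expect_error(pairwise_fst(gm, pm), "fewer than 2")
})

test_that("nucleotide diversity equals the mean pairwise-difference oracle", {
  set.seed(6)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), 10 * 6, replace = TRUE,
                        prob = c(5, 3, 2, 1)), 10, 6)
  gm <- toy_gm(geno, region = rep("r1", 10))
  pm <- population_map(paste0("ind", 1:6), rep("P", 6))
  ours <- nucleotide_diversity(gm, pm, region_length = 10)
  expect_equal(unname(ours["P"]), pi_oracle(geno, 10), tolerance = 1e-12)
  # identical individuals -> zero
  gm0 <- toy_gm(matrix(2L, 5, 6), region = rep("r1", 5))
  expect_equal(unname(nucleotide_diversity(gm0, pm, 10)["P"]), 0)
})

test_that("simulated panmictic diversity approaches 2 N mu (haploid N)", {
  N <- 2000; mu <- 2.5e-7
  m <- demographic_model("p1", N, mu = mu, region_length = 214)
  gm <- simulate_dataset(m, c(p1 = 20), seed = 8, n_regions = 600)
  pm <- popmap_from_simulated(gm)
  pi <- nucleotide_diversity(gm, pm, region_length = 214)
  # total length includes only variable regions here; rescale
  pi_adj <- unname(pi["p1"]) * length(unique(gm$region_id)) / 600
  expect_lt(abs(pi_adj - 2 * N * mu) / (2 * N * mu), 0.15)
})

test_that("AMOVA reproduces printed percentage arithmetic and clamps negatives for display", {
  expect_equal(amova_percentages(c(84.26, 6.21, 75.78)),
               c(50.68, 3.74, 45.58), tolerance = 5e-4)
  expect_equal(sum(amova_percentages(c(-0.3, 2, 8))), 100)
})

test_that("AMOVA: panmictic grouping shows ~0% among groups; fixed groups ~100%", {
  m <- demographic_model("p1", 20000, mu = 2.5e-7, region_length = 214)
  gm <- simulate_dataset(m, c(p1 = 48), seed = 7, n_regions = 200)
  pm <- population_map(gm$individual_ids, rep(c("a", "b", "c", "d"), each = 6))
  am <- amova(gm, pm, c(a = "g1", b = "g1", c = "g2", d = "g2"),
              n_perm = 99, seed = 1)
  expect_lt(am$percentage[1], 2)
  expect_gt(am$p_value[1], 0.05)
  expect_lt(abs(sum(am$percentage) - 100), 0.01)

  geno <- cbind(matrix(0L, 20, 4), matrix(2L, 20, 4))
  gm2 <- toy_gm(geno)
  pm2 <- population_map(paste0("ind", 1:8), rep(c("p1", "p2", "p3", "p4"), each = 2))
  am2 <- amova(gm2, pm2, c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
               n_perm = 99, seed = 1)
  expect_gt(am2$percentage[1], 98)
  # with only four populations there are just three distinct group
  # partitions, so the among-group permutation p cannot fall below ~1/3
  expect_lte(am2$p_value[1], 0.5)
})

test_that("PCA matches a brute-force eigen-decomposition and separates clusters", {
  set.seed(10)
  geno <- matrix(sample(0:2, 30 * 8, replace = TRUE), 30, 8)
  gm <- toy_gm(geno)
  pc <- pca_coordinates(gm)
  # oracle: eigen of covariance of centered dosages (individuals x sites)
  X <- scale(t(geno), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1))
  scores_oracle <- X %*% ev$vectors
  for (k in 1:3) {
    expect_lt(min(sum((pc$scores[, k] - scores_oracle[, k])^2),
                  sum((pc$scores[, k] + scores_oracle[, k])^2)), 1e-8)
  }
  expect_lte(sum(pc$explained), 1 + 1e-12)
  expect_equal(pc$explained[1:3],
               ev$values[1:3] / sum(pmax(ev$values, 0)), tolerance = 1e-8)

  # two clusters of identical individuals: pc1 separates them exactly
  geno2 <- cbind(matrix(0L, 15, 4), matrix(2L, 15, 4))
  pc2 <- pca_coordinates(toy_gm(geno2))
  expect_equal(sd(pc2$scores[1:4, 1]), 0)
  expect_equal(sd(pc2$scores[5:8, 1]), 0)
  expect_gt(abs(mean(pc2$scores[1:4, 1]) - mean(pc2$scores[5:8, 1])), 1)
  # missing data: mean imputation keeps PCA finite
  geno3 <- geno; geno3[1, 1] <- NA
  expect_true(all(is.finite(pca_coordinates(toy_gm(geno3))$scores)))
})

test_that("permutation p-values stay in [1/(n+1), 1]", {
  set.seed(11)
  geno <- matrix(sample(0:2, 40 * 8, replace = TRUE), 40, 8)
  gm <- toy_gm(geno)
  pm <- population_map(paste0("ind", 1:8), rep(c("A", "B"), each = 4))
  f <- pairwise_fst(gm, pm, n_perm = 49, seed = 5)
  expect_gte(f$p_value[1, 2], 1 / 50)
  expect_lte(f$p_value[1, 2], 1)
})
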