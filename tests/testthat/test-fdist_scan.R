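# fdist_scan: null tuning, conditional p-values, classification

test_that("migration tuning hits the target trimmed-mean Fst within 0.002", {
  null <- simulate_fdist_null(0.05, c(20, 20), n_demes = 50, n_sims = 6000,
                              seed = 2, n_tune = 2500)
  expect_lt(abs(attr(null, "achieved_mean_fst") - 0.05), 0.002 + 1e-9)
  expect_true(all(null$He > 0 & null$He <= 1))
  # near-panmixia limit: tiny target -> Fst distribution hugs zero
  low <- simulate_fdist_null(0.004, c(20, 20), n_demes = 20, n_sims = 2000,
                             seed = 3, N = 500, n_tune = 1500, tol = 0.002)
  expect_lt(median(low$Fst), 0.01)
  # determinism
  n2 <- simulate_fdist_null(0.05, c(20, 20), n_demes = 50, n_sims = 6000,
                            seed = 2, n_tune = 2500)
  expect_identical(null$Fst, n2$Fst)
  expect_error(simulate_fdist_null(0, c(20, 20)), "between 0 and 1")
  expect_error(simulate_fdist_null(0.05, c(21, 20)), "even")
})

test_that("p-value extremes and midpoints behave as ranks", {
  null <- data.frame(He = runif(2000, 0.1, 0.5), Fst = runif(2000, 0, 0.2))
  w <- ceiling(0.1 * 2000)
  obs_hi <- data.frame(locus_id = "hi", He = 0.3, Fst = 0.9)
  p <- locus_pvalues(obs_hi, null)
  expect_equal(p$p_value, 1 / (w + 1))
  # observed at the conditional median -> p around 0.5
  obs_med <- data.frame(locus_id = "med", He = 0.3, Fst = 0.1)
  pm <- locus_pvalues(obs_med, null)
  expect_lt(abs(pm$p_value - 0.5), 0.05)
  expect_error(locus_pvalues(obs_hi, null[1:10, ]), "1000")
})

test_that("classification thresholds, monotonicity, and the empty case", {
  rec <- data.frame(locus_id = c("a", "b", "c"),
                    He = c(0.2, 0.3, 0.4), Fst = c(0.9, 0.05, 0.001),
                    p_value = c(0.01, 0.5, 0.999),
                    p_lower = c(0.999, 0.5, 0.01),
                    classification = NA_character_)
  out <- classify_outliers(rec)
  expect_equal(out$classification, c("disruptive", "neutral", "balancing"))
  expect_equal(unname(attr(out, "counts")), c(1L, 1L, 1L))
  # stricter thresholds flag no more loci
  strict <- classify_outliers(rec, upper_q = 0.999, lower_q = 0.001)
  expect_lte(sum(strict$classification != "neutral"),
             sum(out$classification != "neutral"))
  empty <- classify_outliers(rec[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "counts")), c(0L, 0L, 0L))
})

test_that("fdist per-locus Fst is bit-identical to the pairwise Weir-Cockerham estimator", {
  set.seed(12)
  geno <- matrix(sample(0:2, 60 * 12, replace = TRUE), 60, 12)
  gm <- toy_gm(geno)
  pm <- population_map(paste0("ind", 1:12), rep(c("A", "B"), each = 6))
  obs <- observed_locus_stats(gm, pm, c("A", "B"))
  # multi-locus theta from the same components must equal pairwise_fst
  comp <- fwinvade:::wc_abc(geno, rep(c("A", "B"), each = 6))
  expect_identical(fwinvade:::wc_theta(comp),
                   pairwise_fst(gm, pm, n_perm = 0)$fst[1, 2])
  # per-locus values recompute from the identical a, b, c components
  expect_identical(obs$Fst, (comp$a / (comp$a + comp$b + comp$c))[
    !is.na(comp$a / (comp$a + comp$b + comp$c))])
})

test_that("self-null false-positive rate is nominal at desk scale", {
  null <- simulate_fdist_null(0.08, c(26, 36), n_demes = 50, n_sims = 8000,
                              seed = 21, n_tune = 2500)
  obs_st <- simulate_fdist_null(0.08, c(26, 36), n_demes = 50, n_sims = 1500,
                                seed = 77, n_tune = 2500)
  obs <- data.frame(locus_id = paste0("L", seq_len(nrow(obs_st))),
                    He = obs_st$He, Fst = obs_st$Fst)
  rec <- classify_outliers(locus_pvalues(obs, null))
  fpr <- mean(rec$classification == "disruptive")
  expect_gt(fpr, 0.02)
  expect_lt(fpr, 0.09)
})
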