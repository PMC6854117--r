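# abc_inference: reference tables, PLS, rejection, adjustment, HPD

test_that("reference table is reproducible; point-mass prior gives constant rows", {
  builder <- preset_builder("model3", pops = c("CH", "SH"), n_regions = 20)
  priors <- list(T3 = prior_loguniform(500, 5000))
  t1 <- build_reference_table(builder, priors, n_sims = 30,
                              samples = c(CH = 8, SH = 8), seed = 5,
                              n_regions = 20)
  t2 <- build_reference_table(builder, priors, n_sims = 30,
                              samples = c(CH = 8, SH = 8), seed = 5,
                              n_regions = 20)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$summaries, t2$summaries)
  expect_equal(nrow(t1$summaries), 30)

  pt <- build_reference_table(builder, list(T3 = prior_uniform(1000, 1000)),
                              n_sims = 10, samples = c(CH = 8, SH = 8),
                              seed = 6, n_regions = 20)
  expect_true(all(pt$params[, "T3"] == 1000))
  expect_gt(sd(pt$summaries), 0)  # Monte-Carlo noise only
})

test_that("summaries separate small from large divergence times", {
  builder <- preset_builder("model3", pops = c("CH", "SH"), n_regions = 40)
  mean_private <- function(T3) {
    m <- builder(c(T3 = T3))
    sim <- fwinvade:::simulate_site_counts(m, c(CH = 10, SH = 10), 40,
                                           seed = 1234 + T3)
    sfs <- fwinvade:::tally_joint_sfs(sim$counts, sim$samples, 1:2,
                                      m$pop_names, folded = TRUE)
    cnt <- sfs$counts
    sum(cnt[1, -1], cnt[-1, 1], cnt[11, -11], cnt[-11, 11]) / sum(cnt)
  }
  mp <- vapply(c(300, 3000, 30000), mean_private, numeric(1))
  expect_true(all(diff(mp) > 0))
})

test_that("PLS components are centered and track the parameter in a linear world", {
  set.seed(7)
  n <- 300
  theta <- exp(runif(n, log(10), log(1000)))
  S <- cbind(log(theta) * 2 + rnorm(n, 0, 0.1),
             -log(theta) + rnorm(n, 0, 0.1),
             rnorm(n), rnorm(n))
  tab <- structure(list(params = matrix(theta, ncol = 1,
                                        dimnames = list(NULL, "theta")),
                        summaries = S, seed = 1, model_id = "toy"),
                   class = "ReferenceTable")
  red <- pls_reduce(tab, colMeans(S), n_components = 2)
  expect_lt(max(abs(colMeans(red$reduced))), 1e-8)
  expect_gt(abs(cor(red$reduced[, 1], log(theta))), 0.9)

  # one component on a 5-row toy table equals hand linear algebra:
  # w = normalized X_std' y_std, scores proportional to X_std w
  X5 <- cbind(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  y5 <- c(10, 20, 30, 40, 50)
  tab5 <- structure(list(params = matrix(y5, ncol = 1,
                                         dimnames = list(NULL, "p")),
                         summaries = X5, seed = 1, model_id = "toy"),
                    class = "ReferenceTable")
  red5 <- pls_reduce(tab5, colMeans(X5), n_components = 1)
  Xs <- scale(X5)
  ys <- scale(log(y5))
  w <- drop(crossprod(Xs, ys)); w <- w / sqrt(sum(w^2))
  t_hand <- drop(Xs %*% w)
  expect_equal(abs(cor(red5$reduced[, 1], t_hand)), 1, tolerance = 1e-8)
  expect_error(pls_reduce(tab5, colMeans(X5), n_components = 10),
               "n_components")
})

test_that("rejection ABC: exact match accepted at distance zero; full acceptance returns the prior", {
  set.seed(8)
  red <- matrix(rnorm(200), 50, 4)
  params <- matrix(exp(rnorm(50)), ncol = 1, dimnames = list(NULL, "T"))
  post <- abc_rejection(red, red[17, ], params, n_accept = 1)
  expect_equal(post$accepted_index, 17L)
  expect_equal(post$distances, 0)
  all_in <- abc_rejection(red, red[1, ], params, n_accept = 50)
  expect_setequal(all_in$accepted_index, 1:50)
  expect_equal(sort(all_in$draws[, 1]), sort(params[, 1]))
  expect_error(abc_rejection(red, red[1, ], params, n_accept = 51),
               "n_accept")
})

test_that("local-linear adjustment shrinks variance under a linear map and is deterministic", {
  shrink <- function(seed) {
    set.seed(seed)
    n <- 400
    theta <- exp(rnorm(n, 0, 0.5))
    red <- cbind(log(theta) + rnorm(n, 0, 0.2), rnorm(n))
    obs <- c(mean(red[, 1]), 0)
    params <- matrix(theta, ncol = 1, dimnames = list(NULL, "T"))
    post <- abc_rejection(red, obs, params, n_accept = 100)
    adj <- regression_adjust(post, "loclinear")
    c(var(log(adj$draws[, 1])), var(log(post$draws[, 1])))
  }
  wins <- vapply(1:20, function(s) { v <- shrink(s); v[1] < v[2] }, logical(1))
  expect_gte(sum(wins), 18)

  # no-signal case: adjustment is a small perturbation of the rejection draws
  set.seed(30)
  red0 <- matrix(rnorm(400), 200, 2)
  params0 <- matrix(exp(rnorm(200)), ncol = 1, dimnames = list(NULL, "T"))
  p0 <- abc_rejection(red0, c(0, 0), params0, n_accept = 80)
  a0 <- regression_adjust(p0, "loclinear")
  expect_lt(abs(mean(log(a0$draws)) - mean(log(p0$draws))), 0.3)
  a0b <- regression_adjust(p0, "loclinear")
  expect_identical(a0$draws, a0b$draws)
})

test_that("neural-network adjustment runs and is seed-deterministic", {
  set.seed(31)
  n <- 120
  theta <- exp(rnorm(n, 0, 0.5))
  red <- cbind(log(theta) + rnorm(n, 0, 0.3), rnorm(n))
  params <- matrix(theta, ncol = 1, dimnames = list(NULL, "T"))
  post <- abc_rejection(red, c(mean(red[, 1]), 0), params, n_accept = 60)
  n1 <- regression_adjust(post, "neuralnet", seed = 4)
  n2 <- regression_adjust(post, "neuralnet", seed = 4)
  expect_identical(n1$draws, n2$draws)
  expect_true(all(is.finite(n1$draws)))
})

test_that("HPD intervals: uniform span, normal quantiles, degenerate draws, monotone mass", {
  h <- hpd_interval(1:100, mass = 0.95)
  expect_equal(h[2] - h[1], 94)  # spans 95 consecutive values
  set.seed(9)
  x <- rnorm(10000)
  hn <- hpd_interval(x, mass = 0.95)
  expect_lt(abs(hn[1] + 1.96), 0.1)
  expect_lt(abs(hn[2] - 1.96), 0.1)
  expect_equal(hpd_interval(rep(3.3, 50)), c(3.3, 3.3))
  widths <- vapply(c(0.5, 0.8, 0.95, 0.99),
                   function(m) diff(hpd_interval(x, mass = m)), numeric(1))
  expect_true(all(diff(widths) >= 0))
  # weighted: weights concentrate the interval
  hw <- hpd_interval(c(0, 1, 2, 3, 100), weights = c(1, 1, 1, 1, 1e-9),
                     mass = 0.8)
  expect_lte(hw[2], 3)
})
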