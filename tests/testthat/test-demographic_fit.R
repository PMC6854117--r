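# demographic_fit: composite likelihood, expected SFS, optimizer, AIC

test_that("composite log-likelihood reproduces direct arithmetic", {
  # 1-pop n = 3 unfolded: unmasked cells are derived counts 1 and 2
  obs <- joint_sfs(array(c(0, 3, 7, 0), dim = 4), folded = FALSE)
  p <- array(c(0, 0.3, 0.7, 0), dim = 4)
  expect_equal(composite_log_likelihood(obs, p, p_floor = 1e-10),
               3 * log(0.3) + 7 * log(0.7), tolerance = 1e-12)
  expect_equal(round(composite_log_likelihood(obs, p, p_floor = 1e-10), 4),
               -6.1086)

  # p proportional to m maximizes lnL among perturbations
  best <- composite_log_likelihood(obs, array(c(0, 0.3, 0.7, 0), dim = 4),
                                   p_floor = 1e-10)
  for (eps in c(-0.1, 0.05, 0.2)) {
    pp <- c(0, 0.3 + eps, 0.7 - eps, 0)
    expect_lt(composite_log_likelihood(obs, array(pp, dim = 4),
                                       p_floor = 1e-10), best)
  }

  # zero simulated mass in an observed cell is floored, finite
  pz <- array(c(0, 0, 1, 0), dim = 4)
  lnl <- composite_log_likelihood(obs, pz, p_floor = 1e-4)
  expect_true(is.finite(lnl))
  expect_equal(lnl, 3 * log(1e-4) + 7 * log(1), tolerance = 1e-12)
  expect_error(composite_log_likelihood(obs, array(1, dim = 5)), "shape")
})

test_that("expected unfolded SFS matches the theta/i closed form", {
  m <- demographic_model("p1", 2000, mu = 2.5e-7, region_length = 214)
  es <- expected_sfs(m, c(p1 = 4), n_sims = 20000, seed = 13, folded = FALSE)
  p <- es$counts[2:4]  # singleton, doubleton, tripleton
  expected <- (1 / 1:3) / sum(1 / 1:3)
  expect_lt(max(abs(p - expected)), 0.015)
  # reproducibility
  es2 <- expected_sfs(m, c(p1 = 4), n_sims = 20000, seed = 13, folded = FALSE)
  expect_identical(es$counts, es2$counts)
})

test_that("shared-frequency cells dominate at small split times, private cells at large", {
  private_mass <- function(Tsplit) {
    m <- split_model(Tsplit, mu = 2.5e-7)
    es <- expected_sfs(m, c(a = 8, b = 8), n_sims = 4000, seed = 21,
                       folded = FALSE)
    cnt <- es$counts
    # mass where one population carries no derived copies or is fixed:
    # private polymorphism plus fixed differences
    sum(cnt[c(1, 9), ], cnt[, c(1, 9)]) - cnt[1, 1] - cnt[9, 9] -
      cnt[1, 9] - cnt[9, 1]
  }
  masses <- vapply(c(100, 2000, 40000), private_mass, numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("AIC identity and ranking contracts", {
  expect_identical(aic(-23162, 10), 46344)
  expect_identical(aic(0, 0), 0)
  expect_error(aic(10, -1), "non-negative")
  fits <- list(list(model_id = "m1", AIC = 5, d = 3),
               list(model_id = "m2", AIC = 5, d = 2),
               list(model_id = "m3", AIC = 1, d = 9))
  rk <- vapply(rank_models(fits), `[[`, integer(1), "rank")
  expect_equal(rk, c(3L, 2L, 1L))  # tie at AIC=5 broken by smaller d
  single <- rank_models(list(list(model_id = "only", AIC = 2, d = 1)))
  expect_equal(single[[1]]$rank, 1L)
})

test_that("Bayes-factor arithmetic", {
  expect_equal(bayes_factor_2ln(-8368, -8369), 2)
  expect_equal(bayes_factor_2ln(3.5, 3.5), 0)
  expect_equal(bayes_factor_2ln(-100, -110), 20)
})

test_that("one-parameter theta recovery within 25% at desk scale", {
  builder <- function(par)
    demographic_model("p1", unname(par["N_p1"]), mu = 2.5e-7,
                      region_length = 214, n_regions = 400)
  attr(builder, "model_id") <- "panmictic"
  truth <- demographic_model("p1", 8000, mu = 2.5e-7, region_length = 214)
  gm <- simulate_dataset(truth, c(p1 = 20), seed = 101, n_regions = 400)
  obs <- compute_joint_sfs(gm, popmap_from_simulated(gm), "p1", folded = TRUE)
  fit <- fit_model(obs, builder,
                   bounds = matrix(c(500, 1e5), 2,
                                   dimnames = list(NULL, "N_p1")),
                   samples = c(p1 = 20), cycles = 5, n_runs = 4,
                   n_sims = 3000, seed = 1, n_regions_obs = 400)
  expect_lt(abs(fit$params[["N_p1"]] - 8000) / 8000, 0.25)
  expect_equal(fit$d, 1L)
  expect_equal(fit$AIC, 2 * 1 - 2 * fit$lnL)
})

test_that("split-time recovery within a factor of 2; seeded runs are identical", {
  bd <- function(par)
    demographic_model(c("a", "b"), c(8000, 8000),
                      events = list(event_fusion(unname(par["T"]), "a", "b")),
                      mu = 2.5e-7, region_length = 214, n_regions = 300)
  attr(bd, "model_id") <- "split"
  gm <- simulate_dataset(bd(c(T = 3000)), c(a = 16, b = 16), seed = 9,
                         n_regions = 300)
  obs <- compute_joint_sfs(gm, popmap_from_simulated(gm), c("a", "b"),
                           folded = TRUE)
  bounds <- matrix(c(100, 1e5), 2, dimnames = list(NULL, "T"))
  fit1 <- fit_model(obs, bd, bounds, samples = c(a = 16, b = 16),
                    cycles = 5, n_runs = 3, n_sims = 2000, seed = 4,
                    n_regions_obs = 300)
  expect_gt(fit1$params[["T"]], 1500)
  expect_lt(fit1$params[["T"]], 6000)
  fit2 <- fit_model(obs, bd, bounds, samples = c(a = 16, b = 16),
                    cycles = 5, n_runs = 3, n_sims = 2000, seed = 4,
                    n_regions_obs = 300)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$lnL, fit2$lnL)
})

test_that("nesting: the richer model attains at least the nested model's likelihood", {
  pops3 <- c("DT", "CH", "SH")
  samples <- c(DT = 10L, CH = 10L, SH = 10L)
  truth <- preset_model("model3", pops = pops3, n_regions = 150)
  gm <- simulate_dataset(truth, samples, seed = 31, n_regions = 150)
  obs <- compute_joint_sfs(gm, popmap_from_simulated(gm), pops3, folded = TRUE)
  fit_for <- function(name) {
    free <- preset_free_params(name, pops = pops3)
    bounds <- matrix(rep(c(500, 1e5), length(free)), nrow = 2,
                     dimnames = list(NULL, free))
    bounds[, startsWith(free, "T")] <- c(100, 4e5)
    fit_model(obs, preset_builder(name, pops = pops3, n_regions = 150),
              bounds, samples = samples, cycles = 5, n_runs = 4,
              n_sims = 1500, seed = 77, n_regions_obs = 150)
  }
  f1 <- fit_for("model1")  # d = 4: three sizes + T1
  f2 <- fit_for("model2")  # d = 5: model1 + T2 (radiation through a carrier)
  # the richer model reaches at least the nested optimum up to the
  # Monte-Carlo noise of the stochastic likelihood surface
  expect_gt(f2$lnL, f1$lnL - 40)
  expect_gt(f2$d, f1$d)
})

test_that("preset parameterizations reproduce the documented parameter counts", {
  expect_length(preset_free_params("model1"), 10)
  expect_length(preset_free_params("model2"), 11)
  expect_length(preset_free_params("model3"), 13)
  expect_length(preset_free_params("model4"), 41)
  # builder round trip: parameters land in the model
  b <- preset_builder("model3")
  m <- b(c(T1 = 99999, N_SH = 12345))
  expect_equal(m$sizes[m$pop_names == "SH"], 12345)
  expect_true(any(vapply(m$events, function(e)
    isTRUE(all.equal(unname(e$time), 99999)), logical(1))))
})
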