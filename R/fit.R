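# Simulation-based composite-likelihood fitting of demographic models to
# an observed joint SFS, with AIC ranking and Bayes-factor arithmetic for
# externally supplied marginal likelihoods.

#' Composite log-likelihood of an observed SFS
#'
#' Multinomial-style composite likelihood over the unmasked (polymorphic)
#' cells: `lnL = sum m_e * ln(max(p_e, p_floor))`, where the expected
#' probabilities are renormalized over unmasked cells and floored at
#' `p_floor` so cells unobserved in a finite simulation cannot send the
#' likelihood to -Inf. The default floor is `1/(10 * n_sims)` when the
#' expected spectrum carries an `n_sims` attribute (as produced by
#' [expected_sfs()]).
#'
#' @param obs observed `JointSFS` (counts).
#' @param expected_probs `JointSFS` of expected cell probabilities (or an
#'   array of matching shape).
#' @param p_floor probability floor; see above.
#' @return the composite log-likelihood (natural log).
#' @export
composite_log_likelihood <- function(obs, expected_probs, p_floor = NULL) {
  p_arr <- if (inherits(expected_probs, "JointSFS")) expected_probs$counts
           else expected_probs
  assert_that(all(dim(p_arr) == dim(obs$counts)),
              "observed and expected spectra have different shapes")
  assert_that(all(p_arr >= 0), "expected probabilities must be non-negative")
  if (is.null(p_floor)) {
    ns <- attr(expected_probs, "n_sims")
    p_floor <- if (is.null(ns)) 1e-12 else 1 / (10 * ns)
  }
  mask <- sfs_mask(obs)
  m <- obs$counts[mask]
  p <- p_arr[mask]
  tot <- sum(p)
  if (tot <= 0) {
    p <- rep(p_floor, length(p))
  } else {
    p <- p / tot
  }
  floored <- p < p_floor & m > 0
  if (any(floored))
    fw_log(sprintf("composite likelihood: floored %d cells with observations but zero simulated mass",
                   sum(floored)))
  sum(m * log(pmax(p, p_floor)))
}

#' Monte-Carlo expected SFS under a demographic model
#'
#' Simulates `n_sims` regions and tallies the per-cell probability that a
#' polymorphic site falls in each cell (renormalized over unmasked cells).
#' Deterministic for a fixed seed.
#'
#' @param model a `DemographicModel`.
#' @param samples haploid sample counts (named or model-ordered).
#' @param n_sims number of simulated regions (>= 1000 recommended).
#' @param seed integer seed.
#' @param folded return the folded spectrum.
#' @param pops which populations to tally (default: all with samples).
#' @return a `JointSFS` of probabilities with attribute `n_sims`.
#' @export
expected_sfs <- function(model, samples, n_sims, seed, folded = TRUE,
                         pops = NULL) {
  sim <- simulate_site_counts(model, samples, n_sims, seed)
  if (is.null(pops)) {
    pops_idx <- which(sim$samples > 0)
  } else {
    pops_idx <- match(pops, model$pop_names)
    assert_that(!anyNA(pops_idx), "unknown population in pops")
  }
  sfs <- tally_joint_sfs(sim$counts, sim$samples, pops_idx, model$pop_names,
                         folded = folded)
  mask <- sfs_mask(sfs)
  tot <- sum(sfs$counts[mask])
  probs <- sfs$counts
  if (tot > 0) probs <- probs / tot
  out <- joint_sfs(probs, sfs$sample_sizes, sfs$pops, folded = sfs$folded)
  attr(out, "n_sims") <- n_sims
  attr(out, "sites_per_region") <- tot / n_sims
  out
}

#' Akaike information criterion
#' @param lnL maximum log-likelihood (natural log).
#' @param d number of free parameters.
#' @return `2 * d - 2 * lnL`.
#' @export
aic <- function(lnL, d) {
  assert_that(all(d >= 0), "d must be non-negative")
  2 * d - 2 * lnL
}

#' Twice the log Bayes factor
#'
#' `2 * (mlA - mlB)` on externally supplied log marginal likelihoods
#' (e.g. from path sampling); positive values favour model A.
#'
#' @param mlA,mlB log marginal likelihoods of the two models.
#' @return `2ln(BF)`.
#' @export
bayes_factor_2ln <- function(mlA, mlB) 2 * (mlA - mlB)

#' Rank fitted models by AIC
#'
#' @param fits list of `ModelFitResult` objects (or any lists with `AIC`,
#'   `d` and `model_id` fields).
#' @return the list, each element gaining a `rank` field: ascending AIC,
#'   ties broken by smaller `d`, then by `model_id`.
#' @export
rank_models <- function(fits) {
  a <- vapply(fits, `[[`, numeric(1), "AIC")
  d <- vapply(fits, `[[`, numeric(1), "d")
  id <- vapply(fits, function(f) as.character(f$model_id), character(1))
  ord <- order(a, d, id)
  rk <- integer(length(fits)); rk[ord] <- seq_along(fits)
  for (i in seq_along(fits)) fits[[i]]$rank <- rk[i]
  fits
}

#' Fit a demographic model to an observed SFS
#'
#' Simulation-based composite-likelihood maximization in the style of the
#' expectation/conditional-maximization (ECM) SFS fitters: each cycle
#' re-estimates the expected SFS (fresh seed, simulation count annealed
#' from `n_sims / 10` up to `n_sims`) and then updates each free parameter
#' in turn by golden-section search on a log10 scale within its bounds.
#' Within one cycle every candidate parameter vector is evaluated with the
#' same simulation seed (common random numbers), which smooths the
#' stochastic likelihood surface. Several independent seeded runs are
#' launched from log-uniform starting points; the best final likelihood
#' (re-evaluated at the full `n_sims`) wins.
#'
#' @param obs observed `JointSFS`.
#' @param builder either a preset name (see [preset_model()]) or a
#'   function `function(par)` returning a `DemographicModel` from a named
#'   parameter vector.
#' @param bounds 2-row matrix (rows `lower`, `upper`) with one named
#'   column per free parameter; bounds must be finite and positive.
#' @param samples haploid sample counts passed to the simulator.
#' @param cycles number of ECM cycles per run (the classic setting ramps
#'   10 to 40; reduce for desk-scale work).
#' @param n_runs independent optimization runs (classic setting 100).
#' @param n_sims simulated regions per likelihood evaluation at full
#'   annealing.
#' @param seed master seed; all run/cycle seeds derive from it.
#' @param golden_iter golden-section iterations per parameter per cycle.
#' @param n_regions_obs number of regions (including invariant ones)
#'   underlying the observed SFS. When supplied, a Poisson term on the
#'   total number of polymorphic sites is added to the composite
#'   likelihood; without it the likelihood is conditioned on polymorphism
#'   and absolute population sizes are only weakly identified (the folded
#'   one-population spectrum shape carries no information about theta at
#'   all).
#' @return a `ModelFitResult`: `model_id`, `params`, `lnL`
#'   (`MaxEstLhood`, natural log), `d`, `AIC`, and per-run trajectories.
#' @export
fit_model <- function(obs, builder, bounds, samples,
                      cycles = 12L, n_runs = 100L, n_sims = 10000L,
                      seed = 1L, golden_iter = 6L, n_regions_obs = NULL) {
  model_id <- if (is.character(builder)) builder else
    attr(builder, "model_id") %||% "custom"
  if (is.character(builder)) builder <- preset_builder(builder)
  assert_that(is.matrix(bounds) && nrow(bounds) == 2 &&
                !is.null(colnames(bounds)),
              "bounds must be a 2 x d matrix with named columns")
  assert_that(all(is.finite(bounds)) && all(bounds > 0),
              "bounds must be finite and positive (parameters live on a log scale)")
  par_names <- colnames(bounds)
  d <- length(par_names)
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])

  s_obs <- sum(obs$counts[sfs_mask(obs)])
  objective <- function(lpar, n_s, s) {
    par <- setNames(10^lpar, par_names)
    model <- builder(par)
    exp_sfs <- expected_sfs(model, samples, n_s, s, folded = obs$folded)
    lnl <- composite_log_likelihood(obs, exp_sfs)
    if (!is.null(n_regions_obs)) {
      lambda <- max(attr(exp_sfs, "sites_per_region") * n_regions_obs, 1e-8)
      lnl <- lnl + s_obs * log(lambda) - lambda - lgamma(s_obs + 1)
    }
    lnl
  }

  phi <- (sqrt(5) - 1) / 2
  best <- NULL
  trajectories <- vector("list", n_runs)
  any_finite <- FALSE

  for (run in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, run * 1000)
    set.seed(as.integer(run_seed))
    lpar <- lo + runif(d) * (hi - lo)
    traj <- numeric(cycles)
    for (cy in seq_len(cycles)) {
      frac <- if (cycles == 1) 1 else 0.1 + 0.9 * (cy - 1) / (cycles - 1)
      n_s <- max(100L, ceiling(n_sims * frac))
      s_cy <- derive_seed(run_seed, cy)
      f_cur <- objective(lpar, n_s, s_cy)
      for (k in seq_len(d)) {
        a <- lo[k]; b <- hi[k]
        x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
        l1 <- replace(lpar, k, x1); l2 <- replace(lpar, k, x2)
        f1 <- objective(l1, n_s, s_cy); f2 <- objective(l2, n_s, s_cy)
        for (g in seq_len(golden_iter)) {
          if (f1 >= f2) {
            b <- x2; x2 <- x1; f2 <- f1
            x1 <- b - phi * (b - a)
            f1 <- objective(replace(lpar, k, x1), n_s, s_cy)
          } else {
            a <- x1; x1 <- x2; f1 <- f2
            x2 <- a + phi * (b - a)
            f2 <- objective(replace(lpar, k, x2), n_s, s_cy)
          }
        }
        cand <- if (f1 >= f2) x1 else x2
        f_cand <- max(f1, f2)
        if (f_cand >= f_cur) {
          lpar[k] <- cand
          f_cur <- f_cand
        }
      }
      traj[cy] <- f_cur
    }
    final_lnL <- objective(lpar, n_sims, derive_seed(run_seed, 9999))
    trajectories[[run]] <- traj
    if (is.finite(final_lnL)) any_finite <- TRUE
    if (is.null(best) || final_lnL > best$lnL)
      best <- list(lpar = lpar, lnL = final_lnL)
  }
  if (!any_finite)
    stop_fw("optimizer exhausted all runs without a finite composite likelihood")

  params <- setNames(10^best$lpar, par_names)
  structure(list(model_id = model_id, params = params,
                 lnL = best$lnL, d = d, AIC = aic(best$lnL, d),
                 rank = NA_integer_, trajectories = trajectories,
                 settings = list(cycles = cycles, n_runs = n_runs,
                                 n_sims = n_sims, seed = seed)),
            class = "ModelFitResult")
}

#' @export
print.ModelFitResult <- function(x, ...) {
  cat(sprintf("ModelFitResult [%s]: lnL = %.2f, d = %d, AIC = %.2f%s\n",
              x$model_id, x$lnL, x$d, x$AIC,
              if (is.na(x$rank)) "" else paste0(", rank ", x$rank)))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Model-comparison table
#'
#' @param fits a list of (ranked) `ModelFitResult`s.
#' @return a data.frame mirroring the classic comparison layout: model,
#'   MaxEstLhood, number of parameters, AIC, rank.
#' @export
model_comparison_table <- function(fits) {
  fits <- rank_models(fits)
  data.frame(model = vapply(fits, function(f) as.character(f$model_id),
                            character(1)),
             MaxEstLhood = vapply(fits, `[[`, numeric(1), "lnL"),
             n_parameters = vapply(fits, `[[`, numeric(1), "d"),
             AIC = vapply(fits, `[[`, numeric(1), "AIC"),
             rank = vapply(fits, `[[`, numeric(1), "rank"))
}
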