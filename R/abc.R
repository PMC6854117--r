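# Approximate Bayesian computation: reference-table generation, PLS
# summary reduction, rejection sampling, local-linear (and optional
# neural-network) regression adjustment, and weighted HPD intervals.

#' Draw from a prior specification
#'
#' Priors are named lists: `list(T3 = prior_loguniform(100, 1e5), ...)`.
#'
#' @param min,max bounds of the distribution.
#' @return a prior object.
#' @export
prior_loguniform <- function(min, max) {
  assert_that(is.finite(min) && is.finite(max) && min > 0 && max >= min,
              "log-uniform prior needs finite positive bounds")
  structure(list(dist = "loguniform", min = min, max = max), class = "abc_prior")
}

#' @rdname prior_loguniform
#' @export
prior_uniform <- function(min, max) {
  assert_that(is.finite(min) && is.finite(max) && max >= min,
              "uniform prior needs finite bounds")
  structure(list(dist = "uniform", min = min, max = max), class = "abc_prior")
}

draw_prior <- function(pr, n) {
  switch(pr$dist,
         loguniform = exp(runif(n, log(pr$min), log(pr$max))),
         uniform = runif(n, pr$min, pr$max),
         stop_fw("unknown prior distribution: %s", pr$dist))
}

# flattened summary vector: all pairwise folded SFS of the dataset,
# pairs (i < j) in population order, cells in row-major order
pairwise_sfs_summary <- function(counts, samples, pops_idx, pop_names) {
  out <- list()
  for (ii in seq_along(pops_idx)[-length(pops_idx)]) {
    for (jj in (ii + 1):length(pops_idx)) {
      sfs <- tally_joint_sfs(counts, samples, pops_idx[c(ii, jj)],
                             pop_names, folded = TRUE)
      d <- dim(sfs$counts)
      out[[length(out) + 1]] <- as.vector(aperm(sfs$counts, c(2, 1)))
    }
  }
  unlist(out)
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the priors, simulates a dataset
#' with the same configuration as the observed data for each, and records
#' the concatenated pairwise folded SFS as summaries.
#'
#' @param builder a model builder `function(par) -> DemographicModel`
#'   (see [preset_builder()]).
#' @param priors named list of priors over the free parameters.
#' @param n_sims number of simulations (the classic setting is 120000).
#' @param samples haploid sample counts per population.
#' @param seed master seed.
#' @param n_regions regions per simulated dataset (default: model's).
#' @return a `ReferenceTable`: list with `params` (n_sims x d) and
#'   `summaries` (n_sims x S) matrices, `seed`, `model_id`.
#' @export
build_reference_table <- function(builder, priors, n_sims, samples, seed,
                                  n_regions = NULL) {
  assert_that(length(priors) >= 1 && !is.null(names(priors)),
              "priors must be a named list")
  set.seed(as.integer(derive_seed(seed, 1)))
  par_mat <- vapply(priors, draw_prior, numeric(n_sims), n = n_sims)
  if (n_sims == 1) par_mat <- matrix(par_mat, 1, dimnames = list(NULL, names(priors)))
  summaries <- NULL
  for (i in seq_len(n_sims)) {
    par <- setNames(par_mat[i, ], colnames(par_mat))
    model <- builder(par)
    nr <- n_regions %||% model$n_regions
    sim <- simulate_site_counts(model, samples, nr, derive_seed(seed, i + 1))
    pops_idx <- which(sim$samples > 0)
    s <- pairwise_sfs_summary(sim$counts, sim$samples, pops_idx,
                              model$pop_names)
    if (is.null(summaries))
      summaries <- matrix(0, n_sims, length(s))
    summaries[i, ] <- s
  }
  structure(list(params = par_mat, summaries = summaries,
                 seed = seed,
                 model_id = attr(builder, "model_id") %||% "custom"),
            class = "ReferenceTable")
}

#' Observed summary vector matching a reference table
#'
#' @param gm,pm observed genotypes and population map.
#' @param pops populations, in the order used by the reference table.
#' @param project_to optional projection sizes (see [compute_joint_sfs()]).
#' @return numeric summary vector (concatenated pairwise folded SFS).
#' @export
observed_summary <- function(gm, pm, pops, project_to = NULL) {
  out <- list()
  for (ii in seq_along(pops)[-length(pops)]) {
    for (jj in (ii + 1):length(pops)) {
      sfs <- compute_joint_sfs(gm, pm, pops[c(ii, jj)], folded = TRUE,
                               project_to = project_to[c(ii, jj)])
      out[[length(out) + 1]] <- as.vector(aperm(sfs$counts, c(2, 1)))
    }
  }
  unlist(out)
}

#' Partial least squares reduction of ABC summaries
#'
#' Fits PLS components (NIPALS, summaries regressed toward parameters) on
#' the reference table, after centering and unit-variance scaling of both
#' blocks (constant summary columns are dropped). Both the table and the
#' observed summary vector are projected; components have zero mean over
#' the table by construction.
#'
#' @param table a `ReferenceTable`.
#' @param observed_summary the observed summary vector.
#' @param n_components number of components (classic setting: 10).
#' @return list with `reduced` (n_sims x k scores), `observed` (length-k),
#'   and the projection (`center`, `scale`, `W`, `P`, kept columns).
#' @export
pls_reduce <- function(table, observed_summary, n_components = 10L) {
  X <- table$summaries
  Y <- as.matrix(table$params)
  assert_that(length(observed_summary) == ncol(X),
              "observed summary length does not match the table")
  n <- nrow(X)
  assert_that(n_components <= min(ncol(X), n - 1),
              "n_components exceeds min(#summaries, n_sims - 1)")
  keep <- which(apply(X, 2, sd) > 0)
  X <- X[, keep, drop = FALSE]
  cx <- colMeans(X); sx <- apply(X, 2, sd)
  Xc <- sweep(sweep(X, 2, cx), 2, sx, "/")
  Yl <- log(Y)  # parameters are positive scale parameters
  sy <- apply(Yl, 2, sd)
  assert_that(any(sy > 0), "all parameters are constant; nothing to regress on")
  sy[sy == 0] <- 1
  Yc <- sweep(sweep(Yl, 2, colMeans(Yl)), 2, sy, "/")

  p <- ncol(Xc); q <- ncol(Yc)
  W <- P <- matrix(0, p, n_components)
  E <- Xc
  for (h in seq_len(n_components)) {
    u <- Yc[, which.max(apply(Yc, 2, var)), drop = TRUE]
    w <- rep(0, p)
    for (it in seq_len(200)) {
      w_new <- as.vector(crossprod(E, u))
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) break
      w_new <- w_new / nw
      tt <- as.vector(E %*% w_new)
      qv <- as.vector(crossprod(Yc, tt)) / sum(tt^2)
      u_new <- as.vector(Yc %*% qv) / sum(qv^2)
      conv <- sum((w_new - w)^2) < 1e-12
      w <- w_new; u <- u_new
      if (conv || q == 1) break
    }
    tt <- as.vector(E %*% w)
    pv <- as.vector(crossprod(E, tt)) / sum(tt^2)
    W[, h] <- w; P[, h] <- pv
    E <- E - tcrossprod(tt, pv)
  }
  R <- W %*% solve(crossprod(P, W))
  scores <- Xc %*% R
  obs_c <- (observed_summary[keep] - cx) / sx
  obs_scores <- as.vector(obs_c %*% R)
  list(reduced = scores, observed = obs_scores,
       projection = list(center = cx, scale = sx, W = W, P = P, R = R,
                         keep = keep))
}

#' Rejection-sampling ABC
#'
#' Accepts the `n_accept` reference-table rows closest to the observed
#' point in Euclidean distance, computed after standardizing every
#' coordinate by its table standard deviation. Ties at the cutoff are
#' broken by row order.
#'
#' @param reduced reduced table (n_sims x k), e.g. from [pls_reduce()].
#' @param observed reduced observed vector (length k).
#' @param params parameter matrix aligned with `reduced`.
#' @param n_accept number of accepted simulations (classic setting: 5000).
#' @return an `ABCPosterior`: accepted draws, unit weights, distances,
#'   point estimates and 95% HPD intervals.
#' @export
abc_rejection <- function(reduced, observed, params, n_accept = 5000L) {
  reduced <- as.matrix(reduced); params <- as.matrix(params)
  assert_that(n_accept >= 1 && n_accept <= nrow(reduced),
              "n_accept must lie in 1..n_sims")
  sdv <- apply(reduced, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(reduced, 2, sdv, "/")
  zo <- observed / sdv
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  idx <- order(d, seq_along(d))[seq_len(n_accept)]
  new_abc_posterior(draws = params[idx, , drop = FALSE],
                    weights = rep(1, n_accept),
                    method = "rejection",
                    accepted_index = idx, distances = d[idx],
                    reduced_accepted = reduced[idx, , drop = FALSE],
                    observed = observed)
}

new_abc_posterior <- function(draws, weights, method, accepted_index,
                              distances, reduced_accepted, observed) {
  weights <- weights / sum(weights)
  est <- lapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    hpd <- hpd_interval(x, weights, 0.95)
    c(median = weighted_quantile(x, weights, 0.5),
      mode = weighted_mode(x, weights),
      hpd_lower = hpd[1], hpd_upper = hpd[2])
  })
  est <- do.call(rbind, est)
  rownames(est) <- colnames(draws)
  structure(list(draws = draws, weights = weights, method = method,
                 estimates = est, accepted_index = accepted_index,
                 distances = distances,
                 reduced_accepted = reduced_accepted, observed = observed),
            class = "ABCPosterior")
}

#' @export
print.ABCPosterior <- function(x, ...) {
  cat(sprintf("ABCPosterior (%s): %d accepted draws\n", x$method,
              nrow(x$draws)))
  print(signif(x$estimates, 4))
  invisible(x)
}

weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= p)[1]]
}

weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1) return(x[1])
  dd <- suppressWarnings(density(x, weights = w / sum(w)))
  dd$x[which.max(dd$y)]
}

#' Regression adjustment of a rejection posterior
#'
#' Local-linear adjustment (Beaumont-style): a weighted linear regression
#' of each parameter (log scale) on the reduced summaries among the
#' accepted draws, with Epanechnikov weights in the acceptance distance,
#' is used to transport every accepted draw to the observed point.
#' The `neuralnet` method replaces the linear map by a seeded
#' single-hidden-layer network.
#'
#' @param posterior an `ABCPosterior` from [abc_rejection()].
#' @param method `"loclinear"` (default, deterministic) or `"neuralnet"`.
#' @param seed seed (used by `neuralnet` initialization).
#' @param log_params adjust on the log scale (back-transformed after);
#'   appropriate for positive scale parameters.
#' @return a new `ABCPosterior` with adjusted draws and Epanechnikov
#'   weights.
#' @export
regression_adjust <- function(posterior, method = c("loclinear", "neuralnet"),
                              seed = 1L, log_params = TRUE) {
  method <- match.arg(method)
  assert_that(inherits(posterior, "ABCPosterior") &&
                posterior$method == "rejection",
              "regression_adjust expects a rejection ABCPosterior")
  S <- sweep(posterior$reduced_accepted, 2, posterior$observed)
  Y <- posterior$draws
  if (log_params) Y <- log(Y)
  dmax <- max(posterior$distances)
  w <- if (dmax > 0) 1 - (posterior$distances / dmax)^2 else
    rep(1, length(posterior$distances))
  w <- pmax(w, 1e-8)

  if (method == "loclinear") {
    Xd <- cbind(1, S)
    fit <- stats::lm.wfit(Xd, Y, w)
    coefs <- as.matrix(fit$coefficients)
    coefs[is.na(coefs)] <- 0
    adj <- Y - S %*% coefs[-1, , drop = FALSE]
  } else {
    adj <- Y
    for (j in seq_len(ncol(Y)))
      adj[, j] <- Y[, j] - nnet_shift(S, Y[, j], w, derive_seed(seed, j))
  }
  if (log_params) adj <- exp(adj)
  colnames(adj) <- colnames(posterior$draws)
  new_abc_posterior(draws = adj, weights = w, method = method,
                    accepted_index = posterior$accepted_index,
                    distances = posterior$distances,
                    reduced_accepted = posterior$reduced_accepted,
                    observed = posterior$observed)
}

# single-hidden-layer (tanh) regression; returns m(s_i) - m(0), the shift
# removed from each accepted draw
nnet_shift <- function(S, y, w, seed, hidden = 5L, lambda = 1e-3) {
  set.seed(as.integer(seed))
  p <- ncol(S)
  sy <- sd(y); my <- mean(y)
  yn <- if (sy > 0) (y - my) / sy else y * 0
  n_par <- hidden * (p + 1) + hidden + 1
  init <- runif(n_par, -0.5, 0.5)
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(hidden * p)], p, hidden)
    b1 <- th[hidden * p + seq_len(hidden)]
    W2 <- th[hidden * (p + 1) + seq_len(hidden)]
    b2 <- th[n_par]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(th, X) {
    pr <- unpack(th)
    H <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
    as.vector(H %*% pr$W2 + pr$b2)
  }
  obj <- function(th) sum(w * (yn - fwd(th, S))^2) + lambda * sum(th^2)
  opt <- optim(init, obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-8))
  m_s <- fwd(opt$par, S)
  m_0 <- fwd(opt$par, matrix(0, 1, p))
  (m_s - m_0) * if (sy > 0) sy else 1
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted draws containing at least
#' `mass` of the (weighted) posterior mass.
#'
#' @param draws numeric draws.
#' @param weights optional weights (default equal).
#' @param mass target mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, weights = NULL, mass = 0.95) {
  assert_that(mass > 0 && mass <= 1, "mass must be in (0, 1]")
  if (is.null(weights)) weights <- rep(1, length(draws))
  ord <- order(draws)
  x <- draws[ord]
  w <- weights[ord] / sum(weights)
  n <- length(x)
  if (n == 1) return(c(x, x))
  cw <- c(0, cumsum(w))
  best <- c(x[1], x[n]); best_width <- x[n] - x[1]
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && cw[j + 1] - cw[i] < mass) j <- j + 1
    if (cw[j + 1] - cw[i] >= mass - 1e-12) {
      width <- x[j] - x[i]
      if (width < best_width) {
        best_width <- width
        best <- c(x[i], x[j])
      }
    }
  }
  best
}
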