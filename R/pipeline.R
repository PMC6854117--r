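# End-to-end pipeline: stage chaining with config validation, seed
# control, and a reporter that only re-reads stage outputs.

PIPELINE_STAGES <- c("simulate", "sfs", "stats", "fit", "abc", "fdist",
                     "report")

#' Default desk-scale pipeline configuration
#'
#' A complete run (all stages) sized to finish in minutes on one CPU.
#' Every field can be overridden via a JSON config file (JSON is a strict
#' subset of YAML).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "sfs", "stats", "fit", "abc", "fdist", "report"),
    seed = 1L,
    simulate = list(model = "model3", scale = 0.05,
                    sample_sizes = as.list(default_sample_sizes())),
    sfs = list(pops = c("DT", "CH", "SH"), folded = TRUE),
    stats = list(n_perm = 100L,
                 grouping = list(DT = "deep", PY = "deep", NY = "deep",
                                 LA = "recent", CH = "recent", TH = "recent",
                                 HZ = "recent", GY = "recent",
                                 SH = "anadromous")),
    fit = list(models = c("model1", "model3"),
               pops = c("DT", "CH", "SH"),
               n_runs = 2L, cycles = 3L, n_sims = 500L),
    abc = list(n_sims = 400L, n_accept = 50L, n_components = 4L,
               pops = c("CH", "SH"),
               priors = list(T3 = list(dist = "loguniform",
                                       min = 200, max = 20000))),
    fdist = list(pops = c("SH", "DT", "PY"), n_sims = 3000L,
                 n_demes = 50L, upper_q = 0.95, lower_q = 0.05))
}

#' Validate a pipeline configuration
#'
#' @param config nested list (e.g. parsed from JSON).
#' @return the validated config, with defaults filled in; errors name the
#'   offending field.
#' @export
validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), c(names(base), "outdir"))
  if (length(unknown) > 0)
    stop_fw("config: unknown field '%s'", unknown[1])
  bad_stage <- setdiff(config$stages %||% character(0), PIPELINE_STAGES)
  if (length(bad_stage) > 0)
    stop_fw("config field 'stages': unknown stage '%s'", bad_stage[1])
  merged <- utils::modifyList(base, config)
  assert_that(is.numeric(merged$seed) && length(merged$seed) == 1,
              "config field 'seed' must be a single integer")
  merged
}

#' Run the pipeline
#'
#' Executes the configured stages in order (simulate, sfs, stats, fit,
#' abc, fdist, report), writing each stage's tables under
#' `outdir/<stage>/` and a machine-readable manifest
#' (`manifest.json`: package version, seed, per-stage status, wall
#' times, input file hashes). Any stage failure halts the run with an
#' error naming the stage. A rerun with the same config and seed
#' reproduces all numerical outputs.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   JSON config file.
#' @param outdir output directory.
#' @param seed optional master-seed override.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = "fwinvade",
                   version = as.character(packageVersion("fwinvade")),
                   seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    sdir <- file.path(outdir, stage)
    dir.create(sdir, showWarnings = FALSE)
    ok <- tryCatch({
      switch(stage,
             simulate = stage_simulate(config, sdir, state),
             sfs = stage_sfs(config, sdir, state),
             stats = stage_stats(config, sdir, state),
             fit = stage_fit(config, sdir, state),
             abc = stage_abc(config, sdir, state),
             fdist = stage_fdist(config, sdir, state),
             report = report(outdir))
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop_fw("pipeline stage '%s' failed: %s (see %s)", stage,
              conditionMessage(e), file.path(outdir, "manifest.json"))
    })
    outputs <- list.files(sdir, full.names = TRUE)
    manifest$stages[[stage]] <-
      list(status = "ok",
           wall_seconds = round(proc.time()[["elapsed"]] - t0, 2),
           outputs = basename(outputs),
           md5 = as.list(unname(tools::md5sum(outputs))))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

ensure_data <- function(config, state) {
  if (is.null(state$gm)) {
    spec <- fixture_spec(model = config$simulate$model,
                         scale = config$simulate$scale,
                         sample_sizes = unlist(config$simulate$sample_sizes),
                         seed = derive_seed(config$seed, 1))
    fx <- make_fixture(spec)
    state$gm <- fx$gm; state$pm <- fx$pm; state$truth <- fx$truth
  }
  invisible(state)
}

stage_simulate <- function(config, sdir, state) {
  spec <- fixture_spec(model = config$simulate$model,
                       scale = config$simulate$scale,
                       sample_sizes = unlist(config$simulate$sample_sizes),
                       seed = derive_seed(config$seed, 1))
  fx <- make_fixture(spec, dir = sdir)
  state$gm <- fx$gm; state$pm <- fx$pm; state$truth <- fx$truth
}

stage_sfs <- function(config, sdir, state) {
  ensure_data(config, state)
  pops <- unlist(config$sfs$pops)
  sfs_f <- compute_joint_sfs(state$gm, state$pm, pops, folded = TRUE)
  write_sfs(sfs_f, file.path(sdir, "joint_folded.sfs"))
  sfs_u <- compute_joint_sfs(state$gm, state$pm, pops, folded = FALSE)
  write_sfs(sfs_u, file.path(sdir, "joint_unfolded.sfs"))
  for (ii in seq_along(pops)[-length(pops)]) for (jj in (ii + 1):length(pops)) {
    mg <- marginal_pairwise_sfs(sfs_f, ii, jj)
    write_sfs(mg, file.path(sdir, sprintf("pairwise_%s_%s.sfs",
                                          pops[ii], pops[jj])))
  }
  state$sfs <- sfs_f
}

stage_stats <- function(config, sdir, state) {
  ensure_data(config, state)
  pi <- nucleotide_diversity(state$gm, state$pm,
                             region_length = state$truth$region_length)
  write.table(data.frame(population = names(pi), pi = pi),
              file.path(sdir, "pi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fst <- pairwise_fst(state$gm, state$pm, n_perm = config$stats$n_perm,
                      seed = derive_seed(config$seed, 2))
  write.table(fst$fst, file.path(sdir, "fst.tsv"), sep = "\t", quote = FALSE)
  write.table(fst$p_value, file.path(sdir, "fst_pvalues.tsv"), sep = "\t",
              quote = FALSE)
  grouping <- unlist(config$stats$grouping)
  grouping <- grouping[names(grouping) %in% unique(state$pm$population)]
  am <- amova(state$gm, state$pm, grouping,
              n_perm = config$stats$n_perm,
              seed = derive_seed(config$seed, 3))
  write.table(data.frame(source = names(am$sigma), df = am$df,
                         sum_of_squares = am$ss, variance_component = am$sigma,
                         percentage = am$percentage, p_value = am$p_value),
              file.path(sdir, "amova.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pca <- pca_coordinates(state$gm)
  write.table(data.frame(individual = rownames(pca$scores),
                         pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                    drop = FALSE]),
              file.path(sdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

stage_fit <- function(config, sdir, state) {
  ensure_data(config, state)
  pops <- unlist(config$fit$pops)
  samples <- 2L * unlist(config$simulate$sample_sizes)[pops]
  names(samples) <- pops
  obs <- compute_joint_sfs(state$gm, state$pm, pops, folded = TRUE)
  fits <- list()
  for (mn in unlist(config$fit$models)) {
    free <- preset_free_params(mn, pops = pops)
    free <- grep("^(T[0-9]|N_)", free, value = TRUE)  # desk scale: no mig fit
    bounds <- matrix(rep(c(100, 1e6), length(free)), nrow = 2,
                     dimnames = list(c("lower", "upper"), free))
    bounds[, startsWith(free, "T")] <- c(50, 5e5)
    fits[[mn]] <- fit_model(obs, preset_builder(mn, pops = pops),
                            bounds = bounds, samples = samples,
                            cycles = config$fit$cycles,
                            n_runs = config$fit$n_runs,
                            n_sims = config$fit$n_sims,
                            seed = derive_seed(config$seed, 4))
  }
  tab <- model_comparison_table(fits)
  write.table(tab, file.path(sdir, "model_comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

stage_abc <- function(config, sdir, state) {
  ensure_data(config, state)
  pops <- unlist(config$abc$pops)
  samples <- 2L * unlist(config$simulate$sample_sizes)[pops]
  names(samples) <- pops
  priors <- lapply(config$abc$priors, function(p)
    switch(p$dist,
           loguniform = prior_loguniform(p$min, p$max),
           uniform = prior_uniform(p$min, p$max),
           stop_fw("config field 'abc.priors': unknown dist '%s'", p$dist)))
  builder <- preset_builder(config$simulate$model, pops = pops,
                            n_regions = state$truth$n_regions)
  tab <- build_reference_table(builder, priors, config$abc$n_sims, samples,
                               seed = derive_seed(config$seed, 5),
                               n_regions = state$truth$n_regions)
  obs_sum <- observed_summary(state$gm, state$pm, pops)
  red <- pls_reduce(tab, obs_sum, n_components = config$abc$n_components)
  post <- abc_rejection(red$reduced, red$observed, tab$params,
                        n_accept = config$abc$n_accept)
  adj <- regression_adjust(post, "loclinear")
  write.table(data.frame(tab$params, tab$summaries, check.names = FALSE),
              file.path(sdir, "reference_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(adj$draws, weight = adj$weights),
              file.path(sdir, "posterior_draws.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = adj$method,
         estimates = as.data.frame(cbind(parameter = rownames(adj$estimates),
                                         as.data.frame(adj$estimates)))),
    file.path(sdir, "abc_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

stage_fdist <- function(config, sdir, state) {
  ensure_data(config, state)
  pops <- unlist(config$fdist$pops)
  obs <- observed_locus_stats(state$gm, state$pm, pops)
  sizes <- vapply(pops, function(p)
    2L * sum(state$pm$population == p), integer(1))
  target <- max(0.005, min(0.95, mean(obs$Fst, trim = 0.05)))
  null <- simulate_fdist_null(target, sizes,
                              n_demes = config$fdist$n_demes,
                              n_sims = config$fdist$n_sims,
                              seed = derive_seed(config$seed, 6))
  rec <- classify_outliers(locus_pvalues(obs, null),
                           upper_q = config$fdist$upper_q,
                           lower_q = config$fdist$lower_q)
  write.table(rec, file.path(sdir, "outliers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qs <- stats::aggregate(Fst ~ cut(He, breaks = seq(0, 1, 0.05)),
                         data = null,
                         FUN = function(x) quantile(x, c(0.05, 0.5, 0.95)))
  env <- data.frame(he_bin = as.character(qs[[1]]),
                    q05 = qs$Fst[, 1], q50 = qs$Fst[, 2], q95 = qs$Fst[, 3])
  write.table(env, file.path(sdir, "null_envelope.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Render the run report
#'
#' Re-reads stage outputs (never recomputes) and writes a plain-text
#' summary: model-comparison table, AMOVA table, Fst matrix, outlier
#' counts and ABC point estimates with HPDs.
#'
#' @param run_dir a directory previously populated by [run_pipeline()].
#' @return invisibly, the path of the report file.
#' @export
report <- function(run_dir) {
  out <- file.path(run_dir, "report", "report.txt")
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  lines <- c("fwinvade pipeline report", strrep("=", 40))
  add_tsv <- function(lines, path, title) {
    if (!file.exists(path)) return(lines)
    tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
    c(lines, "", title, strrep("-", nchar(title)),
      utils::capture.output(print(tab, row.names = FALSE)))
  }
  lines <- add_tsv(lines, file.path(run_dir, "fit", "model_comparison.tsv"),
                   "Model comparison (composite likelihood, AIC)")
  lines <- add_tsv(lines, file.path(run_dir, "stats", "amova.tsv"), "AMOVA")
  lines <- add_tsv(lines, file.path(run_dir, "stats", "fst.tsv"),
                   "Pairwise Fst")
  lines <- add_tsv(lines, file.path(run_dir, "stats", "pi.tsv"),
                   "Nucleotide diversity")
  outl <- file.path(run_dir, "fdist", "outliers.tsv")
  if (file.exists(outl)) {
    rec <- read.table(outl, sep = "\t", header = TRUE)
    cnt <- table(factor(rec$classification,
                        levels = c("disruptive", "balancing", "neutral")))
    lines <- c(lines, "", "Outlier scan", "------------",
               paste(names(cnt), as.integer(cnt), sep = ": "))
  } else {
    lines <- c(lines, "", "Outlier scan", "------------",
               "disruptive: 0", "balancing: 0", "neutral: 0")
  }
  abcf <- file.path(run_dir, "abc", "abc_summary.json")
  if (file.exists(abcf)) {
    abcs <- jsonlite::read_json(abcf, simplifyVector = TRUE)
    lines <- c(lines, "", "ABC estimates", "-------------",
               utils::capture.output(print(abcs$estimates, row.names = FALSE)))
  }
  writeLines(lines, out)
  invisible(out)
}
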