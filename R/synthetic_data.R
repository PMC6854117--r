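# Seeded synthetic fixtures emulating the shape of the motivating anchovy dataset, so every
# pipeline stage can be exercised without external downloads.

#' Specification of a synthetic fixture
#'
#' @param model preset name (`"model1"` ... `"model4"`) or a custom
#'   `DemographicModel` whose population labels match `sample_sizes`.
#' @param scale fraction of the full 2869 regions to simulate (desk-scale
#'   default 0.1).
#' @param sample_sizes named diploid sample sizes (field defaults:
#'   [default_sample_sizes()]).
#' @param outlier_fraction fraction of regions re-simulated with scaled
#'   between-group migration (a selection proxy; only meaningful for
#'   models with migration).
#' @param outlier_scale migration scaling factor for spiked loci.
#' @param outlier_mode `"disruptive"` (migration divided by the factor)
#'   or `"balancing"` (multiplied).
#' @param groups named group labels per population, defining "between
#'   group" for spiking (default: anadromous SH vs the rest).
#' @param seed master seed, recorded in all outputs.
#' @param ... model parameter overrides passed to [preset_model()]
#'   (`sizes`, `times`, `mig`, `pops`, `n_regions`, ...).
#' @return a `FixtureSpec`.
#' @export
fixture_spec <- function(model = "model3", scale = 0.1,
                         sample_sizes = default_sample_sizes(),
                         outlier_fraction = 0, outlier_scale = 1,
                         outlier_mode = c("disruptive", "balancing"),
                         groups = NULL, seed = 1L, ...) {
  assert_that(scale > 0 && scale <= 1, "scale must lie in (0, 1]")
  assert_that(all(sample_sizes >= 2), "need at least 2 diploids per population")
  assert_that(outlier_fraction >= 0 && outlier_fraction < 1,
              "outlier_fraction must lie in [0, 1)")
  structure(list(model = model, scale = scale,
                 sample_sizes = sample_sizes,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 outlier_mode = match.arg(outlier_mode),
                 groups = groups, seed = as.integer(seed),
                 overrides = list(...)),
            class = "FixtureSpec")
}

fixture_model <- function(spec) {
  if (inherits(spec$model, "DemographicModel")) {
    m <- spec$model
  } else {
    ov <- spec$overrides
    ov$name <- spec$model
    m <- do.call(preset_model, ov)
  }
  m$n_regions <- as.integer(round(spec$scale * m$n_regions))
  m
}

# scale between-group migration entries of a model (initial matrix and
# any migration_change events)
scale_group_migration <- function(model, groups, factor) {
  g <- groups[model$pop_names]
  between <- outer(g, g, `!=`)
  model$migration[between] <- model$migration[between] * factor
  model$events <- lapply(model$events, function(e) {
    if (e$kind == "migration_change") {
      m <- as.matrix(e$matrix)
      m[between] <- m[between] * factor
      e$matrix <- m
    }
    e
  })
  model
}

#' Generate a synthetic fixture
#'
#' Simulates the preset at the spec's parameters, optionally re-simulates
#' a fraction of regions with scaled between-group migration (spiked
#' outliers), and—when `dir` is given—writes a VCF, a population map and
#' a truth JSON (all parameters, seeds and spiked locus ids).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory (created if needed).
#' @return invisibly, a `Fixture`: list with `gm` (GenotypeMatrix), `pm`,
#'   `truth` (list), and—if written—`paths`.
#' @export
make_fixture <- function(spec, dir = NULL) {
  model <- fixture_model(spec)
  samples_hap <- 2L * spec$sample_sizes[model$pop_names]
  names(samples_hap) <- model$pop_names
  gm <- simulate_dataset(model, samples_hap, diploid = TRUE,
                         seed = spec$seed, n_regions = model$n_regions)
  truth <- list(model = if (is.character(spec$model)) spec$model else "custom",
                scale = spec$scale,
                seed = spec$seed,
                sample_sizes = as.list(spec$sample_sizes),
                sizes = as.list(model$sizes),
                n_regions = model$n_regions,
                region_length = model$region_length, mu = model$mu,
                spiked_regions = character(0),
                outlier_scale = spec$outlier_scale,
                outlier_mode = spec$outlier_mode)
  fixture <- structure(list(gm = gm, pm = popmap_from_simulated(gm),
                            truth = truth, spec = spec, model = model),
                       class = "Fixture")
  if (spec$outlier_fraction > 0)
    fixture <- spike_outlier_loci(fixture, spec$outlier_fraction,
                                  spec$outlier_scale, spec$outlier_mode)
  if (!is.null(dir)) fixture <- write_fixture(fixture, dir)
  invisible(fixture)
}

#' Re-simulate designated loci under locus-specific selection proxy
#'
#' Spiked regions are re-simulated with between-group migration divided
#' by `migration_scale` (`mode = "disruptive"`, raising their Fst) or
#' multiplied by it (`mode = "balancing"`); spiked region ids are recorded
#' in the truth list. With `migration_scale = 1` or `fraction = 0` the
#' fixture is unchanged.
#'
#' @param fixture a `Fixture` from [make_fixture()].
#' @param fraction fraction of regions to spike.
#' @param migration_scale scaling factor (> 1).
#' @param mode `"disruptive"` or `"balancing"`.
#' @return the modified `Fixture`.
#' @export
spike_outlier_loci <- function(fixture, fraction, migration_scale,
                               mode = c("disruptive", "balancing")) {
  mode <- match.arg(mode)
  if (fraction == 0) return(fixture)
  spec <- fixture$spec
  model <- fixture$model
  groups <- spec$groups
  if (is.null(groups))
    groups <- setNames(ifelse(model$pop_names == "SH", "anadromous",
                              "resident"), model$pop_names)
  factor <- if (mode == "disruptive") 1 / migration_scale else migration_scale
  spiked_model <- scale_group_migration(model, groups, factor)

  n_reg <- model$n_regions
  set.seed(as.integer(derive_seed(spec$seed, 555)))
  spiked <- sort(sample(n_reg, max(1, round(fraction * n_reg))))
  spiked_ids <- sprintf("reg%05d", spiked)

  if (migration_scale != 1) {
    samples_hap <- 2L * spec$sample_sizes[model$pop_names]
    names(samples_hap) <- model$pop_names
    # independent seed stream for the replacement regions
    regm <- spiked_model
    regm$n_regions <- length(spiked)
    new_gm <- simulate_dataset(regm, samples_hap, diploid = TRUE,
                               seed = derive_seed(spec$seed, 556),
                               n_regions = length(spiked))
    # relabel the replacement regions with the spiked ids
    reg_map <- setNames(spiked_ids, sprintf("reg%05d", seq_along(spiked)))
    new_gm$region_id <- unname(reg_map[new_gm$region_id])
    new_gm$locus_id <- paste0(new_gm$region_id, ":", new_gm$position)
    keep <- !(fixture$gm$region_id %in% spiked_ids)
    gm0 <- fixture$gm
    geno <- rbind(gm0$geno[keep, , drop = FALSE], new_gm$geno)
    ord <- order(c(gm0$region_id[keep], new_gm$region_id),
                 c(gm0$position[keep], new_gm$position))
    fixture$gm <- genotype_matrix(
      geno[ord, , drop = FALSE],
      c(gm0$locus_id[keep], new_gm$locus_id)[ord],
      c(gm0$region_id[keep], new_gm$region_id)[ord],
      c(gm0$position[keep], new_gm$position)[ord],
      c(gm0$ref[keep], new_gm$ref)[ord],
      c(gm0$alt[keep], new_gm$alt)[ord],
      c(gm0$qual[keep], new_gm$qual)[ord],
      gm0$individual_ids)
  }
  fixture$truth$spiked_regions <- spiked_ids
  fixture$truth$outlier_scale <- migration_scale
  fixture$truth$outlier_mode <- mode
  fixture
}

write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "fixture.vcf"),
                popmap = file.path(dir, "fixture.popmap.tsv"),
                truth = file.path(dir, "fixture.truth.json"))
  write_vcf(fixture$gm, paths$vcf)
  write_popmap(fixture$pm, paths$popmap)
  jsonlite::write_json(fixture$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  fixture$paths <- paths
  fixture
}

#' Mean SNPs per variable region of a genotype matrix
#' @param gm a `GenotypeMatrix`.
#' @return mean number of sites among regions with at least one site.
#' @export
snps_per_variable_region <- function(gm) {
  n_sites(gm) / length(unique(gm$region_id))
}
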