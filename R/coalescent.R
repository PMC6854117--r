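# R interface to the structured-coalescent engine.

#' Simulate one non-recombining region
#'
#' Draws a genealogy of the sampled gene copies under the model's
#' structured coalescent, drops Poisson(mu x length x tree length)
#' mutations under infinite sites, and returns the haplotypes.
#'
#' @param model a `DemographicModel`.
#' @param samples named (or model-ordered) haploid sample counts per
#'   population.
#' @param seed integer seed; a fixed seed reproduces the region exactly.
#' @param region_id identifier attached to the region.
#' @return a `HaplotypeSet`: list with `positions` (1-based, sorted),
#'   `haplotypes` (0/1 matrix, rows = gene copies in population order),
#'   `samples`, and `region_id`.
#' @export
simulate_region <- function(model, samples, seed, region_id = "reg1") {
  smp <- match_samples(model, samples)
  res <- sim_regions_cpp(flatten_model(model), smp, 1L,
                         model$region_length, model$mu, as.numeric(seed), TRUE)
  reg <- res$regions[[1]]
  structure(list(positions = reg$positions, haplotypes = reg$haplotypes,
                 samples = smp, pop_names = model$pop_names,
                 region_id = region_id),
            class = "HaplotypeSet")
}

match_samples <- function(model, samples) {
  P <- length(model$pop_names)
  if (!is.null(names(samples))) {
    smp <- integer(P)
    unknown <- setdiff(names(samples), model$pop_names)
    assert_that(length(unknown) == 0, "samples name unknown populations: %s",
                paste(unknown, collapse = ", "))
    smp[match(names(samples), model$pop_names)] <- as.integer(samples)
  } else {
    assert_that(length(samples) == P,
                "unnamed samples must give one count per population")
    smp <- as.integer(samples)
  }
  assert_that(all(smp >= 0) && sum(smp) >= 2,
              "need at least two sampled gene copies overall")
  smp
}

#' Simulate a multi-region SNP dataset
#'
#' Simulates `n_regions` independent regions and assembles all segregating
#' sites into a [genotype_matrix()]. Consecutive haploid copies within each
#' population are paired into diploid individuals.
#'
#' @inheritParams simulate_region
#' @param diploid pair haplotypes into diploids (requires even haploid
#'   counts); if `FALSE` each copy becomes a (homozygous-coded) column.
#' @param n_regions number of regions (default: the model's).
#' @return a `GenotypeMatrix`; the derived allele is coded as ALT (`ref`
#'   "A", `alt` "C" by convention). Monomorphic regions contribute no
#'   sites.
#' @export
simulate_dataset <- function(model, samples, diploid = TRUE, seed = 1L,
                             n_regions = model$n_regions) {
  smp <- match_samples(model, samples)
  if (diploid)
    assert_that(all(smp %% 2L == 0L),
                "diploid output requires an even haploid count per population")
  res <- sim_regions_cpp(flatten_model(model), smp, as.integer(n_regions),
                         model$region_length, model$mu, as.numeric(seed), TRUE)
  pops_of_copy <- rep(model$pop_names, smp)

  if (diploid) {
    ind_of_copy <- rep(seq_len(sum(smp) / 2), each = 2)
    ind_pop <- pops_of_copy[!duplicated(ind_of_copy)]
    ind_ids <- paste0(ind_pop, "_", stats::ave(seq_along(ind_pop), ind_pop,
                                               FUN = seq_along))
  } else {
    ind_ids <- paste0(pops_of_copy, "_h",
                      stats::ave(seq_along(pops_of_copy), pops_of_copy,
                                 FUN = seq_along))
  }

  geno_list <- list(); pos_list <- list(); reg_list <- list()
  for (r in seq_len(n_regions)) {
    reg <- res$regions[[r]]
    if (length(reg$positions) == 0) next
    haps <- reg$haplotypes
    if (diploid) {
      odd <- seq(1, nrow(haps), by = 2)
      dos <- haps[odd, , drop = FALSE] + haps[odd + 1, , drop = FALSE]
    } else {
      dos <- 2L * haps
    }
    geno_list[[length(geno_list) + 1]] <- t(dos)
    pos_list[[length(pos_list) + 1]] <- reg$positions
    reg_list[[length(reg_list) + 1]] <- rep(sprintf("reg%05d", r),
                                            length(reg$positions))
  }
  if (length(geno_list) == 0)
    stop_fw("simulated dataset contains no segregating sites; increase theta or regions")
  geno <- do.call(rbind, geno_list)
  position <- unlist(pos_list)
  region_id <- unlist(reg_list)
  genotype_matrix(geno,
                  locus_id = paste0(region_id, ":", position),
                  region_id = region_id, position = position,
                  ref = rep("A", length(position)),
                  alt = rep("C", length(position)),
                  individual_ids = ind_ids)
}

#' Population map matching a simulated dataset
#' @param gm a `GenotypeMatrix` produced by [simulate_dataset()].
#' @return a `PopulationMap` read off the individual id prefixes.
#' @export
popmap_from_simulated <- function(gm) {
  population_map(gm$individual_ids, sub("_[^_]+$", "", gm$individual_ids))
}

# Fast path: per-site derived-allele counts per population (complete data),
# used by expected SFS estimation and ABC summaries.
simulate_site_counts <- function(model, samples, n_regions, seed) {
  smp <- match_samples(model, samples)
  res <- sim_regions_cpp(flatten_model(model), smp, as.integer(n_regions),
                         model$region_length, model$mu, as.numeric(seed), FALSE)
  list(counts = res$counts, region = res$region, n_sites = res$n_sites,
       samples = smp)
}

# Tally per-site derived counts into a joint SFS over the given populations
tally_joint_sfs <- function(counts, samples, pops_idx, pop_names,
                            folded = TRUE) {
  n <- samples[pops_idx]
  dims <- n + 1L
  sub <- counts[, pops_idx, drop = FALSE]
  stride <- cumprod(c(1, dims[-length(dims)]))
  lin <- 1L + as.vector(sub %*% stride)
  arr <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  out <- joint_sfs(arr, n, pop_names[pops_idx], folded = FALSE)
  if (folded) fold_sfs(out) else out
}
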