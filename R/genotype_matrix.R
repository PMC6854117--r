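#' SNP genotype matrix
#'
#' Container for biallelic SNP genotypes: one row per site, one column per
#' diploid individual. Genotypes are stored as alternate-allele dosages
#' (0, 1, 2) with `NA` for missing; half calls are treated as missing.
#' Sites carry a locus identifier, a region identifier (the capture locus a
#' site belongs to), a 1-based position within the region, the two alleles,
#' and an optional VCF quality score.
#'
#' @param geno integer matrix (sites x individuals) of dosages in
#'   `c(0, 1, 2, NA)`.
#' @param locus_id character vector of per-site identifiers.
#' @param region_id character vector grouping sites into capture regions.
#' @param position 1-based integer positions within the region.
#' @param ref,alt single-base reference / alternate alleles.
#' @param qual numeric site qualities (`NA` when absent).
#' @param individual_ids unique individual names; defaults to
#'   `colnames(geno)`.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(geno, locus_id, region_id, position, ref, alt,
                            qual = rep(NA_real_, nrow(geno)),
                            individual_ids = colnames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(ncol(geno)))
  assert_that(!anyDuplicated(individual_ids),
              "individual ids must be unique")
  assert_that(all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
              "genotype dosages must be 0, 1, 2 or NA")
  for (fld in list(locus_id = locus_id, region_id = region_id,
                   position = position, ref = ref, alt = alt, qual = qual))
    assert_that(length(fld) == n_sites,
                "all per-site fields must have one entry per site")
  assert_that(all(position >= 1), "positions are 1-based (>= 1)")
  ok_base <- function(x) all(x %in% c("A", "C", "G", "T"))
  assert_that(ok_base(ref) && ok_base(alt) && !any(ref == alt),
              "sites must be biallelic SNPs with distinct single-base alleles")
  colnames(geno) <- individual_ids
  structure(list(geno = geno,
                 locus_id = as.character(locus_id),
                 region_id = as.character(region_id),
                 position = as.integer(position),
                 ref = as.character(ref), alt = as.character(alt),
                 qual = as.numeric(qual),
                 individual_ids = as.character(individual_ids)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d sites x %d individuals, %d regions, %.1f%% missing\n",
              n_sites(x), n_individuals(x), length(unique(x$region_id)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `GenotypeMatrix`.
#' @export
n_sites <- function(gm) nrow(gm$geno)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(gm) ncol(gm$geno)

#' Per-site missing-genotype fraction
#' @param gm a `GenotypeMatrix`.
#' @return numeric vector in `[0, 1]`, one entry per site.
#' @export
missing_fraction <- function(gm) rowMeans(is.na(gm$geno))

# subset sites (logical or integer index), preserving order
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$geno[idx, , drop = FALSE],
                  gm$locus_id[idx], gm$region_id[idx], gm$position[idx],
                  gm$ref[idx], gm$alt[idx], gm$qual[idx],
                  gm$individual_ids)
}

#' Population map
#'
#' Assignment of individuals to population labels.
#'
#' @param individual character vector of individual ids.
#' @param population character vector of population labels (same length).
#' @return an object of class `PopulationMap`.
#' @export
population_map <- function(individual, population) {
  assert_that(length(individual) == length(population),
              "individual and population vectors must have equal length")
  assert_that(!anyDuplicated(individual),
              "each individual may appear only once in a population map")
  structure(list(individual = as.character(individual),
                 population = as.character(population)),
            class = "PopulationMap")
}

#' @export
print.PopulationMap <- function(x, ...) {
  tb <- table(x$population)
  cat("PopulationMap:", length(x$individual), "individuals,",
      length(tb), "populations\n")
  print(tb)
  invisible(x)
}

#' Check a population map against a genotype matrix
#'
#' Every individual in the genotype matrix must carry exactly one label and
#' every used population must be non-empty.
#'
#' @param pm a `PopulationMap`.
#' @param gm a `GenotypeMatrix`.
#' @return invisibly `TRUE`; errors name the offending individual.
#' @export
validate_popmap <- function(pm, gm) {
  missing_ind <- setdiff(gm$individual_ids, pm$individual)
  if (length(missing_ind) > 0)
    stop_fw("individuals missing from population map: %s",
            paste(missing_ind, collapse = ", "))
  extra <- setdiff(pm$individual, gm$individual_ids)
  if (length(extra) > 0)
    stop_fw("population map references individuals absent from the data: %s",
            paste(extra, collapse = ", "))
  invisible(TRUE)
}

# individuals (column indices of gm) belonging to population `pop`
pop_columns <- function(gm, pm, pop) {
  ids <- pm$individual[pm$population == pop]
  idx <- match(intersect(gm$individual_ids, ids), gm$individual_ids)
  if (length(idx) == 0) stop_fw("population '%s' has no individuals", pop)
  idx
}
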