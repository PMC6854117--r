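# Site filters applied ahead of the demographic analyses.

#' Filter sites by missing-data fraction
#'
#' Retains exactly the sites whose per-site missing fraction is less than
#' or equal to `max_missing`, preserving site order. Idempotent.
#'
#' @param gm a `GenotypeMatrix`.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return the filtered `GenotypeMatrix` (possibly with zero sites).
#' @export
filter_by_missingness <- function(gm, max_missing) {
  assert_that(is.numeric(max_missing) && length(max_missing) == 1 &&
                max_missing >= 0 && max_missing <= 1,
              "max_missing must be a single value in [0, 1]")
  subset_sites(gm, missing_fraction(gm) <= max_missing)
}

#' Keep one SNP per capture region
#'
#' Selects, for each `region_id`, the single site with the least missing
#' data; ties are broken by highest site quality (sites without a QUAL
#' score rank last), then by smallest position, then by input order. This
#' thins linked SNPs down to approximately independent markers.
#'
#' @param gm a `GenotypeMatrix` with `region_id` populated.
#' @return a `GenotypeMatrix` with exactly one site per region, in input
#'   order of the retained sites.
#' @export
one_snp_per_locus <- function(gm) {
  if (n_sites(gm) == 0) return(gm)
  miss <- missing_fraction(gm)
  qual <- ifelse(is.na(gm$qual), -Inf, gm$qual)
  ord <- order(gm$region_id, miss, -qual, gm$position, seq_len(n_sites(gm)),
               method = "radix")
  first <- ord[!duplicated(gm$region_id[ord])]
  subset_sites(gm, sort(first))
}
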