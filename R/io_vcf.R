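# VCF input/output.
#
# The reader supports the subset of VCF 4.x this pipeline consumes: diploid
# GT calls (phased or unphased), biallelic SNP records; multiallelic and
# non-SNP records are skipped with a logged count. CHROM is interpreted as
# the capture-region identifier, POS as the 1-based position within it.

#' Read SNP genotypes from a VCF file
#'
#' @param path path to a VCF 4.x text file with a GT field.
#' @return a [genotype_matrix()]; the number of skipped (multiallelic or
#'   non-SNP) records is reported via `message()` and attached as attribute
#'   `"n_skipped"`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_fw("cannot read VCF file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1)
    stop_fw("malformed VCF: expected exactly one #CHROM header line in %s", path)
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10)
    stop_fw("VCF has no sample columns: %s", path)
  inds <- header[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]

  n_skipped <- 0L
  rows <- vector("list", length(body))
  meta <- vector("list", length(body))
  gt_map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
              "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  bases <- c("A", "C", "G", "T")

  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop_fw("malformed VCF record at data line %d: expected %d fields, got %d",
              i, length(header), length(f))
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE) || !(ref %in% bases) || !(alt %in% bases)) {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_pos <- match("GT", fmt)
    if (is.na(gt_pos))
      stop_fw("VCF record at data line %d has no GT field", i)
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE),
                    function(x) x[gt_pos], character(1))
    dos <- unname(gt_map[calls])  # anything unrecognised (./., half calls) -> NA
    qual <- suppressWarnings(as.numeric(f[6]))
    id <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    rows[[i]] <- dos
    meta[[i]] <- list(locus_id = id, region_id = f[1],
                      position = as.integer(f[2]),
                      ref = ref, alt = alt, qual = qual)
  }

  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    stop_fw("no biallelic SNP records found in %s", path)
  geno <- do.call(rbind, rows[keep])
  colnames(geno) <- inds
  mt <- meta[keep]
  gm <- genotype_matrix(geno,
                        locus_id = vapply(mt, `[[`, character(1), "locus_id"),
                        region_id = vapply(mt, `[[`, character(1), "region_id"),
                        position = vapply(mt, `[[`, integer(1), "position"),
                        ref = vapply(mt, `[[`, character(1), "ref"),
                        alt = vapply(mt, `[[`, character(1), "alt"),
                        qual = vapply(mt, function(x) as.numeric(x$qual), numeric(1)),
                        individual_ids = inds)
  if (n_skipped > 0)
    fw_log(sprintf("read_vcf: skipped %d multiallelic/non-SNP records", n_skipped))
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF
#'
#' Missing genotypes are written as `./.`, absent qualities as `.`.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  g <- gm$geno
  calls <- matrix("./.", nrow(g), ncol(g))
  idx <- !is.na(g)
  calls[idx] <- gt_str[g[idx] + 1L]
  qual <- ifelse(is.na(gm$qual), ".", format(gm$qual, trim = TRUE, scientific = FALSE))
  recs <- paste(gm$region_id, gm$position, gm$locus_id, gm$ref, gm$alt,
                qual, ".", ".", "GT",
                apply(calls, 1, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=fwinvade",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individual_ids), collapse = "\t"),
               recs), con)
  invisible(path)
}

#' Read a population map
#'
#' Two-column tab-separated text: `individual<TAB>population`.
#'
#' @param path path to the file.
#' @return a [population_map()]; malformed lines raise an error naming the
#'   line number.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop_fw("cannot read population map: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0)
    stop_fw("population map %s: line %d is not two tab-separated fields",
            path, bad[1])
  population_map(vapply(parts, `[[`, character(1), 1),
                 vapply(parts, `[[`, character(1), 2))
}

#' @rdname read_popmap
#' @param pm a `PopulationMap`.
#' @export
write_popmap <- function(pm, path) {
  writeLines(paste(pm$individual, pm$population, sep = "\t"), path)
  invisible(path)
}
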