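# Joint site-frequency spectra: construction, folding, polarization,
# hypergeometric projection, marginalization, and a plain-text file dialect.

#' Joint site-frequency spectrum
#'
#' A k-dimensional array of site counts indexed by derived- (or minor-)
#' allele count per population: dimension `i` has extent `n_i + 1` for a
#' haploid sample size of `n_i`. The monomorphic corner cells (all-zero,
#' and all-`n` when unfolded) are masked out of likelihood computations.
#'
#' @param counts non-negative array (vector for k = 1).
#' @param sample_sizes haploid sample sizes `n_i`; defaults to `dim - 1`.
#' @param pops population labels.
#' @param folded logical: is this a minor-allele (folded) spectrum?
#' @return object of class `JointSFS`.
#' @export
joint_sfs <- function(counts, sample_sizes = NULL, pops = NULL, folded = FALSE) {
  if (is.null(dim(counts))) counts <- array(counts, dim = length(counts))
  d <- dim(counts)
  if (is.null(sample_sizes)) sample_sizes <- d - 1L
  assert_that(all(d == sample_sizes + 1L),
              "counts array extents must equal sample_sizes + 1")
  assert_that(all(counts >= 0), "SFS counts must be non-negative")
  if (is.null(pops)) pops <- paste0("pop", seq_along(d))
  structure(list(counts = counts, sample_sizes = as.integer(sample_sizes),
                 pops = as.character(pops), folded = isTRUE(folded)),
            class = "JointSFS")
}

#' @export
print.JointSFS <- function(x, ...) {
  cat(sprintf("JointSFS (%s): %s; %d pops (%s); %.1f sites in unmasked cells\n",
              if (x$folded) "folded" else "unfolded",
              paste(dim(x$counts), collapse = " x "),
              length(x$pops), paste(x$pops, collapse = ", "),
              sum(x$counts[sfs_mask(x)])))
  invisible(x)
}

#' Mask of informative (polymorphic) cells
#'
#' @param sfs a `JointSFS`.
#' @return logical array, `TRUE` for cells that enter likelihoods: the
#'   all-zero corner is always masked; the all-`n` corner additionally when
#'   the spectrum is unfolded.
#' @export
sfs_mask <- function(sfs) {
  d <- dim(sfs$counts)
  m <- array(TRUE, dim = d)
  m[matrix(1L, 1, length(d))] <- FALSE
  if (!sfs$folded) m[matrix(d, 1, length(d))] <- FALSE
  m
}

# all index vectors (0-based derived counts) of the array, rows = cells
sfs_cell_index <- function(dims) {
  arrayInd(seq_len(prod(dims)), dims) - 1L
}

# The fold mapping depends only on the array dimensions; it is expensive
# to derive for large joint arrays and is recomputed on every likelihood
# evaluation during fitting, so it is memoized per dimension vector.
.fold_cache <- new.env(parent = emptyenv())

fold_map <- function(d) {
  key <- paste(d, collapse = "x")
  hit <- .fold_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- d - 1L
  idx <- sfs_cell_index(d)
  comp <- matrix(rep(n, each = nrow(idx)), nrow(idx)) - idx
  tot <- rowSums(idx)
  half <- sum(n) / 2
  # lexicographic comparison idx vs comp for midpoint cells
  lex_smaller <- rep(FALSE, nrow(idx))
  undecided <- rep(TRUE, nrow(idx))
  for (j in seq_len(ncol(idx))) {
    lt <- undecided & (idx[, j] < comp[, j])
    gt <- undecided & (idx[, j] > comp[, j])
    lex_smaller[lt] <- TRUE
    undecided[lt | gt] <- FALSE
  }
  keep <- tot < half | (tot == half & (lex_smaller | undecided))
  lin_self <- which(keep)
  lin_comp <- 1L + as.vector((comp[lin_self, , drop = FALSE]) %*%
                               cumprod(c(1, d[-length(d)])))
  map <- list(lin_self = lin_self,
              lin_comp = ifelse(lin_comp == lin_self, NA_integer_, lin_comp))
  if (length(.fold_cache) < 32) .fold_cache[[key]] <- map
  map
}

#' Fold a spectrum on total derived count
#'
#' Each cell `v` is combined with its complement `n - v`; mass lands on the
#' cell whose total count is below the midpoint `sum(n)/2`. When the total
#' equals the midpoint exactly, the lexicographically smaller index vector
#' keeps the mass (midpoint self-complementary cells are kept once).
#'
#' @param sfs an unfolded `JointSFS`.
#' @return the folded `JointSFS`.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) return(sfs)
  d <- dim(sfs$counts)
  map <- fold_map(d)
  vals <- as.vector(sfs$counts)
  out <- array(0, dim = d)
  comp_vals <- vals[map$lin_comp]
  comp_vals[is.na(map$lin_comp)] <- 0
  out[map$lin_self] <- vals[map$lin_self] + comp_vals
  joint_sfs(out, sfs$sample_sizes, sfs$pops, folded = TRUE)
}

#' Build a joint SFS from genotypes
#'
#' Each usable site contributes one count (or, under projection, a
#' hypergeometric spread of one count) to the cell of its per-population
#' derived-allele counts. With `project_to = NULL` only sites fully
#' genotyped in every requested population are used; with projection, any
#' site with at least `project_to[i]` called gene copies in population `i`
#' contributes its expected spectrum at the reduced sizes.
#'
#' @param gm a `GenotypeMatrix` (dosages count the ALT allele; polarize
#'   first with [polarize_with_outgroup()] for an unfolded spectrum).
#' @param pm a `PopulationMap`.
#' @param pops population labels, in the axis order wanted.
#' @param folded fold the spectrum on total derived count (default `TRUE`,
#'   appropriate when ancestral alleles are unknown).
#' @param project_to optional haploid sizes to project down to; use e.g.
#'   `round(0.9 * sizes)` to rescue sites with scattered missingness.
#' @return a `JointSFS`. Counts may be fractional under projection.
#' @export
compute_joint_sfs <- function(gm, pm, pops, folded = TRUE, project_to = NULL) {
  absent <- setdiff(pops, unique(pm$population))
  if (length(absent) > 0)
    stop_fw("requested population(s) absent from population map: %s",
            paste(absent, collapse = ", "))
  cols <- lapply(pops, function(p) pop_columns(gm, pm, p))
  full_n <- vapply(cols, function(ix) 2L * length(ix), integer(1))

  S <- n_sites(gm)
  k <- length(pops)
  copies <- derived <- matrix(0L, S, k)
  for (j in seq_len(k)) {
    sub <- gm$geno[, cols[[j]], drop = FALSE]
    copies[, j] <- 2L * as.integer(rowSums(!is.na(sub)))
    derived[, j] <- as.integer(rowSums(sub, na.rm = TRUE))
  }

  if (is.null(project_to)) {
    dims <- full_n + 1L
    counts <- array(0, dim = dims)
    use <- rowSums(copies == rep(full_n, each = S)) == k
    if (any(use)) {
      stride <- cumprod(c(1, dims[-k]))
      lin <- 1L + as.vector(derived[use, , drop = FALSE] %*% stride)
      tab <- tabulate(lin, nbins = prod(dims))
      counts <- array(counts + tab, dim = dims)
    }
    out <- joint_sfs(counts, full_n, pops, folded = FALSE)
  } else {
    assert_that(length(project_to) == k && all(project_to >= 2) &&
                  all(project_to <= full_n),
                "project_to must give a haploid size (2..full size) per population")
    proj <- as.integer(project_to)
    dims <- proj + 1L
    counts <- array(0, dim = dims)
    use <- which(rowSums(copies >= rep(proj, each = S)) == k)
    for (s in use) {
      w <- lapply(seq_len(k), function(j)
        dhyper(0:proj[j], derived[s, j], copies[s, j] - derived[s, j], proj[j]))
      contrib <- Reduce(function(a, b) outer(a, b), w)
      counts <- counts + array(contrib, dim = dims)
    }
    out <- joint_sfs(counts, proj, pops, folded = FALSE)
  }
  if (folded) fold_sfs(out) else out
}

#' Polarize genotypes with an outgroup consensus
#'
#' Recode alleles so that dosage counts the allele differing from the
#' outgroup base. Sites whose outgroup base is unknown (`NA`) or matches
#' neither allele are dropped, with counts reported.
#'
#' @param gm a `GenotypeMatrix`.
#' @param outgroup_alleles character vector, one base (or `NA`) per site.
#' @return a `GenotypeMatrix` whose ALT allele is the derived allele;
#'   attributes `n_dropped_unknown` and `n_dropped_mismatch` count removals.
#' @export
polarize_with_outgroup <- function(gm, outgroup_alleles) {
  assert_that(length(outgroup_alleles) == n_sites(gm),
              "need one outgroup base per site")
  og <- toupper(as.character(outgroup_alleles))
  is_ref <- !is.na(og) & og == gm$ref
  is_alt <- !is.na(og) & og == gm$alt
  drop_unknown <- is.na(og)
  drop_mismatch <- !is.na(og) & !is_ref & !is_alt

  geno <- gm$geno
  flip <- which(is_alt)
  if (length(flip) > 0)
    geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  ref <- gm$ref; alt <- gm$alt
  ref[flip] <- gm$alt[flip]
  alt[flip] <- gm$ref[flip]

  keep <- is_ref | is_alt
  out <- genotype_matrix(geno[keep, , drop = FALSE],
                         gm$locus_id[keep], gm$region_id[keep],
                         gm$position[keep], ref[keep], alt[keep],
                         gm$qual[keep], gm$individual_ids)
  n_unk <- sum(drop_unknown); n_mis <- sum(drop_mismatch)
  if (n_unk + n_mis > 0)
    fw_log(sprintf("polarize: dropped %d sites (outgroup unknown) + %d (matches neither allele)",
                   n_unk, n_mis))
  attr(out, "n_dropped_unknown") <- n_unk
  attr(out, "n_dropped_mismatch") <- n_mis
  out
}

#' Two-population margin of a joint spectrum
#'
#' Sums a k-dimensional spectrum over all axes except `i` and `j`.
#'
#' @param sfs a `JointSFS` with `k >= 2`.
#' @param i,j axis indices (or population labels) to retain.
#' @return a 2-D `JointSFS` carrying the same `folded` flag.
#' @export
marginal_pairwise_sfs <- function(sfs, i, j) {
  k <- length(dim(sfs$counts))
  assert_that(k >= 2, "need at least two populations to marginalize")
  if (is.character(i)) i <- match(i, sfs$pops)
  if (is.character(j)) j <- match(j, sfs$pops)
  assert_that(!is.na(i) && !is.na(j) && i != j && i >= 1 && j <= k,
              "invalid axis selection for marginal_pairwise_sfs")
  m <- apply(sfs$counts, c(i, j), sum)
  joint_sfs(m, sfs$sample_sizes[c(i, j)], sfs$pops[c(i, j)],
            folded = sfs$folded)
}

#' Read / write the SFS text dialect
#'
#' Format: a header line `#dims d1 d2 ... folded|unfolded` (array extents,
#' i.e. haploid size + 1 per population), then whitespace-separated counts
#' in row-major order (last axis fastest).
#'
#' @param sfs a `JointSFS`.
#' @param path file path.
#' @return `write_sfs` returns `path` invisibly; `read_sfs` returns the
#'   `JointSFS`.
#' @export
write_sfs <- function(sfs, path) {
  d <- dim(sfs$counts)
  header <- paste("#dims", paste(d, collapse = " "),
                  if (sfs$folded) "folded" else "unfolded")
  flat <- as.vector(aperm(sfs$counts, rev(seq_along(d))))
  writeLines(c(header, paste(format(flat, trim = TRUE, digits = 15),
                             collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  if (!file.exists(path)) stop_fw("cannot read SFS file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#dims"))
    stop_fw("malformed SFS file %s: line 1 must start with '#dims'", path)
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]][-1]
  fold_tok <- toks[length(toks)]
  if (!fold_tok %in% c("folded", "unfolded"))
    stop_fw("malformed SFS file %s: line 1 must end with 'folded' or 'unfolded'", path)
  d <- as.integer(toks[-length(toks)])
  vals <- suppressWarnings(as.numeric(strsplit(trimws(paste(lines[-1], collapse = " ")),
                                               "\\s+")[[1]]))
  if (anyNA(vals) || length(vals) != prod(d))
    stop_fw("malformed SFS file %s: expected %d numeric counts", path, prod(d))
  arr <- aperm(array(vals, dim = rev(d)), rev(seq_along(d)))
  joint_sfs(arr, d - 1L, folded = fold_tok == "folded")
}
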