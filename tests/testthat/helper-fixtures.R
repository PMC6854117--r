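# Shared helpers: tiny in-code fixtures and independent oracles.

# small genotype matrix with explicit dosages
toy_gm <- function(geno, region = NULL, qual = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  S <- nrow(geno)
  genotype_matrix(geno,
                  locus_id = paste0("site", seq_len(S)),
                  region_id = region %||% paste0("reg", seq_len(S)),
                  position = pos %||% seq_len(S),
                  ref = rep("A", S), alt = rep("C", S),
                  qual = qual %||% rep(NA_real_, S),
                  individual_ids = colnames(geno) %||%
                    paste0("ind", seq_len(ncol(geno))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Weir & Cockerham (1984) oracle: literal per-locus textbook
# formulas, scalar loops only. dos: loci x individuals; pops: labels.
wc_oracle <- function(dos, pops) {
  pops <- as.character(pops)
  labels <- unique(pops)
  r <- length(labels)
  A <- B <- C <- 0
  for (l in seq_len(nrow(dos))) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      g <- dos[l, pops == labels[k]]
      g <- g[!is.na(g)]
      n[k] <- length(g)
      if (n[k] == 0) next
      p[k] <- sum(g) / (2 * n[k])
      h[k] <- sum(g == 1) / n[k]
    }
    if (any(n < 1) || sum(n) <= r) next
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!all(is.finite(c(a, b, cc)))) next
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# brute-force fold: pair every cell with its complement, midpoint cells by
# lexicographic rule, plain loops
fold_oracle <- function(arr, n) {
  d <- dim(arr)
  out <- array(0, dim = d)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    comp <- n - v
    tot <- sum(v); half <- sum(n) / 2
    keep <- if (tot < half) TRUE
            else if (tot > half) FALSE
            else {
              cmpv <- which(v != comp)
              if (length(cmpv) == 0) TRUE else v[cmpv[1]] < comp[cmpv[1]]
            }
    if (keep) {
      lin_self <- r
      lin_comp <- 1 + sum(comp * cumprod(c(1, d[-length(d)])))
      out[lin_self] <- arr[lin_self] +
        if (lin_comp == lin_self) 0 else arr[lin_comp]
    }
  }
  out
}

# mean pairwise mismatch among all gene copies (diversity oracle);
# dosage d codes copies {0,1} (d=1), {0,0} (0) or {1,1} (2)
pi_oracle <- function(dos, total_length) {
  tot <- 0
  n_sites_used <- 0
  for (l in seq_len(nrow(dos))) {
    g <- dos[l, !is.na(dos[l, ])]
    copies <- unlist(lapply(g, function(x) switch(as.character(x),
                                                  "0" = c(0, 0),
                                                  "1" = c(0, 1),
                                                  "2" = c(1, 1))))
    n <- length(copies)
    if (n < 2) next
    pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      pairs <- pairs + abs(copies[i] - copies[j])
    tot <- tot + pairs / choose(n, 2)
  }
  tot / total_length
}

# small split model used across tests
split_model <- function(T_split, N = 5000, mu = 2.5e-7, n_regions = 200) {
  demographic_model(c("a", "b"), c(N, N),
                    events = list(event_fusion(T_split, "a", "b")),
                    mu = mu, region_length = 214, n_regions = n_regions)
}
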