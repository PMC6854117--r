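# sfs_tools: joint spectra, folding, polarization, margins, projection

test_that("compute_joint_sfs tallies hand-enumerated sites", {
  # 2 pops, 1 diploid each (n = 2 haploids), derived counts per site:
  # (1,0), (1,0), (2,1)
  geno <- rbind(c(1L, 0L), c(1L, 0L), c(2L, 1L))
  gm <- toy_gm(geno)
  pm <- population_map(c("ind1", "ind2"), c("A", "B"))
  sfs <- compute_joint_sfs(gm, pm, c("A", "B"), folded = FALSE)
  expected <- array(0, dim = c(3, 3))
  expected[2, 1] <- 2  # cell (1,0)
  expected[3, 2] <- 1  # cell (2,1)
  expect_equal(sfs$counts, expected)
  # monomorphic matrix -> all unmasked cells zero
  sfs0 <- compute_joint_sfs(toy_gm(matrix(0L, 4, 2)), pm, c("A", "B"),
                            folded = FALSE)
  expect_equal(sum(sfs0$counts[sfs_mask(sfs0)]), 0)
})

test_that("folding matches the brute-force complement-pairing oracle", {
  set.seed(8)
  for (dims in list(c(5, 4), c(3, 3, 4), 7)) {
    arr <- array(rpois(prod(dims), 3), dim = dims)
    n <- dims - 1L
    folded <- fold_sfs(joint_sfs(arr, folded = FALSE))
    expect_equal(folded$counts, fold_oracle(arr, n))
    # conservation: total mass invariant under folding
    expect_equal(sum(folded$counts), sum(arr))
  }
})

test_that("polarize_with_outgroup recodes by the outgroup base", {
  geno <- rbind(c(0L, 1L), c(2L, 1L), c(0L, 2L))
  gm <- toy_gm(geno)  # ref A, alt C everywhere
  # outgroup = ref everywhere: unchanged
  p1 <- polarize_with_outgroup(gm, c("A", "A", "A"))
  expect_equal(p1$geno, gm$geno)
  # outgroup = alt at site 2: dosages flipped there, alleles swapped
  p2 <- polarize_with_outgroup(gm, c("A", "C", "A"))
  expect_equal(unname(p2$geno[2, ]), c(0L, 1L))
  expect_equal(p2$ref[2], "C")
  expect_equal(p2$alt[2], "A")
  # outgroup matching neither allele: dropped and counted
  p3 <- polarize_with_outgroup(gm, c("A", "G", NA))
  expect_equal(n_sites(p3), 1L)
  expect_equal(attr(p3, "n_dropped_mismatch"), 1L)
  expect_equal(attr(p3, "n_dropped_unknown"), 1L)
})

test_that("pairwise margins equal brute-force summation", {
  set.seed(9)
  arr <- array(rpois(4 * 3 * 5, 2), dim = c(4, 3, 5))
  sfs <- joint_sfs(arr, folded = FALSE, pops = c("P", "Q", "R"))
  m12 <- marginal_pairwise_sfs(sfs, 1, 2)
  expect_equal(m12$counts, apply(arr, c(1, 2), sum))
  m13 <- marginal_pairwise_sfs(sfs, "P", "R")
  expect_equal(m13$counts, apply(arr, c(1, 3), sum))
  expect_equal(sum(m13$counts), sum(arr))  # conservation, no masking
  # k = 2 margin is the identity
  sfs2 <- joint_sfs(arr[, , 1], folded = FALSE)
  expect_equal(marginal_pairwise_sfs(sfs2, 1, 2)$counts, arr[, , 1])
  expect_error(compute_joint_sfs(toy_gm(matrix(0L, 2, 2)),
                                 population_map(c("ind1", "ind2"), c("A", "A")),
                                 c("A", "Z")), "absent")
})

test_that("hypergeometric projection: identity at full size, mass preserved, missing rescued", {
  geno <- rbind(c(0L, 1L, 2L, 1L), c(1L, 1L, 0L, 0L), c(2L, 2L, 1L, 0L))
  gm <- toy_gm(geno)
  pm <- population_map(paste0("ind", 1:4), c("A", "A", "B", "B"))
  full <- compute_joint_sfs(gm, pm, c("A", "B"), folded = FALSE)
  proj_full <- compute_joint_sfs(gm, pm, c("A", "B"), folded = FALSE,
                                 project_to = c(4, 4))
  expect_equal(proj_full$counts, full$counts, tolerance = 1e-12)
  # a site missing one genotype is skipped complete-case but contributes
  # (fractionally, total mass 1) under projection to the observed copies
  geno_na <- geno; geno_na[1, 4] <- NA
  gm_na <- toy_gm(geno_na)
  cc <- compute_joint_sfs(gm_na, pm, c("A", "B"), folded = FALSE)
  pr <- compute_joint_sfs(gm_na, pm, c("A", "B"), folded = FALSE,
                          project_to = c(4, 2))
  expect_equal(sum(cc$counts), 2)
  expect_equal(sum(pr$counts), 3, tolerance = 1e-12)
  # projected cell weights are hypergeometric: check one site by hand
  one <- toy_gm(rbind(c(1L, 1L, 2L, NA)))
  pr1 <- compute_joint_sfs(one, pm, c("A", "B"), folded = FALSE,
                           project_to = c(2, 2))
  # pop A: 2 derived of 4 copies -> dhyper(j; 2, 2, 2); pop B: 2 of 2
  wA <- dhyper(0:2, 2, 2, 2)
  expected <- outer(wA, c(0, 0, 1))
  expect_equal(pr1$counts, expected, tolerance = 1e-12)
})

test_that("mask excludes the monomorphic corners", {
  u <- joint_sfs(array(1, dim = c(3, 3)), folded = FALSE)
  mu_ <- sfs_mask(u)
  expect_false(mu_[1, 1]); expect_false(mu_[3, 3])
  expect_equal(sum(mu_), 7L)
  f <- joint_sfs(array(1, dim = c(3, 3)), folded = TRUE)
  mf <- sfs_mask(f)
  expect_false(mf[1, 1]); expect_true(mf[3, 3])
})
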