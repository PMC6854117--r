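# coalescent_core: closed-form oracles and structural contracts

test_that("panmictic segregating sites match Watterson's closed form", {
  N <- 1000; mu <- 2.5e-8; l <- 214
  m <- demographic_model("p1", N, mu = mu, region_length = l)
  sim <- fwinvade:::simulate_site_counts(m, c(p1 = 10), 2000, seed = 42)
  S <- sim$n_sites
  expected <- 2 * N * mu * l * sum(1 / (1:9))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("n = 2 pairwise differences match theta (and mean tree length 4N diploid)", {
  N <- 1000; mu <- 2.5e-7; l <- 214
  m <- demographic_model("p1", N, mu = mu, region_length = l)
  sim <- fwinvade:::simulate_site_counts(m, c(p1 = 2), 4000, seed = 7)
  S <- sim$n_sites
  # E[S] = mu*l*E[tree length], tree length for n=2 is 2*T2 with E[T2]=N
  expected <- 2 * N * mu * l
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("fixed seed reproduces haplotypes; seed streams are per-region", {
  m <- split_model(1000)
  r1 <- simulate_region(m, c(a = 6, b = 6), seed = 11)
  r2 <- simulate_region(m, c(a = 6, b = 6), seed = 11)
  expect_identical(r1$haplotypes, r2$haplotypes)
  expect_identical(r1$positions, r2$positions)
  # extending the region count must not reshuffle earlier regions
  a <- fwinvade:::simulate_site_counts(m, c(a = 6, b = 6), 20, seed = 3)
  b <- fwinvade:::simulate_site_counts(m, c(a = 6, b = 6), 40, seed = 3)
  expect_identical(a$counts, b$counts[b$region <= 20, , drop = FALSE])
})

test_that("simulate_dataset pairs haplotypes into diploids and drops monomorphic regions", {
  m <- split_model(1000, n_regions = 30)
  gm <- simulate_dataset(m, c(a = 4, b = 4), seed = 2, n_regions = 30)
  expect_equal(n_individuals(gm), 4L)  # 8 haplotypes -> 4 diploids
  expect_true(all(table(popmap_from_simulated(gm)$population) == 2))
  # monomorphic regions contribute zero sites: region ids present only
  # when the region segregates
  res <- fwinvade:::simulate_site_counts(m, c(a = 4, b = 4), 30, seed = 2)
  expect_setequal(unique(gm$region_id),
                  sprintf("reg%05d", which(res$n_sites > 0)))
  expect_error(simulate_dataset(m, c(a = 3, b = 4), seed = 1),
               "even haploid")
})

test_that("island model mean Fst matches 1/(1 + 4Nm)", {
  # 10 demes, diploid-N convention: 4Nm = 2 * N_hap * m = 1
  im <- island_model(10, 1000, m = 5e-4, mu = 2.5e-7, region_length = 214)
  gm <- simulate_dataset(im, setNames(rep(10L, 10), paste0("deme", 1:10)),
                         seed = 11, n_regions = 2500)
  pm <- popmap_from_simulated(gm)
  lab <- pm$population[match(gm$individual_ids, pm$individual)]
  theta <- fwinvade:::wc_theta(fwinvade:::wc_abc(gm$geno, lab))
  expect_lt(abs(theta - 0.5), 0.05)
})

test_that("label exchangeability: permuting populations with their sizes leaves summaries unchanged", {
  mk <- function(sizes, names) {
    mig <- matrix(1e-3, 2, 2); diag(mig) <- 0
    demographic_model(names, sizes, migration = mig, mu = 2.5e-7,
                      region_length = 214)
  }
  m1 <- mk(c(3000, 9000), c("x", "y"))
  m2 <- mk(c(9000, 3000), c("y", "x"))
  s1 <- fwinvade:::simulate_site_counts(m1, c(x = 8, y = 8), 600, seed = 5)
  s2 <- fwinvade:::simulate_site_counts(m2, c(y = 8, x = 8), 600, seed = 99)
  # mean derived count in pop x (column 1 of m1, column 2 of m2)
  mean1 <- c(mean(s1$counts[, 1]), mean(s1$counts[, 2]))
  mean2 <- c(mean(s2$counts[, 2]), mean(s2$counts[, 1]))
  expect_lt(abs(mean1[1] - mean2[1]), 0.2)
  expect_lt(abs(mean1[2] - mean2[2]), 0.2)
  expect_lt(abs(mean(s1$n_sites) - mean(s2$n_sites)),
            3 * (sd(s1$n_sites) + sd(s2$n_sites)) / sqrt(600))
})

test_that("between-population Fst increases with divergence time", {
  fst_at <- function(Tsplit) {
    gm <- simulate_dataset(split_model(Tsplit, mu = 2.5e-7), c(a = 20, b = 20),
                           seed = 3, n_regions = 300)
    pm <- popmap_from_simulated(gm)
    pairwise_fst(gm, pm, n_perm = 0)$fst[1, 2]
  }
  fsts <- vapply(c(200, 1000, 5000), fst_at, numeric(1))
  expect_true(all(diff(fsts) > 0))
})

test_that("models that cannot coalesce are rejected; config round trips", {
  expect_error(demographic_model(c("a", "b"), c(100, 100)),
               "never fully coalesces")
  m <- demographic_model(c("a", "b"), c(100, 200),
                         events = list(event_fusion(50, "a", "b")),
                         mu = 1e-8, n_regions = 10, region_length = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(m, path)
  back <- read_model_config(path)
  expect_equal(back$sizes, m$sizes)
  expect_equal(back$pop_names, m$pop_names)
  expect_equal(length(back$events), 1L)
  expect_equal(back$events[[1]]$time, 50)
  # diploid convention doubles sizes
  md <- demographic_model("p", 500, mu = 1e-8, diploid_size = TRUE)
  expect_equal(md$sizes, 1000)
})
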