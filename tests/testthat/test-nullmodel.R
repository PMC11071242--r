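test_that("permutation preserves richness and depth on every iteration", {
  set.seed(21)
  counts <- matrix(rpois(12 * 6, 8), nrow = 12,
                   dimnames = list(sprintf("t%02d", 1:12),
                                   sprintf("s%d", 1:6)))
  storage.mode(counts) <- "integer"
  pool <- c(rownames(counts), sprintf("x%02d", 1:8))
  rich0 <- colSums(counts > 0)
  tot0 <- colSums(counts)
  for (it in 1:100) {
    p <- permute_matrix(counts, pool, seed = it)
    expect_identical(unname(colSums(p > 0)), unname(rich0))
    expect_identical(unname(colSums(p)), unname(tot0))
  }
  # pool must cover every occupied taxon, and every sample's richness
  expect_error(permute_matrix(counts, pool = rownames(counts)[1:3]),
               "pool must contain")
  # pool of size k with k equally-filled taxa: only one possible outcome
  eq <- matrix(c(5L, 5L, 5L), ncol = 1,
               dimnames = list(c("a", "b", "c"), "s1"))
  expect_identical(permute_matrix(eq, c("a", "b", "c"), seed = 99), eq)
})

test_that("null moments match exhaustive enumeration on a tiny pool", {
  # two samples, richness 2 each, series pool of 4 taxa (a third sample
  # carries the fourth taxon so the observed union is the full pool)
  counts <- matrix(0L, nrow = 4, ncol = 3,
                   dimnames = list(c("t1", "t2", "t3", "t4"),
                                   c("sA", "sB", "sC")))
  counts["t1", "sA"] <- 5L; counts["t2", "sA"] <- 3L
  counts["t1", "sB"] <- 4L; counts["t3", "sB"] <- 2L
  counts["t4", "sC"] <- 7L
  meta <- make_meta(c("sA", "sB", "sC"), time_days = c(2, 2, 9))
  ds <- new_dataset(counts, meta)
  pairs <- dispersion_pairs(ds)
  expect_equal(nrow(pairs), 1L)

  nz <- null_zscores(ds, pairs, n_resamples = 10000, seed = 31)
  ex <- enum_null_moments(c(5L, 3L), c(4L, 2L), P = 4)

  R <- 10000
  se_mu <- ex$sigma / sqrt(R)
  # delta-method SE of the sample SD from the exact fourth moment
  se_sigma <- sqrt((ex$mu4 - ex$sigma^4) / R) / (2 * ex$sigma)
  expect_lt(abs(nz$mu_expected - ex$mu), 3 * se_mu)
  expect_lt(abs(nz$sigma_expected - ex$sigma), 3 * se_sigma)
  expect_equal(nz$z, (nz$u_observed - nz$mu_expected) / nz$sigma_expected,
               tolerance = 1e-12)
})

test_that("null summaries are bit-identical under a fixed seed", {
  sim <- sim_preset("mammal", n_studies = 2, series_per_study = 1, seed = 3)
  ds <- filter_replicates(rarefy(simulate_dataset(sim)$dataset, 1500,
                                 seed = 3))
  pairs <- dplyr::bind_rows(dispersion_pairs(ds), turnover_pairs(ds))
  a <- null_zscores(ds, pairs, n_resamples = 60, seed = 17)
  b <- null_zscores(ds, pairs, n_resamples = 60, seed = 17)
  expect_identical(a, b)
  c2 <- null_zscores(ds, pairs, n_resamples = 60, seed = 18)
  expect_false(identical(a$mu_expected, c2$mu_expected))
})

test_that("null expectations are invariant to taxon relabeling", {
  set.seed(5)
  counts <- matrix(0L, nrow = 10, ncol = 2,
                   dimnames = list(sprintf("t%02d", 1:10), c("s1", "s2")))
  counts[1:4, 1] <- c(9L, 5L, 3L, 1L)
  counts[3:8, 2] <- c(7L, 4L, 2L, 2L, 1L, 1L)
  meta <- make_meta(c("s1", "s2"), time_days = 1)
  ds <- new_dataset(counts, meta)
  pairs <- dispersion_pairs(ds)
  nz1 <- null_zscores(ds, pairs, n_resamples = 4000, seed = 7)

  perm <- sample(nrow(counts))
  counts2 <- counts[perm, , drop = FALSE]
  ds2 <- new_dataset(counts2, meta)
  nz2 <- null_zscores(ds2, dispersion_pairs(ds2), n_resamples = 4000,
                      seed = 1234)
  # identical observed value; null moments agree within Monte-Carlo error
  expect_equal(nz1$u_observed, nz2$u_observed, tolerance = 1e-12)
  se <- nz1$sigma_expected / sqrt(4000)
  expect_lt(abs(nz1$mu_expected - nz2$mu_expected), 4 * se)
})

test_that("Z-scores center on zero when the data are generated by the null", {
  ds <- make_null_true_dataset(n_series = 170, pool_size = 20,
                               richness = 10, timepoints = 6, seed = 2)
  pairs <- dispersion_pairs(ds)
  expect_gte(nrow(pairs), 1000)
  nz <- null_zscores(ds, pairs, n_resamples = 250, seed = 4)
  expect_lt(abs(mean(nz$z, na.rm = TRUE)), 0.1)
})

test_that("degenerate pairs with zero null variance are flagged, not scored", {
  # one taxon in the pool: every permutation is the identity
  counts <- matrix(c(5L, 7L), nrow = 1,
                   dimnames = list("t1", c("s1", "s2")))
  ds <- new_dataset(counts, make_meta(c("s1", "s2"), time_days = 1))
  pairs <- dispersion_pairs(ds)
  expect_warning(nz <- null_zscores(ds, pairs, n_resamples = 50, seed = 1),
                 "zero null SD")
  expect_true(is.na(nz$z))
  expect_equal(nz$sigma_expected, 0)
})
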