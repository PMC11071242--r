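test_that("Bray-Curtis matches its closed form, a loop oracle, and vegan", {
  expect_identical(bray_curtis(c(3, 1, 0), c(3, 1, 0)), 0)
  expect_identical(bray_curtis(c(4, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 0)), 8 / 12,
               tolerance = 1e-12)
  expect_error(bray_curtis(c(0, 0), c(1, 2)), "all zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")

  set.seed(11)
  for (i in 1:500) {
    x <- rpois(25, 4)
    y <- rpois(25, 4)
    if (all(x == 0) || all(y == 0)) next
    expect_equal(bray_curtis(x, y), bc_loop(x, y), tolerance = 1e-12)
  }
  # cross-check against vegan's implementation
  set.seed(12)
  m <- matrix(rpois(40, 6), nrow = 4)
  vd <- as.matrix(vegan::vegdist(m, method = "bray"))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(bray_curtis(m[i, ], m[j, ]), vd[i, j], tolerance = 1e-12)
  }
})

test_that("dispersion pairs enumerate replicates and exclude shared units", {
  counts <- matrix(rpois(6 * 10, 50), nrow = 6,
                   dimnames = list(paste0("t", 1:6), sprintf("s%02d", 1:10)))
  storage.mode(counts) <- "integer"

  # 3 replicates, distinct units -> C(3,2) = 3 pairs
  ds3 <- new_dataset(counts[, 1:3], make_meta(sprintf("s%02d", 1:3),
                                              time_days = 5))
  expect_equal(nrow(dispersion_pairs(ds3)), 3)

  # 4 replicates, two sharing a unit -> 6 - 1 = 5 pairs
  ds4 <- new_dataset(counts[, 1:4],
                     make_meta(sprintf("s%02d", 1:4), time_days = 5,
                               unit_id = c("uA", "uA", "uB", "uC")))
  expect_equal(nrow(dispersion_pairs(ds4)), 5)

  # all replicates from one unit -> nothing to compare
  ds0 <- new_dataset(counts[, 1:3],
                     make_meta(sprintf("s%02d", 1:3), time_days = 5,
                               unit_id = rep("uA", 3)))
  expect_equal(nrow(dispersion_pairs(ds0)), 0)

  # records carry the shared time point and ordered ids
  p <- dispersion_pairs(ds4)
  expect_true(all(p$time_days == 5))
  expect_true(all(p$sample_a < p$sample_b))
  expect_true(all(p$value >= 0 & p$value <= 1))
})

test_that("turnover pairs take the controls-by-recovery product within the horizon", {
  counts <- matrix(rpois(6 * 12, 50), nrow = 6,
                   dimnames = list(paste0("t", 1:6), sprintf("s%02d", 1:12)))
  storage.mode(counts) <- "integer"

  # 3 controls x 3 replicates at day 7 -> 9 pairs, all at time 7
  ds <- new_dataset(counts[, 1:6],
                    make_meta(sprintf("s%02d", 1:6),
                              time_days = c(-1, -1, -1, 7, 7, 7)))
  p <- turnover_pairs(ds)
  expect_equal(nrow(p), 9)
  expect_true(all(p$time_days == 7))

  # 3 controls x (3 at day 2, 3 at day 10) -> 18 pairs
  ds2 <- new_dataset(counts[, 1:9],
                     make_meta(sprintf("s%02d", 1:9),
                               time_days = c(-1, -1, -1, 2, 2, 2, 10, 10, 10)))
  expect_equal(nrow(turnover_pairs(ds2)), 18)

  # a post sample beyond the horizon contributes no pairs
  ds3 <- new_dataset(counts[, 1:5],
                     make_meta(sprintf("s%02d", 1:5),
                               time_days = c(-1, -1, 7, 7, 60)))
  expect_equal(nrow(turnover_pairs(ds3, horizon = 50)), 4)

  # no pre-disturbance controls -> series excluded with a warning
  ds4 <- new_dataset(counts[, 1:4],
                     make_meta(sprintf("s%02d", 1:4), time_days = c(2, 2, 9, 9)))
  expect_warning(p4 <- turnover_pairs(ds4), "without pre-disturbance")
  expect_equal(nrow(p4), 0)

  # same-unit exclusion is off by default, available as sensitivity flag
  ds5 <- new_dataset(counts[, 1:4],
                     make_meta(sprintf("s%02d", 1:4),
                               time_days = c(-1, -1, 3, 3),
                               unit_id = c("u1", "u2", "u1", "u2")))
  expect_equal(nrow(turnover_pairs(ds5)), 4)
  expect_equal(nrow(turnover_pairs(ds5, exclude_same_unit = TRUE)), 2)
})

test_that("pair counts match closed forms on simulated designs", {
  sim <- sim_preset("null", n_studies = 2, series_per_study = 2, seed = 8)
  ds <- simulate_dataset(sim)$dataset

  disp <- dispersion_pairs(ds)
  expected_disp <- ds$meta |>
    dplyr::group_by(time_series_id, time_days) |>
    dplyr::summarise(
      pairs = {
        u <- unit_id
        cmb <- utils::combn(length(u), 2)
        sum(u[cmb[1, ]] != u[cmb[2, ]])
      }, .groups = "drop") |>
    dplyr::pull(pairs) |> sum()
  expect_equal(nrow(disp), expected_disp)

  turn <- turnover_pairs(ds, horizon = 50)
  expected_turn <- ds$meta |>
    dplyr::group_by(time_series_id) |>
    dplyr::summarise(
      pairs = sum(time_days < 0) *
        sum(time_days >= 0 & time_days <= 50), .groups = "drop") |>
    dplyr::pull(pairs) |> sum()
  expect_equal(nrow(turn), expected_turn)

  # every dispersion record joins two samples of one series and time point
  lookup <- function(ids, col) ds$meta[[col]][match(ids, ds$meta$sample_id)]
  expect_true(all(lookup(disp$sample_a, "time_series_id") ==
                    lookup(disp$sample_b, "time_series_id")))
  expect_true(all(lookup(disp$sample_a, "time_days") ==
                    lookup(disp$sample_b, "time_days")))
  expect_true(all(lookup(disp$sample_a, "time_series_id") ==
                    disp$time_series_id))
})
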