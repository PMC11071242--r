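make_trends <- function(env, n, cls, comparison = "immediate_richness") {
  tibble::tibble(
    scope = "time_series",
    id = sprintf("%s_ts%03d", env, seq_len(n)),
    environment = factor(env, levels = c("aquatic", "mammal", "soil")),
    slope_mean = 0, ci_low = -1, ci_high = 1,
    classification = factor(cls, levels = c("down", "neutral", "up")),
    comparison = comparison
  )
}

test_that("classification counts aggregate trends per environment", {
  # 14 aquatic series all neutral -> 0 / 14 / 0
  t1 <- make_trends("aquatic", 14, "neutral")
  s1 <- table1_summary(t1)
  row <- s1[s1$environment == "aquatic", ]
  expect_equal(c(row$down, row$neutral, row$up), c(0L, 14L, 0L))
  expect_equal(row$n_series, 14L)

  # 19 mammal series all down -> 19 / 0 / 0
  t2 <- make_trends("mammal", 19, "down")
  s2 <- table1_summary(t2)
  row2 <- s2[s2$environment == "mammal", ]
  expect_equal(c(row2$down, row2$neutral, row2$up), c(19L, 0L, 0L))

  # mixed classes sum to the number of analysed series
  t3 <- dplyr::bind_rows(make_trends("soil", 5, "down"),
                         make_trends("soil", 3, "neutral"),
                         make_trends("soil", 2, "up"))
  t3$id <- sprintf("soil_ts%03d", seq_len(nrow(t3)))
  s3 <- table1_summary(t3)
  row3 <- s3[s3$environment == "soil", ]
  expect_equal(row3$n_series, 10L)
  expect_equal(row3$down + row3$neutral + row3$up, row3$n_series)

  # an empty trend set gives an all-NA grid
  s0 <- table1_summary(tibble::tibble())
  expect_true(all(is.na(s0$down)))

  # a requested comparison with no classifications is marked NA
  s4 <- table1_summary(t1, comparisons = c("immediate_richness", "turnover"))
  expect_true(all(is.na(s4$n_series[s4$comparison == "turnover"])))
})

test_that("the pipeline runs end to end and reports coherent counts", {
  sim <- sim_preset("mammal", n_studies = 3, series_per_study = 2, seed = 4)
  rep <- suppressWarnings(run_pipeline(
    sim = sim, seed = 4, use_zscores = TRUE, n_resamples = 60,
    comparisons = c("temporal_richness", "turnover"),
    backend = "laplace"))
  expect_s3_class(rep, "mrc_report")

  # every environment x comparison row sums to the analysed series count
  tab <- rep$table1
  n_series <- dplyr::n_distinct(rep$trends$id[rep$trends$scope ==
                                                "time_series"])
  expect_true(all(tab$n_series == n_series, na.rm = TRUE))
  expect_true(all(tab$down + tab$neutral + tab$up == tab$n_series,
                  na.rm = TRUE))

  # attribution exists for the dissimilarity comparison (raw vs Z)
  expect_true(all(rep$attribution$comparison == "turnover"))
  expect_true(all(rep$attribution$attribution %in%
                    c("richness_driven", "abundance_driven", "none")))

  # stage bookkeeping is recorded
  expect_equal(rep$stage_counts$input_samples, 3 * 2 * 6 * 3)
  expect_gt(rep$stage_counts$turnover_pairs, 0)

  # mean completeness is a summary of the per-sample values
  expect_equal(rep$completeness_mean, mean(rep$diversity$completeness))
})

test_that("pipeline failures name the failing stage", {
  # two replicates everywhere: the filter stage empties the dataset
  counts <- matrix(rpois(40, 30), nrow = 10,
                   dimnames = list(sprintf("t%02d", 1:10),
                                   sprintf("s%d", 1:4)))
  storage.mode(counts) <- "integer"
  meta <- make_meta(sprintf("s%d", 1:4), time_days = c(-1, -1, 5, 5))
  ds <- new_dataset(counts, meta)
  expect_error(
    suppressWarnings(run_pipeline(ds = ds, seed = 1, depth = 10,
                                  backend = "laplace")),
    "stage 'filter'")
  expect_error(run_pipeline(), "provide a dataset")
})

test_that("report JSON is deterministic and round-trips", {
  sim <- sim_preset("null", n_studies = 2, series_per_study = 2, seed = 12)
  mk <- function() suppressWarnings(run_pipeline(
    sim = sim, seed = 12, use_zscores = FALSE,
    comparisons = "temporal_richness", backend = "laplace"))
  r1 <- mk()
  r2 <- mk()
  expect_identical(report_json(r1), report_json(r2))
  path <- tempfile(fileext = ".json")
  report_json(r1, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$provenance$seed, 12)
  expect_equal(nrow(parsed$table1), nrow(r1$table1))
})

test_that("plot constructors return ggplot objects", {
  sim <- sim_preset("mammal", n_studies = 2, series_per_study = 1, seed = 3)
  ds <- filter_replicates(rarefy(simulate_dataset(sim)$dataset, 1500,
                                 seed = 3))
  div <- diversity_table(ds)
  expect_s3_class(plot_trajectories(div), "gg")
  disp <- dispersion_pairs(ds)
  expect_s3_class(plot_pairs(disp), "gg")
  f <- suppressWarnings(fit_trend(div, "richness", backend = "laplace",
                                  seed = 3))
  expect_s3_class(autoplot(classify_trends(f)), "gg")
})
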