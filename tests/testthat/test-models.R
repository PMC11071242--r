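fake_fit <- function(key_draws, env = "mammal", design = "time_series") {
  n <- length(key_draws)
  structure(list(
    response = "richness", design = design, family = "nbinom",
    backend = "laplace", env_levels = env,
    draws_fixed = cbind(intercept = rep(0, n), key = key_draws),
    draws_series = matrix(0, n, 1, dimnames = list(NULL, "ts1")),
    series_tbl = tibble::tibble(
      time_series_id = "ts1",
      environment = factor(env, levels = c("aquatic", "mammal", "soil")),
      study_id = "st1"),
    time_center = 0, window = NA_real_, horizon = 50,
    diagnostics = list(converged = TRUE, max_rhat = NA_real_,
                       min_ess = NA_real_),
    notes = character(0), nobs = n, model = NULL
  ), class = "mrc_fit")
}

test_that("time centering and interval squeezing follow their closed forms", {
  expect_equal(center_time(c(0, 10, 20)), c(-10, 0, 10))
  expect_equal(center_time(7), 0)
  x <- c(-5, 0, 5)
  expect_equal(center_time(x), x)  # idempotent on centered input
  expect_equal(mean(center_time(runif(20, 0, 50))), 0, tolerance = 1e-12)

  expect_equal(squeeze_unit_interval(0, 100), 0.005, tolerance = 1e-12)
  expect_equal(squeeze_unit_interval(1, 100), 0.995, tolerance = 1e-12)
  expect_equal(squeeze_unit_interval(0.5, 17), 0.5, tolerance = 1e-12)
  y <- runif(30)
  s <- squeeze_unit_interval(y)
  expect_true(all(s > 0 & s < 1))
})

test_that("credible-interval classification follows the interval rule", {
  up <- classify_trends(fake_fit(seq(0.02, 0.10, length.out = 1000)))
  expect_true(all(up$classification == "up"))
  neutral <- classify_trends(fake_fit(seq(-0.05, 0.01, length.out = 1000)))
  expect_true(all(neutral$classification == "neutral"))
  down <- classify_trends(fake_fit(seq(-0.20, -0.10, length.out = 1000)))
  expect_true(all(down$classification == "down"))

  # pure function of the draws
  f <- fake_fit(rnorm(500, 0.01, 0.02))
  expect_identical(classify_trends(f), classify_trends(f))

  # monotonicity: shifting all draws upward never moves a class downward
  rank_of <- function(cl) match(as.character(cl), c("down", "neutral", "up"))
  set.seed(2)
  for (i in 1:20) {
    draws <- rnorm(400, rnorm(1, 0, 0.05), 0.02)
    before <- classify_trends(fake_fit(draws))$classification
    after <- classify_trends(fake_fit(draws + abs(rnorm(1, 0.03))))$classification
    expect_true(all(rank_of(after) >= rank_of(before)))
  }
})

test_that("attribution separates richness-driven from abundance-driven change", {
  mk <- function(cls) {
    tibble::tibble(scope = "time_series", id = "ts1",
                   environment = factor("mammal",
                                        levels = c("aquatic", "mammal", "soil")),
                   classification = factor(cls,
                                           levels = c("down", "neutral", "up")))
  }
  expect_equal(attribute_change(mk("down"), mk("down"))$attribution,
               "richness_driven")
  expect_equal(attribute_change(mk("down"), mk("neutral"))$attribution,
               "richness_driven")
  expect_equal(attribute_change(mk("neutral"), mk("up"))$attribution,
               "abundance_driven")
  expect_equal(attribute_change(mk("neutral"), mk("neutral"))$attribution,
               "none")
  z <- mk("down"); z$id <- "ts9"
  expect_error(attribute_change(mk("down"), z), "different scopes")
})

test_that("negative-binomial fits recover means of Poisson-like data within 5%", {
  d <- simulate_response(design = "before_after", family = "nbinom",
                         effect = log(0.6), intercept = log(120),
                         n_studies = 6, series_per_study = 4,
                         replicates = 11, shape = 100,
                         study_sd = 0.05, series_int_sd = 0.02,
                         series_slope_sd = 0.002, seed = 41)
  expect_gte(nrow(d), 500)
  f <- fit_before_after(d, "richness", backend = "laplace", seed = 1)
  est_before <- exp(mean(f$draws_fixed[, "intercept"]))
  expect_lt(abs(est_before - 120) / 120, 0.05)
  est_ratio <- exp(mean(f$draws_fixed[, "key"]))
  expect_lt(abs(est_ratio - 0.6) / 0.6, 0.05)
})

test_that("null effects yield intervals containing zero", {
  d <- simulate_response(design = "time_series", family = "beta",
                         effect = 0, intercept = 0.3, phi = 40,
                         n_studies = 4, series_per_study = 3, seed = 6)
  f <- fit_trend(d, "turnover", backend = "laplace", seed = 6)
  tr <- classify_trends(f)
  env_row <- tr[tr$scope == "environment", ]
  expect_lte(env_row$ci_low, 0)
  expect_gte(env_row$ci_high, 0)
})

test_that("a single-environment before-after model still returns its contrast", {
  d <- simulate_response(design = "before_after", family = "nbinom",
                         effect = log(0.5), intercept = log(90),
                         n_studies = 4, series_per_study = 2, seed = 9)
  f <- fit_before_after(d, "richness", backend = "laplace", seed = 9)
  ct <- env_contrasts(f)
  expect_equal(nrow(ct), 1L)
  expect_equal(as.character(ct$environment), "mammal")
  expect_true(ct$ratio_low < 0.5 & ct$ratio_high > 0.4)
})

test_that("both backends agree on a moderate richness trend", {
  d <- simulate_response(design = "time_series", family = "nbinom",
                         effect = 0.02, intercept = log(40), shape = 15,
                         n_studies = 4, series_per_study = 3, seed = 13)
  fl <- fit_trend(d, "richness", backend = "laplace", seed = 13)
  fm <- fit_trend(d, "richness", backend = "mcmc", seed = 13,
                  control = mcmc_control(chains = 2, warmup = 600,
                                         iter = 800))
  el <- mean(fl$draws_fixed[, "key"])
  em <- mean(fm$draws_fixed[, "key"])
  expect_lt(abs(el - em), 0.005)
  expect_equal(as.character(classify_trends(fl)$classification[1]),
               as.character(classify_trends(fm)$classification[1]))
})
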