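# Response-table preparation shared by the before-after and time-series
# models.

#' Center a time covariate
#'
#' Subtracts the mean observed duration so the fitted intercept refers to
#' the mean sampling day rather than day zero. Applied jointly to all time
#' series entering one model (a single time covariate enters the model, so
#' a single center is used).
#'
#' @param times Numeric vector of post-disturbance times (days).
#' @return The centered vector (mean exactly 0).
#' @export
center_time <- function(times) {
  if (!length(times)) abort("center_time needs a non-empty vector")
  times - mean(times)
}

#' Squeeze unit-interval data into the open interval
#'
#' The Beta family requires responses strictly inside (0, 1); observed
#' dissimilarities can sit on the boundary. The standard compression
#' `y' = (y * (n - 1) + 0.5) / n` (Smithson & Verkuilen) pulls boundary
#' values inward by half an observation's weight.
#'
#' @param y Numeric vector in `[0, 1]`.
#' @param n Number of observations (defaults to `length(y)`).
#' @return Vector strictly inside (0, 1).
#' @export
squeeze_unit_interval <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

RESPONSES <- c("richness", "dispersion", "turnover",
               "z_dispersion", "z_turnover")

response_column <- function(response) {
  switch(response,
         richness = "richness_q0",
         dispersion = "value",
         turnover = "value",
         z_dispersion = "z",
         z_turnover = "z")
}

response_family <- function(response) {
  switch(response,
         richness = "nbinom",
         dispersion = "beta",
         turnover = "beta",
         z_dispersion = "gaussian",
         z_turnover = "gaussian")
}

# Assemble the modeling frame: response column y, key covariate x (after
# indicator or centered time), grouping factors. Returns list(frame,
# time_center, env_levels).
build_model_frame <- function(data, response, design, window = 4,
                              horizon = 50) {
  response <- match.arg(response, RESPONSES)
  col <- response_column(response)
  need <- c(col, "time_days", "study_id", "time_series_id", "environment")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("response table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d <- tibble::as_tibble(data)
  d$y <- d[[col]]
  d <- d[!is.na(d$y), , drop = FALSE]
  time_center <- NA_real_
  if (design == "before_after") {
    d <- d[d$time_days < 0 | (d$time_days >= 0 & d$time_days < window), ,
           drop = FALSE]
    if (!nrow(d)) abort("no observations in the before-after window")
    d$x <- as.numeric(d$time_days >= 0)
    if (all(d$x == 1) || all(d$x == 0)) {
      abort("before-after design needs both pre- and post-disturbance data")
    }
  } else {
    d <- d[d$time_days >= 0 & d$time_days <= horizon, , drop = FALSE]
    if (!nrow(d)) abort("no post-disturbance observations within the horizon")
    time_center <- mean(d$time_days)
    d$x <- center_time(d$time_days)
  }
  d$environment <- droplevels(factor(d$environment, levels = ENV_LEVELS))
  d$study_id <- factor(d$study_id)
  d$time_series_id <- factor(d$time_series_id)
  fam <- response_family(response)
  if (fam == "beta") {
    if (any(d$y < 0 | d$y > 1)) abort("Beta responses must lie in [0, 1]")
    d$y <- squeeze_unit_interval(d$y, nrow(d))
  }
  if (fam == "nbinom" && any(d$y != round(d$y))) {
    abort("richness responses must be integer counts")
  }
  list(frame = d, time_center = time_center,
       env_levels = levels(d$environment))
}

#' MCMC sampler settings
#'
#' @param chains Number of HMC-free Gibbs chains (JAGS).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param iter Retained sampling iterations per chain.
#' @param thin Thinning interval.
#' @return A list of sampler settings for the `"mcmc"` backend.
#' @export
mcmc_control <- function(chains = 4L, warmup = 1000L, iter = 1000L,
                         thin = 1L) {
  list(chains = as.integer(chains), warmup = as.integer(warmup),
       iter = as.integer(iter), thin = as.integer(thin))
}
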