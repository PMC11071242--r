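# Hierarchical before-after and time-series model fitting.
#
# Two backends sit behind one surface:
#   * "mcmc"    — full posterior sampling with JAGS (headline analyses);
#   * "laplace" — glmmTMB maximum-likelihood fit with draws from the
#                 multivariate-normal approximation to the posterior
#                 (fast; used for large simulation studies).
# Both return an `mrc_fit` whose draws use canonical term names
# ("intercept", "key", "env_<level>", "key:env_<level>"), where the key
# term is the after indicator (before-after design) or centered time
# (time-series design), so classification code is backend-agnostic.

#' Fit the before-after disturbance model
#'
#' Contrasts pre-disturbance observations (`time_days < 0`) against
#' observations taken within `window` days post-disturbance, with an
#' after-by-environment interaction (when several environments are
#' present), varying intercepts for studies, varying intercepts and
#' after-effects for time series within studies, and a family dispersion
#' parameter that varies among studies. Families follow the response:
#' negative binomial with log link for richness, Beta with logit link for
#' raw dissimilarities (squeezed off the boundary), Gaussian with identity
#' link and environment/study-structured residual SD for Z-scores.
#'
#' @param data Response table: [diversity_table()] output for richness,
#'   a pair tibble for dispersion/turnover, a [null_zscores()] table for
#'   `z_*` responses.
#' @param response One of `"richness"`, `"dispersion"`, `"turnover"`,
#'   `"z_dispersion"`, `"z_turnover"`.
#' @param window Immediate-response window in days (default 4: "after"
#'   means `0 <= time_days < 4`).
#' @param backend `"mcmc"` (JAGS, full posterior) or `"laplace"` (glmmTMB).
#' @param seed Integer seed for sampling / posterior draws.
#' @param control Sampler settings from [mcmc_control()] (mcmc backend).
#' @param ndraws Number of posterior draws retained by the laplace backend.
#' @return An object of class `mrc_fit`.
#' @export
fit_before_after <- function(data, response, window = 4,
                             backend = c("mcmc", "laplace"), seed = 1L,
                             control = mcmc_control(), ndraws = 1000L) {
  backend <- match.arg(backend)
  prep <- build_model_frame(data, response, "before_after", window = window)
  fit_engine(prep, response, "before_after", backend, seed, control, ndraws,
             window = window, horizon = NA_real_)
}

#' Fit the post-disturbance time-series model
#'
#' Models the response over the first `horizon` days post-disturbance
#' (pre-disturbance samples excluded) as a function of time (centered on
#' the mean observed day) interacting with environment, with varying
#' intercepts for studies and varying slopes and intercepts for time
#' series within studies. Families as in [fit_before_after()]; for
#' Z-score responses the residual SD is modeled as a function of
#' environment and study.
#'
#' @inheritParams fit_before_after
#' @param horizon Latest day included (default 50).
#' @return An object of class `mrc_fit`.
#' @export
fit_trend <- function(data, response, horizon = 50,
                      backend = c("mcmc", "laplace"), seed = 1L,
                      control = mcmc_control(), ndraws = 1000L) {
  backend <- match.arg(backend)
  prep <- build_model_frame(data, response, "time_series", horizon = horizon)
  fit_engine(prep, response, "time_series", backend, seed, control, ndraws,
             window = NA_real_, horizon = horizon)
}

fit_engine <- function(prep, response, design, backend, seed, control,
                       ndraws, window, horizon) {
  d <- prep$frame
  family <- response_family(response)
  series_tbl <- d |>
    dplyr::distinct(.data$time_series_id, .data$environment, .data$study_id) |>
    dplyr::arrange(.data$time_series_id)
  # series observed at < 2 distinct covariate values inform intercepts only
  thin_series <- d |>
    dplyr::group_by(.data$time_series_id) |>
    dplyr::summarise(nx = dplyr::n_distinct(.data$x), .groups = "drop") |>
    dplyr::filter(.data$nx < 2L)
  notes <- character(0)
  if (nrow(thin_series)) {
    notes <- c(notes, paste0("series with < 2 distinct covariate values ",
                             "(intercept-only): ",
                             paste(thin_series$time_series_id, collapse = ", ")))
  }
  if (dplyr::n_distinct(d$study_id) < 2L) {
    notes <- c(notes, "single study: study-level variation not estimable")
  }
  res <- if (backend == "laplace") {
    fit_laplace(d, family, seed = seed, ndraws = ndraws)
  } else {
    fit_jags(d, family, control = control, seed = seed)
  }
  structure(list(
    response = response, design = design, family = family, backend = backend,
    env_levels = prep$env_levels,
    draws_fixed = res$draws_fixed,
    draws_series = res$draws_series,
    series_tbl = series_tbl,
    time_center = prep$time_center,
    window = window, horizon = horizon,
    diagnostics = res$diagnostics,
    notes = c(notes, res$notes),
    nobs = nrow(d),
    model = res$model
  ), class = "mrc_fit")
}

# ---- laplace backend (glmmTMB) ---------------------------------------

glmmtmb_family <- function(family) {
  switch(family,
         nbinom = glmmTMB::nbinom2(),
         beta = glmmTMB::beta_family(),
         gaussian = stats::gaussian())
}

build_formulas <- function(d, family) {
  multi_env <- dplyr::n_distinct(d$environment) > 1L
  multi_study <- dplyr::n_distinct(d$study_id) > 1L
  multi_series <- dplyr::n_distinct(d$time_series_id) > 1L
  fixed <- if (multi_env) "y ~ x * environment" else "y ~ x"
  re <- character(0)
  if (multi_study) re <- c(re, "(1 | study_id)")
  if (multi_series) re <- c(re, "(1 + x | time_series_id)")
  form <- stats::as.formula(paste(c(fixed, re), collapse = " + "))
  disp_terms <- if (family == "gaussian") {
    c(if (multi_env) "environment", if (multi_study) "study_id")
  } else {
    c(if (multi_study) "study_id")
  }
  disp <- stats::as.formula(paste("~", paste(c("1", disp_terms),
                                             collapse = " + ")))
  list(formula = form, dispformula = disp,
       has_series_slope = multi_series, has_study = multi_study,
       has_series = multi_series)
}

# A Laplace fit is *clean* when the optimizer reports convergence and the
# joint Hessian is PD; it is *usable* when the fixed-effect vcov is finite
# with positive variances. Variance components at their boundary (common
# when between-series slope variation is tiny) routinely produce usable
# but not clean fits whose fixed-effect uncertainty is still valid.
tmb_usable <- function(m) {
  if (is.null(m) || inherits(m, "try-error")) return(FALSE)
  V <- try(as.matrix(stats::vcov(m)$cond), silent = TRUE)
  !inherits(V, "try-error") && all(is.finite(V)) && all(diag(V) > 0)
}

tmb_clean <- function(m) {
  tmb_usable(m) && isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
}

fit_laplace <- function(d, family, seed = 1L, ndraws = 1000L) {
  fm <- build_formulas(d, family)
  fam <- glmmtmb_family(family)
  quiet_fit <- function(formula, dispformula) {
    suppressWarnings(try(
      glmmTMB::glmmTMB(formula, data = d, family = fam,
                       dispformula = dispformula),
      silent = TRUE))
  }
  notes <- character(0)
  # progressively simpler structures; the first *clean* fit wins, else the
  # first merely usable one (typically the full model at a variance
  # boundary)
  multi_env <- dplyr::n_distinct(d$environment) > 1L
  fixed <- if (multi_env) "y ~ x * environment" else "y ~ x"
  study_re <- if (fm$has_study) " + (1 | study_id)" else ""
  has_series <- dplyr::n_distinct(d$time_series_id) > 1L
  mk <- function(re) stats::as.formula(paste0(fixed, study_re, re))
  rungs <- list(list(formula = fm$formula, dispformula = fm$dispformula,
                     has_slope = fm$has_series_slope, note = NULL))
  if (has_series) {
    rungs <- c(rungs, list(
      list(formula = mk(" + (1 + x | time_series_id)"), dispformula = ~1,
           has_slope = TRUE,
           note = "dispersion structure dropped (non-convergence)"),
      list(formula = mk(" + (1 | time_series_id)"),
           dispformula = fm$dispformula, has_slope = FALSE,
           note = "series random slopes dropped (non-convergence)"),
      list(formula = mk(" + (1 | time_series_id)"), dispformula = ~1,
           has_slope = FALSE,
           note = "series slopes and dispersion structure dropped"),
      list(formula = stats::as.formula(
             paste0(fixed, " + (1 | time_series_id)")),
           dispformula = ~1, has_slope = FALSE,
           note = "reduced to series intercepts only (non-convergence)")))
  } else {
    rungs <- c(rungs, list(
      list(formula = fm$formula, dispformula = ~1,
           has_slope = fm$has_series_slope,
           note = "dispersion structure dropped (non-convergence)")))
  }
  m <- NULL
  fallback <- NULL
  fallback_rung <- NULL
  for (r in rungs) {
    mr <- quiet_fit(r$formula, r$dispformula)
    if (tmb_clean(mr)) {
      m <- mr
      fm$has_series_slope <- r$has_slope
      notes <- c(notes, r$note)
      break
    }
    if (is.null(fallback) && tmb_usable(mr)) {
      fallback <- mr
      fallback_rung <- r
    }
  }
  if (is.null(m)) {
    if (is.null(fallback)) {
      abort("glmmTMB fit failed: no usable model in the fallback ladder")
    }
    m <- fallback
    fm$has_series_slope <- fallback_rung$has_slope
    notes <- c(notes, fallback_rung$note,
               "variance component at boundary; Laplace vcov used as-is")
  }
  set.seed(seed)
  beta <- glmmTMB::fixef(m)$cond
  V <- as.matrix(stats::vcov(m)$cond)
  draws <- mvn_draws(ndraws, beta, V)
  colnames(draws) <- canonical_terms(names(beta))
  series_ids <- sort(unique(as.character(d$time_series_id)))
  draws_series <- matrix(0, nrow = ndraws, ncol = length(series_ids),
                         dimnames = list(NULL, series_ids))
  if (fm$has_series_slope) {
    re <- as.data.frame(glmmTMB::ranef(m, condVar = TRUE))
    re <- re[re$grpvar == "time_series_id" & re$term == "x", , drop = FALSE]
    for (i in seq_len(nrow(re))) {
      g <- as.character(re$grp[i])
      sdv <- if (is.finite(re$condsd[i])) re$condsd[i] else 0
      draws_series[, g] <- rnorm(ndraws, re$condval[i], sdv)
    }
  }
  list(draws_fixed = draws, draws_series = draws_series,
       diagnostics = list(converged = tmb_usable(m),
                          max_rhat = NA_real_, min_ess = NA_real_),
       notes = notes, model = m)
}

# draws from N(mu, V) via pivoted Cholesky with a jitter fallback
mvn_draws <- function(n, mu, V) {
  p <- length(mu)
  ch <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-8 + 1e-6 * mean(diag(V)), p))
  })
  z <- matrix(rnorm(n * p), nrow = n)
  sweep(z %*% ch, 2L, mu, "+")
}

canonical_terms <- function(nm) {
  out <- nm
  out[nm == "(Intercept)"] <- "intercept"
  out[nm == "x"] <- "key"
  out <- sub("^environment", "env_", out)
  out <- sub("^x:environment", "key:env_", out)
  out
}
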