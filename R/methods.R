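# print / tidy / glance methods for fitted objects.

#' @export
print.mrc_fit <- function(x, ...) {
  cat("<mrc_fit> ", x$design, " model, response = ", x$response,
      " (", x$family, " family), backend = ", x$backend, "\n", sep = "")
  cat("  n = ", x$nobs, " | series = ", nrow(x$series_tbl),
      " | environments: ", paste(x$env_levels, collapse = ", "), "\n",
      sep = "")
  if (x$backend == "mcmc" && is.finite(x$diagnostics$max_rhat)) {
    cat("  max R-hat = ", round(x$diagnostics$max_rhat, 3),
        " | min ESS = ", round(x$diagnostics$min_ess), "\n", sep = "")
  }
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "),
                           "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted disturbance model
#'
#' One row per fixed-effect term with posterior mean, SD, and credible
#' interval computed from the stored draws.
#'
#' @param x An `mrc_fit`.
#' @param conf.level Credible-interval mass.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy mrc_fit
#' @export
tidy.mrc_fit <- function(x, conf.level = 0.95, ...) {
  dr <- x$draws_fixed
  a <- (1 - conf.level) / 2
  tibble::tibble(
    term = colnames(dr),
    estimate = colMeans(dr),
    std.error = apply(dr, 2L, sd),
    conf.low = apply(dr, 2L, quantile, probs = a, names = FALSE),
    conf.high = apply(dr, 2L, quantile, probs = 1 - a, names = FALSE)
  )
}

#' Model-level summary of a fitted disturbance model
#'
#' @param x An `mrc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: observations, series, family, backend,
#'   draws, and convergence diagnostics.
#' @method glance mrc_fit
#' @export
glance.mrc_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    n_series = nrow(x$series_tbl),
    response = x$response,
    design = x$design,
    family = x$family,
    backend = x$backend,
    ndraws = nrow(x$draws_fixed),
    max_rhat = x$diagnostics$max_rhat,
    min_ess = x$diagnostics$min_ess,
    converged = isTRUE(x$diagnostics$converged)
  )
}

#' @export
print.mrc_report <- function(x, ...) {
  cat("<mrc_report> ", length(x$comparisons), " comparison(s): ",
      paste(x$comparisons, collapse = ", "), "\n", sep = "")
  cat("  series analysed: ", dplyr::n_distinct(x$trends$id[
    x$trends$scope == "time_series"]), "\n", sep = "")
  print(x$table1)
  invisible(x)
}
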