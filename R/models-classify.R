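# Credible-interval trend classification and richness-vs-abundance
# attribution.

#' Posterior draws of the key effect per environment and time series
#'
#' The key effect is the after-contrast (before-after design) or the time
#' slope (time-series design), on the link scale. Environment-level draws
#' combine the shared key effect with the environment interaction;
#' series-level draws add the series' own deviation.
#'
#' @param fit An `mrc_fit`.
#' @return A list with matrices `environment` (draws x environments) and
#'   `time_series` (draws x series).
#' @export
trend_draws <- function(fit) {
  stopifnot(inherits(fit, "mrc_fit"))
  dr <- fit$draws_fixed
  env <- fit$env_levels
  env_mat <- vapply(env, function(e) {
    out <- dr[, "key"]
    intc <- paste0("key:env_", e)
    if (intc %in% colnames(dr)) out <- out + dr[, intc]
    out
  }, numeric(nrow(dr)))
  env_mat <- matrix(env_mat, nrow = nrow(dr), dimnames = list(NULL, env))
  st <- fit$series_tbl
  ser_mat <- vapply(seq_len(nrow(st)), function(i) {
    env_mat[, as.character(st$environment[i])] +
      fit$draws_series[, as.character(st$time_series_id[i])]
  }, numeric(nrow(dr)))
  ser_mat <- matrix(ser_mat, nrow = nrow(dr),
                    dimnames = list(NULL, as.character(st$time_series_id)))
  list(environment = env_mat, time_series = ser_mat)
}

classify_interval <- function(lo, hi) {
  factor(ifelse(lo > 0, "up", ifelse(hi < 0, "down", "neutral")),
         levels = c("down", "neutral", "up"))
}

#' Classify trends from posterior credible intervals
#'
#' Summarises the key-effect draws of a fit into per-environment and
#' per-time-series trend classes: *up* if the central credible interval
#' lies wholly above zero, *down* if wholly below, *neutral* otherwise
#' (interval endpoints at the `(1 - level)/2` and `1 - (1 - level)/2`
#' posterior quantiles; the default 95% interval spans the 2.5 and 97.5
#' percentiles).
#'
#' A pure function of the draws: the same draws always produce the same
#' classifications.
#'
#' @param fit An `mrc_fit` (before-after or time-series design).
#' @param level Credible-interval mass (default 0.95).
#' @return A tibble of class `mrc_trends`: `scope` (`"environment"` /
#'   `"time_series"`), `id`, `environment`, `slope_mean`, `ci_low`,
#'   `ci_high`, `classification`.
#' @export
classify_trends <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mrc_fit"))
  if (isFALSE(fit$diagnostics$converged)) {
    warn("classifying trends from a fit flagged as non-converged")
  }
  dd <- trend_draws(fit)
  a <- (1 - level) / 2
  summarise_mat <- function(m, scope, env_of) {
    tibble::tibble(
      scope = scope,
      id = colnames(m),
      environment = factor(env_of, levels = ENV_LEVELS),
      slope_mean = colMeans(m),
      ci_low = apply(m, 2L, quantile, probs = a, names = FALSE),
      ci_high = apply(m, 2L, quantile, probs = 1 - a, names = FALSE)
    )
  }
  out <- dplyr::bind_rows(
    summarise_mat(dd$environment, "environment", colnames(dd$environment)),
    summarise_mat(dd$time_series, "time_series",
                  as.character(fit$series_tbl$environment))
  )
  out$classification <- classify_interval(out$ci_low, out$ci_high)
  structure(out, class = c("mrc_trends", class(out)),
            response = fit$response, design = fit$design, level = level)
}

#' Per-environment before-after contrasts on the response scale
#'
#' For log- or logit-link fits, transforms the environment-level after
#' contrast to the response scale (ratio of after to before means for log
#' links; odds ratio for logit links).
#'
#' @param fit A before-after `mrc_fit`.
#' @param level Credible-interval mass.
#' @return A tibble with link-scale effect summaries and, for non-identity
#'   links, `ratio_mean` / `ratio_low` / `ratio_high`.
#' @export
env_contrasts <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mrc_fit"))
  if (fit$design != "before_after") {
    abort("env_contrasts expects a before-after fit")
  }
  m <- trend_draws(fit)$environment
  a <- (1 - level) / 2
  out <- tibble::tibble(
    environment = factor(colnames(m), levels = ENV_LEVELS),
    effect_mean = colMeans(m),
    ci_low = apply(m, 2L, quantile, probs = a, names = FALSE),
    ci_high = apply(m, 2L, quantile, probs = 1 - a, names = FALSE)
  )
  out$classification <- classify_interval(out$ci_low, out$ci_high)
  if (fit$family %in% c("nbinom", "beta")) {
    r <- exp(m)
    out$ratio_mean <- colMeans(r)
    out$ratio_low <- apply(r, 2L, quantile, probs = a, names = FALSE)
    out$ratio_high <- apply(r, 2L, quantile, probs = 1 - a, names = FALSE)
  }
  out
}

#' Attribute a compositional trend to richness or relative-abundance change
#'
#' Compares classifications of the same comparison computed on raw
#' dissimilarities and on null-model Z-scores. A trend visible in the raw
#' values is attributed to richness change (the Z-score strips the
#' richness signal; its absence there confirms richness as the driver); a
#' trend visible only in the Z-scores is attributed to shifts in relative
#' abundances; no trend in either is `"none"`.
#'
#' @param raw_class,z_class `mrc_trends` tibbles (or compatible) for the
#'   same scope/ids, from the raw-value and Z-score fits respectively.
#' @return A tibble with `scope`, `id`, `environment`, both
#'   classifications, and `attribution` in
#'   `{richness_driven, abundance_driven, none}`.
#' @export
attribute_change <- function(raw_class, z_class) {
  key <- c("scope", "id")
  if (!setequal(paste(raw_class$scope, raw_class$id),
                paste(z_class$scope, z_class$id))) {
    abort("raw and Z-score classifications cover different scopes/ids")
  }
  j <- dplyr::inner_join(
    dplyr::select(raw_class, dplyr::all_of(key), "environment",
                  raw_classification = "classification"),
    dplyr::select(z_class, dplyr::all_of(key),
                  z_classification = "classification"),
    by = key)
  j$attribution <- dplyr::case_when(
    j$raw_classification != "neutral" ~ "richness_driven",
    j$z_classification != "neutral" ~ "abundance_driven",
    TRUE ~ "none"
  )
  j
}
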