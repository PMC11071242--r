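# End-to-end orchestration: ingest/simulate -> standardize -> pair sets ->
# null model -> fits (raw and Z in parallel) -> classification -> summary.

COMPARISONS <- c("immediate_richness", "temporal_richness",
                 "immediate_dispersion", "temporal_dispersion", "turnover")

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full disturbance-recovery pipeline
#'
#' Executes rarefaction, replicate filtering, diversity and pair-set
#' computation, (optionally) the permutation null model, the hierarchical
#' fits for the requested comparisons — raw dissimilarities and Z-scores
#' in parallel — credible-interval classification, richness-vs-abundance
#' attribution, and the classification summary table.
#'
#' @param ds An `mrc_dataset`, or `NULL` to simulate one.
#' @param sim An `mrc_sim_config` used when `ds` is `NULL`.
#' @param seed Master seed for rarefaction, the null model, and sampling.
#' @param depth Rarefaction depth (default 1500 reads).
#' @param min_reps Minimum replicates per time point (default 3).
#' @param window Immediate-response window in days (default 4).
#' @param horizon Post-disturbance horizon in days (default 50).
#' @param comparisons Which of the five standard comparisons to run.
#' @param use_zscores If `TRUE`, run the permutation null model and fit
#'   Z-score models alongside the raw-value models for the dissimilarity
#'   comparisons.
#' @param n_resamples Null-model resamples (default 1000).
#' @param pool_scope Null-model taxon pool scope (see [null_zscores()]).
#' @param backend,control,ndraws Passed to the fitting functions.
#' @param level Credible-interval mass for classification.
#' @param exclude_same_unit_turnover Sensitivity flag for
#'   [turnover_pairs()].
#' @return An object of class `mrc_report`: trends (raw and Z), the
#'   classification count table, attribution labels, per-stage counts, the
#'   fitted models, and full provenance (resolved configuration + seed).
#' @export
run_pipeline <- function(ds = NULL, sim = NULL, seed = 1L, depth = 1500L,
                         min_reps = 3L, window = 4, horizon = 50,
                         comparisons = COMPARISONS, use_zscores = TRUE,
                         n_resamples = 1000L,
                         pool_scope = c("time_series", "study"),
                         backend = c("mcmc", "laplace"),
                         control = mcmc_control(), ndraws = 1000L,
                         level = 0.95,
                         exclude_same_unit_turnover = FALSE) {
  backend <- match.arg(backend)
  pool_scope <- match.arg(pool_scope)
  comparisons <- match.arg(comparisons, COMPARISONS, several.ok = TRUE)
  stage_counts <- list()

  if (is.null(ds)) {
    if (is.null(sim)) abort("provide a dataset (ds) or a sim config (sim)")
    ds <- run_stage("simulate", simulate_dataset(sim)$dataset)
  }
  stage_counts$input_samples <- ncol(ds$counts)

  ds <- run_stage("standardize", rarefy(ds, depth = depth, seed = seed))
  stage_counts$rarefied_samples <- ncol(ds$counts)

  ds <- run_stage("filter", {
    out <- filter_replicates(ds, min_reps = min_reps)
    if (!ncol(out$counts)) abort("no samples left after replicate filtering")
    out
  })
  stage_counts$filtered_samples <- ncol(ds$counts)

  div <- run_stage("diversity", diversity_table(ds))

  need_disp <- any(c("immediate_dispersion", "temporal_dispersion") %in%
                     comparisons)
  need_turn <- "turnover" %in% comparisons
  disp <- if (need_disp) run_stage("dissim", dispersion_pairs(ds)) else NULL
  turn <- if (need_turn) {
    run_stage("dissim", turnover_pairs(
      ds, horizon = horizon, exclude_same_unit = exclude_same_unit_turnover))
  } else NULL
  stage_counts$dispersion_pairs <- if (need_disp) nrow(disp) else NA_integer_
  stage_counts$turnover_pairs <- if (need_turn) nrow(turn) else NA_integer_

  disp_z <- turn_z <- NULL
  if (use_zscores && (need_disp || need_turn)) {
    nz <- run_stage("nullmodel", null_zscores(
      ds, dplyr::bind_rows(disp, turn), n_resamples = n_resamples,
      pool_scope = pool_scope, seed = seed))
    if (need_disp) disp_z <- nz[nz$kind == "dispersion", , drop = FALSE]
    if (need_turn) turn_z <- nz[nz$kind == "turnover", , drop = FALSE]
  }

  fit_one <- function(comparison, data, response, design) {
    run_stage(paste0("fit:", comparison, ":", response), {
      if (design == "before_after") {
        fit_before_after(data, response, window = window, backend = backend,
                         seed = seed, control = control, ndraws = ndraws)
      } else {
        fit_trend(data, response, horizon = horizon, backend = backend,
                  seed = seed, control = control, ndraws = ndraws)
      }
    })
  }

  plan <- list(
    immediate_richness = list(data = div, response = "richness",
                              design = "before_after", z = NULL),
    temporal_richness = list(data = div, response = "richness",
                             design = "time_series", z = NULL),
    immediate_dispersion = list(data = disp, response = "dispersion",
                                design = "before_after",
                                z = list(data = disp_z,
                                         response = "z_dispersion")),
    temporal_dispersion = list(data = disp, response = "dispersion",
                               design = "time_series",
                               z = list(data = disp_z,
                                        response = "z_dispersion")),
    turnover = list(data = turn, response = "turnover",
                    design = "time_series",
                    z = list(data = turn_z, response = "z_turnover"))
  )

  fits <- list()
  trends <- list()
  z_trends <- list()
  attribution <- list()
  for (cmp in comparisons) {
    p <- plan[[cmp]]
    f <- fit_one(cmp, p$data, p$response, p$design)
    fits[[cmp]] <- f
    tr <- classify_trends(f, level = level)
    tr$comparison <- cmp
    trends[[cmp]] <- tr
    if (use_zscores && !is.null(p$z)) {
      fz <- fit_one(cmp, p$z$data, p$z$response, p$design)
      fits[[paste0(cmp, "_z")]] <- fz
      trz <- classify_trends(fz, level = level)
      trz$comparison <- cmp
      z_trends[[cmp]] <- trz
      att <- attribute_change(tr, trz)
      att$comparison <- cmp
      attribution[[cmp]] <- att
    }
  }

  trends_tbl <- dplyr::bind_rows(trends)
  report <- structure(list(
    comparisons = comparisons,
    trends = trends_tbl,
    z_trends = dplyr::bind_rows(z_trends),
    attribution = dplyr::bind_rows(attribution),
    table1 = table1_summary(trends_tbl, comparisons = comparisons),
    diversity = div,
    completeness_mean = mean(div$completeness),
    completeness_sd = sd(div$completeness),
    stage_counts = stage_counts,
    fits = fits,
    provenance = list(
      seed = as.integer(seed), depth = as.integer(depth),
      min_reps = as.integer(min_reps), window = window, horizon = horizon,
      comparisons = comparisons, use_zscores = use_zscores,
      n_resamples = as.integer(n_resamples), pool_scope = pool_scope,
      backend = backend, control = control, ndraws = as.integer(ndraws),
      level = level,
      exclude_same_unit_turnover = exclude_same_unit_turnover,
      sim = if (!is.null(sim)) unclass(sim) else NULL)
  ), class = "mrc_report")
  report
}

#' Classification count table
#'
#' Counts, for each environment and comparison, the number of time series
#' classified down / neutral / up. For every environment-comparison cell
#' the three counts sum to the number of analysed series; comparisons that
#' were not run are reported as NA.
#'
#' @param trends An `mrc_trends` tibble (rows from several comparisons may
#'   be bound together with a `comparison` column; without one, a single
#'   unnamed comparison is assumed).
#' @param comparisons Comparisons to include as rows (defaults to those
#'   present).
#' @param environments Environments to include (defaults to those present).
#' @return A tibble: `comparison`, `environment`, `down`, `neutral`, `up`,
#'   `n_series`.
#' @export
table1_summary <- function(trends, comparisons = NULL, environments = NULL) {
  t <- tibble::as_tibble(trends)
  if (!nrow(t)) {
    comparisons <- comparisons %||% COMPARISONS
    environments <- environments %||% ENV_LEVELS
    return(tidyr::crossing(comparison = comparisons,
                           environment = environments) |>
             dplyr::mutate(down = NA_integer_, neutral = NA_integer_,
                           up = NA_integer_, n_series = NA_integer_))
  }
  if (!"comparison" %in% names(t)) t$comparison <- "comparison"
  t <- t[t$scope == "time_series", , drop = FALSE]
  comparisons <- comparisons %||% unique(t$comparison)
  environments <- environments %||%
    as.character(sort(unique(t$environment)))
  counts <- t |>
    dplyr::count(.data$comparison, .data$environment,
                 .data$classification, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "classification", values_from = "n",
                       values_fill = 0L)
  for (cl in c("down", "neutral", "up")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  grid <- tidyr::crossing(comparison = comparisons,
                          environment = environments)
  counts$environment <- as.character(counts$environment)
  out <- dplyr::left_join(grid, counts, by = c("comparison", "environment"))
  out$comparison <- factor(out$comparison, levels = comparisons)
  out |>
    dplyr::mutate(n_series = .data$down + .data$neutral + .data$up) |>
    dplyr::select("comparison", "environment", "down", "neutral", "up",
                  "n_series") |>
    dplyr::arrange(.data$comparison, .data$environment) |>
    dplyr::mutate(comparison = as.character(.data$comparison))
}

#' Serialise a pipeline report to JSON
#'
#' Deterministic: the same config and seed produce byte-identical JSON
#' (no timestamps or machine identifiers are embedded).
#'
#' @param report An `mrc_report`.
#' @param path Optional output path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mrc_report"))
  strip <- function(tr) {
    tr <- tibble::as_tibble(tr)
    tr$environment <- as.character(tr$environment)
    tr$classification <- as.character(tr$classification)
    tr
  }
  payload <- list(
    comparisons = report$comparisons,
    table1 = report$table1,
    trends = strip(report$trends),
    z_trends = if (nrow(report$z_trends %||% tibble::tibble())) {
      strip(report$z_trends)
    } else NULL,
    attribution = report$attribution,
    completeness_mean = report$completeness_mean,
    completeness_sd = report$completeness_sd,
    stage_counts = report$stage_counts,
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
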