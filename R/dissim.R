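# Bray-Curtis dissimilarity and construction of the dispersion and
# turnover pair sets.

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC = sum|x_i - y_i| / sum(x_i + y_i)`. On rarefied counts (equal column
#' sums) the count-based and relative-abundance formulations coincide.
#'
#' @param x,y Equal-length non-negative count vectors, each with at least
#'   one positive entry.
#' @return Dissimilarity in `[0, 1]`: 0 iff the vectors are identical, 1
#'   iff their supports are disjoint.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (all(x == 0) || all(y == 0)) {
    abort("Bray-Curtis is undefined when a vector is all zero")
  }
  sum(abs(x - y)) / sum(x + y)
}

# Vectorised Bray-Curtis for a set of column pairs of a counts matrix.
# ia/ib are column indices; returns one value per pair.
bc_pairs <- function(counts, ia, ib) {
  a <- counts[, ia, drop = FALSE]
  b <- counts[, ib, drop = FALSE]
  unname(colSums(abs(a - b)) / colSums(a + b))
}

pair_tibble <- function(meta_a, meta_b) {
  # lexicographically order sample ids within each unordered pair
  swap <- meta_a$sample_id > meta_b$sample_id
  sa <- ifelse(swap, meta_b$sample_id, meta_a$sample_id)
  sb <- ifelse(swap, meta_a$sample_id, meta_b$sample_id)
  list(sample_a = sa, sample_b = sb)
}

#' Within-time-point dispersion pairs
#'
#' For each time point within each time series, enumerates all unordered
#' pairs of experimental replicates and computes their Bray-Curtis
#' dissimilarity (compositional *dispersion*). Pairs whose two samples come
#' from the same experimental unit (repeated-measures designs) are
#' excluded, so dispersion reflects between-unit variability only.
#'
#' @param ds An `mrc_dataset`, typically rarefied and replicate-filtered.
#' @return A tibble of pair records: `time_series_id`, `study_id`,
#'   `environment`, `kind = "dispersion"`, `sample_a`, `sample_b`,
#'   `time_days` (the shared time point), `value` (Bray-Curtis), ordered
#'   deterministically.
#' @export
dispersion_pairs <- function(ds) {
  stopifnot(inherits(ds, "mrc_dataset"))
  meta <- ds$meta |> dplyr::arrange(.data$time_series_id, .data$time_days,
                                    .data$sample_id)
  groups <- split(meta, list(meta$time_series_id, meta$time_days),
                  drop = TRUE)
  recs <- purrr::map(groups, function(g) {
    if (nrow(g) < 2L) return(NULL)
    cmb <- combn(nrow(g), 2L)
    same_unit <- g$unit_id[cmb[1L, ]] == g$unit_id[cmb[2L, ]]
    cmb <- cmb[, !same_unit, drop = FALSE]
    if (!ncol(cmb)) return(NULL)
    ab <- pair_tibble(g[cmb[1L, ], ], g[cmb[2L, ], ])
    tibble::tibble(
      time_series_id = g$time_series_id[1L],
      study_id = g$study_id[1L],
      environment = g$environment[1L],
      kind = "dispersion",
      sample_a = ab$sample_a,
      sample_b = ab$sample_b,
      time_days = g$time_days[1L]
    )
  })
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) return(empty_pairs())
  out$value <- bc_pairs(ds$counts,
                        match(out$sample_a, colnames(ds$counts)),
                        match(out$sample_b, colnames(ds$counts)))
  dplyr::arrange(out, .data$time_series_id, .data$time_days,
                 .data$sample_a, .data$sample_b)
}

#' Control-versus-recovery turnover pairs
#'
#' Within each time series, pairs every pre-disturbance control sample
#' (`time_days < 0`; multiple control time points are pooled) with every
#' post-disturbance sample up to `horizon` days, and computes Bray-Curtis
#' dissimilarity (*turnover*). The pair's time coordinate is the
#' post-disturbance sample's `time_days`, so a negative modeled slope over
#' time means recovery toward the pre-disturbance composition and a
#' positive slope means drift away from it.
#'
#' @param ds An `mrc_dataset`.
#' @param horizon Latest post-disturbance day included (default 50).
#' @param exclude_same_unit If `TRUE`, drop control-vs-post pairs sharing an
#'   experimental unit (sensitivity option; by default all control x post
#'   combinations are kept).
#' @return A tibble of pair records as in [dispersion_pairs()], with
#'   `kind = "turnover"`. Time series without any control sample are
#'   excluded with a warning.
#' @export
turnover_pairs <- function(ds, horizon = 50, exclude_same_unit = FALSE) {
  stopifnot(inherits(ds, "mrc_dataset"))
  meta <- ds$meta |> dplyr::arrange(.data$time_series_id, .data$time_days,
                                    .data$sample_id)
  series <- split(meta, meta$time_series_id, drop = TRUE)
  no_ctrl <- character(0)
  recs <- purrr::map(series, function(g) {
    ctrl <- g[g$time_days < 0, , drop = FALSE]
    post <- g[g$time_days >= 0 & g$time_days <= horizon, , drop = FALSE]
    if (!nrow(ctrl)) {
      no_ctrl <<- c(no_ctrl, g$time_series_id[1L])
      return(NULL)
    }
    if (!nrow(post)) return(NULL)
    idx <- expand.grid(i = seq_len(nrow(ctrl)), j = seq_len(nrow(post)))
    if (exclude_same_unit) {
      idx <- idx[ctrl$unit_id[idx$i] != post$unit_id[idx$j], , drop = FALSE]
    }
    if (!nrow(idx)) return(NULL)
    tibble::tibble(
      time_series_id = g$time_series_id[1L],
      study_id = g$study_id[1L],
      environment = g$environment[1L],
      kind = "turnover",
      sample_a = ctrl$sample_id[idx$i],
      sample_b = post$sample_id[idx$j],
      time_days = post$time_days[idx$j]
    )
  })
  if (length(no_ctrl)) {
    warn(paste0("time series without pre-disturbance controls excluded: ",
                paste(unique(no_ctrl), collapse = ", ")))
  }
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) return(empty_pairs())
  out$value <- bc_pairs(ds$counts,
                        match(out$sample_a, colnames(ds$counts)),
                        match(out$sample_b, colnames(ds$counts)))
  dplyr::arrange(out, .data$time_series_id, .data$time_days,
                 .data$sample_a, .data$sample_b)
}

empty_pairs <- function() {
  tibble::tibble(time_series_id = character(), study_id = character(),
                 environment = factor(character(), levels = ENV_LEVELS),
                 kind = character(), sample_a = character(),
                 sample_b = character(), time_days = numeric(),
                 value = numeric())
}
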