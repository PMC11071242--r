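# Depth standardisation (rarefaction), coverage, and Hill-number diversity.

#' Rarefy samples to a common read depth
#'
#' Randomly subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw, one draw per sample) down to a fixed depth. Samples
#' whose total reads fall below the target depth are dropped and recorded in
#' provenance. With `mode = "perstudy"` the depth is the deepest depth
#' attainable by every sample of a study, bounded below by `depth` (the
#' within-study standardisation used as a robustness check on global
#' rarefaction).
#'
#' @param ds An `mrc_dataset` (or a bare counts matrix, in which case a
#'   matrix is returned).
#' @param depth Target reads per sample (default 1500).
#' @param seed Integer seed; the rarefied table is bit-identical across runs
#'   with the same seed.
#' @param mode `"global"` (one depth for all samples) or `"perstudy"`.
#' @return The rarefied `mrc_dataset` (or matrix) in which every retained
#'   sample's column sum equals its target depth exactly.
#' @export
rarefy <- function(ds, depth = 1500L, seed = 1L, mode = c("global", "perstudy")) {
  mode <- match.arg(mode)
  bare <- is.matrix(ds)
  counts <- if (bare) validate_counts(ds) else ds$counts
  if (depth < 1L) abort("depth must be >= 1")
  totals <- colSums(counts)
  target <- rep(as.integer(depth), ncol(counts))
  if (mode == "perstudy") {
    if (bare) abort("perstudy mode needs a dataset with metadata")
    study <- ds$meta$study_id[match(colnames(counts), ds$meta$sample_id)]
    per <- tapply(totals, study, min)
    target <- pmax(as.integer(depth), as.integer(per[study]))
  }
  keep <- totals >= target
  if (!any(keep)) abort("all samples fall below the rarefaction depth")
  dropped <- colnames(counts)[!keep]
  if (length(dropped)) {
    inform(paste0("rarefy: dropping ", length(dropped),
                  " sample(s) below depth"))
  }
  counts <- counts[, keep, drop = FALSE]
  target <- target[keep]
  set.seed(seed)
  # vegan::rrarefy works on sample-rows and accepts per-sample depths; it
  # warns whenever a sample's smallest count exceeds 1, which is spurious
  # here (inputs are validated integer counts)
  out <- suppressWarnings(t(vegan::rrarefy(t(counts), target)))
  storage.mode(out) <- "integer"
  if (bare) return(out)
  meta <- ds$meta[ds$meta$sample_id %in% colnames(out), , drop = FALSE]
  prov <- ds$provenance
  prov$rarefaction <- list(depth = as.integer(depth), mode = mode,
                           seed = as.integer(seed),
                           n_dropped = length(dropped),
                           dropped_samples = dropped)
  structure(list(counts = out, meta = meta, provenance = prov),
            class = "mrc_dataset")
}

#' Estimated sample completeness (coverage)
#'
#' The Chao–Jost coverage estimator: the estimated fraction of the
#' community's individuals that belong to taxa detected in the sample,
#' computed from singleton (`f1`) and doubleton (`f2`) counts at depth `n`:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2}.}
#' With no singletons the sample is taken as complete (returns 1).
#'
#' @param x Integer count vector for one sample.
#' @return Coverage estimate in `[0, 1]`.
#' @export
completeness <- function(x) {
  x <- x[x > 0]
  if (!length(x)) abort("completeness is undefined for an empty sample")
  n <- sum(x)
  f1 <- sum(x == 1L)
  f2 <- sum(x == 2L)
  if (f1 == 0L) return(1)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Hill-number diversity of a sample
#'
#' Order `q = 0` is observed richness (number of taxa with positive count);
#' order `q = 2` is the inverse Simpson index, `1 / sum(p_i^2)`, the
#' dominance-weighted effective number of taxa.
#'
#' @param x Integer count vector for one sample.
#' @param q Hill order, 0 or 2.
#' @return Diversity value; for any sample `q2 <= q0`, with equality iff all
#'   positive counts are equal.
#' @export
hill_diversity <- function(x, q = 0) {
  if (!length(x) || all(x == 0)) abort("hill_diversity needs a non-empty sample")
  if (!q %in% c(0, 2)) abort("q must be 0 or 2")
  if (q == 0) return(sum(x > 0))
  as.numeric(vegan::diversity(x, index = "invsimpson"))
}

#' Per-sample diversity and coverage table
#'
#' Computes, for every sample of a (typically rarefied) dataset, observed
#' richness (Hill q=0), inverse Simpson (Hill q=2), read depth, and
#' estimated sample completeness, joined to the design metadata.
#'
#' @param ds An `mrc_dataset`.
#' @return A tibble with one row per sample: `sample_id`, `richness_q0`,
#'   `invsimpson_q2`, `depth`, `completeness`, plus the design columns.
#' @export
diversity_table <- function(ds) {
  stopifnot(inherits(ds, "mrc_dataset"))
  cts <- ds$counts
  rec <- tibble::tibble(
    sample_id = colnames(cts),
    richness_q0 = as.integer(colSums(cts > 0L)),
    invsimpson_q2 = as.numeric(vegan::diversity(t(cts), index = "invsimpson")),
    depth = as.integer(colSums(cts)),
    completeness = vapply(seq_len(ncol(cts)),
                          function(j) completeness(cts[, j]), numeric(1))
  )
  dplyr::left_join(rec, ds$meta, by = "sample_id")
}
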