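# Richness-preserving permutation null model and Z-scores.
#
# The null randomises *which* taxa carry a sample's abundance values while
# keeping each sample's richness and depth fixed, so deviations of observed
# Bray-Curtis from the null isolate composition-driven change from
# richness-driven change.

#' Richness-preserving permutation of a count table
#'
#' For each sample independently, the multiset of its positive abundance
#' values is reassigned, without replacement, to a uniformly random subset
#' of the candidate taxon pool of size equal to that sample's richness;
#' every other taxon gets zero. Per-sample richness and total reads are
#' preserved exactly.
#'
#' @param counts Integer matrix (taxa x samples).
#' @param pool Character vector of candidate taxon identifiers; must
#'   contain every taxon with a positive count in `counts`.
#' @param seed Integer seed.
#' @return An integer matrix with rows `pool` (in the given order) and the
#'   same sample columns.
#' @export
permute_matrix <- function(counts, pool = rownames(counts), seed = 1L) {
  counts <- validate_counts(counts)
  pool <- unique(as.character(pool))
  occupied <- rownames(counts)[rowSums(counts > 0L) > 0L]
  if (!all(occupied %in% pool)) {
    abort("pool must contain every taxon with positive counts")
  }
  set.seed(seed)
  vals <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    as.integer(v[v > 0L])
  })
  k <- lengths(vals)
  if (any(k > length(pool))) {
    abort("pool smaller than a sample's richness")
  }
  out <- matrix(0L, nrow = length(pool), ncol = ncol(counts),
                dimnames = list(pool, colnames(counts)))
  for (j in seq_len(ncol(counts))) {
    out[sample.int(length(pool), k[j]), j] <- vals[[j]]
  }
  out
}

#' Null expectations and Z-scores for a pair set
#'
#' Generates `n_resamples` richness-preserving permuted matrices and
#' recomputes every pair's Bray-Curtis dissimilarity on each, yielding a
#' per-pair null mean and SD and the Z-score
#' `z = (u_observed - mu_expected) / sigma_expected`. Resampling is
#' matrix-wise: within a time series, the same permuted matrix of a given
#' iteration serves all of that series' dispersion and turnover pairs, so
#' their nulls are coupled. The candidate taxon pool is the union of taxa
#' observed anywhere in the same time series (`pool_scope = "time_series"`,
#' default — taxa from unrelated studies are never candidate colonists) or
#' anywhere in the same study (`"study"`, sensitivity option).
#'
#' @param ds An `mrc_dataset` (the matrix the pairs were computed from).
#' @param pairs Pair tibble from [dispersion_pairs()] / [turnover_pairs()]
#'   (rows may be concatenated).
#' @param n_resamples Number of permuted matrices (default 1000).
#' @param pool_scope `"time_series"` or `"study"`.
#' @param seed Integer master seed; output is bit-identical across runs.
#' @return The pair tibble with columns `u_observed`, `mu_expected`,
#'   `sigma_expected`, `z`, and `n_resamples` appended. Pairs with zero
#'   null SD get `z = NA` with a warning (they carry no compositional
#'   signal beyond richness) and are excluded from Z-score models.
#' @export
null_zscores <- function(ds, pairs, n_resamples = 1000L,
                         pool_scope = c("time_series", "study"),
                         seed = 1L) {
  stopifnot(inherits(ds, "mrc_dataset"))
  pool_scope <- match.arg(pool_scope)
  if (n_resamples < 2L) abort("n_resamples must be >= 2")
  if (!nrow(pairs)) {
    return(dplyr::mutate(pairs, u_observed = numeric(), mu_expected = numeric(),
                         sigma_expected = numeric(), z = numeric(),
                         n_resamples = integer()))
  }
  scope_col <- if (pool_scope == "time_series") "time_series_id" else "study_id"
  meta <- ds$meta
  samp_scope <- meta[[scope_col]][match(colnames(ds$counts), meta$sample_id)]
  pair_scope <- pairs[[scope_col]]

  set.seed(seed)
  out <- pairs
  out$u_observed <- pairs$value
  out$mu_expected <- NA_real_
  out$sigma_expected <- NA_real_

  for (g in sort(unique(pair_scope))) {
    cols <- which(samp_scope == g)
    sub <- ds$counts[, cols, drop = FALSE]
    pool_rows <- which(rowSums(sub > 0L) > 0L)
    sub <- sub[pool_rows, , drop = FALSE]
    P <- nrow(sub)
    vals <- lapply(seq_len(ncol(sub)), function(j) {
      v <- sub[, j]
      as.integer(v[v > 0L])
    })
    k <- lengths(vals)
    rows <- which(pair_scope == g)
    ia <- match(pairs$sample_a[rows], colnames(sub))
    ib <- match(pairs$sample_b[rows], colnames(sub))
    s1 <- numeric(length(rows))
    s2 <- numeric(length(rows))
    X <- matrix(0L, nrow = P, ncol = ncol(sub))
    for (it in seq_len(n_resamples)) {
      X[] <- 0L
      for (j in seq_len(ncol(sub))) {
        X[sample.int(P, k[j]), j] <- vals[[j]]
      }
      bc <- bc_pairs(X, ia, ib)
      s1 <- s1 + bc
      s2 <- s2 + bc * bc
    }
    mu <- s1 / n_resamples
    ss <- pmax(s2 - n_resamples * mu * mu, 0)
    out$mu_expected[rows] <- mu
    out$sigma_expected[rows] <- sqrt(ss / (n_resamples - 1L))
  }
  out$z <- ifelse(out$sigma_expected > 0,
                  (out$u_observed - out$mu_expected) / out$sigma_expected,
                  NA_real_)
  if (anyNA(out$z)) {
    warn(paste0(sum(is.na(out$z)),
                " pair(s) with zero null SD: z recorded as NA"))
  }
  out$n_resamples <- as.integer(n_resamples)
  out
}
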