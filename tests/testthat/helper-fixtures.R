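# Shared fixtures and independent oracles, built in code.

tiny_counts <- function() {
  m <- matrix(c(5L, 0L,
                1L, 2L,
                0L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(c("tA", "tB", "tC"), c("s1", "s2")))
  m
}

make_meta <- function(sample_id, time_series_id = "ts1", study_id = "st1",
                      environment = "soil", time_days = 0,
                      replicate_id = NULL, unit_id = NULL,
                      disturbance_type = "mortality") {
  n <- length(sample_id)
  tibble::tibble(
    sample_id = sample_id,
    study_id = rep_len(study_id, n),
    time_series_id = rep_len(time_series_id, n),
    environment = rep_len(environment, n),
    disturbance_type = rep_len(disturbance_type, n),
    time_days = rep_len(time_days, n),
    replicate_id = replicate_id %||% paste0("r", seq_len(n)),
    unit_id = unit_id %||% paste0("u_", sample_id)
  )
}

write_counts_tsv <- function(counts, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_meta_tsv <- function(meta, path = tempfile(fileext = ".tsv")) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force Bray-Curtis: explicit element loop, independent of the
# vectorised implementation.
bc_loop <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# All possible richness-preserving assignments of one sample's positive
# values onto a pool of P taxa: every ordered choice of k distinct slots.
# Returns a matrix with one column per assignment (P rows).
enum_assignments <- function(values, P) {
  k <- length(values)
  subsets <- utils::combn(P, k)
  perms <- perm_matrix(k)
  out <- matrix(0L, nrow = P,
                ncol = ncol(subsets) * nrow(perms))
  col <- 0L
  for (s in seq_len(ncol(subsets))) {
    slots <- subsets[, s]
    for (p in seq_len(nrow(perms))) {
      col <- col + 1L
      out[slots, col] <- values[perms[p, ]]
    }
  }
  out
}

perm_matrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# Exact null mean/SD (and fourth central moment) of Bray-Curtis between two
# samples under independent uniform richness-preserving assignment.
enum_null_moments <- function(values_a, values_b, P) {
  A <- enum_assignments(values_a, P)
  B <- enum_assignments(values_b, P)
  vals <- numeric(ncol(A) * ncol(B))
  idx <- 0L
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      idx <- idx + 1L
      vals[idx] <- bc_loop(A[, i], B[, j])
    }
  }
  mu <- mean(vals)
  list(mu = mu,
       sigma = sqrt(mean((vals - mu)^2)),
       mu4 = mean((vals - mu)^4))
}

# A dataset generated *by the null process itself*: each sample's support
# is a uniform subset of a fixed per-series pool, with independent pairs
# (two samples per time point), so dispersion Z-scores are null-true.
make_null_true_dataset <- function(n_series = 170L, pool_size = 20L,
                                   richness = 10L, timepoints = 6L,
                                   seed = 1L) {
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(pool_size))
  cols <- list()
  meta <- list()
  for (g in seq_len(n_series)) {
    sid <- sprintf("ts%03d", g)
    for (tp in seq_len(timepoints)) {
      for (r in 1:2) {
        id <- sprintf("%s_tp%02d_r%d", sid, tp, r)
        v <- integer(pool_size)
        v[sample.int(pool_size, richness)] <-
          pmax(1L, as.integer(round(rlnorm(richness, 3, 1))))
        cols[[id]] <- v
        meta[[id]] <- make_meta(id, time_series_id = sid,
                                study_id = sprintf("st%02d", (g - 1) %/% 10 + 1),
                                time_days = tp)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- taxa
  new_dataset(counts, dplyr::bind_rows(meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
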