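# Reading, validation, and design-aware filtering of count tables + metadata.

META_COLUMNS <- c("sample_id", "study_id", "time_series_id", "environment",
                  "disturbance_type", "time_days", "replicate_id", "unit_id")

#' Read a taxon-by-sample count table
#'
#' Reads an integer abundance matrix from a TSV matrix (taxa as rows,
#' samples as columns, first column holding taxon identifiers and the
#' header row holding sample identifiers) or from a BIOM file.
#'
#' @param path Path to the input file.
#' @param format `"tsv_matrix"` (default) or `"biom"`.
#' @param transpose If `TRUE`, the TSV is read as samples-rows by
#'   taxa-columns and transposed. Off by default; the taxa-rows dialect is
#'   the common amplicon convention.
#' @return An integer matrix (taxa x samples) with unique dimnames,
#'   validated by [validate_counts()].
#' @export
read_counts <- function(path, format = c("tsv_matrix", "biom"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("count table not found: ", path))
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) {
      abort(paste0("malformed count table (need >= 2 columns): ", path))
    }
    ids <- as.character(df[[1L]])
    header <- colnames(df)[-1L]  # before subsetting: `[.data.frame`
                                 # silently make.unique()s duplicates
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      abort(paste0("non-numeric counts in column '",
                   header[bad], "' of ", path))
    }
    dimnames(m) <- list(ids, header)
    if (transpose) m <- t(m)
  }
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks that counts are non-negative integers with unique taxon and
#' sample identifiers; drops all-zero sample columns (with a warning) so
#' that downstream relative-abundance computations are well defined.
#'
#' @param counts Numeric matrix, taxa x samples, with dimnames.
#' @return The validated integer matrix.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) abort("counts must be a matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(paste0("duplicated taxon identifiers: ",
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(paste0("duplicated sample identifiers: ",
                 paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                       collapse = ", ")))
  }
  if (anyNA(counts)) abort("counts contain missing values")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    abort(paste0("negative count at taxon '", rownames(counts)[idx[1L]],
                 "', sample '", colnames(counts)[idx[2L]], "'"))
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    abort(paste0("non-integer count at taxon '", rownames(counts)[idx[1L]],
                 "', sample '", colnames(counts)[idx[2L]], "'"))
  }
  storage.mode(counts) <- "integer"
  zero <- colSums(counts) == 0L
  if (any(zero)) {
    warn(paste0("dropping ", sum(zero), " all-zero sample(s): ",
                paste(colnames(counts)[zero], collapse = ", ")))
    counts <- counts[, !zero, drop = FALSE]
  }
  counts
}

#' Read per-sample design metadata
#'
#' Reads a TSV with the eight required design columns (`sample_id`,
#' `study_id`, `time_series_id`, `environment`, `disturbance_type`,
#' `time_days`, `replicate_id`, `unit_id`). Environments are parsed
#' case-insensitively into the three-level factor aquatic / mammal / soil.
#' Samples with `time_days < 0` are the pre-disturbance controls.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with typed columns and an added logical
#'   `pre_disturbance` column (`time_days < 0`).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_metadata(df)
}

#' Validate a metadata table
#'
#' @param meta A data frame with the eight required columns.
#' @return A typed, validated tibble.
#' @export
validate_metadata <- function(meta) {
  missing <- setdiff(META_COLUMNS, names(meta))
  if (length(missing)) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta <- tibble::as_tibble(meta)
  env_raw <- tolower(trimws(as.character(meta$environment)))
  bad <- !env_raw %in% ENV_LEVELS
  if (any(bad)) {
    abort(paste0("unknown environment label(s): ",
                 paste(unique(meta$environment[bad]), collapse = ", "),
                 " (expected aquatic, mammal, or soil)"))
  }
  out <- meta |>
    dplyr::mutate(
      dplyr::across(c("sample_id", "study_id", "time_series_id",
                      "disturbance_type", "replicate_id", "unit_id"),
                    as.character),
      environment = factor(env_raw, levels = ENV_LEVELS),
      time_days = as.numeric(.data$time_days)
    )
  if (anyNA(out$time_days)) abort("time_days contains non-numeric values")
  if (anyDuplicated(out$sample_id)) {
    abort(paste0("duplicated sample_id in metadata: ",
                 paste(unique(out$sample_id[duplicated(out$sample_id)]),
                       collapse = ", ")))
  }
  # one study and one environment per time series
  chk <- out |>
    dplyr::distinct(.data$time_series_id, .data$study_id, .data$environment) |>
    dplyr::count(.data$time_series_id)
  if (any(chk$n > 1L)) {
    abort(paste0("time series mapped to multiple studies/environments: ",
                 paste(chk$time_series_id[chk$n > 1L], collapse = ", ")))
  }
  out$pre_disturbance <- out$time_days < 0
  out
}

#' Bundle counts and metadata into a dataset
#'
#' The canonical container used by every downstream stage. Samples present
#' in the count table but absent from the metadata are a hard error (silent
#' design corruption); metadata rows without counts are dropped with a
#' message.
#'
#' @param counts Validated integer matrix (taxa x samples).
#' @param meta Validated metadata tibble.
#' @param provenance Optional named list of free-form run metadata.
#' @return An object of class `mrc_dataset`: a list with elements
#'   `counts`, `meta`, and `provenance`.
#' @export
new_dataset <- function(counts, meta, provenance = list()) {
  counts <- validate_counts(counts)
  meta <- validate_metadata(meta)
  orphans <- setdiff(colnames(counts), meta$sample_id)
  if (length(orphans)) {
    abort(paste0("samples present in counts but absent from metadata: ",
                 paste(head(orphans, 10L), collapse = ", ")))
  }
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra)) {
    inform(paste0("dropping ", length(extra),
                  " metadata row(s) without counts"))
    meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, meta = meta, provenance = provenance),
            class = "mrc_dataset")
}

#' @export
print.mrc_dataset <- function(x, ...) {
  cat("<mrc_dataset> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  studies: ", dplyr::n_distinct(x$meta$study_id),
      " | time series: ", dplyr::n_distinct(x$meta$time_series_id),
      " | environments: ",
      paste(levels(droplevels(x$meta$environment)), collapse = ", "),
      "\n", sep = "")
  cat("  time range (days): [", min(x$meta$time_days), ", ",
      max(x$meta$time_days), "]\n", sep = "")
  invisible(x)
}

#' Drop under-replicated time points
#'
#' Within each time series, removes every time point (exact `time_days`
#' group) observed with fewer than `min_reps` experimental replicates, so
#' that within-time-point dispersion is measurable everywhere downstream.
#' Idempotent; dropped samples are recorded in the dataset provenance.
#'
#' @param ds An `mrc_dataset`.
#' @param min_reps Minimum replicates per (time series, time point) group.
#' @return The filtered `mrc_dataset` (possibly with zero samples, in which
#'   case a warning is issued).
#' @export
filter_replicates <- function(ds, min_reps = 3L) {
  stopifnot(inherits(ds, "mrc_dataset"))
  keep_tbl <- ds$meta |>
    dplyr::add_count(.data$time_series_id, .data$time_days, name = ".n_reps")
  keep <- keep_tbl$.n_reps >= min_reps
  dropped <- ds$meta$sample_id[!keep]
  if (!any(keep)) {
    warn("replicate filtering removed every sample")
  }
  meta <- ds$meta[keep, , drop = FALSE]
  counts <- ds$counts[, meta$sample_id, drop = FALSE]
  prov <- ds$provenance
  prov$replicate_filter <- list(
    min_reps = as.integer(min_reps),
    n_dropped = length(dropped),
    dropped_samples = dropped,
    reason = "fewer than min_reps replicates at the time point"
  )
  structure(list(counts = counts, meta = meta, provenance = prov),
            class = "mrc_dataset")
}

#' Write a dataset to disk
#'
#' Serialises the canonical dataset as two TSVs (counts matrix + metadata)
#' and a JSON provenance sidecar.
#'
#' @param ds An `mrc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "mrc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- data.frame(taxon_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE)
  utils::write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta_out <- ds$meta
  meta_out$environment <- as.character(meta_out$environment)
  utils::write.table(meta_out[META_COLUMNS], file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding `counts.tsv`, `metadata.tsv`, and
#'   `provenance.json`.
#' @return An `mrc_dataset`.
#' @export
read_dataset <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else list()
  new_dataset(counts, meta, prov)
}
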