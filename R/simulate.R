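# Synthetic multi-study disturbance time series with known parameters.
#
# The generator emulates the structure the analysis assumes: several
# studies per environment, several time series (disturbance treatments)
# per study, >= 3 replicates per time point, pre-disturbance controls,
# post-disturbance sampling within 50 days, study-level intercept
# variation, series-level slope variation, and (optionally) repeated
# measures where the same experimental unit is resampled over time.

#' Simulation configuration
#'
#' @param environment One of `"aquatic"`, `"mammal"`, `"soil"`.
#' @param n_studies,series_per_study Design size.
#' @param pool_size Taxa in the regional pool.
#' @param baseline_richness Expected pre-disturbance richness of one
#'   community (before study/series offsets); must not exceed `pool_size`.
#' @param depth_mean Mean sequencing depth; per-sample depths are
#'   Poisson-distributed around it so rarefaction has real work to do.
#' @param replicate_count Replicates per time point (>= 3, matching the
#'   inclusion criterion the analysis assumes).
#' @param times Sampling days; must include at least one pre-disturbance
#'   day (< 0), one immediate day (in `[0, 4)`), and one later day (in
#'   `[4, 50]`).
#' @param richness_loss_frac Fraction of resident taxa *surviving* the
#'   disturbance (1 = no loss; mammal-like strong loss = 0.43).
#' @param recovery_rate_per_day Multiplicative daily richness recovery
#'   (1.02 = +2%/day); richness is capped at its pre-disturbance value.
#' @param drift_rate_logit_per_day Compositional drift rate: surviving
#'   taxa's log relative abundances diverge from baseline at this rate per
#'   day along a random series-specific direction.
#' @param study_sd Between-study SD of the log-richness intercept.
#' @param series_slope_sd Between-series SD of per-day slopes (applied to
#'   the log-richness recovery rate and the drift rate).
#' @param pool_sdlog SD of the lognormal pool abundance profile.
#' @param repeated_measures If `TRUE`, replicate r shares one experimental
#'   unit across all time points of a series.
#' @param selective_removal If `TRUE` (default), the disturbance removes
#'   the most susceptible taxa by a per-series susceptibility score, so
#'   the same taxa die (and later return) across replicates; if `FALSE`,
#'   removal is iid per sample (non-selective disturbance).
#' @param seed Master seed; the generated dataset is bit-identical across
#'   runs with the same config.
#' @return A list of class `mrc_sim_config`.
#' @export
sim_config <- function(environment = c("soil", "aquatic", "mammal"),
                       n_studies = 3L, series_per_study = 2L,
                       pool_size = 300L, baseline_richness = 100L,
                       depth_mean = 3000L, replicate_count = 3L,
                       times = c(-3, -1, 1, 7, 21, 35),
                       richness_loss_frac = 1,
                       recovery_rate_per_day = 1,
                       drift_rate_logit_per_day = 0,
                       study_sd = 0.15, series_slope_sd = 0.003,
                       pool_sdlog = 1, repeated_measures = TRUE,
                       selective_removal = TRUE, seed = 1L) {
  environment <- match.arg(environment)
  cfg <- list(environment = environment, n_studies = as.integer(n_studies),
              series_per_study = as.integer(series_per_study),
              pool_size = as.integer(pool_size),
              baseline_richness = as.integer(baseline_richness),
              depth_mean = as.integer(depth_mean),
              replicate_count = as.integer(replicate_count),
              times = as.numeric(times),
              n_timepoints = length(times),
              richness_loss_frac = richness_loss_frac,
              recovery_rate_per_day = recovery_rate_per_day,
              drift_rate_logit_per_day = drift_rate_logit_per_day,
              study_sd = study_sd, series_slope_sd = series_slope_sd,
              pool_sdlog = pool_sdlog,
              repeated_measures = isTRUE(repeated_measures),
              selective_removal = isTRUE(selective_removal),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "mrc_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$replicate_count < 3L) {
    abort("replicate_count must be >= 3 (triplicate inclusion criterion)")
  }
  if (!any(cfg$times < 0) || !any(cfg$times >= 0 & cfg$times < 4) ||
      !any(cfg$times >= 4 & cfg$times <= 50)) {
    abort(paste0("times must include a pre-disturbance day (< 0), an ",
                 "immediate day in [0, 4), and a later day in [4, 50]"))
  }
  if (cfg$richness_loss_frac < 0 || cfg$richness_loss_frac > 1) {
    abort("richness_loss_frac (surviving fraction) must be in [0, 1]")
  }
  # study offsets inflate richness; require headroom in the pool
  if (ceiling(cfg$baseline_richness * exp(3 * cfg$study_sd)) > cfg$pool_size) {
    abort("pool_size too small for baseline_richness given study_sd")
  }
  if (cfg$recovery_rate_per_day <= 0) abort("recovery rate must be positive")
  invisible(cfg)
}

#' Environment-flavoured simulation presets
#'
#' Encodes the qualitative disturbance regimes observed per environment:
#' mammal-associated microbiomes lose richness sharply (43% of taxa
#' survive) and recover it at ~2% per day through the return of the lost
#' taxa; aquatic microbiomes keep their richness but drift away from the
#' pre-disturbance composition; soil microbiomes respond weakly, with a
#' large taxon pool and less even abundances. `"null"` is a no-effect
#' configuration (no loss, no recovery, no drift) for calibration checks.
#' Baseline richness per environment follows typical pre-disturbance
#' means (mammal 86, aquatic 184, soil 327 taxa).
#'
#' @param environment `"mammal"`, `"aquatic"`, `"soil"`, or `"null"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return An `mrc_sim_config`.
#' @export
sim_preset <- function(environment = c("mammal", "aquatic", "soil", "null"),
                       ...) {
  environment <- match.arg(environment)
  base <- switch(environment,
    mammal = list(environment = "mammal", baseline_richness = 86L,
                  pool_size = 250L, richness_loss_frac = 0.43,
                  recovery_rate_per_day = 1.02,
                  drift_rate_logit_per_day = 0,
                  study_sd = 0.2, repeated_measures = TRUE,
                  selective_removal = TRUE),
    aquatic = list(environment = "aquatic", baseline_richness = 184L,
                   pool_size = 500L, richness_loss_frac = 1,
                   recovery_rate_per_day = 1,
                   drift_rate_logit_per_day = 0.03,
                   study_sd = 0.15, repeated_measures = TRUE),
    soil = list(environment = "soil", baseline_richness = 327L,
                pool_size = 900L, richness_loss_frac = 0.95,
                recovery_rate_per_day = 1,
                drift_rate_logit_per_day = 0.005,
                pool_sdlog = 1.2, study_sd = 0.15,
                repeated_measures = FALSE),
    null = list(environment = "soil", baseline_richness = 120L,
                pool_size = 400L, richness_loss_frac = 1,
                recovery_rate_per_day = 1,
                drift_rate_logit_per_day = 0,
                repeated_measures = TRUE)
  )
  do.call(sim_config, modifyList(base, list(...)))
}

#' Simulate a multi-study disturbance dataset
#'
#' Generative scheme: (i) a regional taxon pool with lognormal abundance
#' profile; (ii) study-level log-richness intercept offsets and
#' series-level per-day slope offsets; (iii) pre-disturbance communities
#' as abundance-weighted subsets of the pool; (iv) a disturbance at day 0
#' that removes a fraction of resident taxa — by a shared per-series
#' susceptibility ranking (selective mode, default) or iid per sample;
#' (v) recolonisation of the lost taxa so that expected richness follows
#' `R_after * recovery^t` (capped at the pre-disturbance richness), while
#' surviving taxa's relative abundances drift on the log scale at the
#' configured rate; (vi) multinomial counts at Poisson-distributed depth.
#'
#' @param cfg An `mrc_sim_config` from [sim_config()] or [sim_preset()].
#' @return A list with `dataset` (an `mrc_dataset`) and `truth` (per-series
#'   realized parameters: pre-disturbance richness, surviving counts, true
#'   before-after log effect, true log-richness recovery slope, true drift
#'   rate, plus the pool profile).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mrc_sim_config"))
  set.seed(cfg$seed)
  pool_ids <- sprintf("t%05d", seq_len(cfg$pool_size))
  pool_ab <- rlnorm(cfg$pool_size, meanlog = 0, sdlog = cfg$pool_sdlog)

  dist_labels <- c("mortality", "nutrient_addition", "invasion", "drought")
  counts_cols <- list()
  meta_rows <- list()
  truth_rows <- list()

  for (s in seq_len(cfg$n_studies)) {
    study_id <- sprintf("study%02d", s)
    study_off <- rnorm(1, 0, cfg$study_sd)
    for (g in seq_len(cfg$series_per_study)) {
      series_id <- sprintf("%s_ts%02d", study_id, g)
      series_int <- rnorm(1, 0, cfg$study_sd / 2)
      slope_off <- rnorm(1, 0, cfg$series_slope_sd)
      recovery_g <- cfg$recovery_rate_per_day * exp(slope_off)
      # drift variation is multiplicative: dissimilarity grows under drift
      # in any direction, so additive jitter around zero would turn a
      # null configuration into systematic positive turnover
      drift_g <- cfg$drift_rate_logit_per_day * exp(rnorm(1, 0, 0.2))

      R0 <- max(3L, min(cfg$pool_size,
                        round(cfg$baseline_richness * exp(study_off + series_int))))
      residents <- sample.int(cfg$pool_size, R0, prob = pool_ab)
      susceptibility <- stats::runif(R0)
      n_lost <- round((1 - cfg$richness_loss_frac) * R0)
      R_after <- R0 - n_lost
      if (R_after < 1L) { R_after <- 1L; n_lost <- R0 - 1L }
      ord <- order(susceptibility, decreasing = TRUE)
      lost_idx <- ord[seq_len(n_lost)]              # most susceptible die
      surv_idx <- setdiff(seq_len(R0), lost_idx)
      recol_order <- rev(lost_idx)                  # least susceptible return first
      drift_dir <- rnorm(R0)

      expected_present <- function(t) {
        if (t < 0) return(seq_len(R0))
        target <- min(R0, R_after * recovery_g^t)
        m <- max(0L, min(n_lost, round(target) - R_after))
        c(surv_idx, if (m > 0L) recol_order[seq_len(m)])
      }

      for (ti in seq_along(cfg$times)) {
        t <- cfg$times[ti]
        present_det <- expected_present(t)
        for (r in seq_len(cfg$replicate_count)) {
          if (cfg$selective_removal || t < 0) {
            present <- present_det
          } else {
            # iid removal: each resident dies independently per sample,
            # then a random subset of its lost taxa has recolonised
            alive <- stats::runif(R0) < cfg$richness_loss_frac
            lost_r <- which(!alive)
            target <- min(R0, R_after * recovery_g^t)
            p_back <- if (n_lost > 0) {
              max(0, min(1, (round(target) - R_after) / n_lost))
            } else 0
            back <- lost_r[stats::runif(length(lost_r)) < p_back]
            present <- sort(c(which(alive), back))
          }
          w <- pool_ab[residents[present]] *
            exp(drift_g * max(t, 0) * drift_dir[present])
          depth <- rpois(1, cfg$depth_mean)
          cnt <- as.integer(stats::rmultinom(1, depth, w))
          col <- integer(cfg$pool_size)
          col[residents[present]] <- cnt
          sid <- sprintf("%s_tp%02d_r%02d", series_id, ti, r)
          counts_cols[[sid]] <- col
          meta_rows[[sid]] <- tibble::tibble(
            sample_id = sid, study_id = study_id,
            time_series_id = series_id,
            environment = cfg$environment,
            disturbance_type = dist_labels[(g - 1L) %% length(dist_labels) + 1L],
            time_days = t,
            replicate_id = sprintf("r%02d", r),
            unit_id = if (cfg$repeated_measures) {
              sprintf("%s_u%02d", series_id, r)
            } else sid
          )
        }
      }
      truth_rows[[series_id]] <- tibble::tibble(
        time_series_id = series_id, study_id = study_id,
        environment = cfg$environment,
        richness_pre = R0, richness_after = R_after, n_lost = n_lost,
        before_after_log_effect = log(R_after / R0),
        log_richness_slope = log(recovery_g),
        drift_rate = drift_g
      )
    }
  }

  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- pool_ids
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  meta <- dplyr::bind_rows(meta_rows)
  ds <- new_dataset(counts, meta,
                    provenance = list(generator = "simulate_dataset",
                                      seed = cfg$seed,
                                      environment = cfg$environment,
                                      preset_effects = list(
                                        richness_loss_frac = cfg$richness_loss_frac,
                                        recovery_rate_per_day = cfg$recovery_rate_per_day,
                                        drift_rate_logit_per_day = cfg$drift_rate_logit_per_day)))
  truth <- list(series = dplyr::bind_rows(truth_rows),
                pool = tibble::tibble(taxon_id = pool_ids,
                                      abundance = pool_ab),
                config = cfg)
  list(dataset = ds, truth = truth)
}

#' Simulate a response table directly from the hierarchical model
#'
#' Draws observations from the before-after or time-series GLMM itself
#' (negative binomial, Beta, or Gaussian) with a known key effect, study
#' intercept offsets, and series intercept/slope offsets — the generator
#' used for exact parameter-recovery checks, where the injected truth must
#' equal the estimand. The community simulator, by contrast, produces
#' dissimilarity slopes only emergently.
#'
#' @param design `"before_after"` or `"time_series"`.
#' @param family `"nbinom"`, `"beta"`, or `"gaussian"`.
#' @param effect True key effect on the link scale (log ratio, logit
#'   slope per day, or identity slope).
#' @param intercept True intercept on the link scale.
#' @param n_studies,series_per_study,replicates Design size.
#' @param times Post-disturbance sampling days (time-series design); the
#'   before-after design uses days -1 and +1.
#' @param study_sd,series_int_sd,series_slope_sd Group SDs on the link
#'   scale.
#' @param shape NB shape (aggregation) parameter.
#' @param phi Beta precision.
#' @param sigma Gaussian residual SD.
#' @param environment Environment label for the generated series.
#' @param seed Integer seed.
#' @return A tibble shaped like the matching response table
#'   (`richness_q0` / `value` / `z` columns), with the truth attached as
#'   attributes `effect` and `intercept`.
#' @export
simulate_response <- function(design = c("time_series", "before_after"),
                              family = c("nbinom", "beta", "gaussian"),
                              effect, intercept,
                              n_studies = 6L, series_per_study = 4L,
                              replicates = 3L, times = c(1, 7, 14, 21, 35),
                              study_sd = 0.2, series_int_sd = 0.1,
                              series_slope_sd = 0.005,
                              shape = 10, phi = 40, sigma = 1,
                              environment = "mammal", seed = 1L) {
  design <- match.arg(design)
  family <- match.arg(family)
  set.seed(seed)
  xs <- if (design == "before_after") {
    tibble::tibble(time_days = rep(c(-1, 1), each = replicates))
  } else {
    tibble::tibble(time_days = rep(times, each = replicates))
  }
  rows <- list()
  for (s in seq_len(n_studies)) {
    u_s <- rnorm(1, 0, study_sd)
    for (g in seq_len(series_per_study)) {
      u_g <- rnorm(1, 0, series_int_sd)
      b_g <- rnorm(1, 0, series_slope_sd)
      x <- if (design == "before_after") {
        as.numeric(xs$time_days >= 0)
      } else {
        xs$time_days - mean(xs$time_days)
      }
      eta <- intercept + u_s + u_g + (effect + b_g) * x
      y <- switch(family,
        nbinom = rnbinom(length(eta), mu = exp(eta), size = shape),
        beta = {
          mu <- plogis(eta)
          rbeta(length(eta), mu * phi, (1 - mu) * phi)
        },
        gaussian = rnorm(length(eta), eta, sigma))
      rows[[paste(s, g)]] <- tibble::tibble(
        study_id = sprintf("study%02d", s),
        time_series_id = sprintf("study%02d_ts%02d", s, g),
        environment = environment,
        time_days = xs$time_days,
        y = y
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  col <- switch(family, nbinom = "richness_q0", beta = "value",
                gaussian = "z")
  names(out)[names(out) == "y"] <- col
  out$environment <- factor(out$environment, levels = ENV_LEVELS)
  attr(out, "effect") <- effect
  attr(out, "intercept") <- intercept
  out
}
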