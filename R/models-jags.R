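# JAGS backend: full posterior sampling for the hierarchical models.
#
# Weakly regularizing priors throughout: normal(0, 1) for slopes and
# contrasts, a wide normal for the intercept (responses are not
# standardized), half-normal(0, 1) for group SDs, and exponential priors
# for the negative-binomial shape and Beta precision. The shape/precision
# (and, for Gaussian Z-score models, the residual log-SD) vary among
# studies. Group intercepts use hierarchical centering (series means
# centered on study means centered on the global intercept + environment
# effect), which removes the additive confounding that otherwise cripples
# mixing of the intercept chain.

jags_model_string <- function(family, multi_env, multi_study, multi_series) {
  slope <- if (multi_series) {
    "s_series[series[i]] * x[i]"
  } else {
    paste0("(bx", if (multi_env) " + bxenv[env[i]]" else "", ") * x[i]")
  }
  base <- if (multi_series) {
    "c_series[series[i]]"
  } else if (multi_study) {
    paste0("a_study[study[i]]", if (multi_env) " + benv[env[i]]" else "")
  } else {
    paste0("b0", if (multi_env) " + benv[env[i]]" else "")
  }
  eta <- paste0(base, " + ", slope)

  lik <- switch(family,
    nbinom = paste0(
      "    y[i] ~ dnegbin(pr[i], r[study[i]])\n",
      "    pr[i] <- r[study[i]] / (r[study[i]] + mu[i])\n",
      "    log(mu[i]) <- ", eta, "\n"),
    beta = paste0(
      "    y[i] ~ dbeta(sh1[i], sh2[i])\n",
      "    sh1[i] <- mu[i] * phi[study[i]]\n",
      "    sh2[i] <- (1 - mu[i]) * phi[study[i]]\n",
      "    logit(mu[i]) <- ", eta, "\n"),
    gaussian = paste0(
      "    y[i] ~ dnorm(mu[i], pow(sigma_i[i], -2))\n",
      "    mu[i] <- ", eta, "\n",
      "    log(sigma_i[i]) <- g0",
      if (multi_env) " + genv[env[i]]" else "",
      if (multi_study) " + g_study[study[i]]" else "", "\n"))

  # group-level structure (hierarchically centered intercepts)
  series_mean <- paste0(
    if (multi_study) "a_study[study_of[g]]" else "b0",
    if (multi_env) " + benv[env_of[g]]" else "")
  slope_mean <- paste0("bx", if (multi_env) " + bxenv[env_of[g]]" else "")
  group <- paste0(
    if (multi_study) paste0(
      "  for (s in 1:n_study) { a_study[s] ~ dnorm(b0, pow(sd_study, -2)) }\n",
      "  sd_study ~ dnorm(0, 1) T(0,)\n") else "",
    if (multi_series) paste0(
      "  for (g in 1:n_series) {\n",
      "    c_series[g] ~ dnorm(", series_mean, ", pow(sd_int, -2))\n",
      "    s_series[g] ~ dnorm(", slope_mean, ", pow(sd_x, -2))\n",
      "  }\n",
      "  sd_int ~ dnorm(0, 1) T(0,)\n",
      "  sd_x ~ dnorm(0, 1) T(0,)\n") else "")

  env_priors <- if (multi_env) paste0(
    "  benv[1] <- 0\n  bxenv[1] <- 0\n",
    "  for (k in 2:n_env) {\n",
    "    benv[k] ~ dnorm(0, 1)\n    bxenv[k] ~ dnorm(0, 1)\n  }\n") else ""

  fam_priors <- switch(family,
    nbinom = "  for (s in 1:n_study) { r[s] ~ dexp(0.02) }\n",
    beta = "  for (s in 1:n_study) { phi[s] ~ dexp(0.01) }\n",
    gaussian = paste0(
      "  g0 ~ dnorm(0, 0.25)\n",
      if (multi_env) paste0(
        "  genv[1] <- 0\n",
        "  for (k in 2:n_env) { genv[k] ~ dnorm(0, 1) }\n") else "",
      if (multi_study) paste0(
        "  for (s in 1:n_study) { g_study[s] ~ dnorm(0, pow(sd_g, -2)) }\n",
        "  sd_g ~ dnorm(0, 1) T(0,)\n") else ""))

  paste0(
    "model {\n",
    "  for (i in 1:n) {\n", lik, "  }\n",
    "  b0 ~ dnorm(0, 0.04)\n",
    "  bx ~ dnorm(0, 1)\n",
    env_priors, group, fam_priors,
    "}\n")
}

fit_jags <- function(d, family, control = mcmc_control(), seed = 1L) {
  multi_env <- dplyr::n_distinct(d$environment) > 1L
  multi_study <- dplyr::n_distinct(d$study_id) > 1L
  multi_series <- dplyr::n_distinct(d$time_series_id) > 1L
  env_levels <- levels(d$environment)
  series_ids <- sort(unique(as.character(d$time_series_id)))
  study_ids <- sort(unique(as.character(d$study_id)))

  dat <- list(
    y = if (family == "nbinom") as.integer(d$y) else as.numeric(d$y),
    x = as.numeric(d$x),
    n = nrow(d),
    n_study = length(study_ids),
    study = match(as.character(d$study_id), study_ids)
  )
  if (multi_env) {
    dat$env <- match(as.character(d$environment), env_levels)
    dat$n_env <- length(env_levels)
  }
  if (multi_series) {
    dat$series <- match(as.character(d$time_series_id), series_ids)
    dat$n_series <- length(series_ids)
    first <- match(series_ids, as.character(d$time_series_id))
    if (multi_study) dat$study_of <- dat$study[first]
    if (multi_env) dat$env_of <- dat$env[first]
  }
  if (!multi_study) dat$study <- rep(1L, nrow(d))

  monitors <- c("b0", "bx",
                if (multi_env) c("benv", "bxenv"),
                if (multi_series) c("s_series", "sd_int", "sd_x"),
                if (multi_study) "sd_study",
                switch(family, nbinom = "r", beta = "phi",
                       gaussian = c("g0", if (multi_env) "genv")))

  inits <- lapply(seq_len(control$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  model_txt <- jags_model_string(family, multi_env, multi_study, multi_series)
  jm <- rjags::jags.model(textConnection(model_txt), data = dat,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$warmup, quiet = TRUE)
  update(jm, control$warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, variable.names = monitors,
                            n.iter = control$iter, thin = control$thin,
                            progress.bar = "none")

  mat <- as.matrix(sm)
  fixed_cols <- c("b0", "bx")
  canon <- c("intercept", "key")
  if (multi_env) {
    for (k in seq_along(env_levels)[-1L]) {
      fixed_cols <- c(fixed_cols, paste0("benv[", k, "]"),
                      paste0("bxenv[", k, "]"))
      canon <- c(canon, paste0("env_", env_levels[k]),
                 paste0("key:env_", env_levels[k]))
    }
  }
  draws_fixed <- mat[, fixed_cols, drop = FALSE]
  colnames(draws_fixed) <- canon

  # series slope *deviations* from the environment-level slope (the
  # sampled s_series are hierarchically centered)
  draws_series <- matrix(0, nrow = nrow(mat), ncol = length(series_ids),
                         dimnames = list(NULL, series_ids))
  if (multi_series) {
    for (g in seq_along(series_ids)) {
      centre <- mat[, "bx"]
      if (multi_env && dat$env_of[g] > 1L) {
        centre <- centre + mat[, paste0("bxenv[", dat$env_of[g], "]")]
      }
      draws_series[, g] <- mat[, paste0("s_series[", g, "]")] - centre
    }
  }

  scalar_pars <- c(fixed_cols,
                   if (multi_series) c("sd_int", "sd_x"),
                   if (multi_study) "sd_study")
  diag <- mcmc_diagnostics(sm, scalar_pars)
  notes <- character(0)
  if (is.finite(diag$max_rhat) && diag$max_rhat > 1.05) {
    notes <- "R-hat > 1.05 on at least one parameter; inspect convergence"
    warn(paste0("MCMC convergence flag: max R-hat = ",
                round(diag$max_rhat, 3)))
  }
  list(draws_fixed = draws_fixed, draws_series = draws_series,
       diagnostics = diag, notes = notes, model = NULL)
}

mcmc_diagnostics <- function(sm, pars) {
  pars <- intersect(pars, coda::varnames(sm))
  sub <- sm[, pars, drop = FALSE]
  max_rhat <- NA_real_
  if (coda::nchain(sm) >= 2L) {
    gd <- try(coda::gelman.diag(sub, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) {
      max_rhat <- max(gd$psrf[, 1L], na.rm = TRUE)
    }
  }
  ess <- try(coda::effectiveSize(sub), silent = TRUE)
  min_ess <- if (inherits(ess, "try-error")) NA_real_ else min(ess)
  list(converged = !is.finite(max_rhat) || max_rhat <= 1.05,
       max_rhat = max_rhat, min_ess = min_ess)
}
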