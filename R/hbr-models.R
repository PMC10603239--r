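# Hierarchical Bayesian models of AUC vs. hand position, fitted with JAGS.
#
# Population coefficients get weakly-informative normal priors, every
# coefficient carries an uncorrelated subject-level random effect with a
# half-normal SD prior, and the residual scale has a half-normal prior.
# With three observations per subject the subject-level model is
# saturated; partial pooling through the tau priors is what identifies it,
# a fact the parameter-recovery tests assert rather than assume.

#' Specification of one hierarchical HBR model
#'
#' @param form One of `names(HBR_FORMS)`. The response family is fixed by
#'   the form: lognormal for `intercept_only`, `linear`, `quadratic` and
#'   `piecewise`; normal for `exponential`.
#' @return An object of class `hbr_model_spec` with fields `form`,
#'   `family`, `parameter_names`, `n_par` and `random_effects` (all
#'   coefficients).
#' @export
hbr_model_spec <- function(form) {
  form <- match_form(form)
  info <- HBR_FORMS[[form]]
  structure(
    list(form = form, family = info$family,
         parameter_names = info$parameter_names, n_par = info$n_par,
         random_effects = info$parameter_names),
    class = "hbr_model_spec"
  )
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2; default 4).
#' @param warmup Warmup iterations per chain (default 1000).
#' @param iterations Total iterations per chain, inclusive of warmup
#'   (default 5000), so each chain contributes `iterations - warmup`
#'   post-warmup draws.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param n_adapt Sampler adaptation steps before warmup (default 500).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iterations = 5000,
                        seed = 1, n_adapt = 500) {
  assert_count(chains, "chains", min = 2L)
  assert_count(warmup, "warmup")
  assert_count(iterations, "iterations")
  if (iterations <= warmup) stop("'iterations' must exceed 'warmup'")
  structure(
    list(chains = as.integer(chains), warmup = as.integer(warmup),
         iterations = as.integer(iterations), seed = as.integer(seed),
         n_adapt = as.integer(n_adapt)),
    class = "mcmc_config"
  )
}

#' Default priors for a model specification
#'
#' Normal(0, 5) on population coefficients of the lognormal forms (log
#' scale); for the exponential form, Normal(0, 10) on the additive and
#' multiplicative parameters (response scale) and Normal(0, 2) on the rate.
#' Half-Normal(0, 2) on all subject-level SDs and on the residual scale.
#'
#' @param spec An [hbr_model_spec()].
#' @return List with `beta_sd` (vector), `tau_sd`, `sigma_sd`.
#' @export
default_priors <- function(spec) {
  beta_sd <- if (spec$form == "exponential") c(10, 10, 2) else rep(5, spec$n_par)
  list(beta_sd = beta_sd, tau_sd = 2, sigma_sd = 2)
}

jags_model_string <- function(spec) {
  mu_line <- if (spec$form == "exponential") {
    "    mu[k] <- b[subj[k], 1] + b[subj[k], 2] * exp(b[subj[k], 3] * x[k])"
  } else {
    "    mu[k] <- inprod(b[subj[k], 1:P], X[k, 1:P])"
  }
  lik_line <- if (spec$family == "lognormal") {
    "    y[k] ~ dlnorm(mu[k], prec)"
  } else {
    "    y[k] ~ dnorm(mu[k], prec)"
  }
  # non-centered random effects: b = beta + tau * z mixes through the
  # weak-identification funnel far better than the centered form here
  paste(
    "model {",
    "  for (k in 1:N) {",
    mu_line,
    lik_line,
    "  }",
    "  for (i in 1:S) {",
    "    for (j in 1:P) {",
    "      z[i, j] ~ dnorm(0, 1)",
    "      b[i, j] <- beta[j] + tau[j] * z[i, j]",
    "    }",
    "  }",
    "  for (j in 1:P) {",
    "    beta[j] ~ dnorm(0, beta_prior_prec[j])",
    "    tau[j] ~ dnorm(0, tau_prior_prec) T(0,)",
    "  }",
    "  sigma ~ dnorm(0, sigma_prior_prec) T(0,)",
    "  prec <- pow(sigma, -2)",
    "}",
    sep = "\n"
  )
}

# Stable hash of the modelled data so comparisons can assert that all fits
# saw the same observations.
auc_data_hash <- function(data) {
  rlang::hash(list(as.character(data$subject_id),
                   as.character(data$position),
                   as.numeric(data$auc)))
}

validate_auc_data <- function(data, spec, min_subjects = 2) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "position", "auc") %in% names(data)))
  if (length(unique(data$subject_id)) < min_subjects) stop("need >= 2 subjects")
  if (spec$family == "lognormal" && any(data$auc <= 0)) {
    bad <- which(data$auc <= 0)
    stop(sprintf("AUC must be positive under a lognormal family; offending row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(!is.finite(data$auc))) stop("non-finite AUC values")
  invisible(data)
}

#' Fit one hierarchical HBR model by MCMC
#'
#' Samples the hierarchical model for the given form: population
#' coefficients beta with weakly-informative normal priors, independent
#' subject-level deviations b_i ~ Normal(beta, diag(tau^2)) with
#' half-normal priors on tau, and a half-normal prior on the residual
#' scale sigma. The response is lognormal (location mu_i(x), scale sigma on
#' log AUC) for the first four forms and normal for the exponential form.
#'
#' Convergence is diagnosed with rank-normalized split-chain Rhat and
#' bulk/tail effective sample sizes on every population-level parameter; a
#' fit with any population Rhat above 1.05 is returned with
#' `converged = FALSE` (and a warning), never silently.
#'
#' @param data AUC table with columns subject_id, position, auc.
#' @param spec An [hbr_model_spec()] (or a form name).
#' @param mcmc An [mcmc_config()].
#' @param priors Prior scales, as from [default_priors()].
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An object of class `hbr_fit`: the spec, an iterations x chains x
#'   parameters draw array (population parameters and subject coefficients
#'   `b[i,j]`), population diagnostics, a convergence flag, the data and
#'   its hash.
#' @export
fit_hbr_model <- function(data, spec, mcmc = mcmc_config(),
                          priors = NULL, quiet = TRUE) {
  if (is.character(spec)) spec <- hbr_model_spec(spec)
  stopifnot(inherits(spec, "hbr_model_spec"), inherits(mcmc, "mcmc_config"))
  priors <- priors %||% default_priors(spec)
  validate_auc_data(data, spec)

  subjects <- sort(unique(as.character(data$subject_id)))
  subj <- match(as.character(data$subject_id), subjects)
  x <- position_index(data$position)
  S <- length(subjects)
  P <- spec$n_par
  y <- as.numeric(data$auc)

  jags_data <- list(
    N = length(y), S = S, P = P, y = y, subj = subj,
    beta_prior_prec = 1 / priors$beta_sd^2,
    tau_prior_prec = 1 / priors$tau_sd^2,
    sigma_prior_prec = 1 / priors$sigma_sd^2
  )
  if (spec$form == "exponential") {
    jags_data$x <- x
  } else {
    jags_data$X <- design_matrix(spec$form, x)
  }

  beta_init <- if (spec$form == "exponential") {
    c(mean(y), 1, 0.5)
  } else {
    c(mean(log(y)), rep(0, P - 1))
  }
  sigma_init <- if (spec$family == "lognormal") {
    max(stats::sd(log(y)), 0.05)
  } else {
    max(stats::sd(y), 0.05)
  }
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(beta = beta_init, tau = rep(0.5, P), sigma = sigma_init,
         z = matrix(0, S, P),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(mcmc$seed, ch))
  })

  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string(spec)),
                            data = jags_data, inits = inits,
                            n.chains = mcmc$chains, n.adapt = mcmc$n_adapt,
                            quiet = quiet)
    update(jm, mcmc$warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("beta", "tau", "sigma", "b"),
                        n.iter = mcmc$iterations - mcmc$warmup,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  par_names <- coda::varnames(samples)
  # JAGS drops brackets on length-1 vectors; normalize to beta[1]/tau[1]
  par_names[par_names == "beta"] <- "beta[1]"
  par_names[par_names == "tau"] <- "tau[1]"
  n_iter <- nrow(samples[[1]])
  draws <- array(
    NA_real_, dim = c(n_iter, mcmc$chains, length(par_names)),
    dimnames = list(NULL, NULL, par_names)
  )
  for (ch in seq_len(mcmc$chains)) draws[, ch, ] <- as.matrix(samples[[ch]])
  if (any(!is.finite(draws))) stop("sampler produced non-finite draws")

  pop_pars <- c(paste0("beta[", seq_len(P), "]"),
                paste0("tau[", seq_len(P), "]"), "sigma")
  diagnostics <- convergence_diagnostics(draws[, , pop_pars, drop = FALSE])
  pretty <- c(spec$parameter_names, paste0("tau_", spec$parameter_names), "sigma")
  diagnostics$parameter_label <- pretty[match(diagnostics$parameter, pop_pars)]
  converged <- all(diagnostics$rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("model '%s' did not converge (max population Rhat = %.3f)",
                    spec$form, max(diagnostics$rhat, na.rm = TRUE)))
  }

  structure(
    list(spec = spec, mcmc = mcmc, priors = priors, data = data,
         subjects = subjects, draws = draws, pop_pars = pop_pars,
         diagnostics = diagnostics, converged = converged,
         data_hash = auc_data_hash(data)),
    class = "hbr_fit"
  )
}

# Flatten the chain dimension: (iter x chain x par) -> (draw x par).
flat_draws <- function(fit, pars = NULL) {
  d <- fit$draws
  m <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(m) <- dimnames(d)[[3]]
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

#' Posterior summary of the population-level parameters
#'
#' @param fit An `hbr_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with posterior median, mean, SD and equal-tailed
#'   interval per population parameter, merged with the Rhat/ESS
#'   diagnostics.
#' @export
population_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "hbr_fit"))
  m <- flat_draws(fit, fit$pop_pars)
  a <- (1 - prob) / 2
  out <- data.frame(
    parameter = fit$diagnostics$parameter_label,
    median = apply(m, 2, stats::median),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    ci_lower = apply(m, 2, stats::quantile, probs = a),
    ci_upper = apply(m, 2, stats::quantile, probs = 1 - a),
    rhat = fit$diagnostics$rhat,
    bulk_ess = fit$diagnostics$bulk_ess,
    tail_ess = fit$diagnostics$tail_ess,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
print.hbr_fit <- function(x, ...) {
  cat(sprintf("Hierarchical HBR model: %s (%s family)\n", x$spec$form, x$spec$family))
  cat(sprintf("%d subjects, %d observations; %d chains x %d post-warmup draws%s\n",
              length(x$subjects), nrow(x$data), x$mcmc$chains,
              x$mcmc$iterations - x$mcmc$warmup,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(population_summary(x), digits = 3)
  invisible(x)
}

# Per-draw location matrix mu (draws x observations) for a fit.
location_draws <- function(fit, data = fit$data) {
  subj <- match(as.character(data$subject_id), fit$subjects)
  if (anyNA(subj)) stop("data contains subjects absent from the fit")
  x <- position_index(data$position)
  P <- fit$spec$n_par
  b <- lapply(seq_len(P), function(j) {
    flat_draws(fit, paste0("b[", seq_along(fit$subjects), ",", j, "]"))
  })
  if (fit$spec$form == "exponential") {
    b1 <- b[[1]][, subj, drop = FALSE]
    b2 <- b[[2]][, subj, drop = FALSE]
    b3 <- b[[3]][, subj, drop = FALSE]
    xm <- matrix(rep(x, each = nrow(b1)), nrow(b1), length(x))
    b1 + b2 * exp(b3 * xm)
  } else {
    X <- design_matrix(fit$spec$form, x)
    mu <- 0
    for (j in seq_len(P)) {
      mu <- mu + sweep(b[[j]][, subj, drop = FALSE], 2, X[, j], `*`)
    }
    mu
  }
}

#' Pointwise log-likelihood matrix
#'
#' Log-density of every observation under every post-warmup draw,
#' conditional on the subject-level coefficients: lognormal(mu_ik,
#' sigma_k) on AUC for the lognormal forms, Normal(mu_ik, sigma_k) for the
#' exponential form. This draws x observations matrix is the input to
#' [psis_loo()].
#'
#' @param fit An `hbr_fit`.
#' @param data AUC table (defaults to the fitted data).
#' @return Matrix (total draws x observations).
#' @export
log_likelihood_pointwise <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "hbr_fit"))
  validate_auc_data(data, fit$spec, min_subjects = 1)
  mu <- location_draws(fit, data)
  sigma <- flat_draws(fit, "sigma")[, 1]
  y <- as.numeric(data$auc)
  n <- length(y)
  s <- nrow(mu)
  yy <- matrix(rep(y, each = s), s, n)
  if (fit$spec$family == "lognormal") {
    matrix(stats::dlnorm(yy, meanlog = mu, sdlog = sigma, log = TRUE), s, n)
  } else {
    matrix(stats::dnorm(yy, mean = mu, sd = sigma, log = TRUE), s, n)
  }
}

#' Per-subject posterior medians of the piecewise parameters
#'
#' Extracts, for every subject, the posterior median of the subject-level
#' intercept, FAR-to-MIDDLE slope and MIDDLE-to-NEAR slope from a fitted
#' piecewise model. These medians are the per-subject quantities carried
#' into the personality network.
#'
#' @param fit A converged `hbr_fit` of the piecewise form.
#' @return Data frame (subject_id, intercept, FtoM, MtoN), one row per
#'   subject.
#' @export
extract_subject_medians <- function(fit) {
  stopifnot(inherits(fit, "hbr_fit"))
  if (fit$spec$form != "piecewise") {
    stop("subject parameters are derived only from the piecewise fit, got '",
         fit$spec$form, "'")
  }
  if (!fit$converged) {
    warning("extracting subject medians from a non-converged fit")
  }
  S <- length(fit$subjects)
  med <- sapply(1:3, function(j) {
    apply(flat_draws(fit, paste0("b[", seq_len(S), ",", j, "]")), 2, stats::median)
  })
  out <- data.frame(subject_id = fit$subjects, intercept = med[, 1],
                    FtoM = med[, 2], MtoN = med[, 3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize population-level posterior draws to CSV
#'
#' Writes the flattened post-warmup draws of the population parameters
#' (labelled with the model's own coefficient names) plus chain and
#' iteration indices; pairs with the JSON diagnostics written by the
#' pipeline to give a plain-text record of a fit.
#'
#' @param fit An `hbr_fit`.
#' @param path CSV path.
#' @export
write_population_draws <- function(fit, path) {
  stopifnot(inherits(fit, "hbr_fit"))
  m <- flat_draws(fit, fit$pop_pars)
  colnames(m) <- fit$diagnostics$parameter_label
  n_iter <- dim(fit$draws)[1]
  out <- data.frame(
    chain = rep(seq_len(dim(fit$draws)[2]), each = n_iter),
    iteration = rep(seq_len(n_iter), dim(fit$draws)[2]),
    m, check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Posterior probability that a population parameter exceeds a bound
#'
#' Fraction of post-warmup draws in which the named population parameter
#' exceeds `bound`. `parameter` accepts the model's own coefficient names
#' (e.g. `"MtoN"`), `"sigma"`, or `tau_<coefficient>`.
#'
#' @param fit An `hbr_fit`.
#' @param parameter Parameter label.
#' @param bound Threshold (default 0).
#' @return Probability in \[0, 1\].
#' @export
posterior_prob_gt <- function(fit, parameter, bound = 0) {
  stopifnot(inherits(fit, "hbr_fit"))
  lab <- fit$diagnostics$parameter_label
  ix <- match(parameter, lab)
  if (is.na(ix)) {
    stop("unknown parameter '", parameter, "'; available: ",
         paste(lab, collapse = ", "))
  }
  mean(flat_draws(fit, fit$pop_pars[ix]) > bound)
}
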