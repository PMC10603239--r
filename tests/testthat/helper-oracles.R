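# Independent oracles used across the test files. Each deliberately takes
# a different computational route from the implementation it checks.

# Exact leave-one-out ELPD for the conjugate normal model with known
# observation SD: y_i ~ N(theta, sigma^2), theta ~ N(mu0, tau0^2). The
# posterior predictive for the held-out point is available in closed form,
# so LOO can be computed by n exact "refits".
exact_loo_normal <- function(y, sigma, mu0, tau0) {
  pointwise <- vapply(seq_along(y), function(i) {
    yi <- y[-i]
    prec <- 1 / tau0^2 + length(yi) / sigma^2
    mu_post <- (mu0 / tau0^2 + sum(yi) / sigma^2) / prec
    stats::dnorm(y[i], mu_post, sqrt(sigma^2 + 1 / prec), log = TRUE)
  }, numeric(1))
  list(elpd = sum(pointwise), pointwise = pointwise)
}

# Partial correlation of nodes i and j given the rest, via the
# regression-residual route: the conditional covariance of (i, j) given
# the remaining variables is the Schur complement of the covariance.
partial_corr_regression <- function(covariance, i, j) {
  rest <- setdiff(seq_len(nrow(covariance)), c(i, j))
  s_ab <- covariance[c(i, j), c(i, j)]
  if (length(rest)) {
    s_ar <- covariance[c(i, j), rest, drop = FALSE]
    s_ab <- s_ab - s_ar %*% solve(covariance[rest, rest]) %*% t(s_ar)
  }
  s_ab[1, 2] / sqrt(s_ab[1, 1] * s_ab[2, 2])
}

# Textbook lognormal log-density, written out rather than via dlnorm.
lognormal_logpdf <- function(y, mu, sigma) {
  -log(y * sigma * sqrt(2 * pi)) - (log(y) - mu)^2 / (2 * sigma^2)
}

# Bare EMG trace constructor for hand-built fixtures.
make_trace <- function(samples, sampling_rate = 1000, stimulus_onset = 201,
                       subject_id = "S001", side = "ipsi", position = "FAR",
                       trial_index = 1) {
  structure(
    list(subject_id = subject_id, side = side, position = position,
         trial_index = trial_index, sampling_rate = sampling_rate,
         samples = samples, stimulus_onset = stimulus_onset,
         artifact = FALSE),
    class = "emg_trace"
  )
}

# Minimal hand-built hbr_fit whose draws are fully controlled, so the
# likelihood and fitted-value code paths can be checked against closed
# forms. b_draws: draws x subjects x n_par array; sigma_draws: vector.
make_fake_fit <- function(form, b_draws, sigma_draws, data) {
  n_draw <- dim(b_draws)[1]
  S <- dim(b_draws)[2]
  P <- dim(b_draws)[3]
  pars <- c(as.vector(outer(seq_len(S), seq_len(P),
                            function(i, j) sprintf("b[%d,%d]", i, j))),
            sprintf("beta[%d]", seq_len(P)), sprintf("tau[%d]", seq_len(P)),
            "sigma")
  draws <- array(0, dim = c(n_draw, 1, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (i in seq_len(S)) {
    for (j in seq_len(P)) {
      draws[, 1, sprintf("b[%d,%d]", i, j)] <- b_draws[, i, j]
    }
  }
  draws[, 1, "sigma"] <- sigma_draws
  spec <- hbr_model_spec(form)
  structure(
    list(spec = spec, mcmc = NULL, priors = NULL, data = data,
         subjects = sort(unique(as.character(data$subject_id))),
         draws = draws,
         pop_pars = c(sprintf("beta[%d]", seq_len(P)),
                      sprintf("tau[%d]", seq_len(P)), "sigma"),
         diagnostics = NULL, converged = TRUE, data_hash = "fake"),
    class = "hbr_fit"
  )
}

# Small MCMC settings for tests that only need a usable posterior, not
# publication-grade ESS.
quick_mcmc <- function(seed, chains = 2, warmup = 400, iterations = 1400) {
  mcmc_config(chains = chains, warmup = warmup, iterations = iterations,
              seed = seed)
}
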