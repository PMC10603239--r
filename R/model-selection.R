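# Model comparison: self-contained PSIS-LOO (Pareto-smoothed importance
# sampling leave-one-out cross-validation), Bayesian R-squared and
# posterior predictive checks.

# --- generalized Pareto tail fit ---------------------------------------
#
# Profile-likelihood fit of the generalized Pareto distribution to tail
# exceedances (Zhang-Stephens estimator): over a grid of w = xi/sigma the
# shape MLE is xi(w) = mean(log1p(w * x)), the profile log-likelihood is
# n * (log(w / xi(w)) - xi(w) - 1), and the grid is averaged with
# likelihood weights. The shape estimate is shrunk towards 0.5 with 10
# pseudo-observations, which stabilizes the diagnostic at small tail sizes.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0 || stats::sd(x) == 0) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  m <- 30 + floor(sqrt(n))
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  w <- -1 / x[n] + (sqrt(m / (jj - 0.5)) - 1) / (3 * xq)
  w[w == 0] <- 1e-12
  xi <- vapply(w, function(wj) mean(log1p(wj * x)), numeric(1))
  ll <- n * (log(w / xi) - xi - 1)
  wt <- exp(ll - log_sum_exp(ll))
  w_hat <- sum(wt * w)
  k <- mean(log1p(w_hat * x))
  sigma <- k / w_hat
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

# Quantile function of the generalized Pareto (location 0).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-k) - 1) / k
}

# Pareto-smooth one vector of log importance ratios: fit the GPD to the
# largest 20% of ratios, replace them by expected order statistics of the
# fitted tail, truncate at the raw maximum.
psis_smooth <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  m <- ceiling(0.2 * s)
  ord <- order(lw)
  tail_ids <- ord[(s - m + 1):s]
  k <- NA_real_
  if (m >= 5) {
    cut_lw <- lw[ord[s - m]]
    exc <- exp(lw[tail_ids]) - exp(cut_lw)
    fit <- gpd_fit(exc)
    if (is.finite(fit$k)) {
      k <- fit$k
      p <- (seq_len(m) - 0.5) / m
      lw[tail_ids] <- log(qgpd(p, fit$k, fit$sigma) + exp(cut_lw))
    }
  }
  list(log_weights = pmin(lw, 0), k = k)
}

#' PSIS-LOO: approximate leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (ELPD) under
#' leave-one-out cross-validation from a single posterior sample, using
#' Pareto-smoothed importance sampling: the per-observation importance
#' ratios 1/p(y_i | theta_s) are tail-stabilized by a generalized Pareto
#' fit to their largest 20%, replaced by expected order statistics of the
#' fitted tail and truncated at the raw maximum. Observations whose Pareto
#' shape exceeds 0.7 are flagged as unreliable (no refit fallback; they are
#' reported, not fixed).
#'
#' @param x Either a draws x observations pointwise log-likelihood matrix
#'   or an `hbr_fit` (for which the matrix is computed first).
#' @param group Optional factor of length n_observations; log-likelihoods
#'   are summed within group before LOO, giving leave-one-group-out (e.g.
#'   leave-one-subject-out) cross-validation.
#' @param ... Passed to methods.
#' @return An object of class `psis_loo`: `elpd_loo`, its standard error
#'   `se`, `looic = -2 * elpd_loo`, the `pointwise` data frame (elpd_i,
#'   pareto_k) and the indices of flagged observations.
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @rdname psis_loo
#' @export
psis_loo.hbr_fit <- function(x, group = NULL, ...) {
  psis_loo(log_likelihood_pointwise(x), group = group, ...)
}

#' @rdname psis_loo
#' @export
psis_loo.matrix <- function(x, group = NULL, ...) {
  loglik <- x
  if (nrow(loglik) < 100) stop("need >= 100 posterior draws for PSIS-LOO")
  bad <- which(!apply(loglik, 2, function(col) all(is.finite(col))))
  if (length(bad)) {
    stop("non-finite log-likelihood entries for observation(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(group)) {
    group <- as.factor(group)
    stopifnot(length(group) == ncol(loglik))
    loglik <- sapply(split(seq_along(group), group), function(ix) {
      rowSums(loglik[, ix, drop = FALSE])
    })
  }
  n <- ncol(loglik)
  s <- nrow(loglik)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$log_weights
    elpd_i[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
    k_i[i] <- sm$k
  }
  elpd <- sum(elpd_i)
  se <- sqrt(n * stats::var(elpd_i))
  structure(
    list(elpd_loo = elpd, se = se, looic = -2 * elpd,
         pointwise = data.frame(elpd_i = elpd_i, pareto_k = k_i),
         flagged = which(!is.na(k_i) & k_i > 0.7),
         n_obs = n, n_draws = s),
    class = "psis_loo"
  )
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d observations (%d draws)\n", x$n_obs, x$n_draws))
  cat(sprintf("  elpd_loo %8.2f  (SE %.2f)\n", x$elpd_loo, x$se))
  cat(sprintf("  looic    %8.2f\n", x$looic))
  if (length(x$flagged)) {
    cat(sprintf("  %d observation(s) with Pareto k > 0.7: %s\n",
                length(x$flagged), paste(utils::head(x$flagged, 10), collapse = ", ")))
  }
  invisible(x)
}

# --- Bayesian R-squared ------------------------------------------------

# Per-draw fitted values on the response (mV*ms) scale: the lognormal mean
# exp(mu + sigma^2/2) for lognormal forms, mu itself for the normal form.
fitted_draws <- function(fit, data = fit$data) {
  mu <- location_draws(fit, data)
  if (fit$spec$family == "lognormal") {
    sigma <- flat_draws(fit, "sigma")[, 1]
    exp(mu + sigma^2 / 2)
  } else {
    mu
  }
}

#' Bayesian R-squared
#'
#' For each posterior draw, the variance of the fitted values divided by
#' the sum of that variance and the variance of the residuals
#' (observed - fitted), both on the response scale. Every draw's value lies
#' in \[0, 1).
#'
#' @param fit An `hbr_fit`.
#' @param data AUC table (defaults to the fitted data).
#' @return List with the per-draw values (`draws`), their `median` and a
#'   95% equal-tailed interval.
#' @export
bayes_r2 <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "hbr_fit"))
  y <- as.numeric(data$auc)
  if (stats::var(y) == 0) stop("zero total variance in the response")
  f <- fitted_draws(fit, data)
  n <- ncol(f)
  row_var <- function(m) (rowMeans(m^2) - rowMeans(m)^2) * n / (n - 1)
  vf <- row_var(f)
  res <- sweep(-f, 2, y, `+`)
  vr <- row_var(res)
  r2 <- vf / (vf + vr)
  list(draws = r2, median = stats::median(r2),
       ci = stats::quantile(r2, c(0.025, 0.975)))
}

# --- model comparison --------------------------------------------------

#' Compare fitted HBR models by PSIS-LOO
#'
#' Ranks a set of fits on the same data (hash-checked) by ELPD; a higher
#' ELPD (equivalently a lower LOOIC = -2 ELPD) means better out-of-sample
#' prediction. Ties in ELPD are broken in favour of fewer parameters.
#' Models whose ELPD difference from the best is smaller than one standard
#' error of that difference (computed from the pointwise ELPD
#' contributions) are flagged as statistically indistinguishable from the
#' best.
#'
#' @param fits Named list of `hbr_fit` objects (names default to the
#'   forms).
#' @param group Optional grouping passed to [psis_loo()] for
#'   leave-one-subject-out comparison.
#' @return An object of class `hbr_comparison`: a data frame with one row
#'   per model (elpd_loo, se, looic, bayes_r2 median, max Pareto k, elpd
#'   difference from the best and its SE, rank) sorted by rank, with the
#'   per-model `psis_loo` objects attached.
#' @export
compare_models <- function(fits, group = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "hbr_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$spec$form, character(1))
  }
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1) {
    stop("all fits must be estimated on identical data (hash mismatch)")
  }
  loos <- lapply(fits, psis_loo, group = group)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  n_par <- vapply(fits, function(f) f$spec$n_par, integer(1))
  stopifnot(all(-2 * elpd == vapply(loos, `[[`, numeric(1), "looic")))
  rank_order <- order(-elpd, n_par)
  best <- rank_order[1]
  elpd_diff <- elpd - elpd[best]
  se_diff <- vapply(seq_along(fits), function(m) {
    if (m == best) return(0)
    d <- loos[[m]]$pointwise$elpd_i - loos[[best]]$pointwise$elpd_i
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  r2 <- vapply(fits, function(f) bayes_r2(f)$median, numeric(1))
  tab <- data.frame(
    model = names(fits),
    n_par = n_par,
    elpd_loo = elpd,
    se = vapply(loos, `[[`, numeric(1), "se"),
    looic = -2 * elpd,
    bayes_r2 = r2,
    max_pareto_k = vapply(loos, function(l) {
      suppressWarnings(max(l$pointwise$pareto_k, na.rm = TRUE))
    }, numeric(1)),
    elpd_diff = elpd_diff,
    se_diff = se_diff,
    within_1se_of_best = abs(elpd_diff) < se_diff | seq_along(fits) == best,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  tab$rank <- match(seq_along(fits), rank_order)
  tab <- tab[rank_order, ]
  rownames(tab) <- NULL
  structure(list(table = tab, loos = loos), class = "hbr_comparison")
}

#' @export
print.hbr_comparison <- function(x, ...) {
  cat("Model comparison (higher ELPD / lower LOOIC is better):\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

# --- posterior predictive checks ---------------------------------------

#' Posterior predictive check
#'
#' Simulates replicated datasets from a subset of posterior draws and
#' compares observed test statistics with their replicated distributions.
#' The default statistics are the mean and SD of AUC within each hand
#' position. Tail probabilities are computed as
#' (#\{T_rep >= T_obs\} + 0.5) / (n_rep + 1), so they lie strictly inside
#' (0, 1); values near 0 or 1 indicate misfit of that statistic.
#'
#' @param fit An `hbr_fit`.
#' @param data AUC table (defaults to the fitted data).
#' @param stats Named list of functions `f(auc)` applied within position;
#'   defaults to mean and SD.
#' @param n_rep Number of replicated datasets (default 500).
#' @return Data frame (statistic, position, observed, rep_mean, p_value)
#'   of class `hbr_ppc`.
#' @export
posterior_predictive_check <- function(fit, data = fit$data, stats = NULL,
                                       n_rep = 500) {
  stopifnot(inherits(fit, "hbr_fit"))
  if (is.null(stats) || length(stats) == 0) {
    stats <- list(mean = mean, sd = stats::sd)
  }
  mu <- location_draws(fit, data)
  sigma <- flat_draws(fit, "sigma")[, 1]
  n_rep <- min(n_rep, nrow(mu))
  keep <- round(seq(1, nrow(mu), length.out = n_rep))
  pos <- position_factor(data$position)
  y <- as.numeric(data$auc)
  n <- length(y)

  stat_values <- function(values) {
    unlist(lapply(stats, function(f) tapply(values, pos, f)))
  }
  obs <- stat_values(y)
  rep_mat <- t(vapply(keep, function(s) {
    yrep <- if (fit$spec$family == "lognormal") {
      stats::rlnorm(n, meanlog = mu[s, ], sdlog = sigma[s])
    } else {
      stats::rnorm(n, mean = mu[s, ], sd = sigma[s])
    }
    stat_values(yrep)
  }, numeric(length(obs))))
  p <- (colSums(rep_mat >= matrix(obs, n_rep, length(obs), byrow = TRUE)) + 0.5) /
    (n_rep + 1)
  lab <- expand.grid(position = levels(pos), statistic = names(stats),
                     stringsAsFactors = FALSE)
  out <- data.frame(
    statistic = lab$statistic,
    position = lab$position,
    observed = as.numeric(obs),
    rep_mean = colMeans(rep_mat),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hbr_ppc", class(out))
  out
}
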