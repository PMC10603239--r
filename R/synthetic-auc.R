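# Subject-level AUC simulation from any of the five candidate generative
# forms. Used both as a test-bed for the hierarchical fits and as the
# data source for the parameter-recovery runs.

default_population_beta <- function(form) {
  switch(form,
    # piecewise defaults are the published population estimates used as
    # generating truths in the recovery simulations
    piecewise      = c(2.72, 0.02, 0.18),
    intercept_only = 2.80,
    linear         = c(2.72, 0.10),
    quadratic      = c(2.72, -0.02, 0.10),
    exponential    = c(10, 1.5, 0.6)
  )
}

default_population_tau <- function(form) {
  switch(form,
    piecewise      = c(0.30, 0.05, 0.10),
    intercept_only = 0.30,
    linear         = c(0.30, 0.05),
    quadratic      = c(0.30, 0.05, 0.05),
    exponential    = c(2.0, 0.5, 0.1)
  )
}

#' Population parameters of a generative HBR model
#'
#' Bundles the population-level coefficients, the residual scale and the
#' subject-level standard deviations of one of the five candidate forms.
#' Defaults for the piecewise form are the published population estimates
#' (intercept 2.72, FtoM 0.02, MtoN 0.18, sigma 0.16 on the log scale) with
#' subject-level SDs (0.3, 0.05, 0.1); other forms get comparable values on
#' the same response scale.
#'
#' @param form One of `names(HBR_FORMS)`.
#' @param beta Population coefficients (log scale for lognormal forms,
#'   response scale for the exponential form).
#' @param sigma Residual scale (> 0); log-scale SD for lognormal forms,
#'   response-scale SD for the exponential form.
#' @param tau Subject-level SDs, one per coefficient (>= 0).
#' @param seed Optional integer seed for reproducible simulation.
#' @return An object of class `population_params`.
#' @export
population_params <- function(form = "piecewise",
                              beta = default_population_beta(form),
                              sigma = if (form == "exponential") 1.5 else 0.16,
                              tau = default_population_tau(form),
                              seed = NULL) {
  form <- match_form(form)
  info <- HBR_FORMS[[form]]
  beta <- as.numeric(beta)
  tau <- as.numeric(tau)
  assert_positive_scalar(sigma, "sigma")
  if (length(beta) != info$n_par || length(tau) != info$n_par) {
    stop(sprintf("form '%s' needs %d beta and tau values", form, info$n_par))
  }
  if (any(tau < 0)) stop("all 'tau' must be >= 0")
  structure(
    list(form = form, family = info$family, beta = beta, sigma = sigma,
         tau = tau, parameter_names = info$parameter_names, seed = seed),
    class = "population_params"
  )
}

#' Simulate a subject-by-position AUC table from a generative model
#'
#' Draws per-subject coefficients b_i = beta + u_i with independent
#' u_ij ~ Normal(0, tau_j^2), then one AUC value per subject and position:
#' lognormal with log-scale location mu_i(x) and scale sigma for the four
#' lognormal forms, or normal with mean mu_i(x) and SD sigma for the
#' exponential form.
#'
#' @param params A [population_params()] object.
#' @param n_subjects Number of subjects (>= 2).
#' @return A long data frame (subject_id, position, x, auc) with the true
#'   subject coefficients attached as attribute `"subject_coefficients"`.
#' @export
generate_auc_dataset <- function(params, n_subjects) {
  stopifnot(inherits(params, "population_params"))
  assert_count(n_subjects, "n_subjects", min = 2L)
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- length(params$beta)
  b <- matrix(rnorm(n_subjects * p), n_subjects, p)
  b <- sweep(sweep(b, 2, params$tau, `*`), 2, params$beta, `+`)
  colnames(b) <- params$parameter_names
  x <- rep(0:2, times = n_subjects)
  subj <- rep(seq_len(n_subjects), each = 3)
  mu <- vapply(seq_along(x), function(k) {
    hbr_location(params$form, b[subj[k], ], x[k])
  }, numeric(1))
  auc <- if (params$family == "lognormal") {
    stats::rlnorm(length(mu), meanlog = mu, sdlog = params$sigma)
  } else {
    stats::rnorm(length(mu), mean = mu, sd = params$sigma)
  }
  out <- data.frame(
    subject_id = sprintf("S%03d", subj),
    position = position_factor(x),
    x = x,
    auc = auc,
    stringsAsFactors = FALSE
  )
  rownames(b) <- sprintf("S%03d", seq_len(n_subjects))
  attr(out, "subject_coefficients") <- b
  attr(out, "params") <- params
  out
}

#' Write/read an AUC table as CSV
#'
#' Plain-CSV serialization of the subject-by-position AUC table used
#' between pipeline stages.
#' @param auc_table Data frame with at least subject_id, position, auc.
#' @param path File path.
#' @return `read_auc_table` returns the table with `position` restored as
#'   an ordered factor and `x` recomputed.
#' @export
write_auc_table <- function(auc_table, path) {
  utils::write.csv(auc_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_auc_table
#' @export
read_auc_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$position <- position_factor(out$position)
  out$x <- position_index(out$position)
  out
}
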