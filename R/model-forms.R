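# The five candidate generative forms for AUC as a function of hand position.
#
# All positions are encoded 0 (FAR), 1 (MIDDLE), 2 (NEAR). The first four
# forms model the location of a lognormal response on the log scale; the
# exponential form models the mean of a normal response on the raw
# (mV*ms) scale.

#' Registry of candidate HBR model forms
#'
#' Five generative forms of increasing complexity relate the blink-response
#' area (AUC) to the ordinal hand position x in {0, 1, 2}:
#' * `intercept_only`: mu = b0 (no position effect),
#' * `linear`: mu = b0 + b1 x,
#' * `quadratic`: mu = b0 + b1 x + b2 x^2,
#' * `piecewise`: mu = b0 + b1 min(x, 1) + b2 max(x - 1, 0), i.e. two
#'   distinct per-step slopes, FAR-to-MIDDLE (FtoM) and MIDDLE-to-NEAR
#'   (MtoN),
#' * `exponential`: mu = a + b exp(c x).
#'
#' The first four use a lognormal response family (mu is the log-scale
#' location); the exponential uses a normal response.
#' @format A named list with one entry per form giving `family`,
#'   `parameter_names` and `n_par`.
#' @export
HBR_FORMS <- list(
  intercept_only = list(family = "lognormal", parameter_names = "intercept", n_par = 1L),
  linear         = list(family = "lognormal", parameter_names = c("intercept", "slope"), n_par = 2L),
  quadratic      = list(family = "lognormal", parameter_names = c("intercept", "linear", "quadratic"), n_par = 3L),
  piecewise      = list(family = "lognormal", parameter_names = c("intercept", "FtoM", "MtoN"), n_par = 3L),
  exponential    = list(family = "normal", parameter_names = c("a", "b", "c"), n_par = 3L)
)

match_form <- function(form) {
  match.arg(form, names(HBR_FORMS))
}

#' Location of the response distribution for a given form and position
#'
#' Evaluates the linear predictor mu(x) of one of the five candidate forms
#' at hand positions x in {0 = FAR, 1 = MIDDLE, 2 = NEAR}. For the four
#' lognormal forms this is the log-scale location; for the exponential form
#' it is the mean of the normal response.
#'
#' @param form One of `names(HBR_FORMS)`.
#' @param coefficients Numeric vector whose length matches the form
#'   (1, 2, 3, 3 or 3).
#' @param position Positions as 0/1/2 or as "FAR"/"MIDDLE"/"NEAR"
#'   (vectorized).
#' @return Numeric vector of locations, one per position.
#' @examples
#' hbr_location("piecewise", c(2.72, 0.02, 0.18), 2)  # 2.92 at NEAR
#' @export
hbr_location <- function(form, coefficients, position) {
  form <- match_form(form)
  info <- HBR_FORMS[[form]]
  if (length(coefficients) != info$n_par) {
    stop(sprintf("form '%s' needs %d coefficients, got %d",
                 form, info$n_par, length(coefficients)))
  }
  x <- position_index(position)
  cf <- as.numeric(coefficients)
  switch(form,
    intercept_only = rep(cf[1], length(x)),
    linear         = cf[1] + cf[2] * x,
    quadratic      = cf[1] + cf[2] * x + cf[3] * x^2,
    piecewise      = cf[1] + cf[2] * pmin(x, 1) + cf[3] * pmax(x - 1, 0),
    exponential    = cf[1] + cf[2] * exp(cf[3] * x)
  )
}

# Design matrix for the linear-in-parameters forms; NULL for exponential.
design_matrix <- function(form, x) {
  form <- match_form(form)
  switch(form,
    intercept_only = cbind(intercept = rep(1, length(x))),
    linear         = cbind(intercept = 1, slope = x),
    quadratic      = cbind(intercept = 1, linear = x, quadratic = x^2),
    piecewise      = cbind(intercept = 1, FtoM = pmin(x, 1), MtoN = pmax(x - 1, 0)),
    exponential    = NULL
  )
}
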