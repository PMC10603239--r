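# MCMC convergence diagnostics: rank-normalized split-chain Rhat and
# bulk/tail effective sample sizes. Implemented from the rank-normalized
# definitions (split chains; normal scores via qnorm((r - 3/8)/(N + 1/4));
# Rhat as the max of the rank-normalized and folded statistics; ESS from
# Geyer's initial-monotone-sequence truncation of the autocorrelations).

split_chains <- function(m) {
  n <- floor(nrow(m) / 2)
  cbind(m[seq_len(n), , drop = FALSE],
        m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
}

rank_normalize <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

# Classic potential-scale-reduction on an iterations x chains matrix.
rhat_basic <- function(m) {
  n <- nrow(m)
  w <- mean(apply(m, 2, stats::var))
  b <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Effective sample size of an iterations x chains matrix (Geyer truncation).
ess_basic <- function(m) {
  n <- nrow(m)
  ch <- ncol(m)
  if (n < 4) return(NA_real_)
  acov <- sapply(seq_len(ch), function(c) {
    stats::acf(m[, c], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- matrix(acov, nrow = n)
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (ch > 1) var_plus <- var_plus + stats::var(colMeans(m))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum successive pairs while positive, enforce monotone decrease
  max_t <- floor((n - 2) / 2)
  pair <- numeric(0)
  for (t in seq_len(max_t + 1) - 1) {
    p <- rho[2 * t + 1] + ifelse(2 * t + 2 <= n, rho[2 * t + 2], 0)
    if (t > 0 && p < 0) break
    if (t > 0) p <- min(p, pair[t])
    pair <- c(pair, max(p, 0))
  }
  tau <- max(2 * sum(pair) - 1, 1 / log10(n + 1))
  ess <- ch * n / tau
  min(ess, ch * n * log10(ch * n))
}

ess_bulk_one <- function(m) {
  ess_basic(rank_normalize(split_chains(m)))
}

ess_tail_one <- function(m) {
  s <- split_chains(m)
  ess_q <- function(q) {
    ind <- matrix(as.numeric(s <= stats::quantile(s, q)), nrow(s), ncol(s))
    if (stats::sd(ind) == 0) return(NA_real_)
    ess_basic(ind)
  }
  min(ess_q(0.05), ess_q(0.95))
}

rhat_one <- function(m) {
  s <- split_chains(m)
  if (stats::sd(s) == 0) return(NA_real_)
  folded <- abs(s - stats::median(s))
  max(rhat_basic(rank_normalize(s)), rhat_basic(rank_normalize(folded)))
}

#' Convergence diagnostics per parameter
#'
#' Computes the rank-normalized split-chain Rhat (the maximum of the bulk
#' and folded statistics) and the bulk and tail effective sample sizes for
#' each parameter of a draw array. Constant draws yield `NA` diagnostics
#' with `flag = "constant"` rather than propagating NaN.
#'
#' @param draws Either an iterations x chains matrix for one parameter or
#'   an iterations x chains x parameters array (with parameter dimnames).
#' @return Data frame (parameter, rhat, bulk_ess, tail_ess, flag).
#' @export
convergence_diagnostics <- function(draws) {
  if (is.matrix(draws)) {
    draws <- array(draws, dim = c(dim(draws), 1),
                   dimnames = list(NULL, NULL, "parameter"))
  }
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("need >= 2 chains for convergence diagnostics")
  if (dim(draws)[1] < 4) stop("need >= 4 iterations per chain")
  pars <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  out <- lapply(seq_along(pars), function(j) {
    m <- draws[, , j]
    if (any(!is.finite(m))) {
      return(data.frame(parameter = pars[j], rhat = NA_real_,
                        bulk_ess = NA_real_, tail_ess = NA_real_,
                        flag = "non-finite", stringsAsFactors = FALSE))
    }
    if (stats::sd(m) == 0) {
      return(data.frame(parameter = pars[j], rhat = NA_real_,
                        bulk_ess = NA_real_, tail_ess = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    }
    data.frame(parameter = pars[j], rhat = rhat_one(m),
               bulk_ess = ess_bulk_one(m), tail_ess = ess_tail_one(m),
               flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
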