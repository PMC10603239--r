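# Bayesian Gaussian graphical model with a conjugate Wishart prior.
#
# On standardized data Y (n x p), the precision matrix gets a
# Wishart(nu0, I_p) prior; the conjugate posterior is
# Wishart(nu0 + n, (I_p + Y'Y)^-1). Posterior draws of the precision are
# standardized to partial correlations, and an edge enters the network
# when its equal-tailed credible interval at the chosen level excludes
# zero. This is a deliberate, documented simplification of the matrix-F
# parameterization used by dedicated GGM software; the large-sample
# consistency checks against the inverse sample covariance are the guard.

#' Standardize the node table
#'
#' Centres each column to mean 0 and scales to unit population SD
#' (denominator n, not n - 1), so a 3-point column (1, 2, 3) maps to
#' (-1.2247, 0, 1.2247). Partial correlations are scale-free; the
#' standardization stabilizes the prior.
#'
#' @param table Numeric data frame or matrix; columns must be
#'   non-constant.
#' @return The z-scored table (same shape), with `center`/`scale`
#'   attributes.
#' @export
standardize_nodes <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("the node table must be numeric")
  n <- nrow(m)
  ctr <- colMeans(m)
  scl <- sqrt(colMeans(sweep(m, 2, ctr)^2))
  if (any(scl == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[scl == 0] %||% which(scl == 0), collapse = ", "))
  }
  z <- sweep(sweep(m, 2, ctr), 2, scl, `/`)
  out <- as.data.frame(z, check.names = FALSE)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Posterior draws of the precision matrix
#'
#' Conjugate update under a Wishart(nu0, I_p) prior for the precision of
#' zero-mean Gaussian data: draws Theta_s ~ Wishart(nu0 + n,
#' (I_p + Y'Y)^-1). Every draw is positive definite by construction.
#'
#' @param Y Standardized data (n x p), n > p.
#' @param prior_df Prior degrees of freedom nu0 >= p; default p + 2
#'   (weakly informative, proper).
#' @param n_draws Number of posterior draws (default 5000).
#' @param seed Optional integer seed.
#' @return A p x p x n_draws array of precision draws.
#' @export
sample_precision_posterior <- function(Y, prior_df = ncol(Y) + 2,
                                       n_draws = 5000, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  if (n <= p) stop("need more observations than nodes (n > p)")
  if (prior_df < p) stop("'prior_df' must be >= the number of nodes")
  assert_count(n_draws, "n_draws")
  if (!is.null(seed)) set.seed(seed)
  scale_mat <- solve(diag(p) + crossprod(Y))
  draws <- stats::rWishart(n_draws, df = prior_df + n, Sigma = scale_mat)
  dimnames(draws) <- list(colnames(Y), colnames(Y), NULL)
  draws
}

# Standardization without the validity checks, for tight loops over draws.
partial_correlations_ <- function(theta) {
  d <- diag(theta)
  pc <- -theta / sqrt(outer(d, d))
  diag(pc) <- 1
  pc
}

#' Partial correlations from a precision matrix
#'
#' rho_ij = -theta_ij / sqrt(theta_ii * theta_jj) for i != j; the diagonal
#' is set to 1 by convention. The partial correlation is the correlation
#' between nodes i and j after adjusting for all other nodes.
#'
#' @param precision Positive-definite p x p matrix.
#' @return p x p partial-correlation matrix.
#' @export
partial_correlations <- function(precision) {
  theta <- as.matrix(precision)
  if (any(diag(theta) <= 0)) stop("precision matrix has non-positive diagonal")
  ok <- tryCatch({ chol(theta); TRUE }, error = function(e) FALSE)
  if (!ok) stop("precision matrix is not positive definite")
  partial_correlations_(theta)
}

#' Select network edges from partial-correlation draws
#'
#' For every node pair, computes the posterior median and the equal-tailed
#' credible interval at the given level; the edge is included exactly when
#' the interval excludes zero. The default 85% level is deliberately
#' broader than the conventional 95%, trading specificity for sensitivity
#' at small sample sizes and small expected association magnitudes.
#'
#' @param partial_corr_draws p x p x n_draws array of partial-correlation
#'   draws.
#' @param level Credible level in (0.5, 1); default 0.85.
#' @return An object of class `ggm_network`: `partial_corr_median`,
#'   `ci_lower`, `ci_upper`, logical `adjacency` (diagonal FALSE), `level`,
#'   `n_draws` and `nodes`.
#' @export
select_edges <- function(partial_corr_draws, level = 0.85) {
  stopifnot(length(dim(partial_corr_draws)) == 3)
  if (!is.numeric(level) || length(level) != 1 || level <= 0.5 || level >= 1) {
    stop("'level' must lie in (0.5, 1)")
  }
  n_draws <- dim(partial_corr_draws)[3]
  if (n_draws < 1000) stop("need >= 1000 posterior draws for edge selection")
  a <- (1 - level) / 2
  qs <- apply(partial_corr_draws, c(1, 2), stats::quantile,
              probs = c(a, 0.5, 1 - a))
  lower <- qs[1, , ]
  med <- qs[2, , ]
  upper <- qs[3, , ]
  adjacency <- lower > 0 | upper < 0
  diag(adjacency) <- FALSE
  nodes <- dimnames(partial_corr_draws)[[1]] %||%
    paste0("V", seq_len(dim(partial_corr_draws)[1]))
  dimnames(med) <- dimnames(lower) <- dimnames(upper) <-
    dimnames(adjacency) <- list(nodes, nodes)
  structure(
    list(partial_corr_median = med, ci_lower = lower, ci_upper = upper,
         adjacency = adjacency, level = level, n_draws = n_draws,
         nodes = nodes),
    class = "ggm_network"
  )
}

#' Estimate the conditional-dependence network of a node table
#'
#' Full Bayesian GGM workflow: standardize the table, draw precision
#' matrices from the conjugate Wishart posterior, convert each draw to
#' partial correlations and select edges whose credible interval excludes
#' zero.
#'
#' @param table Node table (n subjects x p nodes), e.g. the five PID-5
#'   domain means joined with the three per-subject HBR parameters.
#' @param level Credible level (default 0.85).
#' @param prior_df Prior degrees of freedom (default p + 2).
#' @param n_draws Posterior draws (default 5000).
#' @param seed Optional integer seed.
#' @return A `ggm_network` (see [select_edges()]).
#' @export
estimate_network <- function(table, level = 0.85, prior_df = ncol(table) + 2,
                             n_draws = 5000, seed = NULL) {
  z <- standardize_nodes(table)
  theta_draws <- sample_precision_posterior(as.matrix(z), prior_df = prior_df,
                                            n_draws = n_draws, seed = seed)
  pc_draws <- array(
    apply(theta_draws, 3, partial_correlations_),
    dim = dim(theta_draws), dimnames = dimnames(theta_draws)
  )
  out <- select_edges(pc_draws, level = level)
  out$seed <- seed
  out
}

#' Edge list of a fitted network
#'
#' @param result A `ggm_network`.
#' @param all Include non-selected pairs too (default FALSE).
#' @return Data frame (node_i, node_j, median, ci_lower, ci_upper, sign)
#'   with one row per included edge (i < j).
#' @export
network_edge_list <- function(result, all = FALSE) {
  stopifnot(inherits(result, "ggm_network"))
  p <- length(result$nodes)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  keep <- if (all) rep(TRUE, nrow(pairs)) else result$adjacency[pairs]
  pairs <- pairs[keep, , drop = FALSE]
  med <- result$partial_corr_median[pairs]
  data.frame(
    node_i = result$nodes[pairs[, 1]],
    node_j = result$nodes[pairs[, 2]],
    median = med,
    ci_lower = result$ci_lower[pairs],
    ci_upper = result$ci_upper[pairs],
    sign = ifelse(med >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Export a fitted network to plain-text files
#'
#' Writes the edge list, the median/interval/adjacency matrices (CSV) and
#' a JSON summary into a directory; [read_network()] reconstructs the
#' `ggm_network` from them.
#'
#' @param result A `ggm_network`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
export_network <- function(result, dir) {
  stopifnot(inherits(result, "ggm_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edge_list.csv"),
    median = file.path(dir, "partial_corr_median.csv"),
    lower = file.path(dir, "ci_lower.csv"),
    upper = file.path(dir, "ci_upper.csv"),
    adjacency = file.path(dir, "adjacency.csv"),
    summary = file.path(dir, "network_summary.json")
  )
  utils::write.csv(network_edge_list(result), paths["edges"], row.names = FALSE)
  utils::write.csv(result$partial_corr_median, paths["median"])
  utils::write.csv(result$ci_lower, paths["lower"])
  utils::write.csv(result$ci_upper, paths["upper"])
  utils::write.csv(result$adjacency, paths["adjacency"])
  jsonlite::write_json(
    list(level = result$level, n_draws = result$n_draws,
         nodes = result$nodes, n_edges = sum(result$adjacency) / 2,
         seed = result$seed),
    paths["summary"], auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}

#' @rdname export_network
#' @param dir Directory previously written by [export_network()].
#' @export
read_network <- function(dir) {
  read_mat <- function(name) {
    # na.strings = "" keeps the node named "NA" (negative affectivity)
    # from being read as a missing row name
    m <- utils::read.csv(file.path(dir, name), row.names = 1,
                         check.names = FALSE, na.strings = "")
    as.matrix(m)
  }
  info <- jsonlite::read_json(file.path(dir, "network_summary.json"),
                              simplifyVector = TRUE)
  structure(
    list(partial_corr_median = read_mat("partial_corr_median.csv"),
         ci_lower = read_mat("ci_lower.csv"),
         ci_upper = read_mat("ci_upper.csv"),
         adjacency = apply(read_mat("adjacency.csv"), c(1, 2), isTRUE),
         level = info$level, n_draws = info$n_draws,
         nodes = info$nodes, seed = info$seed),
    class = "ggm_network"
  )
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("Gaussian graphical model: %d nodes, %d edges at the %g%% credible level\n",
              length(x$nodes), sum(x$adjacency) / 2, 100 * x$level))
  el <- network_edge_list(x)
  if (nrow(el)) print(el, digits = 3, row.names = FALSE) else cat("  (no edges)\n")
  invisible(x)
}

#' Plot a fitted network
#'
#' Circle layout; green solid edges are positive partial correlations, red
#' dashed edges negative, with width proportional to magnitude.
#'
#' @param x A `ggm_network`.
#' @param node_colors Optional fill per node.
#' @param ... Unused.
#' @export
plot.ggm_network <- function(x, node_colors = NULL, ...) {
  p <- length(x$nodes)
  ang <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  xs <- cos(ang)
  ys <- sin(ang)
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  el <- network_edge_list(x)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      i <- match(el$node_i[r], x$nodes)
      j <- match(el$node_j[r], x$nodes)
      graphics::segments(xs[i], ys[i], xs[j], ys[j],
                         col = if (el$median[r] >= 0) "forestgreen" else "firebrick",
                         lty = if (el$median[r] >= 0) 1 else 2,
                         lwd = 0.5 + 6 * abs(el$median[r]))
    }
  }
  fill <- node_colors %||% ifelse(x$nodes %in% c("intercept", "FtoM", "MtoN"),
                                  "lightsteelblue", "darkseagreen2")
  graphics::symbols(xs, ys, circles = rep(0.13, p), inches = FALSE,
                    add = TRUE, bg = fill, fg = "grey30")
  graphics::text(xs, ys, x$nodes, cex = 0.8)
  invisible(x)
}
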