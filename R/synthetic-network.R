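# Multivariate-normal data with a planted partial-correlation structure.
#
# The Gaussian graphical model stage operates on standardized values, so
# the synthetic trait scores are left Gaussian rather than clipped to the
# PID-5 0-3 range: clipping would distort the planted partial correlations
# that the recovery tests assert.

#' Default 8-node names: five PID-5 domains plus three HBR parameters
#' @export
GGM_NODES <- c("NA", "DET", "ANT", "DIS", "PSY", "intercept", "FtoM", "MtoN")

#' Default planted partial-correlation matrix
#'
#' Two clusters with a single bridge, mimicking the reported network
#' structure: the maladaptive-trait cluster (NA-DIS, DIS-PSY, DIS-DET,
#' ANT-PSY, ANT-DET, PSY-DET), the HBR-parameter cluster (intercept-FtoM
#' positive, intercept-MtoN negative, FtoM-MtoN positive) and a positive
#' Detachment-MtoN bridge.
#'
#' @param bridge Partial correlation planted between DET and MtoN
#'   (default 0.3).
#' @return An 8 x 8 symmetric matrix with unit diagonal.
#' @export
default_partial_corr <- function(bridge = 0.3) {
  p <- length(GGM_NODES)
  rho <- diag(p)
  dimnames(rho) <- list(GGM_NODES, GGM_NODES)
  set_edge <- function(a, b, v) {
    rho[a, b] <<- v
    rho[b, a] <<- v
  }
  set_edge("NA", "DIS", 0.30)
  set_edge("DIS", "PSY", 0.35)
  set_edge("DIS", "DET", 0.15)
  set_edge("ANT", "PSY", 0.25)
  set_edge("ANT", "DET", 0.20)
  set_edge("PSY", "DET", 0.20)
  set_edge("intercept", "FtoM", 0.30)
  set_edge("intercept", "MtoN", -0.25)
  set_edge("FtoM", "MtoN", 0.25)
  set_edge("DET", "MtoN", bridge)
  rho
}

#' Precision matrix implied by a partial-correlation matrix
#'
#' Under the unit-diagonal standardization theta_ii = 1, off-diagonals are
#' theta_ij = -rho_ij * sqrt(theta_ii * theta_jj) = -rho_ij. Positive
#' definiteness of the implied precision is checked at construction.
#'
#' @param partial_corr Symmetric matrix with unit diagonal and
#'   off-diagonal magnitudes < 1.
#' @return The implied precision matrix.
#' @export
partial_corr_to_precision <- function(partial_corr) {
  rho <- as.matrix(partial_corr)
  if (nrow(rho) != ncol(rho) || max(abs(rho - t(rho))) > 1e-10) {
    stop("'partial_corr' must be a symmetric square matrix")
  }
  if (any(abs(diag(rho) - 1) > 1e-10)) stop("'partial_corr' must have unit diagonal")
  off <- rho[row(rho) != col(rho)]
  if (any(abs(off) >= 1)) stop("off-diagonal partial correlations must have magnitude < 1")
  theta <- -rho
  diag(theta) <- 1
  ok <- tryCatch({ chol(theta); TRUE }, error = function(e) FALSE)
  if (!ok) stop("implied precision matrix is not positive definite")
  theta
}

#' Configuration for the planted-network data generator
#'
#' @param node_names Column names; default the 8 nodes (5 PID-5 domains,
#'   3 HBR parameters).
#' @param target_partial_corr Symmetric unit-diagonal matrix of planted
#'   partial correlations; its implied precision must be positive definite.
#' @param n_samples Number of rows to draw.
#' @param seed Optional integer seed.
#' @return An object of class `network_gen_config`.
#' @export
network_gen_config <- function(node_names = GGM_NODES,
                               target_partial_corr = default_partial_corr(),
                               n_samples = 500,
                               seed = NULL) {
  assert_count(n_samples, "n_samples")
  theta <- partial_corr_to_precision(target_partial_corr)  # validates
  if (length(node_names) != nrow(theta)) {
    stop("'node_names' length must match the partial-correlation dimension")
  }
  structure(
    list(node_names = as.character(node_names),
         target_partial_corr = as.matrix(target_partial_corr),
         precision = theta, n_samples = n_samples, seed = seed),
    class = "network_gen_config"
  )
}

#' Draw multivariate-normal samples with a planted partial-correlation network
#'
#' Builds the precision matrix implied by `target_partial_corr`, inverts it
#' to a covariance and draws `n_samples` zero-mean Gaussian rows. Values are
#' left on the Gaussian scale.
#'
#' @param config A [network_gen_config()].
#' @return Data frame (n_samples x p) with `node_names` as columns.
#' @export
generate_network_dataset <- function(config) {
  stopifnot(inherits(config, "network_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sigma <- solve(config$precision)
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(config$n_samples * p), config$n_samples, p)
  x <- z %*% chol(sigma)
  colnames(x) <- config$node_names
  as.data.frame(x, check.names = FALSE)
}

#' Empirical partial correlations via the inverse sample covariance
#'
#' The large-sample oracle for the Bayesian estimates: invert the sample
#' covariance matrix and standardize it to partial correlations.
#'
#' @param data Numeric data frame or matrix (n x p).
#' @return p x p partial-correlation matrix (unit diagonal).
#' @export
empirical_partial_correlations <- function(data) {
  partial_correlations(solve(stats::cov(as.matrix(data))))
}

#' Published PID-5 domain score moments used for trait rescaling
#' @format Data frame with columns domain, mean, sd (0-3 response scale).
#' @export
PID5_DOMAIN_MOMENTS <- data.frame(
  domain = c("NA", "DET", "ANT", "DIS", "PSY"),
  mean = c(0.98, 0.60, 0.57, 0.66, 0.47),
  sd = c(0.56, 0.46, 0.46, 0.50, 0.39),
  stringsAsFactors = FALSE
)

#' Joint subject-level data: true HBR coefficients plus PID-5 traits
#'
#' Draws one 8-dimensional Gaussian row per subject from the planted
#' network, then rescales columns: the three HBR columns become true
#' piecewise coefficients with the requested population means and
#' subject-level SDs; the five trait columns are shifted and scaled to the
#' published PID-5 domain means and SDs. Affine rescaling leaves partial
#' correlations untouched, so the planted network structure carries through
#' to the rescaled table.
#'
#' @param n_subjects Number of subjects.
#' @param net_config A [network_gen_config()] whose nodes are `GGM_NODES`.
#' @param params A [population_params()] for the piecewise form (its beta
#'   and tau scale the three HBR columns; all tau must be > 0).
#' @param seed Optional integer seed.
#' @return List with `traits` (data frame subject_id + 5 domains),
#'   `subject_coefficients` (matrix n x 3) and the raw Gaussian `table`.
#' @export
generate_joint_subject_data <- function(n_subjects,
                                        net_config = network_gen_config(n_samples = n_subjects),
                                        params = population_params("piecewise"),
                                        seed = NULL) {
  stopifnot(identical(net_config$node_names, GGM_NODES),
            params$form == "piecewise")
  if (any(params$tau <= 0)) {
    stop("all subject-level SDs must be > 0 to scale the joint table")
  }
  cfg <- net_config
  cfg$n_samples <- n_subjects
  cfg$seed <- seed %||% net_config$seed
  raw <- generate_network_dataset(cfg)
  sds <- apply(raw, 2, stats::sd)
  z <- sweep(sweep(raw, 2, colMeans(raw), `-`), 2, sds, `/`)

  traits <- as.data.frame(
    mapply(function(col, m, s) m + s * z[[col]],
           PID5_DOMAIN_MOMENTS$domain, PID5_DOMAIN_MOMENTS$mean,
           PID5_DOMAIN_MOMENTS$sd, SIMPLIFY = FALSE),
    check.names = FALSE
  )
  traits <- cbind(subject_id = sprintf("S%03d", seq_len(n_subjects)), traits,
                  stringsAsFactors = FALSE)

  hbr <- sapply(seq_along(params$parameter_names), function(j) {
    params$beta[j] + params$tau[j] * z[[c("intercept", "FtoM", "MtoN")[j]]]
  })
  colnames(hbr) <- params$parameter_names
  rownames(hbr) <- traits$subject_id
  list(traits = traits, subject_coefficients = hbr, table = raw)
}
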