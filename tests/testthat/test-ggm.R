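# Bayesian Gaussian graphical model: standardization, Wishart posterior,
# partial correlations and edge selection.

test_that("standardization uses the population-SD convention and is idempotent", {
  z <- standardize_nodes(data.frame(a = c(1, 2, 3), b = c(0, 4, 8)))
  expect_equal(z$a, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  z2 <- standardize_nodes(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12)
  expect_error(standardize_nodes(data.frame(a = 1:3, b = rep(2, 3))), "b")
})

test_that("scalar Wishart posterior matches the Gamma closed form", {
  set.seed(131)
  y <- matrix(rnorm(50, 0, 0.7), ncol = 1)
  nu0 <- 3
  draws <- sample_precision_posterior(y, prior_df = nu0, n_draws = 2e4, seed = 132)
  post_mean <- (nu0 + 50) / (1 + sum(y^2))
  # Wishart_1(df, V) = Gamma(df/2, rate 1/(2V)): mean df*V, var 2*df*V^2
  se <- sqrt(2 * (nu0 + 50)) * post_mean / (nu0 + 50) / sqrt(2e4)
  expect_lt(abs(mean(draws) - post_mean), 4 * se)

  # seed reproducibility
  again <- sample_precision_posterior(y, prior_df = nu0, n_draws = 100, seed = 132)
  expect_identical(sample_precision_posterior(y, prior_df = nu0,
                                              n_draws = 100, seed = 132), again)
  expect_error(sample_precision_posterior(matrix(rnorm(4), 2, 2)), "n > p")
})

test_that("posterior precision means are consistent for large n", {
  theta_true <- matrix(c(2, -0.8, -0.5,
                         -0.8, 2, -0.6,
                         -0.5, -0.6, 2), 3, 3)
  sigma <- solve(theta_true)
  set.seed(133)
  yr <- matrix(rnorm(5e4 * 3), ncol = 3) %*% chol(sigma)
  draws <- sample_precision_posterior(yr, n_draws = 2000, seed = 134)
  post_mean <- apply(draws, c(1, 2), mean)
  expect_lt(max(abs(post_mean - theta_true) / abs(theta_true)), 0.05)
})

test_that("partial correlations match the direct formula and a regression oracle", {
  expect_equal(partial_correlations(diag(4)), diag(4))
  expect_equal(partial_correlations(matrix(c(2, -1, -1, 2), 2, 2))[1, 2], 0.5)

  set.seed(135)
  a <- matrix(rnorm(25), 5, 5)
  theta <- crossprod(a) + diag(5)
  pc <- partial_correlations(theta)
  covm <- solve(theta)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(pc[i, j], partial_corr_regression(covm, i, j),
                   tolerance = 1e-10)
    }
  }
  expect_error(partial_correlations(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
  expect_error(partial_correlations(diag(c(-1, 1))), "diagonal")
})

test_that("edge selection respects the credible level, nesting and sign consistency", {
  set.seed(136)
  n_draw <- 2000
  pc_draws <- array(0, dim = c(3, 3, n_draw),
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C"), NULL))
  edge_ab <- rnorm(n_draw, 0.5, 0.05)   # clear edge
  edge_ac <- rnorm(n_draw, 0, 0.05)     # null
  edge_bc <- rnorm(n_draw, -0.4, 0.05)  # clear negative edge
  for (s in seq_len(n_draw)) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- edge_ab[s]
    m[1, 3] <- m[3, 1] <- edge_ac[s]
    m[2, 3] <- m[3, 2] <- edge_bc[s]
    pc_draws[, , s] <- m
  }
  net <- select_edges(pc_draws, level = 0.85)
  expect_true(net$adjacency["A", "B"])
  expect_false(net$adjacency["A", "C"])
  expect_true(net$adjacency["B", "C"])
  expect_false(any(diag(net$adjacency)))
  el <- network_edge_list(net)
  expect_equal(nrow(el), 2)
  expect_equal(el$sign[el$node_i == "B"], "negative")
  # sign consistency: included edges have median and both endpoints same sign
  for (r in seq_len(nrow(el))) {
    expect_equal(length(unique(sign(c(el$median[r], el$ci_lower[r],
                                      el$ci_upper[r])))), 1)
  }
  # 95% intervals contain the 85% intervals
  net95 <- select_edges(pc_draws, level = 0.95)
  expect_true(all(net95$ci_lower <= net$ci_lower + 1e-12))
  expect_true(all(net95$ci_upper >= net$ci_upper - 1e-12))

  expect_error(select_edges(pc_draws, level = 0.4), "level")
  expect_error(select_edges(pc_draws[, , 1:500], level = 0.85), "1000")
})

test_that("a planted bridge is detected on synthetic subjects", {
  rho <- diag(8)
  dimnames(rho) <- list(GGM_NODES, GGM_NODES)
  rho["DET", "MtoN"] <- rho["MtoN", "DET"] <- 0.4
  cfg <- network_gen_config(target_partial_corr = rho, n_samples = 500, seed = 137)
  d <- generate_network_dataset(cfg)
  net <- estimate_network(d, level = 0.85, n_draws = 2000, seed = 138)
  expect_true(net$adjacency["DET", "MtoN"])
  expect_gt(net$partial_corr_median["DET", "MtoN"], 0)
})

test_that("the two-cluster structure with a single bridge is recovered", {
  cfg <- network_gen_config(n_samples = 2000, seed = 139)
  d <- generate_network_dataset(cfg)
  net <- estimate_network(d, level = 0.85, n_draws = 2000, seed = 140)
  planted <- cfg$target_partial_corr
  for (i in 1:7) {
    for (j in (i + 1):8) {
      if (planted[i, j] != 0) {
        expect_true(net$adjacency[i, j],
                    label = sprintf("edge %s-%s detected", GGM_NODES[i], GGM_NODES[j]))
        expect_equal(sign(net$partial_corr_median[i, j]), sign(planted[i, j]),
                     label = sprintf("edge %s-%s sign", GGM_NODES[i], GGM_NODES[j]))
      }
    }
  }
})

test_that("network export round-trips and handles empty graphs", {
  set.seed(141)
  pc_draws <- array(rnorm(3 * 3 * 1200, 0, 0.03), dim = c(3, 3, 1200),
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C"), NULL))
  for (s in 1:1200) {
    pc_draws[, , s] <- (pc_draws[, , s] + t(pc_draws[, , s])) / 2
    diag(pc_draws[, , s]) <- 1
  }
  net <- select_edges(pc_draws, level = 0.85)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  expect_true(all(file.exists(paths)))
  el <- read.csv(paths["edges"])
  expect_equal(nrow(el), sum(net$adjacency) / 2)

  back <- read_network(dir)
  expect_equal(back$partial_corr_median, net$partial_corr_median, tolerance = 1e-12)
  expect_equal(back$adjacency, net$adjacency)
  expect_equal(back$level, net$level)
})
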