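# Synthetic generators: EMG traces, model-based AUC tables, and
# planted-network multivariate data.

test_that("blink amplitude calibration hits the expected rectified AUC", {
  # noiseless baseline: the only signal is the calibrated burst, so the
  # mean extracted AUC must approach the target at the closed-form rate
  target <- 130
  cfg <- emg_gen_config(
    n_subjects = 1, n_trials_per_position = 200, sides = "ipsi",
    baseline_noise_sd = 0, artifact_rate = 0,
    position_auc_targets = c(FAR = target, MIDDLE = target, NEAR = target),
    seed = 101
  )
  ds <- generate_emg_dataset(cfg)
  aucs <- vapply(ds, function(tr) compute_auc(rectify(tr)), numeric(1))
  # per-trial Monte-Carlo SD of the trapezoidal sum of |amp * g * eps|
  t_ms <- 0:130
  g <- exp(-(t_ms - 45)^2 / (2 * 15^2))
  amp <- uniroot(function(a) expected_rectified_auc(a, g, 0, 1) - target,
                 c(0, 100))$root
  w <- c(0.5, rep(1, 129), 0.5)
  mc_sd <- sqrt((1 - 2 / pi) * sum((w * amp * g)^2))
  se <- mc_sd / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - target), 4 * se)
  # and the closed-form oracle itself is exact for a pure rectangle:
  expect_equal(expected_rectified_auc(0, rep(1, 131), 1, 1),
               sqrt(2 / pi) * 130)
})

test_that("artifact flags follow artifact_rate and generation is seed-stable", {
  cfg0 <- emg_gen_config(n_subjects = 2, artifact_rate = 0, seed = 7)
  ds0 <- generate_emg_dataset(cfg0)
  expect_false(any(vapply(ds0, `[[`, logical(1), "artifact")))

  cfg1 <- emg_gen_config(n_subjects = 2, artifact_rate = 0.2, seed = 7)
  ds1 <- generate_emg_dataset(cfg1)
  expect_gt(sum(vapply(ds1, `[[`, logical(1), "artifact")), 0)

  ds1b <- generate_emg_dataset(cfg1)
  expect_identical(lapply(ds1, `[[`, "samples"), lapply(ds1b, `[[`, "samples"))
})

test_that("EMG generator rejects invalid configurations", {
  expect_error(emg_gen_config(position_auc_targets = c(FAR = -1, MIDDLE = 1, NEAR = 1)),
               "positive")
  expect_error(emg_gen_config(position_auc_targets = c(FAR = 1, MID = 1, NEAR = 1)),
               "keyed")
  expect_error(emg_gen_config(artifact_rate = 1), "artifact_rate")
  # a target below the baseline-noise floor cannot be calibrated
  cfg <- emg_gen_config(n_subjects = 1, baseline_noise_sd = 5,
                        position_auc_targets = c(FAR = 1, MIDDLE = 1, NEAR = 1))
  expect_error(generate_emg_dataset(cfg), "baseline")
})

test_that("AUC generator reproduces forced values in the noiseless limit", {
  p <- population_params("piecewise", beta = c(2.72, 0.02, 0.18),
                         tau = c(0, 0, 0), sigma = 1e-9, seed = 1)
  d <- generate_auc_dataset(p, 4)
  expect_equal(unique(round(d$auc[d$x == 2], 6)), round(exp(2.92), 6))
  expect_equal(unique(round(d$auc[d$x == 0], 6)), round(exp(2.72), 6))

  p0 <- population_params("intercept_only", beta = 1.5, tau = 0,
                          sigma = 1e-9, seed = 2)
  d0 <- generate_auc_dataset(p0, 5)
  expect_equal(d0$auc, rep(exp(1.5), 15), tolerance = 1e-6)
  expect_error(generate_auc_dataset(p0, 1), "n_subjects")
})

test_that("log-AUC moments converge to the generating values (LLN)", {
  p <- population_params("piecewise", seed = 11)
  d <- generate_auc_dataset(p, 5000)
  far <- log(d$auc[d$x == 0])
  # SD of one subject's log AUC at FAR: sqrt(tau1^2 + sigma^2)
  mc_se <- sqrt(0.3^2 + 0.16^2) / sqrt(5000)
  expect_lt(abs(mean(far) - 2.72), 3 * mc_se)
  expect_equal(sd(far), sqrt(0.3^2 + 0.16^2), tolerance = 4 / sqrt(5000) * 3)

  near <- log(d$auc[d$x == 2])
  mc_se_near <- sqrt(0.3^2 + 0.05^2 + 0.1^2 + 0.16^2) / sqrt(5000)
  expect_lt(abs(mean(near) - 2.92), 4 * mc_se_near)
})

test_that("planted partial correlations are recovered from large samples", {
  rho <- diag(8)
  dimnames(rho) <- list(GGM_NODES, GGM_NODES)
  rho["DET", "MtoN"] <- rho["MtoN", "DET"] <- 0.4
  cfg <- network_gen_config(target_partial_corr = rho, n_samples = 1e5, seed = 3)
  d <- generate_network_dataset(cfg)
  pc <- empirical_partial_correlations(d)
  expect_lt(abs(pc["DET", "MtoN"] - 0.4), 0.01)
  off <- pc[upper.tri(pc)]
  planted <- which(upper.tri(rho) & rho != 0)
  expect_lt(max(abs(pc[upper.tri(pc) & rho == 0])), 0.015)
})

test_that("a 3-node chain shows zero partial but nonzero marginal correlation", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.5
  rho[2, 3] <- rho[3, 2] <- 0.5
  cfg <- network_gen_config(node_names = c("A", "B", "C"),
                           target_partial_corr = rho,
                           n_samples = 5e4, seed = 4)
  d <- generate_network_dataset(cfg)
  pc <- empirical_partial_correlations(d)
  expect_lt(abs(pc["A", "C"]), 0.02)
  marg <- cor(d)["A", "C"]
  # brute force from the implied covariance: the A-C marginal correlation
  sigma <- solve(partial_corr_to_precision(rho))
  expect_gt(marg, 0.1)
  expect_equal(marg, sigma[1, 3] / sqrt(sigma[1, 1] * sigma[3, 3]),
               tolerance = 0.03)
})

test_that("network generator validates its target matrix", {
  bad <- diag(3)
  bad[1, 2] <- 0.5  # asymmetric
  expect_error(network_gen_config(node_names = c("A", "B", "C"),
                                  target_partial_corr = bad), "symmetric")
  # partial correlations too strong for positive definiteness
  strong <- diag(3)
  strong[1, 2] <- strong[2, 1] <- 0.9
  strong[2, 3] <- strong[3, 2] <- 0.9
  strong[1, 3] <- strong[3, 1] <- 0.9
  expect_error(partial_corr_to_precision(strong), "positive definite")
})

test_that("joint subject tables preserve the planted bridge after rescaling", {
  joint <- generate_joint_subject_data(4000, seed = 9)
  tab <- cbind(joint$traits[, -1], joint$subject_coefficients)
  pc <- empirical_partial_correlations(tab)
  expect_gt(pc["DET", "MtoN"], 0.2)  # planted 0.3
  expect_lt(abs(pc["NA", "ANT"]), 0.06)  # not planted
  # trait columns live on the 0-3 questionnaire scale
  expect_equal(mean(joint$traits$DET), 0.60, tolerance = 0.05)
})
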