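# Preprocessing chain: filter -> rectify -> QC -> average -> AUC ->
# responder criterion.

test_that("the default filter removes DC and preserves in-band sine amplitude", {
  dc <- make_trace(rep(2, 1000))
  out <- filter_trace(dc)
  expect_lt(max(abs(out$samples)), 1e-6 * 2)
  expect_equal(length(out$samples), 1000)
  expect_equal(out$stimulus_onset, dc$stimulus_onset)

  t <- seq_len(2000) / 1000
  sine <- make_trace(sin(2 * pi * 100 * t))
  fo <- filter_trace(sine)
  mid <- fo$samples[500:1500]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)

  expect_error(filter_trace(dc, low_hz = 500, high_hz = 10), "band")
  expect_error(filter_trace(dc, low_hz = 10, high_hz = 900), "Nyquist")
})

test_that("rectification is elementwise absolute value and idempotent", {
  tr <- make_trace(c(-1, 2, -3), stimulus_onset = 1)
  expect_equal(rectify(tr)$samples, c(1, 2, 3))
  expect_equal(rectify(rectify(tr))$samples, rectify(tr)$samples)
  z <- make_trace(rep(0, 10), stimulus_onset = 1)
  expect_equal(rectify(z)$samples, rep(0, 10))
})

test_that("QC discards exactly the trials with abnormal pre-stimulus activity", {
  set.seed(21)
  clean <- lapply(1:6, function(i) {
    make_trace(rnorm(500, 0, 0.01), trial_index = i)
  })
  bad <- make_trace(c(rnorm(200, 0, 0.1), rnorm(300, 0, 0.01)) * 1,
                    trial_index = 7)  # 10x pre-stimulus noise
  qc <- qc_trials(c(clean, list(bad)))
  expect_length(qc$discarded, 1)
  expect_equal(qc$discarded[[1]]$trial_index, 7)
  expect_equal(sum(qc$log$discarded), 1)

  qc_clean <- qc_trials(clean)
  expect_length(qc_clean$discarded, 0)
  qc_inf <- qc_trials(c(clean, list(bad)), k = Inf)
  expect_length(qc_inf$discarded, 0)

  short <- make_trace(rnorm(120), stimulus_onset = 50)
  expect_error(qc_trials(list(short, short)), "pre-stimulus")
})

test_that("generator artifact flags are caught by the QC rule", {
  cfg <- emg_gen_config(n_subjects = 3, artifact_rate = 0.15, seed = 31)
  ds <- generate_emg_dataset(cfg)
  rect <- lapply(lapply(ds, filter_trace), rectify)
  qc <- qc_trials(rect)
  flagged <- which(vapply(ds, `[[`, logical(1), "artifact"))
  discarded <- which(qc$log$discarded)
  expect_setequal(discarded, flagged)
  expect_gt(length(flagged), 0)
})

test_that("QC discard rate on default synthetic data is about 1%", {
  cfg <- emg_gen_config(n_subjects = 55, artifact_rate = 0.01, seed = 41)
  ds <- generate_emg_dataset(cfg)
  rect <- lapply(lapply(ds, filter_trace), rectify)
  qc <- qc_trials(rect)
  rate <- length(qc$discarded) / length(ds)
  # 1650 trials at 1%: well inside [0.2%, 2.5%]
  expect_gt(rate, 0.002)
  expect_lt(rate, 0.025)
})

test_that("condition averaging pools trials and then recording sides", {
  x <- abs(rnorm(500))
  t1 <- make_trace(x, side = "ipsi")
  t2 <- make_trace(x, side = "contra")
  # both FAR only: need all three positions for the table, so test the
  # averaging core on a single position via its error path first
  expect_error(average_condition(list(t1, t2)), "MIDDLE")

  trs <- list()
  for (pos in c("FAR", "MIDDLE", "NEAR")) {
    for (side in c("ipsi", "contra")) {
      trs <- c(trs, list(make_trace(x, side = side, position = pos)))
    }
  }
  waves <- average_condition(trs)
  expect_length(waves, 3)
  expect_equal(waves[["S001.FAR"]]$samples, x)
  expect_equal(waves[["S001.FAR"]]$n_trials_kept, 2)

  # rectification precedes averaging: averaging x and -x after
  # rectification returns |x|, not zero
  neg <- lapply(trs, function(tr) { tr$samples <- -tr$samples; tr })
  both <- c(lapply(trs, rectify), lapply(neg, rectify))
  w2 <- average_condition(both)
  expect_equal(w2[["S001.NEAR"]]$samples, abs(x))
  avg_then_rect <- abs((x + (-x)) / 2)
  expect_false(isTRUE(all.equal(w2[["S001.NEAR"]]$samples, avg_then_rect)))
})

test_that("averaging n noise trials shrinks the SD by sqrt(n)", {
  set.seed(55)
  trs <- list()
  for (pos in c("FAR", "MIDDLE", "NEAR")) {
    for (i in 1:10) {
      trs <- c(trs, list(make_trace(rnorm(500), position = pos, trial_index = i)))
    }
  }
  waves <- average_condition(trs)
  expect_equal(sd(waves[["S001.FAR"]]$samples), 1 / sqrt(10), tolerance = 0.15)
})

test_that("AUC integrates rectangles, triangles and random traces correctly", {
  const <- make_trace(rep(1, 500))
  expect_equal(compute_auc(const), 130)

  ramp_val <- c(rep(0, 200), seq(0, 2, length.out = 131), rep(2, 169))
  ramp <- make_trace(ramp_val)
  expect_equal(compute_auc(ramp), 130)

  set.seed(8)
  y <- abs(rnorm(500))
  tr <- make_trace(y)
  # independent oracle: adaptive quadrature on the linear interpolant
  f <- approxfun((seq_along(y) - 201) * 1, y)
  oracle <- integrate(f, 0, 130, subdivisions = 2000L, rel.tol = 1e-7,
                      stop.on.error = FALSE)$value
  expect_equal(compute_auc(tr), oracle, tolerance = 1e-3)

  # linearity in the waveform amplitude
  tr3 <- make_trace(3 * y)
  expect_equal(compute_auc(tr3), 3 * compute_auc(tr))

  expect_error(compute_auc(make_trace(rep(1, 300), stimulus_onset = 250)),
               "window")
})

test_that("responder criterion compares post-stimulus activity to baseline", {
  set.seed(9)
  base <- rnorm(500, 0, 0.05)
  none <- make_trace(base)
  expect_false(responder_check(none))

  burst <- base
  burst[201:330] <- burst[201:330] + 0.5  # 10x baseline SD
  expect_true(responder_check(make_trace(burst)))

  flat <- make_trace(rep(0, 500))
  expect_warning(flag <- responder_check(flat), "degenerate")
  expect_false(flag)
})

test_that("end-to-end AUC recovery matches the generator targets within 5%", {
  cfg <- emg_gen_config(n_subjects = 5, artifact_rate = 0, seed = 61)
  ds <- generate_emg_dataset(cfg)
  tab <- emg_to_auc_table(ds)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$auc >= 0))
  expect_true(all(table(tab$subject_id) == 3))
  pos_means <- tapply(tab$auc, tab$position, mean)
  targets <- cfg$position_auc_targets
  expect_lt(max(abs(pos_means[names(targets)] - targets) / targets), 0.05)
  expect_true(all(tab$responder))
})
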