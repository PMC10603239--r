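# Trial-level EMG simulation.
#
# Each trial is zero-mean Gaussian baseline noise; after the stimulus onset
# a blink burst is added as Gaussian-envelope-modulated white noise centred
# at the blink latency. The burst amplitude is calibrated so that the
# expected rectified AUC over the 130-ms post-stimulus window equals the
# requested per-position target. Only the AUC integral matters downstream,
# so no attempt is made at realistic blink morphology beyond that.

#' Configuration for the trial-level EMG generator
#'
#' Emulates the HBR acquisition protocol: each subject contributes
#' `n_trials_per_position` trials per hand position (FAR/MIDDLE/NEAR) and
#' recording side (ipsilateral/contralateral orbicularis oculi), digitized
#' at `sampling_rate` Hz with `pre_stimulus_ms` of baseline before the
#' stimulus onset.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_position Trials per subject x side x position
#'   (protocol default 5).
#' @param sides Recording sides; default both `"ipsi"` and `"contra"`.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param pre_stimulus_ms,post_stimulus_ms Trace duration before/after the
#'   stimulus onset, in ms. The post-stimulus segment must cover the 130-ms
#'   AUC window.
#' @param baseline_noise_sd SD of the Gaussian baseline noise, in mV.
#' @param blink_latency_ms Centre of the blink burst after onset (default
#'   45 ms).
#' @param blink_envelope_sd_ms SD of the Gaussian burst envelope (default
#'   15 ms).
#' @param position_auc_targets Named vector (FAR, MIDDLE, NEAR) of expected
#'   rectified AUC over the 130-ms window, in mV*ms. Defaults are the
#'   response-scale medians implied by the published piecewise population
#'   estimates: exp(2.72), exp(2.74), exp(2.92).
#' @param artifact_rate Probability in \[0, 1) that a trial additionally
#'   receives a pre-stimulus burst (flagged internally so QC tests have an
#'   oracle).
#' @param seed Optional integer seed.
#' @param subject_targets Optional n_subjects x 3 matrix (columns FAR,
#'   MIDDLE, NEAR) of per-subject AUC targets overriding
#'   `position_auc_targets`; used when traces must reflect subject-level
#'   heterogeneity.
#' @return An object of class `emg_gen_config`.
#' @export
emg_gen_config <- function(n_subjects = 55,
                           n_trials_per_position = 5,
                           sides = c("ipsi", "contra"),
                           sampling_rate = 1000,
                           pre_stimulus_ms = 200,
                           post_stimulus_ms = 300,
                           baseline_noise_sd = 0.01,
                           blink_latency_ms = 45,
                           blink_envelope_sd_ms = 15,
                           position_auc_targets = c(FAR = exp(2.72), MIDDLE = exp(2.74), NEAR = exp(2.92)),
                           artifact_rate = 0.01,
                           seed = NULL,
                           subject_targets = NULL) {
  assert_count(n_subjects, "n_subjects")
  assert_count(n_trials_per_position, "n_trials_per_position")
  sides <- match.arg(sides, c("ipsi", "contra"), several.ok = TRUE)
  assert_positive_scalar(sampling_rate, "sampling_rate")
  assert_positive_scalar(pre_stimulus_ms, "pre_stimulus_ms")
  assert_positive_scalar(post_stimulus_ms, "post_stimulus_ms")
  assert_positive_scalar(blink_latency_ms, "blink_latency_ms")
  assert_positive_scalar(blink_envelope_sd_ms, "blink_envelope_sd_ms")
  if (!is.numeric(baseline_noise_sd) || baseline_noise_sd < 0) {
    stop("'baseline_noise_sd' must be >= 0")
  }
  if (!setequal(names(position_auc_targets), HBR_POSITIONS)) {
    stop("'position_auc_targets' must be keyed exactly by FAR, MIDDLE, NEAR")
  }
  if (any(position_auc_targets <= 0)) stop("AUC targets must be positive")
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate >= 1) {
    stop("'artifact_rate' must be in [0, 1)")
  }
  if (post_stimulus_ms < 130) {
    stop("'post_stimulus_ms' must cover the 130-ms AUC window")
  }
  if (!is.null(subject_targets)) {
    subject_targets <- as.matrix(subject_targets)
    if (nrow(subject_targets) != n_subjects ||
        !setequal(colnames(subject_targets), HBR_POSITIONS)) {
      stop("'subject_targets' must be n_subjects rows with columns FAR, MIDDLE, NEAR")
    }
    if (any(subject_targets <= 0)) stop("AUC targets must be positive")
  }
  structure(
    list(n_subjects = n_subjects, n_trials_per_position = n_trials_per_position,
         sides = sides, sampling_rate = sampling_rate,
         pre_stimulus_ms = pre_stimulus_ms, post_stimulus_ms = post_stimulus_ms,
         baseline_noise_sd = baseline_noise_sd,
         blink_latency_ms = blink_latency_ms,
         blink_envelope_sd_ms = blink_envelope_sd_ms,
         position_auc_targets = position_auc_targets[HBR_POSITIONS],
         artifact_rate = artifact_rate, seed = seed,
         subject_targets = subject_targets),
    class = "emg_gen_config"
  )
}

# Trapezoidal quadrature weights (in samples) over the AUC window:
# 131 samples at 1 kHz spanning [onset, onset + 130 ms].
auc_window_weights <- function(n_points) {
  w <- rep(1, n_points)
  w[c(1, n_points)] <- 0.5
  w
}

#' Expected rectified AUC of a burst-plus-noise trace
#'
#' Closed form: each sample is Normal(0, s_i^2) with
#' s_i^2 = baseline_sd^2 + (amplitude * envelope_i)^2, so its expected
#' absolute value is sqrt(2/pi) * s_i; the expected trapezoidal integral
#' over the window follows by linearity. Used both to calibrate the burst
#' amplitude and as the independent oracle in tests.
#'
#' @param amplitude Burst amplitude (mV).
#' @param envelope Envelope values at the window samples.
#' @param baseline_sd Baseline noise SD (mV).
#' @param dt_ms Sample spacing in ms.
#' @return Expected AUC in mV*ms.
#' @export
expected_rectified_auc <- function(amplitude, envelope, baseline_sd, dt_ms) {
  s <- sqrt(baseline_sd^2 + (amplitude * envelope)^2)
  w <- auc_window_weights(length(envelope))
  sqrt(2 / pi) * sum(w * s) * dt_ms
}

# Solve for the burst amplitude whose expected rectified AUC equals target.
calibrate_blink_amplitude <- function(target, envelope, baseline_sd, dt_ms) {
  base <- expected_rectified_auc(0, envelope, baseline_sd, dt_ms)
  if (target <= base) {
    stop(sprintf(
      "AUC target %.3f mV*ms is not above the baseline-noise contribution %.3f mV*ms",
      target, base))
  }
  stats::uniroot(
    function(a) expected_rectified_auc(a, envelope, baseline_sd, dt_ms) - target,
    lower = 0, upper = 1, extendInt = "upX", tol = 1e-10
  )$root
}

new_emg_trace <- function(subject_id, side, position, trial_index,
                          sampling_rate, samples, stimulus_onset,
                          artifact = FALSE) {
  structure(
    list(subject_id = subject_id, side = side,
         position = position, trial_index = trial_index,
         sampling_rate = sampling_rate, samples = samples,
         stimulus_onset = stimulus_onset, artifact = artifact),
    class = "emg_trace"
  )
}

#' Generate a trial-level synthetic EMG dataset
#'
#' For each subject, side and position, simulates `n_trials_per_position`
#' traces of baseline Gaussian noise plus a post-stimulus blink burst
#' (Gaussian-envelope-modulated white noise centred at the blink latency)
#' whose amplitude is calibrated so the expected rectified AUC over the
#' 130-ms post-stimulus window equals the position's target. A fraction
#' `artifact_rate` of trials receives an additional pre-stimulus burst and
#' is flagged `artifact = TRUE` (the flag is internal ground truth for QC
#' testing; the preprocessing stage never reads it).
#'
#' @param config An [emg_gen_config()].
#' @return A list of `emg_trace` objects with class `emg_dataset`; the
#'   generating config is attached as attribute `"config"`.
#' @export
generate_emg_dataset <- function(config) {
  stopifnot(inherits(config, "emg_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  dt_ms <- 1000 / fs
  n_pre <- round(config$pre_stimulus_ms / dt_ms)
  n_post <- round(config$post_stimulus_ms / dt_ms)
  n_total <- n_pre + n_post
  onset <- n_pre + 1L
  n_win <- round(130 / dt_ms) + 1L  # samples in [onset, onset + 130 ms]

  t_post_ms <- (seq_len(n_post) - 1) * dt_ms
  envelope_post <- exp(-(t_post_ms - config$blink_latency_ms)^2 /
                         (2 * config$blink_envelope_sd_ms^2))
  envelope_win <- envelope_post[seq_len(n_win)]

  # pre-stimulus artifact burst: same envelope shape, centred mid-baseline
  t_pre_ms <- (seq_len(n_pre) - 1) * dt_ms
  envelope_pre <- exp(-(t_pre_ms - config$pre_stimulus_ms / 2)^2 /
                        (2 * config$blink_envelope_sd_ms^2))

  amp_for_target <- function(target) {
    calibrate_blink_amplitude(target, envelope_win, config$baseline_noise_sd, dt_ms)
  }
  global_amp <- vapply(config$position_auc_targets, amp_for_target, numeric(1))

  traces <- vector("list", config$n_subjects * length(config$sides) *
                     3L * config$n_trials_per_position)
  idx <- 0L
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    amps <- if (is.null(config$subject_targets)) {
      global_amp
    } else {
      vapply(config$subject_targets[i, HBR_POSITIONS], amp_for_target, numeric(1))
    }
    for (side in config$sides) {
      for (pos_i in seq_along(HBR_POSITIONS)) {
        pos <- HBR_POSITIONS[pos_i]
        amp <- amps[pos_i]
        for (tr in seq_len(config$n_trials_per_position)) {
          x <- stats::rnorm(n_total, 0, config$baseline_noise_sd)
          burst <- amp * envelope_post * stats::rnorm(n_post)
          x[(n_pre + 1):n_total] <- x[(n_pre + 1):n_total] + burst
          artifact <- config$artifact_rate > 0 &&
            stats::runif(1) < config$artifact_rate
          if (artifact) {
            x[seq_len(n_pre)] <- x[seq_len(n_pre)] +
              5 * amp * envelope_pre * stats::rnorm(n_pre)
          }
          idx <- idx + 1L
          traces[[idx]] <- new_emg_trace(sid, side, pos, tr, fs, x, onset,
                                         artifact)
        }
      }
    }
  }
  structure(traces, class = "emg_dataset", config = config)
}

#' Write/read a trial-level EMG dataset
#'
#' Long-format CSV (subject_id, side, position, trial, t_ms, value_mV) with
#' a JSON sidecar holding the stimulus-onset index, sampling rate and the
#' generation config.
#'
#' @param dataset An `emg_dataset`.
#' @param csv_path Path of the long CSV.
#' @param json_path Path of the JSON sidecar; default `csv_path` with a
#'   `.json` extension.
#' @return `read_emg_dataset` returns an `emg_dataset`.
#' @export
write_emg_dataset <- function(dataset, csv_path,
                              json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(dataset, "emg_dataset"))
  rows <- lapply(dataset, function(tr) {
    data.frame(
      subject_id = tr$subject_id, side = tr$side, position = tr$position,
      trial = tr$trial_index,
      t_ms = (seq_along(tr$samples) - tr$stimulus_onset) * 1000 / tr$sampling_rate,
      value_mV = tr$samples, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  cfg <- attr(dataset, "config")
  sidecar <- list(
    stimulus_onset = dataset[[1]]$stimulus_onset,
    sampling_rate = dataset[[1]]$sampling_rate,
    n_traces = length(dataset),
    artifact_flags = vapply(dataset, `[[`, logical(1), "artifact"),
    config = if (!is.null(cfg)) unclass(cfg)[setdiff(names(cfg), "subject_targets")]
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_emg_dataset
#' @export
read_emg_dataset <- function(csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  long <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  key <- interaction(long$subject_id, long$side, long$position, long$trial,
                     drop = TRUE, lex.order = TRUE)
  parts <- split(long, key)
  traces <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- parts[[i]][order(parts[[i]]$t_ms), ]
    traces[[i]] <- new_emg_trace(
      d$subject_id[1], d$side[1], d$position[1], d$trial[1],
      side$sampling_rate, d$value_mV, side$stimulus_onset
    )
  }
  structure(traces, class = "emg_dataset")
}
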