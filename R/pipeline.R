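# End-to-end orchestration: simulate -> preprocess -> fit all five models
# -> compare -> extract subject medians -> join with traits -> network.
# Each stage reads only its predecessor's declared artifacts, so partial
# reruns from files are possible; every summary number is determined by
# the config plus its seed.

#' Default pipeline configuration
#'
#' The default run simulates at the study's scale - 55 subjects, 3 hand
#' positions, 5 trials per position on each of 2 recording sides - with
#' piecewise-lognormal subject-level truth, fits all five candidate
#' models with 4 chains of 1,000 warmup + 5,000 total iterations, and
#' estimates the 8-node personality/HBR network at the 85% credible level.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return Nested configuration list of class `hbr_run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    n_subjects = 55,
    emg = list(n_trials_per_position = 5, sides = c("ipsi", "contra"),
               sampling_rate = 1000, pre_stimulus_ms = 200,
               post_stimulus_ms = 300, baseline_noise_sd = 0.01,
               blink_latency_ms = 45, blink_envelope_sd_ms = 15,
               artifact_rate = 0.01),
    population = list(form = "piecewise", beta = c(2.72, 0.02, 0.18),
                      sigma = 0.16, tau = c(0.3, 0.05, 0.1)),
    bridge_partial_corr = 0.3,
    forms = names(HBR_FORMS),
    mcmc = list(chains = 4, warmup = 1000, iterations = 5000),
    network = list(level = 0.85, n_draws = 5000),
    paths = list(traits_csv = NULL, auc_csv = NULL),
    write_raw_emg = FALSE
  ), class = "hbr_run_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' Values omitted from the file fall back to [default_run_config()].
#' @param path YAML file path.
#' @param config A run configuration list.
#' @return `read_run_config` returns an `hbr_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1)
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_into(base[[nm]], new[[nm]])
      } else {
        new[[nm]]
      }
    }
    base
  }
  out <- merge_into(unclass(cfg), user)
  structure(out, class = "hbr_run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message(sprintf("[%s] stage '%s' ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order and writes every artifact under
#' `out_dir`:
#' `simulate` (joint subject truth + trial-level EMG), `preprocess`
#' (filter/rectify/QC/average/AUC -> `auc_table.csv`), `fit` (all
#' configured model forms; population summaries and diagnostics),
#' `compare` (`model_comparison.csv`, posterior predictive checks,
#' `subject_params.csv` from the piecewise fit) and `network` (traits +
#' subject parameters -> `network/`). A JSON + text report with the config
#' hash, seeds and headline results is written last. Re-running with the
#' same config reproduces all summary numbers.
#'
#' When `config$paths$auc_csv` or `config$paths$traits_csv` are set, those
#' stages read the named files instead of simulated data; a missing file
#' is an error naming the path.
#'
#' @param config An `hbr_run_config`.
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "fit", "compare", "network")`.
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("simulate", "preprocess", "fit",
                                    "compare", "network"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "hbr_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  traits_path <- config$paths$traits_csv
  if (!is.null(traits_path) && !file.exists(traits_path)) {
    stop("trait table not found: ", traits_path)
  }
  auc_path <- config$paths$auc_csv
  if (!is.null(auc_path) && !file.exists(auc_path)) {
    stop("AUC table not found: ", auc_path)
  }

  if ("simulate" %in% stages) {
    res$sim <- pipeline_stage("simulate", quiet, {
      params <- population_params(
        config$population$form, beta = config$population$beta,
        sigma = config$population$sigma, tau = config$population$tau
      )
      joint <- generate_joint_subject_data(
        config$n_subjects,
        net_config = network_gen_config(
          target_partial_corr = default_partial_corr(config$bridge_partial_corr),
          n_samples = config$n_subjects
        ),
        params = params,
        seed = derive_seed(config$seed, 11)
      )
      # one lognormal AUC draw per subject x position (location from the
      # subject's true piecewise coefficients, scale sigma); the EMG layer
      # then synthesizes traces whose expected extracted AUC equals that
      # draw, adding only trial-level measurement noise on top
      set.seed(derive_seed(config$seed, 16))
      targets <- t(apply(joint$subject_coefficients, 1, function(bi) {
        mu <- hbr_location("piecewise", bi, 0:2)
        exp(mu + stats::rnorm(3, 0, params$sigma))
      }))
      colnames(targets) <- HBR_POSITIONS
      emg_cfg <- do.call(emg_gen_config, c(
        list(n_subjects = config$n_subjects,
             seed = derive_seed(config$seed, 12),
             subject_targets = targets),
        config$emg
      ))
      emg <- generate_emg_dataset(emg_cfg)
      utils::write.csv(joint$traits, file.path(out_dir, "traits.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(subject_id = rownames(joint$subject_coefficients),
                   joint$subject_coefficients),
        file.path(out_dir, "true_subject_params_synthetic.csv"),
        row.names = FALSE
      )
      if (isTRUE(config$write_raw_emg)) {
        write_emg_dataset(emg, file.path(out_dir, "emg_long.csv"))
      }
      list(joint = joint, emg = emg, params = params)
    })
  }

  if ("preprocess" %in% stages) {
    res$auc <- pipeline_stage("preprocess", quiet, {
      if (!is.null(auc_path)) {
        read_auc_table(auc_path)
      } else {
        if (is.null(res$sim)) stop("no simulated EMG and no 'auc_csv' path configured")
        auc <- emg_to_auc_table(res$sim$emg)
        write_auc_table(auc, file.path(out_dir, "auc_table.csv"))
        utils::write.csv(attr(auc, "qc_log"), file.path(out_dir, "qc_log.csv"),
                         row.names = FALSE)
        auc
      }
    })
  }

  if ("fit" %in% stages) {
    res$fits <- pipeline_stage("fit", quiet, {
      if (is.null(res$auc)) stop("no AUC table available; run 'preprocess' or set paths$auc_csv")
      mc <- mcmc_config(chains = config$mcmc$chains,
                        warmup = config$mcmc$warmup,
                        iterations = config$mcmc$iterations,
                        seed = derive_seed(config$seed, 13))
      fits <- lapply(config$forms, function(form) {
        if (!quiet) message("  fitting '", form, "'")
        suppressWarnings(fit_hbr_model(res$auc, hbr_model_spec(form), mc))
      })
      names(fits) <- config$forms
      for (form in config$forms) {
        utils::write.csv(population_summary(fits[[form]]),
                         file.path(out_dir, sprintf("fit_%s_summary.csv", form)),
                         row.names = FALSE)
        write_population_draws(
          fits[[form]], file.path(out_dir, sprintf("fit_%s_draws.csv", form))
        )
      }
      jsonlite::write_json(
        lapply(fits, function(f) {
          list(converged = f$converged,
               diagnostics = f$diagnostics[, c("parameter_label", "rhat",
                                               "bulk_ess", "tail_ess")])
        }),
        file.path(out_dir, "fit_diagnostics.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      fits
    })
  }

  if ("compare" %in% stages) {
    compare_out <- pipeline_stage("compare", quiet, {
      if (is.null(res$fits)) stop("no fits available; run the 'fit' stage first")
      if (is.null(res$fits[["piecewise"]])) {
        stop("the 'compare' stage requires the piecewise form among the fitted models")
      }
      cmp <- compare_models(res$fits)
      utils::write.csv(cmp$table, file.path(out_dir, "model_comparison.csv"),
                       row.names = FALSE)
      set.seed(derive_seed(config$seed, 14))
      ppc <- posterior_predictive_check(res$fits[["piecewise"]])
      utils::write.csv(ppc, file.path(out_dir, "ppc_piecewise.csv"),
                       row.names = FALSE)
      medians <- extract_subject_medians(res$fits[["piecewise"]])
      utils::write.csv(medians, file.path(out_dir, "subject_params.csv"),
                       row.names = FALSE)
      list(comparison = cmp, subject_params = medians)
    })
    res$comparison <- compare_out$comparison
    res$subject_params <- compare_out$subject_params
  }

  if ("network" %in% stages) {
    res$network <- pipeline_stage("network", quiet, {
      traits <- if (!is.null(traits_path)) {
        utils::read.csv(traits_path, check.names = FALSE)
      } else if (!is.null(res$sim)) {
        res$sim$joint$traits
      } else {
        stop("no trait table: set paths$traits_csv or run the 'simulate' stage")
      }
      params <- res$subject_params %||% {
        sp_path <- file.path(out_dir, "subject_params.csv")
        if (!file.exists(sp_path)) stop("subject parameters not found: ", sp_path)
        utils::read.csv(sp_path)
      }
      node_table <- merge(traits, params, by = "subject_id")
      if (nrow(node_table) == 0) stop("traits and subject parameters share no subjects")
      node_table <- node_table[, c("NA", "DET", "ANT", "DIS", "PSY",
                                   "intercept", "FtoM", "MtoN")]
      net <- estimate_network(node_table, level = config$network$level,
                              n_draws = config$network$n_draws,
                              seed = derive_seed(config$seed, 15))
      export_network(net, file.path(out_dir, "network"))
      net
    })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("hbrnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages,
    best_model = if (!is.null(res$comparison)) res$comparison$table$model[1],
    n_edges = if (!is.null(res$network)) sum(res$network$adjacency) / 2,
    n_subjects = config$n_subjects
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lines <- c(
    "HBR / personality-network pipeline run",
    sprintf("  date: %s", report$timestamp),
    sprintf("  seed: %s  config hash: %s", report$seed, report$config_hash),
    sprintf("  stages: %s", paste(stages, collapse = ", ")),
    if (!is.null(report$best_model)) sprintf("  best model by ELPD: %s", report$best_model),
    if (!is.null(report$n_edges)) sprintf("  network edges at %g%%: %d",
                                          100 * config$network$level, report$n_edges)
  )
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(res)
}
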