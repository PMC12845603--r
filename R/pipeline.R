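# End-to-end orchestration and recording file I/O.

#' Pipeline run configuration
#'
#' A fully serializable description of one pipeline run; together with its
#' seed it reproduces every output byte-for-byte.
#'
#' @param experiment `"stress"` or `"workload"`.
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed for the run.
#' @param effect_scale Condition/level effect scaling for the generator.
#' @param artifact_rates Named artifact events/minute rates.
#' @param label_modes Labelling modes to evaluate (see [label_spec()]).
#' @param model `"ann"`, `"logistic"`, `"svm"` or `"random_forest"`.
#' @param n_folds Cross-validation folds.
#' @param epochs,learning_rate,batch_size Network training settings.
#' @param shap_instances,shap_permutations,shap_background Attribution
#'   settings (instances to explain, permutations per instance, background
#'   rows).
#' @param tasks Workload tasks to include (workload experiment only).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(experiment = c("stress", "workload"),
                       n_subjects = 8, seed = 1, effect_scale = 1,
                       artifact_rates = c(motion = 0.3, muscle = 0.3),
                       label_modes = NULL, model = "ann", n_folds = 3,
                       epochs = 200, learning_rate = 1e-3, batch_size = 32,
                       shap_instances = 20, shap_permutations = 30,
                       shap_background = 100,
                       tasks = c("arithmetic", "finger_tapping",
                                 "lexical_decision", "mental_rotation")) {
  experiment <- match.arg(experiment)
  label_modes <- label_modes %||% if (experiment == "stress") {
    c("stress_binary_med_vs_cp", "stress_binary_eo_vs_cp")
  } else "workload_binary"
  structure(
    list(experiment = experiment, n_subjects = n_subjects, seed = seed,
         effect_scale = effect_scale, artifact_rates = artifact_rates,
         label_modes = label_modes, model = model, n_folds = n_folds,
         epochs = epochs, learning_rate = learning_rate,
         batch_size = batch_size, shap_instances = shap_instances,
         shap_permutations = shap_permutations,
         shap_background = shap_background, tasks = tasks),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$artifact_rates)) {
    vals$artifact_rates <- unlist(vals$artifact_rates)
  }
  do.call(run_config, vals)
}

config_hash <- function(config) substr(rlang::hash(unclass(config)), 1, 8)

stage_log <- function(stage, t0) {
  message(sprintf("[eareeg] %-12s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

model_arch <- function(config, mode) {
  if (config$model != "ann") return(config$model)
  if (mode == "stress_3class") {
    ann_architecture(output = "softmax", n_classes = 3)
  } else if (mode == "stress_regression") {
    ann_architecture(output = "linear")
  } else {
    ann_architecture(output = "sigmoid")
  }
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess (filter, segment, QC), featurize, label,
#' cross-validate, explain, and the protocol statistics, writing the metric,
#' QC, attribution and statistics tables plus a run manifest (config hash,
#' seed, version) to `out_dir`. Every output filename carries the config
#' hash, and a rerun with the same config and seed reproduces the files
#' byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `cv` per label mode, `ranking`, `stats`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("eareeg_run")) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_subjects < config$n_folds) {
    abort(sprintf(
      "grouped %d-fold cross-validation requires at least %d subjects, got %d.",
      config$n_folds, config$n_folds, config$n_subjects))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  path_for <- function(stem, ext = "tsv") file.path(out_dir, sprintf("%s_%s.%s", stem, h, ext))
  t0 <- as.numeric(Sys.time())
  cfg_train <- training_config(config$epochs, config$learning_rate,
                               config$batch_size, seed = config$seed)

  # simulate ---------------------------------------------------------------
  study <- if (config$experiment == "stress") {
    generate_stress_study(config$n_subjects, config$seed, config$effect_scale,
                          config$artifact_rates)
  } else {
    generate_workload_study(config$n_subjects, config$seed, config$effect_scale,
                            tasks = config$tasks,
                            artifact_rates = config$artifact_rates)
  }
  stage_log("simulate", t0)

  # preprocess -------------------------------------------------------------
  filtered <- apply_filters(study, filter_spec())
  segments <- segment_recordings(
    filtered, qc_config(),
    mode = if (config$experiment == "stress") "fixed" else "trial"
  )
  segments <- qc_segments(segments, qc_config())
  write_qc_report(segments, path_for("qc_report"))
  stage_log("preprocess", t0)

  # features ---------------------------------------------------------------
  features <- suppressMessages(compute_features(segments))
  write_feature_table(features, path_for("features"))
  stage_log("features", t0)

  # label + cross-validate --------------------------------------------------
  cv_results <- list()
  metric_rows <- list()
  for (mode in config$label_modes) {
    labelled <- assign_labels(features, mode)
    if (config$experiment == "workload" && mode != "stress_regression") {
      for (task in unique(labelled$task)) {
        sub <- labelled[labelled$task == task, , drop = FALSE]
        cv <- cross_validate(sub, model_arch(config, mode), cfg_train,
                             cv_plan("group_shuffle_by_subject",
                                     config$n_folds, config$seed))
        cv_results[[paste(mode, task, sep = ":")]] <- cv
        metric_rows[[length(metric_rows) + 1L]] <-
          cv$folds |> mutate(mode = mode, task = task, .before = 1)
      }
    } else if (mode == "stress_regression") {
      reg <- subject_regressions(
        labelled, ann_architecture(output = "linear"), cfg_train,
        cv_plan("kfold_within_subject", config$n_folds, config$seed))
      cv_results[[mode]] <- reg
      metric_rows[[length(metric_rows) + 1L]] <-
        reg |> mutate(mode = mode, task = NA_character_, .before = 1)
    } else {
      cv <- cross_validate(labelled, model_arch(config, mode), cfg_train,
                           cv_plan("group_shuffle_by_subject",
                                   config$n_folds, config$seed))
      cv_results[[mode]] <- cv
      metric_rows[[length(metric_rows) + 1L]] <-
        cv$folds |> mutate(mode = mode, task = NA_character_, .before = 1)
    }
  }
  metrics <- list_rbind(map(metric_rows, function(x) {
    x |> mutate(across(-c("mode", "task"), as.numeric))
  }))
  readr::write_tsv(metrics, path_for("metrics"))
  stage_log("models", t0)

  # explain ----------------------------------------------------------------
  first_cls <- cv_results[[which(
    !vapply(cv_results, inherits, TRUE, what = "tbl_df"))[1]]]
  ranking <- NULL
  if (!is.null(first_cls) && inherits(first_cls, "eeg_cv_result")) {
    model <- first_cls$models[[1]]
    labelled <- assign_labels(features, config$label_modes[[1]])
    if (config$experiment == "workload") {
      labelled <- labelled[labelled$task == labelled$task[1], , drop = FALSE]
    }
    with_seed(derive_seed(config$seed, 99), {
      bg_idx <- sample.int(nrow(labelled), min(config$shap_background, nrow(labelled)))
      in_idx <- sample.int(nrow(labelled), min(config$shap_instances, nrow(labelled)))
    })
    att <- explain_model(model, labelled[in_idx, ], labelled[bg_idx, ],
                         n_permutations = config$shap_permutations,
                         seed = derive_seed(config$seed, 7))
    ranking <- rank_features(att)
    readr::write_tsv(att, path_for("attributions"))
    readr::write_tsv(ranking, path_for("feature_ranking"))
    readr::write_tsv(shap_beeswarm_data(att), path_for("beeswarm"))
  }
  stage_log("explain", t0)

  # stats ------------------------------------------------------------------
  stats_out <- if (config$experiment == "stress") {
    rs <- rating_statistics(study |> distinct(.data$subject_id, .data$condition,
                                              .data$rating))
    readr::write_tsv(rs$pairwise |> mutate(n = map_chr(.data$n, toString)),
                     path_for("rating_tests"))
    readr::write_tsv(rs$anova, path_for("rating_anova"))
    rs
  } else {
    NULL
  }
  stage_log("stats", t0)

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("eareeg")),
                   experiment = config$experiment,
                   n_recordings = nrow(study), n_segments = nrow(segments),
                   n_features_rows = nrow(features))
  jsonlite::write_json(c(manifest, list(config = unclass(config))),
                       path_for("manifest", "json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = features, cv = cv_results, ranking = ranking,
                 stats = stats_out, manifest = manifest, out_dir = out_dir))
}

# -- recording file I/O ----------------------------------------------------

#' Write a recording to CSV with a JSON sidecar
#'
#' The CSV carries `sample_index` and `uV` columns; the sidecar stores the
#' provenance (`subject_id`, condition/task metadata, `fs`, `seed`).
#'
#' @param rec A one-row recordings tibble (see [synthesize_recording()]).
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (nrow(rec) != 1L || !"signal" %in% names(rec)) {
    abort("`rec` must be a one-row recordings tibble.")
  }
  sig <- rec$signal[[1]]
  readr::write_csv(tibble(sample_index = seq_along(sig) - 1L, uV = sig), path)
  meta <- rec |> select(-"signal")
  meta <- as.list(meta)
  meta <- map(meta, function(v) if (is.factor(v)) as.character(v) else v)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path; the JSON sidecar must sit next to it.
#' @return A one-row recordings tibble; samples are preserved to better than
#'   1e-6 uV.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such recording: %s", path))
  side <- sidecar_path(path)
  if (!file.exists(side)) abort("recording sidecar (.json) is missing.")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) abort("malformed sidecar: missing `fs`.")
  sig <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("sample_index", "uV") %in% names(sig))) {
    abort("recording CSV must have sample_index and uV columns.")
  }
  if (!is.null(meta$n_samples) && nrow(sig) != meta$n_samples) {
    abort("sidecar/CSV mismatch: sample count differs from `n_samples`.")
  }
  out <- as_tibble(meta)
  out$signal <- list(sig$uV)
  out
}
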