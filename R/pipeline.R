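#' Default configuration for a synthetic end-to-end study
#'
#' Returns the nested configuration consumed by [run_synthetic_study()].
#' The defaults are the package's canonical synthetic study: seven morph
#' sequences of eleven levels at colinearity 0.9, six simulated observers
#' (three "intact", three "lesioned", drawn from identical psychometric
#' parameters — mirroring the absence of a group difference), a ten-layer
#' random-weight encoder read out at `fc7`, and a 32-pixel flattened-pixel
#' baseline. Every stage derives its own seed from `master_seed` via
#' [substream_seed()], so stages can be re-run independently and adding
#' observers or electrodes never perturbs other stages.
#'
#' @param master_seed integer master seed.
#' @return A `run_config` list, serializable to YAML.
#' @export
default_run_config <- function(master_seed = 1L) {
  structure(list(
    master_seed = as.integer(master_seed),
    stimuli = list(n_sequences = 7L, n_levels = 11L, image_size = 64L,
                   colinearity = 0.9, experiment_id = "exp1"),
    observers = list(
      n_per_group = 3L, n_reps = 10L,
      slope = 0.12, bias = 50, lapse = 0.02, image_effect_sd = 1
    ),
    encoder = list(type = "random-cnn", layer = "fc7", pixel_resize = 32L),
    readout = list(c_grid = 10^seq(-5, 5, length.out = 9), inner_folds = 5L,
                   n_iterations = 100L, train_fraction = 4 / 5,
                   stratify = TRUE),
    consistency = list(n_iter = 100L, level = "image", min_reps = 8L),
    oddity = list(enabled = TRUE, n_objects = 6L, n_views = 12L, dim = 16L,
                  separation = 2, noise_sd = 1, n_samples = 2L,
                  n_pseudo = 20L, n_trials = 52L)
  ), class = "run_config")
}

#' Read / write run configurations as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` (write) / a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    vvs_abort_missing_data(sprintf("no config file at %s", path))
  }
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(cfg$master_seed %||% 1L)
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

#' Run the full synthetic study
#'
#' Executes the complete pipeline on synthetic data: stimulus generation,
#' feature extraction (encoder layer + pixel baseline), simulated
#' observers, category readouts under random and sequence-holdout splits
#' for both feature sources, behavioral consistency analyses (split-half
#' reliability, between-subject consistency, model-behavior fits at morph
#' and image level, empirical percentiles, group comparison) and a small
#' feature-level oddity analysis. Every intermediate artifact is written
#' under `out_dir` (PNG stimuli, CSV features/choices/results, YAML
#' config, plain-text log with per-stage seeds) together with a
#' machine-readable `summary.json`. Re-running with the same config is
#' byte-identical in `summary.json`.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created; must be writable).
#' @return The summary list, invisibly; side effect: the run directory.
#' @export
run_synthetic_study <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) vvs_abort(sprintf("cannot create %s", out_dir))
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  ms <- config$master_seed
  summary <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      vvs_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                class = "vvsreadout_stage_error")
    })
  }

  ## stimuli
  seed_stim <- substream_seed(ms, "stimuli")
  log_line(log_path, "stage stimuli seed=", seed_stim)
  st <- stage("stimuli", with(config$stimuli, generate_morph_stimuli(
    n_sequences, n_levels, image_size, colinearity,
    seed = seed_stim, experiment_id = experiment_id
  )))
  write_stimuli(st, file.path(out_dir, "stimuli"))

  ## features
  seed_enc <- substream_seed(ms, "encoder")
  log_line(log_path, "stage features seed=", seed_enc)
  enc <- stage("features", random_cnn_encoder(seed = seed_enc))
  feat <- stage("features", extract_features(enc, st, config$encoder$layer))
  pix <- stage("features", flatten_pixels(st, resize_to = config$encoder$pixel_resize))
  dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
  write_features(feat, file.path(out_dir, "features", "encoder.csv"))
  write_features(pix, file.path(out_dir, "features", "pixels.csv"))

  ## observers
  obs_cfg <- config$observers
  subjects <- list()
  for (g in c("intact", "lesioned")) {
    for (i in seq_len(obs_cfg$n_per_group)) {
      sid <- sprintf("%s_%d", g, i)
      seed_obs <- substream_seed(ms, "observer", sid)
      log_line(log_path, "stage observer ", sid, " seed=", seed_obs)
      par <- observer_params(slope = obs_cfg$slope, bias = obs_cfg$bias,
                             lapse = obs_cfg$lapse,
                             image_effect_sd = obs_cfg$image_effect_sd,
                             seed = seed_obs)
      subjects[[sid]] <- stage("observers", simulate_observer(
        st, par, n_reps = obs_cfg$n_reps, subject_id = sid, group = g
      ))
    }
  }
  choices <- do.call(rbind, c(subjects, list(make.row.names = FALSE)))
  class(choices) <- c("choice_table", "data.frame")
  dir.create(file.path(out_dir, "behavior"), showWarnings = FALSE)
  write_choices(choices, file.path(out_dir, "behavior", "choices.csv"))

  ## readouts: encoder + pixels, random + sequence holdout
  ro_cfg <- config$readout
  readouts <- list()
  for (src in c("encoder", "pixels")) {
    fm <- if (src == "encoder") feat else pix
    cfg_r <- readout_config(
      c_grid = ro_cfg$c_grid, inner_folds = ro_cfg$inner_folds,
      n_iterations = ro_cfg$n_iterations,
      train_fraction = ro_cfg$train_fraction, stratify = ro_cfg$stratify,
      seed = substream_seed(ms, "readout", src)
    )
    log_line(log_path, "stage readout ", src, " seed=", cfg_r$seed)
    readouts[[src]] <- list(
      random = stage("readout", evaluate_random_splits(fm, st, cfg_r)),
      sequence_holdout = stage("readout", evaluate_sequence_holdout(fm, st, cfg_r))
    )
  }
  dir.create(file.path(out_dir, "readout"), showWarnings = FALSE)
  for (src in names(readouts)) {
    for (mode in names(readouts[[src]])) {
      rr <- readouts[[src]][[mode]]
      utils::write.csv(rr$iterations,
                       file.path(out_dir, "readout",
                                 sprintf("%s_%s_iterations.csv", src, mode)),
                       row.names = FALSE)
      utils::write.csv(rr$curve,
                       file.path(out_dir, "readout",
                                 sprintf("%s_%s_curve.csv", src, mode)),
                       row.names = FALSE)
    }
  }

  ## consistency
  cons_cfg <- config$consistency
  seed_cons <- substream_seed(ms, "consistency")
  log_line(log_path, "stage consistency seed=", seed_cons)
  sids <- names(subjects)
  long <- list()
  for (i in seq_along(sids)) {
    for (j in seq_along(sids)) {
      if (j < i) next
      rd <- if (i == j) {
        split_half_reliability(subjects[[i]], cons_cfg$level,
                               n_iter = cons_cfg$n_iter,
                               seed = substream_seed(seed_cons, sids[i]),
                               min_reps = cons_cfg$min_reps)
      } else {
        between_subject_consistency(subjects[[i]], subjects[[j]],
                                    cons_cfg$level, n_iter = cons_cfg$n_iter,
                                    seed = substream_seed(seed_cons, sids[i], sids[j]),
                                    min_reps = cons_cfg$min_reps)
      }
      long[[paste(sids[i], sids[j])]] <- data.frame(
        pair_i = sids[i], pair_j = sids[j],
        iteration = seq_along(rd$values), value = rd$values,
        stringsAsFactors = FALSE
      )
    }
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  dir.create(file.path(out_dir, "consistency"), showWarnings = FALSE)
  utils::write.csv(long, file.path(out_dir, "consistency", "reliability_long.csv"),
                   row.names = FALSE)
  med_tab <- stats::aggregate(value ~ pair_i + pair_j, data = long,
                              FUN = stats::median)
  utils::write.csv(med_tab, file.path(out_dir, "consistency", "reliability_medians.csv"),
                   row.names = FALSE)

  ## model-behavior fits
  model_image <- readouts$encoder$random$per_image$mean_predicted_label
  names(model_image) <- readouts$encoder$random$per_image$image_id
  model_curve <- readouts$encoder$random$curve
  fits <- list()
  percentiles <- list()
  between_ref <- long$value[long$pair_i != long$pair_j]
  for (sid in sids) {
    beh_m <- item_means(subjects[[sid]], "morph")
    mod_m <- model_curve$prop_dog[match(as.numeric(names(beh_m)),
                                        model_curve$morph_level_pct)]
    beh_i <- item_means(subjects[[sid]], "image")
    mod_i <- model_image[names(beh_i)]
    fm <- fit_model_to_behavior(mod_m, beh_m)
    fi <- fit_model_to_behavior(mod_i, beh_i)
    fits[[sid]] <- list(morph = fm, image = fi)
    percentiles[[sid]] <- empirical_percentile(fi$r_squared, between_ref)
  }

  ## group comparison on morph curves
  curves <- lapply(c("intact", "lesioned"), function(g) {
    aggregate_morph_level(choices[choices$group == g, ])
  })
  group_stat <- compare_groups(curves[[1]], curves[[2]])

  ## oddity (feature-level fixture)
  oddity_summary <- NULL
  if (isTRUE(config$oddity$enabled)) {
    oc <- config$oddity
    seed_odd <- substream_seed(ms, "oddity")
    log_line(log_path, "stage oddity seed=", seed_odd)
    sf <- synthetic_object_features(oc$n_objects, oc$n_views, oc$dim,
                                    separation = oc$separation,
                                    noise_sd = oc$noise_sd, seed = seed_odd)
    objs <- unique(sf$index$object_id)
    out <- list()
    for (i in seq_along(objs)) {
      j <- if (i == length(objs)) 1L else i + 1L
      out[[i]] <- stage("oddity", estimate_pair_performance(
        sf$index, sf$features, objs[i], objs[j],
        n_samples = oc$n_samples, n_pseudo = oc$n_pseudo,
        n_trials = oc$n_trials, seed = substream_seed(seed_odd, objs[i])
      ))
    }
    out <- do.call(rbind, out)
    pv <- aggregate_objects(out)
    utils::write.csv(out, file.path(out_dir, "oddity_outcomes.csv"),
                     row.names = FALSE)
    oddity_summary <- list(mean_performance = mean(out$outcome),
                           per_object = as.list(unclass(pv)))
  }

  stat_json <- function(s) {
    list(kind = s$kind, beta = s$beta, statistic = s$statistic,
         df = s$df, p = s$p, r_squared = s$r_squared)
  }
  summary <- list(
    config = unclass(config),
    curves = list(
      model_encoder_random = readouts$encoder$random$curve,
      model_encoder_sequence_holdout = readouts$encoder$sequence_holdout$curve,
      model_pixels_random = readouts$pixels$random$curve,
      model_pixels_sequence_holdout = readouts$pixels$sequence_holdout$curve,
      observers = lapply(subjects, function(s) aggregate_morph_level(s))
    ),
    readout_accuracy = lapply(readouts, function(r) {
      lapply(r, function(x) x$summary[c("accuracy", "accuracy_extreme_levels")])
    }),
    reliability_medians = med_tab,
    model_behavior_fits = lapply(fits, function(f) lapply(f, stat_json)),
    model_percentiles = percentiles,
    group_comparison = stat_json(group_stat),
    oddity = oddity_summary
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_line(log_path, "done")
  invisible(summary)
}

#' Run the pipeline stages on user-supplied (real) data
#'
#' Points the same analysis stages at local copies of downloaded stimuli
#' (PNG tree + `index.csv` manifest, as written by [write_stimuli()]) and
#' behavioral choice tables (CSV in the [write_choices()] schema). Nothing
#' is downloaded. With behavior only, the consistency analyses run and the
#' feature-based stages are skipped with a notice; with stimuli as well,
#' readouts and model-behavior fits are computed with the supplied (or
#' default random-weight) encoder.
#'
#' @param stimuli_dir directory with the stimulus tree, or `NULL`.
#' @param choices_csv path to the choice table CSV, or `NULL`.
#' @param encoder an `image_encoder` (defaults to [random_cnn_encoder()]).
#' @param layer encoder layer for the readout.
#' @param out_dir output directory.
#' @param n_iterations random-split iterations.
#' @param seed integer seed.
#' @return A report list; errors with class `vvsreadout_missing_data` when
#'   no usable input is supplied.
#' @export
replicate_study <- function(stimuli_dir = NULL, choices_csv = NULL,
                            encoder = NULL, layer = "fc7",
                            out_dir = NULL, n_iterations = 100L, seed = 1L) {
  have_stim <- !is.null(stimuli_dir) && file.exists(file.path(stimuli_dir, "index.csv"))
  have_beh <- !is.null(choices_csv) && file.exists(choices_csv)
  if (!have_stim && !have_beh) {
    vvs_abort_missing_data(paste(
      "no usable inputs. Expected layout:",
      "stimuli_dir/: index.csv plus <experiment>/<sequence>/<level>.png,",
      "choices_csv: CSV with header",
      paste(choice_table_columns, collapse = ","),
      sep = "\n  "
    ))
  }
  report <- list(inputs = list(stimuli = have_stim, behavior = have_beh),
                 skipped = character())

  choices <- NULL
  if (have_beh) {
    choices <- read_choices(choices_csv)
    sids <- unique(choices$subject_id)
    cons <- list()
    for (i in seq_along(sids)) {
      for (j in i:length(sids)) {
        ci <- choices[choices$subject_id == sids[i], ]
        cj <- choices[choices$subject_id == sids[j], ]
        rd <- tryCatch({
          if (i == j) {
            split_half_reliability(ci, "image", seed = substream_seed(seed, sids[i]))
          } else {
            between_subject_consistency(ci, cj, "image",
                                        seed = substream_seed(seed, sids[i], sids[j]))
          }
        }, vvsreadout_invalid_argument = function(e) NULL)
        if (!is.null(rd)) cons[[paste(sids[i], sids[j])]] <- rd$median
      }
    }
    report$consistency_medians <- cons
  } else {
    report$skipped <- c(report$skipped, "consistency (no behavior supplied)")
  }

  if (have_stim) {
    st <- read_stimuli(stimuli_dir)
    if (is.null(encoder)) encoder <- random_cnn_encoder(seed = substream_seed(seed, "enc"))
    fm <- extract_features(encoder, st, layer)
    cfg <- readout_config(n_iterations = n_iterations,
                          seed = substream_seed(seed, "readout"))
    rr <- evaluate_random_splits(fm, st, cfg)
    report$readout <- rr$summary
    report$model_curve <- rr$curve
    if (have_beh) {
      curves <- aggregate_morph_level(choices)
      shared <- intersect(curves$morph_level_pct, rr$curve$morph_level_pct)
      report$model_behavior_morph <- fit_model_to_behavior(
        rr$curve$prop_dog[match(shared, rr$curve$morph_level_pct)],
        curves$prop_dog[match(shared, curves$morph_level_pct)]
      )
    }
  } else {
    report$skipped <- c(report$skipped, "feature analyses (no stimuli supplied)")
    message("stimuli not supplied; feature-based analyses skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(inputs = report$inputs, skipped = report$skipped,
           consistency_medians = report$consistency_medians,
           readout = report$readout),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 10
    )
  }
  report
}
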