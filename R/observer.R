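#' Observer parameters for the synthetic psychophysics model
#'
#' A simulated observer responds "dog" (1) with probability
#' `lapse/2 + (1 - lapse) * plogis(slope * (morph_level - bias) + image_offset)`
#' where `image_offset ~ Normal(0, image_effect_sd)` is drawn once per image
#' per observer (on the logit scale) and shared across repetitions. The
#' image offsets are what make image-level choice behavior reliably
#' idiosyncratic within an observer; because offsets are resampled per
#' observer, between-subject image-level consistency arises only through the
#' shared stimulus.
#'
#' @param slope psychometric steepness per morph percentage point (> 0
#'   allowed to be 0 for a guessing observer).
#' @param bias point of subjective equality, in morph percent.
#' @param lapse lapse rate in `[0, 0.5]`; responses are a coin flip on a
#'   fraction `lapse` of trials.
#' @param image_effect_sd SD of per-image logit offsets (>= 0).
#' @param seed integer seed for offset and response draws.
#' @return An `observer_params` list.
#' @export
observer_params <- function(slope = 0.12, bias = 50, lapse = 0.02,
                            image_effect_sd = 1, seed = 1L) {
  if (!is_scalar_number(lapse) || lapse < 0 || lapse > 0.5) {
    vvs_abort("`lapse` must lie in [0, 0.5]")
  }
  if (!is_scalar_number(slope) || slope < 0) vvs_abort("`slope` must be >= 0")
  if (!is_scalar_number(image_effect_sd) || image_effect_sd < 0) {
    vvs_abort("`image_effect_sd` must be >= 0")
  }
  structure(
    list(slope = slope, bias = bias, lapse = lapse,
         image_effect_sd = image_effect_sd, seed = as.integer(seed)),
    class = "observer_params"
  )
}

#' Simulate binary choice behavior on morph stimuli
#'
#' Produces a trial-level choice table for one observer: independent
#' Bernoulli responses across `n_reps` repetitions of every image, with
#' choice probabilities given by the logistic-with-lapse model documented in
#' [observer_params()]. Deterministic given the params' seed.
#'
#' @param stimuli a morph-dialect `stimulus_set`.
#' @param params an `observer_params` object.
#' @param n_reps repetitions per image (>= 1).
#' @param subject_id subject label stored in the table.
#' @param group `"intact"` or `"lesioned"`.
#' @return A `choice_table` data.frame with columns `subject_id`, `group`,
#'   `experiment_id`, `sequence_id`, `morph_level_pct`, `image_id`,
#'   `repetition`, `response`, `correct`. The convention is dog = 1,
#'   cat = 0; `correct` is 1 iff the response equals the image's category
#'   label.
#' @export
simulate_observer <- function(stimuli, params, n_reps = 10L,
                              subject_id = "sim1",
                              group = c("intact", "lesioned")) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            identical(stimuli$dialect, "morph"),
            inherits(params, "observer_params"))
  group <- match.arg(group)
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    vvs_abort("`n_reps` must be >= 1")
  }
  n_reps <- as.integer(n_reps)
  idx <- stimuli$index

  offsets <- vapply(idx$image_id, function(iid) {
    with_seed(substream_seed(params$seed, "offset", subject_id, iid),
              stats::rnorm(1, 0, params$image_effect_sd))
  }, numeric(1))
  logit <- params$slope * (idx$morph_level_pct - params$bias) + offsets
  p_dog <- params$lapse / 2 + (1 - params$lapse) * stats::plogis(logit)

  resp <- vapply(seq_len(nrow(idx)), function(i) {
    with_seed(substream_seed(params$seed, "resp", subject_id, idx$image_id[i]),
              stats::rbinom(n_reps, 1, p_dog[i]))
  }, integer(n_reps))
  resp <- matrix(resp, nrow = n_reps)

  out <- data.frame(
    subject_id = subject_id,
    group = group,
    experiment_id = rep(idx$experiment_id, each = n_reps),
    sequence_id = rep(idx$sequence_id, each = n_reps),
    morph_level_pct = rep(idx$morph_level_pct, each = n_reps),
    image_id = rep(idx$image_id, each = n_reps),
    repetition = rep(seq_len(n_reps), times = nrow(idx)),
    response = as.integer(resp),
    stringsAsFactors = FALSE
  )
  out$correct <- as.integer(out$response == rep(idx$label, each = n_reps))
  class(out) <- c("choice_table", "data.frame")
  out
}

choice_table_columns <- c(
  "subject_id", "group", "experiment_id", "sequence_id", "morph_level_pct",
  "image_id", "repetition", "response", "correct"
)

#' Validate a choice table's invariants
#'
#' Responses must be 0/1; repetitions per (subject, image) must be
#' consecutive integers starting at 1. If `stimuli` is supplied, `correct`
#' is checked against the category rule.
#'
#' @param x a `choice_table` (or plain data.frame with the same columns).
#' @param stimuli optional morph `stimulus_set` for label cross-checks.
#' @return `x`, invisibly.
#' @export
validate_choice_table <- function(x, stimuli = NULL) {
  miss <- setdiff(choice_table_columns, names(x))
  if (length(miss)) vvs_abort(paste("choice table missing columns:",
                                    paste(miss, collapse = ", ")))
  if (!all(x$response %in% c(0L, 1L))) vvs_abort("responses must be 0/1")
  reps_ok <- tapply(x$repetition, paste(x$subject_id, x$image_id),
                    function(r) identical(sort(r), seq_along(r)))
  if (!all(unlist(reps_ok))) {
    vvs_abort("repetitions per (subject, image) must be consecutive from 1")
  }
  if (!is.null(stimuli)) {
    lab <- category_labels(stimuli, x$image_id)
    if (!all(x$correct == as.integer(x$response == lab))) {
      vvs_abort("`correct` disagrees with the category rule")
    }
  }
  invisible(x)
}

#' Write / read choice tables as CSV
#'
#' The CSV header is exactly
#' `subject_id,group,experiment_id,sequence_id,morph_level_pct,image_id,repetition,response,correct`.
#'
#' @param x a `choice_table` (several observers may be `rbind`-ed).
#' @param path output CSV path.
#' @return `path` (write) / a `choice_table` (read), invisibly for write.
#' @export
write_choices <- function(x, path) {
  utils::write.csv(x[, choice_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  if (!file.exists(path)) {
    vvs_abort_missing_data(sprintf("no choice table at %s", path))
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_choice_table(x)
  class(x) <- c("choice_table", "data.frame")
  x
}
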