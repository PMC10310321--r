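# split-half reliability / between-subject consistency / model-behavior fits

# Organize one subject+experiment's trials as item x trial matrix.
# level = "image": items are images; level = "morph": items are morph levels
# (pooling all trials of all images at that level).
item_trials <- function(choices, level = c("image", "morph")) {
  level <- match.arg(level)
  key <- if (level == "image") choices$image_id else choices$morph_level_pct
  split(choices$response, key)
}

check_item_trials <- function(trials, level, min_reps = 2L) {
  if (length(trials) < 3) vvs_abort("need at least 3 items for split-half fits")
  counts <- vapply(trials, length, integer(1))
  bad <- counts < min_reps
  if (any(bad)) {
    vvs_abort(sprintf(
      "insufficient repetitions for %s-level analysis: item(s) %s have < %d trials",
      level, paste(utils::head(names(trials)[bad], 5), collapse = ", "), min_reps
    ))
  }
  invisible(counts)
}

# One random half-split of every item's trials: returns per-item means of
# the two halves. Odd counts assign the extra trial to a random half.
split_half_means <- function(trials) {
  m <- vapply(trials, function(tr) {
    n <- length(tr)
    half <- n %/% 2 + (n %% 2) * stats::rbinom(1, 1, 0.5)
    idx <- sample.int(n, half)
    c(mean(tr[idx]), mean(tr[-idx]))
  }, numeric(2))
  list(v1 = m[1, ], v2 = m[2, ])
}

#' Split-half reliability of one subject's choice behavior
#'
#' Over `n_iter` iterations, each item's trials (items are images or morph
#' levels) are split into two random halves; the per-item half-means form
#' two vectors whose squared Pearson correlation is the iteration's fit
#' value. Image-level analyses refuse data with fewer than `min_reps`
#' repetitions per image (default 8), mirroring the exclusion of
#' experiments with insufficient repetitions.
#'
#' @param choices a `choice_table` restricted to one subject and
#'   experiment.
#' @param level `"image"` or `"morph"`.
#' @param n_iter number of random split halves (default 100).
#' @param seed integer seed.
#' @param min_reps minimum trials per item for the image-level analysis.
#' @return A `reliability_distribution`: list with `values` (length
#'   `n_iter`), `level`, `pair` (subject with itself), `median`.
#' @export
split_half_reliability <- function(choices, level = c("image", "morph"),
                                   n_iter = 100L, seed = 1L,
                                   min_reps = if (match.arg(level) == "image") 8L else 2L) {
  level <- match.arg(level)
  if (length(unique(choices$subject_id)) != 1) {
    vvs_abort("restrict `choices` to a single subject")
  }
  trials <- item_trials(choices, level)
  check_item_trials(trials, level, min_reps = max(2L, min_reps))
  values <- with_seed(substream_seed(seed, "split-half"), {
    vapply(seq_len(n_iter), function(it) {
      h <- split_half_means(trials)
      r <- safe_cor(h$v1, h$v2)
      if (is.na(r)) NA_real_ else r^2
    }, numeric(1))
  })
  new_reliability_distribution(values, level,
                               pair = rep(choices$subject_id[1], 2))
}

#' Between-subject consistency of choice behavior
#'
#' Same protocol as [split_half_reliability()], but each iteration draws a
#' random half from *each* subject and correlates subject i's half-mean
#' vector with subject j's (squared Pearson). Each vector is built from
#' half of that subject's own trials, so the within- and between-subject
#' measures are equally powered and the result is a distribution over
#' splits rather than a single point estimate.
#'
#' @param choices_i,choices_j `choice_table`s for the two subjects; item
#'   sets must overlap.
#' @param level `"image"` or `"morph"`.
#' @param n_iter,seed,min_reps as in [split_half_reliability()].
#' @return A `reliability_distribution` with `pair = c(subject_i,
#'   subject_j)`.
#' @export
between_subject_consistency <- function(choices_i, choices_j,
                                        level = c("image", "morph"),
                                        n_iter = 100L, seed = 1L,
                                        min_reps = if (match.arg(level) == "image") 8L else 2L) {
  level <- match.arg(level)
  ti <- item_trials(choices_i, level)
  tj <- item_trials(choices_j, level)
  shared <- intersect(names(ti), names(tj))
  if (!length(shared)) vvs_abort("subjects share no items")
  ti <- ti[shared]
  tj <- tj[shared]
  check_item_trials(ti, level, min_reps = max(2L, min_reps))
  check_item_trials(tj, level, min_reps = max(2L, min_reps))
  # both subjects' splits are drawn from one shared per-iteration seed, so
  # when the two choice tables are identical the two halves are exactly
  # complementary and the between-subject protocol reduces to the
  # within-subject one; for distinct subjects the coupling is inert
  values <- vapply(seq_len(n_iter), function(it) {
    v1 <- with_seed(substream_seed(seed, "between", it), split_half_means(ti))$v1
    v2 <- with_seed(substream_seed(seed, "between", it), split_half_means(tj))$v2
    r <- safe_cor(v1, v2)
    if (is.na(r)) NA_real_ else r^2
  }, numeric(1))
  new_reliability_distribution(
    values, level,
    pair = c(choices_i$subject_id[1], choices_j$subject_id[1])
  )
}

new_reliability_distribution <- function(values, level, pair) {
  structure(
    list(values = values, level = level, pair = pair,
         median = stats::median(values, na.rm = TRUE)),
    class = "reliability_distribution"
  )
}

#' @export
print.reliability_distribution <- function(x, ...) {
  cat(sprintf("<reliability_distribution [%s-level]> %s vs %s: median R2 = %.3f (%d iterations)\n",
              x$level, x$pair[1], x$pair[2], x$median, length(x$values)))
  invisible(x)
}

#' Regress behavior on model predictions
#'
#' OLS of per-item behavioral values on per-item model values with an
#' intercept; reports the slope, its t statistic on `n - 2` degrees of
#' freedom, and the coefficient of determination.
#'
#' @param model_values per-item model means (e.g. proportion predicted
#'   "dog" per morph level or image).
#' @param behavior_values aligned per-item behavioral means.
#' @return A `vvs_stat` with `kind = "ols_slope_t"` and `r_squared`.
#' @export
fit_model_to_behavior <- function(model_values, behavior_values) {
  if (length(model_values) != length(behavior_values) ||
      length(model_values) < 3) {
    vvs_abort("need aligned per-item vectors with n >= 3")
  }
  ols_slope_stat(as.numeric(model_values), as.numeric(behavior_values),
                 kind = "ols_slope_t")
}

#' Empirical percentile of a model fit within a reference distribution
#'
#' Locates a model-to-behavior fit within a between-subject consistency
#' distribution: the fraction of reference values at or below the model's
#' fit. When several model iterations are supplied, the median percentile
#' over iterations is reported.
#'
#' @param model_fit numeric scalar or vector of fit values.
#' @param reference a `reliability_distribution` or numeric vector.
#' @return A percentile in `[0, 1]`.
#' @export
empirical_percentile <- function(model_fit, reference) {
  ref <- if (inherits(reference, "reliability_distribution")) {
    reference$values
  } else {
    as.numeric(reference)
  }
  ref <- ref[!is.na(ref)]
  if (!length(ref)) vvs_abort("empty reference distribution")
  ps <- vapply(model_fit, function(m) mean(ref <= m), numeric(1))
  stats::median(ps)
}

#' Compare two groups' aggregate performance curves
#'
#' Tests for a group difference in aggregate choice behavior: the two
#' groups' per-(experiment, morph level) proportions are aligned, stacked,
#' and regressed on a group indicator (OLS with intercept). `beta` is the
#' mean group-b minus group-a difference; the F test on
#' `(1, 2n - 2)` degrees of freedom (n aligned points per group) asks
#' whether group membership explains any variance. Equivalent groups give
#' `beta` near 0, `R2` near 0 and a large p, the signature of "no group
#' difference".
#'
#' @param curve_a,curve_b data.frames with `morph_level_pct`, `prop_dog`,
#'   and optionally `experiment_id` columns (as produced by
#'   [aggregate_morph_level()], possibly row-bound over experiments).
#' @return A `vvs_stat` with `kind = "ols_slope_F"`.
#' @export
compare_groups <- function(curve_a, curve_b) {
  key <- function(d) {
    if ("experiment_id" %in% names(d)) {
      paste(d$experiment_id, d$morph_level_pct)
    } else {
      as.character(d$morph_level_pct)
    }
  }
  ka <- key(curve_a)
  kb <- key(curve_b)
  if (!setequal(ka, kb) || nrow(curve_a) != nrow(curve_b)) {
    vvs_abort("group curves must cover identical (experiment, morph level) points")
  }
  b <- curve_b$prop_dog[match(ka, kb)]
  y <- c(curve_a$prop_dog, b)
  group <- rep(c(0, 1), each = length(ka))
  fit <- stats::lm(y ~ group)
  sm <- muffle_warning(summary(fit), "essentially perfect fit")
  tval <- sm$coefficients["group", "t value"]
  vvs_stat("ols_slope_F", beta = unname(stats::coef(fit)["group"]),
           statistic = tval^2, df = c(1, fit$df.residual),
           p = sm$coefficients["group", "Pr(>|t|)"],
           r_squared = sm$r.squared)
}

#' Per-item mean choice behavior
#'
#' Helper collapsing a choice table to per-item means for model-behavior
#' fits: proportion "dog" per image or per morph level.
#'
#' @param choices a `choice_table`.
#' @param level `"image"` or `"morph"`.
#' @return Named numeric vector of per-item means.
#' @export
item_means <- function(choices, level = c("image", "morph")) {
  tr <- item_trials(choices, match.arg(level))
  vapply(tr, mean, numeric(1))
}
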