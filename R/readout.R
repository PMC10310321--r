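#' Configuration for the linear category readout
#'
#' @param c_grid inverse-regularization strengths searched by the inner CV
#'   (sklearn-style `C`); must be positive and sorted ascending. The default
#'   spans nine log-spaced values from 1e-5 to 1e5.
#' @param inner_folds inner cross-validation folds for choosing `C`.
#' @param n_iterations number of random train/test splits.
#' @param train_fraction fraction of images used for training per split.
#' @param split_mode `"random"` (stratified by morph level) or
#'   `"sequence_holdout"` (leave one morph sequence out).
#' @param stratify stratify random splits by morph level.
#' @param seed integer seed.
#' @return A `readout_config` list.
#' @export
readout_config <- function(c_grid = 10^seq(-5, 5, length.out = 9),
                           inner_folds = 5L, n_iterations = 100L,
                           train_fraction = 4 / 5,
                           split_mode = c("random", "sequence_holdout"),
                           stratify = TRUE, seed = 1L) {
  if (!length(c_grid) || any(c_grid <= 0) || is.unsorted(c_grid)) {
    vvs_abort("`c_grid` must be nonempty, strictly positive and sorted")
  }
  if (!is_scalar_number(train_fraction) ||
      train_fraction <= 0 || train_fraction >= 1) {
    vvs_abort("`train_fraction` must lie in (0, 1)")
  }
  structure(
    list(c_grid = c_grid, inner_folds = as.integer(inner_folds),
         n_iterations = as.integer(n_iterations),
         train_fraction = train_fraction,
         split_mode = match.arg(split_mode), stratify = isTRUE(stratify),
         seed = as.integer(seed)),
    class = "readout_config"
  )
}

#' Train an L2-regularized logistic category readout
#'
#' Fits a binomial logistic regression with ridge penalty on the features;
#' the inverse penalty `C` is chosen from `config$c_grid` by stratified
#' inner cross-validation (misclassification loss) on the training data
#' only, then the readout is refit on all training rows at the chosen `C`.
#' `C` maps onto the glmnet penalty as `lambda = 1 / (n_train * C)`.
#'
#' @param x numeric matrix of training features (rows = images).
#' @param y 0/1 labels (dog = 1, cat = 0); both classes must be present.
#' @param config a `readout_config`.
#' @param seed optional seed for the inner folds (defaults to
#'   `config$seed`).
#' @return A `linear_readout`: weights, intercept, `chosen_c`.
#' @export
train_readout <- function(x, y, config = readout_config(), seed = config$seed) {
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (!all(classes %in% c(0L, 1L))) vvs_abort("labels must be 0/1")
  for (cl in c(0L, 1L)) {
    if (!cl %in% classes) {
      vvs_abort(sprintf("training set contains no class-%d ('%s') examples",
                        cl, if (cl == 1L) "dog" else "cat"))
    }
  }
  n <- nrow(x)
  if (all(apply(x, 2, stats::sd) == 0)) {
    # degenerate featureless design: intercept-only readout at the base rate
    return(structure(list(weights = rep(0, ncol(x)),
                          intercept = stats::qlogis(mean(y)),
                          chosen_c = config$c_grid[1]),
                     class = "linear_readout"))
  }
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, 0)  # glmnet requires >= 2 columns
  lam <- 1 / (n * config$c_grid)      # decreasing in C; glmnet wants decreasing lambda
  lam <- sort(lam, decreasing = TRUE)

  chosen_c <- config$c_grid[1]
  if (length(config$c_grid) > 1L) {
    foldid <- with_seed(substream_seed(seed, "inner-cv"), {
      f <- integer(n)
      for (cl in classes) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(config$inner_folds), length(idx)))
      }
      f
    })
    cv <- muffle_warning(
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lam, foldid = foldid,
                        type.measure = "class", standardize = FALSE),
      "fewer than 8|grouped=FALSE enforced"
    )
    chosen_c <- 1 / (n * cv$lambda.min)
  }
  lam_star <- 1 / (n * chosen_c)
  fit <- muffle_warning(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = lam, standardize = FALSE),
    "fewer than 8"
  )
  beta <- as.vector(stats::coef(fit, s = lam_star, exact = FALSE))
  w <- beta[-1]
  if (padded) w <- w[-length(w)]
  structure(list(weights = w, intercept = beta[1], chosen_c = chosen_c),
            class = "linear_readout")
}

#' Predict from a fitted linear readout
#'
#' `predicted_label` is 1 iff the predicted probability is `>= 0.5` (a tie
#' at exactly 0.5 goes to "dog").
#'
#' @param object a `linear_readout`.
#' @param newx feature matrix.
#' @param type `"prob"` or `"label"`.
#' @param ... unused.
#' @return Numeric vector of probabilities or integer 0/1 labels.
#' @export
predict.linear_readout <- function(object, newx, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- stats::plogis(as.vector(as.matrix(newx) %*% object$weights) + object$intercept)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Evaluate the readout under random train/test splits
#'
#' Repeats `config$n_iterations` times: draw a fresh seeded
#' `train_fraction` / `1 - train_fraction` split (stratified by morph level
#' when possible), train the readout on the training images, and record
#' predicted probabilities and labels for the held-out images only. If any
#' image is never held out after the configured iterations, further splits
#' are drawn (with a message) until every image has at least one held-out
#' prediction.
#'
#' @param features a `feature_matrix` covering the stimulus set.
#' @param stimuli a morph `stimulus_set` (supplies labels, levels,
#'   sequences).
#' @param config a `readout_config` with `split_mode = "random"`.
#' @return A `readout_result`; see [readout_result_summary()].
#' @export
evaluate_random_splits <- function(features, stimuli, config = readout_config()) {
  dat <- readout_data(features, stimuli)
  if (nrow(dat$x) < 10) vvs_abort("need at least 10 images for random splits")
  n <- nrow(dat$x)

  strat <- config$stratify
  if (strat && any(table(dat$level) < 2)) {
    message("stratification impossible (a morph level has < 2 images); falling back to unstratified splits")
    strat <- FALSE
  }

  draw_split <- function(it) {
    with_seed(substream_seed(config$seed, "split", it), {
      # randomized rounding keeps the expected train fraction exact even
      # when a stratum size is not divisible by it
      n_train <- function(k) {
        lo <- floor(k * config$train_fraction)
        min(max(lo + stats::rbinom(1, 1, k * config$train_fraction - lo), 1L),
            k - 1L)
      }
      if (strat) {
        tr <- unlist(lapply(split(seq_len(n), dat$level), function(idx) {
          sample(idx, n_train(length(idx)))
        }), use.names = FALSE)
      } else {
        tr <- sample(n, n_train(n))
      }
      sort(tr)
    })
  }

  rows <- list()
  held <- logical(n)
  it <- 0L
  total <- config$n_iterations
  while (it < total) {
    it <- it + 1L
    tr <- draw_split(it)
    if (length(unique(dat$y[tr])) < 2) next  # pathological split; redrawn via extra iterations
    te <- setdiff(seq_len(n), tr)
    model <- train_readout(dat$x[tr, , drop = FALSE], dat$y[tr], config,
                           seed = substream_seed(config$seed, "inner", it))
    p <- predict(model, dat$x[te, , drop = FALSE], type = "prob")
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = it, image_id = dat$ids[te], predicted_prob = p,
      predicted_label = as.integer(p >= 0.5), stringsAsFactors = FALSE
    )
    held[te] <- TRUE
    if (it == total && !all(held)) {
      message(sprintf("%d image(s) never held out after %d iterations; drawing extra splits",
                      sum(!held), total))
      total <- total + 1L
      if (total > config$n_iterations + 50L) {
        vvs_abort("could not cover every image within 50 extra splits")
      }
    }
  }
  build_readout_result(do.call(rbind, rows), dat, mode = "random",
                       n_iterations = config$n_iterations)
}

#' Evaluate the readout under the morph-sequence holdout
#'
#' Leave-one-sequence-out rotation: for each morph sequence, the readout is
#' trained on all images of the other sequences and tested on every image
#' of the held-out sequence, so the test sequence shares no background,
#' position, or texture phase with the training data. Aggregates pool all
#' held-out predictions.
#'
#' @param features a `feature_matrix`.
#' @param stimuli a morph `stimulus_set` with at least 2 sequences.
#' @param config a `readout_config` (split_mode `"sequence_holdout"`).
#' @return A `readout_result`.
#' @export
evaluate_sequence_holdout <- function(features, stimuli,
                                      config = readout_config(split_mode = "sequence_holdout")) {
  dat <- readout_data(features, stimuli)
  seqs <- unique(dat$sequence)
  if (length(seqs) < 2) vvs_abort("sequence holdout needs >= 2 morph sequences")
  rows <- list()
  for (k in seq_along(seqs)) {
    te <- which(dat$sequence == seqs[k])
    tr <- which(dat$sequence != seqs[k])
    if (length(unique(dat$y[tr])) < 2) {
      vvs_abort(sprintf("training set lacks a class when holding out sequence %s", seqs[k]))
    }
    model <- train_readout(dat$x[tr, , drop = FALSE], dat$y[tr], config,
                           seed = substream_seed(config$seed, "inner-seq", k))
    p <- predict(model, dat$x[te, , drop = FALSE], type = "prob")
    rows[[k]] <- data.frame(
      iteration = k, image_id = dat$ids[te], predicted_prob = p,
      predicted_label = as.integer(p >= 0.5), stringsAsFactors = FALSE
    )
  }
  build_readout_result(do.call(rbind, rows), dat, mode = "sequence_holdout",
                       n_iterations = length(seqs))
}

readout_data <- function(features, stimuli) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(stimuli, "stimulus_set"),
            identical(stimuli$dialect, "morph"))
  ids <- stimuli$index$image_id
  list(x = feature_rows(features, ids), ids = ids,
       y = stimuli$index$label,
       level = stimuli$index$morph_level_pct,
       sequence = stimuli$index$sequence_id)
}

build_readout_result <- function(iters, dat, mode, n_iterations) {
  iters$label <- dat$y[match(iters$image_id, dat$ids)]
  iters$morph_level_pct <- dat$level[match(iters$image_id, dat$ids)]
  iters$correct <- as.integer(iters$predicted_label == iters$label)

  per_image <- stats::aggregate(
    cbind(mean_predicted_label = predicted_label,
          mean_predicted_prob = predicted_prob,
          accuracy = correct) ~ image_id, data = iters, FUN = mean
  )
  per_image <- per_image[match(dat$ids, per_image$image_id), ]
  rownames(per_image) <- NULL

  curve_by_iter <- stats::aggregate(
    predicted_label ~ iteration + morph_level_pct, data = iters, FUN = mean
  )
  curve <- stats::aggregate(
    cbind(prop_dog = predicted_label) ~ morph_level_pct,
    data = curve_by_iter, FUN = mean
  )
  curve$sd <- stats::aggregate(
    predicted_label ~ morph_level_pct, data = curve_by_iter, FUN = stats::sd
  )$predicted_label

  lv <- range(dat$level)
  extreme <- iters$morph_level_pct %in% lv
  summary <- list(
    accuracy = mean(iters$correct),
    accuracy_extreme_levels = mean(iters$correct[extreme]),
    per_level_accuracy = stats::aggregate(correct ~ morph_level_pct,
                                          data = iters, FUN = mean)
  )
  structure(
    list(iterations = iters, per_image = per_image, curve = curve,
         summary = summary, mode = mode, n_iterations = n_iterations),
    class = "readout_result"
  )
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result [%s]> %d iterations, held-out accuracy %.3f (extreme levels %.3f)\n",
              x$mode, x$n_iterations, x$summary$accuracy,
              x$summary$accuracy_extreme_levels))
  invisible(x)
}

#' Held-out accuracy summaries of a readout result
#' @param x a `readout_result`.
#' @return List with `accuracy`, `accuracy_extreme_levels`,
#'   `per_level_accuracy`.
#' @export
readout_result_summary <- function(x) {
  stopifnot(inherits(x, "readout_result"))
  x$summary
}

#' Aggregate binary outcomes into a morph-level curve
#'
#' Computes, for each morph level, the pooled proportion of "dog" outcomes
#' (responses for a choice table, predicted labels for readout iterations)
#' plus the SD of per-unit proportions across the grouping unit (subjects
#' for behavior, iterations for model predictions). Missing levels are
#' absent, never imputed.
#'
#' @param x a `choice_table`, `readout_result`, or data.frame containing a
#'   `morph_level_pct` column plus a `response` or `predicted_label`
#'   column.
#' @return Data.frame with `morph_level_pct`, `prop_dog`, `sd`, `n`.
#' @export
aggregate_morph_level <- function(x) {
  if (inherits(x, "readout_result")) x <- x$iterations
  if (!nrow(x)) vvs_abort("empty input: nothing to aggregate")
  outcome <- if ("response" %in% names(x)) "response" else "predicted_label"
  unit <- if ("subject_id" %in% names(x)) "subject_id" else "iteration"
  if (!"morph_level_pct" %in% names(x)) {
    vvs_abort("every referenced image needs a morph level")
  }
  lev <- sort(unique(x$morph_level_pct))
  prop <- vapply(lev, function(l) mean(x[[outcome]][x$morph_level_pct == l]),
                 numeric(1))
  sdv <- vapply(lev, function(l) {
    sub <- x[x$morph_level_pct == l, ]
    if (unit %in% names(sub) && length(unique(sub[[unit]])) > 1) {
      stats::sd(tapply(sub[[outcome]], sub[[unit]], mean))
    } else NA_real_
  }, numeric(1))
  nn <- vapply(lev, function(l) sum(x$morph_level_pct == l), numeric(1))
  data.frame(morph_level_pct = lev, prop_dog = prop, sd = sdv, n = nn)
}
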