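#' Construct an oddity trial
#'
#' A trial is a triple of image ids in slot order, two views of a "pair"
#' object plus one view of a different "oddity" object.
#'
#' @param pair_images character(2), image ids of the two same-object views.
#' @param oddity_image image id of the odd one out.
#' @param pair_object,oddity_object object ids.
#' @param oddity_slot slot (1-3) of the oddity within the triple.
#' @return An `oddity_trial`.
#' @export
oddity_trial <- function(pair_images, oddity_image, pair_object,
                         oddity_object, oddity_slot = 3L) {
  if (identical(pair_object, oddity_object)) {
    vvs_abort("oddity object must differ from the pair object")
  }
  slots <- character(3)
  slots[oddity_slot] <- oddity_image
  slots[setdiff(1:3, oddity_slot)] <- pair_images
  structure(list(slots = slots, oddity_slot = as.integer(oddity_slot),
                 pair_object = pair_object, oddity_object = oddity_object),
            class = "oddity_trial")
}

#' Build pseudo oddity experiments for a sample trial
#'
#' Generates `n_trials` three-image odd-one-out trials drawn from the pool's
#' views of the sample trial's two objects, excluding the three images
#' present in the sample itself. Every pseudo trial preserves the sample's
#' object roles — two views of the sample's pair object plus one view of
#' the sample's oddity object — while viewpoints, backgrounds, and the
#' oddity's slot within the triple are randomized; views within a trial are
#' sampled without replacement. Keeping the roles fixed is what makes the
#' odd slot linearly decodable: a linear slot score can only implement
#' "slot k holds object j", not the role-symmetric relation "slot k differs
#' from the others", whose discriminant flips sign between role
#' assignments.
#'
#' @param sample an `oddity_trial` (the held-out trial).
#' @param pool an oddity-dialect `stimulus_set` (or its index data.frame).
#' @param n_trials number of training trials (default 52).
#' @param seed integer seed.
#' @return List of `oddity_trial` objects, length `n_trials`.
#' @export
build_pseudo_experiments <- function(sample, pool, n_trials = 52L, seed = 1L) {
  stopifnot(inherits(sample, "oddity_trial"))
  index <- if (inherits(pool, "stimulus_set")) pool$index else pool
  objs <- c(sample$pair_object, sample$oddity_object)
  avail <- lapply(objs, function(o) {
    setdiff(index$image_id[index$object_id == o], sample$slots)
  })
  names(avail) <- objs
  short <- vapply(avail, length, integer(1)) < 4L
  if (any(short)) {
    vvs_abort(sprintf(
      "insufficient views for %s: need >= 4 views per object beyond the sample's three images",
      paste(objs[short], collapse = ", ")
    ))
  }
  with_seed(substream_seed(seed, "pseudo", sample$slots[1], sample$slots[2],
                           sample$slots[3]), {
    lapply(seq_len(n_trials), function(k) {
      pair_views <- sample(avail[[sample$pair_object]], 2)
      odd_view <- sample(avail[[sample$oddity_object]], 1)
      oddity_trial(pair_views, odd_view, sample$pair_object,
                   sample$oddity_object, oddity_slot = sample.int(3, 1))
    })
  })
}

# Encode trials for the slot classifier: each trial is the concatenation of
# its three slot feature vectors; the target is the oddity slot.
encode_trials <- function(trials, features) {
  ids <- unique(unlist(lapply(trials, `[[`, "slots")))
  fm <- feature_rows(features, ids)
  X <- t(vapply(trials, function(tr) {
    as.vector(t(fm[match(tr$slots, ids), , drop = FALSE]))
  }, numeric(3 * ncol(fm))))
  y <- vapply(trials, `[[`, integer(1), "oddity_slot")
  list(x = X, y = y)
}

#' Estimate a trial's outcome via leave-one-out pseudo experiments
#'
#' For each of `n_pseudo` draws, builds a fresh set of `n_trials` pseudo
#' oddity experiments (excluding the sample's images), trains an
#' L2-regularized multinomial linear classifier over the three slots (each
#' trial encoded as its three concatenated slot-feature blocks; fixed
#' inverse penalty `C`), predicts the sample trial's oddity slot, and
#' binarizes the prediction into correct (1) / incorrect (0). Returns the
#' mean outcome over draws.
#'
#' The same entry point serves any feature source — encoder layers,
#' flattened pixels, or simulated population responses — so substituting
#' the representation changes only numbers, never code paths.
#'
#' @param sample an `oddity_trial`.
#' @param features a `feature_matrix` covering all needed image ids.
#' @param pool oddity `stimulus_set` (or index) supplying candidate views.
#' @param n_pseudo number of pseudo-experiment draws (default 100).
#' @param n_trials trials per pseudo experiment (default 52).
#' @param C inverse L2 penalty of the slot classifier (default 1).
#' @param seed integer seed.
#' @return Mean binarized outcome in `[0, 1]`.
#' @export
estimate_trial_outcome <- function(sample, features, pool, n_pseudo = 100L,
                                   n_trials = 52L, C = 1, seed = 1L) {
  stopifnot(inherits(sample, "oddity_trial"))
  x_sample <- encode_trials(list(sample), features)$x
  outcomes <- vapply(seq_len(n_pseudo), function(ps) {
    trials <- build_pseudo_experiments(sample, pool, n_trials = n_trials,
                                       seed = substream_seed(seed, "draw", ps))
    tr <- encode_trials(trials, features)
    pred <- fit_slot_classifier(tr$x, tr$y, x_sample, C = C)
    as.numeric(pred == sample$oddity_slot)
  }, numeric(1))
  mean(outcomes)
}

# Multinomial ridge classifier over slots at fixed C; returns predicted slot.
fit_slot_classifier <- function(x, y, newx, C = 1) {
  n <- nrow(x)
  lam_star <- 1 / (n * C)
  lam <- lam_star * c(100, 10, 1)  # short decreasing path for glmnet stability
  # small per-slot class counts are expected here (52 trials over 3 slots);
  # glmnet's small-class warning is uninformative for this design
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y, levels = 1:3), family = "multinomial",
                   alpha = 0, lambda = lam, standardize = FALSE)
  )
  p <- predict(fit, newx = newx, s = lam_star, type = "response")
  apply(p[, , 1, drop = FALSE], 1, which.max)
}

#' Object-level performance across all oddity partners
#'
#' Averages trial outcomes per pair (typical) object over all oddity
#' partners, yielding a single performance estimate per object.
#'
#' @param outcomes data.frame with columns `pair_object`, `oddity_object`,
#'   `outcome`.
#' @param objects optional character vector of objects that must all be
#'   covered as the paired identity; uncovered objects raise an error.
#' @return A `performance_vector`: named numeric vector of per-object mean
#'   accuracies.
#' @export
aggregate_objects <- function(outcomes, objects = NULL) {
  if (is.null(outcomes) || !nrow(outcomes)) {
    vvs_abort("no trial outcomes to aggregate")
  }
  if (!is.null(objects)) {
    miss <- setdiff(objects, outcomes$pair_object)
    if (length(miss)) {
      vvs_abort(paste("no outcomes with pair object:", paste(miss, collapse = ", ")))
    }
  }
  v <- tapply(outcomes$outcome, outcomes$pair_object, mean)
  out <- as.numeric(v)
  names(out) <- names(v)
  structure(out, class = "performance_vector")
}

#' Compare two object-level performance vectors
#'
#' `mode = "slope"` regresses `b` on `a` (OLS with intercept) and reports
#' the slope with an F-test on `(1, n - 2)` degrees of freedom;
#' `mode = "paired_difference"` reports `mean(b - a)` with a one-sample
#' t-test on `n - 1` degrees of freedom.
#'
#' @param a,b `performance_vector`s over identical object sets (n >= 3).
#' @param mode `"slope"` or `"paired_difference"`.
#' @return A `vvs_stat`.
#' @export
compare_performance_vectors <- function(a, b,
                                        mode = c("slope", "paired_difference")) {
  mode <- match.arg(mode)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    vvs_abort("performance vectors must cover identical object sets")
  }
  if (length(a) < 3) vvs_abort("need at least 3 objects")
  b <- b[names(a)]
  if (mode == "slope") {
    ols_slope_stat(as.numeric(a), as.numeric(b), kind = "ols_slope_F")
  } else {
    d <- as.numeric(b) - as.numeric(a)
    if (stats::sd(d) == 0) {
      vvs_stat("paired_t", beta = mean(d), statistic = if (mean(d) == 0) 0 else Inf,
               df = length(d) - 1, p = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(d)
      vvs_stat("paired_t", beta = mean(d), statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
    }
  }
}

#' Sample oddity trials and estimate pair-level performance
#'
#' Convenience wrapper: draws `n_samples` held-out sample trials for the
#' ordered object pair (pair = `object_i`, oddity = `object_j`), estimates
#' each with [estimate_trial_outcome()], and returns the outcome rows.
#'
#' @param pool oddity `stimulus_set`.
#' @param features `feature_matrix` for the pool.
#' @param object_i pair (typical) object id.
#' @param object_j oddity object id.
#' @param n_samples number of held-out sample trials.
#' @param n_pseudo,n_trials,C,seed passed to [estimate_trial_outcome()].
#' @return Data.frame with `pair_object`, `oddity_object`, `sample`,
#'   `outcome`.
#' @export
estimate_pair_performance <- function(pool, features, object_i, object_j,
                                      n_samples = 3L, n_pseudo = 100L,
                                      n_trials = 52L, C = 1, seed = 1L) {
  index <- if (inherits(pool, "stimulus_set")) pool$index else pool
  vi <- index$image_id[index$object_id == object_i]
  vj <- index$image_id[index$object_id == object_j]
  out <- lapply(seq_len(n_samples), function(k) {
    trial <- with_seed(substream_seed(seed, "sample", object_i, object_j, k), {
      oddity_trial(sample(vi, 2), sample(vj, 1), object_i, object_j,
                   oddity_slot = sample.int(3, 1))
    })
    data.frame(
      pair_object = object_i, oddity_object = object_j, sample = k,
      outcome = estimate_trial_outcome(
        trial, features, index, n_pseudo = n_pseudo, n_trials = n_trials,
        C = C, seed = substream_seed(seed, "outcome", object_i, object_j, k)
      ),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
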