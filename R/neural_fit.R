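#' Cross-validated ridge maps from features to electrode responses
#'
#' For each electrode, learns a ridge-regularized linear map from encoder
#' features to repetition-averaged responses and evaluates it on held-out
#' images: the data are split into `n_folds` outer folds; within each outer
#' training set the ridge penalty is chosen per electrode by an inner
#' `n_folds`-fold cross-validation (the penalty maximizing the correlation
#' of concatenated inner held-out predictions, ties resolved toward the
#' stronger penalty); the map is then refit on the full outer training set
#' and used to predict the outer test fold. The returned `r` is the Pearson
#' correlation between each electrode's concatenated out-of-fold predictions
#' and its observed mean responses.
#'
#' Features are centered and variance-scaled with training-set statistics
#' inside every fit; the ridge solution is computed from a single SVD of the
#' training design shared across electrodes and penalties.
#'
#' @param features a `feature_matrix`, or a plain numeric matrix.
#' @param responses n_images x n_electrodes matrix of repetition-averaged
#'   responses, an `electrode_set` (averaged internally), or a vector for a
#'   single electrode.
#' @param n_folds outer (and inner) fold count.
#' @param lambda_grid ridge penalties searched by the nested CV.
#' @param seed integer seed for the fold assignment.
#' @return An `electrode_fit`: list with `r` (per-electrode out-of-fold
#'   Pearson correlation; `NA` when the held-out responses are constant),
#'   `predictions` (n_images x n_electrodes out-of-fold predictions),
#'   `fold` (outer fold of each image), `chosen_lambda`
#'   (n_folds x n_electrodes).
#' @export
fit_electrode_map <- function(features, responses, n_folds = 5L,
                              lambda_grid = 10^seq(-4, 4, by = 1),
                              seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$matrix else as.matrix(features)
  if (inherits(responses, "electrode_set")) responses <- mean_responses(responses)
  Y <- as.matrix(responses)
  if (ncol(Y) == 0) vvs_abort("empty electrode set: nothing to fit")
  if (nrow(Y) != nrow(X)) vvs_abort("features and responses disagree on n_images")
  n <- nrow(X)
  if (n < 2 * n_folds) vvs_abort("need n_images >= 2 * n_folds")
  if (!all(is.finite(X))) vvs_abort("features must be finite")
  lambda_grid <- sort(lambda_grid)

  fold <- with_seed(substream_seed(seed, "outer-folds"),
                    sample(rep_len(seq_len(n_folds), n)))
  preds <- matrix(NA_real_, n, ncol(Y))
  chosen <- matrix(NA_real_, n_folds, ncol(Y))

  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    inner_fold <- with_seed(substream_seed(seed, "inner-folds", f),
                            sample(rep_len(seq_len(n_folds), length(tr))))
    inner_pred <- array(NA_real_, dim = c(length(tr), length(lambda_grid), ncol(Y)))
    for (g in seq_len(n_folds)) {
      itr <- tr[inner_fold != g]
      ite <- tr[inner_fold == g]
      inner_pred[inner_fold == g, , ] <-
        ridge_predict_path(X[itr, , drop = FALSE], Y[itr, , drop = FALSE],
                           X[ite, , drop = FALSE], lambda_grid)
    }
    # per-electrode penalty choice by inner out-of-fold correlation
    for (e in seq_len(ncol(Y))) {
      rs <- apply(inner_pred[, , e, drop = FALSE], 2,
                  function(p) safe_cor(p, Y[tr, e]))
      rs[is.na(rs)] <- -Inf
      best <- if (all(!is.finite(rs))) length(lambda_grid) else max(which(rs == max(rs)))
      chosen[f, e] <- lambda_grid[best]
    }
    full_path <- ridge_predict_path(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                                    X[te, , drop = FALSE], lambda_grid)
    for (e in seq_len(ncol(Y))) {
      li <- match(chosen[f, e], lambda_grid)
      preds[te, e] <- full_path[, li, e]
    }
  }

  r <- vapply(seq_len(ncol(Y)), function(e) safe_cor(preds[, e], Y[, e]),
              numeric(1))
  structure(list(r = r, predictions = preds, fold = fold,
                 chosen_lambda = chosen),
            class = "electrode_fit")
}

# Ridge predictions for every (lambda, electrode) from one training set.
# Training features are centered and scaled (sd floor 1e-8); responses are
# centered. Solution via SVD: beta(lambda) = V diag(s/(s^2+lambda)) U' y.
# Returns an n_test x n_lambda x n_electrode array.
ridge_predict_path <- function(Xtr, Ytr, Xte, lambdas) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1e-8
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
  ybar <- colMeans(Ytr)
  Yc <- sweep(Ytr, 2, ybar)

  sv <- svd(Xtr, nu = min(dim(Xtr)), nv = min(dim(Xtr)))
  keep <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  dvals <- sv$d[keep]
  T_ <- crossprod(U, Yc)          # r x E
  M <- Xte %*% V                  # n_test x r
  out <- array(NA_real_, dim = c(nrow(Xte), length(lambdas), ncol(Ytr)))
  for (li in seq_along(lambdas)) {
    shrink <- dvals / (dvals^2 + lambdas[li])
    P <- M %*% (shrink * T_)      # n_test x E
    out[, li, ] <- sweep(P, 2, ybar, `+`)
  }
  out
}

#' Split-half reliability of electrode responses
#'
#' For each electrode, repetitions are randomly split into two halves
#' `n_iter` times; the Pearson correlation between the two half-mean
#' vectors (across images) is averaged over iterations and mapped through
#' the Spearman-Brown correction `2r / (1 + r)` to estimate the reliability
#' of the full-data mean response.
#'
#' @param responses an `electrode_set`, a 3-D array
#'   (n_images x n_electrodes x n_reps), or an n_images x n_reps matrix for
#'   a single electrode.
#' @param n_iter number of random half-splits.
#' @param seed integer seed.
#' @return Numeric vector of per-electrode reliabilities.
#' @export
estimate_reliability <- function(responses, n_iter = 100L, seed = 1L) {
  if (inherits(responses, "electrode_set")) responses <- responses$responses
  if (is.matrix(responses)) {
    responses <- array(responses, dim = c(nrow(responses), 1, ncol(responses)))
  }
  d <- dim(responses)
  if (d[1] < 2) vvs_abort("need at least 2 images for split-half reliability")
  n_reps <- d[3]
  if (n_reps < 2) vvs_abort("need n_reps >= 2 for split-half reliability")
  half <- n_reps %/% 2
  vapply(seq_len(d[2]), function(e) {
    rs <- with_seed(substream_seed(seed, "elec-rel", e), {
      vapply(seq_len(n_iter), function(it) {
        idx <- sample(n_reps)
        a <- rowMeans(responses[, e, idx[seq_len(half)], drop = FALSE], dims = 1)
        b <- rowMeans(responses[, e, idx[(half + 1):n_reps], drop = FALSE], dims = 1)
        safe_cor(as.vector(a), as.vector(b))
      }, numeric(1))
    })
    m <- mean(rs, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else 2 * m / (1 + m)
  }, numeric(1))
}

#' Noise-correct raw cross-validated correlations
#'
#' Divides each raw correlation by the square root of the electrode's
#' reliability (noise ceiling). Electrodes whose reliability falls below
#' `floor` (default 0.1) are excluded (returned as `NA` with a message)
#' rather than corrected, since dividing by a tiny ceiling explodes the
#' estimate. Corrected values can legitimately exceed 1 when reliability is
#' modest; they are flagged with a warning, never clipped.
#'
#' @param raw_r per-electrode raw correlations.
#' @param reliability per-electrode reliabilities in `(0, 1]`.
#' @param floor reliability floor below which electrodes are excluded.
#' @return Numeric vector of corrected correlations (`NA` = excluded).
#' @export
noise_correct <- function(raw_r, reliability, floor = 0.1) {
  stopifnot(length(raw_r) == length(reliability))
  out <- rep(NA_real_, length(raw_r))
  ok <- !is.na(reliability) & reliability > floor & !is.na(raw_r)
  if (any(!ok)) {
    message(sprintf("noise_correct: excluding %d electrode(s) with reliability <= %.3g or undefined fits",
                    sum(!ok), floor))
  }
  out[ok] <- raw_r[ok] / sqrt(reliability[ok])
  if (any(out > 1, na.rm = TRUE)) {
    warning("some noise-corrected correlations exceed 1 (low reliability); values not clipped")
  }
  out
}

#' Fit every encoder layer to an electrode set
#'
#' Convenience wrapper running [fit_electrode_map()] for each layer's
#' feature matrix, with split-half noise correction, and summarizing each
#' layer by the median corrected correlation over electrodes.
#'
#' @param features_by_layer named list of `feature_matrix` objects, in the
#'   encoder's declared layer order.
#' @param electrodes an `electrode_set`.
#' @param n_folds,lambda_grid,seed passed to [fit_electrode_map()].
#' @param n_iter split-half iterations for the noise ceiling.
#' @param reliability_floor passed to [noise_correct()].
#' @return A `layer_fit_table` data.frame with one row per layer: `layer`,
#'   `region_label`, `median_r_corrected`, `dispersion` (SD across
#'   electrodes), `n_electrodes`; per-electrode values in
#'   `attr(, "per_electrode")`.
#' @export
fit_layers <- function(features_by_layer, electrodes, n_folds = 5L,
                       lambda_grid = 10^seq(-4, 4, by = 1), n_iter = 100L,
                       reliability_floor = 0.1, seed = 1L) {
  stopifnot(inherits(electrodes, "electrode_set"))
  if (dim(electrodes$responses)[2] == 0) {
    vvs_abort("empty electrode set: nothing to fit")
  }
  Y <- mean_responses(electrodes)
  rel <- estimate_reliability(electrodes, n_iter = n_iter,
                              seed = substream_seed(seed, "reliability"))
  per <- list()
  rows <- list()
  for (layer in names(features_by_layer)) {
    fit <- fit_electrode_map(features_by_layer[[layer]], Y, n_folds = n_folds,
                             lambda_grid = lambda_grid,
                             seed = substream_seed(seed, "fit", layer))
    corrected <- suppressWarnings(
      noise_correct(fit$r, rel, floor = reliability_floor)
    )
    per[[layer]] <- data.frame(
      layer = layer, electrode = seq_along(fit$r), raw_r = fit$r,
      reliability = rel, r_corrected = corrected, stringsAsFactors = FALSE
    )
    rows[[layer]] <- data.frame(
      layer = layer, region_label = electrodes$region_label,
      median_r_corrected = stats::median(corrected, na.rm = TRUE),
      dispersion = stats::sd(corrected, na.rm = TRUE),
      n_electrodes = sum(!is.na(corrected)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_electrode") <- do.call(rbind, per)
  class(out) <- c("layer_fit_table", "data.frame")
  out
}

#' Contrast early versus late encoder layers
#'
#' Unpaired two-sample t-test (pooled variance) comparing per-layer median
#' noise-corrected fits between the first `floor(L/2)` layers of the
#' encoder's declared order and the remainder; degrees of freedom are
#' `n_layers - 2`.
#'
#' @param layer_fits a `layer_fit_table` from [fit_layers()], rows in layer
#'   order.
#' @return A `vvs_stat` with `kind = "unpaired_t"`; `beta` is the
#'   early-minus-late mean difference.
#' @export
contrast_layer_halves <- function(layer_fits) {
  v <- layer_fits$median_r_corrected
  L <- length(v)
  n_early <- L %/% 2
  if (n_early < 2 || (L - n_early) < 2) {
    vvs_abort("need at least 2 layers in each half")
  }
  early <- v[seq_len(n_early)]
  late <- v[(n_early + 1):L]
  if (stats::sd(c(early - mean(early), late - mean(late))) == 0) {
    # zero pooled variance (e.g. identical fits everywhere): define t = 0
    return(vvs_stat(kind = "unpaired_t", beta = mean(early) - mean(late),
                    statistic = 0, df = L - 2, p = 1))
  }
  tt <- stats::t.test(early, late, var.equal = TRUE)
  vvs_stat(kind = "unpaired_t", beta = mean(early) - mean(late),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
}

#' Select the layer with the best median noise-corrected fit
#'
#' Ties are broken toward the earlier layer in the declared order.
#'
#' @param layer_fits a `layer_fit_table`, rows in layer order.
#' @return A list with `layer`, `median_r_corrected`, `dispersion`.
#' @export
select_peak_layer <- function(layer_fits) {
  if (is.null(layer_fits) || nrow(layer_fits) == 0) {
    vvs_abort("no layer fits supplied")
  }
  v <- layer_fits$median_r_corrected
  best <- which(v == max(v, na.rm = TRUE))[1]
  list(layer = layer_fits$layer[best],
       median_r_corrected = v[best],
       dispersion = layer_fits$dispersion[best])
}
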