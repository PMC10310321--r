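#' Simulate electrodes as noisy linear mixtures of encoder features
#'
#' Each electrode's expected response is a fixed random linear mixture of
#' the supplied feature matrix; repetitions add independent Gaussian noise:
#' `response[i, e, r] = w_e . features[i, ] + eps`, `eps ~ N(0, noise_sd)`.
#' With `scale_signal = TRUE` (default) every electrode's noiseless signal
#' is z-scored across images, so `noise_sd` is directly interpretable as a
#' noise-to-signal SD ratio and the split-half reliability of the mean over
#' `n` repetitions has the closed form
#' `var_s / (var_s + noise_sd^2 / (n/2))` (after Spearman-Brown) with
#' `var_s = 1`.
#'
#' @param features a `feature_matrix` (the generating layer).
#' @param n_electrodes number of electrodes (0 gives an empty set that
#'   downstream fits refuse).
#' @param n_repetitions repetitions per image (>= 2, needed for the noise
#'   ceiling).
#' @param noise_sd trial noise SD (>= 0).
#' @param seed integer seed.
#' @param region_label free-text region tag (e.g. "V4-like", "IT-like").
#' @param scale_signal z-score each electrode's signal across images.
#' @param whiten draw mixing weights isotropically in the layer's whitened
#'   (PCA-equalized) top principal subspace rather than over raw features
#'   (default `TRUE`). Raw i.i.d. weights would concentrate every electrode
#'   on the layer's few top principal components — which neighboring layers
#'   largely share — whereas equalized mixtures also engage the mid-rank
#'   directions that identify the layer. Mixing is confined to the top
#'   `n_components` components so the signal stays learnable from modest
#'   image counts (fully whitened mixtures would put equal weight on
#'   near-null-variance directions no regression could recover).
#' @param n_components size of the principal subspace used when
#'   `whiten = TRUE`.
#' @return An `electrode_set`: list with `responses`
#'   (`n_images x n_electrodes x n_repetitions` array), `image_ids`,
#'   `generating_layer`, `mixing_weights` (d x n_electrodes), `signal`
#'   (n_images x n_electrodes expected responses), `noise_sd`,
#'   `region_label`.
#' @export
simulate_electrodes <- function(features, n_electrodes, n_repetitions,
                                noise_sd, seed = 1L,
                                region_label = "IT-like",
                                scale_signal = TRUE, whiten = TRUE,
                                n_components = 8L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    vvs_abort("`noise_sd` must be >= 0")
  }
  if (!is_scalar_number(n_repetitions) || n_repetitions < 2) {
    vvs_abort("`n_repetitions` must be >= 2 (noise-ceiling estimation)")
  }
  if (!is_scalar_number(n_electrodes) || n_electrodes < 0) {
    vvs_abort("`n_electrodes` must be >= 0")
  }
  n_electrodes <- as.integer(n_electrodes)
  n_repetitions <- as.integer(n_repetitions)
  X <- features$matrix
  n <- nrow(X)
  d <- ncol(X)

  basis <- NULL
  if (whiten && n_electrodes > 0) {
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc, nu = 0)
    keep <- which(sv$d > max(sv$d) * 1e-8)
    keep <- keep[seq_len(min(length(keep), n_components))]
    # w = V D^{-1} z maps isotropic z onto whitened principal coordinates
    basis <- sweep(sv$v[, keep, drop = FALSE], 2, sv$d[keep], `/`)
  }
  W <- matrix(0, d, n_electrodes)
  signal <- matrix(0, n, n_electrodes)
  if (n_electrodes > 0) {
    for (e in seq_len(n_electrodes)) {
      w <- if (is.null(basis)) {
        with_seed(substream_seed(seed, "elec-w", e),
                  stats::rnorm(d, 0, 1 / sqrt(d)))
      } else {
        z <- with_seed(substream_seed(seed, "elec-w", e),
                       stats::rnorm(ncol(basis), 0, 1 / sqrt(ncol(basis))))
        as.vector(basis %*% z)
      }
      s <- as.vector(X %*% w)
      if (scale_signal) {
        ssd <- stats::sd(s)
        if (ssd > 0) {
          mu <- mean(s)
          s <- (s - mu) / ssd
          w <- w / ssd  # intercept shift not representable in w; stored signal is authoritative
        }
      }
      W[, e] <- w
      signal[, e] <- s
    }
  }

  responses <- array(0, dim = c(n, n_electrodes, n_repetitions))
  if (n_electrodes > 0) {
    for (e in seq_len(n_electrodes)) {
      eps <- with_seed(substream_seed(seed, "elec-noise", e),
                       matrix(stats::rnorm(n * n_repetitions, 0, noise_sd),
                              n, n_repetitions))
      responses[, e, ] <- signal[, e] + eps
    }
  }
  layer <- if (is.character(features$source)) features$source else features$source$layer
  structure(
    list(responses = responses, image_ids = features$image_ids,
         generating_layer = layer, mixing_weights = W, signal = signal,
         noise_sd = noise_sd, region_label = region_label),
    class = "electrode_set"
  )
}

#' @export
print.electrode_set <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf(
    "<electrode_set '%s'> %d images x %d electrodes x %d reps (layer %s, noise_sd %.3g)\n",
    x$region_label, d[1], d[2], d[3], x$generating_layer, x$noise_sd
  ))
  invisible(x)
}

#' Repetition-averaged responses of an electrode set
#' @param electrodes an `electrode_set`.
#' @return n_images x n_electrodes matrix of means over repetitions.
#' @export
mean_responses <- function(electrodes) {
  stopifnot(inherits(electrodes, "electrode_set"))
  apply(electrodes$responses, c(1, 2), mean)
}

#' Write / read an electrode set as plain text
#'
#' Responses go to a long CSV (`image_id, electrode, repetition, response`)
#' and electrode metadata to a `<path>_manifest.csv`
#' (`electrode, region_label, generating_layer, noise_sd`).
#'
#' @param x an `electrode_set`.
#' @param path base CSV path for the responses.
#' @return `path`, invisibly.
#' @export
write_electrodes <- function(x, path) {
  d <- dim(x$responses)
  long <- data.frame(
    image_id = rep(x$image_ids, times = d[2] * d[3]),
    electrode = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    repetition = rep(seq_len(d[3]), each = d[1] * d[2]),
    response = as.vector(x$responses)
  )
  utils::write.csv(long, path, row.names = FALSE)
  utils::write.csv(
    data.frame(electrode = seq_len(d[2]), region_label = x$region_label,
               generating_layer = x$generating_layer, noise_sd = x$noise_sd),
    sub("\\.csv$", "_manifest.csv", path), row.names = FALSE
  )
  invisible(path)
}
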