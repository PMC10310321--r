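#' Synthetic morph-continuum stimuli
#'
#' Generates discrete "cat"-to-"dog" morph sequences as rendered raster
#' images with a controllable amount of within-sequence pixel colinearity.
#' Each sequence interpolates between a sequence-specific cat-family
#' prototype (a large, smooth blob with an unstructured interior) and a
#' dog-family prototype (a spiky star contour with a striped interior whose
#' orientation and phase are sequence-specific). Morph level `p` blends the
#' shape and texture parameters with weight `p/100`. Foreground area is
#' analytically matched across categories so mean image intensity carries no
#' category signal; the family signal lives in boundary frequency and
#' interior texture energy, which a linear pixel readout cannot exploit
#' across sequences but a rectifying convolutional encoder can.
#'
#' `colinearity` in `[0, 1]` controls how much of the background texture and
#' object position is shared across morph levels within a sequence: at high
#' values, images within a sequence are close to linearly related in pixel
#' space (so a pixel readout can succeed under random train/test splits
#' while failing under a morph-sequence holdout).
#'
#' @param n_sequences number of morph sequences (labelled A, B, C, ...).
#' @param n_levels number of morph levels per sequence, spread over 0--100.
#' @param image_size side length in pixels (>= 32).
#' @param colinearity within-sequence shared-variance control in `[0, 1]`.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param experiment_id experiment label stored in the index.
#' @return A `stimulus_set`: list with `images` (named list of
#'   `H x W x 3` arrays in `[0, 1]`), `index` (data.frame with columns
#'   `image_id`, `experiment_id`, `sequence_id`, `morph_level_pct`, `label`)
#'   and `dialect = "morph"`. The category rule is `label = 1` ("dog") iff
#'   `morph_level_pct > 50`, `0` ("cat") iff `< 50`; exactly-50 images carry
#'   an explicit label that alternates across sequences.
#' @export
generate_morph_stimuli <- function(n_sequences = 7L, n_levels = 11L,
                                   image_size = 64L, colinearity = 0.9,
                                   seed = 1L, experiment_id = "exp1") {
  if (!is_scalar_number(n_sequences) || n_sequences < 1) {
    vvs_abort("`n_sequences` must be a positive integer (>= 1)")
  }
  if (!is_scalar_number(n_levels) || n_levels < 2) {
    vvs_abort("`n_levels` must be an integer >= 2")
  }
  if (!is_scalar_number(image_size) || image_size < 32) {
    vvs_abort("`image_size` must be a positive integer >= 32")
  }
  if (!is_scalar_number(colinearity) || colinearity < 0 || colinearity > 1) {
    vvs_abort("`colinearity` must lie in [0, 1]")
  }
  n_sequences <- as.integer(n_sequences)
  n_levels <- as.integer(n_levels)
  image_size <- as.integer(image_size)

  levels <- unique(as.integer(round(seq(0, 100, length.out = n_levels))))
  if (length(levels) != n_levels) {
    vvs_abort("`n_levels` too large: morph levels are integers on [0, 100]")
  }
  seq_ids <- make_sequence_ids(n_sequences)

  images <- list()
  index <- list()
  for (s in seq_len(n_sequences)) {
    sp <- with_seed(substream_seed(seed, "morph-seq", s), draw_sequence_params())
    for (p in levels) {
      iid <- sprintf("%s_%s_%03d", experiment_id, seq_ids[s], p)
      img <- with_seed(
        substream_seed(seed, "morph-img", s, p),
        render_morph_level(image_size, sp, p / 100, colinearity)
      )
      images[[iid]] <- img
      label <- if (p > 50) 1L else if (p < 50) 0L else (s - 1L) %% 2L
      index[[iid]] <- data.frame(
        image_id = iid, experiment_id = experiment_id,
        sequence_id = seq_ids[s], morph_level_pct = p, label = label,
        stringsAsFactors = FALSE
      )
    }
  }
  new_stimulus_set(images, do.call(rbind, index), dialect = "morph")
}

make_sequence_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%02d", seq_len(n))
}

# Sequence-level parameters: prototype shapes for each category endpoint,
# texture orientation/phase, shared background field and base position.
draw_sequence_params <- function() {
  list(
    # cat endpoint: smooth, mostly 3-lobed; dog endpoint: spiky 7-lobed
    a3_cat = stats::runif(1, 0.08, 0.16),
    a7_cat = stats::runif(1, 0.00, 0.04),
    a3_dog = stats::runif(1, 0.02, 0.08),
    a7_dog = stats::runif(1, 0.36, 0.46),
    p3 = stats::runif(1, 0, 2 * pi),
    p7 = stats::runif(1, 0, 2 * pi),
    r0 = stats::runif(1, 0.24, 0.33),
    stripe_amp_dog = stats::runif(1, 0.30, 0.40),
    stripe_freq = stats::runif(1, 3.5, 4.5),
    stripe_dir = stats::runif(1, 0, pi),
    stripe_phase = stats::runif(1, 0, 2 * pi),
    center = 0.5 + stats::runif(2, -0.09, 0.09),
    bg = draw_background_params()
  )
}

draw_background_params <- function(k = 3L) {
  list(
    fx = stats::runif(k, 0.5, 2.5),
    fy = stats::runif(k, 0.5, 2.5),
    ph = stats::runif(k, 0, 2 * pi),
    amp = stats::runif(k, 0.5, 1.0)
  )
}

eval_background <- function(n, bp) {
  xs <- (seq_len(n) - 0.5) / n
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  f <- matrix(0, n, n)
  for (k in seq_along(bp$fx)) {
    f <- f + bp$amp[k] * cos(2 * pi * (bp$fx[k] * X + bp$fy[k] * Y) + bp$ph[k])
  }
  0.45 + 0.12 * f / length(bp$fx) * 2
}

# Renders one morph level. Called inside a sub-stream seed context; the only
# per-image randomness is the image-specific background and position jitter,
# both down-weighted by `colinearity`.
render_morph_level <- function(n, sp, t, colinearity) {
  a3 <- (1 - t) * sp$a3_cat + t * sp$a3_dog
  a7 <- (1 - t) * sp$a7_cat + t * sp$a7_dog
  stripe_amp <- t * sp$stripe_amp_dog
  # area matching: A = pi r^2 (1 + (a3^2 + a7^2)/2)
  r0 <- sp$r0 / sqrt(1 + (a3^2 + a7^2) / 2)

  bg_own <- eval_background(n, draw_background_params())
  bg_seq <- eval_background(n, sp$bg)
  bg <- colinearity * bg_seq + (1 - colinearity) * bg_own
  center <- sp$center + (1 - colinearity) * stats::runif(2, -0.05, 0.05)

  render_shape(
    n = n, center = center, r0 = r0,
    a3 = a3, p3 = sp$p3, a7 = a7, p7 = sp$p7,
    stripe_amp = stripe_amp, stripe_freq = sp$stripe_freq,
    stripe_dir = sp$stripe_dir, stripe_phase = sp$stripe_phase,
    bg = bg
  )
}

# Shared rasterizer for morph and oddity stimuli: a star-blob contour
# r(theta) = r0 (1 + a3 sin(3 theta + p3) + a7 sin(7 theta + p7)) filled with
# a (possibly striped) foreground, alpha-blended onto a background with a
# ~1.5-pixel soft edge, replicated into RGB with a fixed warm tint.
render_shape <- function(n, center, r0, a3, p3, a7, p7,
                         stripe_amp, stripe_freq, stripe_dir, stripe_phase,
                         bg, fg_base = 0.58) {
  xs <- (seq_len(n) - 0.5) / n
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  dx <- X - center[1]
  dy <- Y - center[2]
  th <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  rad <- r0 * (1 + a3 * sin(3 * th + p3) + a7 * sin(7 * th + p7))
  mask <- clamp01((rad - rr) * n / 1.5 + 0.5)
  stripes <- stripe_amp *
    sin(2 * pi * stripe_freq * (X * cos(stripe_dir) + Y * sin(stripe_dir)) +
          stripe_phase)
  # foreground base chosen so the strongest stripes stay inside [0, 1]:
  # clipping would otherwise lower the mean intensity of striped (dog-like)
  # foregrounds and hand a linear pixel readout a global luminance cue
  fg <- fg_base + stripes
  g <- clamp01(bg * (1 - mask) + fg * mask)
  out <- array(0, dim = c(n, n, 3))
  out[, , 1] <- g
  out[, , 2] <- clamp01(g * 0.94)
  out[, , 3] <- clamp01(g * 0.87)
  out
}

#' Synthetic odd-one-out stimulus pool
#'
#' Renders `n_objects` parametric shapes at `n_views` random in-plane
#' rotations each, every view on an independently sampled noise background
#' with a small position jitter. The pool is the raw material for
#' pseudo-oddity experiments (see [build_pseudo_experiments()]).
#'
#' @param n_objects number of distinct objects (>= 2).
#' @param n_views views per object (>= 4).
#' @param image_size side length in pixels (>= 32).
#' @param seed integer seed.
#' @return A `stimulus_set` with `dialect = "oddity"`; its index has columns
#'   `image_id`, `object_id`, `view_id`.
#' @export
generate_oddity_pool <- function(n_objects = 32L, n_views = 20L,
                                 image_size = 64L, seed = 1L) {
  if (!is_scalar_number(n_objects) || n_objects < 2) {
    vvs_abort("`n_objects` must be >= 2: no oddity is definable otherwise")
  }
  if (!is_scalar_number(n_views) || n_views < 4) {
    vvs_abort("`n_views` must be >= 4")
  }
  if (!is_scalar_number(image_size) || image_size < 32) {
    vvs_abort("`image_size` must be a positive integer >= 32")
  }
  n_objects <- as.integer(n_objects)
  n_views <- as.integer(n_views)
  image_size <- as.integer(image_size)

  images <- list()
  index <- list()
  for (o in seq_len(n_objects)) {
    op <- with_seed(substream_seed(seed, "oddity-obj", o), list(
      a3 = stats::runif(1, 0.05, 0.35),
      a7 = stats::runif(1, 0.05, 0.45),
      p3 = stats::runif(1, 0, 2 * pi),
      p7 = stats::runif(1, 0, 2 * pi),
      r0 = stats::runif(1, 0.24, 0.33),
      stripe_amp = stats::runif(1, 0, 0.40),
      stripe_freq = stats::runif(1, 3, 6),
      stripe_dir = stats::runif(1, 0, pi),
      stripe_phase = stats::runif(1, 0, 2 * pi)
    ))
    oid <- sprintf("obj%03d", o)
    for (v in seq_len(n_views)) {
      iid <- sprintf("%s_v%03d", oid, v)
      images[[iid]] <- with_seed(substream_seed(seed, "oddity-view", o, v), {
        rot <- stats::runif(1, 0, 2 * pi)
        bg <- eval_background(image_size, draw_background_params())
        render_shape(
          n = image_size,
          center = 0.5 + stats::runif(2, -0.03, 0.03),
          r0 = op$r0 / sqrt(1 + (op$a3^2 + op$a7^2) / 2),
          a3 = op$a3, p3 = op$p3 + 3 * rot,
          a7 = op$a7, p7 = op$p7 + 7 * rot,
          stripe_amp = op$stripe_amp, stripe_freq = op$stripe_freq,
          stripe_dir = op$stripe_dir + rot, stripe_phase = op$stripe_phase,
          bg = bg
        )
      })
      index[[iid]] <- data.frame(
        image_id = iid, object_id = oid, view_id = sprintf("v%03d", v),
        stringsAsFactors = FALSE
      )
    }
  }
  new_stimulus_set(images, do.call(rbind, index), dialect = "oddity")
}

#' Feature-level object fixture for oddity analyses
#'
#' Generates per-view feature vectors with a controllable object structure,
#' bypassing rendering and encoding: each object has a prototype vector of
#' norm `separation` and each view adds isotropic Gaussian view noise of SD
#' `noise_sd`. `separation = 0` gives object-structure-free (pure noise)
#' features, for which oddity performance must sit at the 1/3 chance level;
#' large separations make the odd object trivially identifiable.
#'
#' @param n_objects number of objects (>= 2).
#' @param n_views views per object.
#' @param dim feature dimensionality.
#' @param separation norm of each object's prototype vector.
#' @param noise_sd SD of per-view feature noise.
#' @param seed integer seed.
#' @return A list with `features` (a `feature_matrix`) and `index`
#'   (data.frame `image_id`, `object_id`, `view_id`) usable wherever an
#'   oddity pool index is accepted.
#' @export
synthetic_object_features <- function(n_objects = 8L, n_views = 12L,
                                      dim = 16L, separation = 1,
                                      noise_sd = 1, seed = 1L) {
  if (!is_scalar_number(n_objects) || n_objects < 2) {
    vvs_abort("`n_objects` must be >= 2")
  }
  rows <- list()
  index <- list()
  for (o in seq_len(n_objects)) {
    proto <- with_seed(substream_seed(seed, "proto", o), stats::rnorm(dim))
    proto <- proto / sqrt(sum(proto^2)) * separation
    oid <- sprintf("obj%03d", o)
    for (v in seq_len(n_views)) {
      iid <- sprintf("%s_v%03d", oid, v)
      rows[[iid]] <- proto + with_seed(substream_seed(seed, "view", o, v),
                                       stats::rnorm(dim, 0, noise_sd))
      index[[iid]] <- data.frame(image_id = iid, object_id = oid,
                                 view_id = sprintf("v%03d", v),
                                 stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, index)
  rownames(index) <- NULL
  list(
    features = new_feature_matrix(do.call(rbind, rows), index$image_id,
                                  source = "synthetic-object-features"),
    index = index
  )
}

new_stimulus_set <- function(images, index, dialect) {
  rownames(index) <- NULL
  x <- structure(
    list(images = images, index = index, dialect = dialect),
    class = "stimulus_set"
  )
  validate_stimulus_set(x)
  x
}

#' Validate a stimulus set's invariants
#'
#' Checks that every image id appears exactly once in the index and has an
#' image, that all images share the same dimensions with values in `[0, 1]`,
#' and (morph dialect) that morph levels within each sequence are strictly
#' increasing and include both endpoints of the generated range.
#'
#' @param x a `stimulus_set`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_stimulus_set <- function(x) {
  stopifnot(inherits(x, "stimulus_set"))
  ids <- x$index$image_id
  if (anyDuplicated(ids)) vvs_abort("duplicate image_id in index")
  if (!setequal(ids, names(x$images)) || length(ids) != length(x$images)) {
    vvs_abort("index and images disagree on image ids")
  }
  dims <- vapply(x$images, function(im) dim(im)[1:2], numeric(2))
  if (any(dims != dims[, 1])) vvs_abort("images differ in H x W dimensions")
  rng <- range(vapply(x$images, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1) vvs_abort("image values outside [0, 1]")
  if (identical(x$dialect, "morph")) {
    for (s in unique(x$index$sequence_id)) {
      lv <- x$index$morph_level_pct[x$index$sequence_id == s]
      if (any(diff(lv) <= 0)) {
        vvs_abort(sprintf("morph levels not strictly increasing in sequence %s", s))
      }
      full <- range(x$index$morph_level_pct)
      if (lv[1] != full[1] || lv[length(lv)] != full[2]) {
        vvs_abort(sprintf("sequence %s is missing a range endpoint", s))
      }
    }
  }
  invisible(x)
}

#' @export
print.stimulus_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "<stimulus_set [%s]> %d images, %dx%dx%d\n",
    x$dialect, nrow(x$index), d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Look up category labels for image ids
#'
#' @param stimuli a morph-dialect `stimulus_set`.
#' @param image_ids character; defaults to all images in index order.
#' @return Integer vector of 0/1 labels (dog = 1, cat = 0).
#' @export
category_labels <- function(stimuli, image_ids = stimuli$index$image_id) {
  stopifnot(identical(stimuli$dialect, "morph"))
  idx <- match(image_ids, stimuli$index$image_id)
  if (anyNA(idx)) vvs_abort("unknown image ids requested")
  stimuli$index$label[idx]
}

#' Write a stimulus set to disk as PNG files
#'
#' Morph stimuli go to `<root>/<experiment>/<sequence>/<level>.png`; oddity
#' pools to `<root>/objects/<object_id>/<view_id>.png`. An `index.csv`
#' manifest is always written at the root so labels (including the explicit
#' label of exactly-50 morphs) survive the round trip.
#'
#' @param x a `stimulus_set`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_stimuli <- function(x, root) {
  stopifnot(inherits(x, "stimulus_set"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(x$index))) {
    row <- x$index[i, ]
    path <- if (identical(x$dialect, "morph")) {
      file.path(root, row$experiment_id, row$sequence_id,
                sprintf("%03d.png", row$morph_level_pct))
    } else {
      file.path(root, "objects", row$object_id, paste0(row$view_id, ".png"))
    }
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(x$images[[row$image_id]], path)
  }
  utils::write.csv(cbind(x$index, dialect = x$dialect),
                   file.path(root, "index.csv"), row.names = FALSE)
  invisible(root)
}

#' Read a stimulus set written by [write_stimuli()]
#'
#' @param root directory containing `index.csv` and the PNG tree.
#' @return A `stimulus_set`.
#' @export
read_stimuli <- function(root) {
  manifest <- file.path(root, "index.csv")
  if (!file.exists(manifest)) {
    vvs_abort_missing_data(sprintf(
      "no stimulus manifest at %s; expected index.csv plus a PNG tree", manifest
    ))
  }
  index <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dialect <- index$dialect[1]
  index$dialect <- NULL
  images <- list()
  for (i in seq_len(nrow(index))) {
    row <- index[i, ]
    path <- if (identical(dialect, "morph")) {
      file.path(root, row$experiment_id, row$sequence_id,
                sprintf("%03d.png", row$morph_level_pct))
    } else {
      file.path(root, "objects", row$object_id, paste0(row$view_id, ".png"))
    }
    im <- png::readPNG(path)
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    images[[row$image_id]] <- im[, , 1:3, drop = FALSE]
  }
  new_stimulus_set(images, index, dialect = dialect)
}
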