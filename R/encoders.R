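#' Standard image preprocessing
#'
#' Bilinearly resizes an `H x W x 3` image (values in `[0, 1]`) to
#' `224 x 224 x 3` and normalizes each channel by the canonical mean
#' `(0.485, 0.456, 0.406)` and SD `(0.229, 0.224, 0.225)` used by
#' ImageNet-trained networks. Resizing uses the bilinear filter of
#' `EBImage::resize()`, whose sample grid places output pixel centers on the
#' input pixel lattice scaled by `W_in / W_out` (a center-aligned
#' convention).
#'
#' @param img numeric array `H x W x 3` with values in `[0, 1]`.
#' @param size target side length (default 224).
#' @return A `size x size x 3` array; values can be negative after
#'   normalization.
#' @export
preprocess_image <- function(img, size = 224L) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    vvs_abort("`img` must be an H x W x 3 array (3 channels required)")
  }
  if (min(img) < -1e-8 || max(img) > 1 + 1e-8) {
    vvs_abort("`img` values must lie in [0, 1]")
  }
  if (dim(img)[1] != size || dim(img)[2] != size) {
    img <- EBImage::imageData(
      EBImage::resize(img, w = size, h = size, filter = "bilinear")
    )
  }
  mu <- c(0.485, 0.456, 0.406)
  sd <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mu[ch]) / sd[ch]
  img
}

#' Image encoder contract
#'
#' An `image_encoder` is a list with fields `name` (character), `layers`
#' (ordered character vector; the order defines "early" vs "late" layers),
#' `encode(img, layer)` returning a numeric feature vector for a
#' preprocessed image, and `feature_dim(layer)`. Encoding must be
#' deterministic. [random_cnn_encoder()] and the pixel baseline
#' ([flatten_pixels()]) are the bundled implementations; any object obeying
#' the contract (e.g. an adapter around a locally available pretrained
#' network) can be plugged into the same pipeline.
#'
#' @param name encoder name.
#' @param layers ordered layer names.
#' @param encode function(img, layer) -> numeric vector.
#' @param feature_dim function(layer) -> integer.
#' @return An `image_encoder`.
#' @export
image_encoder <- function(name, layers, encode, feature_dim) {
  structure(list(name = name, layers = layers, encode = encode,
                 feature_dim = feature_dim),
            class = "image_encoder")
}

#' @export
print.image_encoder <- function(x, ...) {
  cat(sprintf("<image_encoder '%s'> layers: %s\n", x$name,
              paste(x$layers, collapse = " -> ")))
  invisible(x)
}

#' Seeded random-weight convolutional encoder
#'
#' A ten-layer network with fixed random (He-scaled Gaussian) weights:
#' three conv + ReLU + max-pool blocks followed by seven fully connected
#' ReLU layers of gently decreasing width. Untrained random-weight networks
#' retain the architectural priors (local rectified filtering, pooling)
#' that make convolutional features sensitive to local contour and texture
#' energy, so they serve as a download-free stand-in for a task-optimized
#' encoder in every pipeline stage. Convolutional layers are exposed to
#' [extract_features()] after average-pooling their maps to at most a
#' `7 x 7` spatial grid.
#'
#' Expects 224 x 224 x 3 inputs (the output of [preprocess_image()]).
#'
#' @param seed integer seed fixing the weights.
#' @param n_filters filter counts for the three conv blocks.
#' @param fc_dims output dimensions of the fully connected layers.
#' @return An `image_encoder` with layers
#'   `conv1, conv2, conv3, fc4, ..., fc10`.
#' @export
random_cnn_encoder <- function(seed = 1L, n_filters = c(12L, 24L, 32L),
                               fc_dims = c(128L, 96L, 80L, 64L, 56L, 48L, 40L)) {
  arch <- c(
    list(
      list(name = "conv1", kind = "conv", k = 7L, stride = 4L, nf = n_filters[1]),
      list(name = "conv2", kind = "conv", k = 3L, stride = 1L, nf = n_filters[2]),
      list(name = "conv3", kind = "conv", k = 3L, stride = 1L, nf = n_filters[3])
    ),
    lapply(seq_along(fc_dims), function(i) {
      list(name = paste0("fc", i + 3L), kind = "fc", dim = fc_dims[i])
    })
  )
  layers <- vapply(arch, `[[`, character(1), "name")

  # trace shapes from a 224x224x3 input to size the weights
  weights <- list()
  shp <- c(224L, 224L, 3L)
  fc_in <- NULL
  for (li in seq_along(arch)) {
    a <- arch[[li]]
    if (a$kind == "conv") {
      fan_in <- a$k * a$k * shp[3]
      weights[[a$name]] <- with_seed(
        substream_seed(seed, "w", a$name),
        list(W = matrix(stats::rnorm(fan_in * a$nf, 0, sqrt(2 / fan_in)),
                        fan_in, a$nf),
             b = stats::rnorm(a$nf, 0, 0.1))
      )
      side <- (shp[1] - a$k) %/% a$stride + 1L  # conv
      side <- side %/% 2L                        # max pool 2x2 stride 2
      shp <- c(side, side, a$nf)
      fc_in <- prod(shp)
    } else {
      weights[[a$name]] <- with_seed(
        substream_seed(seed, "w", a$name),
        list(W = matrix(stats::rnorm(fc_in * a$dim, 0, sqrt(2 / fc_in)),
                        fc_in, a$dim),
             b = stats::rnorm(a$dim, 0, 0.1))
      )
      fc_in <- a$dim
    }
  }

  im2col_cache <- new.env(parent = emptyenv())
  dims_cache <- new.env(parent = emptyenv())

  forward <- function(img, upto) {
    x <- img  # H x W x C
    for (a in arch) {
      if (a$kind == "conv") {
        x <- conv_relu_maxpool(x, weights[[a$name]], a$k, a$stride, im2col_cache)
        feat <- x
      } else {
        v <- as.vector(x)
        w <- weights[[a$name]]
        x <- pmax(as.vector(crossprod(w$W, v)) + w$b, 0)
        feat <- x
      }
      if (a$name == upto) {
        if (a$kind == "conv") {
          g <- apply(feat, 3, pool_to_grid, g = 7L)  # (cells) x nf
          return(as.vector(g))
        }
        return(feat)
      }
    }
    vvs_abort(sprintf("unknown layer '%s'; available: %s", upto,
                      paste(layers, collapse = ", ")))
  }

  image_encoder(
    name = "random-cnn",
    layers = layers,
    encode = function(img, layer) {
      if (!layer %in% layers) {
        vvs_abort(sprintf("unknown layer '%s'; available: %s", layer,
                          paste(layers, collapse = ", ")))
      }
      forward(img, layer)
    },
    feature_dim = function(layer) {
      if (!is.null(dims_cache[[layer]])) return(dims_cache[[layer]])
      d <- length(forward(array(0.5, dim = c(224, 224, 3)), layer))
      dims_cache[[layer]] <- d
      d
    }
  )
}

# One conv block: valid convolution (im2col + GEMM), ReLU, 2x2 max pool.
conv_relu_maxpool <- function(x, w, k, stride, cache) {
  d <- dim(x)
  key <- paste(d[1], d[2], d[3], k, stride, sep = "_")
  idx <- cache[[key]]
  if (is.null(idx)) {
    out_side <- (d[1] - k) %/% stride + 1L
    r0 <- (seq_len(out_side) - 1L) * stride  # top-left offsets
    # linear indices into the H x W x C array for each patch element
    base <- outer(r0 + 1L, (r0) * d[1], `+`)  # out_side x out_side, index of (r, c, 1)
    patch <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * d[1], `+`)) - 1L
    patch <- as.vector(outer(patch, (seq_len(d[3]) - 1L) * d[1] * d[2], `+`))
    idx <- outer(as.vector(base), patch, `+`)  # (out^2) x (k^2 C)
    cache[[key]] <- idx
  }
  patches <- matrix(x[idx], nrow = nrow(idx))
  out <- patches %*% w$W
  out <- sweep(out, 2, w$b, `+`)
  out[out < 0] <- 0
  side <- as.integer(sqrt(nrow(idx)))
  a <- array(out, dim = c(side, side, ncol(out)))
  # 2x2 max pool, stride 2 (drops a trailing odd row/col)
  half <- side %/% 2L
  o <- seq_len(half) * 2L
  pmax(
    pmax(a[o - 1L, o - 1L, , drop = FALSE], a[o, o - 1L, , drop = FALSE]),
    pmax(a[o - 1L, o, , drop = FALSE], a[o, o, , drop = FALSE])
  )
}

#' Extract an encoder-layer feature matrix for a stimulus set
#'
#' Runs every image through [preprocess_image()] and the encoder, in the
#' stimulus set's index order.
#'
#' @param encoder an `image_encoder`.
#' @param stimuli a `stimulus_set`.
#' @param layer layer name (must be in `encoder$layers`).
#' @return A `feature_matrix`: list with `matrix` (n_images x d),
#'   `image_ids` (aligned), and `source` (encoder and layer names).
#' @export
extract_features <- function(encoder, stimuli, layer) {
  stopifnot(inherits(encoder, "image_encoder"), inherits(stimuli, "stimulus_set"))
  if (!layer %in% encoder$layers) {
    vvs_abort(sprintf("unknown layer '%s'; available: %s", layer,
                      paste(encoder$layers, collapse = ", ")))
  }
  ids <- stimuli$index$image_id
  rows <- lapply(ids, function(iid) {
    encoder$encode(preprocess_image(stimuli$images[[iid]]), layer)
  })
  mat <- do.call(rbind, rows)
  new_feature_matrix(mat, ids, source = list(encoder = encoder$name, layer = layer))
}

#' Flattened-pixel baseline features
#'
#' Optionally resizes each image (bilinear) and flattens it to a vector in
#' R's column-major order. This is the trivial "readout directly from the
#' vectorized images" baseline used to expose colinearity in a stimulus
#' set.
#'
#' @param stimuli a `stimulus_set`.
#' @param resize_to optional side length; `NULL` keeps native resolution.
#' @return A `feature_matrix` with `source = "pixels"`.
#' @export
flatten_pixels <- function(stimuli, resize_to = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  ids <- stimuli$index$image_id
  rows <- lapply(ids, function(iid) {
    im <- stimuli$images[[iid]]
    if (!is.null(resize_to) && dim(im)[1] != resize_to) {
      im <- EBImage::imageData(
        EBImage::resize(im, w = resize_to, h = resize_to, filter = "bilinear")
      )
    }
    as.vector(im)
  })
  new_feature_matrix(do.call(rbind, rows), ids, source = "pixels")
}

new_feature_matrix <- function(mat, image_ids, source) {
  if (!all(is.finite(mat))) vvs_abort("feature matrix contains non-finite values")
  stopifnot(nrow(mat) == length(image_ids))
  rownames(mat) <- image_ids
  structure(list(matrix = mat, image_ids = image_ids, source = source),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  src <- if (is.character(x$source)) x$source else {
    paste0(x$source$encoder, ":", x$source$layer)
  }
  cat(sprintf("<feature_matrix> %d images x %d features [%s]\n",
              nrow(x$matrix), ncol(x$matrix), src))
  invisible(x)
}

#' Feature-matrix rows for a set of image ids
#' @param fm a `feature_matrix`.
#' @param image_ids ids to select (order preserved).
#' @return Numeric matrix.
#' @export
feature_rows <- function(fm, image_ids) {
  idx <- match(image_ids, fm$image_ids)
  if (anyNA(idx)) {
    vvs_abort(paste("feature matrix is missing rows for:",
                    paste(image_ids[is.na(idx)], collapse = ", ")))
  }
  fm$matrix[idx, , drop = FALSE]
}

#' Persist / load feature matrices
#'
#' Features are written as a plain CSV (first column `image_id`, then
#' `f1 ... fd`) plus a JSON sidecar `<path>.json` recording the source and
#' image ids.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `path` (write) / a `feature_matrix` (read).
#' @export
write_features <- function(fm, path) {
  df <- data.frame(image_id = fm$image_ids, fm$matrix,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("image_id", paste0("f", seq_len(ncol(fm$matrix))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(source = fm$source, image_ids = fm$image_ids),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    vvs_abort_missing_data(sprintf("no feature matrix at %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  source <- if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)$source
    if (is.list(s)) s else as.character(s)
  } else "unknown"
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  new_feature_matrix(mat, df$image_id, source)
}
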