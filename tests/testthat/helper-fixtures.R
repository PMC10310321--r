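# Shared, lazily-built fixtures. Everything is generated in code at test
# time; expensive objects (rendered stimuli, encoder features) are cached
# for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) {
    .fixture_env[[name]] <- force(expr)
  }
  .fixture_env[[name]]
}

# canonical morph set: 7 sequences x 11 levels (the default study layout)
fx_stimuli <- function() {
  fixture("stimuli", generate_morph_stimuli(7, 11, 64, 0.9, seed = 1))
}

# 40-image slope-0 reliability stimulus set (4 sequences x 10 levels)
fx_stimuli40 <- function() {
  fixture("stimuli40", generate_morph_stimuli(4, 10, 64, 0.9, seed = 2))
}

fx_encoder <- function() fixture("encoder", random_cnn_encoder(seed = 7))

fx_features <- function(layer) {
  fixture(paste0("feat_", layer),
          extract_features(fx_encoder(), fx_stimuli(), layer))
}

fx_pixels32 <- function() {
  fixture("pixels32", flatten_pixels(fx_stimuli(), resize_to = 32))
}

# diverse object pool used by the neural-fit fixtures
fx_pool <- function() fixture("pool", generate_oddity_pool(24, 8, 64, seed = 5))

fx_pool_features <- function() {
  fixture("pool_features", {
    enc <- fx_encoder()
    lapply(stats::setNames(enc$layers, enc$layers), function(l) {
      extract_features(enc, fx_pool(), l)
    })
  })
}

# toy deterministic encoder: per-channel means of the preprocessed image
toy_mean_encoder <- function() {
  image_encoder(
    name = "channel-means", layers = c("means"),
    encode = function(img, layer) c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3])),
    feature_dim = function(layer) 3L
  )
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
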