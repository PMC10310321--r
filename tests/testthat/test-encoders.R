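test_that("preprocessing normalizes exactly and always yields 224x224x3", {
  mu <- c(0.485, 0.456, 0.406)
  sd <- c(0.229, 0.224, 0.225)
  img <- array(rep(mu, each = 224 * 224), dim = c(224, 224, 3))
  out <- preprocess_image(img)
  expect_equal(max(abs(out)), 0)

  img1 <- array(rep(mu + sd, each = 224 * 224), dim = c(224, 224, 3))
  expect_equal(max(abs(preprocess_image(img1) - 1)), 0)

  odd <- array(stats::runif(50 * 70 * 3), dim = c(50, 70, 3))
  expect_equal(dim(preprocess_image(odd)), c(224, 224, 3))
  # idempotent in shape
  renorm <- preprocess_image(clamp_img <- pmin(pmax((preprocess_image(odd) * 0.1) + 0.5, 0), 1))
  expect_equal(dim(renorm), c(224, 224, 3))

  expect_error(preprocess_image(array(0.5, dim = c(32, 32, 2))),
               class = "vvsreadout_invalid_argument")
})

test_that("extract_features aligns rows with the stimulus index", {
  st <- generate_morph_stimuli(1, 3, 32, 0.9, seed = 6)
  enc <- toy_mean_encoder()
  fm <- extract_features(enc, st, "means")
  expect_equal(dim(fm$matrix), c(3, 3))
  # hand-computed oracle: channel means of each preprocessed image
  for (i in 1:3) {
    img <- preprocess_image(st$images[[st$index$image_id[i]]])
    expect_equal(fm$matrix[i, ], apply(img, 3, mean), tolerance = 1e-12)
  }
  # permuting image order permutes rows identically
  st_perm <- st
  ord <- c(3, 1, 2)
  st_perm$index <- st_perm$index[ord, ]
  fm2 <- extract_features(enc, st_perm, "means")
  expect_equal(fm2$matrix, fm$matrix[ord, ], ignore_attr = TRUE)

  expect_error(extract_features(enc, st, "nope"), "available")
})

test_that("the random-weight encoder is deterministic with ordered layers", {
  enc <- fx_encoder()
  expect_equal(enc$layers,
               c("conv1", "conv2", "conv3", paste0("fc", 4:10)))
  img <- preprocess_image(fx_stimuli()$images[[1]])
  v1 <- enc$encode(img, "fc7")
  v2 <- enc$encode(img, "fc7")
  expect_identical(v1, v2)
  expect_equal(length(v1), enc$feature_dim("fc7"))
  enc_same <- random_cnn_encoder(seed = 7)
  expect_equal(enc_same$encode(img, "conv2"), enc$encode(img, "conv2"))
  expect_error(enc$encode(img, "pool9"), "available")
})

test_that("pixel flattening counts, zeros and round trip", {
  st <- generate_morph_stimuli(1, 3, 64, 0.9, seed = 8)
  fm <- flatten_pixels(st)
  expect_equal(ncol(fm$matrix), 64 * 64 * 3)
  expect_identical(fm$source, "pixels")
  # flatten then reshape recovers the image exactly
  img <- st$images[[st$index$image_id[2]]]
  expect_identical(array(fm$matrix[2, ], dim = dim(img)), img)
  # all-black image flattens to zeros
  st$images[[st$index$image_id[1]]] <- array(0, dim = c(64, 64, 3))
  expect_equal(sum(abs(flatten_pixels(st)$matrix[1, ])), 0)
  # resize path changes dimensionality
  expect_equal(ncol(flatten_pixels(st, resize_to = 16)$matrix), 16 * 16 * 3)
})

test_that("feature matrices persist as CSV + JSON sidecar", {
  st <- generate_morph_stimuli(1, 3, 32, 0.9, seed = 9)
  fm <- extract_features(toy_mean_encoder(), st, "means")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(back$matrix, fm$matrix, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$image_ids, fm$image_ids)
  expect_equal(back$source$layer, "means")
  expect_error(feature_rows(fm, "missing_id"), "missing")
})
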