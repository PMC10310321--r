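test_that("morph generation counts, levels, labels and determinism", {
  st <- generate_morph_stimuli(7, 11, 64, 0.9, seed = 1)
  expect_equal(nrow(st$index), 77)
  expect_equal(sort(unique(st$index$morph_level_pct)), seq(0, 100, by = 10))
  expect_equal(length(unique(st$index$sequence_id)), 7)
  # category rule: dog above the midpoint, cat below, alternating at 50
  expect_true(all(st$index$label[st$index$morph_level_pct > 50] == 1))
  expect_true(all(st$index$label[st$index$morph_level_pct < 50] == 0))
  at50 <- st$index$label[st$index$morph_level_pct == 50]
  expect_equal(sort(unique(at50)), c(0, 1))

  st2 <- generate_morph_stimuli(7, 11, 64, 0.9, seed = 1)
  expect_identical(st$images, st2$images)
  st3 <- generate_morph_stimuli(7, 11, 64, 0.9, seed = 2)
  expect_false(identical(st$images[[1]], st3$images[[1]]))

  expect_error(generate_morph_stimuli(0, 11, 64), class = "vvsreadout_invalid_argument")
  expect_error(generate_morph_stimuli(7, 1, 64), class = "vvsreadout_invalid_argument")
  expect_error(generate_morph_stimuli(7, 11, 16), class = "vvsreadout_invalid_argument")
})

test_that("high colinearity makes within-sequence images more pixel-correlated", {
  st <- fx_stimuli()
  M <- flatten_pixels(st)$matrix
  cc <- stats::cor(t(M))
  seqs <- st$index$sequence_id
  same <- outer(seqs, seqs, `==`) & upper.tri(cc)
  diff <- outer(seqs, seqs, `!=`) & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))
})

test_that("stimulus sets survive a write -> read -> validate round trip", {
  st <- generate_morph_stimuli(2, 5, 32, 0.9, seed = 3)
  root <- withr::local_tempdir()
  write_stimuli(st, root)
  expect_true(file.exists(file.path(root, "index.csv")))
  back <- read_stimuli(root)
  expect_s3_class(validate_stimulus_set(back), "stimulus_set")
  expect_setequal(back$index$image_id, st$index$image_id)
  # labels (including explicit 50% labels) survive via the manifest
  expect_equal(
    category_labels(back, st$index$image_id),
    category_labels(st, st$index$image_id)
  )
  # 8-bit PNG quantization only
  expect_lt(max(abs(back$images[[1]] - st$images[[1]])), 1 / 255)
})

test_that("oddity pool counts, determinism and object structure", {
  small <- generate_oddity_pool(8, 5, 32, seed = 4)
  expect_equal(nrow(small$index), 40)
  expect_equal(length(unique(small$index$object_id)), 8)
  small2 <- generate_oddity_pool(8, 5, 32, seed = 4)
  expect_identical(small$images, small2$images)

  pool <- fx_pool()  # canonical 24 objects x 8 views
  M <- flatten_pixels(pool)$matrix
  cc <- stats::cor(t(M))
  obj <- pool$index$object_id
  same <- outer(obj, obj, `==`) & upper.tri(cc)
  diff <- outer(obj, obj, `!=`) & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))

  expect_error(generate_oddity_pool(1, 5, 32), class = "vvsreadout_invalid_argument")
  expect_error(generate_oddity_pool(8, 3, 32), class = "vvsreadout_invalid_argument")
})

test_that("synthetic object features have the stated geometry", {
  sf <- synthetic_object_features(4, 6, 8, separation = 5, noise_sd = 0.1, seed = 1)
  expect_equal(nrow(sf$features$matrix), 24)
  # prototypes have norm `separation`
  proto <- colMeans(sf$features$matrix[sf$index$object_id == "obj001", ])
  expect_equal(sqrt(sum(proto^2)), 5, tolerance = 0.1)
  # separation 0 removes object structure
  sf0 <- synthetic_object_features(4, 6, 8, separation = 0, noise_sd = 1, seed = 1)
  ct <- stats::cor(t(sf0$features$matrix))
  obj <- sf0$index$object_id
  expect_lt(abs(mean(ct[outer(obj, obj, `==`) & upper.tri(ct)])), 0.25)
})
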