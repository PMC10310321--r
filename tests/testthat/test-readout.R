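test_that("a separable 1-D feature yields perfect held-out predictions", {
  y <- rep(c(0L, 1L), each = 20)
  x <- matrix(as.numeric(y), ncol = 1)
  model <- train_readout(x, y, readout_config(seed = 1))
  expect_equal(predict(model, matrix(c(0, 1), ncol = 1), type = "label"),
               c(0L, 1L))
  expect_gt(model$chosen_c, 0)
})

test_that("degenerate all-zero features fall back to the training base rate", {
  y <- c(rep(0L, 30), rep(1L, 10))  # base rate 0.25
  x <- matrix(0, 40, 3)
  model <- train_readout(x, y, readout_config(seed = 2))
  p <- predict(model, matrix(0, 5, 3), type = "prob")
  expect_equal(p, rep(0.25, 5), tolerance = 1e-6)
})

test_that("single-class training sets are refused naming the missing class", {
  x <- matrix(stats::rnorm(20), 10, 2)
  expect_error(train_readout(x, rep(1L, 10), readout_config()), "cat")
  expect_error(train_readout(x, rep(0L, 10), readout_config()), "dog")
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(5)
  x <- matrix(stats::rnorm(60 * 5), 60, 5)
  y <- rep(c(0L, 1L), 30)
  acc <- replicate(100, {
    yp <- sample(y)
    tr <- sample(60, 48)
    m <- train_readout(x[tr, ], yp[tr], readout_config(c_grid = 1, seed = 1))
    mean(predict(m, x[-tr, ], type = "label") == yp[-tr])
  })
  n_total <- 100 * 12
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / n_total) + 0.02)
})

test_that("random splits record the configured iterations, deterministically", {
  st <- fx_stimuli()
  fm <- fx_features("fc7")
  cfg <- readout_config(n_iterations = 12, seed = 3)
  rr <- evaluate_random_splits(fm, st, cfg)
  expect_gte(length(unique(rr$iterations$iteration)), 12)
  rr2 <- evaluate_random_splits(fm, st, cfg)
  expect_identical(rr$iterations, rr2$iterations)
  # predictions recorded only for held-out images; every image held out
  expect_setequal(unique(rr$iterations$image_id), st$index$image_id)
  per_iter <- split(rr$iterations$image_id, rr$iterations$iteration)
  expect_true(all(vapply(per_iter, anyDuplicated, integer(1)) == 0))
  # no iteration holds out everything (a train set always exists)
  expect_true(all(lengths(per_iter) < nrow(st$index)))
})

test_that("stratification falls back with a message when a level is singleton", {
  st <- generate_morph_stimuli(1, 11, 64, 0.9, seed = 4)
  fm <- flatten_pixels(st, resize_to = 16)
  cfg <- readout_config(n_iterations = 3, seed = 5)
  expect_message(evaluate_random_splits(fm, st, cfg), "unstratified")
})

test_that("sequence holdout rotates every sequence out exactly once", {
  st <- fx_stimuli()
  fm <- fx_features("fc7")
  rr <- evaluate_sequence_holdout(fm, st, readout_config(seed = 6))
  expect_equal(rr$n_iterations, 7)
  expect_equal(sort(table(rr$iterations$image_id)), sort(rep(1L, 77)),
               ignore_attr = TRUE)
  # train and test sequences disjoint in every fold
  seq_of <- st$index$sequence_id[match(rr$iterations$image_id, st$index$image_id)]
  expect_true(all(tapply(seq_of, rr$iterations$iteration,
                         function(s) length(unique(s)) == 1)))
  st1 <- generate_morph_stimuli(1, 11, 64, 0.9, seed = 4)
  expect_error(evaluate_sequence_holdout(flatten_pixels(st1, resize_to = 16), st1),
               ">= 2 morph sequences")
})

test_that("morph-level aggregation matches an independent groupby oracle", {
  df <- data.frame(morph_level_pct = c(10, 10, 10, 10, 20),
                   response = c(1L, 0L, 1L, 0L, 1L),
                   subject_id = "s")
  agg <- aggregate_morph_level(df)
  expect_equal(agg$prop_dog[agg$morph_level_pct == 10], 0.5)

  st <- fx_stimuli40()
  ch <- simulate_observer(st, observer_params(slope = 0.1, seed = 11), n_reps = 6)
  agg <- aggregate_morph_level(ch)
  oracle <- tapply(ch$response, ch$morph_level_pct, mean)
  expect_equal(agg$prop_dog, as.numeric(oracle[as.character(agg$morph_level_pct)]),
               tolerance = 1e-12)

  # slope-0 observer: ~0.5 at every level
  ch0 <- simulate_observer(st, observer_params(slope = 0, image_effect_sd = 0,
                                               lapse = 0, seed = 12),
                           n_reps = 50)
  agg0 <- aggregate_morph_level(ch0)
  expect_true(all(abs(agg0$prop_dog - 0.5) < 3 * sqrt(0.25 / (50 * 4))))
  expect_error(aggregate_morph_level(df[0, ]), "empty")
})
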