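test_that("a deterministic observer has split-half reliability exactly 1", {
  # 4 levels, all far from the boundary: responses are fully deterministic
  st <- generate_morph_stimuli(4, 4, 32, 0.9, seed = 21)
  par <- observer_params(slope = 10, bias = 50, lapse = 0, image_effect_sd = 0,
                         seed = 1)
  ch <- simulate_observer(st, par, n_reps = 8)
  rel <- split_half_reliability(ch, "image", n_iter = 20, seed = 2)
  expect_equal(rel$values, rep(1, 20))
  relm <- split_half_reliability(ch, "morph", n_iter = 20, seed = 2)
  expect_equal(relm$values, rep(1, 20))
})

test_that("insufficient repetitions are refused, mirroring the exclusion rule", {
  st <- fx_stimuli40()
  ch <- simulate_observer(st, observer_params(seed = 3), n_reps = 4)
  expect_error(split_half_reliability(ch, "image"), "insufficient repetitions")
  # configurable floor admits them
  expect_s3_class(split_half_reliability(ch, "image", n_iter = 5, min_reps = 2),
                  "reliability_distribution")
  ch1 <- simulate_observer(st, observer_params(seed = 3), n_reps = 1)
  expect_error(split_half_reliability(ch1, "image", min_reps = 2),
               class = "vvsreadout_invalid_argument")
})

test_that("between-subject consistency of identical data matches within-subject", {
  st <- fx_stimuli40()
  ch <- simulate_observer(st, observer_params(image_effect_sd = 1.5, seed = 4),
                          n_reps = 10, subject_id = "s1")
  within <- split_half_reliability(ch, "image", n_iter = 100, seed = 5)
  twin <- ch
  twin$subject_id <- "s2"
  between <- between_subject_consistency(ch, twin, "image", n_iter = 100, seed = 6)
  ks <- suppressWarnings(stats::ks.test(within$values, between$values))
  expect_gt(ks$p.value, 0.01)

  other <- simulate_observer(generate_morph_stimuli(2, 5, 32, 0.9, seed = 30,
                                                    experiment_id = "exp9"),
                             observer_params(seed = 7), n_reps = 10,
                             subject_id = "s3")
  expect_error(between_subject_consistency(ch, other, "image"),
               "share no items")
})

test_that("within-subject reliability dominates between-subject consistency", {
  st <- fx_stimuli40()
  ok <- vapply(1:5, function(s) {
    c1 <- simulate_observer(st, observer_params(image_effect_sd = 1.5,
                                                seed = 100 + s),
                            n_reps = 10, subject_id = "a")
    c2 <- simulate_observer(st, observer_params(image_effect_sd = 1.5,
                                                seed = 200 + s),
                            n_reps = 10, subject_id = "b")
    w <- split_half_reliability(c1, "image", n_iter = 60, seed = s)$median
    b <- between_subject_consistency(c1, c2, "image", n_iter = 60, seed = s)$median
    w >= b
  }, logical(1))
  expect_true(all(ok))
})

test_that("reliability grows toward 1 with repetitions for idiosyncratic observers", {
  st <- fx_stimuli40()
  meds <- vapply(c(4, 8, 16, 64), function(reps) {
    ch <- simulate_observer(st, observer_params(slope = 0, image_effect_sd = 1,
                                                seed = 31),
                            n_reps = reps)
    split_half_reliability(ch, "image", n_iter = 60, seed = 32,
                           min_reps = 2)$median
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  # at 64 reps residual binomial noise still caps the median squared
  # correlation well below 1, but far above the 4-rep level
  expect_gt(meds[4], meds[1] + 0.3)
  expect_gt(meds[4], 0.6)
})

test_that("model-behavior regression reports slope, R2 and the right df", {
  set.seed(33)
  m <- stats::runif(23)
  s <- fit_model_to_behavior(m, m)
  expect_equal(s$beta, 1, tolerance = 1e-10)
  expect_equal(s$r_squared, 1, tolerance = 1e-10)
  s2 <- fit_model_to_behavior(m, 2 * m + 1)
  expect_equal(s2$beta, 2, tolerance = 1e-10)
  expect_equal(s2$r_squared, 1, tolerance = 1e-10)
  expect_equal(s2$df, 21)  # 23 points -> df = n - 2
  expect_error(fit_model_to_behavior(rep(0.5, 10), stats::runif(10)),
               "zero-variance")
  expect_error(fit_model_to_behavior(m[1:2], m[1:2]), "n >= 3")
})

test_that("empirical percentiles count the reference mass at or below the fit", {
  ref <- seq(0.1, 1, by = 0.1)
  expect_equal(empirical_percentile(0.55, ref), 0.5)
  expect_equal(empirical_percentile(0.01, ref), 0)
  expect_equal(empirical_percentile(1, ref), 1)
  # odd-length reference, fit at the median
  ref9 <- seq_len(9) / 10
  expect_equal(empirical_percentile(0.5, ref9), 5 / 9)
  # vector of model fits: median percentile
  expect_equal(empirical_percentile(c(0.15, 0.55, 0.95), ref), 0.5)
  expect_error(empirical_percentile(0.5, numeric(0)), "empty")
})

test_that("group-curve comparison tests the group indicator on stacked points", {
  set.seed(34)
  curve <- expand.grid(experiment_id = paste0("exp", 1:4),
                       morph_level_pct = seq(0, 100, by = 10))
  curve$prop_dog <- stats::runif(44)
  # identical groups: zero difference, zero explained variance, large p
  s <- compare_groups(curve, curve)
  expect_equal(s$beta, 0, tolerance = 1e-12)
  expect_equal(s$r_squared, 0, tolerance = 1e-12)
  expect_equal(s$df, c(1, 86))  # 44 aligned points per group -> 88 stacked
  expect_gt(s$p, 0.99)
  # a shifted group is detected
  curve_up <- transform(curve, prop_dog = pmin(prop_dog + 0.3, 1))
  s2 <- compare_groups(curve, curve_up)
  expect_gt(s2$beta, 0.1)
  expect_lt(s2$p, 0.01)
  expect_error(compare_groups(curve, curve_up[-1, ]), "identical")
})
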