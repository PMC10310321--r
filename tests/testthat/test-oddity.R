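make_sample <- function(index, oi = "obj001", oj = "obj002", seed = 1) {
  vi <- index$image_id[index$object_id == oi]
  vj <- index$image_id[index$object_id == oj]
  withr::with_seed(seed, {
    oddity_trial(sample(vi, 2), sample(vj, 1), oi, oj,
                 oddity_slot = sample.int(3, 1))
  })
}

test_that("pseudo experiments exclude the sample and preserve object roles", {
  sf <- synthetic_object_features(4, 12, 8, separation = 1, seed = 1)
  smp <- make_sample(sf$index)
  trials <- build_pseudo_experiments(smp, sf$index, n_trials = 52, seed = 2)
  expect_length(trials, 52)
  used <- unlist(lapply(trials, `[[`, "slots"))
  expect_length(intersect(used, smp$slots), 0)
  expect_true(all(vapply(trials, `[[`, character(1), "pair_object") == "obj001"))
  expect_true(all(vapply(trials, `[[`, character(1), "oddity_object") == "obj002"))
  # within a trial the three views are distinct
  expect_true(all(vapply(trials, function(tr) anyDuplicated(tr$slots) == 0,
                         logical(1))))
  # insufficient views beyond the sample
  sf_small <- synthetic_object_features(2, 5, 8, seed = 3)
  smp2 <- make_sample(sf_small$index)
  expect_error(build_pseudo_experiments(smp2, sf_small$index),
               class = "vvsreadout_invalid_argument")
})

test_that("the oddity position is uniform over the three slots", {
  sf <- synthetic_object_features(2, 12, 8, seed = 4)
  smp <- make_sample(sf$index)
  trials <- build_pseudo_experiments(smp, sf$index, n_trials = 999, seed = 5)
  slots <- vapply(trials, `[[`, integer(1), "oddity_slot")
  expect_gt(stats::chisq.test(table(factor(slots, levels = 1:3)))$p.value, 0.01)
})

test_that("trial outcomes are deterministic and separable cases are easy", {
  sf <- synthetic_object_features(4, 12, 16, separation = 10, noise_sd = 0.5,
                                  seed = 6)
  smp <- make_sample(sf$index)
  out <- estimate_trial_outcome(smp, sf$features, sf$index, n_pseudo = 10, seed = 7)
  expect_gte(out, 0.95)
  out2 <- estimate_trial_outcome(smp, sf$features, sf$index, n_pseudo = 10, seed = 7)
  expect_identical(out, out2)
  # missing feature rows produce an informative error
  fm_sub <- vvsreadout:::new_feature_matrix(
    sf$features$matrix[1:5, ], sf$features$image_ids[1:5], "test")
  expect_error(estimate_trial_outcome(smp, fm_sub, sf$index, n_pseudo = 2),
               "missing")
})

test_that("object aggregation matches direct arithmetic", {
  out <- data.frame(
    pair_object = c("a", "a", "b", "c"),
    oddity_object = c("b", "c", "a", "a"),
    outcome = c(0.5, 1, 0.25, 0)
  )
  pv <- aggregate_objects(out)
  expect_equal(as.numeric(pv[c("a", "b", "c")]), c(0.75, 0.25, 0))
  expect_equal(as.numeric(aggregate_objects(transform(out, outcome = 1))),
               rep(1, 3))
  expect_error(aggregate_objects(out[0, ]), "no trial outcomes")
  expect_error(aggregate_objects(out, objects = c("a", "d")), "d")
})

test_that("performance-vector comparisons report the stated statistics", {
  set.seed(8)
  a <- structure(stats::runif(32, 0.4, 0.9), names = sprintf("o%02d", 1:32),
                 class = "performance_vector")
  s_slope <- compare_performance_vectors(a, a, mode = "slope")
  expect_equal(s_slope$beta, 1, tolerance = 1e-10)
  expect_equal(s_slope$df, c(1, 30))  # N = 32 objects
  s_pair <- compare_performance_vectors(a, a, mode = "paired_difference")
  expect_equal(s_pair$beta, 0)
  expect_equal(s_pair$statistic, 0)
  expect_equal(s_pair$df, 31)

  # recovery of a constant offset
  b <- a + 0.2 + stats::rnorm(32, 0, 0.05)
  s <- compare_performance_vectors(a, b, mode = "paired_difference")
  ci_half <- stats::qt(0.975, 31) * stats::sd(b - a) / sqrt(32)
  expect_lt(abs(s$beta - 0.2), ci_half)

  names(b)[1] <- "other"
  expect_error(compare_performance_vectors(a, b), "identical object sets")
})
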