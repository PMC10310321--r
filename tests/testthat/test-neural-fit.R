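test_that("noiseless linear targets are recovered essentially perfectly", {
  set.seed(1)
  X <- matrix(stats::rnorm(80 * 10), 80, 10)
  W <- matrix(stats::rnorm(10 * 4), 10, 4)
  Y <- X %*% W
  fit <- fit_electrode_map(X, Y, seed = 1)
  expect_true(all(fit$r >= 0.999))
  # duplicate feature columns do not change predictions (ridge tolerates collinearity)
  fit_dup <- fit_electrode_map(cbind(X, X), Y, seed = 1)
  expect_equal(fit_dup$predictions, fit$predictions, tolerance = 1e-4)
})

test_that("pure-noise electrodes fit at chance", {
  set.seed(2)
  X <- matrix(stats::rnorm(60 * 15), 60, 15)
  Y <- matrix(stats::rnorm(60 * 50), 60, 50)
  fit <- fit_electrode_map(X, Y, seed = 2)
  se <- stats::sd(fit$r) / sqrt(length(fit$r))
  expect_lt(abs(mean(fit$r)), 3 * se)
})

test_that("the SVD ridge path agrees with a direct normal-equations solve", {
  set.seed(3)
  Xtr <- matrix(stats::rnorm(30 * 6), 30, 6)
  Ytr <- matrix(stats::rnorm(30 * 2), 30, 2)
  Xte <- matrix(stats::rnorm(10 * 6), 10, 6)
  lambdas <- c(0.1, 10)
  got <- vvsreadout:::ridge_predict_path(Xtr, Ytr, Xte, lambdas)
  # oracle: standardize, center, solve (X'X + lambda I) b = X'y directly
  mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
  Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
  Xts <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
  for (li in seq_along(lambdas)) {
    for (e in 1:2) {
      yc <- Ytr[, e] - mean(Ytr[, e])
      b <- solve(crossprod(Xs) + diag(lambdas[li], 6), crossprod(Xs, yc))
      expect_equal(got[, li, e], as.vector(Xts %*% b) + mean(Ytr[, e]),
                   tolerance = 1e-8)
    }
  }
})

test_that("held-out responses never influence held-out predictions", {
  set.seed(4)
  X <- matrix(stats::rnorm(50 * 8), 50, 8)
  y <- X %*% stats::rnorm(8) + stats::rnorm(50, 0, 0.5)
  fit <- fit_electrode_map(X, y, seed = 9)
  f1 <- which(fit$fold == 1)
  y2 <- y
  y2[f1] <- sample(y2[f1])  # shuffle only fold 1's held-out responses
  fit2 <- fit_electrode_map(X, y2, seed = 9)
  expect_equal(fit2$fold, fit$fold)
  # predictions for fold 1 come only from the other folds' data
  expect_equal(fit2$predictions[f1, 1], fit$predictions[f1, 1], tolerance = 1e-10)
})

test_that("noise correction follows r / sqrt(reliability) with a floor", {
  expect_equal(suppressMessages(noise_correct(0.4, 0.64)), 0.5)
  expect_equal(suppressMessages(noise_correct(0.7, 1)), 0.7)
  expect_message(out <- noise_correct(c(0.4, 0.3), c(0.64, 0.05)), "excluding")
  expect_true(is.na(out[2]))
  expect_warning(suppressMessages(noise_correct(0.6, 0.25)), "exceed 1")
})

test_that("layer-half contrasts have the right df and null behavior", {
  lf <- data.frame(layer = paste0("L", 1:10), region_label = "V4-like",
                   median_r_corrected = rep(0.5, 10), dispersion = 0.1,
                   n_electrodes = 8)
  s <- contrast_layer_halves(lf)
  expect_equal(s$statistic, 0)
  expect_equal(s$df, 8)  # 10 layers -> df = n_layers - 2
  expect_gt(s$p, 0.99)
  expect_error(contrast_layer_halves(lf[1:3, ]), "2 layers")
})

test_that("peak-layer selection breaks ties toward the earlier layer", {
  lf <- data.frame(layer = c("a", "b", "c"), region_label = "IT-like",
                   median_r_corrected = c(0.8, 0.9, 0.9), dispersion = 0.1,
                   n_electrodes = 8)
  expect_equal(select_peak_layer(lf)$layer, "b")
  lf$median_r_corrected <- c(0.7, 0.7, 0.7)
  expect_equal(select_peak_layer(lf)$layer, "a")
  expect_equal(select_peak_layer(lf[2, ])$layer, "b")
  expect_error(select_peak_layer(lf[0, ]), "no layer")
})

test_that("early-layer electrodes make the early half significantly better", {
  fb <- fx_pool_features()
  nsd <- sqrt(8 * (1 / 0.7 - 1))
  es <- simulate_electrodes(fb[["conv1"]], 16, 8, nsd, seed = 300,
                            region_label = "V4-like")
  lf <- suppressMessages(fit_layers(fb, es, seed = 9))
  s <- contrast_layer_halves(lf)
  expect_gt(s$beta, 0)
  expect_lt(s$p, 0.05)
  expect_equal(s$df, 8)
})
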