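test_that("spline interpolation fixes length, preserves endpoints and lines", {
  tg <- seq(0, 89)
  cc <- gamma_variate(tg, gamma_params(2, 5, 3, 1.5))
  out <- interpolate_curve(cc)
  expect_length(out, 500L)
  expect_equal(out$values[1], cc$values[1], tolerance = 1e-12)
  expect_equal(out$values[500], cc$values[length(tg)], tolerance = 1e-12)
  ramp <- conc_curve(tg, 0.3 * tg + 1)
  rout <- interpolate_curve(ramp, 200)
  expect_equal(rout$values, 0.3 * rout$times + 1, tolerance = 1e-9)
  expect_error(interpolate_curve(conc_curve(0:2, c(0, 1, 0))), "at least 4")
})

test_that("augmentation yields exactly three transformed pairs per source", {
  bank <- fixture_bank()
  expect_length(bank$pairs, 384L)
  aug <- fixture_train_pairs()
  expect_length(aug, 3L * 384L)
  expect_length(aug, 1152L)
  with_orig <- augment_pairs(bank$pairs[1:5], seed = 1, include_originals = TRUE)
  expect_length(with_orig, 20L)
})

test_that("mirroring is an involution and zero rotation is the identity", {
  p <- fixture_bank()$pairs[[1]]
  mir2 <- ctperf:::rotate_pair(p, 0)
  expect_equal(mir2$input, p$input, tolerance = 1e-9)
  expect_equal(mir2$label, p$label, tolerance = 1e-9)
  once <- curve_pair(p$times, rev(p$input), rev(p$label))
  twice <- curve_pair(p$times, rev(once$input), rev(once$label))
  expect_identical(twice$input, p$input)
  expect_identical(twice$label, p$label)
})

test_that("model building is seeded and architecture dimensions check out", {
  cfg <- cnn_config(seed = 9)
  m1 <- build_cnn(cfg)
  m2 <- build_cnn(cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$n_params, m2$n_params)
  expect_equal(ncol(m1$params$Wd2), 500L)
  # softmax output sums to one on any input
  x <- matrix(runif(500), 1)
  fw <- ctperf:::cnn_forward(m1$params, x, cfg)
  expect_equal(sum(fw$prob), 1, tolerance = 1e-6)
  expect_true(all(fw$prob >= 0))
  # inconsistent pooling is rejected
  expect_error(cnn_config(input_length = 5, pool_size = 10), "pooling")
})

test_that("the network overfits a single batch to near-zero loss", {
  pairs <- fixture_train_pairs()[1:32]
  model <- build_cnn(cnn_config(seed = 3))
  model <- train_cnn(model, pairs, epochs = 300)
  expect_lt(tail(model$history, 1), 0.05)
  expect_lt(tail(model$history, 1), model$history[1] / 10)
})

test_that("training reduces the loss and predictions are valid curves", {
  model <- fixture_model()
  expect_true(model$trained)
  expect_lt(tail(model$history, 1), model$history[1])
  p <- fixture_val_bank()$pairs[[1]]
  pred <- predict_aif(model, conc_curve(p$times, p$input))
  expect_true(all(is.finite(pred$values)))
  expect_true(all(pred$values >= 0))
  expect_identical(pred$times, p$times)
})

test_that("an untrained model refuses to predict", {
  m <- build_cnn(cnn_config(seed = 1))
  cc <- gamma_variate(seq(0, 89), gamma_params(2, 5, 3, 1.5))
  expect_error(predict_aif(m, cc), "untrained")
})

test_that("a clean gamma curve passes through the network nearly unchanged", {
  model <- fixture_model()
  tg <- seq(0, 89)
  p <- gamma_params(2.2, 6, 3, 1.6)
  clean <- conc_curve(tg, gamma_eval(tg, p$K, p$AT, p$alpha, p$beta) +
                        gamma_eval(tg, 0.35, 31, 3, 3))
  pred <- predict_aif(model, clean)
  lab <- suppressWarnings(fit_gamma(clean))
  label <- gamma_eval(tg, lab$K, lab$AT, lab$alpha, lab$beta)
  expect_lt(rmse(pred$values, label), 0.10 * max(label))
})

test_that("baseline drift is removed from the predicted curve", {
  model <- fixture_model()
  tg <- seq(0, 89)
  clean <- conc_curve(tg, gamma_eval(tg, 2.2, 8, 3, 1.5) +
                        gamma_eval(tg, 0.35, 33, 3, 3))
  drifted <- distort_aif(clean, distortion_params(baseline_slope = 0.05),
                         seed = 4)
  pred <- predict_aif(model, drifted)
  fp <- first_passage(pred)
  pre <- seq_len(max(fp$arrival - 1L, 1L))
  expect_lt(mean(pred$values[pre]), 0.05 * max(pred$values))
})

test_that("curve banks round-trip through the on-disk container", {
  bank <- list(pairs = fixture_bank()$pairs[1:4])
  dir <- withr::local_tempdir()
  write_curve_bank(bank, dir)
  back <- read_curve_bank(dir)
  expect_length(back$pairs, 4L)
  expect_equal(back$pairs[[2]]$input, bank$pairs[[2]]$input, tolerance = 1e-6)
  expect_equal(back$pairs[[2]]$label, bank$pairs[[2]]$label, tolerance = 1e-6)
})
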