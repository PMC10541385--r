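test_that("gamma variate is zero up to arrival and matches the closed-form peak", {
  p <- gamma_params(K = 1, AT = 5, alpha = 3, beta = 1.5)
  cc <- gamma_variate(seq(0, 40, 0.5), p)
  expect_equal(cc$values[cc$times <= 5], rep(0, sum(cc$times <= 5)))
  expect_true(all(cc$values >= 0))

  # stationary point: dense numerical evaluation against the closed form
  dense <- gamma_variate(seq(5, 15, 1e-4), p)
  peak_num <- max(dense$values)
  t_num <- dense$times[which.max(dense$values)]
  expect_equal(t_num, gamma_peak_time(p), tolerance = 1e-3)
  expect_equal(peak_num, gamma_peak_value(p), tolerance = 1e-6)
  expect_equal(gamma_peak_value(p), 1 * (3 * 1.5)^3 * exp(-3), tolerance = 1e-12)
})

test_that("gamma variate rejects invalid parameters and grids", {
  expect_error(gamma_params(1, 5, -1, 1.5), "alpha")
  expect_error(gamma_params(1, 5, 3, 0), "beta")
  expect_error(gamma_params(-1, 5, 3, 1.5), "K")
  expect_error(gamma_variate(c(0, 2, 1), gamma_params(1, 5, 3, 1.5)),
               "strictly increasing")
})

test_that("gamma curves are unimodal beyond arrival with the peak on-grid", {
  grid <- expand.grid(K = c(0.5, 2), AT = c(2, 10), alpha = c(2, 5),
                      beta = c(1, 3))
  tg <- seq(0, 60, 0.5)
  for (i in seq_len(nrow(grid))) {
    p <- gamma_params(grid$K[i], grid$AT[i], grid$alpha[i], grid$beta[i])
    cc <- gamma_variate(tg, p)
    post <- cc$values[cc$times > p$AT]
    ip <- which.max(post)
    expect_true(all(diff(post[seq_len(ip)]) >= 0))
    expect_true(all(diff(post[ip:length(post)]) <= 0))
    expect_lt(abs(cc$times[cc$times > p$AT][ip] - gamma_peak_time(p)), 0.5 + 1e-9)
  }
})

test_that("fitting noiseless curves recovers the generating parameters", {
  tg <- seq(0, 60)
  for (K in c(0.5, 1, 2)) for (AT in c(2, 5, 10)) for (alpha in c(2, 3, 5))
    for (beta in c(1, 1.5, 3)) {
      p <- gamma_params(K, AT, alpha, beta)
      fit <- fit_gamma(gamma_variate(tg, p))
      rel <- abs(c(fit$K - K, fit$AT - AT, fit$alpha - alpha, fit$beta - beta) /
                   c(K, AT, alpha, beta))
      expect_lt(max(rel), 1e-3)
    }
})

test_that("a restricted fit window excludes a recirculation bump", {
  tg <- seq(0, 60)
  p <- gamma_params(1, 5, 3, 1.5)
  cc <- gamma_variate(tg, p)
  bump <- gamma_eval(tg, 0.4, 32, 3, 4)
  noisy <- conc_curve(tg, cc$values + bump)
  fit <- fit_gamma(noisy, fit_window = c(0, 25))
  expect_lt(abs(fit$AT - 5) / 5, 0.05)
  expect_lt(abs(fit$alpha - 3) / 3, 0.05)
  expect_lt(abs(fit$beta - 1.5) / 1.5, 0.05)
})

test_that("degenerate curves are rejected", {
  tg <- seq(0, 30)
  expect_error(fit_gamma(conc_curve(tg, rep(0, length(tg)))), "degenerate")
  expect_error(fit_gamma(conc_curve(tg, rep(3, length(tg)))), "degenerate")
  short <- gamma_variate(seq(0, 3), gamma_params(1, 0.5, 2, 0.5))
  expect_error(fit_gamma(short), "at least 8")
})

test_that("parameter recovery is robust to additive noise at SNR 20", {
  # The shape/timing parameters and the identifiable amplitude (the fitted
  # peak value) are recovered to better than 10% in median. The raw scale
  # factor K is excluded: it trades off against alpha and beta, and its
  # Cramer-Rao bound at this noise level already exceeds 10%, so no
  # estimator can pin it down (see the methods vignette).
  tg <- seq(0, 60, 0.5)
  p <- gamma_params(1, 5, 2, 3)
  clean <- gamma_variate(tg, p)
  sigma <- gamma_peak_value(p) / 20
  set.seed(202)
  E <- t(replicate(100, {
    noisy <- conc_curve(tg, clean$values + rnorm(length(tg), 0, sigma))
    fit <- suppressWarnings(fit_gamma(noisy))
    c(abs(fit$AT - p$AT) / p$AT,
      abs(fit$alpha - p$alpha) / p$alpha,
      abs(fit$beta - p$beta) / p$beta,
      abs(gamma_peak_value(fit) - gamma_peak_value(p)) / gamma_peak_value(p))
  }))
  expect_true(all(apply(E, 2, median) < 0.10))
})
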