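ca_test <- function(tg = seq(0, 89)) {
  conc_curve(tg, gamma_eval(tg, 2.2, 5, 3, 1.5) + gamma_eval(tg, 0.35, 30, 3, 3))
}

test_that("deconvolving a zero tissue curve gives a zero residue", {
  ca <- ca_test()
  rf <- deconvolve(conc_curve(ca$times, numeric(length(ca$times))), ca)
  expect_equal(max(abs(rf$values)), 0, tolerance = 1e-10)
  expect_equal(compute_cbf(rf), 0)
})

test_that("a zero-area AIF is rejected", {
  tg <- seq(0, 20)
  expect_error(deconv_operator(conc_curve(tg, numeric(length(tg)))), "zero area")
})

test_that("boxcar forward construction recovers flow height and traces delays", {
  ca <- ca_test()
  tg <- ca$times
  FF <- 0.008
  r0 <- as.numeric(tg >= 0 & tg < 6) * FF
  ct0 <- conc_curve(tg, conv_forward(ca$values, r0, 1))
  rf0 <- deconvolve(ct0, ca)
  expect_lt(abs(max(rf0$values) - FF) / FF, 0.05)
  # delaying the tissue curve by 4 s moves the residue argmax by 4 s (+/- dt)
  r4 <- as.numeric(tg >= 4 & tg < 10) * FF
  ct4 <- conc_curve(tg, conv_forward(ca$values, r4, 1))
  rf4 <- deconvolve(ct4, ca)
  shift <- compute_tmax(rf4) - compute_tmax(rf0)
  expect_lte(abs(shift - 4), 1)
})

test_that("truncated-SVD deconvolution matches an explicit least-squares oracle", {
  # small problems, same truncation; oracle solves the kept singular subspace
  # by QR least squares, an independent computational path
  set.seed(31)
  for (n in c(8, 12, 16)) {
    tg <- seq(0, n - 1)
    ca <- conc_curve(tg, gamma_eval(tg, 1, 1, 2, 1.2) + 1e-3)
    ct <- conc_curve(tg, conv_forward(ca$values, exp(-tg / 3) * 0.01, 1))
    reg <- reg_config(method = "fixed", threshold = 0.1)
    rf <- deconvolve(ct, ca, reg)
    M <- 2L * n
    cap <- c(ca$values, numeric(n))
    A <- matrix(0, M, M)
    for (j in seq_len(M)) A[, j] <- cap[((seq_len(M) - j) %% M) + 1L]
    s <- svd(A)
    keep <- s$d > 0.1 * s$d[1]
    B <- A %*% s$v[, keep, drop = FALSE]
    z <- qr.solve(qr(B), c(ct$values, numeric(n)))
    oracle <- drop(s$v[, keep, drop = FALSE] %*% z)
    expect_lt(max(abs(rf$values - oracle)), 1e-6)
  }
})

test_that("CBF and Tmax read the residue maximum with earliest-tie rule", {
  rf <- structure(list(times = seq(0, 9), values = c(0, 0, 1, 3, 1, 0, 0, 0, 0, 0)),
                  class = "residue_fn")
  expect_equal(compute_tmax(rf), 3)
  expect_equal(compute_cbf(rf, scale = 10), 30)
  rf2 <- rf; rf2$values <- rf$values * 2
  expect_equal(compute_cbf(rf2), 2 * compute_cbf(rf))
  flat <- structure(list(times = seq(0, 9), values = rep(2, 10)),
                    class = "residue_fn")
  expect_equal(compute_tmax(flat), 0)
  zero <- structure(list(times = seq(0, 9), values = numeric(10)),
                    class = "residue_fn")
  expect_equal(compute_cbf(zero), 0)
})

test_that("tissue delay shifts Tmax without corrupting CBF (delay insensitivity)", {
  ca <- ca_test()
  tg <- ca$times
  FF <- 0.0075
  base <- exp(-tg / 5) * FF
  ct0 <- conc_curve(tg, conv_forward(ca$values, base, 1))
  rf0 <- deconvolve(ct0, ca)
  for (k in c(3, 6, 9)) {
    rk <- c(numeric(k), base)[seq_along(tg)]
    ctk <- conc_curve(tg, conv_forward(ca$values, rk, 1))
    rfk <- deconvolve(ctk, ca)
    expect_lte(abs((compute_tmax(rfk) - compute_tmax(rf0)) - k), 1)
    expect_lt(abs(compute_cbf(rfk) - compute_cbf(rf0)) / compute_cbf(rf0), 0.10)
  }
})

test_that("CBF recovery degrades as the measured AIF peak is attenuated", {
  ph <- fixture_phantom_noiseless()
  ca <- ph$truth$aif_clean
  idx <- which(ph$truth$penumbra_mask_true, arr.ind = TRUE)[1, ]
  ct <- voxel_curve(ph$study, idx)
  cbf_true <- ph$truth$cbf_true[idx[1], idx[2], idx[3]]
  errs <- vapply(c(1, 0.8, 0.6, 0.4), function(pa) {
    aif <- distort_aif(ca, distortion_params(peak_attenuation = pa), seed = 2)
    abs(compute_cbf(deconvolve(ct, aif)) - cbf_true) / cbf_true
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-9))
})

test_that("map computation is deterministic and handles empty signal", {
  ph <- fixture_phantom_noiseless()
  aif <- ph$truth$aif_clean
  m1 <- compute_maps(ph$study, aif)
  m2 <- compute_maps(ph$study, aif)
  expect_identical(m1$cbf, m2$cbf)
  expect_identical(m1$tmax, m2$tmax)
  # all-zero volume -> all-zero maps
  z <- ph$study
  z$volume[] <- 0
  mz <- compute_maps(z, aif)
  expect_equal(max(abs(mz$cbf)), 0, tolerance = 1e-9)
  # mismatched AIF grid is rejected
  bad <- conc_curve(ph$study$times[-1], aif$values[-1])
  expect_error(compute_maps(ph$study, bad), "time grid")
})

test_that("noiseless phantom maps recover true CBF in the lesion", {
  ph <- fixture_phantom_noiseless()
  maps <- compute_maps(ph$study, ph$truth$aif_clean)
  lesioned <- ph$truth$penumbra_mask_true
  rel <- abs(maps$cbf[lesioned] - ph$truth$cbf_true[lesioned]) /
    ph$truth$cbf_true[lesioned]
  expect_lt(median(rel), 0.10)
})
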