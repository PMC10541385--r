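test_that("identical seeds give bit-identical phantoms", {
  cfg <- phantom_config(dims = c(24, 24, 2), n_frames = 40,
                        lesion_center = c(17, 12, 1.5),
                        penumbra_radii = c(4, 5, 1),
                        core_radii = c(2, 2.5, 0.8))
  a <- generate_phantom(cfg, seed = 7)
  b <- generate_phantom(cfg, seed = 7)
  expect_identical(a$study$volume, b$study$volume)
  expect_identical(a$truth$cbf_true, b$truth$cbf_true)
  c2 <- generate_phantom(cfg, seed = 8)
  expect_false(identical(a$study$volume, c2$study$volume))
})

test_that("phantom geometry bookkeeping is exact", {
  ph <- fixture_phantom_noiseless()
  truth <- ph$truth
  study <- ph$study
  expect_true(all(truth$penumbra_mask_true[truth$core_mask_true]))
  expect_true(any(truth$penumbra_mask_true & !truth$core_mask_true))
  expect_true(all(!(study$artery_mask & !study$brain_mask)))
  expect_true(all(truth$cbf_true >= 0))
  # volume in mL is voxel count times voxel volume
  voxel_mL <- prod(study$spacing) / 1000
  sc <- synth_clinical_scores(truth)
  expect_equal(sc$core_mL, sum(truth$core_mask_true) * voxel_mL)
  expect_equal(sc$penumbra_mL, sum(truth$penumbra_mask_true) * voxel_mL)
})

test_that("a lesion placed outside the brain is rejected", {
  cfg <- phantom_config(lesion_center = c(2, 2, 1))
  expect_error(generate_phantom(cfg, seed = 1), "outside the brain")
})

test_that("noiseless tissue voxels deconvolve back to their true CBF and delay", {
  ph <- fixture_phantom_noiseless()
  op <- deconv_operator(ph$truth$aif_clean)
  dt <- diff(ph$study$times)[1]
  for (msk in list(ph$truth$core_mask_true,
                   ph$truth$penumbra_mask_true & !ph$truth$core_mask_true)) {
    idx <- which(msk, arr.ind = TRUE)[1, ]
    rf <- deconvolve(voxel_curve(ph$study, idx), op)
    cbf_true <- ph$truth$cbf_true[idx[1], idx[2], idx[3]]
    delay_true <- ph$truth$delay_true[idx[1], idx[2], idx[3]]
    expect_lt(abs(compute_cbf(rf) - cbf_true) / cbf_true, 0.05)
    expect_lte(abs(compute_tmax(rf) - delay_true), 1.5 * dt)
  }
})

test_that("zero-strength distortion is the identity", {
  ca <- fixture_phantom_noiseless()$truth$aif_clean
  out <- distort_aif(ca, distortion_params(), seed = 1)
  expect_equal(out$values, ca$values, tolerance = 1e-12)
})

test_that("baseline drift adds exactly a linear ramp before arrival", {
  ca <- fixture_phantom_noiseless()$truth$aif_clean
  out <- distort_aif(ca, distortion_params(baseline_slope = 0.1), seed = 1)
  fp <- first_passage(ca)
  pre <- seq_len(fp$arrival - 1L)
  expect_equal(out$values[pre] - ca$values[pre], 0.1 * ca$times[pre],
               tolerance = 1e-9)
})

test_that("peak attenuation scales the first-pass peak", {
  ca <- fixture_phantom_noiseless()$truth$aif_clean
  out <- distort_aif(ca, distortion_params(peak_attenuation = 0.5), seed = 1)
  expect_equal(max(out$values), 0.5 * max(ca$values), tolerance = 0.05)
})

test_that("distortion severity decreases monotonically as attenuation vanishes", {
  ca <- fixture_phantom_noiseless()$truth$aif_clean
  errs <- vapply(c(0.4, 0.6, 0.8, 1.0), function(pa) {
    out <- distort_aif(ca, distortion_params(peak_attenuation = pa), seed = 5)
    rmse(out$values, ca$values)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("synthetic clinical scores are monotone in lesion volume and clamped", {
  small <- generate_phantom(phantom_config(lesion_scale = 0.7), seed = 1)$truth
  large <- generate_phantom(phantom_config(lesion_scale = 1.4), seed = 1)$truth
  s_small <- synth_clinical_scores(small)
  s_large <- synth_clinical_scores(large)
  expect_lte(s_small$nihss, s_large$nihss)
  expect_gte(s_small$aspects, s_large$aspects)
  expect_true(s_small$nihss >= 0 && s_small$nihss <= 42)
  expect_true(s_small$aspects >= 0 && s_small$aspects <= 10)
  # no core at all pins ASPECTS at the healthy ceiling
  healthy <- small
  healthy$core_mask_true <- array(FALSE, dim(small$core_mask_true))
  expect_identical(synth_clinical_scores(healthy, b = 5)$aspects, 10L)
})
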