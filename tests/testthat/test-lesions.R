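make_maps <- function(cbf, tmax, mask) {
  structure(list(cbf = cbf, tmax = tmax, mask = mask,
                 reg = reg_config(), scale = 6000, duration = 89),
            class = "perfusion_maps")
}

test_that("a uniform CBF map is its own reference", {
  dims <- c(10, 10, 2)
  mask <- array(TRUE, dims)
  maps <- make_maps(array(50, dims), array(0, dims), mask)
  study <- list(midline_axis = 1L, spacing = c(1, 1, 1), brain_mask = mask)
  expect_equal(as.numeric(reference_cbf(maps, study)), 50)
})

test_that("fully hypoperfused maps fall back to the whole-brain median", {
  dims <- c(10, 10, 2)
  mask <- array(TRUE, dims)
  maps <- make_maps(array(30, dims), array(12, dims), mask)
  study <- list(midline_axis = 1L, spacing = c(1, 1, 1), brain_mask = mask)
  expect_warning(ref <- reference_cbf(maps, study), "whole-brain")
  expect_equal(as.numeric(ref), 30)
})

test_that("volume conversion counts voxels times voxel volume", {
  dims <- c(40, 25, 10)          # 10,000 voxels at 1 mm^3
  mask <- array(TRUE, dims)
  cbf <- array(100, dims)
  cbf[seq_len(10000)] <- 1       # below every core threshold
  maps <- make_maps(cbf, array(0, dims), mask)
  study <- list(midline_axis = 1L, spacing = c(1, 1, 1), brain_mask = mask)
  res <- segment_lesions(maps, study, reference = 100)
  expect_equal(lesion_volume(res, "CBF < 30%"), 10)
  expect_equal(lesion_volume(res, "Tmax > 6 s"), 0)
})

test_that("no core is reported when CBF stays above all thresholds", {
  dims <- c(8, 8, 2)
  mask <- array(TRUE, dims)
  maps <- make_maps(array(60, dims), array(0, dims), mask)
  study <- list(midline_axis = 1L, spacing = c(2, 2, 5), brain_mask = mask)
  res <- segment_lesions(maps, study, reference = 100)
  for (lab in c("CBF < 20%", "CBF < 30%", "CBF < 38%"))
    expect_equal(lesion_volume(res, lab), 0)
  expect_error(segment_lesions(maps, study, reference = 0), "positive")
})

test_that("threshold families nest by construction", {
  ph <- fixture_phantom_noisy()
  maps <- compute_maps(ph$study, ph$truth$aif_clean)
  res <- segment_lesions(maps, ph$study)
  v <- function(l) lesion_volume(res, l)
  expect_true(v("Tmax > 10 s") <= v("Tmax > 8 s"))
  expect_true(v("Tmax > 8 s") <= v("Tmax > 6 s"))
  expect_true(v("Tmax > 6 s") <= v("Tmax > 4 s"))
  expect_true(v("CBF < 20%") <= v("CBF < 30%"))
  expect_true(v("CBF < 30%") <= v("CBF < 38%"))
})

test_that("phantom reference lands near the healthy CBF and core volume near truth", {
  ph <- fixture_phantom_noiseless()
  maps <- compute_maps(ph$study, ph$truth$aif_clean)
  ref <- reference_cbf(maps, ph$study)
  expect_lt(abs(as.numeric(ref) - 60) / 60, 0.10)
  res <- segment_lesions(maps, ph$study)
  true_mL <- sum(ph$truth$core_mask_true) * prod(ph$study$spacing) / 1000
  expect_lt(abs(lesion_volume(res, "CBF < 30%") - true_mL) / true_mL, 0.25)
})
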