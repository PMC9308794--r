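test_that("input-function convention: endpoint average above the V1 baseline", {
  expect_equal(compute_c_in(100, 700), 300)
  expect_equal(compute_c_in(100, 700, baseline = 50), 350)
  expect_error(suppressWarnings(compute_c_in(100, 100)), "non-positive")
})

test_that("series-average input function reduces to the endpoint value on a line", {
  curve <- 45 + seq(0, 400, length.out = 7)
  expect_equal(compute_c_in_series(curve, 1, 7), 200)
  expect_equal(compute_c_in_series(curve, 1, 7), compute_c_in(curve[1], curve[7]))
  expect_error(compute_c_in_series(c(100, NA, 300), 1, 3), "missing")
})

test_that("enhancement summary integrates V2 and scales with 1/dt", {
  v2 <- volume_scan(array(c(100, 140), c(2, 1, 1)), c(10, 10, 10))
  myo <- full_mask(v2)
  s <- summarize_enhancement(v2, myo, hu_v1_mean = 60, dt_s = 60)
  expect_equal(s$sum_hu_v2, 240)
  expect_equal(s$n, 2)
  expect_equal(s$v_vox_ml, 1)
  expect_equal(s$delta_hu_avg, 60)
  expect_equal(s$dmc_dt, 120)
  s2 <- summarize_enhancement(v2, myo, 60, dt_s = 120)
  expect_equal(s2$dmc_dt, 60)
  expect_equal(s2$delta_hu_avg, 60)
  expect_warning(summarize_enhancement(v2, myo, 120, 60), "not a valid first-pass")
})

test_that("average perfusion reproduces the hand-computed worked example", {
  # 4.7 s V1-V2 delay and ~25 HU enhancement change, the reported scales
  v2 <- volume_scan(array(60 + 24.7455, c(1, 1, 1)), c(10, 10, 10))
  s <- summarize_enhancement(v2, full_mask(v2), 60, dt_s = 4.7)
  p <- average_perfusion(s, perfusion_params(300, 4.7, 1.053))
  expect_equal(p, 1.0000, tolerance = 1e-10)
  # homogeneity: doubling the enhancement change doubles perfusion
  v2b <- volume_scan(array(60 + 2 * 24.7455, c(1, 1, 1)), c(10, 10, 10))
  sb <- summarize_enhancement(v2b, full_mask(v2b), 60, dt_s = 4.7)
  expect_equal(average_perfusion(sb, perfusion_params(300, 4.7, 1.053)), 2 * p)
  # zero enhancement change -> zero perfusion
  v0 <- volume_scan(array(60, c(1, 1, 1)), c(10, 10, 10))
  s0 <- suppressWarnings(summarize_enhancement(v0, full_mask(v0), 60, 4.7))
  expect_equal(average_perfusion(s0, perfusion_params(300, 4.7, 1.053)), 0)
})

test_that("integrated-sum and mean-difference formulations agree algebraically", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(c(1, 10, 1000, 1e5), 1)
    dims <- c(n, 1, 1)
    sp <- runif(3, 0.3, 2)
    hu1 <- runif(1, 30, 70)
    v2 <- volume_scan(array(hu1 + rnorm(n, 25, 10), dims), sp)
    dt <- runif(1, 2, 10)
    s <- suppressWarnings(summarize_enhancement(v2, full_mask(v2), hu1, dt))
    pp <- perfusion_params(runif(1, 100, 400), dt, 1.053)
    expect_equal(average_perfusion(s, pp),
                 s$delta_hu_avg / ((dt / 60) * pp$c_in * pp$rho),
                 tolerance = 1e-10)
  }
})

test_that("MI map scales the enhancement ratio by the average perfusion", {
  v2 <- volume_scan(array(c(110, 90), c(2, 1, 1)), c(1, 1, 1))
  myo <- full_mask(v2)
  res <- mi_map(v2, myo, hu_v1_mean = 60, p_avg = 2)
  expect_equal(as.numeric(res$map[!is.na(res$map)]), c(2.5, 1.5))
  expect_equal(mean(res$map[myo$data]), res$p_avg, tolerance = 1e-12)

  uni <- const_volume(80, c(4, 4, 4))
  r2 <- mi_map(uni, full_mask(uni), 60, p_avg = 1.7)
  expect_true(all(abs(r2$map - 1.7) < 1e-12))

  v3 <- volume_scan(array(c(60, 100), c(2, 1, 1)), c(1, 1, 1))
  r3 <- mi_map(v3, full_mask(v3), 60, 2)   # voxel at the V1 mean maps to 0
  expect_equal(r3$map[1, 1, 1], 0)
  expect_error(mi_map(const_volume(60), full_mask(const_volume(60)), 60, 1),
               "degenerate")
})

test_that("MS map implements the voxel-wise subtraction worked example", {
  v1 <- volume_scan(array(c(50, 70), c(2, 1, 1)), c(1, 1, 1))
  v2 <- volume_scan(array(c(110, 90), c(2, 1, 1)), c(1, 1, 1))
  myo <- full_mask(v1)
  # normalizers chosen so P_AVG = 40 / ((60/60) * 20 * 1) = 2 mL/min/g
  res <- ms_map(v1, v2, myo, perfusion_params(20, 60, 1))
  expect_equal(res$p_avg, 2)
  expect_equal(as.numeric(res$map[!is.na(res$map)]), c(3, 1))
  expect_error(ms_map(v1, v1, myo, perfusion_params(20, 60, 1)), "degenerate")
})

test_that("MI and MS coincide when the V1 myocardium is homogeneous", {
  set.seed(3)
  dims <- c(6, 6, 6)
  v1 <- const_volume(48, dims)
  v2 <- volume_scan(array(48 + rnorm(prod(dims), 30, 8), dims), c(1, 1, 1))
  myo <- full_mask(v1)
  pp <- perfusion_params(200, 5, 1.053)
  s <- summarize_enhancement(v2, myo, 48, 5)
  mi <- mi_map(v2, myo, 48, average_perfusion(s, pp))
  ms <- ms_map(v1, v2, myo, pp)
  expect_equal(mi$map, ms$map, tolerance = 1e-12)
  expect_equal(mi$p_avg, ms$p_avg, tolerance = 1e-12)
})

test_that("perfusion-ratio map has mask-mean exactly one", {
  set.seed(9)
  for (i in 1:20) {
    dims <- c(8, 8, 8)
    sel <- array(runif(prod(dims)) < 0.5, dims)
    if (!any(sel)) next
    v2 <- volume_scan(array(rnorm(prod(dims), 90, 20), dims), c(1, 1, 1))
    myo <- new_mask(sel, c(1, 1, 1))
    res <- suppressWarnings(mi_map(v2, myo, 50, p_avg = 1.3))
    expect_equal(mean(res$map[sel]), 1.3, tolerance = 1e-9)
  }
})

test_that("MI output is invariant to V1 rearrangements that keep its summaries", {
  # any spatial rearrangement of V1 voxel values preserving the lateral-wall
  # ROI sample leaves the MI result bit-identical, while the MS map changes
  acc <- oracle_acquisition(small_cfg(
    motion = list(max_translation_mm = 0, max_rotation_deg = 0),
    aif = list(mode = "ramp"),
    study = list(n_subjects = 1L, ffr_grades = 0.8),
    perfusion = list(subject_sdlog = 0, lcx_acq_sdlog = 0)))
  acq <- acc$acq; lmk <- acc$lmk
  run <- function(v1, m) fpa_perfusion(v1, acq$v2, acq$myo, lmk$aorta_seed,
                                       lmk$roi_center, method = m)
  mi0 <- run(acq$v1, "mi"); ms0 <- run(acq$v1, "ms")
  # permute V1 myocardial voxels outside the ROI ball (an extreme "motion")
  v1p <- acq$v1
  roi <- mifpa:::sphere_indices(lmk$roi_center, lmk$roi_radius_mm,
                                acq$v1$spacing, dim(acq$v1$data))
  sel <- setdiff(which(acq$myo$data), roi)
  set.seed(5)
  v1p$data[sel] <- v1p$data[sample(sel)]
  mi1 <- run(v1p, "mi")
  expect_identical(mi1$map, mi0$map)
  expect_identical(mi1$p_avg, mi0$p_avg)
  ms1 <- run(v1p, "ms")
  expect_equal(ms1$p_avg, ms0$p_avg, tolerance = 1e-12)  # mask sum preserved
  expect_false(identical(ms1$map, ms0$map))
})
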