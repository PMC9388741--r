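test_that("calibration line is recovered exactly and noisily", {
  cal <- fit_calibration(c(0, 1000), c(0, 1))
  expect_equal(cal$slope, 0.001, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)

  hu <- c(-50, 100, 300, 600, 900)
  cal3 <- fit_calibration(hu[1:3], 0.0008 * hu[1:3] + 0.01)
  expect_equal(max(abs(cal3$residuals)), 0, tolerance = 1e-12)

  set.seed(4)
  dens <- 0.0009 * hu - 0.02 + rnorm(5, 0, 0.01)
  cal5 <- fit_calibration(hu, dens)
  # closed-form normal equations oracle
  b <- sum((hu - mean(hu)) * (dens - mean(dens))) / sum((hu - mean(hu))^2)
  a <- mean(dens) - b * mean(hu)
  expect_equal(cal5$slope, b, tolerance = 1e-12)
  expect_equal(cal5$intercept, a, tolerance = 1e-12)

  expect_error(fit_calibration(5, 0.1), ">= 2 rods")
  expect_error(fit_calibration(c(100, 100), c(0.1, 0.2)), "degenerate")
})

test_that("segmentation thresholds, labels and fills holes", {
  cal <- fit_calibration(c(0, 1000), c(0, 1))
  flat <- ct_volume(array(-1000, c(8, 8, 8)), c(1, 1, 1))
  expect_error(segment_periosteal(flat, cal), "threshold")

  # hollow box with one missing surface voxel: interior still captured
  arr <- array(-1000, c(20, 20, 12))
  arr[5:15, 5:15, 3:10] <- 1000       # solid block shell
  arr[7:13, 7:13, 5:8] <- 0           # hollow interior below threshold
  arr[10, 5, 6] <- -1000              # one surface voxel below threshold
  vol <- ct_volume(arr, c(1, 1, 1))
  mask <- segment_periosteal(vol, cal)
  expect_true(all(mask[7:13, 7:13, 5:8]))   # interior still captured

  # a distant small blob is not part of the largest component
  arr[1, 1, 1] <- 1000
  mask2 <- segment_periosteal(ct_volume(arr, c(1, 1, 1)), cal)
  expect_false(mask2[1, 1, 1])
})

test_that("cortical erosion uses round(3.5/pixel) and matches brute force", {
  # pixel-count rule at protocol resolutions
  disk <- matrix(FALSE, 48, 48)
  xs <- row(disk) - 24.5; ys <- col(disk) - 24.5
  disk[xs^2 + ys^2 <= 20^2] <- TRUE
  m3 <- array(disk, c(48, 48, 1))
  s07 <- split_cortical_trabecular(m3, c(0.7, 0.7, 1))
  expect_equal(s07$erosion_px, 5L)                     # 3.5/0.7 exact
  s977 <- split_cortical_trabecular(m3, c(0.977, 0.977, 1))
  expect_equal(s977$erosion_px, 4L)                    # round(3.582) = 4

  # disk radius 20, erosion 5: compare to per-pixel brute-force oracle
  expect_equal(s07$trabecular[, , 1], erode_bruteforce(disk, 5L))
  # and roughly a radius-15 disk
  expect_equal(sum(s07$trabecular), sum(xs^2 + ys^2 <= 15^2), tolerance = 0.05)

  # partition invariant: cortical and trabecular tile the periosteal mask
  expect_true(all((s07$cortical | s07$trabecular) == m3))
  expect_false(any(s07$cortical & s07$trabecular))

  tiny <- array(FALSE, c(6, 6, 1)); tiny[3, 3, 1] <- TRUE
  expect_warning(split_cortical_trabecular(tiny, c(0.7, 0.7, 1)), "empty")
})

test_that("region partition slices 10/20/30% bands from the reference end", {
  arr <- array(FALSE, c(4, 4, 320))
  arr[2:3, 2:3, 11:310] <- TRUE       # bone spans 300 slices
  vol <- ct_volume(array(0, c(4, 4, 320)), c(1, 1, 1))
  part <- partition_regions(arr, vol)
  expect_equal(part$n_slices, 300L)
  expect_length(part$epiphysis, 30L)
  expect_length(part$metaphysis, 30L)
  expect_length(part$diaphysis, 30L)
  expect_equal(part$epiphysis, 11:40)
  expect_equal(length(intersect(part$epiphysis, part$metaphysis)), 0L)
  expect_equal(sort(c(part$epiphysis, part$metaphysis, part$diaphysis)),
               11:100)

  # proximal reference end (e.g. tibia scanned the other way up)
  volr <- ct_volume(array(0, c(4, 4, 320)), c(1, 1, 1), distal_first = FALSE)
  partr <- partition_regions(arr, volr)
  expect_equal(partr$epiphysis, 310:281)
  expect_warning(partition_regions(arr[, , 1:15, drop = FALSE],
                                   ct_volume(array(0, c(4, 4, 15)), c(1, 1, 1))),
                 "fewer than 10")
})

test_that("MAT volume counts windowed voxels with unit conversion", {
  arr <- array(0, c(20, 20, 40))
  trab <- array(TRUE, c(20, 20, 40))
  vol <- ct_volume(arr, c(1, 1, 1))
  part <- partition_regions(trab, vol)
  expect_equal(sum(quantify_mat(vol, trab, part)$volume_cm3), 0)

  # 1000 fat voxels at 1 mm^3 = exactly 1 cm^3
  arr[1:10, 1:10, 1:10] <- -120
  vol <- ct_volume(arr, c(1, 1, 1))
  mat <- quantify_mat(vol, trab, part)
  expect_equal(sum(mat$voxels), 1000L)
  expect_equal(sum(mat$volume_cm3), 1)

  # anisotropic spacing: voxel volume 0.8*0.8*1.25 mm^3
  vol2 <- ct_volume(arr, c(0.8, 0.8, 1.25))
  mat2 <- quantify_mat(vol2, trab, partition_regions(trab, vol2))
  expect_equal(sum(mat2$volume_cm3), 1000 * 0.8 * 0.8 * 1.25 / 1000)

  # inclusive window bounds and monotonicity under widening
  arr[1, 1, 1] <- -205; arr[1, 2, 1] <- -50; arr[1, 3, 1] <- -206
  vol3 <- ct_volume(arr, c(1, 1, 1))
  m3 <- quantify_mat(vol3, trab, part)
  expect_equal(sum(m3$voxels), 999L)   # -205 and -50 stay in, -206 drops out
  wide <- quantify_mat(vol3, trab, part, hu_window = c(-300, -40))
  expect_gte(sum(wide$voxels), sum(m3$voxels))
})

test_that("BMC integrates calibrated density, preserving sign", {
  cal <- fit_calibration(c(0, 1000), c(0, 1))
  arr <- array(500, c(10, 10, 30))         # 0.5 g/cm^3 everywhere
  trab <- array(TRUE, c(10, 10, 30))
  vol <- ct_volume(arr, c(2, 2, 2))        # voxel = 8 mm^3
  part <- partition_regions(trab, vol)
  bmc <- trabecular_bmc(vol, cal, trab, part)
  # 30% of 30 slices = 9 slices of 100 voxels, 0.008 cm^3 each at 0.5 g/cm^3
  expect_equal(bmc$bmc_g[bmc$region == "total"], 900 * 0.008 * 0.5)

  arr2 <- array(-300, c(10, 10, 30))       # calibrates to -0.3 g/cm^3
  bmc2 <- trabecular_bmc(ct_volume(arr2, c(2, 2, 2)), cal, trab, part)
  expect_lt(bmc2$bmc_g[bmc2$region == "total"], 0)
})

test_that("phantom closure: end-to-end recovery of generator truth", {
  ph <- small_phantom()
  res <- run_qct(ph$volume, ph$descriptor)
  expect_equal(res$calibration$slope, ph$truth$calibration$slope,
               tolerance = 1e-10)
  expect_equal(res$calibration$intercept, ph$truth$calibration$intercept,
               tolerance = 1e-10)
  expect_equal(res$mat$voxels, ph$truth$mat$voxels)
  expect_equal(res$mat$volume_cm3, ph$truth$mat$volume_cm3, tolerance = 1e-12)
  expect_equal(res$bmc$bmc_g, ph$truth$bmc$bmc_g, tolerance = 1e-9)
  expect_equal(unclass(res$masks$periosteal) & TRUE, ph$truth$periosteal)
  expect_true(all((unclass(res$masks$trabecular) & TRUE) == ph$truth$trabecular))
  # masks tile
  expect_true(all((res$masks$cortical | res$masks$trabecular) ==
                    unclass(res$masks$periosteal)))
  expect_false(any(res$masks$cortical & res$masks$trabecular))

  # deterministic rerun
  res2 <- run_qct(ph$volume, ph$descriptor)
  expect_identical(res$mat, res2$mat)
  expect_identical(res$bmc, res2$bmc)
})

test_that("volumes scale with voxel spacing as the cube", {
  arr <- array(0, c(12, 12, 20))
  arr[4:9, 4:9, 1:6] <- -120
  trab <- array(TRUE, dim(arr))
  v1 <- ct_volume(arr, c(1, 1, 1)); v2 <- ct_volume(arr, c(2, 2, 2))
  m1 <- quantify_mat(v1, trab, partition_regions(trab, v1))
  m2 <- quantify_mat(v2, trab, partition_regions(trab, v2))
  expect_equal(m2$volume_cm3, m1$volume_cm3 * 8)
})

test_that("noisy phantoms still recover MAT volume approximately", {
  rel_err <- vapply(1:3, function(i) {
    ph <- small_phantom(seed = 100 + i, noise_sd_hu = 10)
    res <- run_qct(ph$volume, ph$descriptor)
    tot <- sum(res$mat$volume_cm3); tru <- sum(ph$truth$mat$volume_cm3)
    abs(tot - tru) / tru
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
})

test_that("NIfTI round-trip preserves voxels and spacing", {
  ph <- small_phantom()
  td <- tempfile(); dir.create(td)
  paths <- write_phantom(ph, td)
  vol <- read_ct_nifti(file.path(td, "phantom.nii.gz"))
  expect_equal(vol$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)
  expect_equal(vol$voxels, ph$volume$voxels, tolerance = 1e-4)
  side <- jsonlite::read_json(file.path(td, "phantom.json"), simplifyVector = TRUE)
  expect_equal(side$truth$calibration$slope, 0.001)
  unlink(td, recursive = TRUE)
})
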