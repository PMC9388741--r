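test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_cohort(sci_cohort_spec(seed = 4)),
                   generate_cohort(sci_cohort_spec(seed = 4)))
  spec <- count_sim_spec(n_mirnas = 50, seed = 4)
  expect_identical(generate_counts(spec)$counts, generate_counts(spec)$counts)
  hp <- hairpin_sim_spec(n_candidates = 10, seed = 4)
  expect_identical(generate_hairpins(hp), generate_hairpins(hp))
  ps <- phantom_spec(bone_length_mm = 60, bone_radius_mm = 10,
                     n_fat_voxels_per_region = c(epiphysis = 20L,
                                                 metaphysis = 20L,
                                                 diaphysis = 20L), seed = 4)
  expect_identical(generate_ct_phantom(ps)$volume$voxels,
                   generate_ct_phantom(ps)$volume$voxels)
  # generator calls do not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(generate_cohort(sci_cohort_spec(seed = 9)))
  expect_identical(runif(1), a)
})

test_that("zero-noise cohorts sit exactly at group means; draws are unbiased", {
  spec <- sci_cohort_spec(seed = 1)
  spec$sds <- lapply(spec$sds, function(v) ifelse(is.na(v), NA, 0))
  co <- generate_cohort(spec)
  expect_equal(unique(co$age[co$group == "acute"]), 36.88)
  expect_equal(unique(co$mat_diaphysis_cm3[co$group == "chronic"]), 7.80)
  expect_true(all(is.na(co$mat_diaphysis_cm3[co$group == "none"])))

  # Monte-Carlo unbiasedness of the marrow-adiposity means
  reps <- vapply(1:300, function(i) {
    co <- generate_cohort(sci_cohort_spec(seed = i))
    c(mean(co$mat_diaphysis_cm3[co$group == "acute"]),
      mean(co$mat_diaphysis_cm3[co$group == "chronic"]))
  }, numeric(2))
  se_acute <- 1.77 / sqrt(12) / sqrt(300)
  se_chronic <- 4.08 / sqrt(18) / sqrt(300)
  expect_lt(abs(mean(reps[1, ]) - 3.45), 4 * se_acute)
  expect_lt(abs(mean(reps[2, ]) - 7.80), 4 * se_chronic)

  bad <- sci_cohort_spec(); bad$group_sizes["acute"] <- 0L
  expect_error(cohort_spec(bad$group_sizes, bad$means, bad$sds), "positive")
})

test_that("count generator obeys Poisson limit, labels and library factors", {
  # dispersion 0, no effect, unit factors: counts ~ Poisson(abundance)
  sim <- generate_counts(count_sim_spec(
    n_mirnas = 1, samples_per_group = c(a = 300L, b = 300L),
    baseline_abundances = 50, library_size_factors = rep(1, 600),
    de_fraction = 0, dispersion = 0, seed = 8))
  x <- as.numeric(sim$counts)
  expect_lt(abs(mean(x) - 50), 3 * sqrt(50 / 600))
  expect_lt(abs(var(x) - 50), 4 * 50 * sqrt(2 / 599))

  expect_equal(sum(generate_counts(count_sim_spec(n_mirnas = 100,
                                                  de_fraction = 0,
                                                  seed = 2))$truth$de), 0L)

  # one sample at double library factor has ~2x the totals of its peers
  lf <- c(2, rep(1, 5))
  sim2 <- generate_counts(count_sim_spec(
    n_mirnas = 3000, samples_per_group = c(a = 3L, b = 3L),
    library_size_factors = lf, de_fraction = 0, dispersion = 0.05, seed = 3))
  tot <- colSums(sim2$counts)
  expect_equal(unname(tot[1] / mean(tot[-1])), 2, tolerance = 0.1)
})

test_that("phantom construction enforces capacity and encodes exact truth", {
  expect_error(generate_ct_phantom(phantom_spec(
    bone_length_mm = 40, bone_radius_mm = 8,
    n_fat_voxels_per_region = c(epiphysis = 50000L, metaphysis = 10L,
                                diaphysis = 10L))), "fat voxels")

  ph <- small_phantom()
  # 100 + 150 + 200 fat voxels at 0.8*0.8*1 mm
  expect_equal(ph$truth$mat$voxels, c(100L, 150L, 200L))
  expect_equal(ph$truth$mat$volume_cm3, c(100, 150, 200) * 0.64 / 1000)
  expect_equal(length(ph$truth$fat_indices), 450L)
  # fat voxels live inside the truth trabecular mask
  expect_true(all(ph$truth$trabecular[ph$truth$fat_indices]))
  # spec guards
  expect_error(phantom_spec(fat_hu = -300), "window")
  expect_error(phantom_spec(marrow_hu = -100), "window")
})

test_that("a cubic-millimetre check: 1000 unit fat voxels is 1 cm^3", {
  ph <- generate_ct_phantom(phantom_spec(
    bone_length_mm = 120, bone_radius_mm = 14, voxel_spacing_mm = c(1, 1, 1),
    n_fat_voxels_per_region = c(epiphysis = 10L, metaphysis = 10L,
                                diaphysis = 1000L), seed = 6))
  expect_equal(ph$truth$mat$volume_cm3[ph$truth$mat$region == "diaphysis"], 1.0)
  res <- run_qct(ph$volume, ph$descriptor)
  expect_equal(res$mat$volume_cm3[res$mat$region == "diaphysis"], 1.0)
})

test_that("hairpin generator labels agree with the filter and edge fractions", {
  all_valid <- generate_hairpins(hairpin_sim_spec(30, valid_fraction = 1, seed = 5))
  res <- filter_hairpins(all_valid$candidates)
  expect_length(res$passing, 30L)

  none_valid <- generate_hairpins(hairpin_sim_spec(22, valid_fraction = 0, seed = 5))
  res0 <- filter_hairpins(none_valid$candidates)
  expect_length(res0$passing, 0L)
  expect_equal(sort(unique(none_valid$truth$violates)),
               sort(names(marrowmir:::hairpin_violation_builders)))
})
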