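# Phantom generator: diameter sampling, paired-phase construction,
# determinism, dataset splitting, IO round trip.

test_that("diameter sampling respects bounds, the empty case and degeneracy", {
  cfg <- phantom_config()
  expect_identical(sample_tumor_diameters(cfg, 0), numeric(0))
  d <- sample_tumor_diameters(cfg, 500, seed = 9)
  expect_true(all(d >= cfg$diameter_min_mm & d <= cfg$diameter_max_mm))
  tiny <- phantom_config(diameter_mean_mm = 10, diameter_sd_mm = 3,
                         diameter_min_mm = 10, diameter_max_mm = 10 + 1e-9)
  expect_equal(sample_tumor_diameters(tiny, 20, seed = 1), rep(10, 20),
               tolerance = 1e-6)
  expect_error(phantom_config(diameter_min_mm = 5, diameter_max_mm = 4), "min")
})

test_that("sampled diameters match the numerically integrated truncated mean", {
  cfg <- phantom_config()  # mean 24.6, sd 18.3, bounds [3.2, 87.5]
  d <- sample_tumor_diameters(cfg, 10000, seed = 123)
  target <- truncnorm_mean_numeric(24.6, 18.3, 3.2, 87.5)
  expect_lt(abs(mean(d) - target), 1.5)
})

test_that("generated cases are deterministic and geometrically aligned", {
  cfg <- small_phantom_config(seed = 5)
  c1 <- generate_case(cfg, seed = 11)
  c2 <- generate_case(cfg, seed = 11)
  expect_identical(c1$noncontrast$data, c2$noncontrast$data)
  expect_identical(c1$venous$data, c2$venous$data)
  expect_identical(c1$mask, c2$mask)
  c3 <- generate_case(cfg, seed = 12)
  expect_false(identical(c1$mask, c3$mask))
  expect_identical(dim(c1$noncontrast$data), dim(c1$venous$data))
  expect_identical(dim(c1$mask), dim(c1$venous$data))
  expect_identical(c1$noncontrast$spacing, c1$venous$spacing)
  expect_true(all(c1$mask %in% c(0, 1)))
})

test_that("noise-free construction reproduces the configured HU offsets", {
  cfg <- phantom_config(image_size = 64, noise_sd_hu = 0, liver_texture_sd_hu = 0,
                        tumor_contrast_hu = c(noncontrast = -12, venous = -40))
  cs <- generate_case(cfg, seed = 3)
  off_ve <- mean(cs$venous$data[cs$mask == 1]) - mean(cs$venous$data[cs$mask == 0])
  off_nc <- mean(cs$noncontrast$data[cs$mask == 1]) - mean(cs$noncontrast$data[cs$mask == 0])
  expect_equal(off_ve, -40, tolerance = 0.5)
  expect_equal(off_nc, -12, tolerance = 0.5)
})

test_that("the venous phase is always the conspicuous one (contrast ordering)", {
  cfg <- small_phantom_config(seed = 2)
  deltas <- vapply(1:100, function(i) {
    cs <- generate_case(cfg, seed = 1000 + i)
    ve <- abs(mean(cs$venous$data[cs$mask == 1]) - mean(cs$venous$data[cs$mask == 0]))
    nc <- abs(mean(cs$noncontrast$data[cs$mask == 1]) - mean(cs$noncontrast$data[cs$mask == 0]))
    ve - nc
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.99)
  expect_error(
    phantom_config(tumor_contrast_hu = c(noncontrast = -40, venous = -12)),
    "premise")
})

test_that("fixed diameters 8/15/30 mm produce the Tiny/Small/Big strata", {
  cfg <- phantom_config(image_size = 128, n_tumors_per_slice = 3,
                        noise_sd_hu = 0, liver_texture_sd_hu = 0)
  cs <- generate_case(cfg, seed = 21, diameters_mm = c(8, 15, 30))
  expect_identical(sort(cs$tumor_records$stratum), sort(c("Tiny", "Small", "Big")))
})

test_that("recorded diameters agree with the brute-force measurement oracle", {
  cfg <- small_phantom_config(seed = 8, n_tumors_per_slice = 1)
  for (i in 1:5) {
    cs <- generate_case(cfg, seed = 300 + i)
    d_oracle <- oracle_max_diameter(cs$mask, cs$noncontrast$spacing[1:2])
    expect_equal(cs$tumor_records$max_diameter_mm, d_oracle,
                 tolerance = 1e-8)
    expect_identical(cs$tumor_records$stratum, stratify(d_oracle))
  }
})

test_that("oversized lesions fail placement with a clear error", {
  cfg <- phantom_config(image_size = 32, n_tumors_per_slice = 1)
  expect_error(generate_case(cfg, seed = 1, diameters_mm = 80),
               "field of view")
})

test_that("dataset splits are disjoint, sized by floor, and reproduce 524/65/65", {
  cfg <- small_phantom_config(size = 32, seed = 4)
  ds <- generate_dataset(cfg, 10, seed = 7)
  expect_length(ds$train, 8); expect_length(ds$val, 1); expect_length(ds$test, 1)
  seeds <- function(set) vapply(set, `[[`, numeric(1), "seed")
  all_seeds <- c(seeds(ds$train), seeds(ds$val), seeds(ds$test))
  expect_length(unique(all_seeds), 10)
  ds2 <- generate_dataset(cfg, 10, seed = 8)
  expect_false(identical(seeds(ds$train), seeds(ds2$train)))
  # the reference 80/10/10 arithmetic at the full cohort size
  n <- 654
  n_val <- floor(n * 0.1); n_test <- floor(n * 0.1)
  expect_equal(c(n - n_val - n_test, n_val, n_test), c(524, 65, 65))
  expect_error(generate_dataset(cfg, 2, c(0.8, 0.1, 0.1)), "too small")
  expect_error(generate_dataset(cfg, 10, c(0.5, 0.2)), "fractions")
})

test_that("NIfTI round trip preserves voxels, spacing and the manifest", {
  cs <- small_cases(1, seed = 33)[[1]]
  dir <- withr::local_tempdir()
  write_case_nifti(cs, dir, prefix = "t")
  back <- read_case_nifti(dir, prefix = "t")
  expect_equal(back$noncontrast$data, cs$noncontrast$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$venous$spacing, cs$venous$spacing, tolerance = 1e-6)
  expect_equal(back$mask, cs$mask, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$tumor_records$max_diameter_mm,
               cs$tumor_records$max_diameter_mm, tolerance = 1e-6)
})

test_that("thin 3D stacks share anatomy across slices", {
  cfg <- small_phantom_config(size = 32, n_slices = 3)
  cs <- generate_case(cfg, seed = 2)
  expect_identical(dim(cs$mask), c(32L, 32L, 3L))
  expect_identical(cs$mask[, , 1], cs$mask[, , 3])
})
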