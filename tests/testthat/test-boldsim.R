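small_geom <- function(nv = 40) {
  bold_geometry(dim = c(8, 8, 5), n_volumes = nv)
}

toy_timeline <- function() {
  data.frame(onset_s = seq(6, 96, by = 10),
             category = rep(c("ST", "UT"), 5))
}

test_that("zero noise, zero effects gives a constant baseline", {
  ser <- simulate_bold(toy_timeline(), list(), small_geom(),
                       noise = list(white_sd = 0, ar1 = 0, drift_amp = 0),
                       baseline = 100)
  expect_true(all(ser$data == 100))
  expect_equal(dim(ser$data), c(8, 8, 5, 40))
})

test_that("a single-voxel effect equals amplitude times the regressor", {
  geom <- small_geom()
  ef <- effect_spec(matrix(c(3, 4, 2), 1), "ST", amplitude = 1.7)
  ser <- simulate_bold(toy_timeline(), list(ef), geom,
                       noise = list(white_sd = 0, ar1 = 0, drift_amp = 0),
                       baseline = 0)
  X <- build_design(toy_timeline()$onset_s, toy_timeline()$category,
                    tr_s = 3, n_volumes = 40)
  expect_equal(ser$data[3, 4, 2, ], 1.7 * X[, "ST"], tolerance = 1e-12)
  expect_true(all(ser$data[-3, , , ] == 0))
})

test_that("default geometry matches the acquisition: 304 volumes at TR 3 s", {
  g <- bold_geometry()
  expect_equal(g$n_volumes, 304L)
  expect_equal(g$tr_s, 3)
  ser <- simulate_bold(toy_timeline(), list(), g,
                       noise = list(white_sd = 0, ar1 = 0, drift_amp = 0))
  expect_equal(dim(ser$data)[4], 304L)
})

test_that("the generative model is linear in the effects", {
  geom <- small_geom()
  efA <- effect_spec(matrix(c(2, 2, 2), 1), "ST", 1.0)
  efB <- effect_spec(matrix(c(5, 5, 3), 1), "UT", -0.8)
  nz <- list(white_sd = 0, ar1 = 0, drift_amp = 0)
  sA <- simulate_bold(toy_timeline(), list(efA), geom, nz, baseline = 0)
  sB <- simulate_bold(toy_timeline(), list(efB), geom, nz, baseline = 0)
  sAB <- simulate_bold(toy_timeline(), list(efA, efB), geom, nz, baseline = 0)
  expect_equal(sA$data + sB$data, sAB$data, tolerance = 1e-12)
})

test_that("effects outside the volume or mask are rejected", {
  geom <- small_geom()
  expect_error(
    simulate_bold(toy_timeline(),
                  list(effect_spec(matrix(c(99, 1, 1), 1), "ST", 1)),
                  geom, list(white_sd = 0)),
    "outside")
  mask <- array(TRUE, c(8, 8, 5)); mask[3, 4, 2] <- FALSE
  gm <- bold_geometry(dim = c(8, 8, 5), n_volumes = 40, mask = mask)
  expect_error(
    simulate_bold(toy_timeline(),
                  list(effect_spec(matrix(c(3, 4, 2), 1), "ST", 1)),
                  gm, list(white_sd = 0)),
    "mask")
})

test_that("simulation is reproducible under a fixed seed", {
  geom <- small_geom()
  s1 <- simulate_bold(toy_timeline(), list(), geom,
                      noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 1),
                      seed = 9)
  s2 <- simulate_bold(toy_timeline(), list(), geom,
                      noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 1),
                      seed = 9)
  expect_identical(s1$data, s2$data)
})

test_that("preprocessing discards dummy volumes: 304 in, 300 out", {
  ser <- simulate_bold(toy_timeline(), list(), bold_geometry(dim = c(4, 4, 3)),
                       noise = list(white_sd = 0.5), seed = 1)
  pp <- preprocess_bold(ser, n_dummy = 4, highpass_cycles = 0, fwhm_mm = 0)
  expect_equal(pp$geometry$n_volumes, 300L)
  expect_equal(pp$data[, , , 1], ser$data[, , , 5])
  expect_error(preprocess_bold(ser, n_dummy = 304), "smaller")
})

test_that("high-pass removes sub-cutoff frequencies and keeps the mean", {
  geom <- small_geom(60)
  ser <- simulate_bold(toy_timeline(), list(), geom,
                       noise = list(white_sd = 0, ar1 = 0, drift_amp = 0),
                       baseline = 50)
  tt <- (0:59) / 60
  ser$data[2, 2, 2, ] <- 50 + 3 * sin(2 * pi * tt + 0.4)   # 1 cycle/run
  pp <- preprocess_bold(ser, n_dummy = 0, highpass_cycles = 3, fwhm_mm = 0)
  expect_equal(pp$data[2, 2, 2, ], rep(50, 60), tolerance = 1e-9)
  # a 5-cycle component is above the cutoff and must survive
  ser$data[2, 2, 2, ] <- 50 + 3 * sin(2 * pi * 5 * tt)
  pp2 <- preprocess_bold(ser, n_dummy = 0, highpass_cycles = 3, fwhm_mm = 0)
  expect_gt(sd(pp2$data[2, 2, 2, ]), 2)
})

test_that("smoothing preserves constants and approximately conserves the mean", {
  geom <- small_geom(5)
  ser <- simulate_bold(toy_timeline()[1:2, ], list(), geom,
                       noise = list(white_sd = 0), baseline = 7)
  pp <- preprocess_bold(ser, n_dummy = 0, highpass_cycles = 0, fwhm_mm = 6)
  expect_equal(pp$data[, , , 1], array(7, c(8, 8, 5)), tolerance = 1e-12)

  set.seed(5)
  vol <- array(rnorm(8 * 8 * 5, mean = 10), c(8, 8, 5))
  sm <- smooth_volume(vol, fwhm_mm = 6, voxel_mm = c(3.75, 3.75, 4))
  expect_lt(abs(mean(sm) - mean(vol)), 0.05)
})

test_that("volumes round-trip through NIfTI with their voxel geometry", {
  set.seed(2)
  vol <- array(rnorm(60), c(5, 4, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path, voxel_mm = c(3.75, 3.75, 4))
  back <- read_volume(path)
  expect_equal(array(back, dim(vol)), vol, tolerance = 1e-6)
  expect_equal(attr(back, "pixdim")[1:3], c(3.75, 3.75, 4))
})
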