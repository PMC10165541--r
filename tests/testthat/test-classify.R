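test_that("unit intensity: equal amplitudes give the amplitude with zero spread", {
  u <- estimate_unit_intensity(rep(120, 40))
  expect_equal(u$unit, 120)
  expect_equal(u$spread, 0)
})

test_that("unit intensity resists focus contamination in the upper tail", {
  set.seed(4)
  amps <- c(rnorm(90, 100, 3), rep(500, 10))   # 90 singles, 10 foci at 5x
  u <- estimate_unit_intensity(amps)
  expect_lt(abs(u$unit - 100) / 100, 0.05)     # oracle: median of known singles
})

test_that("unit intensity needs at least 10 candidates", {
  expect_error(estimate_unit_intensity(rep(5, 9)), class = "ss_input_error")
  expect_error(estimate_unit_intensity(empty_spot_table <- data.frame(amplitude = numeric(0))),
               class = "ss_input_error")
})

test_that("classification follows the amplitude and size gates", {
  psf <- psf_model(); params <- detection_params()
  base <- data.frame(channel = "a", z_um = 1, y_um = 1, x_um = 1,
                     amplitude = NA_real_, sigma_lat_um = NA_real_,
                     sigma_ax_um = psf$sigma_axial, response = 1,
                     spot_class = NA_character_, focus_transcript_estimate = NA_real_,
                     compartment = NA_character_)
  mk <- function(amp, sig) { r <- base; r$amplitude <- amp; r$sigma_lat_um <- sig; r }
  unit <- 100
  # nominal single
  out <- classify_spots(mk(100, psf$sigma_lateral), unit, psf, params)
  expect_equal(out$spot_class, "single")
  # bright nuclear spot -> focus with transcript estimate 4
  out <- classify_spots(mk(400, psf$sigma_lateral), unit, psf, params)
  expect_equal(out$spot_class, "focus")
  expect_equal(out$focus_transcript_estimate, 4.0)
  # too dim -> rejected
  out <- classify_spots(mk(30, psf$sigma_lateral), unit, psf, params)
  expect_equal(out$spot_class, "rejected")
  # at the size gate boundary (2x PSF) -> rejected
  out <- classify_spots(mk(50, 2 * psf$sigma_lateral), unit, psf, params)
  expect_equal(out$spot_class, "rejected")
})

test_that("a rendered blob at 2x PSF and half unit intensity is rejected", {
  vs <- c(0.35, 0.13, 0.13); psf <- psf_model()
  blob <- data.frame(z_um = 2.1, y_um = 3.1, x_um = 3.1, amplitude = 50,
                     sigma_lat_um = 2 * psf$sigma_lateral,
                     sigma_ax_um = 2 * psf$sigma_axial)
  img <- asNamespace("spotscreen")$render_spots(blob, c(14L, 48L, 48L), vs)
  sp <- detect_spots(img, psf, detection_params(), voxel_size = vs, subtract = FALSE)
  expect_equal(nrow(sp), 1L)
  out <- classify_spots(sp, unit = 100, psf, detection_params())
  expect_equal(out$spot_class, "rejected")
})

test_that("the nucleus mask gates the focus class", {
  psf <- psf_model(); params <- detection_params()
  lab <- array(0L, c(4, 10, 10)); lab[, 1:5, ] <- 1L
  nuc <- compartment_mask(lab, c("1" = "nucleus"), c(0.35, 0.13, 0.13))
  spots <- data.frame(channel = "a", z_um = 0.7, y_um = c(0.26, 1.04), x_um = 0.5,
                      amplitude = 400, sigma_lat_um = psf$sigma_lateral,
                      sigma_ax_um = psf$sigma_axial, response = 1,
                      spot_class = NA_character_, focus_transcript_estimate = NA_real_,
                      compartment = NA_character_)
  out <- classify_spots(spots, 100, psf, params, nucleus_mask = nuc)
  expect_equal(out$spot_class, c("focus", "single"))
})

test_that("classification partitions every row into exactly one class", {
  cfg <- small_cfg(seed = 28L)
  sim <- simulate_image_stack(cfg)
  sp <- detect_and_classify(sim, cfg, "probe_a", nucleus_mask_of(sim))
  expect_true(all(sp$spot_class %in% c("single", "focus", "rejected")))
  expect_true(all(is.na(sp$focus_transcript_estimate) != (sp$spot_class == "focus")))
})
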