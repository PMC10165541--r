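test_that("simulation is bit-deterministic for a fixed config and seed", {
  cfg <- small_cfg(seed = 42L)
  a <- simulate_image_stack(cfg)
  b <- simulate_image_stack(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$spots, b$truth$spots)
})

test_that("ground-truth spot counts match the configured counts", {
  cfg <- small_cfg(n_single_spots = 25L, n_foci = 3L, n_background_blobs = 4L,
                   seed = 5L)
  sim <- simulate_image_stack(cfg)
  tab <- table(sim$truth$spots$class[sim$truth$spots$channel == "probe_a"])
  expect_equal(unname(tab[["single"]]), 25L)
  expect_equal(unname(tab[["focus"]]), 3L)
  expect_equal(unname(tab[["blob"]]), 4L)
})

test_that("empty configuration renders pure noise with empty ground truth", {
  cfg <- small_cfg(n_single_spots = 0L, n_foci = 0L, n_background_blobs = 0L,
                   seed = 3L)
  sim <- simulate_image_stack(cfg)
  expect_equal(nrow(sim$truth$spots), 0L)
  # nothing but baseline + noise in the probe channels
  expect_lt(abs(mean(sim$stack$channels$probe_a) - cfg$noise$baseline), 2)
})

test_that("codetection_fraction = 1 pairs every probe-A single", {
  cfg <- small_cfg(codetection_fraction = 1, seed = 8L)
  sim <- simulate_image_stack(cfg)
  a <- subset(sim$truth$spots, channel == "probe_a" & class == "single")
  b <- subset(sim$truth$spots, channel == "probe_b")
  expect_true(all(!is.na(a$shared_id)))
  expect_setequal(a$shared_id, b$shared_id)
  expect_equal(sim$truth$true_codetection_fraction, 1)
})

test_that("per-compartment ground-truth counts equal exhaustive voxel lookup", {
  cfg <- sim_config(image_shape = c(14L, 96L, 96L), n_single_spots = 200L,
                    n_foci = 0L, n_background_blobs = 0L, seed = 31L)
  sim <- simulate_image_stack(cfg)
  m <- sim$truth$mask
  singles <- subset(sim$truth$spots, channel == "probe_a" & class == "single")
  # oracle: direct voxel lookup of each true position
  d <- dim(m$labels)
  lab <- vapply(seq_len(nrow(singles)), function(i) {
    iz <- min(max(round(singles$z_um[i] / m$voxel_size[1]) + 1, 1), d[1])
    iy <- min(max(round(singles$y_um[i] / m$voxel_size[2]) + 1, 1), d[2])
    ix <- min(max(round(singles$x_um[i] / m$voxel_size[3]) + 1, 1), d[3])
    id <- m$labels[iz, iy, ix]
    if (id == 0L) "outside" else unname(m$label_names[as.character(id)])
  }, character(1))
  oracle <- table(factor(lab, levels = names(sim$truth$per_compartment_counts)))
  expect_equal(as.integer(sim$truth$per_compartment_counts), as.integer(oracle))
  # conservation: compartment counts sum to the number of singles
  expect_equal(sum(sim$truth$per_compartment_counts), nrow(singles))
})

test_that("codetection fraction converges to the configured value over seeds", {
  fr <- vapply(subseeds(99, 12), function(s) {
    cfg <- small_cfg(n_single_spots = 60L, codetection_fraction = 0.7, seed = s)
    simulate_image_stack(cfg)$truth$true_codetection_fraction
  }, numeric(1))
  # binomial se at n = 60 x 12 draws
  expect_lt(abs(mean(fr) - 0.7), 3 * sqrt(0.7 * 0.3 / (60 * 12)))
})

test_that("photometry: fitted amplitude on a noise-free render is within 2%", {
  cfg <- sim_config(image_shape = c(14L, 72L, 72L), n_single_spots = 20L,
                    n_foci = 0L, n_background_blobs = 0L,
                    single_amplitude_cv = 0, noise = list(baseline = 0, read_sd = 0),
                    seed = 12L)
  sim <- simulate_image_stack(cfg)
  sp <- detect_spots(sim$stack, cfg$psf, detection_params(), channel = "probe_a",
                     subtract = FALSE)
  expect_gte(nrow(sp), 18)
  expect_lt(abs(mean(sp$amplitude) - cfg$single_amplitude_mean) /
              cfg$single_amplitude_mean, 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(codetection_fraction = 1.2), class = "ss_config_error")
  expect_error(small_cfg(blob_sigma_factor = 0.9), class = "ss_config_error")
  expect_error(small_cfg(blob_amplitude_factor = 1.5), class = "ss_config_error")
  expect_error(small_cfg(single_amplitude_mean = -5), class = "ss_config_error")
  expect_error(small_cfg(n_single_spots = -1), class = "ss_config_error")
  # geometry that does not fit the image
  expect_error(
    small_cfg(compartment_layout = list(ellipsoid("soma", c(2, 2, 2), c(50, 50, 50)))),
    class = "ss_config_error")
})

test_that("condition pairs scale arm-B counts by the reduction fraction", {
  cfg <- small_cfg(n_single_spots = 50L, seed = 77L)
  expect_error(simulate_condition_pair(cfg, 0.5, 1), class = "ss_config_error")
  # reduction 1: arm B has zero true spots
  cp <- simulate_condition_pair(cfg, 1, 3, images = TRUE)
  expect_true(all(cp$counts_b == 0))
  expect_true(all(vapply(cp$arm_b, function(x) nrow(subset(x$truth$spots,
    class == "single" & channel == "probe_a")) == 0, logical(1))))
  # reduction 0: arms exchangeable (same mean within sampling error)
  cp0 <- simulate_condition_pair(cfg, 0, 40, images = FALSE)
  expect_lt(abs(mean(cp0$counts_a) - mean(cp0$counts_b)),
            4 * sqrt(50 / 40 * 2))
  # count-level oracle at the published reduction: direct Poisson simulation
  cfg2 <- small_cfg(n_single_spots = 50L, seed = 101L)
  cp84 <- simulate_condition_pair(cfg2, 0.84, 10, images = FALSE)
  ratio <- mean(cp84$counts_b) / mean(cp84$counts_a)
  se <- sqrt(8 / 10) / 50 + 0.16 * sqrt(50 / 10) / 50
  expect_lt(abs(ratio - 0.16), 3 * (sqrt(8 / 10) / 50 + 0.16 * sqrt(50 / 10) / 50))
})
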