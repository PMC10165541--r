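test_that("taxonomy maps every label to one cell class and one subregion", {
  tax <- compartment_taxonomy()
  expect_equal(anyDuplicated(tax$label), 0L)
  expect_true(all(tax$cell_class %in% c("neuron", "glia", "muscle")))
  expect_true(all(tax$subregion %in% c("soma", "periphery")))
})

test_that("a blank marker channel segments to an empty mask with a warning", {
  st <- image_stack(list(marker = array(rnorm(6 * 24 * 24, 100, 2), c(6, 24, 24))),
                    c(0.35, 0.13, 0.13))
  expect_warning(m <- segment_marker(st, "marker"), "no component")
  expect_equal(length(m$label_names), 0L)
  expect_true(all(m$labels == 0L))
})

test_that("a rendered axon tube is recovered at high voxel-wise Jaccard", {
  cfg <- sim_config(image_shape = c(16L, 96L, 96L), n_single_spots = 0L,
                    n_foci = 0L, n_background_blobs = 0L, seed = 14L)
  sim <- simulate_image_stack(cfg)
  seg <- segment_marker(sim$stack, "marker", list(min_volume = 50))
  tm <- sim$truth$mask
  tube_id <- as.integer(names(tm$label_names)[tm$label_names == "nmj_axon_terminal"])
  truth_vox <- tm$labels == tube_id
  jac <- vapply(as.integer(names(seg$label_names)), function(id) {
    v <- seg$labels == id
    sum(v & truth_vox) / sum(v | truth_vox)
  }, numeric(1))
  expect_gte(max(jac), 0.9)
})

test_that("two disjoint rendered somata give exactly two components", {
  shape <- c(12L, 64L, 64L); vs <- c(0.35, 0.13, 0.13)
  ext <- (shape - 1) * vs
  layout <- list(
    ellipsoid("central_brain_soma", c(ext[1] / 2, ext[2] * 0.25, ext[3] * 0.25),
              c(1.2, 1.5, 1.5)),
    ellipsoid("central_brain_soma", c(ext[1] / 2, ext[2] * 0.75, ext[3] * 0.75),
              c(1.2, 1.5, 1.5)))
  cfg <- sim_config(image_shape = shape, voxel_size = vs, n_single_spots = 0L,
                    n_foci = 0L, n_background_blobs = 0L,
                    compartment_layout = layout, seed = 4L)
  sim <- simulate_image_stack(cfg)
  seg <- segment_marker(sim$stack, "marker", list(min_volume = 50, label = "soma"))
  expect_equal(length(seg$label_names), 2L)
  expect_setequal(unname(seg$label_names), c("soma_1", "soma_2"))
})

test_that("segmentation labelling is deterministic (centroid-ordered)", {
  cfg <- small_cfg(seed = 3L)
  sim <- simulate_image_stack(cfg)
  s1 <- segment_marker(sim$stack, "marker", list(min_volume = 40))
  s2 <- segment_marker(sim$stack, "marker", list(min_volume = 40))
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$label_names, s2$label_names)
})

test_that("spot assignment equals brute-force voxel lookup and conserves totals", {
  cfg <- sim_config(image_shape = c(14L, 72L, 72L), n_single_spots = 500L,
                    n_foci = 0L, n_background_blobs = 0L, seed = 41L)
  sim <- simulate_image_stack(cfg)
  m <- sim$truth$mask
  sp <- subset(sim$truth$spots, channel == "probe_a")
  sp$spot_class <- "single"
  tab <- assign_spots(sp, m)
  d <- dim(m$labels)
  oracle <- vapply(seq_len(nrow(sp)), function(i) {
    iz <- min(max(round(sp$z_um[i] / m$voxel_size[1]) + 1, 1), d[1])
    iy <- min(max(round(sp$y_um[i] / m$voxel_size[2]) + 1, 1), d[2])
    ix <- min(max(round(sp$x_um[i] / m$voxel_size[3]) + 1, 1), d[3])
    id <- m$labels[iz, iy, ix]
    if (id == 0L) "outside" else unname(m$label_names[as.character(id)])
  }, character(1))
  expect_identical(tab$compartment, oracle)
  counts <- per_compartment_counts(tab, m)
  expect_equal(sum(counts$n_single_mRNA), nrow(tab))   # conservation incl. outside
})

test_that("frame mismatches between spots and mask are rejected", {
  lab <- array(1L, c(4, 8, 8))
  m <- compartment_mask(lab, c("1" = "soma"), c(0.3, 0.1, 0.1))
  sp <- data.frame(z_um = 0.5, y_um = 0.5, x_um = 0.5)
  attr(sp, "voxel_size") <- c(0.35, 0.13, 0.13)
  expect_error(assign_spots(sp, m), class = "ss_input_error")
})

test_that("counts separate singles from foci and handle empty tables", {
  lab <- array(0L, c(4, 10, 10)); lab[, 1:5, ] <- 1L; lab[, 6:10, ] <- 2L
  m <- compartment_mask(lab, c("1" = "soma", "2" = "neuropil"), c(0.35, 0.13, 0.13))
  empty <- data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      spot_class = character(0), compartment = character(0),
                      focus_transcript_estimate = numeric(0))
  c0 <- per_compartment_counts(empty, m)
  expect_true(all(c0$n_single_mRNA == 0L) && all(c0$n_foci == 0L))
  sp <- data.frame(z_um = c(0.5, 0.5, 0.5), y_um = c(0.2, 0.2, 0.9), x_um = 0.5,
                   spot_class = c("single", "focus", "single"),
                   focus_transcript_estimate = c(NA, 3.5, NA),
                   compartment = NA_character_)
  cc <- per_compartment_counts(sp, m)
  soma <- cc[cc$compartment == "soma", ]
  expect_equal(soma$n_single_mRNA, 1L)      # foci excluded from singles
  expect_equal(soma$n_foci, 1L)
  expect_equal(soma$sum_focus_transcripts, 3.5)
  # protein channel averaging
  prot <- array(0, c(4, 10, 10)); prot[, 1:5, ] <- 7
  cp <- per_compartment_counts(sp, m, protein_channel = prot)
  expect_equal(cp$protein_mean_intensity[cp$compartment == "soma"], 7)
  expect_equal(cp$protein_mean_intensity[cp$compartment == "neuropil"], 0)
})

test_that("ghost and mature boutons are classified by PSD signal", {
  lab <- array(0L, c(4, 10, 30))
  lab[, 4:7, 2:6] <- 1L; lab[, 4:7, 12:16] <- 2L; lab[, 4:7, 22:26] <- 3L
  m <- compartment_mask(lab, c("1" = "bouton_1", "2" = "bouton_2", "3" = "bouton_3"),
                        c(0.35, 0.13, 0.13))
  presyn <- array(100, c(4, 10, 30))
  psd <- array(0, c(4, 10, 30)); psd[lab == 2L] <- 80
  out <- classify_boutons(m, presyn, psd, params = list(psd_threshold = 40))
  expect_equal(out$maturity, c("ghost", "mature", "ghost"))
  # empty mask -> empty list
  e <- compartment_mask(array(0L, c(2, 4, 4)), character(0), c(1, 1, 1))
  expect_equal(nrow(classify_boutons(e, presyn, psd)), 0L)
})

test_that("simulated NMJ recovers the planted ghost boutons", {
  shape <- c(16L, 128L, 128L); vs <- c(0.35, 0.13, 0.13)
  cfg <- sim_config(image_shape = shape, voxel_size = vs,
                    compartment_layout = bouton_layout(shape, vs, 10L),
                    n_single_spots = 0L, n_foci = 0L, n_background_blobs = 0L,
                    bouton_psd_negative = 3L, seed = 9L)
  sim <- simulate_image_stack(cfg)
  seg <- segment_marker(sim$stack, "presyn", list(min_volume = 10, label = "bouton"))
  expect_equal(length(seg$label_names), 10L)
  out <- classify_boutons(seg, sim$stack$channels$presyn, sim$stack$channels$psd)
  expect_equal(sum(out$maturity == "ghost"), 3L)
})
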