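#' Configuration for the synthetic image generator
#'
#' The generator renders the signal structure the downstream analysis
#' assumes: diffraction-limited single-molecule spots of near-uniform
#' intensity, brighter nuclear transcription foci whose amplitude is an
#' integer multiple of the single-molecule intensity, wider and dimmer
#' background blobs, a marker channel delineating the compartment layout,
#' and a second probe channel sharing a configurable fraction of the first
#' channel's spot positions.
#'
#' @param image_shape integer `(z, y, x)` voxel counts.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param psf [psf_model()] giving lateral/axial Gaussian widths in um.
#' @param n_single_spots number of single-molecule spots in probe channel A.
#' @param single_amplitude_mean mean single-molecule peak amplitude (photons).
#' @param single_amplitude_cv coefficient of variation of single amplitudes;
#'   small, reflecting the near-uniform intensity of tiled-probe smFISH.
#' @param n_foci number of nuclear transcription foci.
#' @param focus_transcript_counts integer transcript count per focus
#'   (each >= 2); `NULL` draws uniformly from 3..8.
#' @param n_background_blobs number of background shapes.
#' @param blob_sigma_factor blob width as a multiple of the PSF sigma (> 1).
#' @param blob_amplitude_factor blob amplitude as a fraction of the
#'   single-molecule amplitude (< 1).
#' @param codetection_fraction probability that a probe-A single spot has a
#'   jittered partner in probe channel B.
#' @param noise list with `baseline` (photons) and `read_sd` (camera read
#'   noise standard deviation).
#' @param compartment_layout list of [ellipsoid()] / [tube()] primitives;
#'   defaults to a soma + nucleus + axon-terminal layout scaled to the image.
#' @param bouton_psd_negative number of bouton objects rendered without PSD
#'   signal (ghost boutons) when the layout contains boutons.
#' @param seed integer seed; all randomness in one generator call derives
#'   from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(image_shape = c(20L, 160L, 160L),
                       voxel_size = c(0.35, 0.13, 0.13),
                       psf = psf_model(0.13, 0.35),
                       n_single_spots = 200L,
                       single_amplitude_mean = 200,
                       single_amplitude_cv = 0.05,
                       n_foci = 2L,
                       focus_transcript_counts = NULL,
                       n_background_blobs = 5L,
                       blob_sigma_factor = 2.5,
                       blob_amplitude_factor = 0.3,
                       codetection_fraction = 0.85,
                       noise = list(baseline = 100, read_sd = 2),
                       compartment_layout = NULL,
                       bouton_psd_negative = 0L,
                       seed = 1L) {
  check_that(length(image_shape) == 3L && all(image_shape >= 4), "image_shape must be 3 values >= 4")
  check_that(all(voxel_size > 0), "voxel_size must be positive")
  check_that(inherits(psf, "psf_model"), "psf must be a psf_model")
  counts <- c(n_single_spots, n_foci, n_background_blobs)
  check_that(all(counts >= 0), "spot/foci/blob counts must be >= 0")
  check_that(single_amplitude_mean > 0 && single_amplitude_cv >= 0 &&
               noise$baseline >= 0 && noise$read_sd >= 0,
             "photon parameters must be non-negative")
  check_that(codetection_fraction >= 0 && codetection_fraction <= 1,
             "codetection_fraction must lie in [0, 1]")
  check_that(blob_sigma_factor > 1, "blob_sigma_factor must be > 1")
  check_that(blob_amplitude_factor < 1, "blob_amplitude_factor must be < 1")
  if (!is.null(focus_transcript_counts))
    check_that(all(focus_transcript_counts >= 2), "focus transcript counts must be >= 2")
  extent <- (image_shape - 1) * voxel_size
  if (is.null(compartment_layout))
    compartment_layout <- default_compartment_layout(image_shape, voxel_size)
  for (prim in compartment_layout) {
    bb <- primitive_bbox(prim)
    check_that(all(bb[1, ] >= -1e-9) && all(bb[2, ] <= extent + 1e-9),
               sprintf("layout primitive '%s' does not fit the image", prim$label))
  }
  if (n_foci > 0)
    check_that(any(vapply(compartment_layout, function(p) identical(p$channel, "nuclear"),
                          logical(1))),
               "n_foci > 0 requires a nucleus (channel = 'nuclear') in the layout")
  structure(list(image_shape = as.integer(image_shape), voxel_size = as.numeric(voxel_size),
                 psf = psf, n_single_spots = as.integer(n_single_spots),
                 single_amplitude_mean = single_amplitude_mean,
                 single_amplitude_cv = single_amplitude_cv,
                 n_foci = as.integer(n_foci),
                 focus_transcript_counts = focus_transcript_counts,
                 n_background_blobs = as.integer(n_background_blobs),
                 blob_sigma_factor = blob_sigma_factor,
                 blob_amplitude_factor = blob_amplitude_factor,
                 codetection_fraction = codetection_fraction,
                 noise = noise, compartment_layout = compartment_layout,
                 bouton_psd_negative = as.integer(bouton_psd_negative),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default soma / nucleus / axon-terminal layout scaled to an image
#'
#' Places a cell-body ellipsoid with a nucleus inside it in one corner of
#' the field and an axon-terminal tube along the other side, proportioned to
#' the physical extent of the stack.
#' @inheritParams render_compartments
#' @export
default_compartment_layout <- function(shape, voxel_size) {
  ext <- (shape - 1) * voxel_size
  zc <- ext[1] / 2
  soma_c <- c(zc, ext[2] * 0.30, ext[3] * 0.30)
  soma_r <- c(ext[1] * 0.42, ext[2] * 0.24, ext[3] * 0.24)
  nuc_r <- soma_r * 0.55
  list(
    ellipsoid("central_brain_soma", soma_c, soma_r, channel = "marker"),
    ellipsoid("nucleus", soma_c, nuc_r, channel = "nuclear"),
    tube("nmj_axon_terminal",
         c(zc, ext[2] * 0.75, ext[3] * 0.10),
         c(zc, ext[2] * 0.75, ext[3] * 0.90),
         radius_um = min(ext[1], ext[2]) * 0.12, channel = "marker")
  )
}

#' Bouton-row layout for neuromuscular-junction simulations
#'
#' An axon tube with `n_boutons` spherical boutons along it, for ghost-bouton
#' classification tests.
#' @inheritParams render_compartments
#' @param n_boutons number of boutons.
#' @export
bouton_layout <- function(shape, voxel_size, n_boutons = 10L) {
  ext <- (shape - 1) * voxel_size
  zc <- ext[1] / 2
  xs <- seq(ext[3] * 0.08, ext[3] * 0.92, length.out = n_boutons)
  spacing <- if (n_boutons > 1) xs[2] - xs[1] else ext[3] * 0.4
  r <- min(ext[1] * 0.30, 0.28 * spacing)
  prims <- list(tube("nmj_axon_terminal", c(zc, ext[2] * 0.35, ext[3] * 0.05),
                     c(zc, ext[2] * 0.35, ext[3] * 0.95), radius_um = r * 0.5))
  for (i in seq_len(n_boutons)) {
    prims[[length(prims) + 1L]] <-
      ellipsoid("bouton", c(zc, ext[2] * 0.65, xs[i]), c(r, r, r), channel = "presyn")
  }
  prims
}

uniform_positions <- function(n, shape, voxel_size, margin_um) {
  ext <- (shape - 1) * voxel_size
  check_that(all(ext > 2 * margin_um), "image too small for spot margin")
  cbind(z_um = stats::runif(n, margin_um[1], ext[1] - margin_um[1]),
        y_um = stats::runif(n, margin_um[2], ext[2] - margin_um[2]),
        x_um = stats::runif(n, margin_um[3], ext[3] - margin_um[3]))
}

#' Simulate a multichannel smFISH stack with complete ground truth
#'
#' Renders probe channel A (singles + foci + blobs), probe channel B sharing
#' `codetection_fraction` of A's single positions within localization
#' jitter, a marker channel drawn from the compartment layout, a nuclear
#' channel, and (for bouton layouts) presynaptic/PSD channels. Poisson shot
#' noise plus Gaussian read noise is applied to every channel.
#'
#' @param config a [sim_config()].
#' @return list with elements `stack` ([image_stack()]) and `truth` (list:
#'   `spots` data frame with class/channel/shared_id/compartment,
#'   `mask` the true [compartment_mask()], `true_codetection_fraction`,
#'   `per_compartment_counts`, `boutons`, and the `seed` used).
#' @export
simulate_image_stack <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, {
    shape <- config$image_shape; vs <- config$voxel_size
    psf <- config$psf
    mask <- render_compartments(config$compartment_layout, shape, vs)
    margin <- 4 * c(psf$sigma_axial, psf$sigma_lateral, psf$sigma_lateral)

    empty_spots <- data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                              amplitude = numeric(0), sigma_lat_um = numeric(0),
                              sigma_ax_um = numeric(0), class = character(0),
                              channel = character(0), shared_id = integer(0))
    spots <- empty_spots

    if (config$n_single_spots > 0) {
      pos <- uniform_positions(config$n_single_spots, shape, vs, margin)
      amp <- pmax(stats::rnorm(config$n_single_spots, config$single_amplitude_mean,
                               config$single_amplitude_mean * config$single_amplitude_cv),
                  config$single_amplitude_mean * 0.2)
      spots <- rbind(spots, data.frame(pos, amplitude = amp,
                                       sigma_lat_um = psf$sigma_lateral,
                                       sigma_ax_um = psf$sigma_axial,
                                       class = "single", channel = "probe_a",
                                       shared_id = NA_integer_))
    }
    if (config$n_foci > 0) {
      nuc_ids <- which(vapply(config$compartment_layout,
                              function(p) identical(p$channel, "nuclear"), logical(1)))
      nuc_vox <- which(mask$labels %in% nuc_ids)
      check_that(length(nuc_vox) > 0, "nucleus primitive renders no voxels")
      pick <- sample(nuc_vox, config$n_foci, replace = TRUE)
      ai <- arrayInd(pick, shape)
      counts <- config$focus_transcript_counts %||% sample(3:8, config$n_foci, replace = TRUE)
      check_that(length(counts) == config$n_foci, "need one transcript count per focus")
      spots <- rbind(spots, data.frame(
        z_um = (ai[, 1] - 1 + stats::runif(config$n_foci, -0.4, 0.4)) * vs[1],
        y_um = (ai[, 2] - 1 + stats::runif(config$n_foci, -0.4, 0.4)) * vs[2],
        x_um = (ai[, 3] - 1 + stats::runif(config$n_foci, -0.4, 0.4)) * vs[3],
        amplitude = counts * config$single_amplitude_mean,
        sigma_lat_um = psf$sigma_lateral, sigma_ax_um = psf$sigma_axial,
        class = "focus", channel = "probe_a", shared_id = NA_integer_))
    }
    if (config$n_background_blobs > 0) {
      pos <- uniform_positions(config$n_background_blobs, shape, vs, margin)
      spots <- rbind(spots, data.frame(
        pos, amplitude = config$blob_amplitude_factor * config$single_amplitude_mean,
        sigma_lat_um = psf$sigma_lateral * config$blob_sigma_factor,
        sigma_ax_um = psf$sigma_axial * config$blob_sigma_factor,
        class = "blob", channel = "probe_a", shared_id = NA_integer_))
    }

    # probe B: jittered partners of a codetection_fraction share of A singles,
    # plus unshared B-only singles keeping |B| ~ |A|
    a_single <- which(spots$class == "single" & spots$channel == "probe_a")
    shared <- a_single[stats::runif(length(a_single)) < config$codetection_fraction]
    b_spots <- empty_spots
    if (length(shared) > 0) {
      jit <- 0.5 * psf$sigma_lateral
      spots$shared_id[shared] <- seq_along(shared)
      b_spots <- rbind(b_spots, data.frame(
        z_um = spots$z_um[shared] + stats::rnorm(length(shared), 0, jit),
        y_um = spots$y_um[shared] + stats::rnorm(length(shared), 0, jit),
        x_um = spots$x_um[shared] + stats::rnorm(length(shared), 0, jit),
        amplitude = pmax(stats::rnorm(length(shared), config$single_amplitude_mean,
                                      config$single_amplitude_mean * config$single_amplitude_cv),
                         config$single_amplitude_mean * 0.2),
        sigma_lat_um = psf$sigma_lateral, sigma_ax_um = psf$sigma_axial,
        class = "single", channel = "probe_b", shared_id = seq_along(shared)))
    }
    n_b_only <- length(a_single) - length(shared)
    if (n_b_only > 0) {
      pos <- uniform_positions(n_b_only, shape, vs, margin)
      b_spots <- rbind(b_spots, data.frame(
        pos, amplitude = pmax(stats::rnorm(n_b_only, config$single_amplitude_mean,
                                           config$single_amplitude_mean * config$single_amplitude_cv),
                              config$single_amplitude_mean * 0.2),
        sigma_lat_um = psf$sigma_lateral, sigma_ax_um = psf$sigma_axial,
        class = "single", channel = "probe_b", shared_id = NA_integer_))
    }
    spots <- rbind(spots, b_spots)
    rownames(spots) <- NULL

    # render channels
    clean_a <- render_spots(spots[spots$channel == "probe_a", , drop = FALSE], shape, vs)
    clean_b <- render_spots(spots[spots$channel == "probe_b", , drop = FALSE], shape, vs)
    marker <- array(0, shape); nuclear <- array(0, shape)
    presyn <- NULL; psd <- NULL
    has_boutons <- any(vapply(config$compartment_layout,
                              function(p) identical(p$channel, "presyn"), logical(1)))
    bouton_truth <- NULL
    if (has_boutons) { presyn <- array(0, shape); psd <- array(0, shape) }
    grids <- coord_grids(shape, vs)
    bouton_idx <- 0L
    if (has_boutons) {
      n_b <- sum(vapply(config$compartment_layout,
                        function(p) identical(p$channel, "presyn"), logical(1)))
      check_that(config$bouton_psd_negative <= n_b,
                 "bouton_psd_negative exceeds number of boutons")
      ghost_ids <- if (config$bouton_psd_negative > 0)
        sample(n_b, config$bouton_psd_negative) else integer(0)
      bouton_truth <- data.frame(bouton = seq_len(n_b),
                                 maturity = ifelse(seq_len(n_b) %in% ghost_ids,
                                                   "ghost", "mature"))
    }
    for (prim in config$compartment_layout) {
      mem <- primitive_membership(prim, grids)
      lvl <- prim$level
      if (identical(prim$channel, "nuclear")) nuclear[mem] <- nuclear[mem] + lvl
      else if (identical(prim$channel, "presyn")) {
        bouton_idx <- bouton_idx + 1L
        presyn[mem] <- presyn[mem] + lvl
        if (bouton_truth$maturity[bouton_idx] == "mature") psd[mem] <- psd[mem] + lvl
      } else marker[mem] <- marker[mem] + lvl
    }

    bl <- config$noise$baseline; rs <- config$noise$read_sd
    channels <- list(probe_a = apply_noise(clean_a, bl, rs),
                     probe_b = apply_noise(clean_b, bl, rs),
                     marker = apply_noise(marker, bl, rs),
                     nuclear = apply_noise(nuclear, bl, rs))
    if (has_boutons) {
      channels$presyn <- apply_noise(presyn, bl, rs)
      channels$psd <- apply_noise(psd, bl, rs)
    }
    stack <- image_stack(channels, vs)

    spots$compartment <- mask_label_at(mask, spots[, c("z_um", "y_um", "x_um")])
    a_singles <- spots[spots$channel == "probe_a" & spots$class == "single", ]
    per_comp <- table(factor(a_singles$compartment,
                             levels = c(unname(mask$label_names), "outside")))
    truth <- list(spots = spots, mask = mask,
                  true_codetection_fraction =
                    if (length(a_single) > 0) length(shared) / length(a_single) else NA_real_,
                  per_compartment_counts = per_comp,
                  boutons = bouton_truth, seed = config$seed)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a two-arm condition pair with a known count reduction
#'
#' Arm A draws per-image single-spot counts from Poisson(`n_single_spots`);
#' arm B from a Poisson whose mean is scaled by `1 - reduction_fraction`
#' (the structure of a transport-mutant experiment where transcript counts
#' per terminal collapse). With `images = FALSE` only the count draws are
#' returned, for count-level Monte Carlo work.
#'
#' @param config a [sim_config()]; `n_single_spots` is the arm-A mean.
#' @param reduction_fraction fraction by which the arm-B mean is reduced.
#' @param n_replicates_per_arm images per arm (>= 2).
#' @param images render full stacks (`TRUE`) or counts only.
#' @return list with `arm_a`, `arm_b` (lists of `simulate_image_stack()`
#'   results, or integer counts), `counts_a`, `counts_b`, `true_ratio`.
#' @export
simulate_condition_pair <- function(config, reduction_fraction, n_replicates_per_arm,
                                    images = TRUE) {
  check_that(reduction_fraction >= 0 && reduction_fraction <= 1,
             "reduction_fraction must lie in [0, 1]")
  check_that(n_replicates_per_arm >= 2, "need >= 2 replicates per arm (comparison undefined)")
  with_seed(config$seed, {
    n <- n_replicates_per_arm
    mu_a <- config$n_single_spots
    mu_b <- mu_a * (1 - reduction_fraction)
    counts_a <- stats::rpois(n, mu_a)
    counts_b <- stats::rpois(n, mu_b)
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    build <- function(count, seed) {
      cfg <- config
      cfg$n_single_spots <- as.integer(count)
      cfg$seed <- seed
      class(cfg) <- "sim_config"
      simulate_image_stack(cfg)
    }
    out <- list(counts_a = counts_a, counts_b = counts_b,
                true_ratio = 1 - reduction_fraction)
    if (images) {
      out$arm_a <- mapply(build, counts_a, seeds[seq_len(n)], SIMPLIFY = FALSE)
      out$arm_b <- mapply(build, counts_b, seeds[n + seq_len(n)], SIMPLIFY = FALSE)
    }
    out
  })
}
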