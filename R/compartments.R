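#' Labelled 3D compartment mask
#'
#' @param labels integer 3D array aligned to an image stack; 0 = outside.
#' @param label_names named character vector mapping label id (as name) to
#'   compartment name; names must be injective.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @export
compartment_mask <- function(labels, label_names, voxel_size) {
  check_that(length(dim(labels)) == 3L, "labels must be a 3D array")
  label_names <- stats::setNames(as.character(label_names), names(label_names))
  check_that(!anyDuplicated(label_names), "label names must be unique (ids map injectively)")
  structure(list(labels = labels, label_names = label_names,
                 voxel_size = as.numeric(voxel_size)),
            class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat(sprintf("<compartment_mask> %s voxels, %d compartments: %s\n",
              paste(dim(x$labels), collapse = " x "), length(x$label_names),
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

# Compartment name at the voxel nearest each position (um). Positions are a
# data frame / matrix with columns z_um, y_um, x_um. Outside any labelled
# component (or outside the volume) -> "outside".
mask_label_at <- function(mask, positions) {
  if (NROW(positions) == 0L) return(character(0))
  positions <- as.data.frame(positions)
  d <- dim(mask$labels)
  iz <- pmin(pmax(round(positions$z_um / mask$voxel_size[1]) + 1, 1), d[1])
  iy <- pmin(pmax(round(positions$y_um / mask$voxel_size[2]) + 1, 1), d[2])
  ix <- pmin(pmax(round(positions$x_um / mask$voxel_size[3]) + 1, 1), d[3])
  ids <- mask$labels[cbind(iz, iy, ix)]
  out <- rep("outside", length(ids))
  hit <- ids > 0
  out[hit] <- unname(mask$label_names[as.character(ids[hit])])
  out
}

#' Nervous-system compartment taxonomy
#'
#' The fixed set of scored compartments, each mapped to a cell class
#' (neuron / glia / muscle), a subregion (soma / periphery), and the tissue
#' it is scored in. The neuronal periphery is the neuropil, nerve and
#' axon-terminal set; the glial periphery is the glial-process set.
#'
#' @return data frame with columns `label`, `cell_class`, `subregion`,
#'   `tissue`.
#' @export
compartment_taxonomy <- function() {
  data.frame(
    label = c("central_brain_soma", "neuroblast_lineage", "mushroom_body_neuropil",
              "optic_lobe_neuropil", "vnc_neuropil", "segmental_nerve",
              "nmj_axon_terminal", "psd", "muscle_cytoplasm", "muscle_nucleus",
              "glial_process_cortex", "glial_process_neuropil", "glial_process_nmj"),
    cell_class = c("neuron", "neuron", "neuron", "neuron", "neuron", "neuron",
                   "neuron", "muscle", "muscle", "muscle", "glia", "glia", "glia"),
    subregion = c("soma", "soma", "periphery", "periphery", "periphery", "periphery",
                  "periphery", "periphery", "soma", "soma",
                  "periphery", "periphery", "periphery"),
    tissue = c("brain", "brain", "brain", "brain", "vnc", "vnc",
               "nmj", "nmj", "nmj", "nmj", "brain", "brain", "nmj"),
    stringsAsFactors = FALSE
  )
}

#' Segment a marker channel into labelled 3D compartments
#'
#' Gaussian smoothing, a global threshold (Otsu unless overridden),
#' morphological closing, 26-connected components, and a minimum-volume
#' filter. Components are ordered deterministically by centroid `(z, y, x)`.
#'
#' @param stack an [image_stack()].
#' @param marker_channel channel to segment.
#' @param params list: `smooth_sigma_vox` (default 1), `threshold` (NULL =
#'   Otsu), `close_radius` (voxels, default 1), `min_volume` (voxels,
#'   default 30), `label` (compartment name for retained components),
#'   `background_radius` (pixels; NULL skips rolling-ball subtraction).
#' @return a [compartment_mask()]; empty (no surviving component) gives an
#'   all-zero mask with a warning, not an error.
#' @export
segment_marker <- function(stack, marker_channel = "marker", params = list()) {
  img <- get_channel(stack, marker_channel)
  p <- utils::modifyList(list(smooth_sigma_vox = 1, threshold = NULL, close_radius = 1L,
                              min_volume = 30L, label = "compartment",
                              background_radius = NULL, min_contrast = 3), params)
  if (!is.null(p$background_radius))
    img <- subtract_background_array(img, p$background_radius)
  sm <- gaussian_smooth3(img, rep(p$smooth_sigma_vox, 3))
  thr <- p$threshold %||% otsu_threshold(sm)
  # a usable global threshold must clear the background level by a real
  # margin, otherwise a blank channel would be split down the noise
  floor_thr <- stats::median(sm) + p$min_contrast * stats::mad(sm)
  if (is.null(p$threshold) && thr < floor_thr) {
    warning("segment_marker: no component survived the volume filter; empty mask")
    return(compartment_mask(array(0L, dim(img)), character(0), stack$voxel_size))
  }
  b <- sm > thr
  if (p$close_radius >= 1) b <- binary_close3(b, p$close_radius)
  cc <- connected_components3(b)
  k <- max(cc)
  keep <- integer(0)
  if (k > 0) {
    vol <- tabulate(cc[cc > 0], k)
    keep <- which(vol >= p$min_volume)
  }
  if (length(keep) == 0L) {
    warning("segment_marker: no component survived the volume filter; empty mask")
    return(compartment_mask(array(0L, dim(img)), character(0), stack$voxel_size))
  }
  # deterministic ordering by centroid (z, y, x)
  cent <- t(vapply(keep, function(id) colMeans(arrayInd(which(cc == id), dim(cc))),
                   numeric(3)))
  ord <- order(cent[, 1], cent[, 2], cent[, 3])
  keep <- keep[ord]
  lab <- array(0L, dim(img))
  for (i in seq_along(keep)) lab[cc == keep[i]] <- i
  nms <- if (length(keep) == 1L) p$label else paste0(p$label, "_", seq_along(keep))
  compartment_mask(lab, stats::setNames(nms, seq_along(keep)), stack$voxel_size)
}

#' Assign detected spots to compartments
#'
#' Each spot receives the label of its nearest voxel in the mask; spots in
#' unlabelled space get `"outside"`. Assignment is total and exclusive, so
#' `n_outside + sum(per-compartment) == nrow(spots)`.
#'
#' @param spots a spot table (see [detect_spots()]).
#' @param mask a [compartment_mask()] sharing the spot coordinate frame.
#' @return the spot table with its `compartment` column filled in.
#' @export
assign_spots <- function(spots, mask) {
  vs <- attr(spots, "voxel_size")
  if (!is.null(vs))
    check_that(isTRUE(all.equal(vs, mask$voxel_size)),
               "spot table and mask voxel sizes differ (coordinate frame mismatch)",
               input_error)
  spots$compartment <- mask_label_at(mask, spots)
  spots
}

#' Per-compartment transcript counts
#'
#' Singles are counted per compartment; transcription foci are counted
#' separately with their transcript-estimate sum; optionally the mean
#' intensity of a protein channel over each compartment's voxels is added.
#'
#' @param spots classified, compartment-assigned spot table.
#' @param mask a [compartment_mask()].
#' @param protein_channel optional 3D array (or [image_stack()] channel
#'   name via `protein_from`) to average per compartment.
#' @param image_id identifier copied into the output rows.
#' @return data frame: `image_id`, `compartment`, `n_single_mRNA`,
#'   `n_foci`, `sum_focus_transcripts`, `protein_mean_intensity`.
#' @export
per_compartment_counts <- function(spots, mask, protein_channel = NULL,
                                   image_id = "image") {
  labs <- c(unname(mask$label_names), "outside")
  if (is.null(spots$compartment) || anyNA(spots$compartment))
    spots <- assign_spots(spots, mask)
  cls <- spots$spot_class %||% spots$class
  singles <- spots[!is.na(cls) & cls == "single", , drop = FALSE]
  foci <- spots[!is.na(cls) & cls == "focus", , drop = FALSE]
  n_single <- table(factor(singles$compartment, levels = labs))
  n_foci <- table(factor(foci$compartment, levels = labs))
  tr <- foci$focus_transcript_estimate %||% rep(0, nrow(foci))
  sum_tr <- vapply(labs, function(l) sum(tr[foci$compartment == l]), numeric(1))
  prot <- rep(NA_real_, length(labs))
  if (!is.null(protein_channel)) {
    for (i in seq_along(mask$label_names)) {
      id <- as.integer(names(mask$label_names)[i])
      sel <- mask$labels == id
      prot[i] <- if (any(sel)) mean(protein_channel[sel]) else NA_real_
    }
  }
  data.frame(image_id = image_id, compartment = labs,
             n_single_mRNA = as.integer(n_single), n_foci = as.integer(n_foci),
             sum_focus_transcripts = sum_tr, protein_mean_intensity = prot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify bouton objects as ghost or mature
#'
#' Ghost boutons carry the presynaptic marker but have not yet acquired the
#' postsynaptic-density marker: an object is a ghost when its mean PSD
#' intensity falls below the PSD threshold while its presynaptic mean is
#' above the presynaptic threshold. The default PSD threshold is Otsu over
#' the per-object PSD means (override with `params$psd_threshold`).
#'
#' @param mask [compartment_mask()] whose labelled objects are boutons.
#' @param presyn_channel,psd_channel 3D intensity arrays.
#' @param params list: `psd_threshold`, `presyn_threshold` (default 0).
#' @return data frame of bouton objects: id, centroid (um), volume (um^3),
#'   marker means, `maturity`; zero rows when the mask is empty.
#' @export
classify_boutons <- function(mask, presyn_channel, psd_channel, params = list()) {
  p <- utils::modifyList(list(psd_threshold = NULL, presyn_threshold = 0), params)
  ids <- as.integer(names(mask$label_names))
  if (length(ids) == 0L)
    return(data.frame(object = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), volume_um3 = numeric(0),
                      presynaptic_marker_mean = numeric(0), psd_marker_mean = numeric(0),
                      maturity = character(0)))
  vs <- mask$voxel_size
  vox_vol <- prod(vs)
  rows <- lapply(seq_along(ids), function(i) {
    sel <- which(mask$labels == ids[i])
    ai <- arrayInd(sel, dim(mask$labels))
    cen <- (colMeans(ai) - 1) * vs
    data.frame(object = i, z_um = cen[1], y_um = cen[2], x_um = cen[3],
               volume_um3 = length(sel) * vox_vol,
               presynaptic_marker_mean = mean(presyn_channel[sel]),
               psd_marker_mean = mean(psd_channel[sel]))
  })
  out <- do.call(rbind, rows)
  thr <- p$psd_threshold %||% otsu_threshold(out$psd_marker_mean, nbins = 64L)
  out$maturity <- ifelse(out$psd_marker_mean < thr &
                           out$presynaptic_marker_mean > p$presyn_threshold,
                         "ghost", "mature")
  out
}
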