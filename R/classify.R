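#' Estimate the single-molecule unit intensity
#'
#' Tiled-probe smFISH renders single transcripts at near-uniform intensity,
#' so the unit intensity is taken as a robust centre of the candidate
#' amplitudes after excluding the top decile, which transcription foci
#' contaminate. Spread is the MAD on the same trimmed set.
#'
#' @param spots spot table or numeric amplitude vector (>= 10 candidates).
#' @return list: `unit` (median), `spread` (MAD), `n_used`.
#' @export
estimate_unit_intensity <- function(spots) {
  amps <- if (is.numeric(spots)) spots else spots$amplitude
  amps <- amps[is.finite(amps)]
  if (length(amps) < 10L)
    input_error("need >= 10 candidate spots to estimate the unit intensity; pool spots across images")
  cut <- stats::quantile(amps, 0.9, names = FALSE)
  core <- amps[amps <= cut]
  list(unit = stats::median(core), spread = stats::mad(core), n_used = length(core))
}

#' Classify detections as single molecules, transcription foci, or rejects
#'
#' A spot is a focus when its amplitude reaches
#' `focus_intensity_factor x unit` and (when a nucleus mask is supplied) it
#' lies inside the nucleus; nuclear foci override the size gate, since
#' nascent-transcript clusters may exceed the PSF width. Otherwise a spot is
#' rejected when its fitted lateral sigma reaches
#' `max_size_factor x psf sigma` or its amplitude falls below
#' `min_intensity_factor x unit`; everything else is a single molecule.
#' Foci get `focus_transcript_estimate = amplitude / unit`.
#'
#' @param spots spot table from [detect_spots()].
#' @param unit unit intensity (number or result of
#'   [estimate_unit_intensity()]).
#' @param psf a [psf_model()].
#' @param params a [detection_params()].
#' @param nucleus_mask optional [compartment_mask()] of the nucleus; when
#'   absent the focus rule is intensity-only.
#' @return the spot table with `spot_class` and `focus_transcript_estimate`
#'   filled; classification is total (every row gets exactly one class).
#' @export
classify_spots <- function(spots, unit, psf, params = detection_params(),
                           nucleus_mask = NULL) {
  if (is.list(unit)) unit <- unit$unit
  check_that(is.numeric(unit) && is.finite(unit) && unit > 0,
             "unit intensity must be a positive number", input_error)
  if (nrow(spots) == 0L) return(spots)
  in_nucleus <- if (is.null(nucleus_mask)) rep(TRUE, nrow(spots)) else
    mask_label_at(nucleus_mask, spots) != "outside"
  is_focus <- spots$amplitude >= params$focus_intensity_factor * unit & in_nucleus
  too_big <- spots$sigma_lat_um >= params$max_size_factor * psf$sigma_lateral
  too_dim <- spots$amplitude < params$min_intensity_factor * unit
  cls <- ifelse(is_focus, "focus", ifelse(too_big | too_dim, "rejected", "single"))
  spots$spot_class <- cls
  spots$focus_transcript_estimate <- ifelse(cls == "focus", spots$amplitude / unit,
                                            NA_real_)
  prov <- attr(spots, "provenance")
  if (!is.null(prov)) {
    prov$unit_intensity <- unit
    prov$classify_params <- unclass(params)
    attr(spots, "provenance") <- prov
  }
  spots
}
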