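#' Detection and classification parameters
#'
#' Defaults follow the screen's processing choices: rolling-ball radii of
#' 5 px (smFISH) and 20 px (cell markers); a detection threshold of
#' `detection_threshold_k` robust sigmas of the band-pass response; size and
#' intensity gates expressed relative to the PSF width and the
#' single-molecule unit intensity; and a codetection match radius of twice
#' the lateral PSF sigma unless set explicitly.
#'
#' @param background_radius_smfish,background_radius_marker rolling-ball
#'   radii in pixels.
#' @param detection_threshold_k threshold in multiples of the robust
#'   background spread of the filtered image.
#' @param max_size_factor reject spots whose fitted lateral sigma reaches
#'   this multiple of the PSF sigma (> 1).
#' @param min_intensity_factor reject spots dimmer than this fraction of the
#'   unit intensity (in (0, 1)).
#' @param focus_intensity_factor call a focus at or above this multiple of
#'   the unit intensity (> 1).
#' @param match_radius codetection match radius in um (NULL = 2 x lateral
#'   PSF sigma).
#' @export
detection_params <- function(background_radius_smfish = 5,
                             background_radius_marker = 20,
                             detection_threshold_k = 5,
                             max_size_factor = 2.0,
                             min_intensity_factor = 0.4,
                             focus_intensity_factor = 2.5,
                             match_radius = NULL) {
  check_that(background_radius_smfish > 0 && background_radius_marker > 0,
             "background radii must be > 0")
  check_that(max_size_factor > 1, "max_size_factor must be > 1")
  check_that(min_intensity_factor > 0 && min_intensity_factor < 1,
             "min_intensity_factor must lie in (0, 1)")
  check_that(focus_intensity_factor > 1, "focus_intensity_factor must be > 1")
  structure(list(background_radius_smfish = background_radius_smfish,
                 background_radius_marker = background_radius_marker,
                 detection_threshold_k = detection_threshold_k,
                 max_size_factor = max_size_factor,
                 min_intensity_factor = min_intensity_factor,
                 focus_intensity_factor = focus_intensity_factor,
                 match_radius = match_radius),
            class = "detection_params")
}

empty_spot_table <- function(channel = NA_character_) {
  data.frame(channel = character(0), z_um = numeric(0), y_um = numeric(0),
             x_um = numeric(0), amplitude = numeric(0), sigma_lat_um = numeric(0),
             sigma_ax_um = numeric(0), response = numeric(0),
             spot_class = character(0), focus_transcript_estimate = numeric(0),
             compartment = character(0), stringsAsFactors = FALSE)
}

# Weighted log-quadratic (Caruana/Guo) 1D Gaussian profile fit.
# Returns c(mu, sigma) in the coordinate units of `t`, or NULL when the
# profile carries no usable curvature.
fit_profile_gaussian <- function(t, p) {
  keep <- p > 0.05 * max(p)
  if (sum(keep) < 3L) return(NULL)
  t <- t[keep]; p <- p[keep]
  w <- p^2
  X <- cbind(1, t, t^2)
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * log(p))
  beta <- tryCatch(solve(xtwx, xtwy), error = function(e) NULL)
  if (is.null(beta) || beta[3] >= -1e-12) return(NULL)
  c(mu = -beta[2] / (2 * beta[3]), sigma = sqrt(-1 / (2 * beta[3])))
}

# Local 3D Gaussian refinement of one candidate: the local background
# (median of the window's border shell) is removed, the centre and widths
# come from separable projection fits, and the amplitude is a matched-filter
# linear least squares against a PSF-width template at the fitted centre.
# The PSF template keeps the amplitude estimate unbiased under noise in the
# fitted widths; classification gates are ratios against the unit intensity
# estimated with the same template, so any residual template bias cancels.
fit_spot <- function(img, center, sigma_vox) {
  d <- dim(img)
  mu <- as.numeric(center); sig <- sigma_vox
  w <- NULL; axes <- NULL
  contaminated <- FALSE
  # the window tracks the current width estimate, so objects wider than the
  # PSF (background blobs) are measured over their own scale
  for (pass in 1:3) {
    r <- pmax(2L, ceiling(2.5 * sig))
    iz <- max(1L, center[1] - r[1]):min(d[1], center[1] + r[1])
    iy <- max(1L, center[2] - r[2]):min(d[2], center[2] + r[2])
    ix <- max(1L, center[3] - r[3]):min(d[3], center[3] + r[3])
    w <- img[iz, iy, ix, drop = FALSE]
    border <- array(TRUE, dim(w))
    if (all(dim(w) > 2L))
      border[2:(dim(w)[1] - 1L), 2:(dim(w)[2] - 1L), 2:(dim(w)[3] - 1L)] <- FALSE
    w <- w - stats::median(w[border])
    axes <- list(iz, iy, ix)
    prev <- sig
    # profiles are projections weighted by the current-width Gaussian along
    # the other two axes: a neighbouring spot inside the window is strongly
    # down-weighted, and for an exact Gaussian the weighted projection is
    # still an exact Gaussian along the profiled axis
    for (sweep in 1:2) for (ax in 1:3) {
      others <- setdiff(1:3, ax)
      w1 <- exp(-((axes[[others[1]]] - mu[others[1]])^2) / (2 * sig[others[1]]^2))
      w2 <- exp(-((axes[[others[2]]] - mu[others[2]])^2) / (2 * sig[others[2]]^2))
      wm <- w1 %o% w2
      prof <- apply(w, ax, function(s) sum(s * wm))
      fit <- fit_profile_gaussian(axes[[ax]], prof)
      if (!is.null(fit)) {
        mu[ax] <- min(max(fit[["mu"]], axes[[ax]][1]), axes[[ax]][length(axes[[ax]])])
        sig[ax] <- min(max(fit[["sigma"]], 0.3 * sigma_vox[ax]), 4 * sigma_vox[ax])
      }
    }
    # a projection fit that drifts off its own candidate maximum signals a
    # neighbouring spot inside the window, not a wide object: reset to the
    # candidate anchor and let the Gauss-Newton stage resolve it locally
    if (max(abs(mu - as.numeric(center)) / pmax(sigma_vox, 1)) > 0.9) {
      mu <- as.numeric(center); sig <- sigma_vox
      contaminated <- TRUE
      break
    }
    # only clearly-wider-than-PSF objects earn a larger window; PSF-scale
    # spots must not chase neighbours in dense fields
    if (all(sig / sigma_vox < 1.6) || all(sig / prev < 1.1)) break
  }
  shape <- function(m) {
    list(gz = exp(-((axes[[1]] - m[1])^2) / (2 * sigma_vox[1]^2)),
         gy = exp(-((axes[[2]] - m[2])^2) / (2 * sigma_vox[2]^2)),
         gx = exp(-((axes[[3]] - m[3])^2) / (2 * sigma_vox[3]^2)))
  }
  g <- shape(mu)
  G <- g$gz %o% g$gy %o% g$gx
  amp <- sum(w * G) / sum(G * G)
  # Gauss-Newton refinement of centre, amplitude, and a local offset against
  # the PSF-width template; PSF-scale spots only (wider objects keep the
  # projection fit). The free offset removes any residual pedestal bias from
  # the border-median estimate.
  if (amp > 0) {
    offs <- 0
    for (it in 1:6) {
      G <- g$gz %o% g$gy %o% g$gx
      dz <- G * rep((axes[[1]] - mu[1]) / sigma_vox[1]^2, length(axes[[2]]) * length(axes[[3]]))
      dy <- G * rep(rep((axes[[2]] - mu[2]) / sigma_vox[2]^2, each = length(axes[[1]])),
                    length(axes[[3]]))
      dx <- G * rep((axes[[3]] - mu[3]) / sigma_vox[3]^2, each = length(axes[[1]]) * length(axes[[2]]))
      J <- cbind(as.vector(G), 1, amp * as.vector(dz), amp * as.vector(dy),
                 amp * as.vector(dx))
      r <- as.vector(w) - amp * as.vector(G) - offs
      step <- tryCatch(solve(crossprod(J), crossprod(J, r)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      amp <- amp + step[1]
      offs <- offs + step[2]
      mu_new <- mu + pmin(pmax(step[3:5], -1), 1)
      # stay anchored to this candidate's maximum
      mu_new <- pmin(pmax(mu_new, as.numeric(center) - 1.5), as.numeric(center) + 1.5)
      mu <- c(min(max(mu_new[1], axes[[1]][1]), axes[[1]][length(axes[[1]])]),
              min(max(mu_new[2], axes[[2]][1]), axes[[2]][length(axes[[2]])]),
              min(max(mu_new[3], axes[[3]][1]), axes[[3]][length(axes[[3]])]))
      g <- shape(mu)
      if (max(abs(step[3:5])) < 1e-3) break
    }
    G <- g$gz %o% g$gy %o% g$gx
    GG <- cbind(as.vector(G), 1)
    ab <- tryCatch(solve(crossprod(GG), crossprod(GG, as.vector(w))),
                   error = function(e) NULL)
    if (!is.null(ab) && all(is.finite(ab))) amp <- ab[1]
  }
  # width by template-scale profile likelihood: the LS residual of an
  # amplitude-free fit at scale s * PSF is minimised over a log-spaced scale
  # grid with parabolic refinement. Exact for a pure Gaussian (the true
  # scale zeroes the residual); much heavier-tailed estimators are avoided.
  scales <- c(0.6, 0.8, 1.0, 1.3, 1.6, 2.0, 2.5, 3.2, 4.0)
  sc_template <- function(s) {
    exp(-((axes[[1]] - mu[1])^2) / (2 * (s * sigma_vox[1])^2)) %o%
      exp(-((axes[[2]] - mu[2])^2) / (2 * (s * sigma_vox[2])^2)) %o%
      exp(-((axes[[3]] - mu[3])^2) / (2 * (s * sigma_vox[3])^2))
  }
  sc_score <- function(s) {
    # explained sum of squares of the LS fit with amplitude and offset free:
    # exact (zero residual) at the true scale for a pure Gaussian even after
    # the border-median subtraction
    Gs <- sc_template(s)
    q <- c(sum(w * Gs), sum(w))
    M <- matrix(c(sum(Gs * Gs), sum(Gs), sum(Gs), length(Gs)), 2)
    drop(crossprod(q, solve(M, q)))
  }
  score <- vapply(scales, sc_score, numeric(1))
  k <- which.max(score)
  s_hat <- scales[k]
  if (k > 1L && k < length(scales)) {
    lx <- log(scales[(k - 1):(k + 1)]); fy <- score[(k - 1):(k + 1)]
    den <- (fy[1] - 2 * fy[2] + fy[3])
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (fy[1] - fy[3]) / den
      s_ref <- exp(lx[2] + max(min(delta, 0.5), -0.5) * (lx[3] - lx[2]))
      # keep the interpolated scale only if it actually explains more
      if (sc_score(s_ref) > score[k]) s_hat <- s_ref
    }
  }
  sig <- s_hat * sigma_vox
  if (s_hat >= 1.6) {               # wide object: report its own peak height
    Gs <- sc_template(s_hat)
    GG <- cbind(as.vector(Gs), 1)
    ab <- tryCatch(solve(crossprod(GG), crossprod(GG, as.vector(w))),
                   error = function(e) NULL)
    if (!is.null(ab) && all(is.finite(ab))) amp <- ab[1]
  }
  list(mu = mu, sigma = sig, amplitude = amp, scale = s_hat)
}

#' Detect diffraction-limited spots in a 3D stack
#'
#' Candidates come from a scale-normalised Laplacian-of-Gaussian filter at
#' the PSF scale (anisotropy from the voxel size) and 3D local maxima above
#' `detection_threshold_k` robust sigmas of the filtered background. Each
#' candidate is refined by a local 3D Gaussian fit giving subpixel position,
#' amplitude and widths; duplicates within one lateral PSF sigma
#' (anisotropy-scaled distance) are merged keeping the brighter.
#'
#' @param image an [image_stack()] (name the channel via `channel`) or a 3D
#'   array with `voxel_size` supplied.
#' @param psf a [psf_model()].
#' @param params a [detection_params()].
#' @param channel channel name when `image` is a stack.
#' @param voxel_size um per voxel for bare arrays; an error if absent.
#' @param subtract apply rolling-ball subtraction internally (default TRUE).
#' @param image_id provenance tag.
#' @return a spot-table data frame (one row per detection) with attributes
#'   `voxel_size` and `provenance` (parameter snapshot).
#' @export
detect_spots <- function(image, psf, params = detection_params(), channel = NULL,
                         voxel_size = NULL, subtract = TRUE, image_id = "image") {
  if (inherits(image, "image_stack")) {
    voxel_size <- image$voxel_size
    img <- get_channel(image, channel)
  } else {
    check_that(!is.null(voxel_size),
               "voxel_size metadata is required (anisotropy unknown)", input_error)
    img <- image
  }
  channel <- channel %||% "channel_1"
  if (subtract) img <- subtract_background_array(img, params$background_radius_smfish)

  sv <- psf_sigma_vox(psf, voxel_size)
  sm <- gaussian_smooth3(img, sv)
  resp <- -(sv[1]^2 * second_diff3(sm, 1) + sv[2]^2 * second_diff3(sm, 2) +
              sv[3]^2 * second_diff3(sm, 3))
  noise <- stats::mad(resp)
  thr <- params$detection_threshold_k * noise
  maxima <- local_maxima3(resp) & resp > thr
  # exclude a PSF-sized border shell: the band-pass response and the local
  # fits are both unreliable against the image edge
  m <- pmin(ceiling(2 * sv) + 1L, (dim(img) - 1L) %/% 2L)
  d <- dim(img)
  if (m[1] > 0) maxima[c(seq_len(m[1]), d[1] - seq_len(m[1]) + 1L), , ] <- FALSE
  if (m[2] > 0) maxima[, c(seq_len(m[2]), d[2] - seq_len(m[2]) + 1L), ] <- FALSE
  if (m[3] > 0) maxima[, , c(seq_len(m[3]), d[3] - seq_len(m[3]) + 1L)] <- FALSE
  cand <- which(maxima)
  prov <- list(image_id = image_id, channel = channel, psf = unclass(psf),
               params = unclass(params), voxel_size = voxel_size)
  if (length(cand) == 0L) {
    out <- empty_spot_table()
    attr(out, "voxel_size") <- voxel_size; attr(out, "provenance") <- prov
    return(out)
  }
  cand <- cand[order(resp[cand], decreasing = TRUE)]
  ai <- arrayInd(cand, dim(img))
  fits <- lapply(seq_len(nrow(ai)), function(i) fit_spot(img, ai[i, ], sv))
  mu <- t(vapply(fits, `[[`, numeric(3), "mu"))       # R indices, fractional
  amp <- vapply(fits, `[[`, numeric(1), "amplitude")
  sig <- t(vapply(fits, `[[`, numeric(3), "sigma"))

  keep <- amp > 0
  mu <- mu[keep, , drop = FALSE]; amp <- amp[keep]; sig <- sig[keep, , drop = FALSE]
  rsp <- resp[cand][keep]
  if (length(amp) == 0L) {
    out <- empty_spot_table()
    attr(out, "voxel_size") <- voxel_size; attr(out, "provenance") <- prov
    return(out)
  }

  # merge: anisotropy-scaled distance below one lateral PSF sigma
  n <- length(amp)
  alive <- rep(TRUE, n)
  if (n > 1) {
    pos <- cbind((mu[, 1] - 1) * voxel_size[1], (mu[, 2] - 1) * voxel_size[2],
                 (mu[, 3] - 1) * voxel_size[3])
    zscale <- psf$sigma_lateral / psf$sigma_axial
    ord <- order(amp, decreasing = TRUE)
    for (i in seq_along(ord)) {
      a <- ord[i]
      if (!alive[a]) next
      later <- ord[-seq_len(i)]
      later <- later[alive[later]]
      if (length(later) == 0) next
      dd <- sqrt((pos[later, 2] - pos[a, 2])^2 + (pos[later, 3] - pos[a, 3])^2 +
                   ((pos[later, 1] - pos[a, 1]) * zscale)^2)
      alive[later[dd < psf$sigma_lateral]] <- FALSE
    }
  }
  mu <- mu[alive, , drop = FALSE]; amp <- amp[alive]; sig <- sig[alive, , drop = FALSE]
  rsp <- rsp[alive]

  out <- data.frame(channel = channel,
                    z_um = (mu[, 1] - 1) * voxel_size[1],
                    y_um = (mu[, 2] - 1) * voxel_size[2],
                    x_um = (mu[, 3] - 1) * voxel_size[3],
                    amplitude = amp,
                    sigma_lat_um = (sig[, 2] * voxel_size[2] + sig[, 3] * voxel_size[3]) / 2,
                    sigma_ax_um = sig[, 1] * voxel_size[1],
                    response = rsp,
                    spot_class = NA_character_,
                    focus_transcript_estimate = NA_real_,
                    compartment = NA_character_, stringsAsFactors = FALSE)
  attr(out, "voxel_size") <- voxel_size
  attr(out, "provenance") <- prov
  out
}
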