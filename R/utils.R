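# Internal helpers: error classes, seeded RNG scoping, array primitives.

ss_error <- function(msg, class) {
  stop(structure(class = c(class, "ss_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

config_error <- function(msg) ss_error(msg, "ss_config_error")
input_error  <- function(msg) ss_error(msg, "ss_input_error")

#' @noRd
check_that <- function(ok, msg, error = config_error) {
  if (!isTRUE(ok)) error(msg)
  invisible(TRUE)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All generator entry points route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# ---- array primitives (dim order is (z, y, x) throughout) -------------------

# Shift a 3D array by integer offsets, filling exposed voxels with `fill`.
shift3 <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
  tz <- sz + dz; ty <- sy + dy; tx <- sx + dx
  kz <- tz >= 1 & tz <= d[1]; ky <- ty >= 1 & ty <= d[2]; kx <- tx >= 1 & tx <= d[3]
  if (!any(kz) || !any(ky) || !any(kx)) return(out)
  out[tz[kz], ty[ky], tx[kx]] <- a[sz[kz], sy[ky], sx[kx]]
  out
}

# Reflected (mirror) index into 1..n for out-of-range i.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Separable 1D convolution along one axis of a 3D array, reflecting borders.
conv_axis3 <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- reflect_index(seq_len(d[axis]) + off, d[axis])
    term <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
    out <- out + kernel[j] * term
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis sigmas in voxels.
gaussian_smooth3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0.05) a <- conv_axis3(a, gaussian_kernel(sigma_vox[ax]), ax)
  }
  a
}

# Second difference along an axis (unit voxel spacing), reflected borders.
second_diff3 <- function(a, axis) {
  d <- dim(a)
  up <- reflect_index(seq_len(d[axis]) + 1L, d[axis])
  dn <- reflect_index(seq_len(d[axis]) - 1L, d[axis])
  pick <- function(idx) switch(axis, a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
  pick(up) + pick(dn) - 2 * a
}

# TRUE at voxels that are >= all 26 neighbours.
local_maxima3 <- function(a) {
  nb <- array(-Inf, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pmax(nb, shift3(a, dz, dy, dx, fill = -Inf))
  }
  a >= nb
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
}

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); tot <- w[nbins]
  mu <- cumsum(h * mids); mu_t <- mu[nbins]
  w1 <- w[-nbins]; w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu_t * w1[valid] / tot - mu[-nbins][valid])^2 /
    (w1[valid] / tot * w2[valid] / tot) / tot^2
  mids[which.max(between)]
}

# Binary closing of a 3D logical array with a 3x3x3 box.
binary_close3 <- function(b, radius = 1L) {
  if (radius < 1L) return(b)
  dil <- b
  for (dz in -radius:radius) for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dz == 0 && dy == 0 && dx == 0) next
    dil <- dil | shift3(b, dz, dy, dx, fill = FALSE) > 0
  }
  ero <- dil
  for (dz in -radius:radius) for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dz == 0 && dy == 0 && dx == 0) next
    ero <- ero & shift3(dil, dz, dy, dx, fill = FALSE) > 0
  }
  ero
}

# 26-connected components of a 3D logical array. Returns an integer array with
# components numbered 1..k in order of first (z,y,x) voxel; 0 = background.
connected_components3 <- function(b) {
  d <- dim(b)
  lab <- array(0L, d)
  idx <- which(b)
  if (length(idx) == 0L) return(lab)
  parent <- seq_along(idx)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ai <- arrayInd(idx, d)
  nz <- d[1]; ny <- d[2]
  # half-neighbourhood: offsets strictly "before" in linear order
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[order(offs$dx, offs$dy, offs$dz), ]
  offs <- offs[seq_len(13L), ]
  for (k in seq_len(nrow(offs))) {
    zz <- ai[, 1] + offs$dz[k]; yy <- ai[, 2] + offs$dy[k]; xx <- ai[, 3] + offs$dx[k]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    if (!any(ok)) next
    nb_lin <- zz[ok] + (yy[ok] - 1L) * nz + (xx[ok] - 1L) * nz * ny
    nb_pos <- pos[nb_lin]
    here <- which(ok)[nb_pos > 0L]
    nb_pos <- nb_pos[nb_pos > 0L]
    for (j in seq_along(here)) {
      a <- find(here[j]); bb <- find(nb_pos[j])
      if (a != bb) parent[max(a, bb)] <- min(a, bb)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[idx] <- relab
  lab
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95, one_sided = FALSE) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- if (one_sided) stats::qnorm(conf) else stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
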