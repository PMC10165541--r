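# Two-channel codetection: one-to-one matching of single-molecule spots
# between two spectrally separate probe channels.

# Anisotropy-aware squared distance: axial differences are scaled by the
# lateral/axial sigma ratio so one "distance unit" means the same
# localization confidence on every axis.
aniso_dist <- function(a, b, zscale) {
  sqrt((a[, 2] - b[, 2])^2 + (a[, 3] - b[, 3])^2 + ((a[, 1] - b[, 1]) * zscale)^2)
}

# Exact maximum-cardinality, minimum-total-distance matching on one small
# connected component, by branch-and-bound enumeration over the A side.
match_component_exact <- function(cand) {
  a_ids <- sort(unique(cand$a)); n_a <- length(a_ids)
  best <- list(size = -1L, cost = Inf, pairs = cand[0, ])
  recurse <- function(i, used_b, pairs, cost) {
    if (i > n_a) {
      sz <- nrow(pairs)
      if (sz > best$size || (sz == best$size && cost < best$cost))
        best <<- list(size = sz, cost = cost, pairs = pairs)
      return()
    }
    opts <- cand[cand$a == a_ids[i] & !(cand$b %in% used_b), , drop = FALSE]
    if (nrow(opts) > 0) {
      for (j in order(opts$d)) {
        recurse(i + 1L, c(used_b, opts$b[j]), rbind(pairs, opts[j, ]), cost + opts$d[j])
      }
    }
    recurse(i + 1L, used_b, pairs, cost)   # leave this A spot unmatched
  }
  recurse(1L, integer(0), cand[0, ], 0)
  best$pairs
}

# Greedy fallback for large components: A spots in amplitude-descending
# order (ties by lexicographic position) each take their nearest free B.
match_component_greedy <- function(cand, amp_a, pos_a) {
  a_ids <- unique(cand$a)
  ord <- a_ids[order(-amp_a[a_ids], pos_a[a_ids, 1], pos_a[a_ids, 2], pos_a[a_ids, 3])]
  used_b <- integer(0)
  out <- cand[0, ]
  for (a in ord) {
    opts <- cand[cand$a == a & !(cand$b %in% used_b), , drop = FALSE]
    if (nrow(opts) == 0) next
    j <- which.min(opts$d)
    out <- rbind(out, opts[j, ])
    used_b <- c(used_b, opts$b[j])
  }
  out
}

#' Two-channel spot codetection
#'
#' Restricts both tables to single-molecule spots, forms all candidate pairs
#' within `match_radius` (anisotropy-aware distance), and resolves them to a
#' one-to-one matching that maximises the number of matched pairs and, among
#' those, minimises total distance. Matching is exact per connected
#' component of the candidate-pair graph (components above
#' `max_exact_component` spots fall back to deterministic greedy
#' nearest-neighbour). The codetection fraction is
#' `matched_A / total_A`, reported with a Wilson binomial interval.
#'
#' @param spots_a,spots_b spot tables; rows with `spot_class` other than
#'   "single" are dropped (unclassified tables are used as-is).
#' @param match_radius um; default `2 x lateral PSF sigma`.
#' @param psf [psf_model()] (for the default radius and the axial scaling).
#' @param method `"assignment"` (default) or `"any_neighbor"`, which counts
#'   an A spot as codetected when any B spot lies within the radius.
#' @param max_exact_component exact-enumeration size cap per component.
#' @return object of class `codetection`: `fraction` (NA with
#'   `status = "undefined"` when the reference table is empty — distinct
#'   from 0), `n_matched`, `n_a`, `n_b`, `conf_int`, `matching` (data frame
#'   of index pairs with distances).
#' @export
codetect <- function(spots_a, spots_b, match_radius = NULL, psf = psf_model(),
                     method = c("assignment", "any_neighbor"),
                     max_exact_component = 10L) {
  method <- match.arg(method)
  match_radius <- match_radius %||% (2 * psf$sigma_lateral)
  sel <- function(s) {
    if (!is.null(s$spot_class) && any(!is.na(s$spot_class)))
      s <- s[!is.na(s$spot_class) & s$spot_class == "single", , drop = FALSE]
    s
  }
  a <- sel(spots_a); b <- sel(spots_b)
  empty_match <- data.frame(a = integer(0), b = integer(0), d = numeric(0))
  if (nrow(a) == 0L) {
    return(structure(list(fraction = NA_real_, status = "undefined",
                          n_matched = 0L, n_a = 0L, n_b = nrow(b),
                          conf_int = c(lower = NA_real_, upper = NA_real_),
                          matching = empty_match, match_radius = match_radius),
                     class = "codetection"))
  }
  pa <- cbind(a$z_um, a$y_um, a$x_um)
  pb <- cbind(b$z_um, b$y_um, b$x_um)
  zscale <- psf$sigma_lateral / psf$sigma_axial
  cand <- empty_match
  if (nrow(b) > 0L) {
    # candidate pairs within radius (coarse prefilter on y to stay light)
    for (i in seq_len(nrow(a))) {
      near <- which(abs(pb[, 2] - pa[i, 2]) <= match_radius)
      if (length(near) == 0) next
      d <- aniso_dist(pb[near, , drop = FALSE],
                      matrix(pa[i, ], length(near), 3, byrow = TRUE), zscale)
      hit <- near[d <= match_radius]
      if (length(hit) > 0)
        cand <- rbind(cand, data.frame(a = i, b = hit, d = d[d <= match_radius]))
    }
  }
  if (method == "any_neighbor") {
    matched_a <- unique(cand$a)
    matching <- if (length(matched_a)) do.call(rbind, lapply(matched_a, function(i) {
      rows <- cand[cand$a == i, ]
      rows[which.min(rows$d), ]
    })) else empty_match
  } else if (nrow(cand) == 0L) {
    matching <- empty_match
  } else {
    # connected components of the candidate graph (nodes: a_i, b_j)
    nodes <- c(paste0("a", cand$a), paste0("b", cand$b))
    uid <- unique(nodes)
    parent <- seq_along(uid)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    ia <- match(paste0("a", cand$a), uid); ib <- match(paste0("b", cand$b), uid)
    for (k in seq_len(nrow(cand))) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    comp <- vapply(ia, find, integer(1))
    matching <- empty_match
    for (cc in unique(comp)) {
      sub <- cand[comp == cc, , drop = FALSE]
      n_nodes <- length(unique(sub$a)) + length(unique(sub$b))
      m <- if (n_nodes <= max_exact_component) match_component_exact(sub)
      else match_component_greedy(sub, a$amplitude, pa)
      matching <- rbind(matching, m)
    }
  }
  k <- nrow(matching); n <- nrow(a)
  structure(list(fraction = k / n, status = "ok", n_matched = k, n_a = n,
                 n_b = nrow(b), conf_int = wilson_interval(k, n),
                 matching = matching[order(matching$a), , drop = FALSE],
                 match_radius = match_radius, method = method),
            class = "codetection")
}

#' @export
print.codetection <- function(x, ...) {
  if (identical(x$status, "undefined")) {
    cat("<codetection> undefined (empty reference table)\n")
  } else {
    cat(sprintf("<codetection> %.1f%% (%d/%d matched; 95%% CI %.1f-%.1f%%; radius %.3g um)\n",
                100 * x$fraction, x$n_matched, x$n_a,
                100 * x$conf_int[["lower"]], 100 * x$conf_int[["upper"]],
                x$match_radius))
  }
  invisible(x)
}
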