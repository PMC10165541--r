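# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and kept free of the package's own implementation paths.

# small, fast simulation config for unit tests
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(12L, 64L, 64L), n_single_spots = 30L, n_foci = 1L,
         n_background_blobs = 2L),
    list(...))
  do.call(sim_config, args)
}

# direct nested-loop grey-scale opening of a matrix by a disk (erosion then
# dilation, +/-Inf outside), for tiny arrays only
oracle_grey_open <- function(m, radius) {
  d <- dim(m)
  offs <- list()
  r <- floor(radius)
  for (dy in -r:r) for (dx in -r:r)
    if (dy^2 + dx^2 <= radius^2) offs[[length(offs) + 1L]] <- c(dy, dx)
  ero <- matrix(Inf, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    v <- Inf
    for (o in offs) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= d[1] && xx >= 1 && xx <= d[2]) v <- min(v, m[yy, xx])
    }
    ero[y, x] <- v
  }
  dil <- matrix(-Inf, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    v <- -Inf
    for (o in offs) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy >= 1 && yy <= d[1] && xx >= 1 && xx <= d[2]) v <- max(v, ero[yy, xx])
    }
    dil[y, x] <- v
  }
  dil
}

# exhaustive one-to-one matching oracle: maximise matched pairs, then
# minimise total distance; enumerates all assignments (small inputs only)
oracle_match <- function(pa, pb, radius, zscale) {
  n_a <- nrow(pa); n_b <- nrow(pb)
  dmat <- matrix(Inf, n_a, max(n_b, 1L))
  if (n_b > 0) for (i in seq_len(n_a)) for (j in seq_len(n_b)) {
    dmat[i, j] <- sqrt((pa[i, 2] - pb[j, 2])^2 + (pa[i, 3] - pb[j, 3])^2 +
                         ((pa[i, 1] - pb[j, 1]) * zscale)^2)
  }
  best <- list(size = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, cost) {
    if (i > n_a) {
      sz <- length(pairs) / 2
      if (sz > best$size || (sz == best$size && cost < best$cost))
        best <<- list(size = sz, cost = cost, pairs = pairs)
      return()
    }
    recurse(i + 1L, used, pairs, cost)
    if (n_b > 0) for (j in seq_len(n_b)) {
      if (!(j %in% used) && dmat[i, j] <= radius)
        recurse(i + 1L, c(used, j), c(pairs, i, j), cost + dmat[i, j])
    }
  }
  recurse(1L, integer(0), integer(0), 0)
  best
}

# hand-coded oracle of the published test-selection table
oracle_select_test <- function(groups, alpha = 0.05) {
  sw <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  k <- length(groups)
  if (all(sw > alpha)) {
    vp <- if (k == 2L) stats::var.test(groups[[1]], groups[[2]])$p.value else {
      z <- unlist(lapply(groups, function(g) abs(g - mean(g))))
      f <- factor(rep(seq_along(groups), lengths(groups)))
      stats::anova(stats::lm(z ~ f))$`Pr(>F)`[1]
    }
    if (vp > alpha) { if (k == 2L) "student_t" else "anova" }
    else { if (k == 2L) "welch_t" else "welch_anova" }
  } else {
    if (k == 2L) "wilcoxon" else "kruskal_wallis"
  }
}

# truth table for discordance typing over one cell class with soma and
# periphery subregions; arguments are the per-subregion presence bits
oracle_class_type <- function(m_soma, m_peri, p_soma, p_peri) {
  m_any <- m_soma || m_peri; p_any <- p_soma || p_peri
  inter <- xor(m_any, p_any)
  intra <- m_any && p_any && (m_soma != p_soma || m_peri != p_peri)
  c(inter = inter, intra = intra)
}

# extract the nucleus-only mask out of a simulation ground truth
nucleus_mask_of <- function(sim) {
  m <- sim$truth$mask
  id <- as.integer(names(m$label_names)[m$label_names == "nucleus"])
  lab <- array(0L, dim(m$labels))
  lab[m$labels == id] <- 1L
  compartment_mask(lab, c("1" = "nucleus"), m$voxel_size)
}

detect_and_classify <- function(sim, cfg, channel, nucleus = NULL) {
  sp <- detect_spots(sim$stack, cfg$psf, detection_params(), channel = channel)
  classify_spots(sp, estimate_unit_intensity(sp), cfg$psf, detection_params(),
                 nucleus_mask = nucleus)
}

# anisotropy-scaled distance used for ground-truth matching
aniso_d <- function(za, ya, xa, zb, yb, xb, psf = psf_model()) {
  zs <- psf$sigma_lateral / psf$sigma_axial
  sqrt((ya - yb)^2 + (xa - xb)^2 + ((za - zb) * zs)^2)
}

# Gene-level screen fixture reproducing the published marginal tallies:
# 195/200 genes discordant somewhere; mushroom-body protein in 94 genes of
# which 30 carry mRNA there; 67 mushroom-body mRNAs of which 28 recur in the
# optic lobe; 19 genes with NMJ-glial expression; 131/200 homozygous-viable;
# neuroblast classes 114 homogeneous / 43 not detected / 31 + 12 cell-specific.
make_screen_fixture <- function() {
  n <- 200L
  gene_ids <- sprintf("gene_%03d", seq_len(n))
  tax <- compartment_taxonomy()
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    df <- data.frame(gene_id = gene_ids[i], tissue = tax$tissue,
                     compartment = tax$label, mrna = FALSE, protein = FALSE,
                     stringsAsFactors = FALSE)
    set_call <- function(df, comp, mrna, protein) {
      at <- df$compartment == comp
      df$mrna[at] <- mrna; df$protein[at] <- protein
      df
    }
    df <- set_call(df, "central_brain_soma", TRUE, TRUE)   # everyone expressed
    if (i <= 195) df <- set_call(df, "vnc_neuropil", TRUE, FALSE)  # discordance
    if (i <= 94) df <- set_call(df, "mushroom_body_neuropil", i >= 65, TRUE)
    if (i >= 95 && i <= 131) df <- set_call(df, "mushroom_body_neuropil", TRUE, FALSE)
    if (i >= 65 && i <= 92) df <- set_call(df, "optic_lobe_neuropil", TRUE, FALSE)
    if (i <= 19) df <- set_call(df, "glial_process_nmj", TRUE, FALSE)
    df
  }))
  patterns <- data.frame(
    gene_id = gene_ids,
    class = rep(c("homogeneous", "not_detected", "cell_specific_transcriptional",
                  "cell_specific_posttranscriptional"), c(114L, 43L, 31L, 12L)),
    stringsAsFactors = FALSE)
  metadata <- data.frame(gene_id = gene_ids,
                         homozygous_viable = seq_len(n) <= 131L,
                         stringsAsFactors = FALSE)
  list(calls = calls, patterns = patterns, metadata = metadata)
}

# derive a reproducible small sub-seed stream from one master seed
subseeds <- function(seed, n) {
  set.seed(seed)
  sample.int(1e6, n)
}
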