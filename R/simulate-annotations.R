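#' Configuration for the synthetic annotation-table generator
#'
#' Each gene draws a true expression pattern class; per-compartment
#' (mRNA, protein) presence vectors are realised from the class, then every
#' individual annotator call flips independently with
#' `annotator_error_rate`, and NA is injected at `na_rate`. Default pattern
#' priors reflect a screen in which nearly all genes are discordant
#' somewhere, with intercellular and intracellular events at similar
#' frequency.
#'
#' @param n_genes number of genes.
#' @param compartments compartment taxonomy data frame
#'   ([compartment_taxonomy()] by default).
#' @param pattern_priors named probabilities for the four true classes
#'   `concordant`, `intercellular`, `intracellular`, `silent`; must sum
#'   to 1.
#' @param annotator_error_rate per-call flip probability, in `[0, 0.5)`.
#' @param n_annotators number of annotators (>= 3; majority vote is
#'   undefined for fewer in this design).
#' @param na_rate probability a call is recorded as NA.
#' @param seed integer seed.
#' @export
annotation_sim_config <- function(n_genes = 200L,
                                  compartments = compartment_taxonomy(),
                                  pattern_priors = c(concordant = 0.025,
                                                     intercellular = 0.497,
                                                     intracellular = 0.478,
                                                     silent = 0),
                                  annotator_error_rate = 0.05,
                                  n_annotators = 3L,
                                  na_rate = 0.02,
                                  seed = 1L) {
  check_that(n_genes >= 1, "n_genes must be >= 1")
  check_that(abs(sum(pattern_priors) - 1) < 1e-9, "pattern_priors must sum to 1")
  check_that(all(sort(names(pattern_priors)) ==
                   sort(c("concordant", "intercellular", "intracellular", "silent"))),
             "pattern_priors must name the four classes")
  check_that(annotator_error_rate >= 0 && annotator_error_rate < 0.5,
             "annotator_error_rate must lie in [0, 0.5)")
  if (n_annotators < 3) config_error("n_annotators must be >= 3 (majority vote undefined)")
  check_that(na_rate >= 0 && na_rate < 1, "na_rate must lie in [0, 1)")
  structure(list(n_genes = as.integer(n_genes), compartments = compartments,
                 pattern_priors = pattern_priors,
                 annotator_error_rate = annotator_error_rate,
                 n_annotators = as.integer(n_annotators), na_rate = na_rate,
                 seed = as.integer(seed)),
            class = "annotation_sim_config")
}

# Realise one gene's true per-compartment (mrna, protein) calls.
realize_pattern <- function(pattern, tax, p_present = 0.6) {
  n <- nrow(tax)
  out <- data.frame(tissue = tax$tissue, compartment = tax$label,
                    mrna = logical(n), protein = logical(n))
  if (pattern == "silent") return(out)
  base <- stats::runif(n) < p_present
  out$mrna <- base; out$protein <- base               # concordant scaffold
  if (pattern == "concordant") return(out)

  if (pattern == "intercellular") {
    # one whole cell class in one tissue carries one molecule but not the other
    combos <- unique(tax[, c("tissue", "cell_class")])
    pick <- combos[sample(nrow(combos), 1L), ]
    rows <- which(tax$tissue == pick$tissue & tax$cell_class == pick$cell_class)
    present <- stats::runif(length(rows)) < 0.7
    if (!any(present)) present[sample(length(rows), 1L)] <- TRUE
    if (stats::runif(1) < 0.5) {
      out$mrna[rows] <- present; out$protein[rows] <- FALSE
    } else {
      out$mrna[rows] <- FALSE; out$protein[rows] <- present
    }
  } else {                                            # intracellular
    # a class with both subregions in one tissue: both molecules present in
    # the class, but the soma/periphery presence patterns differ
    combos <- unique(tax[, c("tissue", "cell_class")])
    ok <- vapply(seq_len(nrow(combos)), function(i) {
      sub <- tax[tax$tissue == combos$tissue[i] & tax$cell_class == combos$cell_class[i], ]
      all(c("soma", "periphery") %in% sub$subregion)
    }, logical(1))
    combos <- combos[ok, , drop = FALSE]
    pick <- combos[sample(nrow(combos), 1L), ]
    sub <- tax$tissue == pick$tissue & tax$cell_class == pick$cell_class
    soma <- which(sub & tax$subregion == "soma")
    peri <- which(sub & tax$subregion == "periphery")
    # mRNA reaches the periphery, protein stays somatic (or the reverse)
    fill <- function(rows) {
      v <- stats::runif(length(rows)) < 0.7
      if (!any(v)) v[sample(length(rows), 1L)] <- TRUE
      v
    }
    if (stats::runif(1) < 0.5) {
      out$mrna[soma] <- fill(soma); out$mrna[peri] <- fill(peri)
      out$protein[soma] <- fill(soma); out$protein[peri] <- FALSE
    } else {
      out$protein[soma] <- fill(soma); out$protein[peri] <- fill(peri)
      out$mrna[soma] <- fill(soma); out$mrna[peri] <- FALSE
    }
  }
  out
}

#' Simulate a multi-annotator presence/absence scoring table
#'
#' @param config an [annotation_sim_config()].
#' @return list: `table` (rows gene_id x tissue x compartment x annotator
#'   with `mrna_present` / `protein_present` in `{TRUE, FALSE, NA}`),
#'   `truth` (list with per-gene `patterns` and the true `calls`), and the
#'   `seed` used.
#' @export
simulate_annotation_table <- function(config) {
  check_that(inherits(config, "annotation_sim_config"),
             "config must be an annotation_sim_config")
  with_seed(config$seed, {
    tax <- config$compartments
    classes <- names(config$pattern_priors)
    patterns <- sample(classes, config$n_genes, replace = TRUE,
                       prob = config$pattern_priors)
    gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
    truth_calls <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
      cbind(gene_id = gene_ids[i], realize_pattern(patterns[i], tax))
    }))
    n_ann <- config$n_annotators
    eps <- config$annotator_error_rate
    rows <- truth_calls[rep(seq_len(nrow(truth_calls)), each = n_ann), ]
    rows$annotator <- paste0("annotator_", rep(seq_len(n_ann), nrow(truth_calls)))
    n <- nrow(rows)
    flip1 <- stats::runif(n) < eps; flip2 <- stats::runif(n) < eps
    mrna <- xor(rows$mrna, flip1); protein <- xor(rows$protein, flip2)
    mrna[stats::runif(n) < config$na_rate] <- NA
    protein[stats::runif(n) < config$na_rate] <- NA
    table <- data.frame(gene_id = rows$gene_id, tissue = rows$tissue,
                        compartment = rows$compartment, annotator = rows$annotator,
                        mrna_present = mrna, protein_present = protein,
                        stringsAsFactors = FALSE)
    rownames(table) <- NULL
    list(table = table,
         truth = list(patterns = data.frame(gene_id = gene_ids, pattern = patterns,
                                            stringsAsFactors = FALSE),
                      calls = truth_calls),
         seed = config$seed)
  })
}

#' Simulate a per-cell neuroblast-lineage expression panel
#'
#' For each gene, a lineage of `n_cells` cells is drawn from one of four
#' expression-pattern classes: `not_detected`, `homogeneous` (both molecules
#' in essentially every cell), `cell_specific_transcriptional` (a cell
#' subset expresses both, mRNA and protein agreeing per cell), and
#' `cell_specific_posttranscriptional` (mRNA and transcription foci broadly
#' present, protein restricted to a minority of cells). Expressing cells
#' draw Poisson mRNA counts and Gaussian protein intensities well above the
#' background levels; each per-cell presence call then flips independently
#' with `flip_rate`, emulating scoring error.
#'
#' @param n_genes panel size.
#' @param priors class probabilities (default: the screen's observed
#'   distribution).
#' @param n_cells cells per lineage (a type-I lineage: the neuroblast, a few
#'   ganglion mother cells, and a few dozen progeny).
#' @param flip_rate per-cell, per-molecule presence flip probability.
#' @param mean_mrna,protein_level,protein_background,protein_sd photometric
#'   levels of the emitted measurements.
#' @param seed integer seed.
#' @return list: `cells` (gene_id, cell_id, cell_type, mrna_count,
#'   protein_intensity, has_transcription_focus), `truth` (gene_id, class).
#' @export
simulate_neuroblast_panel <- function(n_genes = 200L,
                                      priors = c(not_detected = 0.215,
                                                 homogeneous = 0.570,
                                                 cell_specific_transcriptional = 0.155,
                                                 cell_specific_posttranscriptional = 0.060),
                                      n_cells = 40L, flip_rate = 0.05,
                                      mean_mrna = 8, protein_level = 100,
                                      protein_background = 10, protein_sd = 3,
                                      seed = 1L) {
  check_that(abs(sum(priors) - 1) < 1e-9, "priors must sum to 1")
  check_that(n_cells >= 5, "need >= 5 cells per lineage")
  with_seed(seed, {
    classes <- names(priors)
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    truth <- sample(classes, n_genes, replace = TRUE, prob = priors)
    cell_types <- c("neuroblast", rep("GMC", 3L), rep("progeny", n_cells - 4L))
    rows <- lapply(seq_len(n_genes), function(i) {
      cl <- truth[i]
      m_on <- switch(cl,
        not_detected = rep(FALSE, n_cells),
        homogeneous = rep(TRUE, n_cells),
        cell_specific_transcriptional = stats::runif(n_cells) <
          stats::runif(1, 0.2, 0.6),
        cell_specific_posttranscriptional = rep(TRUE, n_cells))
      p_on <- switch(cl,
        not_detected = rep(FALSE, n_cells),
        homogeneous = rep(TRUE, n_cells),
        cell_specific_transcriptional = m_on,
        cell_specific_posttranscriptional = {
          v <- stats::runif(n_cells) < stats::runif(1, 0.1, 0.3)
          if (!any(v)) v[sample(n_cells, 1L)] <- TRUE
          v
        })
      if (cl == "cell_specific_transcriptional" && !any(m_on)) {
        m_on[sample(n_cells, 1L)] <- TRUE; p_on <- m_on
      }
      m_on <- xor(m_on, stats::runif(n_cells) < flip_rate)
      p_on <- xor(p_on, stats::runif(n_cells) < flip_rate)
      data.frame(gene_id = gene_ids[i], cell_id = seq_len(n_cells),
                 cell_type = cell_types,
                 mrna_count = ifelse(m_on, stats::rpois(n_cells, mean_mrna),
                                     stats::rpois(n_cells, 0.2)),
                 protein_intensity = stats::rnorm(
                   n_cells,
                   ifelse(p_on, protein_level, protein_background), protein_sd),
                 has_transcription_focus = m_on &
                   cl %in% c("homogeneous", "cell_specific_transcriptional",
                             "cell_specific_posttranscriptional"),
                 stringsAsFactors = FALSE)
    })
    list(cells = do.call(rbind, rows),
         truth = data.frame(gene_id = gene_ids, class = truth,
                            stringsAsFactors = FALSE))
  })
}
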