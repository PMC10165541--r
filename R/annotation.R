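# Multi-annotator aggregation and screen-level scoring.

validate_annotation_table <- function(table) {
  need <- c("gene_id", "tissue", "compartment", "annotator", "mrna_present",
            "protein_present")
  miss <- setdiff(need, names(table))
  check_that(length(miss) == 0,
             sprintf("annotation table missing columns: %s", paste(miss, collapse = ", ")),
             input_error)
  key <- paste(table$gene_id, table$tissue, table$compartment, table$annotator)
  check_that(!anyDuplicated(key),
             "duplicate (gene, tissue, compartment, annotator) rows", input_error)
  invisible(table)
}

vote <- function(v) {
  v <- v[!is.na(v)]
  nt <- sum(v); nf <- length(v) - nt
  if (nt == nf) return(list(call = NA, resolution = "escalated_unresolved"))
  list(call = nt > nf,
       resolution = if (nt == 0L || nf == 0L) "unanimous" else "majority")
}

#' Aggregate annotator calls by strict majority vote
#'
#' Per (gene, tissue, compartment) and per molecule, the call is the strict
#' majority of non-NA votes; unanimity is recorded. Keys where either
#' molecule has no strict majority (e.g. a 1-1 split with one NA) are marked
#' `escalated_unresolved`, excluded from downstream tabulation, and listed
#' in the conflict report (`attr(, "conflicts")`) for a fourth expert.
#'
#' @param table annotation table (>= 3 annotators per key).
#' @return data frame of gene-compartment calls: `gene_id`, `tissue`,
#'   `compartment`, `mrna`, `protein`, `resolution`, `n_annotators`.
#' @export
aggregate_majority <- function(table) {
  validate_annotation_table(table)
  key <- interaction(table$gene_id, table$tissue, table$compartment, drop = TRUE,
                     lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  rows <- lapply(idx, function(i) {
    sub <- table[i, ]
    if (length(i) < 3L)
      input_error(sprintf("fewer than 3 annotators for key (%s, %s, %s)",
                          sub$gene_id[1], sub$tissue[1], sub$compartment[1]))
    vm <- vote(sub$mrna_present); vp <- vote(sub$protein_present)
    res <- if (identical(vm$resolution, "escalated_unresolved") ||
                 identical(vp$resolution, "escalated_unresolved")) "escalated_unresolved"
    else if (vm$resolution == "unanimous" && vp$resolution == "unanimous") "unanimous"
    else "majority"
    data.frame(gene_id = sub$gene_id[1], tissue = sub$tissue[1],
               compartment = sub$compartment[1],
               mrna = if (res == "escalated_unresolved") NA else vm$call,
               protein = if (res == "escalated_unresolved") NA else vp$call,
               resolution = res, n_annotators = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$tissue, out$compartment), ]
  rownames(out) <- NULL
  attr(out, "conflicts") <- out[out$resolution == "escalated_unresolved",
                                c("gene_id", "tissue", "compartment")]
  out
}

#' Per-annotator agreement with the consensus
#'
#' @param table annotation table.
#' @param calls optional precomputed [aggregate_majority()] result.
#' @return list: `per_annotator` (disagreement rate vs consensus over
#'   resolved keys, both molecules pooled), `per_question` (keys with any
#'   conflicting vote and their conflict counts).
#' @export
annotator_agreement <- function(table, calls = NULL) {
  calls <- calls %||% aggregate_majority(table)
  resolved <- calls[calls$resolution != "escalated_unresolved", ]
  m <- merge(table, resolved, by = c("gene_id", "tissue", "compartment"))
  dis_m <- !is.na(m$mrna_present) & m$mrna_present != m$mrna
  dis_p <- !is.na(m$protein_present) & m$protein_present != m$protein
  n_votes <- as.numeric(!is.na(m$mrna_present)) + as.numeric(!is.na(m$protein_present))
  per_ann <- vapply(split(seq_len(nrow(m)), m$annotator), function(i) {
    sum(dis_m[i] + dis_p[i]) / sum(n_votes[i])
  }, numeric(1))
  conf <- dis_m | dis_p
  key <- paste(m$gene_id, m$tissue, m$compartment, sep = "|")
  per_q <- table(key[conf])
  list(per_annotator = per_ann,
       per_question = data.frame(key = names(per_q), n_conflicts = as.integer(per_q),
                                 stringsAsFactors = FALSE))
}

# Discordance-type evidence for one gene x tissue, over one cell class.
# Returns c(inter, intra) logicals.
class_evidence <- function(sub) {
  m_any <- any(sub$mrna); p_any <- any(sub$protein)
  inter <- xor(m_any, p_any)
  intra <- FALSE
  if (m_any && p_any) {
    pat <- function(mol) vapply(c("soma", "periphery"), function(s) {
      rows <- sub$subregion == s
      if (!any(rows)) NA else any(sub[[mol]][rows])
    }, logical(1))
    pm <- pat("mrna"); pp <- pat("protein")
    ok <- !is.na(pm) & !is.na(pp)
    intra <- any(pm[ok] != pp[ok])
  }
  c(inter = inter, intra = intra)
}

#' Classify mRNA/protein discordance per gene and tissue
#'
#' A gene x tissue is discordant when some compartment carries exactly one
#' of the molecules. The type is resolved per cell class present in the
#' tissue: when one molecule is present somewhere in the class while the
#' other is absent across the whole class, the evidence is intercellular;
#' when both are present in the class but their soma/periphery presence
#' patterns differ, the evidence is intracellular; one gene x tissue may
#' carry both. Peripheral-mRNA flags are set per gene when mRNA is called
#' in any periphery compartment of the respective cell class.
#'
#' @param calls resolved calls from [aggregate_majority()] (unresolved keys
#'   are dropped) or any data frame with gene_id / tissue / compartment /
#'   mrna / protein.
#' @param taxonomy [compartment_taxonomy()] or compatible data frame.
#' @return data frame with one row per gene x tissue (`status`,
#'   `discordance_type`); gene-level roll-up in `attr(, "genes")` with
#'   `any_discordance`, `peripheral_mrna_neuron`, `peripheral_mrna_glia`.
#' @export
classify_discordance <- function(calls, taxonomy = compartment_taxonomy()) {
  if (!is.null(calls$resolution))
    calls <- calls[calls$resolution != "escalated_unresolved", ]
  calls <- merge(calls, taxonomy[, c("label", "cell_class", "subregion")],
                 by.x = "compartment", by.y = "label", all.x = TRUE)
  if (anyNA(calls$cell_class))
    input_error(sprintf("compartments outside the taxonomy: %s",
                        paste(unique(calls$compartment[is.na(calls$cell_class)]),
                              collapse = ", ")))
  skipped <- character(0)
  keys <- unique(calls[, c("gene_id", "tissue")])
  keys <- keys[order(keys$gene_id, keys$tissue), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- calls[calls$gene_id == keys$gene_id[i] & calls$tissue == keys$tissue[i], ]
    if (nrow(sub) == 0L) {
      skipped <<- c(skipped, paste(keys$gene_id[i], keys$tissue[i]))
      return(NULL)
    }
    discord <- any(xor(sub$mrna, sub$protein))
    ev <- rowSums(vapply(split(sub, sub$cell_class), class_evidence, numeric(2))) > 0
    type <- if (!discord) "none"
    else if (ev[["inter"]] && ev[["intra"]]) "both"
    else if (ev[["inter"]]) "intercellular"
    else if (ev[["intra"]]) "intracellular"
    else "none"
    data.frame(gene_id = keys$gene_id[i], tissue = keys$tissue[i],
               status = if (discord) "discordant" else "concordant",
               discordance_type = type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(skipped) > 0)
    warning(sprintf("tissues with no scored compartments omitted: %s",
                    paste(skipped, collapse = ", ")))
  peri <- calls$subregion == "periphery" & calls$mrna
  genes <- data.frame(gene_id = sort(unique(calls$gene_id)), stringsAsFactors = FALSE)
  genes$any_discordance <- vapply(genes$gene_id, function(g)
    any(out$status[out$gene_id == g] == "discordant"), logical(1))
  genes$peripheral_mrna_neuron <- vapply(genes$gene_id, function(g)
    any(peri & calls$gene_id == g & calls$cell_class == "neuron"), logical(1))
  genes$peripheral_mrna_glia <- vapply(genes$gene_id, function(g)
    any(peri & calls$gene_id == g & calls$cell_class == "glia"), logical(1))
  attr(out, "genes") <- genes
  out
}

#' Screen-level expression tables
#'
#' Per compartment, the four-way split of genes (both present / mRNA only /
#' protein only / neither) as counts and percentages summing to 100.
#'
#' @param calls resolved calls.
#' @return data frame, one row per compartment x category.
#' @export
tabulate_expression <- function(calls) {
  if (!is.null(calls$resolution))
    calls <- calls[calls$resolution != "escalated_unresolved", ]
  rows <- lapply(split(calls, calls$compartment), function(sub) {
    # a gene counts as present if called present in any scored tissue
    m <- tapply(sub$mrna, sub$gene_id, any)
    p <- tapply(sub$protein, sub$gene_id, any)
    n <- length(m)
    cnt <- c(both = sum(m & p), mrna_only = sum(m & !p),
             protein_only = sum(!m & p), neither = sum(!m & !p))
    data.frame(compartment = sub$compartment[1],
               category = names(cnt), n_genes = as.integer(cnt),
               percent = 100 * as.integer(cnt) / n, genes_scored = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gene_presence <- function(calls, molecule, compartment) {
  sub <- calls[calls$compartment == compartment, ]
  if (nrow(sub) == 0L) return(character(0))
  pres <- tapply(sub[[molecule]], sub$gene_id, any)
  names(pres)[pres]
}

#' Headline screen statistics
#'
#' The scalar summaries a screen report leads with: percent of genes with
#' any mRNA/protein discordance; percent with peripheral neuronal and
#' peripheral glial mRNA; intercellular/intracellular shares of gene x
#' tissue discordance events (and the gene-level roll-up); mushroom-body
#' protein prevalence and its mRNA co-presence; mushroom-body to optic-lobe
#' mRNA overlap; NMJ-glial expression; and, when supplied, neuroblast
#' pattern-class percentages and homozygous-viability from gene metadata.
#'
#' @param calls resolved calls.
#' @param profiles result of [classify_discordance()] on those calls
#'   (computed when omitted).
#' @param patterns optional neuroblast classification (data frame with
#'   `gene_id`, `class`).
#' @param metadata optional per-gene metadata with a `homozygous_viable`
#'   logical column.
#' @return named list of headline values; percentages on the 0-100 scale.
#' @export
screen_headlines <- function(calls, profiles = NULL,
                             patterns = NULL, metadata = NULL) {
  if (!is.null(calls$resolution))
    calls <- calls[calls$resolution != "escalated_unresolved", ]
  profiles <- profiles %||% classify_discordance(calls)
  genes <- attr(profiles, "genes")
  n_genes <- nrow(genes)
  out <- list(
    n_genes = n_genes,
    n_any_discordance = sum(genes$any_discordance),
    pct_any_discordance = 100 * mean(genes$any_discordance),
    pct_peripheral_mrna_neuron = 100 * mean(genes$peripheral_mrna_neuron),
    pct_peripheral_mrna_glia = 100 * mean(genes$peripheral_mrna_glia)
  )
  # event-level inter/intra shares over gene x tissue discordance events;
  # "both" contributes one evidence of each kind
  ev <- profiles$discordance_type[profiles$status == "discordant"]
  n_inter <- sum(ev %in% c("intercellular", "both"))
  n_intra <- sum(ev %in% c("intracellular", "both"))
  tot <- n_inter + n_intra
  out$share_intercellular <- if (tot > 0) 100 * n_inter / tot else NA_real_
  out$share_intracellular <- if (tot > 0) 100 * n_intra / tot else NA_real_
  # gene-level roll-up of the same split
  gtype <- tapply(profiles$discordance_type, profiles$gene_id, function(tt) {
    i <- any(tt %in% c("intercellular", "both")); a <- any(tt %in% c("intracellular", "both"))
    if (i && a) "both" else if (i) "intercellular" else if (a) "intracellular" else "none"
  })
  out$gene_share_intercellular <- 100 * mean(gtype %in% c("intercellular", "both"))
  out$gene_share_intracellular <- 100 * mean(gtype %in% c("intracellular", "both"))

  if ("mushroom_body_neuropil" %in% calls$compartment) {
    mb_p <- gene_presence(calls, "protein", "mushroom_body_neuropil")
    mb_m <- gene_presence(calls, "mrna", "mushroom_body_neuropil")
    out$n_mb_protein <- length(mb_p)
    out$pct_mb_protein <- 100 * length(mb_p) / n_genes
    out$pct_mb_protein_with_mrna <- if (length(mb_p) > 0)
      100 * length(intersect(mb_p, mb_m)) / length(mb_p) else NA_real_
    if ("optic_lobe_neuropil" %in% calls$compartment) {
      ol_m <- gene_presence(calls, "mrna", "optic_lobe_neuropil")
      out$n_mb_mrna <- length(mb_m)
      out$pct_mb_mrna_also_ol <- if (length(mb_m) > 0)
        100 * length(intersect(mb_m, ol_m)) / length(mb_m) else NA_real_
    }
  }
  if ("glial_process_nmj" %in% calls$compartment) {
    nmj_glia <- union(gene_presence(calls, "mrna", "glial_process_nmj"),
                      gene_presence(calls, "protein", "glial_process_nmj"))
    out$n_nmj_glial <- length(nmj_glia)
    out$pct_nmj_glial <- 100 * length(nmj_glia) / n_genes
  }
  if (!is.null(patterns)) {
    n <- nrow(patterns)
    cs <- patterns$class %in% c("cell_specific_transcriptional",
                                "cell_specific_posttranscriptional")
    out$n_cell_specific <- sum(cs)
    out$pct_cell_specific <- 100 * mean(cs)
    out$pct_homogeneous <- 100 * mean(patterns$class == "homogeneous")
    out$pct_not_detected <- 100 * mean(patterns$class == "not_detected")
    if (sum(cs) > 0) {
      out$pct_cs_correlated <- 100 *
        sum(patterns$class == "cell_specific_transcriptional") / sum(cs)
      out$pct_cs_discordant <- 100 *
        sum(patterns$class == "cell_specific_posttranscriptional") / sum(cs)
    }
  }
  if (!is.null(metadata) && "homozygous_viable" %in% names(metadata)) {
    out$pct_homozygous_viable <- 100 * mean(metadata$homozygous_viable, na.rm = TRUE)
  }
  out
}

#' Classify neuroblast-lineage expression patterns
#'
#' Detection floors: a cell expresses mRNA at >= `mrna_floor` single
#' molecules (or a transcription focus); it expresses protein above
#' `protein_background + 3 * protein_sigma`. A gene is `not_detected` when
#' the expressing-cell fraction stays at or below `detect_fraction` for both
#' molecules; `homogeneous` when it reaches `homogeneous_fraction` for
#' both; otherwise it is cell-specific, split by per-cell presence
#' agreement: `cell_specific_transcriptional` at agreement >=
#' `agreement_threshold` (mRNA and protein rise and fall together, the
#' signature of transcriptional control), else
#' `cell_specific_posttranscriptional` (mRNA broadly present while protein
#' is restricted).
#'
#' @param per_cell data frame: `gene_id` (optional for a single gene),
#'   `cell_id`, `cell_type`, `mrna_count`, `protein_intensity`,
#'   `has_transcription_focus`; >= 5 cells per lineage.
#' @param params list overriding `mrna_floor` (2), `protein_background`
#'   (10), `protein_sigma` (3), `detect_fraction` (0.1),
#'   `homogeneous_fraction` (0.9), `agreement_threshold` (0.8).
#' @return data frame: gene_id, class, expressing fractions, agreement.
#' @export
classify_neuroblast_pattern <- function(per_cell, params = list()) {
  p <- utils::modifyList(list(mrna_floor = 2, protein_background = 10,
                              protein_sigma = 3, detect_fraction = 0.1,
                              homogeneous_fraction = 0.9,
                              agreement_threshold = 0.8), params)
  if (is.null(per_cell$gene_id)) per_cell$gene_id <- "gene"
  one <- function(sub) {
    if (nrow(sub) < 5L)
      input_error(sprintf("gene %s: need >= 5 cells per lineage", sub$gene_id[1]))
    m_on <- sub$mrna_count >= p$mrna_floor
    if (!is.null(sub$has_transcription_focus))
      m_on <- m_on | sub$has_transcription_focus %in% TRUE
    prot_floor <- p$protein_background + 3 * p$protein_sigma
    p_on <- sub$protein_intensity > prot_floor
    fm <- mean(m_on); fp <- mean(p_on)
    agree <- mean(m_on == p_on)
    cls <- if (fm <= p$detect_fraction && fp <= p$detect_fraction) "not_detected"
    else if (fm >= p$homogeneous_fraction && fp >= p$homogeneous_fraction) "homogeneous"
    else if (agree >= p$agreement_threshold) "cell_specific_transcriptional"
    else "cell_specific_posttranscriptional"
    data.frame(gene_id = sub$gene_id[1], class = cls, frac_mrna = fm,
               frac_protein = fp, agreement = agree, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(per_cell, per_cell$gene_id), one))
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Gene-set intersection counts for an UpSet plot
#'
#' @param calls resolved calls.
#' @param molecule `"mrna"` or `"protein"`.
#' @return list: `patterns` (one row per exact compartment-membership
#'   pattern with its gene count), `marginals` (per-compartment totals).
#' @export
upset_counts <- function(calls, molecule = c("mrna", "protein")) {
  molecule <- match.arg(molecule)
  if (!is.null(calls$resolution))
    calls <- calls[calls$resolution != "escalated_unresolved", ]
  comps <- sort(unique(calls$compartment))
  genes <- sort(unique(calls$gene_id))
  memb <- vapply(comps, function(cp) genes %in% gene_presence(calls, molecule, cp),
                 logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, comps))
  pat <- apply(memb, 1, function(r) paste(comps[r], collapse = "&"))
  pat[pat == ""] <- "(none)"
  tab <- sort(table(pat), decreasing = TRUE)
  list(patterns = data.frame(pattern = names(tab), n_genes = as.integer(tab),
                             stringsAsFactors = FALSE),
       marginals = data.frame(compartment = comps, n_genes = colSums(memb),
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Extrapolate a screened fraction to the genome
#'
#' Point estimate `genome_protein_coding * k / n` with a Wilson binomial
#' interval. Because the result is reported as an "at least" claim, the
#' default interval is the one-sided 95% lower bound.
#'
#' @param k genes with the pattern among `n` screened.
#' @param n genes screened (> 0).
#' @param genome_protein_coding genome-wide protein-coding gene count
#'   (default 13,900).
#' @param conf confidence level.
#' @param one_sided use the one-sided lower/upper bounds (default TRUE).
#' @return list: `estimate`, `lower`, `upper`, `at_least` (floor of the
#'   lower bound).
#' @export
extrapolate_genome <- function(k, n, genome_protein_coding = 13900, conf = 0.95,
                               one_sided = TRUE) {
  check_that(n > 0, "n must be > 0", input_error)
  check_that(k >= 0 && k <= n, "need 0 <= k <= n", input_error)
  check_that(genome_protein_coding > 0, "genome_protein_coding must be > 0")
  ci <- wilson_interval(k, n, conf = conf, one_sided = one_sided)
  list(estimate = genome_protein_coding * k / n,
       lower = genome_protein_coding * ci[["lower"]],
       upper = genome_protein_coding * ci[["upper"]],
       at_least = floor(genome_protein_coding * ci[["lower"]]))
}

#' Flat per-gene export for the multi-dimensional data viewer
#'
#' One row per gene; a pair of columns per compartment
#' (`<compartment>_mrna`, `<compartment>_protein`), the discordance fields,
#' and any metadata columns appended. A JSON schema sidecar describing the
#' columns can be written alongside with [write_mdv()].
#'
#' @param calls resolved calls.
#' @param profiles optional [classify_discordance()] result.
#' @param metadata optional per-gene data frame keyed by `gene_id`.
#' @export
mdv_export <- function(calls, profiles = NULL, metadata = NULL) {
  if (!is.null(calls$resolution))
    calls <- calls[calls$resolution != "escalated_unresolved", ]
  profiles <- profiles %||% classify_discordance(calls)
  genes <- attr(profiles, "genes")
  out <- genes
  for (cp in sort(unique(calls$compartment))) {
    out[[paste0(cp, "_mrna")]] <- out$gene_id %in% gene_presence(calls, "mrna", cp)
    out[[paste0(cp, "_protein")]] <- out$gene_id %in% gene_presence(calls, "protein", cp)
  }
  for (ts in sort(unique(profiles$tissue))) {
    sub <- profiles[profiles$tissue == ts, ]
    out[[paste0("discordance_", ts)]] <-
      sub$discordance_type[match(out$gene_id, sub$gene_id)]
  }
  if (!is.null(metadata)) out <- merge(out, metadata, by = "gene_id", all.x = TRUE)
  out[order(out$gene_id), ]
}

#' @rdname mdv_export
#' @param x an [mdv_export()] data frame.
#' @param path CSV output path; the JSON schema goes to `<path>.schema.json`.
#' @export
write_mdv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "NA")
  schema <- list(columns = lapply(names(x), function(nm)
    list(name = nm, type = class(x[[nm]])[1])))
  jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
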