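mk_votes <- function(mrna_votes, protein_votes = mrna_votes,
                     gene = "g1", tissue = "brain", comp = "central_brain_soma") {
  data.frame(gene_id = gene, tissue = tissue, compartment = comp,
             annotator = paste0("annotator_", seq_along(mrna_votes)),
             mrna_present = mrna_votes, protein_present = protein_votes,
             stringsAsFactors = FALSE)
}

test_that("majority vote resolves unanimity, majority, and ties", {
  out <- aggregate_majority(mk_votes(c(TRUE, TRUE, TRUE)))
  expect_true(out$mrna); expect_equal(out$resolution, "unanimous")
  out <- aggregate_majority(mk_votes(c(TRUE, TRUE, FALSE)))
  expect_true(out$mrna); expect_equal(out$resolution, "majority")
  # (T, F, NA): 1-1 among non-NA votes -> escalated
  out <- aggregate_majority(mk_votes(c(TRUE, FALSE, NA)))
  expect_equal(out$resolution, "escalated_unresolved")
  expect_true(is.na(out$mrna))
  expect_equal(nrow(attr(out, "conflicts")), 1L)
})

test_that("aggregation is annotator-order invariant and idempotent on unanimity", {
  tab <- rbind(mk_votes(c(TRUE, FALSE, TRUE), c(FALSE, FALSE, TRUE)),
               mk_votes(c(FALSE, FALSE, FALSE), gene = "g2"))
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(aggregate_majority(tab), aggregate_majority(shuffled),
               ignore_attr = TRUE)
  unan <- mk_votes(c(TRUE, TRUE, TRUE))
  expect_equal(aggregate_majority(unan)$resolution, "unanimous")
})

test_that("fewer than three annotators is an error naming the key", {
  expect_error(aggregate_majority(mk_votes(c(TRUE, TRUE))),
               "central_brain_soma", class = "ss_input_error")
  dup <- rbind(mk_votes(TRUE), mk_votes(TRUE))
  expect_error(aggregate_majority(dup), "duplicate", class = "ss_input_error")
})

test_that("agreement report recovers annotator error rates", {
  # noiseless table: zero disagreement
  cfg0 <- annotation_sim_config(n_genes = 12, annotator_error_rate = 0,
                                na_rate = 0, seed = 6)
  tab0 <- simulate_annotation_table(cfg0)$table
  rep0 <- annotator_agreement(tab0)
  expect_true(all(rep0$per_annotator == 0))
  expect_equal(nrow(rep0$per_question), 0L)
  # eps = 0.05: per-annotator disagreement close to eps
  cfg <- annotation_sim_config(n_genes = 150, annotator_error_rate = 0.05,
                               na_rate = 0, seed = 7)
  tab <- simulate_annotation_table(cfg)$table
  rep <- annotator_agreement(tab)
  n_calls <- nrow(tab) / cfg$n_annotators * 2
  expect_true(all(abs(rep$per_annotator - 0.05) < 4 * sqrt(0.05 * 0.95 / n_calls)))
})

test_that("discordance typing agrees with the truth table on all 16 patterns", {
  tax <- data.frame(label = c("soma_c", "peri_c"), cell_class = "neuron",
                    subregion = c("soma", "periphery"), tissue = "brain")
  grid <- expand.grid(m_soma = c(FALSE, TRUE), m_peri = c(FALSE, TRUE),
                      p_soma = c(FALSE, TRUE), p_peri = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    calls <- data.frame(gene_id = "g", tissue = "brain",
                        compartment = c("soma_c", "peri_c"),
                        mrna = c(g$m_soma, g$m_peri),
                        protein = c(g$p_soma, g$p_peri))
    prof <- classify_discordance(calls, tax)
    expected <- oracle_class_type(g$m_soma, g$m_peri, g$p_soma, g$p_peri)
    discordant <- g$m_soma != g$p_soma || g$m_peri != g$p_peri
    expect_equal(prof$status, if (discordant) "discordant" else "concordant",
                 info = paste(unlist(g), collapse = ","))
    exp_type <- if (!discordant) "none"
    else if (expected[["inter"]] && expected[["intra"]]) "both"
    else if (expected[["inter"]]) "intercellular"
    else if (expected[["intra"]]) "intracellular" else "none"
    expect_equal(prof$discordance_type, exp_type,
                 info = paste(unlist(g), collapse = ","))
  }
})

test_that("spec discordance examples behave as stated", {
  tax <- compartment_taxonomy()
  # mRNA in soma and periphery, protein absent in the class -> intercellular
  calls <- data.frame(gene_id = "g", tissue = "brain",
                      compartment = c("central_brain_soma", "mushroom_body_neuropil"),
                      mrna = c(TRUE, TRUE), protein = c(FALSE, FALSE))
  expect_equal(classify_discordance(calls, tax)$discordance_type, "intercellular")
  # mRNA somatic only, protein in soma and periphery -> intracellular
  calls$mrna <- c(TRUE, FALSE); calls$protein <- c(TRUE, TRUE)
  expect_equal(classify_discordance(calls, tax)$discordance_type, "intracellular")
  # concordant everywhere
  calls$mrna <- c(TRUE, TRUE); calls$protein <- c(TRUE, TRUE)
  prof <- classify_discordance(calls, tax)
  expect_equal(prof$status, "concordant")
  expect_equal(prof$discordance_type, "none")
})

test_that("expression tables recount correctly and normalise to 100", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:40)
  calls <- expand.grid(gene_id = genes,
                       compartment = c("central_brain_soma", "psd"),
                       stringsAsFactors = FALSE)
  calls$tissue <- "t"
  calls$mrna <- runif(nrow(calls)) < 0.5
  calls$protein <- runif(nrow(calls)) < 0.5
  tab <- tabulate_expression(calls)
  for (cp in unique(tab$compartment)) {
    sub <- tab[tab$compartment == cp, ]
    expect_equal(sum(sub$percent), 100, tolerance = 1e-9)
    expect_equal(sum(sub$n_genes), 40L)
    # brute-force recount oracle
    sc <- calls[calls$compartment == cp, ]
    expect_equal(sub$n_genes[sub$category == "both"], sum(sc$mrna & sc$protein))
    expect_equal(sub$n_genes[sub$category == "mrna_only"], sum(sc$mrna & !sc$protein))
  }
})

test_that("upset counts equal exhaustive enumeration and conserve marginals", {
  set.seed(12)
  comps <- c("a_comp", "b_comp", "c_comp")
  calls <- expand.grid(gene_id = sprintf("g%02d", 1:50), compartment = comps,
                       stringsAsFactors = FALSE)
  calls$tissue <- "t"
  calls$mrna <- runif(nrow(calls)) < 0.4
  calls$protein <- FALSE
  up <- upset_counts(calls, "mrna")
  # oracle: tabulate membership patterns directly
  memb <- sapply(comps, function(cp) {
    v <- calls$mrna[calls$compartment == cp]
    v[order(calls$gene_id[calls$compartment == cp])]
  })
  pat <- apply(memb, 1, function(r) if (!any(r)) "(none)" else
    paste(comps[r], collapse = "&"))
  oracle <- sort(table(pat), decreasing = TRUE)
  expect_equal(sum(up$patterns$n_genes), 50L)
  expect_setequal(up$patterns$pattern, names(oracle))
  expect_equal(up$patterns$n_genes[match(names(oracle), up$patterns$pattern)],
               as.integer(oracle))
  expect_equal(up$marginals$n_genes, unname(colSums(memb)))
  # single gene in all compartments -> one pattern of count 1
  one <- calls[calls$gene_id == "g01", ]; one$mrna <- TRUE
  up1 <- upset_counts(one, "mrna")
  expect_equal(up1$patterns,
               data.frame(pattern = "a_comp&b_comp&c_comp", n_genes = 1L))
})

test_that("genome extrapolation reproduces the published arithmetic", {
  out <- extrapolate_genome(12, 200, 13900)
  expect_equal(out$estimate, 834)
  expect_gte(out$at_least, 500)
  expect_equal(extrapolate_genome(0, 200, 13900)$estimate, 0)
  expect_equal(extrapolate_genome(200, 200, 13900)$estimate, 13900)
  expect_error(extrapolate_genome(1, 0), class = "ss_input_error")
  expect_error(extrapolate_genome(5, 4), class = "ss_input_error")
})

test_that("neuroblast patterns classify canonical lineages", {
  base <- data.frame(cell_id = 1:12, cell_type = c("neuroblast", rep("GMC", 3),
                                                   rep("progeny", 8)))
  zero <- transform(base, mrna_count = 0, protein_intensity = 10,
                    has_transcription_focus = FALSE)
  expect_equal(classify_neuroblast_pattern(zero)$class, "not_detected")
  all_on <- transform(base, mrna_count = 8, protein_intensity = 100,
                      has_transcription_focus = TRUE)
  expect_equal(classify_neuroblast_pattern(all_on)$class, "homogeneous")
  half <- transform(base, mrna_count = rep(c(8, 0), 6),
                    protein_intensity = rep(c(100, 10), 6),
                    has_transcription_focus = rep(c(TRUE, FALSE), 6))
  expect_equal(classify_neuroblast_pattern(half)$class,
               "cell_specific_transcriptional")
  post <- transform(base, mrna_count = 8,
                    protein_intensity = c(rep(100, 2), rep(10, 10)),
                    has_transcription_focus = TRUE)
  expect_equal(classify_neuroblast_pattern(post)$class,
               "cell_specific_posttranscriptional")
  expect_error(classify_neuroblast_pattern(zero[1:4, ]), class = "ss_input_error")
})

test_that("screen headlines and MDV export run on simulated annotations", {
  cfg <- annotation_sim_config(n_genes = 60, seed = 33)
  sim <- simulate_annotation_table(cfg)
  calls <- aggregate_majority(sim$table)
  resolved <- calls[calls$resolution != "escalated_unresolved", ]
  prof <- classify_discordance(resolved)
  heads <- screen_headlines(resolved, prof)
  expect_equal(heads$n_genes, length(unique(resolved$gene_id)))
  expect_equal(heads$share_intercellular + heads$share_intracellular, 100,
               tolerance = 1e-9)
  mdv <- mdv_export(resolved, prof)
  expect_equal(nrow(mdv), heads$n_genes)
  expect_true(all(c("any_discordance", "mushroom_body_neuropil_mrna") %in% names(mdv)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mdv(mdv, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".schema.json")))
})
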