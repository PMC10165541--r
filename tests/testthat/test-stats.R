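test_that("the decision tree picks the published tests on canonical inputs", {
  set.seed(1)
  # two large normal samples -> Student's t
  plan <- select_test(list(rnorm(60), rnorm(60)))
  expect_equal(plan$test, "student_t")
  # two small lognormal samples failing Shapiro-Wilk -> Wilcoxon rank sum
  found <- FALSE
  for (i in 1:20) {
    g <- list(exp(rnorm(12, 0, 1.5)), exp(rnorm(12, 0.5, 1.5)))
    plan <- select_test(g)
    if (!plan$normal) { expect_equal(plan$test, "wilcoxon"); found <- TRUE; break }
  }
  expect_true(found)
  # three normal groups -> one-way ANOVA with Tukey
  plan <- select_test(list(rnorm(30), rnorm(30), rnorm(30)))
  expect_equal(plan$test, "anova")
  expect_equal(plan$posthoc, "tukey")
})

test_that("groups below n = 3 are refused", {
  expect_error(select_test(list(rnorm(2), rnorm(10))), class = "ss_input_error")
  expect_error(select_test(list(rnorm(10))), class = "ss_input_error")
})

test_that("the tree matches a hand-coded oracle over a simulated grid", {
  cases <- expand.grid(dist = c("normal", "lognormal"),
                       vars = c("equal", "unequal"),
                       k = c(2, 3), rep = 1:5)
  seeds <- subseeds(2024, nrow(cases))
  for (i in seq_len(nrow(cases))) {
    set.seed(seeds[i])
    k <- cases$k[i]
    groups <- lapply(seq_len(k), function(j) {
      sd <- if (cases$vars[i] == "equal") 1 else j
      if (cases$dist[i] == "normal") rnorm(15, 0, sd) else exp(rnorm(15, 0, sd))
    })
    expect_equal(select_test(groups)$test, oracle_select_test(groups),
                 info = paste(unlist(cases[i, ]), collapse = "/"))
  }
})

test_that("Levene and Dunn helpers behave sensibly", {
  set.seed(1)
  eq <- list(rnorm(40), rnorm(40), rnorm(40))
  uneq <- list(rnorm(40, 0, 1), rnorm(40, 0, 4), rnorm(40, 0, 1))
  expect_gt(levene_test(eq)$p_value, 0.05)
  expect_lt(levene_test(uneq)$p_value, 0.01)
  d <- dunn_test(list(a = rnorm(25), b = rnorm(25), c = rnorm(25, 5)))
  expect_equal(nrow(d), 3L)
  expect_lt(d$p_adjusted[d$group_1 == "a" & d$group_2 == "c"], 0.01)
  expect_gt(d$p_value[d$group_1 == "a" & d$group_2 == "b"], 0.05)
})

test_that("comparisons report percent change with forced or selected tests", {
  a <- c(48, 52, 50, 49, 51, 50, 47, 53, 50, 50)
  cmp <- compare_conditions(a, a)
  expect_equal(cmp$percent_change, 0)
  expect_gt(cmp$p_value, 0.99)
  b <- a * 0.2
  cmp <- compare_conditions(a, b, tail = "one", force_test = "student_t")
  expect_equal(cmp$test_used, "student_t")
  expect_equal(cmp$percent_change, -80)
  expect_lt(cmp$p_value, 1e-6)
  # arm B all zeros: -100% change
  cmp <- compare_conditions(a, rep(0, 10))
  expect_equal(cmp$percent_change, -100)
  # zero reference arm: undefined, signalled
  cmp <- compare_conditions(rep(0, 5), c(1, 2, 3, 2, 1))
  expect_identical(cmp$status, "undefined_reference")
  expect_true(is.na(cmp$percent_change))
})

test_that("count tables feed comparisons through the compartment column", {
  mk <- function(vals) do.call(rbind, lapply(seq_along(vals), function(i)
    data.frame(image_id = paste0("img", i), compartment = "nmj_axon_terminal",
               n_single_mRNA = vals[i], n_foci = 0L, sum_focus_transcripts = 0,
               protein_mean_intensity = NA_real_)))
  cmp <- compare_conditions(mk(c(50, 52, 48, 49, 51)), mk(c(9, 8, 7, 9, 8)),
                            compartment = "nmj_axon_terminal")
  expect_lt(cmp$percent_change, -80)
  expect_lt(cmp$p_value, 0.001)
  expect_error(compare_conditions(mk(1:5), mk(1:5), compartment = "psd"),
               class = "ss_input_error")
})
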