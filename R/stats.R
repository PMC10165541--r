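# Assumption-checked test selection and condition comparison.
#
# The selection tree: Shapiro-Wilk per group for normality; the
# equal-variance assumption via an F test (2 groups) or Levene's test
# (> 2 groups). Normal + equal variance -> Student's t / one-way ANOVA with
# Tukey; non-normal -> Wilcoxon rank sum / Kruskal-Wallis with Dunn. The
# published tree leaves normal-but-unequal-variance data unspecified; that
# cell uses Welch's t / Welch one-way ANOVA.

#' Levene's test for homogeneity of variances
#'
#' Classic (mean-centred) Levene: one-way ANOVA on absolute deviations from
#' the group means.
#' @param groups list of numeric vectors.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(groups) {
  z <- unlist(lapply(groups, function(g) abs(g - mean(g))))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ f))
  list(statistic = a$`F value`[1], df = a$Df, p_value = a$`Pr(>F)`[1])
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie correction; p-values are
#' two-sided with Holm adjustment.
#' @param groups named list of numeric vectors.
#' @return data frame of pairwise comparisons.
#' @export
dunn_test <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  cmb <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((N * (N + 1) / 12) * tie_corr * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    data.frame(group_1 = a, group_2 = b, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, "holm")
  out
}

#' Choose a hypothesis test by the screen's decision tree
#'
#' @param groups list of >= 2 numeric samples, each with n >= 3.
#' @param paired paired design (2 groups only): the tree is applied to the
#'   differences and the paired t / Wilcoxon signed-rank test is chosen.
#' @param alpha significance level for the assumption checks.
#' @return a `test_plan` list: chosen `test`, `posthoc`, logical
#'   `normal` / `equal_variance`, and all assumption-test p-values.
#' @export
select_test <- function(groups, paired = FALSE, alpha = 0.05) {
  check_that(is.list(groups) && length(groups) >= 2L, "need >= 2 groups", input_error)
  ns <- lengths(groups)
  if (any(ns < 3L)) input_error("every group needs n >= 3")
  k <- length(groups)
  if (paired) {
    check_that(k == 2L && ns[1] == ns[2], "paired designs need two equal-length groups",
               input_error)
    d <- groups[[1]] - groups[[2]]
    sw <- stats::shapiro.test(d)$p.value
    normal <- sw > alpha
    return(structure(list(test = if (normal) "paired_t" else "wilcoxon_signed_rank",
                          posthoc = NA_character_, normal = normal,
                          equal_variance = NA, shapiro_p = sw,
                          variance_test = NA_character_, variance_p = NA_real_,
                          paired = TRUE), class = "test_plan"))
  }
  sw <- vapply(groups, function(g) {
    if (length(unique(g)) == 1L) return(0)   # degenerate: constant sample
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  normal <- all(sw > alpha)
  if (normal) {
    if (k == 2L) {
      vt <- stats::var.test(groups[[1]], groups[[2]])
      var_name <- "F"; vp <- vt$p.value
    } else {
      lv <- levene_test(groups)
      var_name <- "levene"; vp <- lv$p_value
    }
    equal <- vp > alpha
    test <- if (k == 2L) {
      if (equal) "student_t" else "welch_t"
    } else {
      if (equal) "anova" else "welch_anova"
    }
    posthoc <- if (k > 2L && equal) "tukey" else NA_character_
  } else {
    var_name <- NA_character_; vp <- NA_real_; equal <- NA
    test <- if (k == 2L) "wilcoxon" else "kruskal_wallis"
    posthoc <- if (k > 2L) "dunn" else NA_character_
  }
  structure(list(test = test, posthoc = posthoc, normal = normal,
                 equal_variance = equal, shapiro_p = sw,
                 variance_test = var_name, variance_p = vp, paired = FALSE),
            class = "test_plan")
}

# Execute a test plan on the groups; returns statistic, p-value, posthoc.
run_test_plan <- function(plan, groups, alternative = "two.sided") {
  k <- length(groups)
  posthoc <- NULL
  res <- switch(plan$test,
    student_t = stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE,
                              alternative = alternative),
    welch_t = stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE,
                            alternative = alternative),
    paired_t = stats::t.test(groups[[1]], groups[[2]], paired = TRUE,
                             alternative = alternative),
    wilcoxon = stats::wilcox.test(groups[[1]], groups[[2]], alternative = alternative,
                                  exact = FALSE, correct = TRUE),
    wilcoxon_signed_rank = stats::wilcox.test(groups[[1]], groups[[2]], paired = TRUE,
                                              alternative = alternative,
                                              exact = FALSE, correct = TRUE),
    anova = {
      x <- unlist(groups)
      g <- factor(rep(seq_len(k), lengths(groups)))
      fit <- stats::aov(x ~ g)
      posthoc <- stats::TukeyHSD(fit)$g
      s <- summary(fit)[[1]]
      list(statistic = s$`F value`[1], p.value = s$`Pr(>F)`[1])
    },
    welch_anova = {
      x <- unlist(groups)
      g <- factor(rep(seq_len(k), lengths(groups)))
      w <- stats::oneway.test(x ~ g, var.equal = FALSE)
      list(statistic = unname(w$statistic), p.value = w$p.value)
    },
    kruskal_wallis = {
      kk <- stats::kruskal.test(groups)
      posthoc <- dunn_test(groups)
      list(statistic = unname(kk$statistic), p.value = kk$p.value)
    },
    input_error(sprintf("unknown test '%s'", plan$test)))
  list(statistic = unname(res$statistic), p_value = res$p.value, posthoc = posthoc)
}

#' Compare transcript counts between two conditions
#'
#' Reports the percent change of means, `100 * (mean_B - mean_A) / mean_A`,
#' with per-arm SEMs and a delta-method confidence interval, and tests the
#' difference with the test chosen by [select_test()] unless a test is
#' forced (a one-tailed Student's t can be forced for directional transport
#' experiments).
#'
#' @param counts_a,counts_b count tables from [per_compartment_counts()]
#'   (one row per image for the chosen compartment) or bare numeric vectors.
#' @param compartment compartment to compare (ignored for bare vectors).
#' @param value column to compare (default `n_single_mRNA`).
#' @param tail `"two"` or `"one"`; one-tailed tests the direction of the
#'   observed change.
#' @param force_test optionally bypass the decision tree
#'   (`"student_t"`, `"welch_t"`, `"wilcoxon"`).
#' @param alpha assumption-check level.
#' @return a `comparison_result` list.
#' @export
compare_conditions <- function(counts_a, counts_b, compartment = NULL,
                               value = "n_single_mRNA", tail = c("two", "one"),
                               force_test = NULL, alpha = 0.05) {
  tail <- match.arg(tail)
  pull <- function(ct) {
    if (is.numeric(ct)) return(as.numeric(ct))
    check_that(!is.null(compartment) && compartment %in% ct$compartment,
               "compartment not present in count table", input_error)
    ct[[value]][ct$compartment == compartment]
  }
  a <- pull(counts_a); b <- pull(counts_b)
  check_that(length(a) >= 3 && length(b) >= 3, "need n >= 3 per arm", input_error)
  m_a <- mean(a); m_b <- mean(b)
  sem_a <- stats::sd(a) / sqrt(length(a)); sem_b <- stats::sd(b) / sqrt(length(b))
  if (m_a == 0) {
    pct <- NA_real_; pct_ci <- c(NA_real_, NA_real_); status <- "undefined_reference"
  } else {
    pct <- 100 * (m_b - m_a) / m_a
    # delta-method variance of the mean ratio
    vr <- sem_b^2 / m_a^2 + m_b^2 * sem_a^2 / m_a^4
    pct_ci <- pct + c(-1, 1) * 100 * stats::qnorm(0.975) * sqrt(vr)
    status <- "ok"
  }
  if (is.null(force_test)) {
    plan <- select_test(list(a, b), alpha = alpha)
  } else {
    plan <- structure(list(test = force_test, posthoc = NA_character_, normal = NA,
                           equal_variance = NA, shapiro_p = NA_real_,
                           variance_test = "forced", variance_p = NA_real_,
                           paired = FALSE), class = "test_plan")
  }
  alternative <- if (tail == "two") "two.sided" else if (m_b < m_a) "greater" else "less"
  fit <- run_test_plan(plan, list(a, b), alternative = alternative)
  structure(list(n_a = length(a), n_b = length(b), mean_a = m_a, mean_b = m_b,
                 sem_a = sem_a, sem_b = sem_b, percent_change = pct,
                 percent_change_ci = pct_ci, status = status,
                 test_used = plan$test, tail = tail, statistic = fit$statistic,
                 p_value = fit$p_value, assumption_checks = plan),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: change %.1f%% (A %.2f +/- %.2f, B %.2f +/- %.2f), %s p = %.3g\n",
              x$status, x$percent_change, x$mean_a, x$sem_a, x$mean_b, x$sem_b,
              x$test_used, x$p_value))
  invisible(x)
}
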