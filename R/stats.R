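#' Significance band for a p-value
#'
#' Convention used on all figures: `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05, `ns` above 0.05; boundary values get the band (p = 0.05
#' is `*`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of bands.
#' @export
signif_band <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
}

#' Long-format group table
#'
#' @param value Numeric observations.
#' @param group Group labels, same length.
#' @return A validated data frame with columns `value`, `group`.
#' @export
group_table <- function(value, group) {
  if (length(value) != length(group)) stop("value and group lengths differ")
  df <- data.frame(value = as.numeric(value), group = as.character(group))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df
}

check_groups <- function(table, min_groups = 2, min_n = 2) {
  sizes <- table(table$group)
  if (length(sizes) < min_groups)
    stop(sprintf("need at least %d groups", min_groups))
  if (any(sizes < min_n))
    stop(sprintf("every group needs at least %d observations", min_n))
  invisible(sizes)
}

new_test_result <- function(test_name, statistic, p_value, pairwise = NULL,
                            extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, pairwise = pairwise), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g [%s]\n",
              x$test_name, x$statistic, x$p_value, signif_band(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (adjusted):\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: p = %.4g [%s]\n",
                  x$pairwise$group_a[i], x$pairwise$group_b[i],
                  x$pairwise$adjusted_p[i], x$pairwise$band[i]))
  }
  invisible(x)
}

#' One-way ANOVA with Tukey's HSD post hoc
#'
#' Omnibus F test across groups followed by Tukey honest-significant-
#' difference pairwise comparisons (family-wise adjusted p-values).
#'
#' @param table A [group_table()].
#' @return A `test_result` with pairwise comparisons.
#' @export
anova_tukey <- function(table) {
  check_groups(table)
  table$group <- factor(table$group)
  if (stats::var(table$value) == 0) {    # constant data: no effect anywhere
    lv <- levels(table$group)
    comb <- utils::combn(lv, 2)
    pw <- data.frame(group_a = comb[2, ], group_b = comb[1, ],
                     adjusted_p = 1, band = "ns")
    return(new_test_result("one-way ANOVA + Tukey HSD", 0, 1, pw))
  }
  fit <- stats::aov(value ~ group, data = table)
  s <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  padj <- unname(tuk[, "p adj"])
  padj[is.na(padj)] <- 1             # zero-variance groups: no difference
  pw <- data.frame(group_a = vapply(pairs, `[`, "", 1),
                   group_b = vapply(pairs, `[`, "", 2),
                   adjusted_p = padj, band = signif_band(padj))
  p <- s[["Pr(>F)"]][1]
  f <- s[["F value"]][1]
  if (is.na(f)) { f <- 0; p <- 1 }   # zero between- and within-group variance
  new_test_result("one-way ANOVA + Tukey HSD", f, p, pw)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across groups; pairwise Dunn z-tests on
#' mean ranks with the pooled tie-corrected variance, adjusted for multiple
#' comparisons (Bonferroni by default).
#'
#' @param table A [group_table()].
#' @param adjust `"bonferroni"` (default), `"holm"` or `"sidak"`.
#' @return A `test_result`; `$dunn_z` holds the pairwise z statistics.
#' @export
kruskal_dunn <- function(table, adjust = c("bonferroni", "holm", "sidak")) {
  adjust <- match.arg(adjust)
  check_groups(table)
  if (length(unique(table$value)) == 1)
    stop("all values tied across all groups; H undefined after tie correction")
  kw <- stats::kruskal.test(table$value, factor(table$group))
  g <- factor(table$group)
  r <- rank(table$value)
  N <- length(r)
  ni <- tabulate(g)
  rbar <- tapply(r, g, mean)
  ties <- table(table$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  comb <- utils::combn(seq_along(lv), 2)
  z <- p_raw <- numeric(ncol(comb))
  for (k in seq_len(ncol(comb))) {
    i <- comb[1, k]; j <- comb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  m <- length(p_raw)
  p_adj <- switch(adjust,
                  bonferroni = pmin(1, p_raw * m),
                  holm = stats::p.adjust(p_raw, "holm"),
                  sidak = 1 - (1 - p_raw)^m)
  pw <- data.frame(group_a = lv[comb[1, ]], group_b = lv[comb[2, ]],
                   adjusted_p = p_adj, band = signif_band(p_adj))
  new_test_result("Kruskal-Wallis + Dunn", unname(kw$statistic), kw$p.value,
                  pw, extra = list(dunn_z = z, adjust = adjust))
}

#' Two-sided Mann-Whitney U test
#'
#' Unpaired two-tailed rank-sum comparison of two groups. The p-value is
#' exact when feasible: for tie-free data the exact U distribution is used;
#' with ties, the full permutation distribution of U is enumerated when
#' `choose(n_a + n_b, n_a)` is at most `max_enumeration`. Otherwise the
#' tie-corrected normal approximation with continuity correction applies.
#'
#' @param a,b Numeric vectors.
#' @param max_enumeration Enumeration budget (default 2e5 label assignments).
#' @return A `test_result`; statistic is U for group `a`, `$method` records
#'   which p-value route was taken.
#' @export
mann_whitney <- function(a, b, max_enumeration = 2e5) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na * nb <= 400) {
    p <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
    method <- "exact"
  } else if (ties && choose(na + nb, na) <= max_enumeration) {
    p <- mw_permutation_p(r, na, U)
    method <- "exact-enumeration"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE)$p.value)
    method <- "normal-approximation"
  }
  new_test_result("Mann-Whitney U (two-sided)", U, min(1, p),
                  extra = list(method = method, n = c(na, nb)))
}

# Exact two-sided p for U by complete enumeration of group-label assignments
# on the (possibly tied) rank vector; two-sided as twice the smaller tail,
# measured by distance of U from its mean.
mw_permutation_p <- function(r, na, U_obs) {
  n <- length(r)
  idx <- utils::combn(n, na)
  mu <- na * (n - na) / 2
  Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

#' Welch's two-sided t-test
#'
#' Unpaired t-test with Welch's correction (Satterthwaite degrees of
#' freedom); the convention for two zero-variance groups with equal means is
#' t = 0, p = 1, while zero variance with unequal means is an error.
#'
#' @param a,b Numeric vectors.
#' @return A `test_result`; `$df` holds the Satterthwaite df.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result("Welch t (two-sided)", 0, 1,
                             extra = list(df = NA_real_)))
    stop("both groups have zero variance with unequal means; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new_test_result("Welch t (two-sided)", unname(tt$statistic), tt$p.value,
                  extra = list(df = unname(tt$parameter)))
}

#' Distribution summary: mean +/- SEM and median with quartiles
#'
#' Quartiles use linear interpolation between order statistics (R quantile
#' type 7); the SEM of a single observation is `NA`.
#'
#' @param values Numeric vector, n >= 1.
#' @return List with n, mean, sem, median, q25, q75.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("empty input has no summary")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = n, mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
       median = q[2], q25 = q[1], q75 = q[3])
}
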