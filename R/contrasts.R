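#' 2x2 contingency table
#'
#' @param a,b Group-1 successes and failures.
#' @param c,d Group-2 successes and failures.
#' @return Integer matrix of class `table2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(x), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("g1", "g2"),
                              outcome = c("success", "failure")))
  class(m) <- c("table2x2", class(m))
  m
}

.test_result <- function(method, statistic, df, p_value) {
  data.frame(method = method, statistic = as.numeric(statistic),
             df = ifelse(is.null(df) || is.na(df), NA_real_, as.numeric(df)),
             p_value = as.numeric(p_value), stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson statistic `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1
#' degree of freedom and no continuity correction (the convention that
#' reproduces the study's printed chi-square values).
#'
#' @param tab A [contingency_2x2()] matrix (or any 2x2 matrix of counts).
#' @return One-row data.frame: `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: a margin of the table is zero",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(unclass(tab), correct = FALSE))
  .test_result("chi-square (no continuity correction)",
               res$statistic, res$parameter, res$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by probability summation (minimum-likelihood
#' convention): the sum, over all tables with the observed margins, of
#' hypergeometric point probabilities no larger than the observed table's.
#' The doubling convention (twice the smaller one-sided tail, capped at 1) is
#' available via `convention = "doubling"`. Computation is in log space via
#' the hypergeometric density, so large counts never overflow.
#'
#' @param tab A [contingency_2x2()] matrix.
#' @param convention `"minlik"` (default) or `"doubling"`.
#' @return One-row data.frame: `method`, `statistic` (the odds-ratio
#'   estimate), `df` (NA), `p_value`.
#' @export
fisher_exact_2x2 <- function(tab, convention = c("minlik", "doubling")) {
  convention <- match.arg(convention)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("Fisher test undefined: a margin of the table is zero",
         call. = FALSE)
  }
  m <- unclass(tab)
  if (convention == "minlik") {
    res <- stats::fisher.test(m)
    return(.test_result("Fisher exact (two-sided, probability summation)",
                        res$estimate, NA, res$p.value))
  }
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  p_lo <- stats::phyper(a, c1, N - c1, r1)
  p_hi <- stats::phyper(a - 1, c1, N - c1, r1, lower.tail = FALSE)
  p <- min(1, 2 * min(p_lo, p_hi))
  or <- stats::fisher.test(m)$estimate
  .test_result("Fisher exact (two-sided, doubled one-tail)", or, NA, p)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value; used to compare
#' the shape of two genome-wide D distributions.
#'
#' @param x,y Numeric samples.
#' @return One-row data.frame: `method`, `statistic` (K-S D), `df` (NA),
#'   `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  .test_result("two-sample Kolmogorov-Smirnov (asymptotic)",
               res$statistic, NA, res$p.value)
}

#' Wilcoxon rank-sum test
#'
#' W counts pairs with `x > y` plus half the tied pairs (the scale reported
#' by common statistical software), with the normal approximation and tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @return One-row data.frame: `method`, `statistic` (W), `df` (NA),
#'   `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  .test_result("Wilcoxon rank-sum (normal approximation)",
               res$statistic, NA, res$p.value)
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default (`df = n1 + n2 - 2`); Welch available
#' with `pooled = FALSE`. The sign follows `mean(x) - mean(y)`.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param pooled Use the pooled-variance form? Default `TRUE`.
#' @return One-row data.frame: `method`, `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("t test undefined: zero variance in both samples", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = pooled)
  .test_result(if (pooled) "Student t (pooled variance)" else "Welch t",
               res$statistic, res$parameter, res$p.value)
}

#' Selection-by-expression contrast report
#'
#' Joins per-gene selection classes with expression classes (differentially /
#' non-differentially expressed) and produces the counts, percentages and
#' Fisher exact comparisons of the expression-class analysis: for each of
#' {any significant D, significant positive, significant negative}, the
#' differential class is contrasted against the non-differential class and
#' against the global scan.
#'
#' @param gene_classes Output of [classify_genes()].
#' @param expression data.frame with columns `gene_id` and
#'   `expression_class` (`DIFFERENTIAL` / `NON_DIFFERENTIAL`).
#' @param global_counts Optional named vector as from [gene_class_counts()]
#'   describing the global scan; defaults to counts over `gene_classes`
#'   itself (analysed genes only).
#' @return List with `counts` (per expression class: N, significant,
#'   positive, negative and percentages) and `tests` (data.frame of Fisher
#'   comparisons). Classes absent from the join yield a warning and skipped
#'   tests.
#' @export
selection_by_expression_contrast <- function(gene_classes, expression,
                                             global_counts = NULL) {
  merged <- merge(gene_classes[, c("gene_id", "class")], expression,
                  by = "gene_id")
  merged <- merged[merged$class != "NOT_ANALYSED", , drop = FALSE]
  if (nrow(merged) == 0) {
    warning("no genes joined across selection and expression tables",
            call. = FALSE)
    return(list(counts = data.frame(), tests = data.frame()))
  }
  if (is.null(global_counts)) {
    gc <- gene_class_counts(gene_classes)
    global_counts <- c(
      N = unname(gc["analysed"] + gc["significant"]),
      significant = unname(gc["significant"]),
      positive = unname(gc["significant_positive"]),
      negative = unname(gc["significant_negative"]))
  }

  count_one <- function(cls) {
    sub <- merged[merged$expression_class == cls, , drop = FALSE]
    c(N = nrow(sub),
      significant = sum(sub$class %in% c("SIGNIFICANT_POSITIVE",
                                         "SIGNIFICANT_NEGATIVE")),
      positive = sum(sub$class == "SIGNIFICANT_POSITIVE"),
      negative = sum(sub$class == "SIGNIFICANT_NEGATIVE"))
  }
  diff <- count_one("DIFFERENTIAL")
  nond <- count_one("NON_DIFFERENTIAL")
  counts <- data.frame(
    group = c("DIFFERENTIAL", "NON_DIFFERENTIAL", "GLOBAL"),
    N = c(diff["N"], nond["N"], global_counts["N"]),
    significant = c(diff["significant"], nond["significant"],
                    global_counts["significant"]),
    significant_positive = c(diff["positive"], nond["positive"],
                             global_counts["positive"]),
    significant_negative = c(diff["negative"], nond["negative"],
                             global_counts["negative"]),
    row.names = NULL)
  counts$pct_significant <- 100 * counts$significant / counts$N
  counts$pct_positive <- 100 * counts$significant_positive / counts$N
  counts$pct_negative <- 100 * counts$significant_negative / counts$N

  tests <- list()
  if (diff["N"] > 0 && nond["N"] > 0) {
    for (what in c("significant", "positive", "negative")) {
      key <- if (what == "significant") "significant" else
        paste0("significant_", what)
      d_k <- counts[[key]][1]; n_k <- counts[[key]][2]
      g_k <- counts[[key]][3]
      t1 <- fisher_exact_2x2(contingency_2x2(
        d_k, diff["N"] - d_k, n_k, nond["N"] - n_k))
      t1$comparison <- paste0("differential vs non-differential: ", what)
      t2 <- fisher_exact_2x2(contingency_2x2(
        d_k, diff["N"] - d_k, g_k, global_counts["N"] - g_k))
      t2$comparison <- paste0("differential vs global scan: ", what)
      tests <- c(tests, list(t1, t2))
    }
  } else {
    warning("an expression class is empty; Fisher tests skipped",
            call. = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else data.frame()
  list(counts = counts, tests = tests)
}
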