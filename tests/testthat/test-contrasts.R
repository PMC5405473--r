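test_that("Pearson chi-square on 2x2 tables reproduces published statistics", {
  r1 <- chi_square_2x2(contingency_2x2(214, 5910, 178, 2884))
  expect_equal(r1$statistic, 26.87, tolerance = 0.01 / 26.87)
  expect_equal(r1$df, 1)
  expect_lt(r1$p_value, 3e-7)

  r2 <- chi_square_2x2(contingency_2x2(400, 69294, 21, 65912))
  expect_equal(r2$statistic, 321.74, tolerance = 0.1 / 321.74)

  # equal proportions give zero
  expect_equal(chi_square_2x2(contingency_2x2(10, 90, 20, 180))$statistic, 0)

  # invariance under transposition and row/column swaps
  tabs <- list(c(7, 3, 11, 19), c(40, 60, 25, 75))
  for (x in tabs) {
    base <- chi_square_2x2(contingency_2x2(x[1], x[2], x[3], x[4]))$statistic
    expect_equal(chi_square_2x2(contingency_2x2(x[3], x[4], x[1], x[2]))$statistic, base)
    expect_equal(chi_square_2x2(contingency_2x2(x[2], x[1], x[4], x[3]))$statistic, base)
    expect_equal(chi_square_2x2(t(contingency_2x2(x[1], x[2], x[3], x[4])))$statistic,
                 base)
  }

  expect_error(chi_square_2x2(contingency_2x2(0, 0, 5, 5)), "margin")
})

test_that("Fisher exact two-sided p-values match publication and enumeration", {
  expect_equal(fisher_exact_2x2(contingency_2x2(11, 132, 30, 417))$p_value,
               0.706381, tolerance = 1e-4 / 0.706381)
  expect_equal(fisher_exact_2x2(contingency_2x2(23, 986, 29, 2055))$p_value,
               0.075006, tolerance = 1e-4 / 0.075006)
  expect_equal(fisher_exact_2x2(contingency_2x2(1, 1, 1, 1))$p_value, 1.0)

  # random tables vs the enumeration oracle
  set.seed(71)
  for (rep in 1:30) {
    x <- rmultinom(1, sample(8:200, 1), prob = runif(4, 0.05, 1))[, 1] + 1L
    got <- fisher_exact_2x2(contingency_2x2(x[1], x[2], x[3], x[4]))$p_value
    expect_equal(got, oracle_fisher_minlik(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-7)
  }

  # doubling convention never below the one-sided tail, capped at 1
  d <- fisher_exact_2x2(contingency_2x2(2, 8, 8, 2),
                        convention = "doubling")$p_value
  expect_lte(d, 1)
  expect_gte(d, fisher_exact_2x2(contingency_2x2(2, 8, 8, 2))$p_value / 2)
})

test_that("K-S, rank-sum and t tests reduce to their textbook forms", {
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(rnorm(40), rnorm(40) + 100)$statistic, 1)

  expect_equal(rank_sum_test(0, 0)$statistic, 0.5)
  expect_equal(rank_sum_test(c(2, 3, 4), c(0, 0.5, 1, 1.5))$statistic, 12)

  expect_equal(two_sample_t(x, x)$statistic, 0)
  r <- two_sample_t(c(0, 0, 1, 1), c(1, 1, 2, 2), pooled = TRUE)
  expect_equal(r$statistic, -2.449, tolerance = 0.01 / 2.449)
  expect_equal(r$df, 6)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("equal-mean simulations keep the t test near its nominal size", {
  set.seed(73)
  rej <- mean(replicate(200, {
    two_sample_t(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.04)
})

test_that("shifted distributions are detected by the rank-sum test", {
  set.seed(79)
  rej <- mean(replicate(100, {
    rank_sum_test(rnorm(500) + 0.5, rnorm(500))$p_value < 0.01
  }))
  expect_gte(rej, 0.95)
})

test_that("selection-by-expression contrast reproduces the printed comparison", {
  # gene classes emulating the published intraspecific joined table:
  # differential 1009 genes (42 significant: 23 positive, 19 negative),
  # non-differential 2084 (79 significant: 29 positive, 50 negative)
  mk <- function(prefix, n, pos, neg) {
    cls <- c(rep("SIGNIFICANT_POSITIVE", pos), rep("SIGNIFICANT_NEGATIVE", neg),
             rep("ANALYSED", n - pos - neg))
    data.frame(gene_id = paste0(prefix, seq_len(n)), class = cls,
               stringsAsFactors = FALSE)
  }
  gene_classes <- rbind(mk("d", 1009, 23, 19), mk("n", 2084, 29, 50))
  expression <- data.frame(
    gene_id = gene_classes$gene_id,
    expression_class = c(rep("DIFFERENTIAL", 1009),
                         rep("NON_DIFFERENTIAL", 2084)),
    stringsAsFactors = FALSE)
  global <- c(N = 14994, significant = 530, positive = 228, negative = 302)
  rep <- selection_by_expression_contrast(gene_classes, expression, global)

  expect_equal(rep$counts$significant[1:2], c(42, 79))
  expect_equal(rep$counts$pct_positive[1], 100 * 23 / 1009, tolerance = 1e-9)

  tests <- rep$tests
  get_p <- function(cmp) tests$p_value[tests$comparison == cmp]
  expect_equal(get_p("differential vs non-differential: significant"),
               0.621698, tolerance = 1e-4 / 0.621698)
  expect_equal(get_p("differential vs global scan: significant"),
               0.292928, tolerance = 1e-4 / 0.292928)
  expect_equal(get_p("differential vs non-differential: positive"),
               0.075006, tolerance = 1e-4 / 0.075006)
  expect_equal(get_p("differential vs global scan: positive"),
               0.066236, tolerance = 1e-4 / 0.066236)

  # one class empty: counts still reported, tests skipped
  expr_one <- expression
  expr_one$expression_class <- "DIFFERENTIAL"
  expect_warning(rep2 <- selection_by_expression_contrast(
    gene_classes, expr_one, global), "empty")
  expect_equal(nrow(rep2$tests), 0)
  expect_equal(rep2$counts$N[1], 3093)
})

test_that("planted expression enrichment is detected with decent power", {
  set.seed(83)
  hits <- replicate(40, {
    overlaps <- c(rep(TRUE, 300), rep(FALSE, 2700))
    truth <- data.frame(gene_id = sprintf("g%d", 1:3000),
                        overlaps_balancing = overlaps)
    expr <- plant_expression_classes(truth, enrichment = 2, base_rate = 0.25)
    diff_bal <- sum(expr$expression_class == "DIFFERENTIAL" & overlaps)
    tab <- contingency_2x2(
      diff_bal, sum(overlaps) - diff_bal,
      sum(expr$expression_class == "DIFFERENTIAL" & !overlaps),
      sum(!overlaps) - sum(expr$expression_class == "DIFFERENTIAL" & !overlaps))
    fisher_exact_2x2(tab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.5)
})
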