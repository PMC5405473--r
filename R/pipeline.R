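#' Run a full intraspecific selection scan
#'
#' Ties the stages together: read the inputs, tile the genome, compute
#' per-window diversity, build the observed D distribution, derive the
#' theoretical and empirically corrected confidence limits, flag significant
#' windows and classify genes. When `out_dir` is given, writes `windows.tsv`,
#' `distribution.tsv`, `significant_windows.tsv`, `genes.tsv`,
#' `summary.json` and a `manifest.json` recording inputs and configuration.
#'
#' @param vcf Path to the multi-sample VCF.
#' @param fai Path to the reference `.fai` index.
#' @param mask Optional BED mask path.
#' @param gff Optional GFF3 gene-model path.
#' @param strains Strains to analyse (default: all VCF samples).
#' @param config A [scan_config()].
#' @param tail_fraction Per-tail mass for the empirical limits.
#' @param ties Tie policy for [empirical_limits()].
#' @param out_dir Optional output directory.
#' @return List: `windows` (classified window table), `dist`
#'   (d_distribution), `genes` (gene classification or NULL), `report`
#'   (named list of the bookkeeping numbers).
#' @export
run_scan <- function(vcf, fai, mask = NULL, gff = NULL, strains = NULL,
                     config = scan_config(), tail_fraction = 0.02,
                     ties = "exclude", out_dir = NULL) {
  index <- load_reference_index(fai)
  mask_gr <- load_mask(mask, index)
  variants <- load_variants(vcf, strains)
  windows <- partition_genome(index, config)
  stats <- scan_windows(windows, variants, mask_gr, config)
  dist <- build_distribution(stats)
  dist <- empirical_limits(dist, tail_fraction, ties)
  stats <- classify_windows(stats, dist)
  genes <- NULL
  if (!is.null(gff)) {
    gene_models <- load_genes(gff, index)
    genes <- classify_genes(gene_models, stats)
  }
  counts <- scan_counts(stats)
  sig <- attr(stats, "sig_counts")
  report <- list(
    n_strains = length(attr(variants, "strains")),
    n_seq = attr(stats, "n_seq"),
    window_size = config$window_size,
    min_callable_fraction = config$min_callable_fraction,
    tail_fraction = tail_fraction,
    tie_policy = ties,
    windows_total = unname(counts["total"]),
    windows_discarded = unname(counts["discarded"]),
    windows_invariable = unname(counts["invariable"]),
    windows_analysed = unname(counts["analysed"]),
    d_min = dist$min, d_max = dist$max, d_mean = dist$mean,
    theoretical_lower = dist$theoretical$lower,
    theoretical_upper = dist$theoretical$upper,
    empirical_lower = dist$empirical_lower,
    empirical_upper = dist$empirical_upper,
    achieved_lower_mass = dist$achieved_lower_mass,
    achieved_upper_mass = dist$achieved_upper_mass,
    significant_windows_positive = unname(sig["positive"]),
    significant_windows_negative = unname(sig["negative"]),
    theta_window_mean = mean(stats$theta_window[stats$status == "ANALYSED"]),
    pi_site_mean = mean(stats$pi_site[stats$status == "ANALYSED"]))
  if (!is.null(genes)) {
    report <- c(report, as.list(stats::setNames(
      gene_class_counts(genes),
      paste0("genes_", names(gene_class_counts(genes))))))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(stats, file.path(out_dir, "windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dtab <- as.data.frame(table(dist$values), stringsAsFactors = FALSE)
    names(dtab) <- c("value", "count")
    utils::write.table(dtab, file.path(out_dir, "distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stats[stats$significance != "NONE", , drop = FALSE],
                       file.path(out_dir, "significant_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(genes)) {
      utils::write.table(genes, file.path(out_dir, "genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(inputs = list(vcf = vcf, fai = fai, mask = mask, gff = gff),
           strains = attr(variants, "strains"),
           config = unclass(config), tail_fraction = tail_fraction,
           tie_policy = ties),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  list(windows = stats, dist = dist, genes = genes, report = report)
}

#' Compare two scans
#'
#' The four between-species comparisons: Kolmogorov-Smirnov and Wilcoxon
#' rank-sum on the D distributions, pooled t on the per-window Watterson
#' theta of analysed windows, and chi-square (no continuity correction) on
#' the invariable-window proportions (invariable vs windows with D, among
#' covered windows).
#'
#' @param scan_a,scan_b Results of [run_scan()] (or any lists with a
#'   `windows` table and `report`).
#' @return data.frame with one row per comparison: `comparison`, `method`,
#'   `statistic`, `df`, `p_value`.
#' @export
run_compare <- function(scan_a, scan_b) {
  d_a <- scan_a$dist$values
  d_b <- scan_b$dist$values
  th_a <- scan_a$windows$theta_window[scan_a$windows$status == "ANALYSED"]
  th_b <- scan_b$windows$theta_window[scan_b$windows$status == "ANALYSED"]
  tests <- list(
    cbind(comparison = "D distribution shape", ks_two_sample(d_a, d_b)),
    cbind(comparison = "D location", rank_sum_test(d_a, d_b)),
    cbind(comparison = "theta per window", two_sample_t(th_a, th_b)),
    cbind(comparison = "invariable-window proportion",
          tryCatch(
            invariable_proportion_test(
              scan_a$report$windows_invariable,
              scan_a$report$windows_analysed,
              scan_b$report$windows_invariable,
              scan_b$report$windows_analysed),
            error = function(e) {
              # a zero margin (e.g. no invariable window in either scan)
              # leaves the statistic degenerate; equal proportions score 0
              pa <- scan_a$report$windows_invariable /
                max(1, scan_a$report$windows_analysed)
              pb <- scan_b$report$windows_invariable /
                max(1, scan_b$report$windows_analysed)
              data.frame(method = "chi-square (degenerate margin)",
                         statistic = if (pa == pb) 0 else NA_real_,
                         df = NA_real_, p_value = NA_real_)
            })))
  do.call(rbind, tests)
}

#' Chi-square test on invariable-window proportions
#'
#' @param inv_a,analysed_a Invariable and analysed (with-D) window counts of
#'   scan A.
#' @param inv_b,analysed_b The same for scan B.
#' @return One-row data.frame as from [chi_square_2x2()].
#' @export
invariable_proportion_test <- function(inv_a, analysed_a, inv_b, analysed_b) {
  chi_square_2x2(contingency_2x2(inv_a, analysed_a, inv_b, analysed_b))
}

#' Contrast report from printed contingency counts
#'
#' Runs the requested 2x2 test on counts supplied directly (successes and
#' failures per group), for reproducing published comparisons without the
#' underlying gene tables.
#'
#' @param a,b,c,d Counts, row-wise.
#' @param test `"fisher"` or `"chisq"`.
#' @return One-row data.frame with the test result.
#' @export
contrast_counts <- function(a, b, c, d, test = c("fisher", "chisq")) {
  test <- match.arg(test)
  tab <- contingency_2x2(a, b, c, d)
  if (test == "fisher") fisher_exact_2x2(tab) else chi_square_2x2(tab)
}

#' Selection-by-expression contrast over scan outputs
#'
#' Thin wrapper over [selection_by_expression_contrast()] that also writes
#' the report when `out_dir` is given.
#'
#' @param gene_classes Output of [classify_genes()] (or [run_scan()]'s
#'   `genes`).
#' @param expression Expression-class table (`gene_id`,
#'   `expression_class`).
#' @param global_counts Optional global-scan counts (see
#'   [selection_by_expression_contrast()]).
#' @param out_dir Optional output directory for `contrast_counts.tsv` and
#'   `contrast_tests.tsv`.
#' @return The contrast report list.
#' @export
run_contrast <- function(gene_classes, expression, global_counts = NULL,
                         out_dir = NULL) {
  rep <- selection_by_expression_contrast(gene_classes, expression,
                                          global_counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(rep$counts, file.path(out_dir, "contrast_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$tests, file.path(out_dir, "contrast_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}

#' Simulate a genome bundle (pipeline entry point)
#'
#' @param spec A [sim_spec()].
#' @param out_dir Output directory.
#' @return See [emit_genome_bundle()].
#' @export
run_simulate <- function(spec, out_dir) {
  emit_genome_bundle(spec, out_dir)
}
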