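#' Fraction of a gene covered by analysed windows
#'
#' For each gene, the fraction of its bases overlapped by `ANALYSED` windows.
#' A gene enters the analysed set when more than half of its length is
#' covered (the >50% rule used for the analysed-gene denominator).
#'
#' @param genes [GenomicRanges::GRanges] from [load_genes()].
#' @param window_stats Window table from [scan_windows()] (status column
#'   required).
#' @return Numeric vector of coverage fractions, one per gene.
#' @export
gene_coverage_fraction <- function(genes, window_stats) {
  if (length(genes) == 0) return(numeric())
  aw <- window_stats[window_stats$status == "ANALYSED", , drop = FALSE]
  if (nrow(aw) == 0) return(rep(0, length(genes)))
  awgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    aw$chrom, IRanges::IRanges(aw$start, aw$end)))
  g <- GenomicRanges::granges(genes)
  GenomicRanges::strand(g) <- "*"
  hits <- GenomicRanges::findOverlaps(g, awgr, ignore.strand = TRUE)
  cov <- numeric(length(genes))
  if (length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      g[S4Vectors::queryHits(hits)], awgr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / IRanges::width(g)
}

#' Classify genes by overlap with significant windows
#'
#' Each gene receives exactly one class. Genes with analysed-window coverage
#' of at most 50% are `NOT_ANALYSED`. Analysed genes overlapping at least one
#' significant window take the sign of the overlapping significant window
#' with the largest |D| (a tie resolves to positive and is logged in the
#' returned attribute `sign_conflicts`); analysed genes without such an
#' overlap stay `ANALYSED`. Significance requires any overlap with a
#' significant window — the >50% rule applies only to the analysed-gene
#' denominator.
#'
#' @param genes [GenomicRanges::GRanges] from [load_genes()].
#' @param window_stats Window table from [classify_windows()] (significance
#'   column required).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `coverage_fraction`, `class`, `extreme_D` (D of the decisive window, NA
#'   otherwise), `supporting_windows` (comma-joined window ids of overlapping
#'   significant windows). Attribute `sign_conflicts` lists genes that
#'   overlapped both signs.
#' @export
classify_genes <- function(genes, window_stats) {
  if (!"significance" %in% names(window_stats)) {
    stop("window_stats lacks a significance column; ",
         "run classify_windows() first", call. = FALSE)
  }
  cov <- gene_coverage_fraction(genes, window_stats)
  out <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    coverage_fraction = cov,
    class = ifelse(cov > 0.5, "ANALYSED", "NOT_ANALYSED"),
    extreme_D = NA_real_,
    supporting_windows = "",
    stringsAsFactors = FALSE)

  sw <- window_stats[window_stats$significance != "NONE", , drop = FALSE]
  conflicts <- character()
  if (nrow(sw) > 0 && length(genes) > 0) {
    swgr <- GenomicRanges::GRanges(sw$chrom,
                                   IRanges::IRanges(sw$start, sw$end))
    g <- GenomicRanges::granges(genes)
    GenomicRanges::strand(g) <- "*"
    hits <- GenomicRanges::findOverlaps(g, swgr, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (gi in unique(qh)) {
        if (out$class[gi] != "ANALYSED") next
        wi <- sh[qh == gi]
        out$supporting_windows[gi] <- paste(sw$window_id[wi], collapse = ",")
        Dv <- sw$D[wi]
        best <- wi[order(-abs(Dv), -sign(Dv))][1]  # tie in |D| -> positive
        out$extreme_D[gi] <- sw$D[best]
        out$class[gi] <- sw$significance[best]
        signs <- unique(sw$significance[wi])
        if (length(signs) > 1) conflicts <- c(conflicts, out$gene_id[gi])
      }
    }
  }
  attr(out, "sign_conflicts") <- conflicts
  out
}

#' Gene-class totals
#'
#' @param gene_classes Output of [classify_genes()].
#' @return Named integer vector: total, not_analysed, analysed (non-
#'   significant), significant, significant_positive, significant_negative.
#' @export
gene_class_counts <- function(gene_classes) {
  cl <- gene_classes$class
  c(total = length(cl),
    not_analysed = sum(cl == "NOT_ANALYSED"),
    analysed = sum(cl == "ANALYSED"),
    significant = sum(cl %in% c("SIGNIFICANT_POSITIVE",
                                "SIGNIFICANT_NEGATIVE")),
    significant_positive = sum(cl == "SIGNIFICANT_POSITIVE"),
    significant_negative = sum(cl == "SIGNIFICANT_NEGATIVE"))
}
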