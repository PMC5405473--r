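#' Scan configuration
#'
#' Defaults mirror the study design: non-overlapping 1,000-bp windows,
#' windows with less than 90% callable sequence discarded, five diploid
#' strains giving `n = 10` sequences.
#'
#' @param window_size Window length in bp.
#' @param min_callable_fraction Minimum callable fraction for a window to be
#'   analysed (in (0, 1]).
#' @param ploidy Sequences per strain.
#' @param step Distance between window starts; defaults to `window_size`
#'   (non-overlapping tiling). Must not exceed `window_size`.
#' @param include_partial Include the trailing partial window of each
#'   chromosome in the D distribution? Default `FALSE`: partial windows are
#'   computed and reported but excluded from the distribution, since unequal
#'   window lengths distort S-based statistics.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_size = 1000L, min_callable_fraction = 0.9,
                        ploidy = 2L, step = window_size,
                        include_partial = FALSE) {
  stopifnot(window_size > 0, step > 0, step <= window_size,
            min_callable_fraction > 0, min_callable_fraction <= 1,
            ploidy >= 1)
  structure(list(window_size = as.integer(window_size),
                 min_callable_fraction = min_callable_fraction,
                 ploidy = as.integer(ploidy),
                 step = as.integer(step),
                 include_partial = include_partial),
            class = "scan_config")
}

#' Tile a genome into windows
#'
#' Produces, per chromosome, `floor(L / window_size)` full windows plus one
#' trailing partial window when the length is not a multiple, flagged in the
#' `partial` column. With the default `step = window_size` the windows tile
#' each chromosome without overlap.
#'
#' @param index Reference index from [load_reference_index()].
#' @param config A [scan_config()].
#' @return A data.frame: `window_id`, `chrom`, `start`, `end` (1-based,
#'   closed), `length`, `partial`.
#' @export
partition_genome <- function(index, config = scan_config()) {
  parts <- lapply(seq_len(nrow(index)), function(i) {
    L <- index$length[i]
    starts <- seq.int(1L, L, by = config$step)
    starts <- starts[starts <= L]
    ends <- pmin(starts + config$window_size - 1L, L)
    data.frame(chrom = index$chrom[i], start = starts, end = ends,
               length = ends - starts + 1L,
               partial = (ends - starts + 1L) < config$window_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- cbind(window_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Callable fraction of a window
#'
#' The fraction of a window's bases that are unmasked and fully genotyped:
#' `(length - masked bases - unmasked sites with a missing genotype) /
#' length`. A site with any missing genotype among the strains counts as
#' uncallable (the scan requires completeness across all samples).
#'
#' @param window One row of [partition_genome()] output (or a list with
#'   `chrom`, `start`, `end`, `length`).
#' @param mask Mask [GenomicRanges::GRanges] from [load_mask()].
#' @param missing_sites Optional data.frame of sites with missing genotypes
#'   (`chrom`, `pos`).
#' @return Fraction in [0, 1].
#' @export
window_callable_fraction <- function(window, mask, missing_sites = NULL) {
  wgr <- GenomicRanges::GRanges(window$chrom,
                                IRanges::IRanges(window$start, window$end))
  masked <- sum(IRanges::width(GenomicRanges::intersect(
    wgr, GenomicRanges::granges(mask), ignore.strand = TRUE)))
  n_missing <- 0L
  if (!is.null(missing_sites) && nrow(missing_sites) > 0) {
    inw <- missing_sites$chrom == window$chrom &
      missing_sites$pos >= window$start & missing_sites$pos <= window$end
    if (any(inw)) {
      pos <- missing_sites$pos[inw]
      if (length(mask) > 0) {
        mgr <- GenomicRanges::GRanges(window$chrom, IRanges::IRanges(pos, pos))
        in_mask <- IRanges::overlapsAny(mgr, mask, ignore.strand = TRUE)
        n_missing <- sum(!in_mask)
      } else {
        n_missing <- length(pos)
      }
    }
  }
  (window$length - masked - n_missing) / window$length
}

# masked bases per window, vectorised over the window table
.masked_per_window <- function(windows, mask) {
  if (length(mask) == 0) return(integer(nrow(windows)))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  hits <- GenomicRanges::findOverlaps(wgr, mask, ignore.strand = TRUE)
  if (length(hits) == 0) return(integer(nrow(windows)))
  ov <- IRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                            GenomicRanges::granges(mask)[S4Vectors::subjectHits(hits)])
  masked <- integer(nrow(windows))
  agg <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
  masked[as.integer(names(agg))] <- as.integer(agg)
  masked
}

#' Window-by-window diversity scan
#'
#' Classifies every window and computes its diversity statistics. A window is
#' `DISCARDED_LOW_COVERAGE` when its callable fraction falls below the
#' threshold, `INVARIABLE` when covered but without a segregating site (D is
#' then undefined), otherwise `ANALYSED`, with `S`, mean pairwise differences
#' `k_hat`, per-callable-site diversity `pi_site`, per-window Watterson
#' `theta_window` (and auxiliary `theta_site`), and Tajima's D computed from
#' callable, unmasked sites only with `n = strains x ploidy` sequences.
#'
#' @param windows Window table from [partition_genome()].
#' @param variants Variant table from [load_variants()].
#' @param mask Mask from [load_mask()] (may be empty).
#' @param config A [scan_config()].
#' @return The window table extended with `callable_fraction`, `S`, `k_hat`,
#'   `pi_site`, `theta_window`, `theta_site`, `D` (NA when undefined) and
#'   `status`. Attribute `n_seq` records the sample size used.
#' @export
scan_windows <- function(windows, variants, mask, config = scan_config()) {
  strains <- attr(variants, "strains")
  n_seq <- length(strains) * config$ploidy
  if (n_seq < 4) stop("need at least 4 sequences (strains x ploidy)",
                      call. = FALSE)
  if (nrow(variants) > 0) {
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  }

  masked <- .masked_per_window(windows, mask)

  # map variants to windows (windows tile each chromosome, sorted by start)
  win_of <- rep(NA_integer_, nrow(variants))
  if (nrow(variants) > 0) {
    for (ch in unique(windows$chrom)) {
      wi <- which(windows$chrom == ch)
      vi <- which(variants$chrom == ch)
      if (length(vi) == 0) next
      j <- findInterval(variants$pos[vi], windows$start[wi])
      ok <- j >= 1 & variants$pos[vi] <= windows$end[wi[pmax(j, 1)]]
      win_of[vi[ok]] <- wi[j[ok]]
    }
    # variants inside the mask are invisible to the scan
    if (length(mask) > 0) {
      vgr <- GenomicRanges::GRanges(variants$chrom,
                                    IRanges::IRanges(variants$pos,
                                                     variants$pos))
      win_of[IRanges::overlapsAny(vgr, mask, ignore.strand = TRUE)] <-
        NA_integer_
    }
  }

  n <- nrow(windows)
  miss_per_win <- integer(n)
  S <- integer(n)
  k_hat <- numeric(n)
  in_win <- !is.na(win_of)
  if (any(in_win)) {
    miss_idx <- which(in_win & !variants$callable)
    if (length(miss_idx) > 0) {
      tab <- table(win_of[miss_idx])
      miss_per_win[as.integer(names(tab))] <- as.integer(tab)
    }
    call_idx <- which(in_win & variants$callable)
    if (length(call_idx) > 0) {
      cts <- variants$counts[call_idx]
      seg <- vapply(cts, function(x) sum(x > 0) >= 2L, logical(1))
      seg_idx <- call_idx[seg]
      if (length(seg_idx) > 0) {
        het <- vapply(variants$counts[seg_idx],
                      function(x) 1 - sum((x / n_seq)^2), numeric(1)) *
          n_seq / (n_seq - 1)
        for (w in unique(win_of[seg_idx])) {
          sel <- win_of[seg_idx] == w
          S[w] <- sum(sel)
          k_hat[w] <- sum(het[sel])
        }
      }
    }
  }

  callable_len <- windows$length - masked - miss_per_win
  callable_fraction <- callable_len / windows$length
  consts <- tajima_constants(n_seq)
  theta_window <- S / consts$a1
  pi_site <- ifelse(callable_len > 0, k_hat / callable_len, NA_real_)
  theta_site <- ifelse(callable_len > 0, theta_window / callable_len,
                       NA_real_)
  varD <- consts$e1 * S + consts$e2 * S * (S - 1)
  D <- ifelse(S > 0 & varD > 0,
              (k_hat - S / consts$a1) / sqrt(pmax(varD, .Machine$double.xmin)),
              NA_real_)
  status <- ifelse(callable_fraction < config$min_callable_fraction,
                   "DISCARDED_LOW_COVERAGE",
                   ifelse(is.na(D), "INVARIABLE", "ANALYSED"))

  out <- windows
  out$callable_fraction <- callable_fraction
  out$S <- S
  out$k_hat <- k_hat
  out$pi_site <- pi_site
  out$theta_window <- theta_window
  out$theta_site <- theta_site
  out$D <- D
  out$status <- status
  attr(out, "n_seq") <- n_seq
  attr(out, "config") <- config
  out
}

#' Bookkeeping counts of a scan
#'
#' @param stats Output of [scan_windows()].
#' @return Named integer vector: `total`, `discarded`, `invariable`,
#'   `analysed`.
#' @export
scan_counts <- function(stats) {
  c(total = nrow(stats),
    discarded = sum(stats$status == "DISCARDED_LOW_COVERAGE"),
    invariable = sum(stats$status == "INVARIABLE"),
    analysed = sum(stats$status == "ANALYSED"))
}
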