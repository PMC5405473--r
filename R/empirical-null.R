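#' Observed genome-wide distribution of Tajima's D
#'
#' Collects the D values of `ANALYSED` windows (discarded and invariable
#' windows never contribute; trailing partial windows are excluded unless the
#' scan config says otherwise) and summarises them. The theoretical
#' beta-approximation limits for the scan's sample size are attached for
#' comparison.
#'
#' @param stats Window table from [scan_windows()].
#' @param include_partial Override of the scan config's partial-window rule;
#'   `NULL` uses the config.
#' @param coverage Coverage of the theoretical limits (default 0.95).
#' @return Object of class `d_distribution`: list with `values`, `window_id`
#'   (ids of contributing windows), `count`, `mean`, `min`, `max`,
#'   `theoretical` ([beta_confidence_limits()] for the scan's `n`), and
#'   placeholders for the empirical limits filled by [empirical_limits()].
#' @export
build_distribution <- function(stats, include_partial = NULL,
                               coverage = 0.95) {
  if (is.null(include_partial)) {
    cfg <- attr(stats, "config")
    include_partial <- if (is.null(cfg)) FALSE else cfg$include_partial
  }
  keep <- stats$status == "ANALYSED"
  if (!include_partial) keep <- keep & !stats$partial
  values <- stats$D[keep]
  if (length(values) == 0) {
    stop("no analysed windows: cannot build a D distribution", call. = FALSE)
  }
  if (length(values) < 50) {
    warning("only ", length(values), " analysed windows; the empirical ",
            "distribution will be unstable", call. = FALSE)
  }
  n_seq <- attr(stats, "n_seq")
  theo <- if (!is.null(n_seq) && n_seq >= 4) {
    beta_confidence_limits(n_seq, coverage)
  }
  structure(
    list(values = values, window_id = stats$window_id[keep],
         count = length(values), mean = mean(values),
         min = min(values), max = max(values),
         theoretical = theo,
         tail_fraction = NA_real_,
         empirical_lower = NA_real_, empirical_upper = NA_real_,
         achieved_lower_mass = NA_real_, achieved_upper_mass = NA_real_,
         tie_policy = NA_character_),
    class = "d_distribution")
}

# one tail: distinct-value blocks from the extreme inward; "exclude" takes
# the largest prefix of whole blocks with mass <= tail_fraction, "include"
# additionally admits the straddling block
.tail_cut <- function(sorted_desc_counts, total, tail_fraction, ties) {
  mass <- cumsum(sorted_desc_counts) / total
  if (ties == "exclude") {
    k <- sum(mass <= tail_fraction)
  } else {
    k <- if (all(mass < tail_fraction)) length(mass) else
      which(mass >= tail_fraction)[1]
  }
  k
}

#' Empirically corrected confidence limits
#'
#' Percentile-tail device for absorbing genome-wide demographic effects: the
#' most extreme `tail_fraction` of the observed D distribution on each side
#' is flagged as significant, and the limits are the cut D values (the least
#' extreme flagged value per tail). Because windowed D takes discrete values,
#' runs of tied values are included or excluded as whole blocks; with the
#' default conservative policy a tied block that would push the tail past the
#' requested fraction is excluded entirely (the achieved mass is then below
#' the requested one), mirroring a scan forced to choose between the 2nd and
#' 3rd percentile. The permissive policy (`ties = "include"`) admits the
#' straddling block instead.
#'
#' @param dist A `d_distribution` from [build_distribution()].
#' @param tail_fraction Mass per tail (default 0.02).
#' @param ties `"exclude"` (default, conservative) or `"include"`.
#' @return The distribution with `empirical_lower`, `empirical_upper`,
#'   `achieved_lower_mass`, `achieved_upper_mass`, `tail_fraction` and
#'   `tie_policy` filled. When no block fits a tail the limit is `Inf`
#'   (upper) or `-Inf` (lower) and its achieved mass 0.
#' @export
empirical_limits <- function(dist, tail_fraction = 0.02,
                             ties = c("exclude", "include")) {
  ties <- match.arg(ties)
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  v <- sort(dist$values)
  if (length(unique(v)) <= 2) {
    warning("degenerate D distribution (<= 2 distinct values); ",
            "empirical limits undefined", call. = FALSE)
    dist$tail_fraction <- tail_fraction
    dist$tie_policy <- ties
    return(dist)
  }
  m <- length(v)
  lo_rle <- rle(v)                      # ascending: most negative first
  hi_rle <- rle(rev(v))                 # descending: most positive first

  k_lo <- .tail_cut(lo_rle$lengths, m, tail_fraction, ties)
  k_hi <- .tail_cut(hi_rle$lengths, m, tail_fraction, ties)

  dist$empirical_lower <- if (k_lo > 0) lo_rle$values[k_lo] else -Inf
  dist$empirical_upper <- if (k_hi > 0) hi_rle$values[k_hi] else Inf
  dist$achieved_lower_mass <- if (k_lo > 0)
    sum(lo_rle$lengths[seq_len(k_lo)]) / m else 0
  dist$achieved_upper_mass <- if (k_hi > 0)
    sum(hi_rle$lengths[seq_len(k_hi)]) / m else 0
  dist$tail_fraction <- tail_fraction
  dist$tie_policy <- ties
  dist
}

#' Flag significant windows against the empirical limits
#'
#' Adds a `significance` column: `ANALYSED` windows contributing to the
#' distribution with `D >= empirical_upper` become `SIGNIFICANT_POSITIVE`
#' (balancing-selection candidates), those with `D <= empirical_lower`
#' `SIGNIFICANT_NEGATIVE` (sweep candidates); all other windows `NONE`.
#'
#' @param stats Window table from [scan_windows()].
#' @param dist Distribution with limits from [empirical_limits()].
#' @return `stats` with a `significance` column; attribute `sig_counts`
#'   holds the per-class totals.
#' @export
classify_windows <- function(stats, dist) {
  if (is.na(dist$tail_fraction)) {
    stop("empirical limits not set; call empirical_limits() first",
         call. = FALSE)
  }
  sig <- rep("NONE", nrow(stats))
  in_dist <- stats$window_id %in% dist$window_id
  up <- in_dist & !is.na(stats$D) & stats$D >= dist$empirical_upper
  lo <- in_dist & !is.na(stats$D) & stats$D <= dist$empirical_lower
  sig[up] <- "SIGNIFICANT_POSITIVE"
  sig[lo] <- "SIGNIFICANT_NEGATIVE"
  stats$significance <- sig
  attr(stats, "sig_counts") <- c(positive = sum(up), negative = sum(lo))
  stats
}
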