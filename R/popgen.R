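#' Constants for Tajima's D
#'
#' Computes the sample-size-dependent constants `a1, a2, b1, b2, c1, c2, e1,
#' e2` of Tajima's (1989) neutrality test for a sample of `n` sequences.
#' `a1` is the harmonic number used by the Watterson estimator; `e1` and
#' `e2` weight the variance of `k_hat - S/a1`.
#'
#' @param n Integer number of sequences sampled (>= 2).
#' @return An object of class `tajima_constants`: a list with elements
#'   `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @examples
#' tajima_constants(10)$a1  # 2.828968...
#' @export
tajima_constants <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  structure(
    list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
         c1 = c1, c2 = c2, e1 = e1, e2 = e2),
    class = "tajima_constants"
  )
}

#' Mean pairwise differences per window
#'
#' Computes `k_hat`, the average number of nucleotide differences over all
#' `choose(n, 2)` pairs of sequences, from per-site allele counts. The
#' frequency form `(1 - sum(p_a^2)) * n / (n - 1)` summed over sites is used;
#' it is phase-free and identical to the explicit pairwise mean, so unphased
#' diploid genotypes are valid input. Multi-allelic sites are handled by the
#' generalized heterozygosity.
#'
#' @param sites List of integer vectors, one per callable site, each giving
#'   the count of every observed allele among the `n` sequences. Monomorphic
#'   sites (a single positive count) contribute zero and may be omitted.
#' @param n Number of sequences; every site's counts must sum to `n`.
#' @return `k_hat`, a non-negative real.
#' @export
mean_pairwise_differences <- function(sites, n) {
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (length(sites) == 0L) return(0)
  sums <- vapply(sites, sum, numeric(1))
  if (any(sums != n)) {
    stop("allele counts at ", sum(sums != n),
         " site(s) do not sum to n = ", n, call. = FALSE)
  }
  het <- vapply(sites, function(cnt) 1 - sum((cnt / n)^2), numeric(1))
  sum(het) * n / (n - 1)
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_w = S / a1(n)`, reported on the same scale as `S` (per window when
#' `S` counts a window's segregating sites).
#'
#' @param S Non-negative integer count of segregating sites.
#' @param n Number of sequences (>= 2).
#' @return `theta_w`.
#' @export
watterson_theta <- function(S, n) {
  if (any(S < 0)) stop("`S` must be non-negative", call. = FALSE)
  S / tajima_constants(n)$a1
}

#' Tajima's D
#'
#' `D = (k_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))`. When `S = 0` the statistic
#' is undefined (no variation, zero variance) and `NA` is returned with a
#' `reason` attribute `"no_variation"`. Should the variance term be zero with
#' `S > 0` (impossible for `n >= 4`), `NA` with reason `"zero_variance"` is
#' returned rather than an infinity.
#'
#' @param S Segregating-site count of the window.
#' @param k_hat Mean pairwise differences of the same window.
#' @param n Number of sequences.
#' @return `D`, or `NA` with attribute `reason` when undefined.
#' @export
tajimas_d <- function(S, k_hat, n) {
  k <- tajima_constants(n)
  if (S == 0) {
    return(structure(NA_real_, reason = "no_variation"))
  }
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) {
    return(structure(NA_real_, reason = "zero_variance"))
  }
  (k_hat - S / k$a1) / sqrt(v)
}

#' Theoretical confidence limits for Tajima's D (beta approximation)
#'
#' Under neutrality Tajima (1989) approximates the distribution of D by a
#' rescaled beta density on the support `[Dmin, Dmax]`, with shape parameters
#' chosen so the density has mean 0 and variance 1:
#' `Dmin = (2/n - 1/a1)/sqrt(e2)` (all variants singletons),
#' `Dmax = (n/(2(n-1)) - 1/a1)/sqrt(e2)` (all variants at frequency 1/2),
#' `alpha = -(1 + Dmin*Dmax) * Dmax / (Dmax - Dmin)`,
#' `beta  =  (1 + Dmin*Dmax) * Dmin / (Dmax - Dmin)`.
#' With `U ~ Beta(alpha, beta)`, `D = Dmax - (Dmax - Dmin) * U`; confidence
#' limits are the matching beta quantiles.
#'
#' @param n Number of sequences (>= 4 so that the variance constants are
#'   positive).
#' @param coverage Central coverage of the interval (default 0.95).
#' @return An object of class `beta_approx_limits`: list with `n`, `Dmin`,
#'   `Dmax`, `alpha`, `beta_shape`, `coverage`, `lower`, `upper`.
#' @examples
#' lim <- beta_confidence_limits(10)
#' round(c(lim$lower, lim$upper), 3)  # -1.733  1.975
#' @export
beta_confidence_limits <- function(n, coverage = 0.95) {
  if (n < 4L) stop("`n` must be >= 4 for the beta approximation", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must be in (0, 1)", call. = FALSE)
  }
  k <- tajima_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / k$a1) / sqrt(k$e2)
  ab <- dmin * dmax
  alpha <- -(1 + ab) * dmax / (dmax - dmin)
  beta_shape <- (1 + ab) * dmin / (dmax - dmin)
  if (alpha <= 0 || beta_shape <= 0) {
    stop("beta shape parameters non-positive; approximation invalid for n = ",
         n, call. = FALSE)
  }
  tail <- (1 - coverage) / 2
  lower <- dmax - (dmax - dmin) * stats::qbeta(1 - tail, alpha, beta_shape)
  upper <- dmax - (dmax - dmin) * stats::qbeta(tail, alpha, beta_shape)
  structure(
    list(n = as.integer(n), Dmin = dmin, Dmax = dmax,
         alpha = alpha, beta_shape = beta_shape,
         coverage = coverage, lower = lower, upper = upper),
    class = "beta_approx_limits"
  )
}

#' Density of the beta approximation to Tajima's D
#'
#' Helper used when checking that the fitted density on `[Dmin, Dmax]` has
#' mean 0 and variance 1, and for plotting against observed distributions.
#'
#' @param x Vector of D values.
#' @param limits A `beta_approx_limits` object.
#' @return Density values.
#' @export
dtajima_beta <- function(x, limits) {
  width <- limits$Dmax - limits$Dmin
  u <- (limits$Dmax - x) / width
  stats::dbeta(u, limits$alpha, limits$beta_shape) / width
}
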