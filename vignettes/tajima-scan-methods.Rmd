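---
title: "Methods: windowed Tajima's D scans with empirically corrected confidence limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed Tajima's D scans with empirically corrected confidence limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`tajscan` scans multi-strain resequencing data of a single species for
genomic signatures of selection. The unit of analysis is a non-overlapping
1,000-bp window. Within a window with `S` segregating sites among `n`
sampled sequences, two estimators of the population mutation rate
`theta = 4*N*mu` are compared:

* Watterson's estimator `theta_W = S / a1(n)`, with
  `a1(n) = sum(1/i, i = 1..n-1)`, driven by the *number* of variable sites;
* the mean pairwise difference `k_hat` (nucleotide diversity when divided by
  the callable length), driven by the *frequencies* of the variants.

Tajima's D is their standardized difference,

```
D = (k_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))
```

with `e1`, `e2` the variance constants of Tajima (1989). Under neutrality
`E[D]` is near zero. An excess of intermediate-frequency variants —
the footprint of balancing selection, as expected under host–parasite
"trench warfare" dynamics — pushes D positive; an excess of rare variants
after a selective sweep pushes it negative.

All three statistics are computed from per-site allele counts, never from
phased haplotypes: they are functions of allele frequencies only, so
unphased diploid genotypes are valid input. This matters because the strains
are sequenced as diploid isolates without phasing. Multi-allelic SNVs enter
through the generalized heterozygosity `1 - sum(p_a^2)`; indels are excluded
by default because the upstream variant calling the scan expects is
SNV-oriented.

### Sample size

Five diploid strains are treated as `n = 10` sequences, not 5. The
theoretical 95% limits for `n = 10` are (−1.733, 1.975); for `n = 5` they
would differ. Since the published limits match the `n = 10` values, the
diploid reading is the one the package defaults to (`ploidy = 2` in
`scan_config()`).

## Window filtering

* Windows with less than 90% callable sequence are discarded
  (`min_callable_fraction = 0.9`). Callable means: not covered by the BED
  mask (repeats, low coverage) and not a site where any strain has a missing
  genotype — a completeness requirement across all samples.
* Covered windows without a segregating site are `INVARIABLE`; `D` is
  undefined there (the variance is zero) and they never enter the D
  distribution.
* A trailing partial window at a chromosome end is computed and reported but
  excluded from the distribution by default, because unequal window lengths
  distort `S`-based statistics (`include_partial` in `scan_config()`
  overrides this).
* `pi_site` divides `k_hat` by the window's *callable* length, not the
  nominal window size, so partially masked windows are not artificially
  deflated. Watterson's theta is reported per window (`theta_window`), with
  a per-callable-site version (`theta_site`) as an auxiliary column — the
  two normalizations differ by roughly three orders of magnitude at 1-kb
  windows, and published per-window summaries are on the window scale.

## Confidence limits for D

Two sets of limits are reported side by side.

**Theoretical (beta approximation).** Tajima (1989) approximates the null
distribution of D by a rescaled beta density on `[Dmin, Dmax]`, where
`Dmin = (2/n - 1/a1)/sqrt(e2)` (every variant a singleton) and
`Dmax = (n/(2(n-1)) - 1/a1)/sqrt(e2)` (every variant at frequency 1/2), with
shape parameters fixed by requiring mean 0 and variance 1. Quantiles come
from `stats::qbeta` (numerical inversion of the regularized incomplete beta
function). The construction constraints are verified numerically to 1e−6 in
the test suite.

**Empirical (percentile tails).** Demographic processes (bottlenecks,
expansion) shift D genome-wide, while selection acts locally. The corrected
limits are therefore taken from the observed genome-wide distribution
itself: the most extreme 2% of values on each tail (`tail_fraction = 0.02`)
are flagged as candidates, and the limits are the least extreme flagged
values. Windowed D is discrete — many windows share exactly the same
`(S, k_hat)` pair — so tied runs must be handled as blocks. The default
policy is conservative: a tied block that would push a tail past the
requested mass is excluded entirely, so the achieved mass is recorded and
never exceeds the request. The permissive alternative (`ties = "include"`)
admits the straddling block. Both are exposed because with discrete D
values the achievable percentile jumps (a scan can face a choice between a
2nd and a 3rd percentile); the conservative choice matches flagged counts
that stay under the ceiling.

## Gene mapping

A gene is *analysed* when more than 50% of its length is covered by analysed
windows — this is the denominator rule. An analysed gene is *significant*
when it overlaps at least one significant window by any amount; requiring
50% overlap with significant windows specifically would conflate the
denominator rule with the hit rule and systematically miss genes straddling
a single extreme window. Genes overlapping both a positive and a negative
significant window take the sign of the window with the largest |D| (a tie
resolves to positive); such conflicts are rare and logged in the
`sign_conflicts` attribute, so each gene is counted exactly once and the
positive and negative gene counts add up to the significant total.

## Contrast statistics

Between-scan comparisons use K-S and Wilcoxon rank-sum on the D values,
pooled-variance Student t on per-window theta, and a Pearson chi-square on
invariable-window proportions. Two conventions were fixed by checking them
against published values reproducible from printed counts:

* chi-square **without** Yates continuity correction (the corrected version
  does not reproduce the printed statistics);
* two-sided Fisher exact p by **probability summation** (sum of
  hypergeometric point probabilities no larger than the observed table's),
  which reproduces all six printed p-values to 1e−4; the doubled-one-tail
  convention is available behind a flag.

These standard tests are delegated to base R (`chisq.test`, `fisher.test`,
`ks.test`, `wilcox.test`, `t.test`); the suite checks them against
independent oracles (hand formulas and exhaustive hypergeometric
enumeration) rather than trusting either route alone.

## The synthetic-data generator

Real strain resequencing data cannot ship with the package, so every stage
is exercised against coalescent simulations with known truth.

* **Neutral windows**: a Kingman coalescent over `n` lineages (waiting times
  `Exp(k(k-1)/2)` in units of 2N generations), with mutations dropped as a
  Poisson process of rate `theta/2` per unit branch length under the
  infinite-sites model. This gives the textbook identities `E[S] = theta*a1`
  and `E[k_hat] = theta` per window, which the tests verify within 3% and
  which make `theta_per_window = 5` reproduce the scale of the published
  per-window theta average (≈ 5.4).
* **Balancing windows**: a neutral genealogy whose two root-adjacent
  branches are stretched (default ×5). An anciently balanced split deepens
  the root and loads variants at intermediate frequency — the positive-D
  signature — while keeping an analytic handle on the tree. No
  frequency-dependent forward simulation is attempted.
* **Sweep windows**: a star genealogy (all lineages coalescing at depth
  `1 - 1/n`, half the expected neutral tree height), so every variant is a
  singleton and D approaches its lower bound as S grows.

Windows are independent (free recombination between windows, none within),
which matches the independence the windowed scan itself implicitly assumes.
Diploid genotypes pair consecutive haplotypes within each strain, with no
inbreeding structure. The generator writes standard formats (FASTA with a
`.fai` index, VCF 4.2 with per-strain `GT`, BED mask of random 100–500-bp
blocks, GFF3 genes of 500–3,000 bp placed without overlap) plus truth
tables, and is byte-reproducible from its seed.

What the simulations do **not** emulate: the real strains' relatedness
structure and population history, within-window recombination, sequencing
error, and reference bias. Passing the calibration and recovery tests
therefore shows the estimators and the percentile device behave correctly
under the stated model, not that the model captures every property of real
resequencing data.

### Default study conditions

| parameter | default | why |
|---|---|---|
| strains × ploidy | 5 × 2 (n = 10) | matches the published theoretical limits |
| window size | 1,000 bp | the scan's window size |
| min callable fraction | 0.90 | the coverage filter |
| theta per window | 5 | scale of the published per-window theta average |
| tail fraction | 0.02 per tail | the percentile the discrete distribution allowed |
| masked fraction | 0.05 | a modest repeat/low-coverage load |
| balancing stretch | 5 | separates regimes clearly at theta = 5 |
| gene coverage rule | > 0.5 | the analysed-gene denominator rule |

## Numerical choices and degenerate inputs

* `S = 0` gives `D = NA` with reason `no_variation`; a hypothetical
  zero-variance case with `S > 0` (impossible for `n >= 4`) would give `NA`
  with reason `zero_variance` rather than ±Inf, so non-finite values never
  enter the distribution.
* When no tied block fits a tail, the empirical limit is ±Inf, the achieved
  mass 0 and nothing is flagged on that side.
* A distribution with ≤ 2 distinct values leaves the limits undefined with a
  warning.
* If neither scan in a comparison has invariable windows the
  invariable-proportion chi-square is degenerate; equal proportions are
  reported as statistic 0 with an explanatory method label instead of an
  error.
* Internally all intervals are held as Bioconductor `GRanges`/`IRanges`
  (1-based, closed); BED (0-based half-open) and GFF3 (1-based inclusive)
  are converted at the boundary, and the conversions are covered by
  per-base-oracle tests.

## Problem sizes used by the tests

The suite calibrates the neutral generator on 5,000 windows (and two
independent 2,000-window replicates), checks regime separation on 600
windows per regime, runs the end-to-end recovery on a 2,000-window bundle
with 10% planted balancing windows, and verifies the Fisher implementation
exhaustively for every table with total ≤ 25 plus 1,000 random tables with
totals up to 200. These sizes keep the full suite to a few minutes on one
CPU while leaving Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The percentile device fixes the flagged fraction per tail by design, so
  the *proportion* of significant windows carries no information between
  scans; only the distribution's shape and the identity of the flagged
  windows do. This is inherent to the method, not an implementation limit.
* Published window totals from real assemblies depend on assembly details
  (e.g. whether trailing partial windows were counted) that cannot be
  recovered without the data; the package exposes both choices.
* The exact tie policy behind published flagged counts is likewise not
  recoverable; both policies are implemented and reported.
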