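#!/usr/bin/env Rscript
# Step 1: simulate the two study genomes.
#
# Bundle A emulates a pathogen-like genome in which a tenth of the windows
# evolve under balancing selection (host-parasite trench warfare keeps
# alleles at intermediate frequency) and a small fraction under sweeps;
# bundle B is an entirely neutral relative. Both use five diploid strains
# (n = 10 sequences), 1-kb windows at theta = 5 per window and 5% of the
# genome masked — the scale of the real scans.

suppressMessages(library(tajscan))

spec_a <- sim_spec(contig_lengths = c(1e6, 1e6),
                   regime_probs = c(NEUTRAL = 0.88, BALANCING = 0.10,
                                    SWEEP = 0.02),
                   n_genes = 600, seed = 20260901)
spec_b <- sim_spec(contig_lengths = c(1e6, 1e6),
                   regime_probs = c(NEUTRAL = 1),
                   n_genes = 600, seed = 20260902)

a <- emit_genome_bundle(spec_a, "results/bundle_A")
b <- emit_genome_bundle(spec_b, "results/bundle_B")

for (x in list(a, b)) {
  tw <- x$truth$windows
  cat(sprintf("%s: %d windows (%s), %d mutations, %d genes\n",
              x$dir, nrow(tw),
              paste(sprintf("%s=%d", names(table(tw$regime)),
                            table(tw$regime)), collapse = ", "),
              sum(tw$n_mutations), nrow(x$truth$genes)))
}
cat("bundles written under results/bundle_A and results/bundle_B\n")
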