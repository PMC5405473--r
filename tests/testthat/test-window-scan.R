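test_that("genome partitioning tiles chromosomes with a trailing partial", {
  cfg <- scan_config()
  idx <- data.frame(chrom = "chr1", length = 10000L)
  w <- partition_genome(idx, cfg)
  expect_equal(nrow(w), 10)
  expect_false(any(w$partial))
  expect_equal(w$start, seq(1, 9001, by = 1000))

  idx2 <- data.frame(chrom = "chr1", length = 10500L)
  w2 <- partition_genome(idx2, cfg)
  expect_equal(nrow(w2), 11)
  expect_equal(sum(w2$partial), 1)
  expect_equal(w2$length[11], 500)

  # window count over a multi-contig index is sum of ceilings
  idx3 <- data.frame(chrom = c("a", "b", "c"),
                     length = c(5000L, 7499L, 1L))
  expect_equal(nrow(partition_genome(idx3, cfg)),
               sum(ceiling(idx3$length / 1000)))
})

test_that("callable fraction combines mask and missing-genotype sites", {
  idx <- data.frame(chrom = "chr1", length = 10000L)
  win <- list(chrom = "chr1", start = 1L, end = 1000L, length = 1000L)
  empty_mask <- load_mask(NULL, load_reference_index(
    write_fai_fixture(10000L, "chr1")))
  expect_equal(window_callable_fraction(win, empty_mask), 1.0)

  mask <- load_mask(write_bed_fixture(
    data.frame(chrom = "chr1", start = 100L, end = 250L)),
    load_reference_index(write_fai_fixture(10000L, "chr1")))
  expect_equal(window_callable_fraction(win, mask), 0.85)
  expect_true(0.85 < scan_config()$min_callable_fraction)

  # a missing site inside the mask is not double-subtracted
  miss <- data.frame(chrom = "chr1", pos = c(150L, 500L))
  expect_equal(window_callable_fraction(win, mask, miss), 0.849)

  # random masks vs the per-base oracle
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(1:8, 1)
    s0 <- sample(0:900, k)
    e0 <- pmin(s0 + sample(20:200, k, replace = TRUE), 1000L)
    m <- load_mask(write_bed_fixture(data.frame("chr1", s0, e0)),
                   load_reference_index(write_fai_fixture(10000L, "chr1")))
    expect_equal(window_callable_fraction(win, m) * 1000,
                 oracle_callable_bases(1, 1000, s0, e0))
  }
})

test_that("scan classifies windows and computes diversity on callable sites", {
  idx <- load_reference_index(write_fai_fixture(10000L, "chr1"))
  strains <- c("s1", "s2", "s3", "s4", "s5")
  # variants only in window 3 (positions 2001..3000)
  rec <- data.frame(chrom = "chr1", pos = c(2100L, 2200L, 2300L),
                    ref = "A", alt = "G", filter = "PASS",
                    s1 = c("0/1", "0/0", "0/1"),
                    s2 = c("0/0", "0/1", "0/1"),
                    s3 = c("0/0", "0/0", "0/1"),
                    s4 = c("0/0", "0/1", "0/0"),
                    s5 = c("0/0", "0/0", "0/0"),
                    stringsAsFactors = FALSE)
  vcf <- write_vcf_fixture(rec, strains,
                           contigs = data.frame(chrom = "chr1",
                                                length = 10000L))
  v <- load_variants(vcf, strains)
  mask <- load_mask(NULL, idx)
  stats <- scan_windows(partition_genome(idx), v, mask)

  expect_equal(sum(stats$status == "ANALYSED"), 1)
  expect_equal(sum(stats$status == "INVARIABLE"), 9)
  expect_equal(stats$S[3], 3)
  # derived counts 1, 2, 3 out of n = 10
  k_expected <- sum(2 * (c(1, 2, 3) / 10) * (1 - c(1, 2, 3) / 10)) * 10 / 9
  expect_equal(stats$k_hat[3], k_expected, tolerance = 1e-12)
  expect_equal(stats$pi_site[3], k_expected / 1000, tolerance = 1e-12)
  expect_equal(stats$theta_window[3], 3 / tajima_constants(10)$a1,
               tolerance = 1e-12)
  expect_equal(stats$D[3],
               as.numeric(tajimas_d(3, k_expected, 10)), tolerance = 1e-12)

  # count conservation
  cnt <- scan_counts(stats)
  expect_equal(unname(cnt["total"]),
               unname(cnt["discarded"] + cnt["invariable"] + cnt["analysed"]))

  # a site in a masked region is invisible and lowers callable length
  mask2 <- load_mask(write_bed_fixture(
    data.frame(chrom = "chr1", start = 2050L, end = 2150L)), idx)
  stats2 <- scan_windows(partition_genome(idx), v, mask2)
  expect_equal(stats2$S[3], 2)
  expect_equal(stats2$callable_fraction[3], 0.9)
})

test_that("scan is invariant to variant order, strain order and coordinate shift", {
  set.seed(41)
  spec <- sim_spec(contig_lengths = 30000L, masked_fraction = 0, seed = 7)
  b <- emit_genome_bundle(spec, file.path(tempdir(), "inv_bundle"))
  idx <- load_reference_index(b$paths$fai)
  mask <- load_mask(NULL, idx)
  v <- load_variants(b$paths$vcf, b$strains)
  base <- scan_windows(partition_genome(idx), v, mask)

  # shuffled variant rows
  shuf <- v[sample(nrow(v)), , drop = FALSE]
  for (a in c("strains", "ploidy", "n_seq")) attr(shuf, a) <- attr(v, a)
  again <- scan_windows(partition_genome(idx), shuf, mask)
  expect_equal(again$D, base$D)

  # reversed strain order
  v2 <- load_variants(b$paths$vcf, rev(b$strains))
  expect_equal(scan_windows(partition_genome(idx), v2, mask)$D, base$D)

  # shifting all coordinates by one window leaves the D multiset unchanged
  vcf_lines <- readLines(b$paths$vcf)
  is_rec <- !grepl("^#", vcf_lines)
  parts <- strsplit(vcf_lines[is_rec], "\t")
  shifted <- vapply(parts, function(p) {
    p[2] <- as.character(as.integer(p[2]) + 1000L)
    paste(p, collapse = "\t")
  }, character(1))
  hdr <- sub("length=30000", "length=31000",
             vcf_lines[!is_rec])
  vcf3 <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, shifted), vcf3)
  idx3 <- load_reference_index(write_fai_fixture(31000L, "contig01"))
  v3 <- load_variants(vcf3, b$strains)
  stats3 <- scan_windows(partition_genome(idx3), v3, load_mask(NULL, idx3))
  expect_equal(sort(stats3$D[!is.na(stats3$D)]),
               sort(base$D[!is.na(base$D)]))
})
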