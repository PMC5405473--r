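test_that("reference index loads in file order and validates", {
  fai <- write_fai_fixture(c(10000L, 3500L), c("ctgA", "ctgB"))
  idx <- load_reference_index(fai)
  expect_equal(idx$chrom, c("ctgA", "ctgB"))
  expect_equal(sum(idx$length), 13500)

  empty <- tempfile()
  file.create(empty)
  expect_warning(idx0 <- load_reference_index(empty), "empty")
  expect_equal(nrow(idx0), 0)

  dup <- write_fai_fixture(c(100L, 200L), c("ctgA", "ctgA"))
  expect_error(load_reference_index(dup), "duplicate")
})

test_that("mask loading merges, clips and validates intervals", {
  idx <- load_reference_index(write_fai_fixture(1000L, "chr1"))

  bed <- write_bed_fixture(data.frame(chrom = "chr1",
                                      start = c(100L, 150L),
                                      end = c(200L, 300L)))
  m <- load_mask(bed, idx)
  expect_equal(length(m), 1)
  expect_equal(IRanges::start(m), 101)  # 0-based half-open -> 1-based closed
  expect_equal(IRanges::end(m), 300)

  expect_equal(length(load_mask(NULL, idx)), 0)
  expect_equal(length(load_mask(write_bed_fixture(data.frame()[0, ]), idx)), 0)

  expect_warning(
    m2 <- load_mask(write_bed_fixture(
      data.frame(chrom = c("chr1", "chrX"), start = c(0L, 0L),
                 end = c(50L, 50L))), idx),
    "absent")
  expect_equal(length(m2), 1)

  expect_warning(
    m3 <- load_mask(write_bed_fixture(
      data.frame(chrom = "chr1", start = c(10L, 60L), end = c(5L, 80L))),
      idx),
    "start >= end")
  expect_equal(sum(IRanges::width(m3)), 20)

  # clipping to chromosome bounds
  m4 <- load_mask(write_bed_fixture(
    data.frame(chrom = "chr1", start = 900L, end = 5000L)), idx)
  expect_equal(IRanges::end(m4), 1000)
})

test_that("mask callable length agrees with the per-base oracle", {
  set.seed(7)
  idx <- load_reference_index(write_fai_fixture(2000L, "chr1"))
  for (rep in 1:10) {
    k <- sample(1:15, 1)
    s0 <- sort(sample(0:1900, k))
    e0 <- pmin(s0 + sample(10:300, k, replace = TRUE), 2000L)
    m <- load_mask(write_bed_fixture(data.frame("chr1", s0, e0)), idx)
    callable <- 2000 - sum(IRanges::width(m))
    expect_equal(callable, oracle_callable_bases(1, 2000, s0, e0))
  }
})

test_that("variant loading parses genotypes, filters and flags missingness", {
  strains <- c("s1", "s2")
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                    ref = c("A", "C", "G", "AT", "T"),
                    alt = c("G", "T", "A,T", "A", "C"),
                    filter = c("PASS", ".", "PASS", "PASS", "LowQual"),
                    s1 = c("0/1", "./.", "1/2", "0/1", "0/1"),
                    s2 = c("0/0", "0/1", "0/0", "0/0", "1/1"),
                    stringsAsFactors = FALSE)
  vcf <- write_vcf_fixture(rec, strains)
  v <- suppressMessages(load_variants(vcf, strains))

  # indel (pos 40) and non-PASS (pos 50) dropped
  expect_equal(v$pos, c(10L, 20L, 30L))
  expect_equal(attr(v, "n_seq"), 4)

  # 0/1 + 0/0 -> 3 ref, 1 alt
  expect_equal(v$counts[[1]], c(3L, 1L))
  expect_true(v$callable[1])

  # any missing genotype -> uncallable
  expect_false(v$callable[2])

  # multi-allelic retained with all alternates: 1/2 + 0/0
  expect_equal(v$counts[[3]], c(2L, 1L, 1L))

  # filtered records kept on request
  v2 <- suppressMessages(load_variants(vcf, strains, keep_filtered = TRUE))
  expect_equal(v2$pos, c(10L, 20L, 30L, 50L))

  expect_error(load_variants(vcf, c("s1", "nope")), "not in VCF header")
})

test_that("gene models convert GFF3 coordinates and filter by feature type", {
  idx <- load_reference_index(write_fai_fixture(100000L, "chr1"))
  gff <- write_gff_fixture(c(
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=gA.t1",
    "chr1\tsrc\tgene\t2001\t2500\t.\t-\t.\tID=gB"))
  g <- load_genes(gff, idx)
  expect_equal(S4Vectors::mcols(g)$gene_id, c("gA", "gB"))
  expect_equal(IRanges::width(g)[1], 1000)  # 1..1000 inclusive
  expect_equal(as.character(GenomicRanges::strand(g)), c("+", "-"))

  expect_warning(
    g0 <- load_genes(write_gff_fixture(
      "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1"), idx),
    "no features of type 'gene'")
  expect_equal(length(g0), 0)

  expect_warning(
    g1 <- load_genes(write_gff_fixture(c(
      "chr1\tsrc\tgene\t100\t50\t.\t+\t.\tID=bad",
      "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=ok")), idx),
    "end < start")
  expect_equal(S4Vectors::mcols(g1)$gene_id, "ok")
})

test_that("synthetic bundle round-trips through the readers", {
  spec <- sim_spec(contig_lengths = c(20000L, 10000L), n_genes = 15,
                   masked_fraction = 0.05, seed = 99)
  b <- emit_genome_bundle(spec, file.path(tempdir(), "rt_bundle"))

  idx <- load_reference_index(b$paths$fai)
  expect_equal(idx$length, spec$contig_lengths)

  # index regenerated from the FASTA matches the emitted one
  fa <- readLines(b$paths$fasta)
  seq_len_fa <- tapply(nchar(fa), cumsum(grepl("^>", fa)), function(x)
    sum(x) - x[1])
  expect_equal(unname(as.integer(seq_len_fa)), idx$length)

  v <- load_variants(b$paths$vcf, b$strains)
  expect_equal(nrow(v), sum(b$truth$windows$n_mutations))
  expect_true(all(v$callable))

  g <- load_genes(b$paths$gff3, idx)
  expect_equal(length(g), nrow(b$truth$genes))
  expect_equal(S4Vectors::mcols(g)$gene_id, b$truth$genes$gene_id)

  m <- load_mask(b$paths$mask, idx)
  masked <- sum(IRanges::width(m))
  expect_gte(masked, 0.05 * sum(spec$contig_lengths) * 0.9)

  # haplotype-map-like export round-trips
  tsv <- tempfile(fileext = ".tsv")
  export_variant_table(v, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(v))
  expect_equal(back$pos, v$pos)
})
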