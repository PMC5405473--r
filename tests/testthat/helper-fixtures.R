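# tiny plain-text fixtures built in code at test time

write_fai_fixture <- function(lengths, names = sprintf("chr%d", seq_along(lengths)),
                              path = tempfile(fileext = ".fai")) {
  writeLines(sprintf("%s\t%d\t%d\t70\t71", names, lengths,
                     seq_along(lengths) * 100L), path)
  path
}

write_bed_fixture <- function(df, path = tempfile(fileext = ".bed")) {
  if (nrow(df) == 0) file.create(path) else
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  path
}

write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# minimal VCF with `strains` diploid samples; records = data.frame with
# chrom, pos, ref, alt, filter and one genotype string column per strain
write_vcf_fixture <- function(records, strains,
                              contigs = data.frame(chrom = "chr1",
                                                   length = 100000L),
                              path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", records$filter[i], ".", "GT",
            unlist(records[i, strains])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# a small scanned-window table with chosen statuses and D values, shaped like
# scan_windows() output
fake_window_stats <- function(D, status = NULL, chrom = "chr1",
                              window_size = 1000L, partial = FALSE,
                              n_seq = 10L) {
  n <- length(D)
  if (is.null(status)) status <- ifelse(is.na(D), "INVARIABLE", "ANALYSED")
  out <- data.frame(
    window_id = seq_len(n), chrom = chrom,
    start = (seq_len(n) - 1L) * window_size + 1L,
    end = seq_len(n) * window_size,
    length = window_size, partial = partial,
    callable_fraction = 1, S = ifelse(is.na(D), 0L, 5L),
    k_hat = 0, pi_site = 0, theta_window = 0, theta_site = 0,
    D = D, status = status, stringsAsFactors = FALSE)
  attr(out, "n_seq") <- n_seq
  attr(out, "config") <- scan_config()
  out
}
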