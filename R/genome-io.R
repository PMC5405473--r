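#' Load a reference sequence index
#'
#' Reads a samtools `.fai`-style index (tab-separated; first two columns are
#' sequence name and length) into an ordered chromosome table. Order follows
#' the file.
#'
#' @param path Path to the index file.
#' @return A data.frame with columns `chrom` (character) and `length`
#'   (integer bp), in file order.
#' @export
load_reference_index <- function(path) {
  if (file.size(path) == 0) {
    warning("empty reference index: ", path, call. = FALSE)
    return(data.frame(chrom = character(), length = integer()))
  }
  fai <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  idx <- data.frame(chrom = as.character(fai[[1]]),
                    length = as.integer(fai[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(idx$chrom)) {
    stop("duplicate sequence names in index: ",
         paste(unique(idx$chrom[duplicated(idx$chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(idx$length <= 0)) {
    stop("non-positive sequence length in index", call. = FALSE)
  }
  idx
}

#' Load an uncallable-region mask from BED
#'
#' BED intervals (0-based, half-open) flag regions to exclude from the scan
#' (repeats, low coverage). Overlapping or bookended intervals are merged and
#' intervals are clipped to chromosome bounds. Records on chromosomes absent
#' from the index are skipped with a warning; records with `start >= end`
#' are rejected.
#'
#' @param path Path to a BED file (>= 3 columns), or `NULL` for an empty
#'   mask.
#' @param index Reference index from [load_reference_index()].
#' @return A [GenomicRanges::GRanges] of merged uncallable intervals
#'   (1-based, closed, the Bioconductor convention).
#' @export
load_mask <- function(path, index) {
  empty <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    seqlengths = stats::setNames(index$length, index$chrom))
  if (is.null(path) || file.size(path) == 0) return(empty)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  chrom <- as.character(bed[[1]])
  start0 <- as.numeric(bed[[2]])
  end0 <- as.numeric(bed[[3]])
  bad <- start0 >= end0
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end rejected",
            call. = FALSE)
    chrom <- chrom[!bad]; start0 <- start0[!bad]; end0 <- end0[!bad]
  }
  unknown <- !(chrom %in% index$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " BED record(s) on chromosomes ",
            "absent from the index: ",
            paste(unique(chrom[unknown]), collapse = ", "), call. = FALSE)
    chrom <- chrom[!unknown]; start0 <- start0[!unknown]; end0 <- end0[!unknown]
  }
  if (length(chrom) == 0) return(empty)
  len <- index$length[match(chrom, index$chrom)]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pmax(start0 + 1, 1),
                              end = pmin(end0, len)),
    seqlengths = stats::setNames(index$length, index$chrom))
  GenomicRanges::reduce(gr)
}

#' Load multi-sample variants from a VCF
#'
#' Restricts records to the requested strains (all must be present in the
#' header), keeps SNVs only by default (single-base REF and ALT; indels and
#' symbolic alleles dropped), drops records failing FILTER (anything other
#' than `PASS` or `.`) unless `keep_filtered = TRUE`, and keeps multi-allelic
#' SNVs with all alternate alleles. A site with any missing genotype call
#' among the strains is marked uncallable.
#'
#' @param path Path to a VCF (v4.x, GT field required; plain text or gzip).
#' @param strains Character vector of sample names, in the order wanted.
#'   `NULL` takes all samples in header order.
#' @param keep_filtered Keep records failing FILTER? Default `FALSE`.
#' @param snv_only Drop indels and symbolic alleles? Default `TRUE`.
#' @return A data.frame, one row per retained site: `chrom`, `pos` (1-based),
#'   `ref`, `alt` (comma-joined), `callable` (no missing genotype), a
#'   list-column `counts` (integer allele counts over the `n = strains x
#'   ploidy` sequences; `ref` is allele 1), and one genotype column per
#'   strain. Attributes `strains`, `ploidy` and `n_seq` record the sample
#'   structure.
#' @export
load_variants <- function(path, strains = NULL, keep_filtered = FALSE,
                          snv_only = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  header_samples <- colnames(vcf@gt)[-1]
  if (is.null(strains)) strains <- header_samples
  missing_strains <- setdiff(strains, header_samples)
  if (length(missing_strains) > 0) {
    stop("strain(s) not in VCF header: ",
         paste(missing_strains, collapse = ", "), call. = FALSE)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- gt[, strains, drop = FALSE]

  keep <- rep(TRUE, nrow(fix))
  if (!keep_filtered) {
    filt <- fix$FILTER
    keep <- keep & (is.na(filt) | filt == "." | filt == "PASS")
  }
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  if (snv_only) {
    is_snv <- vapply(seq_len(nrow(fix)), function(i) {
      ref <- fix$REF[i]; alts <- alt_list[[i]]
      nchar(ref) == 1L && ref %in% c("A", "C", "G", "T") &&
        length(alts) > 0 && all(nchar(alts) == 1L) &&
        all(alts %in% c("A", "C", "G", "T"))
    }, logical(1))
    dropped <- keep & !is_snv
    if (any(dropped)) {
      message("dropped ", sum(dropped), " non-SNV record(s)")
    }
    keep <- keep & is_snv
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  alt_list <- alt_list[keep]

  n_sites <- nrow(fix)
  ploidy <- 2L
  if (n_sites > 0) {
    first_gt <- gt[!is.na(gt)][1]
    if (!is.na(first_gt)) {
      ploidy <- length(strsplit(first_gt, "[/|]")[[1]])
    }
  }
  n_seq <- length(strains) * ploidy

  counts <- vector("list", n_sites)
  callable <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    n_alleles <- 1L + length(alt_list[[i]])
    alleles <- unlist(strsplit(gt[i, ], "[/|]"))
    idx <- suppressWarnings(as.integer(alleles))
    if (length(idx) != n_seq || anyNA(idx) || any(idx < 0) ||
        any(idx >= n_alleles)) {
      callable[i] <- FALSE
      counts[[i]] <- rep(NA_integer_, n_alleles)
    } else {
      callable[i] <- TRUE
      counts[[i]] <- tabulate(idx + 1L, nbins = n_alleles)
    }
  }

  out <- data.frame(chrom = as.character(fix$CHROM),
                    pos = as.integer(fix$POS),
                    ref = as.character(fix$REF),
                    alt = vapply(alt_list, paste, character(1), collapse = ","),
                    callable = callable,
                    stringsAsFactors = FALSE)
  out$counts <- counts
  for (s in strains) out[[s]] <- unname(gt[, s])
  attr(out, "strains") <- strains
  attr(out, "ploidy") <- ploidy
  attr(out, "n_seq") <- n_seq
  out
}

#' Export a haplotype-map-like variant table
#'
#' Writes the per-site view of the strains' variation (chrom, pos, ref, alt,
#' one genotype column per strain) as TSV for inspection. Missing genotypes
#' are written as `.`.
#'
#' @param variants Table from [load_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_variant_table <- function(variants, path) {
  strains <- attr(variants, "strains")
  tab <- variants[, c("chrom", "pos", "ref", "alt", strains)]
  for (s in strains) tab[[s]][is.na(tab[[s]])] <- "."
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene models from GFF3
#'
#' Retains features of the requested type (default `gene`), converting the
#' 1-based inclusive GFF3 coordinates into the package's interval
#' representation. The gene identifier is taken from the `ID=` attribute.
#'
#' @param path Path to a GFF3 file.
#' @param index Reference index from [load_reference_index()].
#' @param feature_type Feature type to keep (third GFF column).
#' @return A [GenomicRanges::GRanges] with metadata column `gene_id` and
#'   strand; empty (with a warning) when no matching feature exists.
#' @export
load_genes <- function(path, index, feature_type = "gene") {
  seqlens <- stats::setNames(index$length, index$chrom)
  empty <- GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  seqlengths = seqlens)
  S4Vectors::mcols(empty)$gene_id <- character()
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    warning("no records in GFF3: ", path, call. = FALSE)
    return(empty)
  }
  gff <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
  gff <- gff[gff$type == feature_type, , drop = FALSE]
  if (nrow(gff) == 0) {
    warning("no features of type '", feature_type, "' in ", path,
            call. = FALSE)
    return(empty)
  }
  bad <- gff$end < gff$start
  if (any(bad)) {
    warning(sum(bad), " GFF3 record(s) with end < start rejected",
            call. = FALSE)
    gff <- gff[!bad, , drop = FALSE]
  }
  unknown <- !(gff$seqid %in% index$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " gene(s) on chromosomes absent ",
            "from the index", call. = FALSE)
    gff <- gff[!unknown, , drop = FALSE]
  }
  if (nrow(gff) == 0) return(empty)
  ids <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
  no_id <- !grepl("ID=", gff$attributes)
  if (any(no_id)) ids[no_id] <- paste0("gene_", which(no_id))
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in GFF3: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = gff$seqid,
    ranges = IRanges::IRanges(start = gff$start, end = gff$end),
    strand = ifelse(gff$strand %in% c("+", "-"), gff$strand, "*"),
    seqlengths = seqlens)
  S4Vectors::mcols(gr)$gene_id <- ids
  gr
}
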