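#' Simulate a window genealogy
#'
#' Standard Kingman coalescent for `NEUTRAL` windows: while `k` lineages
#' remain, wait an Exponential(k(k-1)/2) time (coalescent units of 2N
#' generations) and merge a uniformly chosen pair. `BALANCING` windows take a
#' neutral genealogy whose two root-adjacent branches are multiplied by
#' `stretch`, emulating an anciently balanced split that piles variants at
#' intermediate frequency. `SWEEP` windows use a star genealogy — all `n`
#' lineages coalescing at a single node at depth `1 - 1/n` (half the expected
#' neutral tree height `2(1 - 1/n)`) — so every variant is a singleton.
#'
#' @param n Number of haploid lineages (>= 2).
#' @param regime One of `"NEUTRAL"`, `"BALANCING"`, `"SWEEP"`.
#' @param stretch Multiplier (> 1) applied to the root-adjacent branches
#'   under `BALANCING`.
#' @return List of class `genealogy`: `lengths` (branch lengths, coalescent
#'   units), `carriers` (leaf indices below each branch), `total_length`,
#'   `height`, `n`, `regime`. Uses the current RNG stream.
#' @export
simulate_genealogy <- function(n, regime = c("NEUTRAL", "BALANCING", "SWEEP"),
                               stretch = 5) {
  regime <- match.arg(regime)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (regime == "SWEEP") {
    depth <- 1 - 1 / n
    return(structure(list(lengths = rep(depth, n),
                          carriers = as.list(seq_len(n)),
                          total_length = n * depth, height = depth,
                          n = as.integer(n), regime = regime),
                     class = "genealogy"))
  }
  leafsets <- as.list(seq_len(n))
  acc <- numeric(n)
  edge_len <- numeric(2 * (n - 1))
  edge_car <- vector("list", 2 * (n - 1))
  height <- 0
  k <- n
  e <- 0L
  while (k > 1) {
    w <- stats::rexp(1, rate = k * (k - 1) / 2)
    acc <- acc + w
    height <- height + w
    pair <- sort(sample.int(k, 2))
    edge_len[e + 1L] <- acc[pair[1]]
    edge_len[e + 2L] <- acc[pair[2]]
    edge_car[[e + 1L]] <- leafsets[[pair[1]]]
    edge_car[[e + 2L]] <- leafsets[[pair[2]]]
    e <- e + 2L
    merged <- c(leafsets[[pair[1]]], leafsets[[pair[2]]])
    keep <- setdiff(seq_len(k), pair)
    leafsets <- c(leafsets[keep], list(merged))
    acc <- c(acc[keep], 0)
    k <- k - 1L
  }
  if (regime == "BALANCING") {
    # the last two finalised edges hang off the root
    edge_len[c(e - 1L, e)] <- edge_len[c(e - 1L, e)] * stretch
  }
  structure(list(lengths = edge_len, carriers = edge_car,
                 total_length = sum(edge_len), height = height,
                 n = as.integer(n), regime = regime),
            class = "genealogy")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutation count is Poisson(`theta/2` x total branch length), so that
#' `E[S] = theta * a1(n)` and `E[k_hat] = theta` per window under neutrality.
#' Each mutation lands on a branch with probability proportional to its
#' length, takes a unique position uniform in the window (positions are drawn
#' without replacement, so a saturated window simply truncates), and its
#' derived allele is carried by the leaves below the branch.
#'
#' @param tree A [simulate_genealogy()] result.
#' @param theta Per-window population mutation rate (> 0 allowed to be 0).
#' @param window_length Window length in bp.
#' @return data.frame with `pos` (1-based offset within the window, sorted)
#'   and list-column `carriers` (derived-allele leaf indices).
#' @export
drop_mutations <- function(tree, theta, window_length) {
  if (theta < 0) stop("`theta` must be non-negative", call. = FALSE)
  count <- stats::rpois(1, theta / 2 * tree$total_length)
  count <- min(count, window_length)
  if (count == 0) {
    out <- data.frame(pos = integer())
    out$carriers <- list()
    return(out)
  }
  branch <- sample.int(length(tree$lengths), count, replace = TRUE,
                       prob = tree$lengths)
  pos <- sort(sample.int(window_length, count))
  out <- data.frame(pos = pos)
  out$carriers <- tree$carriers[branch]
  out
}

#' Per-window diversity statistics from direct simulation
#'
#' Convenience path that simulates genealogies and mutations for a batch of
#' independent windows and scores them with the package's estimators, without
#' writing any files. Used for neutral calibration and regime-separation
#' checks.
#'
#' @param n_windows Number of windows.
#' @param n Sequences per window.
#' @param theta Per-window population mutation rate.
#' @param regime Genealogy regime (see [simulate_genealogy()]).
#' @param stretch Balancing root stretch.
#' @param window_size Window length in bp.
#' @return data.frame: `S`, `k_hat`, `theta_w`, `D` per window.
#' @export
simulate_window_diversity <- function(n_windows, n, theta,
                                      regime = "NEUTRAL", stretch = 5,
                                      window_size = 1000L) {
  consts <- tajima_constants(n)
  S <- integer(n_windows)
  k_hat <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    tree <- simulate_genealogy(n, regime, stretch)
    muts <- drop_mutations(tree, theta, window_size)
    S[i] <- nrow(muts)
    if (S[i] > 0) {
      d <- vapply(muts$carriers, length, integer(1))
      p <- d / n
      k_hat[i] <- sum(2 * p * (1 - p)) * n / (n - 1)
    }
  }
  varD <- consts$e1 * S + consts$e2 * S * (S - 1)
  data.frame(S = S, k_hat = k_hat, theta_w = S / consts$a1,
             D = ifelse(S > 0 & varD > 0,
                        (k_hat - S / consts$a1) / sqrt(pmax(varD, 1e-300)),
                        NA_real_))
}

#' Specification of a synthetic genome bundle
#'
#' Defaults emulate the study conditions: five diploid natural isolates (10
#' sequences), 1,000-bp windows, a per-window theta of 5 (the scale of the
#' printed genome-wide average), 5% of the genome masked as repetitive or
#' uncovered, and gene models overlapping the windows.
#'
#' @param contig_lengths Contig lengths in bp.
#' @param n_strains Number of diploid strains.
#' @param ploidy Sequences per strain.
#' @param theta_per_window Population mutation rate per window.
#' @param window_size Window size used to assign selection regimes.
#' @param regime_probs Named probabilities over `NEUTRAL`, `BALANCING`,
#'   `SWEEP` used to draw each window's regime.
#' @param balancing_stretch Root-branch multiplier for `BALANCING` windows.
#' @param masked_fraction Fraction of each contig masked (random blocks).
#' @param n_genes Number of non-overlapping genes to place.
#' @param seed Integer seed; the bundle is fully determined by it.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(contig_lengths = c(1e6, 1e6), n_strains = 5L,
                     ploidy = 2L, theta_per_window = 5,
                     window_size = 1000L,
                     regime_probs = c(NEUTRAL = 1),
                     balancing_stretch = 5, masked_fraction = 0.05,
                     n_genes = 500L, seed = 1L) {
  regimes <- c("NEUTRAL", "BALANCING", "SWEEP")
  if (!all(names(regime_probs) %in% regimes)) {
    stop("regime_probs names must be among ",
         paste(regimes, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(contig_lengths > 0), n_strains >= 2, ploidy >= 1,
            theta_per_window >= 0, masked_fraction >= 0, masked_fraction < 1,
            balancing_stretch > 1, n_genes >= 0)
  structure(list(contig_lengths = as.integer(contig_lengths),
                 n_strains = as.integer(n_strains),
                 ploidy = as.integer(ploidy),
                 theta_per_window = theta_per_window,
                 window_size = as.integer(window_size),
                 regime_probs = regime_probs / sum(regime_probs),
                 balancing_stretch = balancing_stretch,
                 masked_fraction = masked_fraction,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.random_mask_blocks <- function(L, fraction) {
  if (fraction <= 0) return(IRanges::IRanges())
  target <- round(fraction * L)
  ir <- IRanges::IRanges()
  for (iter in seq_len(10000)) {
    len <- sample(100:500, 1)
    st <- sample.int(max(L - len, 1), 1)
    ir <- IRanges::reduce(c(ir, IRanges::IRanges(st, min(st + len - 1, L))))
    if (sum(IRanges::width(ir)) >= target) break
  }
  ir
}

.place_genes <- function(index, n_genes) {
  placed <- vector("list", length(index$chrom))
  names(placed) <- index$chrom
  for (ch in index$chrom) placed[[ch]] <- IRanges::IRanges()
  out <- vector("list", n_genes)
  got <- 0L
  tries <- 0L
  while (got < n_genes && tries < 50L * n_genes) {
    tries <- tries + 1L
    ci <- sample.int(nrow(index), 1)
    ch <- index$chrom[ci]
    len <- sample(500:3000, 1)
    if (index$length[ci] <= len) next
    st <- sample.int(index$length[ci] - len, 1)
    cand <- IRanges::IRanges(st, st + len - 1L)
    if (length(IRanges::findOverlaps(cand, placed[[ch]])) > 0) next
    placed[[ch]] <- c(placed[[ch]], cand)
    got <- got + 1L
    out[[got]] <- data.frame(chrom = ch, start = st, end = st + len - 1L,
                             strand = sample(c("+", "-"), 1),
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out[seq_len(got)])
  if (is.null(genes)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  cbind(gene_id = sprintf("gene%04d", seq_len(nrow(genes))), genes)
}

#' Emit a synthetic genome bundle
#'
#' Writes, fully determined by the spec's seed: a reference FASTA (random
#' sequence) with a `.fai` index, a multi-sample VCF with unphased diploid
#' genotypes (consecutive simulated haplotypes paired within each strain), a
#' BED mask of random uncallable blocks, a GFF3 of non-overlapping genes,
#' per-window and per-gene truth tables (TSV) and a JSON manifest echoing the
#' spec.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `dir`, file `paths`, `truth` (window and gene
#'   truth data.frames) and the `spec`.
#' @export
emit_genome_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  n_contigs <- length(spec$contig_lengths)
  contigs <- sprintf("contig%02d", seq_len(n_contigs))
  index <- data.frame(chrom = contigs, length = spec$contig_lengths,
                      stringsAsFactors = FALSE)
  strains <- sprintf("strain%d", seq_len(spec$n_strains))
  n_seq <- spec$n_strains * spec$ploidy
  bases <- c("A", "C", "G", "T")

  # reference sequence
  seqs <- lapply(spec$contig_lengths, function(L) {
    sample(bases, L, replace = TRUE)
  })
  fasta_path <- file.path(out_dir, "reference.fa")
  fai_path <- paste0(fasta_path, ".fai")
  con <- file(fasta_path, "w")
  offsets <- numeric(n_contigs)
  offset <- 0
  line_w <- 70L
  for (i in seq_len(n_contigs)) {
    header <- paste0(">", contigs[i])
    writeLines(header, con)
    offset <- offset + nchar(header) + 1
    offsets[i] <- offset
    L <- spec$contig_lengths[i]
    starts <- seq.int(1L, L, by = line_w)
    lines <- vapply(starts, function(s) {
      paste(seqs[[i]][s:min(s + line_w - 1L, L)], collapse = "")
    }, character(1))
    writeLines(lines, con)
    offset <- offset + L + length(lines)
  }
  close(con)
  writeLines(sprintf("%s\t%d\t%.0f\t%d\t%d", contigs, spec$contig_lengths,
                     offsets, line_w, line_w + 1L), fai_path)

  # mask
  mask_path <- file.path(out_dir, "mask.bed")
  mask_rows <- list()
  for (i in seq_len(n_contigs)) {
    ir <- .random_mask_blocks(spec$contig_lengths[i], spec$masked_fraction)
    if (length(ir) > 0) {
      mask_rows[[i]] <- data.frame(chrom = contigs[i],
                                   start0 = IRanges::start(ir) - 1L,
                                   end0 = IRanges::end(ir))
    }
  }
  mask_df <- do.call(rbind, mask_rows)
  if (is.null(mask_df)) {
    file.create(mask_path)
  } else {
    utils::write.table(mask_df, mask_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  # per-window coalescent simulation
  windows <- partition_genome(index, scan_config(
    window_size = spec$window_size))
  regimes <- sample(names(spec$regime_probs), nrow(windows), replace = TRUE,
                    prob = spec$regime_probs)
  vcf_rows <- vector("list", nrow(windows))
  n_mut <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    tree <- simulate_genealogy(n_seq, regimes[w], spec$balancing_stretch)
    theta_w <- spec$theta_per_window * windows$length[w] / spec$window_size
    muts <- drop_mutations(tree, theta_w, windows$length[w])
    n_mut[w] <- nrow(muts)
    if (nrow(muts) == 0) next
    ci <- match(windows$chrom[w], contigs)
    gpos <- windows$start[w] - 1L + muts$pos
    ref <- seqs[[ci]][gpos]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    gts <- vapply(muts$carriers, function(car) {
      hap <- integer(n_seq)
      hap[car] <- 1L
      paste(vapply(seq_len(spec$n_strains), function(s) {
        idx <- ((s - 1L) * spec$ploidy + 1L):(s * spec$ploidy)
        paste(hap[idx], collapse = "/")
      }, character(1)), collapse = "\t")
    }, character(1))
    vcf_rows[[w]] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                             windows$chrom[w], gpos, ref, alt, gts)
  }
  vcf_path <- file.path(out_dir, "variants.vcf")
  vcf_header <- c(
    "##fileformat=VCFv4.2",
    "##source=tajscan coalescent simulator",
    sprintf("##contig=<ID=%s,length=%d>", contigs, spec$contig_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
  writeLines(c(vcf_header, unlist(vcf_rows)), vcf_path)

  # genes
  genes <- .place_genes(index, spec$n_genes)
  gff_path <- file.path(out_dir, "genes.gff3")
  gff_lines <- "##gff-version 3"
  if (nrow(genes) > 0) {
    gff_lines <- c(gff_lines, sprintf(
      "%s\ttajscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id))
  }
  writeLines(gff_lines, gff_path)

  # truth tables
  win_truth <- data.frame(windows[, c("window_id", "chrom", "start", "end")],
                          regime = regimes,
                          theta = spec$theta_per_window *
                            windows$length / spec$window_size,
                          n_mutations = n_mut)
  gene_truth <- genes
  if (nrow(genes) > 0) {
    bal <- win_truth[win_truth$regime == "BALANCING", , drop = FALSE]
    overlaps_bal <- logical(nrow(genes))
    if (nrow(bal) > 0) {
      ggr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
      bgr <- GenomicRanges::GRanges(bal$chrom,
                                    IRanges::IRanges(bal$start, bal$end))
      overlaps_bal <- IRanges::overlapsAny(ggr, bgr)
    }
    gene_truth$overlaps_balancing <- overlaps_bal
  }
  win_truth_path <- file.path(out_dir, "truth_windows.tsv")
  gene_truth_path <- file.path(out_dir, "truth_genes.tsv")
  utils::write.table(win_truth, win_truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gene_truth, gene_truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(generator = "tajscan emit_genome_bundle",
         spec = unclass(spec), strains = strains,
         files = c(fasta = "reference.fa", fai = "reference.fa.fai",
                   vcf = "variants.vcf", mask = "mask.bed",
                   gff3 = "genes.gff3", truth_windows = "truth_windows.tsv",
                   truth_genes = "truth_genes.tsv")),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dir = out_dir,
                 paths = list(fasta = fasta_path, fai = fai_path,
                              vcf = vcf_path, mask = mask_path,
                              gff3 = gff_path,
                              truth_windows = win_truth_path,
                              truth_genes = gene_truth_path,
                              manifest = manifest_path),
                 truth = list(windows = win_truth, genes = gene_truth),
                 strains = strains, spec = spec))
}

#' Plant expression classes over simulated genes
#'
#' Assigns each gene `DIFFERENTIAL` with base probability `base_rate`,
#' multiplied by `enrichment` (capped at 1) for genes overlapping a
#' `BALANCING` window — creating a known association between expression class
#' and balancing-selection signatures for power checks. Uses the current RNG
#' stream.
#'
#' @param gene_truth Gene truth table from [emit_genome_bundle()] (needs
#'   `gene_id` and `overlaps_balancing`).
#' @param enrichment Odds multiplier (>= 1; `Inf` labels every
#'   balancing-overlap gene differential).
#' @param base_rate Baseline probability of `DIFFERENTIAL`.
#' @return data.frame: `gene_id`, `expression_class`.
#' @export
plant_expression_classes <- function(gene_truth, enrichment = 1,
                                     base_rate = 1 / 3) {
  p <- rep(base_rate, nrow(gene_truth))
  if ("overlaps_balancing" %in% names(gene_truth)) {
    p[gene_truth$overlaps_balancing] <- min(1, base_rate * enrichment)
  }
  data.frame(gene_id = gene_truth$gene_id,
             expression_class = ifelse(stats::runif(nrow(gene_truth)) < p,
                                       "DIFFERENTIAL", "NON_DIFFERENTIAL"),
             stringsAsFactors = FALSE)
}
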