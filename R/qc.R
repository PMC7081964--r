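# Assembly evaluation metrics: Nx/NGx contiguity, Phred-scaled consensus
# quality (QV) from small-variant calls, chromosome-end repeat
# classification, merged repeat-region statistics, gap-to-gene proximity and
# transcript alignment classes.

#' Contiguity statistics (Nx, NGx, Lx, LGx)
#'
#' `NGx` is the length of the sequence at which the cumulative
#' length-sorted total first reaches `x%` of a fixed `genome_size`; `Nx`
#' uses the assembly's own total instead.  `LGx`/`Lx` are the 1-based counts
#' of sequences needed to get there.  When the assembly does not reach `x%`
#' of the genome size, `NGx` is reported as `NA` (absent), distinguishing a
#' short assembly from a zero-length contig.
#'
#' @param lengths Numeric vector of positive contig/scaffold lengths.
#' @param genome_size Fixed genome size in bp for the NG statistics
#'   (default 2.8e9).
#' @return Object of class `contiguity_stats`: list with `lengths` (sorted
#'   decreasing), `total_bp`, `genome_size`, and length-101 vectors `nx`,
#'   `lx`, `ngx`, `lgx` indexed by `x = 0..100` (use e.g. `$ngx[["50"]]`).
#' @export
contiguity <- function(lengths, genome_size = 2.8e9) {
  if (length(lengths) == 0 || any(lengths <= 0))
    stop("lengths must be non-empty and positive")
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be > 0")
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lengths)
  total <- cum[length(cum)]
  xs <- 0:100
  stat_for <- function(base) {
    thr <- xs / 100 * base
    idx <- findInterval(thr, cum, left.open = TRUE) + 1L
    n <- ifelse(idx <= length(lengths), lengths[pmin(idx, length(lengths))],
                NA_real_)
    l <- ifelse(idx <= length(lengths), idx, NA_integer_)
    list(n = stats::setNames(n, xs), l = stats::setNames(l, xs))
  }
  own <- stat_for(total)
  fixed <- stat_for(genome_size)
  structure(list(lengths = lengths, total_bp = total,
                 genome_size = genome_size, nx = own$n, lx = own$l,
                 ngx = fixed$n, lgx = fixed$l),
            class = "contiguity_stats")
}

#' @export
print.contiguity_stats <- function(x, ...) {
  cat(sprintf(paste0("<contiguity_stats> %d sequences, %.0f bp total\n",
                     "  N50 %.0f (L50 %d); NG50 %s (genome size %.3g bp)\n"),
              length(x$lengths), x$total_bp, x$nx[["50"]], x$lx[["50"]],
              ifelse(is.na(x$ngx[["50"]]), "NA",
                     sprintf("%.0f", x$ngx[["50"]])), x$genome_size))
  invisible(x)
}

#' Estimate consensus quality (QV) from an error-base count
#'
#' `QV = -10 * log10(error_bases / assessed_bases)`.  With zero error bases
#' the estimate is reported as a lower bound at the detection cap
#' `-10 * log10(1 / assessed_bases)`.
#'
#' @param error_bases Number of erroneous bases.
#' @param assessed_bases Number of bases assessed.
#' @return List with `error_bases`, `assessed_bases`, `error_rate`, `qv`,
#'   `capped` (TRUE when `error_bases == 0`) and `qv_label` (the 2-decimal
#'   report string, `">= cap"` when capped).
#' @export
estimate_qv <- function(error_bases, assessed_bases) {
  stopifnot(is_count(error_bases), assessed_bases > 0)
  if (error_bases > assessed_bases)
    stop("error_bases exceeds assessed_bases")
  if (error_bases == 0) {
    cap <- -10 * log10(1 / assessed_bases)
    return(list(error_bases = 0, assessed_bases = assessed_bases,
                error_rate = 0, qv = Inf, capped = TRUE,
                qv_label = sprintf(">= %.2f", cap)))
  }
  rate <- error_bases / assessed_bases
  qv <- -10 * log10(rate)
  list(error_bases = error_bases, assessed_bases = assessed_bases,
       error_rate = rate, qv = qv, capped = FALSE,
       qv_label = sprintf("%.2f", qv))
}

#' Count error bases implied by a variant table
#'
#' Each retained record contributes `max(nchar(ref), nchar(alt))` error
#' bases, so a SNP counts 1 and a 3-bp deletion (`ACGT -> A`) counts 4.  By
#' default only `PASS` records are used and both heterozygous and
#' homozygous-alternate calls count; both conventions are configurable.
#'
#' @param variants Data frame from [read_variants()].
#' @param pass_only Keep only `FILTER == "PASS"` records (default TRUE).
#' @param hom_only Count only homozygous-alternate records (default FALSE).
#' @return Integer error-base count.
#' @export
count_error_bases <- function(variants, pass_only = TRUE, hom_only = FALSE) {
  v <- variants
  if (pass_only) v <- v[v$filter == "PASS", , drop = FALSE]
  if (hom_only) v <- v[v$genotype == "hom_alt", , drop = FALSE]
  if (nrow(v) == 0) return(0L)
  sum(pmax(nchar(v$ref_allele), nchar(v$alt_allele)))
}

#' Classify a chromosome's ends by centromeric/telomeric repeat content
#'
#' Booleans record whether any interval of each repeat class overlaps the
#' first or last `end_window` bases.  For an acrocentric chromosome the
#' expected pattern is a centromere at the start and a telomere at the end;
#' centromeric repeats in both windows are flagged as the classic
#' `centromere_both_ends` misassembly signature.  For a metacentric
#' chromosome the complete pattern is telomeres at both ends with no
#' centromeric repeats in either end window.  The verdict is a pure
#' function of the four booleans and the karyotype.
#'
#' @param chromosome_length Length in bp.
#' @param repeat_intervals Data frame with 0-based half-open `start`, `end`
#'   and `class` (`"centromeric"`/`"telomeric"`) columns for this
#'   chromosome.
#' @param karyotype `"acrocentric"` or `"metacentric"`.
#' @param end_window Window size in bp at each end (default 500000).
#' @return List with the four booleans and `verdict`.
#' @export
classify_ends <- function(chromosome_length, repeat_intervals,
                          karyotype = c("acrocentric", "metacentric"),
                          end_window = 500000L) {
  karyotype <- match.arg(karyotype)
  if (end_window > chromosome_length / 2)
    stop("end_window larger than half the chromosome length")
  hit <- function(cls, lo, hi) {
    r <- repeat_intervals[repeat_intervals$class == cls, , drop = FALSE]
    any(r$start < hi & r$end > lo)
  }
  cen_s <- hit("centromeric", 0, end_window)
  tel_s <- hit("telomeric", 0, end_window)
  cen_e <- hit("centromeric", chromosome_length - end_window,
               chromosome_length)
  tel_e <- hit("telomeric", chromosome_length - end_window,
               chromosome_length)
  verdict <- end_verdict(cen_s, tel_s, cen_e, tel_e, karyotype)
  list(has_centromere_start = cen_s, has_telomere_start = tel_s,
       has_centromere_end = cen_e, has_telomere_end = tel_e,
       karyotype = karyotype, verdict = verdict)
}

#' @rdname classify_ends
#' @param cen_start,tel_start,cen_end,tel_end The four end-window booleans.
#' @export
end_verdict <- function(cen_start, tel_start, cen_end, tel_end, karyotype) {
  if (karyotype == "acrocentric") {
    if (cen_start && cen_end) return("centromere_both_ends")
    if (cen_start && tel_end) return("complete")
    if (cen_start) return("missing_telomere")
    if (tel_end) return("missing_centromere")
    if (!tel_start && !cen_end) return("missing_both")
    return("other")
  }
  # metacentric: telomeres expected at both ends, centromere internal
  if (cen_start || cen_end) return("other")
  if (tel_start && tel_end) return("complete")
  if (tel_start || tel_end) return("missing_telomere")
  "missing_both"
}

#' Merged repeat-region statistics by genomic category
#'
#' Intervals of one repeat class are merged when they overlap by at least 1
#' bp (abutting intervals are not merged).  Each merged region is
#' categorised `CHRSTART` (starting within the first `start_window` bases of
#' a chromosome), `UNPLACED` (on an unplaced scaffold) or `CHRSCAFF`
#' (elsewhere on a chromosome), and per class and category the mean region
#' length is reported with a 95% confidence interval of
#' `mean +/- 2 * sd / sqrt(n)` (NA when `n < 2`).
#'
#' @param repeat_intervals Data frame with `chrom`, `start`, `end`, `class`.
#' @param chromosome_lengths Named vector of chromosome lengths (unused for
#'   categorisation beyond naming, kept for interface symmetry).
#' @param unplaced_names Character vector of unplaced scaffold names.
#' @param start_window CHRSTART window in bp (default 500000).
#' @return Data frame with `class`, `category`, `n`, `mean_length`,
#'   `ci_low`, `ci_high`.
#' @export
repeat_region_stats <- function(repeat_intervals, chromosome_lengths,
                                unplaced_names = character(0),
                                start_window = 500000L) {
  rows <- list()
  for (cls in sort(unique(repeat_intervals$class))) {
    r <- repeat_intervals[repeat_intervals$class == cls, , drop = FALSE]
    merged <- do.call(rbind, lapply(sort(unique(r$chrom)), function(ch) {
      rc <- r[r$chrom == ch, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(rc$start + 1L, rc$end),
                            min.gapwidth = 0L)
      data.frame(chrom = ch, start = BiocGenerics::start(ir) - 1L,
                 end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
    }))
    merged$category <- ifelse(merged$chrom %in% unplaced_names, "UNPLACED",
                              ifelse(merged$start < start_window,
                                     "CHRSTART", "CHRSCAFF"))
    merged$len <- merged$end - merged$start
    for (cat in c("CHRSTART", "UNPLACED", "CHRSCAFF")) {
      lens <- merged$len[merged$category == cat]
      n <- length(lens)
      m <- if (n) mean(lens) else NA_real_
      se2 <- if (n >= 2) 2 * stats::sd(lens) / sqrt(n) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        class = cls, category = cat, n = n, mean_length = m,
        ci_low = m - se2, ci_high = m + se2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gap-to-gene proximity
#'
#' Counts genes with a gap inside a derived intron, and genes with a gap
#' anywhere within `flank_bp` of the gene (gene body included, so
#' intron-gap genes are a subset of flank-gap genes).
#'
#' @param gaps Data frame of gap records (`scaffold`, `start`, `end`).
#' @param genes List of gene models (see [read_gff3_genes()]).
#' @param flank_bp Flank size in bp (default 10000).
#' @return List with `n_genes`, `n_genes_gap_in_intron`,
#'   `n_genes_gap_within_flank`, `flank_bp`, `pct_gap_in_intron`,
#'   `pct_gap_within_flank`.
#' @export
gap_gene_proximity <- function(gaps, genes, flank_bp = 10000L) {
  gap_by_scf <- split(gaps, gaps$scaffold)
  n_intron <- 0L
  n_flank <- 0L
  for (g in genes) {
    gs <- gap_by_scf[[g$scaffold]]
    if (is.null(gs) || nrow(gs) == 0) next   # gene on a gap-free scaffold
    ovl <- function(iv) any(outer(gs$start, iv[, 2], `<`) &
                              outer(gs$end, iv[, 1], `>`))
    if (nrow(g$introns) && ovl(g$introns)) n_intron <- n_intron + 1L
    if (any(gs$start < g$end + flank_bp & gs$end > g$start - flank_bp))
      n_flank <- n_flank + 1L
  }
  n <- length(genes)
  list(n_genes = n, n_genes_gap_in_intron = n_intron,
       n_genes_gap_within_flank = n_flank, flank_bp = flank_bp,
       pct_gap_in_intron = if (n) 100 * n_intron / n else NA_real_,
       pct_gap_within_flank = if (n) 100 * n_flank / n else NA_real_)
}

#' Classify transcript alignments
#'
#' Placements (groups of alignment blocks) compete on summed matches; ties
#' break on fewer target sequences, then longer query coverage.  Statuses
#' are assigned in priority order: `not_aligning` (no alignments at all),
#' `split` (best placement spans two or more target sequences),
#' `low_cds_coverage` (best placement covers less than `min_cds_cov` of the
#' CDS), else `ok`.
#'
#' @param alignments Alignment blocks with a `query` column naming the
#'   transcript; an optional `placement` column groups blocks into compound
#'   placements (default: one placement per target sequence).
#' @param cds_ranges Data frame with `transcript`, `cds_start`, `cds_end`
#'   (0-based half-open on the transcript) and `transcript_len` columns.
#' @param min_cds_cov Minimum CDS coverage fraction (default 0.95).
#' @return Data frame with `transcript_id`, `status`, `best_cds_coverage`,
#'   `n_target_sequences`.
#' @export
classify_transcripts <- function(alignments, cds_ranges, min_cds_cov = 0.95) {
  bad <- cds_ranges$cds_start < 0 |
    cds_ranges$cds_end > cds_ranges$transcript_len |
    cds_ranges$cds_end <= cds_ranges$cds_start
  if (any(bad))
    stop("CDS range outside transcript length for ",
         cds_ranges$transcript[which(bad)[1]])
  if (!"placement" %in% names(alignments) && nrow(alignments))
    alignments$placement <- alignments$target
  rows <- list()
  for (i in seq_len(nrow(cds_ranges))) {
    tx <- cds_ranges$transcript[i]
    cds <- c(cds_ranges$cds_start[i], cds_ranges$cds_end[i])
    al <- alignments[alignments$query == tx, , drop = FALSE]
    if (nrow(al) == 0) {
      rows[[i]] <- data.frame(transcript_id = tx, status = "not_aligning",
                              best_cds_coverage = 0, n_target_sequences = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    pl <- split(al, al$placement)
    score <- vapply(pl, function(p) sum(p$matches), numeric(1))
    n_tgt <- vapply(pl, function(p) length(unique(p$target)), numeric(1))
    qcov <- vapply(pl, function(p) {
      ir <- IRanges::reduce(IRanges::IRanges(p$query_start + 1L, p$query_end))
      sum(BiocGenerics::width(ir))
    }, numeric(1))
    best <- order(-score, n_tgt, -qcov)[1]
    p <- pl[[best]]
    ir <- IRanges::reduce(IRanges::IRanges(p$query_start + 1L, p$query_end))
    cds_ir <- IRanges::IRanges(cds[1] + 1L, cds[2])
    cov_bp <- sum(BiocGenerics::width(IRanges::intersect(ir, cds_ir)))
    cds_cov <- cov_bp / (cds[2] - cds[1])
    status <- if (n_tgt[best] >= 2) "split" else
      if (cds_cov < min_cds_cov) "low_cds_coverage" else "ok"
    rows[[i]] <- data.frame(transcript_id = tx, status = status,
                            best_cds_coverage = cds_cov,
                            n_target_sequences = as.integer(n_tgt[best]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find tandem motif arrays in a sequence
#'
#' Reports maximal runs of at least `min_copies` consecutive copies of a
#' motif (forward or reverse-complement), the usual thin detector for
#' telomeric `TTAGGG`-type arrays and planted satellite monomers.
#'
#' @param seq Sequence string.
#' @param motif Motif string.
#' @param min_copies Minimum consecutive copies (default 3).
#' @param both_strands Also scan the reverse-complement motif (default TRUE).
#' @return Data frame with 0-based half-open `start`, `end`, `n_copies`.
#' @export
find_motif_runs <- function(seq, motif, min_copies = 3L, both_strands = TRUE) {
  pats <- motif
  if (both_strands) pats <- unique(c(motif, revcomp(motif)))
  rows <- list()
  for (p in pats) {
    rx <- sprintf("(?:%s){%d,}", p, min_copies)
    m <- gregexpr(rx, seq)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    rows[[length(rows) + 1]] <- data.frame(
      start = as.integer(m - 1L), end = as.integer(m - 1L + len),
      n_copies = as.integer(len / nchar(p)))
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      n_copies = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}
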