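# Deterministic synthetic genomes with planted truth: chromosomes carrying
# centromeric/telomeric repeat arrays and multi-exon genes; draft assemblies
# fragmented into scaffolds with N gaps, inter-chromosome misjoins,
# inversions and collapses; genetic maps with exact marker placements; patch
# assemblies engineered per gap-spanning case; and variant tables with an
# exact planted error-base total.  All alignments are computed by coordinate
# bookkeeping, never by running an aligner, so the threshold geometry under
# test is exact.

# fixed toy satellite monomer used as the centromeric repeat unit
.cen_monomer <- paste0(
  "AGGTCACCTGAAGACAATTCCCGGTTGAAATCCACCTGGGAGTTACGCATAGTCTTAGAA",
  "CCTGCGTAATGCTTTGAACGGATTCTAAGCTGACCATAGGCACCTAGTTGCATAAGCCAT")

#' Default planted-repeat configuration
#'
#' The centromeric class is a tandem array of a fixed 120-bp satellite
#' monomer planted at chromosome starts (acrocentric convention); the
#' telomeric class is a `TTAGGG` tandem array at the distal end.
#'
#' @param cen_copies,tel_copies Tandem copy numbers (defaults 250 and 500,
#'   i.e. 30 kb and 3 kb arrays).
#' @return Nested list with `centromeric` and `telomeric` entries
#'   (`motif`, `copies`).
#' @export
default_repeat_config <- function(cen_copies = 250L, tel_copies = 500L) {
  list(centromeric = list(motif = .cen_monomer, copies = cen_copies),
       telomeric = list(motif = "TTAGGG", copies = tel_copies))
}

#' Simulate a truth genome
#'
#' Chromosomes are i.i.d. uniform ACGT background with a centromeric
#' satellite array planted at the start and a telomeric array at the distal
#' end; non-overlapping multi-exon genes are placed away from the repeat
#' arrays.
#'
#' @param seed Integer seed; same seed, same genome.
#' @param n_chromosomes Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 2e6; must be at
#'   least 2e5 so end-window logic has room).
#' @param n_genes Total gene count across chromosomes (default 60).
#' @param repeat_config See [default_repeat_config()].
#' @return List with `sequences` (named character vector), `genes` (list of
#'   gene models as in [read_gff3_genes()]), `repeats` (BED-like data
#'   frame), `repeat_config` and `seed`.
#' @export
simulate_genome <- function(seed, n_chromosomes = 3L, chrom_length = 2e6,
                            n_genes = 60L,
                            repeat_config = default_repeat_config()) {
  stopifnot(chrom_length >= 2e5, n_chromosomes >= 1)
  set.seed(seed)
  cen <- strrep(repeat_config$centromeric$motif,
                repeat_config$centromeric$copies)
  tel <- strrep(repeat_config$telomeric$motif, repeat_config$telomeric$copies)
  L <- as.integer(chrom_length)
  sequences <- character(n_chromosomes)
  names(sequences) <- sprintf("chr%d", seq_len(n_chromosomes))
  repeats <- list()
  for (i in seq_len(n_chromosomes)) {
    bg <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    s <- paste0(cen, substr(bg, nchar(cen) + 1, L - nchar(tel)), tel)
    sequences[i] <- s
    repeats[[length(repeats) + 1]] <- data.frame(
      chrom = names(sequences)[i],
      start = c(0L, L - nchar(tel)), end = c(nchar(cen), L),
      class = c("centromeric", "telomeric"), stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, repeats)
  genes <- place_genes(sequences, n_genes, lo_margin = nchar(cen) + 2000L,
                       hi_margin = nchar(tel) + 2000L)
  list(sequences = sequences, genes = genes, repeats = repeats,
       repeat_config = repeat_config, seed = seed)
}

place_genes <- function(sequences, n_genes, lo_margin, hi_margin) {
  if (n_genes == 0) return(list())
  chroms <- rep(names(sequences), length.out = n_genes)
  occupied <- lapply(sequences, function(x) cbind(start = integer(0),
                                                  end = integer(0)))
  genes <- vector("list", n_genes)
  for (k in seq_len(n_genes)) {
    ch <- chroms[k]
    L <- nchar(sequences[[ch]])
    n_ex <- sample(2:5, 1)
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    in_len <- sample(200:800, n_ex - 1, replace = TRUE)
    span <- sum(ex_len) + sum(in_len)
    placed <- FALSE
    for (try in 1:200) {
      start <- sample(seq(lo_margin, L - hi_margin - span), 1)
      occ <- occupied[[ch]]
      if (nrow(occ) == 0 ||
          !any(occ[, "start"] < start + span + 500 &
                 occ[, "end"] > start - 500)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place gene ", k, "; reduce n_genes")
    offs <- cumsum(c(0L, ex_len[-n_ex] + in_len))
    exons <- cbind(start = start + offs, end = start + offs + ex_len)
    gid <- sprintf("gene%03d", k)
    occupied[[ch]] <- rbind(occupied[[ch]],
                            cbind(start = start, end = start + span))
    genes[[k]] <- list(gene_id = gid, scaffold = ch, start = start,
                       end = start + span,
                       strand = sample(c("+", "-"), 1), exons = exons,
                       introns = intervals_complement(exons, start,
                                                      start + span))
  }
  genes
}

#' Write gene models as GFF3
#'
#' Deterministic, byte-stable writer emitting `gene`/`mRNA`/`exon` rows
#' (one transcript per gene) with 1-based inclusive coordinates.
#'
#' @param genes List of gene models.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    tid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tasmforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold, g$start + 1L, g$end, g$strand,
                       g$gene_id), con)
    writeLines(sprintf("%s\tasmforge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$scaffold, g$start + 1L, g$end, g$strand, tid,
                       g$gene_id), con)
    for (j in seq_len(nrow(g$exons))) {
      writeLines(sprintf(
        "%s\tasmforge\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$scaffold, g$exons[j, "start"] + 1L, g$exons[j, "end"], g$strand,
        tid, j, tid), con)
    }
  }
  invisible(path)
}

# map a truth interval [t1, t2) on `part` (one row of the parts table) to
# draft scaffold coordinates; returns list(start, end, strand)
part_map_interval <- function(part, t1, t2) {
  P <- part$t_end - part$t_start
  if (!part$inverted) {
    list(start = part$s_start + (t1 - part$t_start),
         end = part$s_start + (t2 - part$t_start), strand = "+")
  } else {
    list(start = part$s_start + (P - (t2 - part$t_start)),
         end = part$s_start + (P - (t1 - part$t_start)), strand = "-")
  }
}

#' Fragment a truth genome into a draft assembly with planted defects
#'
#' Chromosomes are cut into per-chromosome segments; segments become
#' scaffolds whose internal gaps replace true sequence with equal-length N
#' runs (so declared gap size equals true size).  `n_misjoins` chimeric
#' scaffolds concatenate segments from two different chromosomes across a
#' junction gap; `n_inversions` scaffolds are wholly reverse-complemented;
#' `n_collapses` scaffolds silently omit a stretch of true sequence inside
#' a contig (a negative gap).
#'
#' @param truth Output of [simulate_genome()].
#' @param n_scaffolds_per_chrom Segments per chromosome (default 4).
#' @param gaps_per_scaffold Ordinary gaps per scaffold (default 2).
#' @param gap_len_range Inclusive range of gap lengths in bp (default
#'   60-200; the minimum must exceed the N-run detection threshold).
#' @param n_misjoins,n_inversions,n_collapses Planted defect counts.
#' @param collapse_size_range Range of omitted bp per collapse.
#' @param junction_gap Gap size at misjoin junctions (default 100).
#' @param seed Integer seed.
#' @return Draft list: `layouts`, `contigs`, `scaffolds` (sequences),
#'   `parts` (truth-to-draft coordinate map), `gaps` (with truth
#'   intervals), `assignments` (truth order/orientation of unbroken
#'   scaffolds), `misjoins`, `collapses`, `negative_gaps`.
#' @export
fragment_assembly <- function(truth, n_scaffolds_per_chrom = 4L,
                              gaps_per_scaffold = 2L,
                              gap_len_range = c(60L, 200L),
                              n_misjoins = 0L, n_inversions = 0L,
                              n_collapses = 0L,
                              collapse_size_range = c(100L, 300L),
                              junction_gap = 100L, seed = 1L) {
  set.seed(seed)
  edge_margin <- 20000L   # keep gaps clear of part edges for patch flanks
  chroms <- names(truth$sequences)
  units <- list()
  for (ch in chroms) {
    L <- nchar(truth$sequences[[ch]])
    k <- n_scaffolds_per_chrom
    bounds <- round(L * seq_len(k - 1) / k +
                      stats::runif(k - 1, -0.04, 0.04) * L / k)
    bounds <- c(0L, as.integer(bounds), L)
    for (j in seq_len(k))
      units[[length(units) + 1]] <- list(chrom = ch, t_start = bounds[j],
                                         t_end = bounds[j + 1], order = j)
  }
  n_units <- length(units)
  if (2 * n_misjoins + n_inversions + n_collapses > n_units)
    stop("requested defects exceed available scaffold segments")
  # deterministic defect selection: shuffle unit indices once
  idx <- sample(n_units)
  mis_idx <- list()
  used <- logical(n_units)
  # pair units from different chromosomes for misjoins
  pool <- idx
  while (length(mis_idx) < n_misjoins) {
    a <- pool[1]; pool <- pool[-1]
    b_pos <- which(vapply(pool, function(b)
      units[[b]]$chrom != units[[a]]$chrom, logical(1)))[1]
    if (is.na(b_pos)) stop("cannot pair misjoins across chromosomes")
    b <- pool[b_pos]; pool <- pool[-b_pos]
    mis_idx[[length(mis_idx) + 1]] <- c(a, b)
    used[c(a, b)] <- TRUE
  }
  inv_idx <- pool[seq_len(n_inversions)]
  if (n_inversions > 0) pool <- pool[-seq_len(n_inversions)]
  col_idx <- pool[seq_len(n_collapses)]
  pure_idx <- if (n_collapses > 0) pool[-seq_len(n_collapses)] else pool

  scaffolds <- character(0)
  layouts <- list()
  contigs <- character(0)
  parts_rows <- list()
  gaps_rows <- list()
  assignments <- list()
  misjoins <- list()
  collapses <- list()
  negative_rows <- list()
  scf_i <- 0L

  build_scaffold <- function(part_units, inverted, joins, collapse = NULL) {
    # part_units: list of (chrom, t_start, t_end); joins: N bp after part i
    scf_i <<- scf_i + 1L
    name <- sprintf("scaf%03d", scf_i)
    s_off <- 0L
    seq_parts <- character(0)
    for (pi in seq_along(part_units)) {
      u <- part_units[[pi]]
      P <- u$t_end - u$t_start
      seg <- substr(truth$sequences[[u$chrom]], u$t_start + 1, u$t_end)
      # ordinary gaps inside this part (part-local, truth-strand coords)
      n_g <- u$n_gaps %||% 0L
      gpos <- list()
      if (n_g > 0) {
        centers <- round(P * seq_len(n_g) / (n_g + 1) +
                           stats::runif(n_g, -0.03, 0.03) * P)
        glen <- sample(seq(gap_len_range[1], gap_len_range[2]), n_g,
                       replace = TRUE)
        keep <- centers > edge_margin & centers + glen < P - edge_margin
        if (n_g > 1) {
          sep <- c(Inf, diff(centers)) > 2 * edge_margin
          keep <- keep & sep
        }
        centers <- centers[keep]; glen <- glen[keep]
        for (gi in seq_along(centers)) {
          g1 <- centers[gi]; g2 <- g1 + glen[gi]
          seg <- paste0(substr(seg, 1, g1), n_run(glen[gi]),
                        substring(seg, g2 + 1))
          gpos[[gi]] <- c(g1, g2)
        }
      }
      if (inverted) seg <- revcomp(seg)
      part_row <- data.frame(scaffold = name, part = pi, chrom = u$chrom,
                             t_start = u$t_start, t_end = u$t_end,
                             inverted = inverted, s_start = s_off,
                             s_end = s_off + P, stringsAsFactors = FALSE)
      parts_rows[[length(parts_rows) + 1]] <<- part_row
      for (g in gpos) {
        m <- part_map_interval(part_row, u$t_start + g[1], u$t_start + g[2])
        gaps_rows[[length(gaps_rows) + 1]] <<- data.frame(
          scaffold = name, s_start = m$start, s_end = m$end,
          chrom = u$chrom, t_start = u$t_start + g[1],
          t_end = u$t_start + g[2], inverted = inverted, kind = "ordinary",
          stringsAsFactors = FALSE)
      }
      seq_parts <- c(seq_parts, seg)
      s_off <- s_off + P
      if (pi < length(part_units) && joins[pi] > 0) {
        seq_parts <- c(seq_parts, n_run(joins[pi]))
        s_off <- s_off + joins[pi]
      }
    }
    sseq <- paste(seq_parts, collapse = "")
    scaffolds[name] <<- sseq
    lf <- layout_from_sequence(name, sseq, min_gap_run = 30L)
    layouts[[name]] <<- lf$layout
    contigs <<- c(contigs, lf$contigs)
    name
  }

  # distribute ordinary gap counts onto units (none inside misjoin or
  # collapse parts shorter than needed)
  for (u in seq_along(units)) units[[u]]$n_gaps <- gaps_per_scaffold

  for (pair in mis_idx) {
    ua <- units[[pair[1]]]; ub <- units[[pair[2]]]
    name <- build_scaffold(list(ua, ub), inverted = FALSE,
                           joins = junction_gap)
    junction <- (ua$t_end - ua$t_start)  # junction gap starts here
    misjoins[[length(misjoins) + 1]] <- data.frame(
      scaffold = name, junction = junction, lg1 = ua$chrom, lg2 = ub$chrom,
      stringsAsFactors = FALSE)
  }
  for (i in inv_idx) {
    u <- units[[i]]
    name <- build_scaffold(list(u), inverted = TRUE, joins = integer(0))
    assignments[[length(assignments) + 1]] <- data.frame(
      scaffold = name, chrom = u$chrom, true_order = u$order,
      true_orientation = "-", stringsAsFactors = FALSE)
  }
  for (i in col_idx) {
    u <- units[[i]]
    P <- u$t_end - u$t_start
    m <- sample(seq(collapse_size_range[1], collapse_size_range[2]), 1)
    t_pos <- u$t_start + round(P * stats::runif(1, 0.45, 0.55))
    u1 <- list(chrom = u$chrom, t_start = u$t_start, t_end = t_pos,
               n_gaps = 1L)
    u2 <- list(chrom = u$chrom, t_start = t_pos + m, t_end = u$t_end,
               n_gaps = 1L)
    name <- build_scaffold(list(u1, u2), inverted = FALSE, joins = 0L)
    s_pos <- t_pos - u$t_start
    collapses[[length(collapses) + 1]] <- data.frame(
      scaffold = name, s_pos = s_pos, size = m, chrom = u$chrom,
      t_pos = t_pos, stringsAsFactors = FALSE)
    negative_rows[[length(negative_rows) + 1]] <- data.frame(
      scaffold = name, start = s_pos, end = s_pos,
      declared_length = -m, stringsAsFactors = FALSE)
    assignments[[length(assignments) + 1]] <- data.frame(
      scaffold = name, chrom = u$chrom, true_order = u$order,
      true_orientation = "+", stringsAsFactors = FALSE)
  }
  for (i in pure_idx) {
    u <- units[[i]]
    name <- build_scaffold(list(u), inverted = FALSE, joins = integer(0))
    assignments[[length(assignments) + 1]] <- data.frame(
      scaffold = name, chrom = u$chrom, true_order = u$order,
      true_orientation = "+", stringsAsFactors = FALSE)
  }

  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(layouts = layouts, contigs = contigs, scaffolds = scaffolds,
       parts = bind(parts_rows), gaps = bind(gaps_rows),
       assignments = bind(assignments), misjoins = bind(misjoins),
       collapses = bind(collapses), negative_gaps = bind(negative_rows),
       seed = seed)
}

# locate a truth interval [m, m + len) on the draft; NULL when it falls in
# a gap, spans a part boundary, or lands on an N
locate_in_draft <- function(draft, chrom, m, len) {
  p <- draft$parts[draft$parts$chrom == chrom &
                     draft$parts$t_start <= m &
                     draft$parts$t_end >= m + len, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  p <- p[1, , drop = FALSE]
  mp <- part_map_interval(p, m, m + len)
  s <- substr(draft$scaffolds[[p$scaffold]], mp$start + 1, mp$end)
  if (grepl("N", s, fixed = TRUE)) return(NULL)
  list(scaffold = p$scaffold, position = mp$start, strand = mp$strand)
}

#' Simulate a genetic map and its draft alignments
#'
#' Markers are sampled at increasing positions along each chromosome (one
#' per equal-width window), skipping repeat arrays, draft gaps and part
#' boundaries.  Linkage group equals chromosome, map order is positional
#' rank, and cM is proportional to position.  Hits against the draft are
#' produced by exact coordinate bookkeeping (identity 1, full-length,
#' unique), with `dropout_rate` of markers omitted from the hit table and
#' `n_duplicated` markers marked as multi-placement.
#'
#' @param truth Output of [simulate_genome()].
#' @param draft Output of [fragment_assembly()].
#' @param markers_per_chrom Markers per chromosome (at least 2).
#' @param marker_len Marker sequence length in bp (at least 30).
#' @param dropout_rate Fraction of markers with no hit.
#' @param n_duplicated Markers flagged with `n_placements = 2`.
#' @param seed Integer seed.
#' @return List with `markers` (including a `truth_pos` column) and `hits`.
#' @export
simulate_genetic_map <- function(truth, draft, markers_per_chrom = 40L,
                                 marker_len = 60L, dropout_rate = 0,
                                 n_duplicated = 0L, seed = 1L) {
  stopifnot(markers_per_chrom >= 2, marker_len >= 30)
  set.seed(seed)
  mk_rows <- list()
  hit_rows <- list()
  for (ch in names(truth$sequences)) {
    L <- nchar(truth$sequences[[ch]])
    reps <- truth$repeats[truth$repeats$chrom == ch, , drop = FALSE]
    accepted <- integer(0)
    for (w in seq_len(markers_per_chrom)) {
      lo <- floor(L * (w - 1) / markers_per_chrom)
      hi <- floor(L * w / markers_per_chrom) - marker_len
      if (hi <= lo) next
      for (try in 1:60) {
        pos <- sample(seq(lo, hi), 1)
        if (any(reps$start < pos + marker_len & reps$end > pos)) next
        if (is.null(locate_in_draft(draft, ch, pos, marker_len))) next
        accepted <- c(accepted, pos)
        break
      }
    }
    accepted <- sort(accepted)
    for (j in seq_along(accepted)) {
      pos <- accepted[j]
      id <- sprintf("%s_mk%03d", ch, j)
      mk_rows[[length(mk_rows) + 1]] <- data.frame(
        marker_id = id, linkage_group = ch, map_order = j,
        map_position = round(100 * pos / L, 4),
        sequence = substr(truth$sequences[[ch]], pos + 1, pos + marker_len),
        truth_pos = pos, stringsAsFactors = FALSE)
      loc <- locate_in_draft(draft, ch, pos, marker_len)
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        marker_id = id, scaffold = loc$scaffold, position = loc$position,
        identity = 1, coverage = 1, n_placements = 1L,
        stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, mk_rows)
  hits <- do.call(rbind, hit_rows)
  if (n_duplicated > 0) {
    dup <- utils::head(markers$marker_id, n_duplicated)
    hits$n_placements[hits$marker_id %in% dup] <- 2L
  }
  if (dropout_rate > 0) {
    k <- round(dropout_rate * nrow(hits))
    if (k >= nrow(hits)) hits <- hits[0, , drop = FALSE]
    else if (k > 0) hits <- hits[-sample(nrow(hits), k), , drop = FALSE]
  }
  rownames(markers) <- rownames(hits) <- NULL
  list(markers = markers, hits = hits)
}

paf_row <- function(query, query_len, q1, q2, strand, target, target_len,
                    t1, t2) {
  data.frame(query = query, query_len = query_len, query_start = q1,
             query_end = q2, strand = strand, target = target,
             target_len = target_len, target_start = t1, target_end = t2,
             matches = q2 - q1, block_len = q2 - q1, mapq = 60L,
             stringsAsFactors = FALSE)
}

#' Simulate two patch assemblies with engineered gap-spanning geometry
#'
#' Every ordinary draft gap is assigned a case from `case_cycle` in
#' deterministic rotation: qualifying spans from assembly A, B or both,
#' the exact-boundary cases (flanks of exactly `min_flank` bp; an edge
#' distance of `max_distance + 1`), or no span at all.  Planted collapses
#' alternate between an agreeing pair (confirmable) and a size-disagreeing
#' pair.  Patch contigs are copied from the truth genome; their PAF
#' alignments are computed from the construction.
#'
#' @param truth Output of [simulate_genome()].
#' @param draft Output of [fragment_assembly()].
#' @param seed Integer seed.
#' @param min_flank,max_distance The spanning-rule thresholds the boundary
#'   cases are built against (defaults 5000 and 10).
#' @param case_cycle Character vector of case labels to rotate through.
#' @return List with per-assembly `contigs`/`paf` under `A` and `B`,
#'   `gap_cases`, `collapse_cases` and `negative_gaps`.
#' @export
simulate_patch_assemblies <- function(truth, draft, seed = 1L,
                                      min_flank = 5000L, max_distance = 10L,
                                      case_cycle = c("spannable_A",
                                                     "spannable_B",
                                                     "spannable_both",
                                                     "flank_5000_exact",
                                                     "distance_11",
                                                     "unspanned")) {
  set.seed(seed)
  out <- list(A = list(contigs = character(0), paf = empty_paf()),
              B = list(contigs = character(0), paf = empty_paf()))
  add_patch <- function(asm, gap, f, d, tag) {
    # gap: one row of draft$gaps; f, d: length-2 aligned-flank sizes and
    # edge distances (left/right in TRUTH orientation)
    part <- draft$parts[draft$parts$scaffold == gap$scaffold &
                          draft$parts$chrom == gap$chrom &
                          draft$parts$t_start <= gap$t_start &
                          draft$parts$t_end >= gap$t_end, , drop = FALSE][1, ]
    chrom_seq <- truth$sequences[[gap$chrom]]
    lo <- gap$t_start - d[1] - f[1]
    hi <- gap$t_end + d[2] + f[2]
    stopifnot(lo >= 0, hi <= nchar(chrom_seq))
    pname <- sprintf("patch%s_%s", asm, tag)
    pseq <- substr(chrom_seq, lo + 1, hi)
    tlen <- nchar(draft$scaffolds[[gap$scaffold]])
    blk <- function(t1, t2) {
      m <- part_map_interval(part, t1, t2)
      paf_row(pname, hi - lo, t1 - lo, t2 - lo, m$strand, gap$scaffold,
              tlen, m$start, m$end)
    }
    rows <- rbind(blk(lo, gap$t_start - d[1]),
                  blk(gap$t_end + d[2], hi))
    out[[asm]]$contigs[pname] <<- pseq
    out[[asm]]$paf <<- rbind(out[[asm]]$paf, rows)
    pname
  }

  gap_cases <- NULL
  g <- draft$gaps
  if (!is.null(g)) {
    g <- g[g$kind == "ordinary", , drop = FALSE]
    g <- g[order(g$scaffold, g$s_start), , drop = FALSE]
    cases <- rep(case_cycle, length.out = nrow(g))
    for (i in seq_len(nrow(g))) {
      gi <- g[i, , drop = FALSE]
      tag <- sprintf("g%03d", i)
      case <- cases[i]
      if (case %in% c("spannable_A", "spannable_both"))
        add_patch("A", gi, f = sample(6000:8000, 2), d = sample(0:5, 2),
                  tag = tag)
      if (case %in% c("spannable_B", "spannable_both"))
        add_patch("B", gi, f = sample(9000:9500, 2), d = sample(0:5, 2),
                  tag = tag)
      if (case == "flank_5000_exact")
        add_patch("A", gi, f = c(min_flank, min_flank), d = c(0L, 0L),
                  tag = tag)
      if (case == "distance_11")
        add_patch("A", gi, f = c(7000L, 7000L),
                  d = c(max_distance + 1L, 0L), tag = tag)
    }
    gap_cases <- data.frame(scaffold = g$scaffold, start = g$s_start,
                            end = g$s_end, case = cases,
                            stringsAsFactors = FALSE)
  }

  collapse_cases <- NULL
  if (!is.null(draft$collapses) && nrow(draft$collapses)) {
    cc <- draft$collapses
    cases <- rep(c("negative_agreeing", "negative_disagreeing"),
                 length.out = nrow(cc))
    f <- 7000L
    for (i in seq_len(nrow(cc))) {
      r <- cc[i, ]
      tag <- sprintf("c%03d", i)
      chrom_seq <- truth$sequences[[r$chrom]]
      tlen <- nchar(draft$scaffolds[[r$scaffold]])
      # assembly A: exact evidence implying +size at s_pos
      pa <- sprintf("patchA_%s", tag)
      out$A$contigs[pa] <- substr(chrom_seq, r$t_pos - f + 1,
                                  r$t_pos + r$size + f)
      out$A$paf <- rbind(out$A$paf,
        paf_row(pa, 2 * f + r$size, 0L, f, "+", r$scaffold, tlen,
                r$s_pos - f, r$s_pos),
        paf_row(pa, 2 * f + r$size, f + r$size, 2L * f + r$size, "+",
                r$scaffold, tlen, r$s_pos, r$s_pos + f))
      pb <- sprintf("patchB_%s", tag)
      if (cases[i] == "negative_agreeing") {
        # same patch, left block truncated by 8 bp: position shifts within
        # tolerance, implied size unchanged
        out$B$contigs[pb] <- substr(chrom_seq, r$t_pos - f + 1,
                                    r$t_pos + r$size + f)
        out$B$paf <- rbind(out$B$paf,
          paf_row(pb, 2 * f + r$size, 0L, f - 8L, "+", r$scaffold, tlen,
                  r$s_pos - f, r$s_pos - 8L),
          paf_row(pb, 2 * f + r$size, f + r$size, 2L * f + r$size, "+",
                  r$scaffold, tlen, r$s_pos, r$s_pos + f))
      } else {
        # 400 extra bases in the fill: implied size disagrees
        extra <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                       collapse = "")
        out$B$contigs[pb] <- paste0(
          substr(chrom_seq, r$t_pos - f + 1, r$t_pos), extra,
          substr(chrom_seq, r$t_pos + 1, r$t_pos + r$size),
          substr(chrom_seq, r$t_pos + r$size + 1, r$t_pos + r$size + f))
        qlen <- 2L * f + r$size + 400L
        out$B$paf <- rbind(out$B$paf,
          paf_row(pb, qlen, 0L, f, "+", r$scaffold, tlen, r$s_pos - f,
                  r$s_pos),
          paf_row(pb, qlen, f + r$size + 400L, qlen, "+", r$scaffold,
                  tlen, r$s_pos, r$s_pos + f))
      }
    }
    collapse_cases <- data.frame(scaffold = cc$scaffold, pos = cc$s_pos,
                                 size = cc$size, case = cases,
                                 stringsAsFactors = FALSE)
  }
  list(A = out$A, B = out$B, gap_cases = gap_cases,
       collapse_cases = collapse_cases,
       negative_gaps = draft$negative_gaps)
}

#' Simulate a variant-call table with an exact planted error-base total
#'
#' Records are generated so the default error-base convention (PASS
#' records, `max(nchar(ref), nchar(alt))` per record) sums exactly to
#' `round(assessed_bases * error_rate)`.  About `indel_fraction` of records
#' are 2-5 bp indels; a handful of non-PASS decoy records are added and
#' must be ignored by the counting convention.
#'
#' @param assessed_bases Number of bases assessed.
#' @param error_rate Planted per-base error rate, in (0, 1).
#' @param indel_fraction Fraction of records that are indels (default 0.1).
#' @param seed Integer seed.
#' @return List with `variants`, `planted_error_bases`, `assessed_bases`
#'   and `error_rate`.
#' @export
simulate_variant_calls <- function(assessed_bases, error_rate,
                                   indel_fraction = 0.1, seed = 1L) {
  stopifnot(error_rate > 0, error_rate < 1)
  set.seed(seed)
  target <- round(assessed_bases * error_rate)
  sizes <- integer(0)
  remaining <- target
  buf <- integer(target)
  n <- 0L
  while (remaining > 0) {
    s <- if (remaining >= 6 && stats::runif(1) < indel_fraction)
      sample(3:6, 1) else 1L
    n <- n + 1L
    buf[n] <- s
    remaining <- remaining - s
  }
  sizes <- buf[seq_len(n)]
  n_decoy <- max(1L, round(0.05 * n))
  pos <- sort(sample.int(assessed_bases - 10L, n + n_decoy))
  bases <- c("A", "C", "G", "T")
  mk_alleles <- function(s) {
    if (s == 1) {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
    } else if (stats::runif(1) < 0.5) {  # deletion of s-1 bases
      ref <- paste(sample(bases, s, replace = TRUE), collapse = "")
      alt <- substr(ref, 1, 1)
    } else {                             # insertion of s-1 bases
      alt <- paste(sample(bases, s, replace = TRUE), collapse = "")
      ref <- substr(alt, 1, 1)
    }
    c(ref, alt)
  }
  all_sizes <- c(sizes, sample(c(1L, 3L), n_decoy, replace = TRUE))
  al <- vapply(all_sizes, mk_alleles, character(2))
  filt <- c(rep("PASS", n), rep("LowQual", n_decoy))
  ord <- sample(n + n_decoy)   # interleave decoys among PASS records
  variants <- data.frame(scaffold = "seq1", position = pos,
                         ref_allele = al[1, ord], alt_allele = al[2, ord],
                         genotype = sample(c("het", "hom_alt"), n + n_decoy,
                                           replace = TRUE),
                         filter = filt[ord], stringsAsFactors = FALSE)
  list(variants = variants, planted_error_bases = target,
       assessed_bases = assessed_bases, error_rate = error_rate)
}

#' Build a complete synthetic truth set
#'
#' Runs the genome, fragmentation, genetic-map, patch-assembly and
#' variant-call simulators with linked seeds and (optionally) writes the
#' fixture directory consumed by the pipeline subcommands.
#'
#' @param seed Master seed; sub-simulators use `seed + 1 .. seed + 4`.
#' @param out_dir Optional directory to write the fixture into.
#' @param n_chromosomes,chrom_length,n_genes See [simulate_genome()].
#' @param n_scaffolds_per_chrom,gaps_per_scaffold,n_misjoins,n_inversions,n_collapses
#'   See [fragment_assembly()].
#' @param markers_per_chrom,marker_len See [simulate_genetic_map()].
#' @param assessed_bases,error_rate,indel_fraction See
#'   [simulate_variant_calls()].
#' @return A truth-set list with components `truth`, `draft`, `map`,
#'   `patches`, `variants` and `seed`.
#' @export
simulate_truth_set <- function(seed = 42L, out_dir = NULL,
                               n_chromosomes = 3L, chrom_length = 2e6,
                               n_genes = 60L, n_scaffolds_per_chrom = 4L,
                               gaps_per_scaffold = 2L, n_misjoins = 3L,
                               n_inversions = 2L, n_collapses = 2L,
                               markers_per_chrom = 40L, marker_len = 60L,
                               assessed_bases = 2e7, error_rate = 5e-4,
                               indel_fraction = 0.1) {
  truth <- simulate_genome(seed, n_chromosomes, chrom_length, n_genes)
  draft <- fragment_assembly(truth,
                             n_scaffolds_per_chrom = n_scaffolds_per_chrom,
                             gaps_per_scaffold = gaps_per_scaffold,
                             n_misjoins = n_misjoins,
                             n_inversions = n_inversions,
                             n_collapses = n_collapses, seed = seed + 1L)
  map <- simulate_genetic_map(truth, draft,
                              markers_per_chrom = markers_per_chrom,
                              marker_len = marker_len, seed = seed + 2L)
  patches <- simulate_patch_assemblies(truth, draft, seed = seed + 3L)
  variants <- simulate_variant_calls(assessed_bases, error_rate,
                                     indel_fraction, seed = seed + 4L)
  ts <- list(truth = truth, draft = draft, map = map, patches = patches,
             variants = variants, seed = seed)
  if (!is.null(out_dir)) write_truth_set(ts, out_dir)
  ts
}

#' Write a truth set as a fixture directory
#'
#' Emits `truth/` (genome FASTA, GFF3, repeat BED), `draft/` (scaffold and
#' contig FASTA, AGP, negative-gap TSV), `map/` (marker and hit TSV),
#' `patches/` (two patch FASTA + PAF pairs), `variants/calls.vcf` and a
#' `truth.json` manifest of every planted fact.  Same truth set, same
#' bytes.
#'
#' @param ts Truth set from [simulate_truth_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_truth_set <- function(ts, dir) {
  for (d in c("truth", "draft", "map", "patches", "variants"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  write_fasta(ts$truth$sequences, file.path(dir, "truth", "genome.fa"))
  write_gff3(ts$truth$genes, file.path(dir, "truth", "genes.gff3"))
  writeLines(with(ts$truth$repeats, paste(chrom, start, end, class,
                                          sep = "\t")),
             file.path(dir, "truth", "repeats.bed"))
  write_fasta(ts$draft$scaffolds, file.path(dir, "draft", "scaffolds.fa"))
  write_fasta(ts$draft$contigs, file.path(dir, "draft", "contigs.fa"))
  write_agp(ts$draft$layouts, file.path(dir, "draft", "draft.agp"))
  if (!is.null(ts$draft$negative_gaps))
    write_negative_gaps(ts$draft$negative_gaps,
                        file.path(dir, "draft", "negative_gaps.tsv"))
  write_tsv_plain(ts$map$markers[, c("marker_id", "linkage_group",
                                     "map_order", "map_position",
                                     "sequence")],
                  file.path(dir, "map", "markers.tsv"))
  write_tsv_plain(ts$map$hits, file.path(dir, "map", "hits.tsv"))
  for (asm in c("A", "B")) {
    write_fasta(ts$patches[[asm]]$contigs,
                file.path(dir, "patches", sprintf("patch%s.fa", asm)))
    write_paf(ts$patches[[asm]]$paf,
              file.path(dir, "patches", sprintf("patch%s.paf", asm)))
  }
  write_vcf(ts$variants$variants, file.path(dir, "variants", "calls.vcf"),
            contigs = c(seq1 = ts$variants$assessed_bases))
  manifest <- list(
    seed = ts$seed,
    n_chromosomes = length(ts$truth$sequences),
    chrom_length = nchar(ts$truth$sequences[[1]]),
    assignments = ts$draft$assignments,
    parts = ts$draft$parts,
    misjoins = ts$draft$misjoins,
    collapses = ts$draft$collapses,
    gap_cases = ts$patches$gap_cases,
    collapse_cases = ts$patches$collapse_cases,
    planted_error_bases = ts$variants$planted_error_bases,
    assessed_bases = ts$variants$assessed_bases,
    error_rate = ts$variants$error_rate,
    n_markers = nrow(ts$map$markers))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
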