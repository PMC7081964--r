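# Gap filling with independent patch assemblies.  A gap is closed when a
# patch contig aligns on both sides of it with more than `min_flank` bases
# per flank, ending at most `max_distance` bases from the gap edge.
# Negative gaps (collapses) are only confirmed, never spliced: both patch
# assemblies must agree on the position and size of the implied insertion.

#' Collect gap-spanning evidence from patch alignments
#'
#' For each gap and each patch contig/strand, pairs the nearest alignment
#' blocks left and right of the gap and records flank lengths (aligned bases
#' in the flanking block), edge distances, the implied patch fill interval
#' and, for collapse assessment, the implied insertion position and size.
#' A single block crossing the whole gap is the strongest possible evidence
#' and is treated as two flanks with zero edge distance.
#'
#' @param gaps Data frame of gap records (`scaffold`, 0-based half-open
#'   `start`, `end`; negative gaps have `start == end`).
#' @param alignments PAF-style alignment blocks (see [read_paf()]) with the
#'   scaffolded assembly as target.
#' @param assembly_id Label of the patch assembly the alignments come from.
#' @param min_flank Flank threshold in bp; the rule is strict (`> min_flank`).
#' @param max_distance Maximum distance in bp from block end to gap edge
#'   (inclusive).
#' @param known_scaffolds Optional character vector; an alignment targeting
#'   a scaffold outside it is an error.
#' @return Data frame of evidence rows with a logical `qualifying` column.
#' @export
collect_span_evidence <- function(gaps, alignments, assembly_id = "A",
                                  min_flank = 5000L, max_distance = 10L,
                                  known_scaffolds = NULL) {
  if (!is.null(known_scaffolds)) {
    bad <- setdiff(unique(alignments$target), known_scaffolds)
    if (length(bad))
      stop("alignment references unknown scaffold: ", bad[1])
  }
  rows <- list()
  for (gi in seq_len(nrow(gaps))) {
    gs <- gaps$start[gi]; ge <- gaps$end[gi]; scf <- gaps$scaffold[gi]
    al <- alignments[alignments$target == scf, , drop = FALSE]
    if (nrow(al) == 0) next
    for (key in unique(paste(al$query, al$strand))) {
      a <- al[paste(al$query, al$strand) == key, , drop = FALSE]
      strand <- a$strand[1]
      span <- a[a$target_start < gs & a$target_end > ge, , drop = FALSE]
      if (nrow(span)) {
        # one contiguous block crossing the gap
        b <- span[which.max(b_len <- span$block_len), , drop = FALSE]
        lf <- gs - b$target_start; rf <- b$target_end - ge
        if (strand == "+") {
          fs <- b$query_start + (gs - b$target_start)
          fe <- b$query_end - (b$target_end - ge)
        } else {
          fs <- b$query_start + (b$target_end - ge)
          fe <- b$query_end - (gs - b$target_start)
        }
        rows[[length(rows) + 1]] <- data.frame(
          scaffold = scf, gap_start = gs, gap_end = ge,
          assembly = assembly_id, patch_contig = b$query, strand = strand,
          left_flank = lf, right_flank = rf, left_distance = 0L,
          right_distance = 0L, splice_start = gs, splice_end = ge,
          fill_start = fs, fill_end = fe, strand_consistent = fs <= fe,
          stringsAsFactors = FALSE)
        next
      }
      lefts <- a[a$target_end <= gs, , drop = FALSE]
      rights <- a[a$target_start >= ge, , drop = FALSE]
      if (nrow(lefts) == 0 || nrow(rights) == 0) next
      lb <- lefts[which.max(lefts$target_end), , drop = FALSE]
      rb <- rights[which.min(rights$target_start), , drop = FALSE]
      if (strand == "+") {
        fs <- lb$query_end; fe <- rb$query_start
      } else {
        fs <- rb$query_end; fe <- lb$query_start
      }
      rows[[length(rows) + 1]] <- data.frame(
        scaffold = scf, gap_start = gs, gap_end = ge,
        assembly = assembly_id, patch_contig = lb$query, strand = strand,
        left_flank = lb$block_len, right_flank = rb$block_len,
        left_distance = gs - lb$target_end,
        right_distance = rb$target_start - ge,
        splice_start = lb$target_end, splice_end = rb$target_start,
        fill_start = fs, fill_end = fe, strand_consistent = fs <= fe,
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else data.frame(
    scaffold = character(0), gap_start = integer(0), gap_end = integer(0),
    assembly = character(0), patch_contig = character(0),
    strand = character(0), left_flank = integer(0), right_flank = integer(0),
    left_distance = integer(0), right_distance = integer(0),
    splice_start = integer(0), splice_end = integer(0),
    fill_start = integer(0), fill_end = integer(0),
    strand_consistent = logical(0))
  ev$implied_pos <- ev$splice_start
  ev$implied_size <- (ev$fill_end - ev$fill_start) -
    (ev$splice_end - ev$splice_start)
  ev$qualifying <- ev$strand_consistent &
    ev$left_flank > min_flank & ev$right_flank > min_flank &
    ev$left_distance <= max_distance & ev$right_distance <= max_distance
  rownames(ev) <- NULL
  ev
}

#' Decide fill status for positive gaps
#'
#' A gap is filled if any single patch assembly supplies qualifying
#' evidence.  When several do, the evidence with the longer minimum flank
#' wins; ties break on lexicographic assembly id, then patch contig name.
#'
#' @param gaps Positive gap records (`scaffold`, `start`, `end`).
#' @param evidence Evidence rows from [collect_span_evidence()] (all
#'   assemblies combined).
#' @return Data frame of per-gap decisions with `status`
#'   ("filled"/"unfilled"), provenance columns and `fill_len`.
#' @export
decide_fill <- function(gaps, evidence) {
  out <- list()
  for (gi in seq_len(nrow(gaps))) {
    gs <- gaps$start[gi]; scf <- gaps$scaffold[gi]
    ev <- evidence[evidence$scaffold == scf & evidence$gap_start == gs &
                     evidence$qualifying, , drop = FALSE]
    if (nrow(ev) == 0) {
      out[[gi]] <- data.frame(
        scaffold = scf, gap_start = gs, gap_end = gaps$end[gi],
        status = "unfilled", assembly = NA_character_,
        patch_contig = NA_character_, strand = NA_character_,
        left_flank = NA_integer_, right_flank = NA_integer_,
        left_distance = NA_integer_, right_distance = NA_integer_,
        splice_start = NA_integer_, splice_end = NA_integer_,
        fill_start = NA_integer_, fill_end = NA_integer_,
        fill_len = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    minfl <- pmin(ev$left_flank, ev$right_flank)
    ev <- ev[order(-minfl, ev$assembly, ev$patch_contig), , drop = FALSE]
    best <- ev[1, , drop = FALSE]
    out[[gi]] <- data.frame(
      scaffold = scf, gap_start = gs, gap_end = gaps$end[gi],
      status = "filled", assembly = best$assembly,
      patch_contig = best$patch_contig, strand = best$strand,
      left_flank = best$left_flank, right_flank = best$right_flank,
      left_distance = best$left_distance,
      right_distance = best$right_distance,
      splice_start = best$splice_start, splice_end = best$splice_end,
      fill_start = best$fill_start, fill_end = best$fill_end,
      fill_len = best$fill_end - best$fill_start, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confirm a collapse (negative gap) by cross-assembly agreement
#'
#' A collapse is confirmed only when two distinct patch assemblies imply an
#' insertion at positions within `pos_tol` of each other and of sizes within
#' `max(size_tol_abs, size_tol_frac * larger size)`.
#'
#' @param negative_gap One gap record with `declared_length < 0` and
#'   `start == end`.
#' @param evidence Evidence rows for that gap from [collect_span_evidence()]
#'   (all assemblies combined).
#' @param pos_tol Position agreement tolerance in bp (default 20).
#' @param size_tol_abs Absolute size tolerance in bp (default 20).
#' @param size_tol_frac Relative size tolerance (default 0.10).
#' @return One-row decision data frame with `status`
#'   ("collapse_confirmed"/"collapse_unconfirmed") and the per-assembly
#'   implied positions/sizes.
#' @export
confirm_collapse <- function(negative_gap, evidence, pos_tol = 20L,
                             size_tol_abs = 20L, size_tol_frac = 0.10) {
  stopifnot(negative_gap$declared_length < 0,
            negative_gap$start == negative_gap$end)
  ev <- evidence[evidence$scaffold == negative_gap$scaffold &
                   evidence$gap_start == negative_gap$start &
                   evidence$qualifying, , drop = FALSE]
  best_per_asm <- lapply(split(ev, ev$assembly), function(e) {
    e[which.max(pmin(e$left_flank, e$right_flank)), , drop = FALSE]
  })
  status <- "collapse_unconfirmed"
  pos <- size <- c(NA_real_, NA_real_)
  asm <- c(NA_character_, NA_character_)
  if (length(best_per_asm) >= 2) {
    pair <- do.call(rbind, best_per_asm[order(names(best_per_asm))][1:2])
    pos <- pair$implied_pos; size <- pair$implied_size
    asm <- pair$assembly
    size_tol <- max(size_tol_abs, size_tol_frac * max(abs(size)))
    if (abs(pos[1] - pos[2]) <= pos_tol && abs(size[1] - size[2]) <= size_tol)
      status <- "collapse_confirmed"
  }
  data.frame(scaffold = negative_gap$scaffold,
             gap_start = negative_gap$start, gap_end = negative_gap$end,
             declared_length = negative_gap$declared_length, status = status,
             assembly_1 = asm[1], pos_1 = pos[1], size_1 = size[1],
             assembly_2 = asm[2], pos_2 = pos[2], size_2 = size[2],
             stringsAsFactors = FALSE)
}

# merge the components overlapping a splice into one contig component
splice_layout <- function(layout, splice_start, splice_end, fill_len, new_id) {
  cmp <- layout$components
  delta <- fill_len - (splice_end - splice_start)
  i_left <- which(cmp$kind == "contig" & cmp$object_start < splice_start &
                    cmp$object_end >= splice_start)
  i_right <- which(cmp$kind == "contig" & cmp$object_start <= splice_end &
                     cmp$object_end > splice_end)
  if (length(i_left) != 1 || length(i_right) != 1 || i_left >= i_right)
    stop("splice points do not bracket a gap in ", layout$name)
  gaps_removed <- sum(cmp$kind[i_left:i_right] == "gap")
  new_start <- cmp$object_start[i_left]
  new_end <- cmp$object_end[i_right] + delta
  merged <- contig_component(new_start, new_id, 0L, new_end - new_start)
  before <- cmp[seq_len(i_left - 1), , drop = FALSE]
  after <- cmp[seq(i_right + 1, length.out = nrow(cmp) - i_right), ,
               drop = FALSE]
  if (nrow(after)) {
    after$object_start <- after$object_start + delta
    after$object_end <- after$object_end + delta
  }
  list(layout = scaffold_layout(layout$name, rbind(before, merged, after)),
       removed_ids = cmp$component_id[i_left:i_right][
         cmp$kind[i_left:i_right] == "contig"],
       new_span = c(new_start, new_end), gaps_removed = gaps_removed)
}

#' Apply fill decisions to layouts and sequences
#'
#' Each filled gap is replaced by the patch interval sequence
#' (reverse-complemented for `-` strand evidence); the two flanking contigs
#' and the fill merge into a single contig component.  Bases outside the
#' spliced regions are untouched.
#'
#' @param layouts Named list of [scaffold_layout()] objects.
#' @param sequences Named character vector of scaffold sequences.
#' @param patch_sequences Named character vector of patch contig sequences.
#' @param decisions Decision rows from [decide_fill()]; only rows with
#'   `status == "filled"` are applied.
#' @return List with updated `layouts`, `sequences`, `contigs` (named vector
#'   of new merged contig sequences, keyed by their component ids) and a
#'   `summary` list (gap/contig counts before and after, bases added).
#' @export
apply_fills <- function(layouts, sequences, patch_sequences, decisions) {
  filled <- decisions[decisions$status == "filled", , drop = FALSE]
  count_gaps <- function(ls) sum(vapply(ls, function(l)
    sum(l$components$kind == "gap"), numeric(1)))
  count_contigs <- function(ls) sum(vapply(ls, function(l)
    sum(l$components$kind == "contig"), numeric(1)))
  summary <- list(gaps_before = count_gaps(layouts),
                  contigs_before = count_contigs(layouts),
                  n_filled = nrow(filled), bases_added = 0L)
  new_contigs <- character(0)
  fill_i <- 0L
  if (nrow(filled)) {
    missing <- setdiff(unique(filled$patch_contig), names(patch_sequences))
    if (length(missing))
      stop("patch contig missing from patch sequences: ", missing[1])
    for (scf in unique(filled$scaffold)) {
      d <- filled[filled$scaffold == scf, , drop = FALSE]
      d <- d[order(-d$splice_start), , drop = FALSE]  # right to left
      seq <- sequences[[scf]]
      for (i in seq_len(nrow(d))) {
        fill_i <- fill_i + 1L
        fill_seq <- substr(patch_sequences[[d$patch_contig[i]]],
                           d$fill_start[i] + 1, d$fill_end[i])
        if (d$strand[i] == "-") fill_seq <- revcomp(fill_seq)
        seq <- paste0(substr(seq, 1, d$splice_start[i]), fill_seq,
                      substring(seq, d$splice_end[i] + 1))
        new_id <- sprintf("%s_fill%d", scf, fill_i)
        sp <- splice_layout(layouts[[scf]], d$splice_start[i],
                            d$splice_end[i], nchar(fill_seq), new_id)
        layouts[[scf]] <- sp$layout
        summary$bases_added <- summary$bases_added + nchar(fill_seq) -
          (d$splice_end[i] - d$splice_start[i])
        new_contigs[new_id] <- NA_character_
      }
      sequences[[scf]] <- seq
    }
    # extract merged contig sequences from the updated scaffolds
    for (scf in unique(filled$scaffold)) {
      cmp <- layouts[[scf]]$components
      for (j in which(cmp$kind == "contig" &
                        cmp$component_id %in% names(new_contigs))) {
        new_contigs[cmp$component_id[j]] <-
          substr(sequences[[scf]], cmp$object_start[j] + 1, cmp$object_end[j])
      }
    }
    new_contigs <- new_contigs[!is.na(new_contigs)]
  }
  summary$gaps_after <- count_gaps(layouts)
  summary$contigs_after <- count_contigs(layouts)
  list(layouts = layouts, sequences = sequences, contigs = new_contigs,
       summary = summary)
}

#' Run the full gap-filling stage
#'
#' Collects spanning evidence from each patch assembly, decides every
#' positive gap, confirms or rejects negative gaps (collapses), and applies
#' the fills.
#'
#' @param layouts Named list of [scaffold_layout()] objects.
#' @param sequences Named character vector of scaffold sequences.
#' @param patches Named list, one entry per patch assembly, each a list with
#'   `contigs` (named character vector) and `paf` (alignment blocks against
#'   the scaffolds).
#' @param negative_gaps Optional data frame of collapse records (see
#'   [read_negative_gaps()]).
#' @param config Pipeline configuration (see [default_config()]).
#' @return List with `layouts`, `sequences`, `contigs`, `decisions`,
#'   `collapse_decisions`, `evidence` and `summary`.
#' @export
gap_fill <- function(layouts, sequences, patches, negative_gaps = NULL,
                     config = default_config()) {
  gaps <- do.call(rbind, c(lapply(layouts, gaps_from_layout),
                           make.row.names = FALSE))
  all_gaps <- gaps[, c("scaffold", "start", "end")]
  if (!is.null(negative_gaps) && nrow(negative_gaps))
    all_gaps <- rbind(all_gaps,
                      negative_gaps[, c("scaffold", "start", "end")])
  evidence <- do.call(rbind, lapply(names(patches), function(id) {
    collect_span_evidence(all_gaps, patches[[id]]$paf, id,
                          min_flank = config$min_flank,
                          max_distance = config$max_distance,
                          known_scaffolds = names(layouts))
  }))
  decisions <- decide_fill(gaps, evidence)
  collapse_decisions <- NULL
  if (!is.null(negative_gaps) && nrow(negative_gaps)) {
    collapse_decisions <- do.call(rbind, lapply(
      seq_len(nrow(negative_gaps)), function(i)
        confirm_collapse(negative_gaps[i, , drop = FALSE], evidence,
                         pos_tol = config$collapse_pos_tol,
                         size_tol_abs = config$collapse_size_tol_abs,
                         size_tol_frac = config$collapse_size_tol_frac)))
  }
  patch_seqs <- do.call(c, unname(lapply(patches, `[[`, "contigs")))
  applied <- apply_fills(layouts, sequences, patch_seqs, decisions)
  list(layouts = applied$layouts, sequences = applied$sequences,
       contigs = applied$contigs, decisions = decisions,
       collapse_decisions = collapse_decisions, evidence = evidence,
       summary = applied$summary)
}
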