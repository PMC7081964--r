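# Genetic-map-guided scaffolding: filter marker alignments, detect and break
# inter-linkage-group chimeras, orient and order scaffolds by rank
# correlation with the map, and assemble chromosome-scale layouts.

#' Filter raw marker alignments
#'
#' Retains hits with mapping identity at or above `min_identity` (default
#' 0.98), full-length marker coverage when `require_full_length`, and a
#' single genomic placement when `unique_only`.  At most one hit per marker
#' survives: with `unique_only` markers hit more than once are discarded,
#' otherwise the highest-identity hit is kept.
#'
#' @param hits Data frame with `marker_id`, `scaffold`, `position`,
#'   `identity`, `coverage`, `n_placements` columns.
#' @param min_identity Minimum alignment identity, in `(0, 1]`.
#' @param require_full_length Require `coverage == 1`.
#' @param unique_only Require `n_placements == 1`.
#' @return The retained subset of `hits`.
#' @export
filter_marker_hits <- function(hits, min_identity = 0.98,
                               require_full_length = TRUE,
                               unique_only = TRUE) {
  if (!is.numeric(min_identity) || length(min_identity) != 1 ||
      min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  keep <- hits$identity >= min_identity
  if (require_full_length) keep <- keep & hits$coverage == 1
  if (unique_only) keep <- keep & hits$n_placements == 1
  out <- hits[keep, , drop = FALSE]
  dup <- out$marker_id[duplicated(out$marker_id)]
  if (length(dup)) {
    if (unique_only) {
      out <- out[!out$marker_id %in% dup, , drop = FALSE]
    } else {
      out <- out[order(out$marker_id, -out$identity), , drop = FALSE]
      out <- out[!duplicated(out$marker_id), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

join_linkage_groups <- function(hits, markers) {
  idx <- match(hits$marker_id, markers$marker_id)
  if (anyNA(idx))
    stop("marker hit references unknown marker: ",
         hits$marker_id[which(is.na(idx))[1]])
  hits$linkage_group <- markers$linkage_group[idx]
  hits$map_order <- markers$map_order[idx]
  hits$map_position <- markers$map_position[idx]
  hits
}

#' Detect inter-linkage-group chimeric scaffolds
#'
#' A scaffold is flagged when markers from two or more linkage groups map to
#' it and every non-dominant group contributes at least
#' `min_conflict_markers` hits (a single stray marker is treated as
#' mismapping noise).  One breakpoint is placed at the midpoint between the
#' last hit of one maximal same-group run and the first hit of the next;
#' when `layouts` are supplied and a gap component lies between those two
#' hits, the breakpoint snaps into the gap closest to the midpoint (gaps are
#' the least destructive split sites).
#'
#' @param hits Filtered marker hits (see [filter_marker_hits()]).
#' @param markers Marker table carrying `linkage_group` per `marker_id`.
#' @param min_conflict_markers Minimum hits a minority linkage group needs
#'   to count as real conflict (default 2).
#' @param layouts Optional named list of [scaffold_layout()] objects used to
#'   snap breakpoints into gaps.
#' @return List of break decisions: `scaffold`, `breakpoints`,
#'   `segment_groups` (linkage group per resulting segment) and `evidence`
#'   (marker ids per segment).  Scaffolds without conflict are absent.
#' @export
detect_chimeras <- function(hits, markers, min_conflict_markers = 2L,
                            layouts = NULL) {
  hits <- join_linkage_groups(hits, markers)
  decisions <- list()
  for (scf in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == scf, , drop = FALSE]
    tab <- sort(table(h$linkage_group), decreasing = TRUE)
    qual <- names(tab)[tab >= min_conflict_markers]
    qual <- union(names(tab)[1], qual)   # dominant group always qualifies
    if (length(qual) < 2) next
    h <- h[h$linkage_group %in% qual, , drop = FALSE]
    h <- h[order(h$position), , drop = FALSE]
    run_id <- cumsum(c(1L, h$linkage_group[-1] != h$linkage_group[-nrow(h)]))
    n_runs <- max(run_id)
    if (n_runs < 2) next
    bps <- integer(n_runs - 1)
    for (r in seq_len(n_runs - 1)) {
      left <- max(h$position[run_id == r])
      right <- min(h$position[run_id == r + 1])
      mid <- (left + right) %/% 2L
      bp <- mid
      if (!is.null(layouts) && scf %in% names(layouts)) {
        cmp <- layouts[[scf]]$components
        g <- cmp[cmp$kind == "gap" & cmp$object_start > left &
                   cmp$object_end < right, , drop = FALSE]
        if (nrow(g)) {
          gm <- (g$object_start + g$object_end) %/% 2L
          bp <- gm[which.min(abs(gm - mid))]
        }
      }
      bps[r] <- bp
    }
    decisions[[length(decisions) + 1]] <- list(
      scaffold = scf, breakpoints = bps,
      segment_groups = h$linkage_group[!duplicated(run_id)],
      evidence = split(h$marker_id, run_id))
  }
  decisions
}

#' Orient and order one scaffold (or segment) against the genetic map
#'
#' The Pearson correlation between the rank order of hit positions along the
#' segment and the map order of the corresponding markers decides
#' orientation: `+` for positive correlation, `-` for negative, `unknown`
#' when fewer than two markers are present, the correlation is zero, or
#' either rank vector is constant.  The ordering key is the median map
#' position (cM) of the segment's markers.
#'
#' @param seg_hits Marker hits of a single scaffold/segment, all from one
#'   linkage group (run [detect_chimeras()] and break first).
#' @param markers Marker table.
#' @return One-row data frame: `scaffold`, `linkage_group`, `orientation`,
#'   `order_key`, `pearson_r`, `n_markers`.
#' @export
orient_and_order <- function(seg_hits, markers) {
  h <- join_linkage_groups(seg_hits, markers)
  if (length(unique(h$scaffold)) != 1)
    stop("orient_and_order expects hits from a single scaffold")
  if (length(unique(h$linkage_group)) != 1)
    stop("hits span multiple linkage groups; run detect_chimeras first")
  n <- nrow(h)
  r <- NA_real_
  if (n >= 2) {
    pr <- rank(h$position)
    mr <- rank(h$map_order)
    if (stats::sd(pr) > 0 && stats::sd(mr) > 0)
      r <- stats::cor(pr, mr)
  }
  orientation <- if (is.na(r) || r == 0) "unknown" else if (r > 0) "+" else "-"
  data.frame(scaffold = h$scaffold[1], linkage_group = h$linkage_group[1],
             orientation = orientation,
             order_key = stats::median(h$map_position), pearson_r = r,
             n_markers = n, stringsAsFactors = FALSE)
}

#' Per-scaffold assignments for a hit table
#'
#' Applies [orient_and_order()] to each scaffold present in `hits`.
#'
#' @inheritParams orient_and_order
#' @param hits Filtered, linkage-group-consistent marker hits.
#' @return Data frame with one row per scaffold.
#' @export
assign_scaffolds <- function(hits, markers) {
  parts <- lapply(split(hits, hits$scaffold), orient_and_order,
                  markers = markers)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Assemble chromosome layouts from scaffold assignments
#'
#' Within each linkage group, segments are sorted by `order_key` (median
#' marker cM), ties broken by descending segment length then name.
#' Segments oriented `-` are reverse-complemented in the emitted layout;
#' segments with unknown orientation keep their input orientation.  A gap
#' component of `inter_scaffold_gap` bp (AGP gap type `"map"`) joins
#' consecutive segments.  Scaffolds without an assignment go to the
#' unplaced list.
#'
#' @param assignments Data frame from [assign_scaffolds()].
#' @param layouts Named list of [scaffold_layout()] objects covering every
#'   assigned scaffold.
#' @param inter_scaffold_gap Gap size in bp between joined segments
#'   (default 100).
#' @return List with `chromosomes` (named list of layouts, one per linkage
#'   group) and `unplaced` (character vector of scaffold names).
#' @export
build_chromosomes <- function(assignments, layouts, inter_scaffold_gap = 100L) {
  if (anyDuplicated(assignments$scaffold))
    stop("scaffold assigned more than once: ",
         assignments$scaffold[duplicated(assignments$scaffold)][1])
  missing <- setdiff(assignments$scaffold, names(layouts))
  if (length(missing))
    stop("assignment references unknown layout: ", missing[1])
  chromosomes <- list()
  emitted_order <- list()
  for (lg in sort(unique(assignments$linkage_group))) {
    a <- assignments[assignments$linkage_group == lg, , drop = FALSE]
    a$len <- vapply(layouts[a$scaffold], layout_length, numeric(1))
    a <- a[order(a$order_key, -a$len, a$scaffold), , drop = FALSE]
    parts <- list()
    for (i in seq_len(nrow(a))) {
      seg <- layouts[[a$scaffold[i]]]
      if (a$orientation[i] == "-") seg <- reverse_layout(seg)
      if (length(parts))
        parts[[length(parts) + 1]] <-
          gap_component(0L, as.integer(inter_scaffold_gap), "map")
      parts[[length(parts) + 1]] <- seg$components
    }
    cmp <- renumber_components(do.call(rbind, parts))
    chromosomes[[lg]] <- scaffold_layout(lg, cmp)
    emitted_order[[lg]] <- a$scaffold
  }
  list(chromosomes = chromosomes, order = emitted_order,
       unplaced = setdiff(names(layouts), assignments$scaffold))
}

#' Run the full map-guided scaffolding stage
#'
#' Filters raw hits, detects and breaks inter-linkage-group chimeras,
#' remaps hits onto the resulting segments, orients and orders every
#' marker-bearing segment, and assembles one chromosome layout per linkage
#' group.
#'
#' @param layouts Named list of draft [scaffold_layout()] objects.
#' @param raw_hits Raw marker-hit table (see [read_marker_hits()]).
#' @param markers Marker table (see [read_markers()]).
#' @param config Pipeline configuration (see [default_config()]); the
#'   relevant entries are `min_identity`, `require_full_length`,
#'   `unique_only`, `min_conflict_markers` and `inter_scaffold_gap`.
#' @return List with `chromosomes`, `unplaced`, `assignments`, `breaks`,
#'   and `segment_layouts` (all post-break layouts by name).
#' @export
map_guided_scaffold <- function(layouts, raw_hits, markers,
                                config = default_config()) {
  hits <- filter_marker_hits(raw_hits, config$min_identity,
                             config$require_full_length, config$unique_only)
  breaks <- detect_chimeras(hits, markers, config$min_conflict_markers,
                            layouts)
  seg_layouts <- layouts
  for (brk in breaks) {
    segs <- break_layout(layouts[[brk$scaffold]], brk$breakpoints)
    seg_layouts[[brk$scaffold]] <- NULL
    origins <- vapply(segs, attr, numeric(1), which = "origin")
    lens <- vapply(segs, layout_length, numeric(1))
    for (s in segs) seg_layouts[[s$name]] <- s
    # remap hit coordinates onto the segments
    on_scf <- which(hits$scaffold == brk$scaffold)
    if (length(on_scf)) {
      pos <- hits$position[on_scf]
      seg_idx <- rep(NA_integer_, length(pos))
      for (j in seq_along(segs))
        seg_idx[pos >= origins[j] & pos < origins[j] + lens[j]] <- j
      segnames <- vapply(segs, function(s) s$name, character(1))
      hit_in_seg <- !is.na(seg_idx)
      keep_rows <- on_scf[hit_in_seg]
      hits$scaffold[keep_rows] <- segnames[seg_idx[hit_in_seg]]
      hits$position[keep_rows] <- pos[hit_in_seg] - origins[seg_idx[hit_in_seg]]
      if (any(!hit_in_seg))
        hits <- hits[-on_scf[!hit_in_seg], , drop = FALSE]
    }
  }
  assignments <- if (nrow(hits)) assign_scaffolds(hits, markers) else
    data.frame(scaffold = character(0), linkage_group = character(0),
               orientation = character(0), order_key = numeric(0),
               pearson_r = numeric(0), n_markers = integer(0))
  built <- build_chromosomes(assignments, seg_layouts,
                             config$inter_scaffold_gap)
  list(chromosomes = built$chromosomes, order = built$order,
       unplaced = built$unplaced, assignments = assignments,
       breaks = breaks, segment_layouts = seg_layouts)
}
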