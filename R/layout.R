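# ScaffoldLayout: the AGP-equivalent description of one scaffold as an
# ordered tiling of contig and gap components.  All coordinates held here are
# 0-based half-open; conversion to AGP's 1-based inclusive convention happens
# only in read_agp()/write_agp().

#' Construct a scaffold layout
#'
#' @param name Scaffold name.
#' @param components Data frame with columns `kind` ("contig"/"gap"),
#'   `object_start`, `object_end` (0-based half-open scaffold coordinates),
#'   `component_id`, `component_start`, `component_end` (contig coordinates,
#'   `NA` for gaps), `orientation` ("+"/"-", `NA` for gaps), `gap_length`,
#'   `gap_type` ("scaffold", "map" or "contamination", `NA` for contigs).
#' @return An object of class `scaffold_layout`.
#' @export
scaffold_layout <- function(name, components) {
  components <- components[order(components$object_start), , drop = FALSE]
  rownames(components) <- NULL
  layout <- structure(list(name = name, components = components),
                      class = "scaffold_layout")
  validate_layout(layout)
  layout
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cmp <- x$components
  cat(sprintf("<scaffold_layout> %s: %d bp, %d contig(s), %d gap(s)\n",
              x$name, layout_length(x), sum(cmp$kind == "contig"),
              sum(cmp$kind == "gap")))
  invisible(x)
}

#' Total span of a layout in bp
#' @param layout A `scaffold_layout`.
#' @export
layout_length <- function(layout) {
  cmp <- layout$components
  if (nrow(cmp) == 0) 0L else max(cmp$object_end)
}

#' Validate the tiling invariants of a layout
#'
#' Components must tile `[0, length)` with no holes or overlaps, no two gap
#' components may be adjacent, the first and last components must be contigs,
#' and contig components must have matching object/component widths.
#'
#' @param layout A `scaffold_layout`.
#' @return Invisibly `TRUE`; otherwise an error naming the scaffold.
#' @export
validate_layout <- function(layout) {
  cmp <- layout$components
  nm <- layout$name
  if (nrow(cmp) == 0) stop("layout ", nm, ": no components")
  if (cmp$object_start[1] != 0)
    stop("layout ", nm, ": first component starts at ", cmp$object_start[1],
         ", expected 0")
  if (any(cmp$object_end <= cmp$object_start))
    stop("layout ", nm, ": empty or inverted component span")
  if (nrow(cmp) > 1) {
    gapped <- which(cmp$object_start[-1] != cmp$object_end[-nrow(cmp)])
    if (length(gapped))
      stop("layout ", nm, ": coordinate hole/overlap at component ",
           gapped[1] + 1)
    twogap <- which(cmp$kind[-1] == "gap" & cmp$kind[-nrow(cmp)] == "gap")
    if (length(twogap))
      stop("layout ", nm, ": adjacent gap components at ", twogap[1])
  }
  if (cmp$kind[1] != "contig" || cmp$kind[nrow(cmp)] != "contig")
    stop("layout ", nm, ": first and last components must be contigs")
  ct <- cmp$kind == "contig"
  bad <- ct & (cmp$component_end - cmp$component_start !=
                 cmp$object_end - cmp$object_start)
  if (any(bad, na.rm = TRUE))
    stop("layout ", nm, ": contig component width mismatch")
  gp <- cmp$kind == "gap"
  badg <- gp & (cmp$object_end - cmp$object_start != cmp$gap_length)
  if (any(badg, na.rm = TRUE))
    stop("layout ", nm, ": gap length does not match object span")
  invisible(TRUE)
}

empty_components <- function(n = 0) {
  data.frame(kind = character(n), object_start = integer(n),
             object_end = integer(n), component_id = character(n),
             component_start = integer(n), component_end = integer(n),
             orientation = character(n), gap_length = integer(n),
             gap_type = character(n), stringsAsFactors = FALSE)
}

contig_component <- function(object_start, component_id, component_start,
                             component_end, orientation = "+") {
  w <- component_end - component_start
  data.frame(kind = "contig", object_start = object_start,
             object_end = object_start + w, component_id = component_id,
             component_start = component_start, component_end = component_end,
             orientation = orientation, gap_length = NA_integer_,
             gap_type = NA_character_, stringsAsFactors = FALSE)
}

gap_component <- function(object_start, gap_length, gap_type = "scaffold") {
  data.frame(kind = "gap", object_start = object_start,
             object_end = object_start + gap_length,
             component_id = NA_character_, component_start = NA_integer_,
             component_end = NA_integer_, orientation = NA_character_,
             gap_length = gap_length, gap_type = gap_type,
             stringsAsFactors = FALSE)
}

# renumber object coordinates after components have been reordered/edited
renumber_components <- function(cmp) {
  w <- cmp$object_end - cmp$object_start
  cmp$object_start <- c(0L, cumsum(w)[-length(w)])
  cmp$object_end <- cmp$object_start + w
  rownames(cmp) <- NULL
  cmp
}

#' Derive a layout (and its contig sequences) from a scaffold sequence
#'
#' Maximal N runs of at least `min_gap_run` become gap components; the
#' remaining stretches become contigs named `<name>_ctg<i>`.
#'
#' @param name Scaffold name.
#' @param seq Scaffold sequence string.
#' @param min_gap_run Minimum N-run length treated as a gap.
#' @param gap_type AGP gap type for derived gaps.
#' @return List with elements `layout` and `contigs` (named character vector).
#' @export
layout_from_sequence <- function(name, seq, min_gap_run = 10L,
                                 gap_type = "scaffold") {
  gaps <- gaps_from_sequence(seq, min_gap_run)
  bounds <- c(0L, as.vector(rbind(gaps$start, gaps$end)), nchar(seq))
  parts <- list()
  contigs <- character(0)
  ctg_i <- 0L
  for (i in seq_len(length(bounds) / 2)) {
    s <- bounds[2 * i - 1]; e <- bounds[2 * i]
    if (e > s) {
      ctg_i <- ctg_i + 1L
      id <- sprintf("%s_ctg%d", name, ctg_i)
      contigs[id] <- substr(seq, s + 1, e)
      parts[[length(parts) + 1]] <- contig_component(s, id, 0L, e - s)
    }
    if (i <= nrow(gaps)) {
      parts[[length(parts) + 1]] <-
        gap_component(gaps$end[i] - (gaps$end[i] - gaps$start[i]),
                      gaps$end[i] - gaps$start[i], gap_type)
    }
  }
  cmp <- do.call(rbind, parts)
  # gap components were appended with start at gap$start already correct:
  cmp <- cmp[order(cmp$object_start), , drop = FALSE]
  list(layout = scaffold_layout(name, cmp), contigs = contigs)
}

#' Assemble the sequence of a layout from its contig sequences
#'
#' @param layout A `scaffold_layout`.
#' @param contigs Named character vector of contig sequences.
#' @return The scaffold sequence string (gaps rendered as N runs).
#' @export
layout_sequence <- function(layout, contigs) {
  cmp <- layout$components
  pieces <- character(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    if (cmp$kind[i] == "gap") {
      pieces[i] <- n_run(cmp$gap_length[i])
    } else {
      id <- cmp$component_id[i]
      if (!id %in% names(contigs))
        stop("layout ", layout$name, ": contig ", id, " not in sequence set")
      s <- substr(contigs[[id]], cmp$component_start[i] + 1,
                  cmp$component_end[i])
      if (nchar(s) != cmp$component_end[i] - cmp$component_start[i])
        stop("layout ", layout$name, ": contig ", id,
             " shorter than component span")
      if (cmp$orientation[i] == "-") s <- revcomp(s)
      pieces[i] <- s
    }
  }
  paste(pieces, collapse = "")
}

#' Reverse-complement a layout
#'
#' Components are emitted in reverse order with contig orientations flipped;
#' contig-local coordinates are unchanged (the contig sequences themselves
#' are not edited).
#'
#' @param layout A `scaffold_layout`.
#' @export
reverse_layout <- function(layout) {
  cmp <- layout$components[rev(seq_len(nrow(layout$components))), ,
                           drop = FALSE]
  ct <- cmp$kind == "contig"
  cmp$orientation[ct] <- ifelse(cmp$orientation[ct] == "+", "-", "+")
  scaffold_layout(layout$name, renumber_components(cmp))
}

#' Split a layout at breakpoints
#'
#' A breakpoint falling inside a gap component removes that gap and splits
#' there; a breakpoint inside a contig splits the contig's local coordinates
#' (respecting orientation); a breakpoint on a component boundary splits
#' cleanly, dropping any gap component left dangling at a new segment edge.
#'
#' @param layout A `scaffold_layout`.
#' @param breakpoints Integer vector of 0-based coordinates, strictly inside
#'   `(0, layout_length(layout))`.
#' @return List of `scaffold_layout` segments named `<name>_seg<i>`; each
#'   carries attribute `origin`, its start coordinate in the input layout.
#' @export
break_layout <- function(layout, breakpoints) {
  L <- layout_length(layout)
  breakpoints <- sort(unique(as.integer(breakpoints)))
  if (length(breakpoints) == 0) {
    out <- layout
    attr(out, "origin") <- 0L
    return(list(out))
  }
  if (any(breakpoints <= 0 | breakpoints >= L))
    stop("breakpoint outside (0, ", L, ") for ", layout$name)

  cmp <- layout$components
  bounds <- c(0L, breakpoints, L)
  segs <- list()
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    sel <- cmp$object_end > lo & cmp$object_start < hi
    part <- cmp[sel, , drop = FALSE]
    # clip first component at lo
    if (part$object_start[1] < lo) {
      if (part$kind[1] == "gap") {
        part$gap_length[1] <- part$object_end[1] - lo
      } else {
        off <- lo - part$object_start[1]
        if (part$orientation[1] == "+") {
          part$component_start[1] <- part$component_start[1] + off
        } else {
          part$component_end[1] <- part$component_end[1] - off
        }
      }
      part$object_start[1] <- lo
    }
    n <- nrow(part)
    # clip last component at hi
    if (part$object_end[n] > hi) {
      if (part$kind[n] == "gap") {
        part$gap_length[n] <- hi - part$object_start[n]
      } else {
        off <- part$object_end[n] - hi
        if (part$orientation[n] == "+") {
          part$component_end[n] <- part$component_end[n] - off
        } else {
          part$component_start[n] <- part$component_start[n] + off
        }
      }
      part$object_end[n] <- hi
    }
    # drop gap components left at segment edges (a segment must start and
    # end with a contig)
    while (nrow(part) > 0 && part$kind[1] == "gap")
      part <- part[-1, , drop = FALSE]
    while (nrow(part) > 0 && part$kind[nrow(part)] == "gap")
      part <- part[-nrow(part), , drop = FALSE]
    if (nrow(part) == 0)
      stop("breakpoints leave an empty segment in ", layout$name)
    origin <- part$object_start[1]
    part <- renumber_components(part)
    seg <- scaffold_layout(sprintf("%s_seg%d", layout$name, i), part)
    attr(seg, "origin") <- origin
    segs[[i]] <- seg
  }
  segs
}

#' Gap records of a layout
#'
#' @param layout A `scaffold_layout`.
#' @return Data frame with `scaffold`, 0-based half-open `start`/`end`, and
#'   `declared_length` columns, one row per gap component.
#' @export
gaps_from_layout <- function(layout) {
  cmp <- layout$components
  g <- cmp[cmp$kind == "gap", , drop = FALSE]
  data.frame(scaffold = rep(layout$name, nrow(g)), start = g$object_start,
             end = g$object_end, declared_length = g$gap_length,
             stringsAsFactors = FALSE)
}

#' Total contig (non-gap) bases referenced by layouts
#' @param layouts A list of `scaffold_layout` objects.
#' @export
layout_contig_bases <- function(layouts) {
  if (inherits(layouts, "scaffold_layout")) layouts <- list(layouts)
  sum(vapply(layouts, function(l) {
    cmp <- l$components
    sum(cmp$object_end[cmp$kind == "contig"] -
          cmp$object_start[cmp$kind == "contig"])
  }, numeric(1)))
}
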