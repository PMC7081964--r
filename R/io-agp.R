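# AGP v2.0 reader/writer.  On disk AGP is 1-based inclusive; in memory all
# coordinates are 0-based half-open.  Negative gaps (collapses) cannot be
# represented in AGP and travel in a sidecar TSV (see read_negative_gaps()).

agp_gap_evidence <- c(scaffold = "paired-ends", map = "map",
                      contamination = "na")

#' Read an AGP v2.0 file
#'
#' Supports `W` (contig), `N` and `U` (gap) component types.  The tiling
#' invariant of every scaffold is verified on read; a hole or overlap is a
#' hard error naming the scaffold and line.
#'
#' @param path Path to a 9-column AGP v2.0 file.
#' @return Named list of [scaffold_layout()] objects, in file order.
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stop("AGP file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("empty AGP file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("AGP line ", lineno[which(nf < 9)[1]], ": fewer than 9 columns")
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  obj <- mat[, 1]
  rows_by_obj <- split(seq_along(obj), factor(obj, levels = unique(obj)))
  layouts <- lapply(names(rows_by_obj), function(nm) {
    idx <- rows_by_obj[[nm]]
    idx <- idx[order(as.integer(mat[idx, 4]))]
    parts <- lapply(idx, function(i) {
      beg <- as.integer(mat[i, 2]); end <- as.integer(mat[i, 3])
      type <- mat[i, 5]
      if (type == "W") {
        contig_component(beg - 1L, mat[i, 6], as.integer(mat[i, 7]) - 1L,
                         as.integer(mat[i, 8]), mat[i, 9])
      } else if (type %in% c("N", "U")) {
        gtype <- mat[i, 7]
        if (!gtype %in% names(agp_gap_evidence)) gtype <- "scaffold"
        gap_component(beg - 1L, as.integer(mat[i, 6]), gtype)
      } else {
        stop("AGP line ", lineno[i], ": unsupported component type ", type)
      }
    })
    tryCatch(scaffold_layout(nm, do.call(rbind, parts)),
             error = function(e) stop("AGP ", path, " scaffold ", nm,
                                      " (near line ", lineno[idx[1]], "): ",
                                      conditionMessage(e)))
  })
  names(layouts) <- names(rows_by_obj)
  layouts
}

#' Write layouts to an AGP v2.0 file
#'
#' Exact inverse of [read_agp()]: `read_agp(write_agp(x))` reproduces `x`.
#'
#' @param layouts List of [scaffold_layout()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agp <- function(layouts, path) {
  if (inherits(layouts, "scaffold_layout")) layouts <- list(layouts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  for (layout in layouts) {
    cmp <- layout$components
    for (i in seq_len(nrow(cmp))) {
      if (cmp$kind[i] == "contig") {
        line <- paste(layout$name, cmp$object_start[i] + 1L,
                      cmp$object_end[i], i, "W", cmp$component_id[i],
                      cmp$component_start[i] + 1L, cmp$component_end[i],
                      cmp$orientation[i], sep = "\t")
      } else {
        line <- paste(layout$name, cmp$object_start[i] + 1L,
                      cmp$object_end[i], i, "N", cmp$gap_length[i],
                      cmp$gap_type[i], "yes",
                      agp_gap_evidence[[cmp$gap_type[i]]], sep = "\t")
      }
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read a negative-gap (collapse) sidecar TSV
#'
#' AGP v2.0 has no representation for negative gaps, so implied collapses
#' are carried beside the AGP as a TSV with columns `scaffold`, `pos`
#' (0-based collapse point) and `declared_length` (negative bp).
#'
#' @param path Path to the sidecar TSV.
#' @return Data frame with `scaffold`, `start`, `end` (both equal to the
#'   collapse point) and `declared_length` columns.
#' @export
read_negative_gaps <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("scaffold", "pos", "declared_length")
  if (!all(need %in% names(df)))
    stop("negative-gap TSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (any(df$declared_length >= 0))
    stop("negative-gap TSV ", path, ": declared_length must be < 0")
  data.frame(scaffold = df$scaffold, start = as.integer(df$pos),
             end = as.integer(df$pos),
             declared_length = as.integer(df$declared_length),
             stringsAsFactors = FALSE)
}

#' @rdname read_negative_gaps
#' @param gaps Data frame as returned by [read_negative_gaps()].
#' @export
write_negative_gaps <- function(gaps, path) {
  write_tsv_plain(data.frame(scaffold = gaps$scaffold, pos = gaps$start,
                             declared_length = gaps$declared_length), path)
}
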