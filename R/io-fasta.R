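#' Read a FASTA file
#'
#' Reads sequences as uppercase `{A,C,G,T,N}` strings.  Characters outside
#' that alphabet (for example IUPAC ambiguity codes, common in real
#' assemblies) are mapped to `N` with a single warning reporting how many
#' were replaced.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("zero-length FASTA record in ", path, ": ",
         paste(nm[nchar(seqs) == 0], collapse = ", "))
  }
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN character(s) in ", path, " replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- nm
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param line_width Wrap width in bases (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is_count(line_width), line_width >= 1)
  if (length(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(records)
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' Locate assembly gaps (N runs) in a sequence
#'
#' A gap is a maximal run of `N` of length at least `min_run`.  Shorter runs
#' (for example single ambiguous bases left by polishing) are not counted as
#' structural gaps.
#'
#' @param seq A single sequence string.
#' @param min_run Minimum run length to qualify as a gap (default 10).
#' @return Data frame with 0-based half-open `start`, `end` columns, sorted.
#' @export
gaps_from_sequence <- function(seq, min_run = 10L) {
  stopifnot(length(seq) == 1, is_count(min_run), min_run >= 1)
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.integer(m[keep] - 1L),
             end = as.integer(m[keep] - 1L + len[keep]))
}
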