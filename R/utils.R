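`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# strrep("N", n) but tolerant of n == 0
n_run <- function(n) strrep("N", n)

# deterministic TSV writer: fixed column order, no quoting, "." for NA
write_tsv_plain <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names, na = ".")
  invisible(path)
}

read_tsv_plain <- function(path, col_classes = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = col_classes, na.strings = ".")
}

stop_usage <- function(...) {
  stop(structure(class = c("asmforge_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
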