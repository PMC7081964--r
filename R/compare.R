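# Two-assembly comparison arithmetic: percent reductions, fold changes and
# the contig -> gap accounting used when comparing chromosome-placed
# assemblies.

#' Percent reduction of A relative to B
#'
#' `100 * (1 - a / b)`; undefined (`NA`) when `b == 0`.
#'
#' @param a,b Numeric values (A is the newer/smaller quantity by convention).
#' @export
percent_reduction <- function(a, b) {
  ifelse(b == 0, NA_real_, 100 * (1 - a / b))
}

#' Fold change between two values
#'
#' Returns `larger / smaller` with a direction label; undefined (`NA`) when
#' the smaller value is 0.
#'
#' @param a,b Numeric scalars.
#' @return List with `fold` and `direction` (`"a_larger"`, `"b_larger"` or
#'   `"equal"`).
#' @export
fold_change <- function(a, b) {
  lo <- min(a, b); hi <- max(a, b)
  list(fold = if (lo == 0) NA_real_ else hi / lo,
       direction = if (a > b) "a_larger" else if (b > a) "b_larger" else "equal")
}

#' Gaps implied by contig and chromosome counts
#'
#' For an assembly whose contigs are placed on chromosomes, the number of
#' internal gaps is `contigs - chromosomes`.
#'
#' @param n_contigs Number of contigs placed on chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @export
chromosome_gap_count <- function(n_contigs, n_chromosomes) {
  stopifnot(n_contigs >= n_chromosomes)
  n_contigs - n_chromosomes
}

#' Compare two keyed metric tables
#'
#' For every shared key the report carries both absolute values, the
#' percent reduction `100 * (1 - A/B)` and the fold change
#' (larger/smaller, labelled).  Division by zero yields `NA`, not an error.
#'
#' @param metrics_a,metrics_b Named numeric vectors (e.g. error-feature
#'   class counts, SV class counts, contig counts).
#' @return Data frame with `key`, `value_a`, `value_b`, `pct_reduction`,
#'   `fold`, `direction`.
#' @export
compare_assemblies <- function(metrics_a, metrics_b) {
  keys <- union(names(metrics_a), names(metrics_b))
  rows <- lapply(keys, function(k) {
    a <- unname(metrics_a[k]); b <- unname(metrics_b[k])
    fc <- if (!is.na(a) && !is.na(b)) fold_change(a, b) else
      list(fold = NA_real_, direction = NA_character_)
    data.frame(key = k, value_a = a, value_b = b,
               pct_reduction = if (!is.na(a) && !is.na(b))
                 percent_reduction(a, b) else NA_real_,
               fold = fc$fold, direction = fc$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
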