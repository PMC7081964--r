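# Shared fixtures and independent oracles.  The truth sets are built once
# per test run and cached; every expected value asserted against them is
# recomputed from the planted truth, never from the code path under test.

.fixture_cache <- new.env(parent = emptyenv())

# small truth set exercising every planted defect class
small_truth_set <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_truth_set(
      seed = 7L, n_chromosomes = 2L, chrom_length = 6e5, n_genes = 10L,
      n_scaffolds_per_chrom = 3L, gaps_per_scaffold = 2L, n_misjoins = 1L,
      n_inversions = 1L, n_collapses = 1L, markers_per_chrom = 16L,
      assessed_bases = 1e6, error_rate = 5e-4)
  }
  .fixture_cache$small
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force Pearson correlation, written from the definition
bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force N-run scan: walk the string character by character
bf_gap_scan <- function(seq, min_run) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  i <- 1
  while (i <= length(ch)) {
    if (ch[i] == "N") {
      j <- i
      while (j <= length(ch) && ch[j] == "N") j <- j + 1
      if (j - i >= min_run) out <- rbind(out, c(i - 1, j - 1))
      i <- j
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = out[, 1], end = out[, 2])
}

# brute-force NGx: walk the cumulative sum explicitly
bf_ngx <- function(lengths, x, base) {
  lengths <- sort(lengths, decreasing = TRUE)
  thr <- x / 100 * base
  acc <- 0
  for (i in seq_along(lengths)) {
    acc <- acc + lengths[i]
    if (acc >= thr) return(list(n = lengths[i], l = i))
  }
  list(n = NA_real_, l = NA_integer_)
}

# random valid layout for AGP round-trip properties
random_layout <- function(name, n_contigs = 3) {
  parts <- list()
  pos <- 0L
  for (i in seq_len(n_contigs)) {
    w <- sample(50:500, 1)
    cs <- sample(0:20, 1)
    parts[[length(parts) + 1]] <- contig_component(
      pos, sprintf("%s_c%d", name, i), cs, cs + w,
      sample(c("+", "-"), 1))
    pos <- pos + w
    if (i < n_contigs) {
      g <- sample(20:200, 1)
      parts[[length(parts) + 1]] <- gap_component(
        pos, g, sample(c("scaffold", "map"), 1))
      pos <- pos + g
    }
  }
  scaffold_layout(name, do.call(rbind, parts))
}

# truth key for a placed scaffold/segment: chromosome, truth position of its
# left edge, and expected orientation, derived from the parts table
segment_truth <- function(draft, seg_layouts, seg_name) {
  if (seg_name %in% draft$parts$scaffold) {
    scf <- seg_name
    origin <- 0L
  } else {
    scf <- sub("_seg[0-9]+$", "", seg_name)
    origin <- attr(seg_layouts[[seg_name]], "origin")
  }
  p <- draft$parts[draft$parts$scaffold == scf, , drop = FALSE]
  row <- p[p$s_start <= origin & p$s_end > origin, , drop = FALSE]
  if (nrow(row) == 0) row <- p[which.min(abs(p$s_start - origin)), ,
                               drop = FALSE]
  row <- row[1, ]
  seg_len <- layout_length(seg_layouts[[seg_name]])
  # left edge of the segment's truth interval (for an inverted segment the
  # draft-left edge corresponds to the truth-right edge)
  list(chrom = row$chrom,
       t_pos = if (row$inverted)
         row$t_end - (origin - row$s_start) - seg_len else
         row$t_start + (origin - row$s_start),
       orientation = if (row$inverted) "-" else "+")
}
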