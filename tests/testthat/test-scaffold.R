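mk_hits <- function(pos, scf = "s1", ids = NULL, identity = 1,
                    coverage = 1, n_placements = 1L) {
  data.frame(marker_id = ids %||% sprintf("m%02d", seq_along(pos)),
             scaffold = scf, position = pos, identity = identity,
             coverage = coverage, n_placements = n_placements,
             stringsAsFactors = FALSE)
}

mk_markers <- function(ids, lg, ord, cm = NULL) {
  data.frame(marker_id = ids, linkage_group = lg, map_order = ord,
             map_position = cm %||% as.numeric(ord),
             sequence = strrep("A", 30), stringsAsFactors = FALSE)
}

test_that("marker-hit filtering enforces identity, full length and uniqueness", {
  h <- rbind(mk_hits(100, ids = "a", identity = 0.97),
             mk_hits(200, ids = "b", identity = 1, n_placements = 2L),
             mk_hits(300, ids = "c", identity = 0.99),
             mk_hits(400, ids = "d", identity = 0.98, coverage = 0.9))
  out <- filter_marker_hits(h)
  expect_identical(out$marker_id, "c")
  # identity exactly at threshold is retained
  expect_identical(nrow(filter_marker_hits(mk_hits(1, identity = 0.98))), 1L)
  # non-unique retained when unique_only is off
  out <- filter_marker_hits(h, unique_only = FALSE,
                            require_full_length = FALSE)
  expect_setequal(out$marker_id, c("b", "c", "d"))
  # duplicate hits of one marker are discarded under unique_only
  dup <- mk_hits(c(10, 20), ids = c("x", "x"))
  expect_identical(nrow(filter_marker_hits(dup)), 0L)
  expect_error(filter_marker_hits(h, min_identity = 0), "min_identity")
})

test_that("chimera detection places the midpoint breakpoint and ignores singleton noise", {
  mks <- mk_markers(sprintf("m%02d", 1:5), c(rep("LG1", 3), rep("LG5", 2)),
                    c(1:3, 1:2))
  h <- mk_hits(c(10000, 20000, 30000, 40000, 50000))
  brk <- detect_chimeras(h, mks)
  expect_length(brk, 1)
  expect_equal(brk[[1]]$breakpoints, 35000)
  expect_identical(brk[[1]]$segment_groups, c("LG1", "LG5"))

  # a single stray marker from another group is noise
  mks2 <- mk_markers(c("m01", "m02", "m03"), c("LG1", "LG1", "LG2"),
                     c(1, 2, 1))
  h2 <- mk_hits(c(10000, 20000, 30000), ids = c("m01", "m02", "m03"))
  expect_length(detect_chimeras(h2, mks2, min_conflict_markers = 2), 0)
  expect_length(detect_chimeras(h2, mks2, min_conflict_markers = 1), 1)

  # all hits from one linkage group: nothing to break
  mks3 <- mk_markers(sprintf("m%02d", 1:3), "LG1", 1:3)
  expect_length(detect_chimeras(mk_hits(c(1, 2, 3) * 1e4), mks3), 0)
})

test_that("breakpoints snap into a gap between the conflicting runs", {
  mks <- mk_markers(sprintf("m%02d", 1:4), c("LG1", "LG1", "LG2", "LG2"),
                    c(1, 2, 1, 2))
  h <- mk_hits(c(1000, 2000, 9000, 9500))
  s <- paste0(rand_seq(4000), strrep("N", 100), rand_seq(5400))
  lf <- layout_from_sequence("s1", s)
  brk <- detect_chimeras(h, mks, layouts = list(s1 = lf$layout))
  expect_equal(brk[[1]]$breakpoints, 4050)  # centre of the gap
})

test_that("orientation follows the sign of the rank correlation", {
  mks <- mk_markers(sprintf("m%02d", 1:3), "LG1", 1:3, cm = c(5, 10, 20))
  a <- orient_and_order(mk_hits(c(100, 200, 300)), mks)
  expect_identical(a$orientation, "+")
  expect_equal(a$pearson_r, 1)
  expect_equal(a$order_key, 10)

  mks_rev <- mk_markers(sprintf("m%02d", 1:3), "LG1", 3:1)
  b <- orient_and_order(mk_hits(c(100, 200, 300)), mks_rev)
  expect_identical(b$orientation, "-")
  expect_equal(b$pearson_r, -1)

  single <- orient_and_order(mk_hits(100, ids = "m01"),
                             mk_markers("m01", "LG1", 1, cm = 7.5))
  expect_identical(single$orientation, "unknown")
  expect_equal(single$order_key, 7.5)

  # mixed linkage groups must error
  mks_mix <- mk_markers(c("m01", "m02"), c("LG1", "LG2"), c(1, 1))
  expect_error(orient_and_order(mk_hits(c(1, 2), ids = c("m01", "m02")),
                                mks_mix), "linkage groups")
})

test_that("rank correlation matches a brute-force Pearson on ranks", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    pos <- sample(1e6, n)
    ord <- sample(n)
    mks <- mk_markers(sprintf("m%02d", 1:n), "LG1", ord)
    a <- orient_and_order(mk_hits(pos), mks)
    expected <- bf_pearson(rank(pos), rank(ord))
    if (is.na(a$pearson_r)) expect_true(abs(expected) < 1e-12)
    else expect_equal(a$pearson_r, expected, tolerance = 1e-12)
  }
})

test_that("chromosome building orders by map position and reverses '-' segments", {
  s1 <- layout_from_sequence("s1", rand_seq(300))
  s2 <- layout_from_sequence("s2", paste0(rand_seq(100), strrep("N", 40),
                                          rand_seq(150)))
  layouts <- list(s1 = s1$layout, s2 = s2$layout)
  contigs <- c(s1$contigs, s2$contigs)
  asg <- data.frame(scaffold = c("s2", "s1"), linkage_group = "chrA",
                    orientation = c("+", "-"), order_key = c(55, 10),
                    pearson_r = c(1, -1), n_markers = c(3L, 3L),
                    stringsAsFactors = FALSE)
  built <- build_chromosomes(asg, layouts, inter_scaffold_gap = 100)
  expect_identical(built$order$chrA, c("s1", "s2"))
  chr <- built$chromosomes$chrA
  seq <- layout_sequence(chr, contigs)
  expect_identical(
    seq,
    paste0(revcomp(layout_sequence(s1$layout, contigs)), strrep("N", 100),
           layout_sequence(s2$layout, contigs)))
  # total contig bases conserved
  expect_identical(layout_contig_bases(list(chr)),
                   layout_contig_bases(layouts))
  # no assignments: everything unplaced
  none <- build_chromosomes(asg[0, ], layouts)
  expect_length(none$chromosomes, 0)
  expect_setequal(none$unplaced, c("s1", "s2"))
  # duplicated scaffold is an error
  expect_error(build_chromosomes(rbind(asg, asg[1, ]), layouts),
               "more than once")
})

test_that("map-guided scaffolding recovers planted order, orientation and misjoins", {
  ts <- small_truth_set()
  draft <- ts$draft
  res <- map_guided_scaffold(draft$layouts, ts$map$hits, ts$map$markers)

  # every planted misjoin broken; no false break on clean scaffolds
  expect_setequal(vapply(res$breaks, `[[`, "", "scaffold"),
                  draft$misjoins$scaffold)
  # each break lies strictly between the two linkage-group blocks: the
  # resulting segments carry exactly the two planted chromosomes
  for (b in res$breaks)
    expect_setequal(b$segment_groups,
                    unlist(draft$misjoins[draft$misjoins$scaffold ==
                                            b$scaffold, c("lg1", "lg2")]))

  # all chromosomes recovered with perfect order (Kendall tau = 1) and
  # orientation per the planted truth
  expect_setequal(names(res$chromosomes), names(ts$truth$sequences))
  expect_length(res$unplaced, 0)
  for (lg in names(res$order)) {
    segs <- res$order[[lg]]
    tr <- lapply(segs, segment_truth, draft = draft,
                 seg_layouts = res$segment_layouts)
    expect_true(all(vapply(tr, `[[`, "", "chrom") == lg))
    tpos <- vapply(tr, `[[`, numeric(1), "t_pos")
    expect_equal(stats::cor(seq_along(tpos), tpos, method = "kendall"), 1)
    a <- res$assignments[match(segs, res$assignments$scaffold), ]
    expect_identical(a$orientation,
                     vapply(tr, `[[`, "", "orientation"))
  }

  # sequence conservation: contig bases in chromosomes equal the draft's
  expect_identical(layout_contig_bases(res$chromosomes),
                   layout_contig_bases(draft$layouts))

  # rebuilt chromosomes carry the truth sequence: regularly spaced truth
  # probes must be found verbatim (probes hitting gap-masked or collapsed
  # stretches are the only permissible misses)
  contigs <- draft$contigs
  for (lg in names(res$chromosomes)) {
    got <- layout_sequence(res$chromosomes[[lg]], contigs)
    truth_seq <- ts$truth$sequences[[lg]]
    probes <- seq(1, nchar(truth_seq) - 2000, by = 100000)
    hits <- vapply(probes, function(q) {
      grepl(substr(truth_seq, q, q + 80), got, fixed = TRUE)
    }, logical(1))
    expect_gt(mean(hits), 0.9)
  }
})

test_that("marker dropout of 1 leaves all scaffolds unplaced", {
  ts <- small_truth_set()
  map0 <- simulate_genetic_map(ts$truth, ts$draft, markers_per_chrom = 4,
                               dropout_rate = 1, seed = 5)
  expect_identical(nrow(map0$hits), 0L)
  res <- map_guided_scaffold(ts$draft$layouts, map0$hits, map0$markers)
  expect_length(res$chromosomes, 0)
  expect_setequal(res$unplaced, names(ts$draft$layouts))
})
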