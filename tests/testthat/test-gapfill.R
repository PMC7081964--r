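mk_block <- function(query, t1, t2, q1 = 0L, q2 = t2 - t1 + q1,
                     strand = "+", target = "s1", qlen = 50000L,
                     tlen = 50000L) {
  data.frame(query = query, query_len = qlen, query_start = q1,
             query_end = q2, strand = strand, target = target,
             target_len = tlen, target_start = t1, target_end = t2,
             matches = q2 - q1, block_len = q2 - q1, mapq = 60L,
             stringsAsFactors = FALSE)
}

test_that("span evidence applies the strict flank and inclusive distance rules", {
  gap <- data.frame(scaffold = "s1", start = 10000L, end = 10100L)
  al <- rbind(mk_block("p1", 4900L, 9995L, 0L, 5095L),
              mk_block("p1", 10105L, 15300L, 5300L, 10495L))
  ev <- collect_span_evidence(gap, al, "A")
  expect_identical(nrow(ev), 1L)
  expect_identical(c(ev$left_flank, ev$right_flank), c(5095L, 5195L))
  expect_identical(c(ev$left_distance, ev$right_distance), c(5L, 5L))
  expect_true(ev$qualifying)
  expect_identical(c(ev$fill_start, ev$fill_end), c(5095L, 5300L))

  # a flank of exactly 5000 bp does not qualify (rule is strictly > 5000)
  al2 <- rbind(mk_block("p1", 5000L, 10000L, 0L, 5000L),
               mk_block("p1", 10100L, 15101L, 5100L, 10101L))
  ev2 <- collect_span_evidence(gap, al2, "A")
  expect_false(ev2$qualifying)
  expect_identical(ev2$left_flank, 5000L)

  # an edge distance of 11 bp does not qualify (at most 10 bp away)
  al3 <- rbind(mk_block("p1", 3000L, 10000L, 0L, 7000L),
               mk_block("p1", 10111L, 17111L, 7111L, 14111L))
  ev3 <- collect_span_evidence(gap, al3, "A")
  expect_false(ev3$qualifying)
  expect_identical(ev3$right_distance, 11L)

  # unknown scaffold target is a hard error
  expect_error(collect_span_evidence(gap, mk_block("p1", 0L, 6000L,
                                                   target = "zz"),
                                     "A", known_scaffolds = "s1"),
               "unknown scaffold")
})

test_that("a single block crossing the gap is treated as zero-distance evidence", {
  gap <- data.frame(scaffold = "s1", start = 10000L, end = 10100L)
  ev <- collect_span_evidence(gap, mk_block("p1", 2000L, 18000L, 0L, 16000L),
                              "A")
  expect_true(ev$qualifying)
  expect_identical(c(ev$left_distance, ev$right_distance), c(0L, 0L))
  expect_identical(c(ev$left_flank, ev$right_flank), c(8000L, 7900L))
  expect_identical(ev$fill_end - ev$fill_start, 100L)
})

test_that("fill decisions prefer the assembly with the longer minimum flank", {
  gap <- data.frame(scaffold = "s1", start = 10000L, end = 10100L)
  evA <- collect_span_evidence(gap, rbind(
    mk_block("pa", 4000L, 10000L, 0L, 6000L),
    mk_block("pa", 10100L, 16100L, 6100L, 12100L)), "A")
  evB <- collect_span_evidence(gap, rbind(
    mk_block("pb", 1000L, 10000L, 0L, 9000L),
    mk_block("pb", 10100L, 19100L, 9100L, 18100L)), "B")
  d <- decide_fill(gap, rbind(evA, evB))
  expect_identical(d$status, "filled")
  expect_identical(d$assembly, "B")
  # with A only, A is the source
  dA <- decide_fill(gap, evA)
  expect_identical(dA$assembly, "A")
  # no evidence at all
  d0 <- decide_fill(gap, evA[0, ])
  expect_identical(d0$status, "unfilled")
})

test_that("collapses are confirmed only under cross-assembly agreement", {
  neg <- data.frame(scaffold = "s1", start = 1000000L, end = 1000000L,
                    declared_length = -500L)
  ev_pair <- function(pos_b, size_b) {
    # assembly A implies +500 bp exactly at the collapse point
    evA <- collect_span_evidence(neg, rbind(
      mk_block("pa", 1000000L - 7000L, 1000000L, 0L, 7000L, qlen = 14500L),
      mk_block("pa", 1000000L, 1000000L + 7000L, 7500L, 14500L,
               qlen = 14500L)), "A")
    # assembly B's left block ends pos_b (<= collapse point); the query
    # jump between its blocks implies size_b inserted bases
    tgap <- 1000000L - pos_b
    qgap <- size_b + tgap
    qlenb <- 14000L + qgap
    evB <- collect_span_evidence(neg, rbind(
      mk_block("pb", pos_b - 7000L, pos_b, 0L, 7000L, qlen = qlenb),
      mk_block("pb", 1000000L, 1000000L + 7000L, 7000L + qgap, qlenb,
               qlen = qlenb)), "B")
    rbind(evA, evB)
  }
  # positions 8 bp apart, sizes 500 vs 505: within default tolerances
  ok <- confirm_collapse(neg, ev_pair(999992L, 505L))
  expect_identical(ok$status, "collapse_confirmed")
  # size disagreement 500 vs 900
  bad <- confirm_collapse(neg, ev_pair(1000000L, 900L))
  expect_identical(bad$status, "collapse_unconfirmed")
  # evidence from a single assembly can never satisfy "both"
  single <- confirm_collapse(neg, ev_pair(999992L, 505L)[1, ])
  expect_identical(single$status, "collapse_unconfirmed")
})

test_that("apply_fills merges contigs, conserves flanks and honours '-' strand", {
  set.seed(31)
  left <- rand_seq(200); right <- rand_seq(200); fill <- rand_seq(60)
  s <- paste0(left, strrep("N", 50), right)
  lf <- layout_from_sequence("s1", s)
  patch <- c(p1 = revcomp(paste0(substr(left, 101, 200), fill,
                                 substr(right, 1, 100))))
  dec <- data.frame(scaffold = "s1", gap_start = 200L, gap_end = 250L,
                    status = "filled", assembly = "A", patch_contig = "p1",
                    strand = "-", left_flank = 100L, right_flank = 100L,
                    left_distance = 0L, right_distance = 0L,
                    splice_start = 200L, splice_end = 250L,
                    fill_start = 100L, fill_end = 160L, fill_len = 60L,
                    stringsAsFactors = FALSE)
  res <- apply_fills(list(s1 = lf$layout), c(s1 = s), patch, dec)
  expect_identical(res$sequences[["s1"]], paste0(left, fill, right))
  cmp <- res$layouts$s1$components
  expect_identical(nrow(cmp), 1L)              # two contigs + gap merged
  expect_identical(cmp$kind, "contig")
  expect_identical(res$summary$gaps_after, 0)
  expect_identical(res$summary$contigs_after, 1)
  expect_identical(res$summary$bases_added, 10L)
  # merged contig sequence is extracted and registered
  expect_identical(unname(res$contigs), paste0(left, fill, right))
  # zero decisions: byte-identical pass-through
  same <- apply_fills(list(s1 = lf$layout), c(s1 = s), patch,
                      dec[0, , drop = FALSE])
  expect_identical(same$sequences[["s1"]], s)
  expect_equal(same$layouts$s1$components, lf$layout$components)
  # missing patch contig is an error
  dec2 <- dec; dec2$patch_contig <- "nope"
  expect_error(apply_fills(list(s1 = lf$layout), c(s1 = s), patch, dec2),
               "missing")
})

test_that("planted spannable gaps fill and boundary cases stay open on the truth set", {
  ts <- small_truth_set()
  draft <- ts$draft
  gf <- gap_fill(draft$layouts, draft$scaffolds,
                 list(A = ts$patches$A, B = ts$patches$B),
                 negative_gaps = draft$negative_gaps)
  dec <- merge(gf$decisions, ts$patches$gap_cases,
               by.x = c("scaffold", "gap_start"),
               by.y = c("scaffold", "start"))
  spannable <- dec$case %in% c("spannable_A", "spannable_B",
                               "spannable_both")
  boundary <- dec$case %in% c("flank_5000_exact", "distance_11",
                              "unspanned")
  expect_true(all(dec$status[spannable] == "filled"))
  expect_true(all(dec$status[boundary] == "unfilled"))
  # single-source cases credit the right assembly; dual spans pick the
  # longer minimum flank (assembly B by construction)
  expect_true(all(dec$assembly[dec$case == "spannable_A"] == "A"))
  expect_true(all(dec$assembly[dec$case == "spannable_B"] == "B"))
  expect_true(all(dec$assembly[dec$case == "spannable_both"] == "B"))

  # collapse confirmation follows the planted agreement plan
  cd <- merge(gf$collapse_decisions, ts$patches$collapse_cases,
              by.x = c("scaffold", "gap_start"), by.y = c("scaffold", "pos"))
  expect_identical(cd$status[cd$case == "negative_agreeing"],
                   rep("collapse_confirmed",
                       sum(cd$case == "negative_agreeing")))
  expect_identical(cd$status[cd$case == "negative_disagreeing"],
                   rep("collapse_unconfirmed",
                       sum(cd$case == "negative_disagreeing")))

  # contig count drops by exactly the number of filled gaps; N50 does not
  # decrease under filling
  s <- gf$summary
  expect_identical(s$contigs_after, s$contigs_before - s$n_filled)
  expect_identical(s$gaps_after, s$gaps_before - s$n_filled)
  n50_before <- contiguity(nchar(draft$contigs), 1e6)$nx[["50"]]
  after_lens <- unlist(lapply(gf$layouts, function(l) {
    cmp <- l$components
    cmp$object_end[cmp$kind == "contig"] -
      cmp$object_start[cmp$kind == "contig"]
  }))
  expect_gte(contiguity(after_lens, 1e6)$nx[["50"]], n50_before)

  # bases outside edited regions are untouched and each fill matches the
  # source patch interval exactly
  for (i in which(gf$decisions$status == "filled")) {
    d <- gf$decisions[i, ]
    patch <- c(ts$patches$A$contigs, ts$patches$B$contigs)[[d$patch_contig]]
    want <- substr(patch, d$fill_start + 1, d$fill_end)
    if (d$strand == "-") want <- revcomp(want)
    expect_true(grepl(want, gf$sequences[[d$scaffold]], fixed = TRUE))
  }
  for (scf in names(draft$scaffolds)) {
    d <- gf$decisions[gf$decisions$scaffold == scf &
                        gf$decisions$status == "filled", , drop = FALSE]
    if (nrow(d) == 0) {
      expect_identical(gf$sequences[[scf]], draft$scaffolds[[scf]])
    } else {
      # prefix before the first splice is untouched
      first <- min(d$splice_start)
      expect_identical(substr(gf$sequences[[scf]], 1, first),
                       substr(draft$scaffolds[[scf]], 1, first))
    }
  }
})
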