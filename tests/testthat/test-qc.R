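test_that("Nx/NGx match worked examples and the brute-force oracle", {
  st <- contiguity(c(5, 4, 3, 2, 1), genome_size = 12)
  expect_equal(st$ngx[["50"]], 4)
  expect_equal(st$lgx[["50"]], 2)
  expect_equal(st$nx[["50"]], 4)   # total 15, half 7.5, cumsum 5, 9
  expect_equal(st$lx[["50"]], 2)

  one <- contiguity(100, genome_size = 100)
  expect_equal(one$ngx[["50"]], 100)
  expect_equal(one$lgx[["50"]], 1)

  # an assembly shorter than x% of the genome reports NGx as absent
  short <- contiguity(c(10, 10), genome_size = 1000)
  expect_true(is.na(short$ngx[["50"]]))

  expect_error(contiguity(c(5, 0)), "positive")
  expect_error(contiguity(5, genome_size = 0), "genome_size")

  set.seed(41)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    base <- sample(c(sum(lens), round(sum(lens) * runif(1, 0.5, 2))), 1)
    base <- max(base, 1)
    st <- contiguity(lens, genome_size = base)
    for (x in sample(1:100, 4)) {
      oracle <- bf_ngx(lens, x, base)
      expect_equal(unname(st$ngx[[as.character(x)]]), oracle$n)
      expect_equal(unname(st$lgx[[as.character(x)]]), oracle$l)
    }
    # monotonicity invariants
    expect_true(all(diff(st$nx[!is.na(st$nx)]) <= 0))
    expect_true(all(diff(st$lx[!is.na(st$lx)]) >= 0))
  }
})

test_that("QV estimation is Phred-consistent and caps at zero errors", {
  expect_equal(estimate_qv(1, 1000)$qv, 30)
  q <- estimate_qv(159, 1e6)
  expect_gte(round(q$qv, 2), 37.98)
  expect_lte(round(q$qv, 2), 37.99)
  z <- estimate_qv(0, 1e6)
  expect_true(z$capped)
  expect_identical(z$qv_label, ">= 60.00")
  expect_error(estimate_qv(10, 5), "exceeds")
})

test_that("error-base counting follows the max-allele-length convention", {
  v <- data.frame(scaffold = "c", position = 1:3,
                  ref_allele = c("A", "ACGT", "G"),
                  alt_allele = c("T", "A", "C"),
                  genotype = c("het", "hom_alt", "het"),
                  filter = c("PASS", "PASS", "LowQual"),
                  stringsAsFactors = FALSE)
  expect_identical(count_error_bases(v), 5L)            # 1 + 4, LowQual out
  expect_identical(count_error_bases(v, pass_only = FALSE), 6L)
  expect_identical(count_error_bases(v, hom_only = TRUE), 4L)
  expect_identical(count_error_bases(v[0, ]), 0L)
})

test_that("QV recovered from a planted variant table is within 0.05 of truth", {
  sim <- simulate_variant_calls(2e7, 5e-4, seed = 99)
  got <- estimate_qv(count_error_bases(sim$variants), sim$assessed_bases)
  expect_equal(count_error_bases(sim$variants), sim$planted_error_bases)
  expect_lt(abs(got$qv - (-10 * log10(sim$error_rate))), 0.05)
})

test_that("chromosome-end classification matches the expected patterns", {
  reps <- function(...) {
    v <- c(...)
    if (is.null(v))
      return(data.frame(start = numeric(0), end = numeric(0),
                        class = character(0)))
    m <- matrix(v, ncol = 3, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2],
               class = c("centromeric", "telomeric")[m[, 3]])
  }
  L <- 2e6
  ok <- classify_ends(L, reps(0, 50e3, 1, L - 5e3, L, 2), "acrocentric")
  expect_identical(ok$verdict, "complete")
  both <- classify_ends(L, reps(0, 50e3, 1, L - 40e3, L, 1), "acrocentric")
  expect_identical(both$verdict, "centromere_both_ends")
  none <- classify_ends(L, reps(), "acrocentric")
  expect_identical(none$verdict, "missing_both")
  meta <- classify_ends(L, reps(0, 5e3, 2, L - 5e3, L, 2), "metacentric")
  expect_identical(meta$verdict, "complete")
  expect_error(classify_ends(100, reps(), "acrocentric",
                             end_window = 60), "end_window")
})

test_that("the end-verdict table is total over all boolean combinations", {
  verdicts <- c("complete", "missing_centromere", "missing_telomere",
                "missing_both", "centromere_both_ends", "other")
  for (karyo in c("acrocentric", "metacentric")) {
    for (i in 0:15) {
      b <- as.logical(bitwAnd(i, c(1L, 2L, 4L, 8L)))
      v <- end_verdict(b[1], b[2], b[3], b[4], karyo)
      expect_length(v, 1)
      expect_true(v %in% verdicts)
    }
  }
  # spot-check the acrocentric corners
  expect_identical(end_verdict(TRUE, FALSE, FALSE, TRUE, "acrocentric"),
                   "complete")
  expect_identical(end_verdict(TRUE, FALSE, TRUE, TRUE, "acrocentric"),
                   "centromere_both_ends")
  expect_identical(end_verdict(FALSE, TRUE, TRUE, FALSE, "acrocentric"),
                   "other")
})

test_that("repeat regions merge on >= 1 bp overlap, never on abutment", {
  r <- data.frame(chrom = "chr1", start = c(0, 99), end = c(100, 200),
                  class = "centromeric")
  st <- repeat_region_stats(r, c(chr1 = 1e6))
  chrstart <- st[st$category == "CHRSTART", ]
  expect_identical(chrstart$n, 1L)
  expect_equal(chrstart$mean_length, 200)

  ab <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                   class = "centromeric")
  st2 <- repeat_region_stats(ab, c(chr1 = 1e6))
  expect_identical(st2[st2$category == "CHRSTART", "n"], 2L)
  expect_equal(st2[st2$category == "CHRSTART", "mean_length"], 100)

  # single region: CI undefined at n < 2
  one <- repeat_region_stats(ab[1, ], c(chr1 = 1e6))
  expect_true(is.na(one[one$category == "CHRSTART", "ci_low"]))

  # categorisation: unplaced beats position; middle of chromosome is
  # CHRSCAFF
  mix <- data.frame(chrom = c("chr1", "scaf9"), start = c(7e5, 10),
                    end = c(7e5 + 100, 200), class = "centromeric")
  st3 <- repeat_region_stats(mix, c(chr1 = 1e6), unplaced_names = "scaf9")
  expect_identical(st3[st3$category == "CHRSCAFF", "n"], 1L)
  expect_identical(st3[st3$category == "UNPLACED", "n"], 1L)
})

test_that("gap-gene proximity counts intron and flank hits correctly", {
  gene <- list(gene_id = "g1", scaffold = "s1", start = 0L, end = 200L,
               strand = "+", exons = cbind(start = c(0, 150),
                                           end = c(50, 200)),
               introns = matrix(c(50, 150), 1,
                                dimnames = list(NULL, c("start", "end"))))
  gaps <- data.frame(scaffold = "s1", start = 100L, end = 120L)
  p <- gap_gene_proximity(gaps, list(gene))
  expect_identical(p$n_genes_gap_in_intron, 1L)
  expect_identical(p$n_genes_gap_within_flank, 1L)

  # gap 5 kb upstream: flank hit only
  up <- data.frame(scaffold = "s1", start = -5200L + 0L, end = -5000L)
  up <- data.frame(scaffold = "s1", start = 0L, end = 0L)  # placeholder
  gene2 <- gene; gene2$start <- 10000L; gene2$end <- 10200L
  gene2$exons <- gene$exons + 10000L
  gene2$introns <- gene$introns + 10000L
  gaps2 <- data.frame(scaffold = "s1", start = 4900L, end = 5000L)
  p2 <- gap_gene_proximity(gaps2, list(gene2))
  expect_identical(p2$n_genes_gap_in_intron, 0L)
  expect_identical(p2$n_genes_gap_within_flank, 1L)

  # no gaps at all; genes on scaffolds absent from the gap table are
  # gap-free
  p3 <- gap_gene_proximity(gaps[0, ], list(gene))
  expect_identical(p3$n_genes_gap_in_intron, 0L)
  expect_identical(p3$n_genes_gap_within_flank, 0L)
})

test_that("intron gap hits are a subset of flank hits on random instances", {
  set.seed(43)
  for (i in 1:20) {
    genes <- lapply(1:10, function(k) {
      start <- sample(1e5, 1)
      ex <- cbind(start = start + c(0, 400), end = start + c(200, 600))
      list(gene_id = paste0("g", k), scaffold = "s1", start = start,
           end = start + 600L, strand = "+", exons = ex,
           introns = matrix(c(start + 200, start + 400), 1,
                            dimnames = list(NULL, c("start", "end"))))
    })
    gs <- sort(sample(1e5, 5))
    gaps <- data.frame(scaffold = "s1", start = gs,
                       end = gs + sample(10:500, 5, replace = TRUE))
    p <- gap_gene_proximity(gaps, genes, flank_bp = sample(0:20000, 1))
    expect_lte(p$n_genes_gap_in_intron, p$n_genes_gap_within_flank)
  }
})

test_that("transcript classes follow the not_aligning > split > low-coverage order", {
  cds <- data.frame(transcript = c("t1", "t2", "t3", "t4"),
                    cds_start = 0L, cds_end = 1000L, transcript_len = 1200L,
                    stringsAsFactors = FALSE)
  al <- rbind(
    # t2: one placement split across two chromosomes
    data.frame(query = "t2", target = c("chr1", "chr7"),
               query_start = c(0L, 600L), query_end = c(600L, 1200L),
               matches = c(600L, 600L), placement = "t2p1"),
    # t3: covers 94% of the CDS
    data.frame(query = "t3", target = "chr1", query_start = 0L,
               query_end = 940L, matches = 940L, placement = "t3p1"),
    # t4: clean full-coverage alignment
    data.frame(query = "t4", target = "chr2", query_start = 0L,
               query_end = 1200L, matches = 1200L, placement = "t4p1"))
  cl <- classify_transcripts(al, cds)
  expect_identical(cl$status,
                   c("not_aligning", "split", "low_cds_coverage", "ok"))
  expect_equal(cl$best_cds_coverage[3], 0.94)
  # the best placement is the one with maximal summed matches
  al2 <- rbind(al,
               data.frame(query = "t2", target = "chr1", query_start = 0L,
                          query_end = 1200L, matches = 1250L,
                          placement = "t2p2"))
  cl2 <- classify_transcripts(al2, cds)
  expect_identical(cl2$status[2], "ok")
  # CDS outside the transcript errors
  bad <- cds; bad$cds_end[1] <- 2000L
  expect_error(classify_transcripts(al, bad), "CDS range")
})

test_that("motif-run finding locates planted tandem arrays on both strands", {
  s <- paste0(rand_seq(100), strrep("TTAGGG", 10), rand_seq(50),
              strrep(revcomp("TTAGGG"), 5), rand_seq(30))
  runs <- find_motif_runs(s, "TTAGGG", min_copies = 3)
  expect_identical(nrow(runs), 2L)
  expect_identical(runs$start[1], 100L)
  expect_identical(runs$n_copies, c(10L, 5L))
  expect_identical(nrow(find_motif_runs(rand_seq(200), "TTAGGG")), 0L)
})

test_that("classify_ends reports complete ends on every truth chromosome", {
  ts <- small_truth_set()
  cfg <- ts$truth$repeat_config
  for (ch in names(ts$truth$sequences)) {
    s <- ts$truth$sequences[[ch]]
    reps <- rbind(
      cbind(find_motif_runs(s, cfg$centromeric$motif)[, 1:2],
            class = "centromeric"),
      cbind(find_motif_runs(s, cfg$telomeric$motif)[, 1:2],
            class = "telomeric"))
    ec <- classify_ends(nchar(s), reps, "acrocentric", end_window = 1e5)
    expect_identical(ec$verdict, "complete")
  }
})
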