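# Readers for the tabular formats the pipeline consumes: GFF3 gene models,
# PAF alignment blocks, a minimal VCF subset, BED4 repeat intervals, and the
# genetic-map marker tables.  Internal coordinates are 0-based half-open
# except VariantRecord positions, which stay 1-based as in VCF.

#' Read gene models from a GFF3 file
#'
#' Consumes `gene`/`mRNA`/`exon` features linked by `Parent`.  Exons are the
#' union over all of a gene's transcripts (merged when overlapping or
#' abutting), and GFF's 1-based inclusive coordinates are converted to
#' 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return List of gene models; each a list with `gene_id`, `scaffold`,
#'   `start`, `end`, `strand`, `exons` (two-column matrix of 0-based
#'   half-open intervals) and `introns` (complement of exons in the span).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gdf <- as.data.frame(gr)
  type <- as.character(gdf$type)
  genes <- which(type == "gene")
  if (length(genes) == 0) return(list())
  ids <- as.character(gdf$ID)
  parent <- vapply(gdf$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  # map transcript id -> gene id, then exon -> gene
  tx <- which(type %in% c("mRNA", "transcript"))
  tx_gene <- stats::setNames(parent[tx], ids[tx])
  out <- vector("list", length(genes))
  starts <- gdf$start; ends <- gdf$end
  chroms <- as.character(gdf$seqnames)
  strands <- as.character(gdf$strand)
  exon_idx <- which(type == "exon")
  exon_gene <- tx_gene[parent[exon_idx]]
  direct <- is.na(exon_gene)           # exons parented directly on a gene
  exon_gene[direct] <- parent[exon_idx][direct]
  for (k in seq_along(genes)) {
    i <- genes[k]
    gid <- ids[i]
    g_start <- starts[i] - 1L
    g_end <- ends[i]
    ex <- exon_idx[!is.na(exon_gene) & exon_gene == gid]
    if (length(ex)) {
      ir <- IRanges::reduce(IRanges::IRanges(starts[ex], ends[ex]))
      exons <- cbind(start = BiocGenerics::start(ir) - 1L,
                     end = BiocGenerics::end(ir))
      if (any(exons[, "start"] < g_start | exons[, "end"] > g_end))
        stop("GFF3 ", path, ": exon outside gene span for ", gid)
    } else {
      exons <- cbind(start = g_start, end = g_end)
    }
    out[[k]] <- list(gene_id = gid, scaffold = chroms[i], start = g_start,
                     end = g_end, strand = strands[i], exons = exons,
                     introns = intervals_complement(exons, g_start, g_end))
  }
  out
}

# complement of sorted disjoint intervals within [lo, hi)
intervals_complement <- function(iv, lo, hi) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  bounds <- c(lo, t(iv), hi)
  m <- matrix(bounds, ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  m[m[, "end"] > m[, "start"], , drop = FALSE]
}

#' Read alignment blocks from a PAF file
#'
#' Parses the 12 mandatory PAF columns (coordinates are already 0-based
#' half-open in PAF); optional SAM-style tags are ignored.
#'
#' @param path Path to a PAF file.
#' @return Data frame of alignment blocks: `query`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target`, `target_len`,
#'   `target_start`, `target_end`, `matches`, `block_len`, `mapq`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_paf())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad)) stop("PAF ", path, " line ", bad[1], ": fewer than 12 columns")
  mat <- do.call(rbind, lapply(fields, `[`, 1:12))
  df <- data.frame(query = mat[, 1], query_len = as.integer(mat[, 2]),
                   query_start = as.integer(mat[, 3]),
                   query_end = as.integer(mat[, 4]), strand = mat[, 5],
                   target = mat[, 6], target_len = as.integer(mat[, 7]),
                   target_start = as.integer(mat[, 8]),
                   target_end = as.integer(mat[, 9]),
                   matches = as.integer(mat[, 10]),
                   block_len = as.integer(mat[, 11]),
                   mapq = as.integer(mat[, 12]), stringsAsFactors = FALSE)
  bad <- which(is.na(df$query_start) | is.na(df$target_start) |
                 df$query_start >= df$query_end |
                 df$target_start >= df$target_end |
                 !df$strand %in% c("+", "-"))
  if (length(bad)) stop("PAF ", path, " line ", bad[1], ": malformed record")
  df
}

empty_paf <- function() {
  data.frame(query = character(0), query_len = integer(0),
             query_start = integer(0), query_end = integer(0),
             strand = character(0), target = character(0),
             target_len = integer(0), target_start = integer(0),
             target_end = integer(0), matches = integer(0),
             block_len = integer(0), mapq = integer(0))
}

#' Write alignment blocks to a PAF file
#' @param blocks Data frame as returned by [read_paf()].
#' @param path Output path.
#' @export
write_paf <- function(blocks, path) {
  if (nrow(blocks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  lines <- with(blocks, paste(query, query_len, query_start, query_end,
                              strand, target, target_len, target_start,
                              target_end, matches, block_len, mapq,
                              sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read small-variant records from a VCF file
#'
#' Reads a fixed subset of VCF 4.x (CHROM, POS, REF, ALT, FILTER and the
#' first sample's GT) sufficient for consensus-quality estimation.
#' Positions stay 1-based as in VCF.
#'
#' @param path Path to an uncompressed VCF.
#' @return Data frame with `scaffold`, `position`, `ref_allele`,
#'   `alt_allele`, `genotype` ("het"/"hom_alt") and `filter` columns.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(data.frame(scaffold = character(0), position = integer(0),
                      ref_allele = character(0), alt_allele = character(0),
                      genotype = character(0), filter = character(0)))
  }
  gt <- rep(NA_character_, n)
  if (ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  }
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  genotype <- vapply(alleles, function(a) {
    a <- a[!is.na(a) & a != "."]
    if (length(a) == 0) return("het")
    if (length(unique(a)) == 1 && a[1] != "0") "hom_alt" else "het"
  }, character(1))
  ref <- unname(fix[, "REF"]); alt <- unname(fix[, "ALT"])
  if (any(!nzchar(ref) | !nzchar(alt) | is.na(alt)))
    stop("VCF ", path, ": empty REF/ALT allele")
  if (any(ref == alt))
    stop("VCF ", path, ": REF equals ALT")
  data.frame(scaffold = unname(fix[, "CHROM"]),
             position = as.integer(fix[, "POS"]), ref_allele = ref,
             alt_allele = alt, genotype = genotype,
             filter = unname(fix[, "FILTER"]), stringsAsFactors = FALSE)
}

#' Write variant records as a minimal VCF
#' @param variants Data frame as returned by [read_variants()].
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the header.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "sample1", sep = "\t"), con)
  if (nrow(variants)) {
    gt <- ifelse(variants$genotype == "hom_alt", "1/1", "0/1")
    writeLines(paste(variants$scaffold, variants$position, ".",
                     variants$ref_allele, variants$alt_allele, ".",
                     variants$filter, ".", "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Read labelled repeat intervals from a BED4 file
#'
#' @param path Path to a BED file whose fourth column is a repeat class
#'   label (for example `centromeric` or `telomeric`).
#' @return Data frame with `chrom`, 0-based half-open `start`/`end`, and
#'   `class` columns.
#' @export
read_bed_repeats <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad)) stop("BED ", path, " line ", bad[1], ": fewer than 4 columns")
  mat <- do.call(rbind, lapply(fields, `[`, 1:4))
  df <- data.frame(chrom = mat[, 1], start = as.integer(mat[, 2]),
                   end = as.integer(mat[, 3]), class = mat[, 4],
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)
  if (length(bad)) stop("BED ", path, " line ", bad[1], ": malformed interval")
  df
}

#' Read a genetic-map marker table
#'
#' @param path TSV with header columns `marker_id`, `linkage_group`,
#'   `map_order`, `map_position` (centimorgans) and `sequence`.
#' @return Data frame of markers.
#' @export
read_markers <- function(path) {
  df <- read_tsv_plain(path, col_classes = "character")
  need <- c("marker_id", "linkage_group", "map_order", "map_position",
            "sequence")
  if (!all(need %in% names(df)))
    stop("marker TSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df$map_order <- as.integer(df$map_order)
  df$map_position <- as.numeric(df$map_position)
  if (anyDuplicated(df[c("linkage_group", "map_order")]))
    stop("marker TSV ", path, ": map_order not unique within linkage group")
  df
}

#' Read a precomputed marker-hit table
#'
#' @param path TSV with header columns `marker_id`, `scaffold`, `position`
#'   (0-based), `identity`, `coverage`, `n_placements`.
#' @return Data frame of marker hits.
#' @export
read_marker_hits <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("marker_id", "scaffold", "position", "identity", "coverage",
            "n_placements")
  if (!all(need %in% names(df)))
    stop("marker-hit TSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df
}
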