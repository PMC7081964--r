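# Stage orchestration: configuration, file-level pipeline entry points and
# the subcommand dispatcher behind the inst/scripts/asmforge wrapper.
# Logs go to stderr; data go to files; reports embed the package version,
# a config hash and input checksums for provenance.

#' Default pipeline configuration
#'
#' All tunables in one validated list: marker filtering (`min_identity`
#' 0.98, full-length, unique-only), chimera breaking
#' (`min_conflict_markers` 2), chromosome building (`inter_scaffold_gap`
#' 100 bp), gap filling (`min_flank` 5000 bp strict, `max_distance` 10 bp
#' inclusive, collapse tolerances 20 bp / max(20 bp, 10%)), and QC
#' (`ng_genome_size` 2.8e9, `min_cds_cov` 0.95, `flank_bp` 10000,
#' `end_window` 500000, `min_gap_run` 10, telomere motif `TTAGGG`).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(min_identity = 0.98, require_full_length = TRUE, unique_only = TRUE,
       min_conflict_markers = 2L, inter_scaffold_gap = 100L,
       min_flank = 5000L, max_distance = 10L, collapse_pos_tol = 20L,
       collapse_size_tol_abs = 20L, collapse_size_tol_frac = 0.10,
       ng_genome_size = 2.8e9, min_cds_cov = 0.95, flank_bp = 10000L,
       end_window = 500000L, min_gap_run = 10L,
       telomere_motif = "TTAGGG", centromere_motif = NA_character_,
       seed = 42L)
}

#' Validate a configuration list
#' @param config Configuration list.
#' @return Invisibly `TRUE`, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  chk <- function(cond, field) if (!cond) stop("invalid config: ", field)
  chk(config$min_identity > 0 && config$min_identity <= 1, "min_identity")
  chk(is.logical(config$require_full_length), "require_full_length")
  chk(is.logical(config$unique_only), "unique_only")
  chk(config$min_conflict_markers >= 1, "min_conflict_markers")
  chk(config$inter_scaffold_gap >= 1, "inter_scaffold_gap")
  chk(config$min_flank >= 0, "min_flank")
  chk(config$max_distance >= 0, "max_distance")
  chk(config$collapse_pos_tol >= 0, "collapse_pos_tol")
  chk(config$collapse_size_tol_abs >= 0, "collapse_size_tol_abs")
  chk(config$collapse_size_tol_frac >= 0, "collapse_size_tol_frac")
  chk(config$ng_genome_size > 0, "ng_genome_size")
  chk(config$min_cds_cov > 0 && config$min_cds_cov <= 1, "min_cds_cov")
  chk(config$flank_bp >= 0, "flank_bp")
  chk(config$end_window >= 1, "end_window")
  chk(config$min_gap_run >= 1, "min_gap_run")
  invisible(TRUE)
}

#' Read a TOML-style key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are parsed
#' as logical (`true`/`false`), number, or string.  Unknown keys are an
#' error; omitted keys keep their [default_config()] value.
#'
#' @param path Path to the config file.
#' @param base Configuration list to override (default [default_config()]).
#' @return The merged, validated configuration.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                                ln))[[1]]
    if (length(m) != 3) stop("config ", path, ": cannot parse line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(base)) stop("config ", path, ": unknown key: ", key)
    val <- gsub('^"|"$', "", val)
    parsed <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (grepl("^[-+0-9.eE]+$", val) &&
                 !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
    base[[key]] <- parsed
  }
  validate_config(base)
  base
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

report_provenance <- function(config, inputs) {
  list(tool = "asmforge",
       version = as.character(utils::packageVersion("asmforge")),
       config = config, config_hash = config_hash(config),
       input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])))
}

log_msg <- function(...) message("[asmforge] ", ...)

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Generate a synthetic fixture directory
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Passed on to [simulate_truth_set()].
#' @return Invisibly, `out_dir`.
#' @export
pipeline_simulate <- function(out_dir, seed = 42L, ...) {
  log_msg("simulate: seed ", seed, " -> ", out_dir)
  simulate_truth_set(seed = seed, out_dir = out_dir, ...)
  invisible(out_dir)
}

#' Run the scaffolding stage on files
#'
#' @param agp Draft AGP path.
#' @param contig_fasta FASTA of the contigs the AGP references.
#' @param markers_tsv Genetic-map marker TSV.
#' @param hits_tsv Marker-hit TSV.
#' @param out_dir Output directory.
#' @param config Pipeline configuration.
#' @return Invisibly, the [map_guided_scaffold()] result.
#' @export
pipeline_scaffold <- function(agp, contig_fasta, markers_tsv, hits_tsv,
                              out_dir, config = default_config()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layouts <- read_agp(agp)
  contigs <- read_fasta(contig_fasta)
  markers <- read_markers(markers_tsv)
  hits <- read_marker_hits(hits_tsv)
  log_msg("scaffold: ", length(layouts), " scaffolds, ", nrow(hits),
          " raw marker hits")
  res <- map_guided_scaffold(layouts, hits, markers, config)
  log_msg("scaffold: ", length(res$breaks), " chimera(s) broken, ",
          length(res$chromosomes), " chromosome(s), ",
          length(res$unplaced), " unplaced")
  out_layouts <- c(res$chromosomes, res$segment_layouts[res$unplaced])
  write_agp(out_layouts, file.path(out_dir, "chromosomes.agp"))
  seqs <- vapply(out_layouts, layout_sequence, character(1),
                 contigs = contigs)
  write_fasta(seqs, file.path(out_dir, "chromosomes.fa"))
  write_tsv_plain(res$assignments, file.path(out_dir, "assignments.tsv"))
  breaks_df <- if (length(res$breaks)) do.call(rbind, lapply(
    res$breaks, function(b) data.frame(
      scaffold = b$scaffold,
      breakpoints = paste(b$breakpoints, collapse = ","),
      segment_groups = paste(b$segment_groups, collapse = ","),
      stringsAsFactors = FALSE))) else
    data.frame(scaffold = character(0), breakpoints = character(0),
               segment_groups = character(0))
  write_tsv_plain(breaks_df, file.path(out_dir, "breaks.tsv"))
  writeLines(res$unplaced, file.path(out_dir, "unplaced.txt"))
  rep <- c(report_provenance(config, c(agp, contig_fasta, markers_tsv,
                                       hits_tsv)),
           list(n_input_scaffolds = length(layouts),
                n_raw_hits = nrow(hits), n_breaks = length(res$breaks),
                n_chromosomes = length(res$chromosomes),
                n_unplaced = length(res$unplaced)))
  write_report_json(rep, file.path(out_dir, "scaffold_report.json"))
  invisible(res)
}

#' Run the gap-filling stage on files
#'
#' @param agp Scaffolded AGP path.
#' @param scaffold_fasta FASTA of the scaffold sequences.
#' @param patch_fastas Named character vector of patch FASTA paths (names
#'   are the patch-assembly ids).
#' @param patch_pafs Named character vector of matching PAF paths.
#' @param out_dir Output directory.
#' @param negative_gaps_tsv Optional collapse sidecar TSV.
#' @param config Pipeline configuration.
#' @return Invisibly, the [gap_fill()] result.
#' @export
pipeline_gapfill <- function(agp, scaffold_fasta, patch_fastas, patch_pafs,
                             out_dir, negative_gaps_tsv = NULL,
                             config = default_config()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layouts <- read_agp(agp)
  sequences <- read_fasta(scaffold_fasta)
  patches <- lapply(stats::setNames(names(patch_fastas),
                                    names(patch_fastas)), function(id) {
    list(contigs = read_fasta(patch_fastas[[id]]),
         paf = read_paf(patch_pafs[[id]]))
  })
  neg <- if (!is.null(negative_gaps_tsv)) read_negative_gaps(negative_gaps_tsv)
  res <- gap_fill(layouts, sequences, patches, negative_gaps = neg,
                  config = config)
  log_msg("gapfill: ", res$summary$n_filled, "/", res$summary$gaps_before,
          " gaps filled")
  write_fasta(res$sequences, file.path(out_dir, "filled.fa"))
  write_agp(res$layouts, file.path(out_dir, "filled.agp"))
  write_tsv_plain(res$decisions, file.path(out_dir, "decisions.tsv"))
  if (!is.null(res$collapse_decisions))
    write_tsv_plain(res$collapse_decisions,
                    file.path(out_dir, "collapse_decisions.tsv"))
  rep <- c(report_provenance(config, c(agp, scaffold_fasta,
                                       unname(patch_fastas),
                                       unname(patch_pafs))),
           res$summary)
  write_report_json(rep, file.path(out_dir, "gapfill_summary.json"))
  invisible(res)
}

#' Compute a QC report for an assembly
#'
#' Works from in-memory sequences; see [pipeline_qc()] for the file-level
#' wrapper.  Contig lengths come from splitting scaffolds at N runs of at
#' least `config$min_gap_run`.
#'
#' @param sequences Named character vector of scaffold/chromosome sequences.
#' @param config Pipeline configuration.
#' @param variants Optional variant table for QV estimation.
#' @param assessed_bases Bases assessed for QV (default: total non-N bases).
#' @param genes Optional gene-model list for gap-gene proximity.
#' @param repeats Optional repeat BED data frame; when absent and motifs
#'   are configured, repeat intervals are found by motif scanning.
#' @param karyotypes Named character vector ("acrocentric"/"metacentric")
#'   per sequence; default acrocentric.
#' @return List of QC components (class `qc_report`).
#' @export
qc_report <- function(sequences, config = default_config(), variants = NULL,
                      assessed_bases = NULL, genes = NULL, repeats = NULL,
                      karyotypes = NULL) {
  scaffold_lengths <- nchar(sequences)
  gap_list <- lapply(names(sequences), function(nm) {
    g <- gaps_from_sequence(sequences[[nm]], config$min_gap_run)
    if (nrow(g)) cbind(scaffold = nm, g) else NULL
  })
  gaps <- do.call(rbind, gap_list)
  if (is.null(gaps))
    gaps <- data.frame(scaffold = character(0), start = integer(0),
                       end = integer(0))
  contig_lengths <- unlist(lapply(names(sequences), function(nm) {
    g <- gaps[gaps$scaffold == nm, , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(g$start, g$end)),
                scaffold_lengths[[nm]])
    w <- bounds[seq(2, length(bounds), 2)] -
      bounds[seq(1, length(bounds), 2)]
    w[w > 0]
  }))
  out <- list(
    scaffold_stats = contiguity(scaffold_lengths, config$ng_genome_size),
    contig_stats = contiguity(contig_lengths, config$ng_genome_size),
    n_gaps = nrow(gaps), gaps = gaps)
  if (!is.null(variants)) {
    ab <- assessed_bases %||% sum(contig_lengths)
    out$qv <- estimate_qv(count_error_bases(variants), ab)
  }
  if (is.null(repeats) && !is.na(config$centromere_motif)) {
    repeats <- do.call(rbind, lapply(names(sequences), function(nm) {
      rbind(
        within_class(find_motif_runs(sequences[[nm]],
                                     config$centromere_motif), nm,
                     "centromeric"),
        within_class(find_motif_runs(sequences[[nm]],
                                     config$telomere_motif), nm,
                     "telomeric"))
    }))
  }
  if (!is.null(repeats)) {
    if (is.null(karyotypes))
      karyotypes <- stats::setNames(rep("acrocentric", length(sequences)),
                                    names(sequences))
    out$ends <- lapply(stats::setNames(names(sequences), names(sequences)),
                       function(nm) {
      r <- repeats[repeats$chrom == nm, , drop = FALSE]
      ew <- min(config$end_window, floor(scaffold_lengths[[nm]] / 2))
      classify_ends(scaffold_lengths[[nm]], r, karyotypes[[nm]], ew)
    })
    out$repeats <- repeats
  }
  if (!is.null(genes)) {
    out$gap_gene <- gap_gene_proximity(gaps, genes, config$flank_bp)
  }
  class(out) <- "qc_report"
  out
}

within_class <- function(runs, chrom, cls) {
  if (nrow(runs) == 0) return(NULL)
  data.frame(chrom = chrom, start = runs$start, end = runs$end, class = cls,
             stringsAsFactors = FALSE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  scaffolds: %d (N50 %.0f), contigs: %d (N50 %.0f), gaps: %d\n",
              length(x$scaffold_stats$lengths), x$scaffold_stats$nx[["50"]],
              length(x$contig_stats$lengths), x$contig_stats$nx[["50"]],
              x$n_gaps))
  if (!is.null(x$qv)) cat("  QV:", x$qv$qv_label, "\n")
  if (!is.null(x$ends)) {
    v <- vapply(x$ends, `[[`, character(1), "verdict")
    cat("  ends:", paste(sprintf("%s=%s", names(v), v), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Run the QC stage on files
#'
#' @param fasta Assembly FASTA path.
#' @param out_dir Output directory.
#' @param config Pipeline configuration.
#' @param vcf Optional VCF of non-matching base calls for QV.
#' @param gff3 Optional gene annotation for gap-gene proximity.
#' @param repeats_bed Optional repeat BED4 for end classification.
#' @param assessed_bases Optional explicit assessed-base count for QV.
#' @return Invisibly, the [qc_report()] list.
#' @export
pipeline_qc <- function(fasta, out_dir, config = default_config(),
                        vcf = NULL, gff3 = NULL, repeats_bed = NULL,
                        assessed_bases = NULL) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sequences <- read_fasta(fasta)
  variants <- if (!is.null(vcf)) read_variants(vcf)
  genes <- if (!is.null(gff3)) read_gff3_genes(gff3)
  repeats <- if (!is.null(repeats_bed)) read_bed_repeats(repeats_bed)
  rep <- qc_report(sequences, config, variants = variants,
                   assessed_bases = assessed_bases, genes = genes,
                   repeats = repeats)
  log_msg("qc: ", length(sequences), " sequences, ", rep$n_gaps, " gaps",
          if (!is.null(rep$qv)) paste0(", QV ", rep$qv$qv_label) else "")
  json <- list(
    scaffold = list(n = length(rep$scaffold_stats$lengths),
                    total_bp = rep$scaffold_stats$total_bp,
                    n50 = rep$scaffold_stats$nx[["50"]],
                    l50 = rep$scaffold_stats$lx[["50"]],
                    ng50 = rep$scaffold_stats$ngx[["50"]],
                    lg50 = rep$scaffold_stats$lgx[["50"]]),
    contig = list(n = length(rep$contig_stats$lengths),
                  total_bp = rep$contig_stats$total_bp,
                  n50 = rep$contig_stats$nx[["50"]],
                  l50 = rep$contig_stats$lx[["50"]],
                  ng50 = rep$contig_stats$ngx[["50"]],
                  lg50 = rep$contig_stats$lgx[["50"]]),
    n_gaps = rep$n_gaps)
  if (!is.null(rep$qv)) json$qv <- rep$qv
  if (!is.null(rep$ends))
    json$ends <- lapply(rep$ends, function(e)
      e[c("verdict", "has_centromere_start", "has_telomere_start",
          "has_centromere_end", "has_telomere_end")])
  if (!is.null(rep$gap_gene)) json$gap_gene <- rep$gap_gene
  json <- c(report_provenance(config, c(fasta, vcf, gff3, repeats_bed)),
            json)
  write_report_json(json, file.path(out_dir, "qc_report.json"))
  invisible(rep)
}

#' Compare two metric tables from files
#'
#' @param table_a,table_b Paths to two-column TSVs (`key`, `value`).
#' @param out_dir Output directory.
#' @param config Pipeline configuration.
#' @return Invisibly, the comparison data frame.
#' @export
pipeline_compare <- function(table_a, table_b, out_dir,
                             config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  read_metrics <- function(p) {
    df <- read_tsv_plain(p)
    if (!all(c("key", "value") %in% names(df)))
      stop("metric table ", p, " must have key/value columns")
    stats::setNames(as.numeric(df$value), df$key)
  }
  cmp <- compare_assemblies(read_metrics(table_a), read_metrics(table_b))
  write_tsv_plain(cmp, file.path(out_dir, "comparison.tsv"))
  write_report_json(c(report_provenance(config, c(table_a, table_b)),
                      list(comparison = cmp)),
                    file.path(out_dir, "comparison.json"))
  invisible(cmp)
}

usage_text <- function() {
  paste(
    "usage: asmforge <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --out-dir DIR [--seed N]",
    "  scaffold  --agp FILE --contigs FILE --markers FILE --hits FILE",
    "            --out-dir DIR [--config FILE]",
    "  gapfill   --agp FILE --fasta FILE --patch-a FILE --paf-a FILE",
    "            [--patch-b FILE --paf-b FILE] [--negative-gaps FILE]",
    "            --out-dir DIR [--config FILE]",
    "  qc        --fasta FILE [--vcf FILE] [--gff3 FILE] [--repeats FILE]",
    "            --out-dir DIR [--config FILE]",
    "  compare   --table-a FILE --table-b FILE --out-dir DIR",
    "",
    "global options: --config FILE, --seed N, --out-dir DIR",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop_usage("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key == "help") {
      flags[["help"]] <- TRUE
      i <- i + 1
    } else {
      if (i + 1 > length(args)) stop_usage("missing value for --", key)
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}

need_flag <- function(flags, key) {
  v <- flags[[key]]
  if (is.null(v)) stop_usage("missing required option --", key)
  if (key != "out-dir" && key != "seed" && !file.exists(v))
    stop_usage("input file not found: ", v)
  v
}

#' Dispatch a command-line subcommand
#'
#' Thin argument-parsing layer over the `pipeline_*` functions, used by the
#' `inst/scripts/asmforge` wrapper.  Usage problems (unknown subcommand,
#' missing input, bad config) return exit status 2; runtime failures return
#' 1; success returns 0.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly.
#' @export
run_subcommand <- function(args) {
  status <- tryCatch({
    if (length(args) == 0 || args[1] %in% c("--help", "-h", "help")) {
      cat(usage_text(), "\n")
      return(invisible(0L))
    }
    cmd <- args[1]
    if (!cmd %in% c("simulate", "scaffold", "gapfill", "qc", "compare"))
      stop_usage("unknown subcommand: ", cmd)
    flags <- parse_flags(args[-1])
    if (isTRUE(flags$help)) {
      cat(usage_text(), "\n")
      return(invisible(0L))
    }
    config <- if (!is.null(flags$config)) read_config(need_flag(flags, "config"))
      else default_config()
    if (!is.null(flags$seed)) {
      config$seed <- suppressWarnings(as.integer(flags$seed))
      if (is.na(config$seed)) stop_usage("--seed must be an integer")
    }
    switch(cmd,
      simulate = pipeline_simulate(need_flag(flags, "out-dir"),
                                   seed = config$seed),
      scaffold = pipeline_scaffold(need_flag(flags, "agp"),
                                   need_flag(flags, "contigs"),
                                   need_flag(flags, "markers"),
                                   need_flag(flags, "hits"),
                                   need_flag(flags, "out-dir"), config),
      gapfill = {
        pf <- c(A = need_flag(flags, "patch-a"))
        pp <- c(A = need_flag(flags, "paf-a"))
        if (!is.null(flags[["patch-b"]])) {
          pf["B"] <- need_flag(flags, "patch-b")
          pp["B"] <- need_flag(flags, "paf-b")
        }
        pipeline_gapfill(need_flag(flags, "agp"), need_flag(flags, "fasta"),
                         pf, pp, need_flag(flags, "out-dir"),
                         negative_gaps_tsv = flags[["negative-gaps"]],
                         config = config)
      },
      qc = pipeline_qc(need_flag(flags, "fasta"),
                       need_flag(flags, "out-dir"), config,
                       vcf = flags$vcf, gff3 = flags$gff3,
                       repeats_bed = flags$repeats),
      compare = pipeline_compare(need_flag(flags, "table-a"),
                                 need_flag(flags, "table-b"),
                                 need_flag(flags, "out-dir"), config))
    0L
  },
  asmforge_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    message(usage_text())
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
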