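#' Run a pipeline stage with a resolved configuration
#'
#' Single programmatic entry point behind the `frepscreen` command line
#' script. Each subcommand reads TSV inputs, runs the corresponding package
#' functions, and writes a fixed set of TSV/JSON artifacts into `out_dir`,
#' together with a copy of the fully resolved configuration
#' (`resolved_config.yaml`) and a run log. Unknown configuration keys are
#' rejected by name; reruns with identical inputs, configuration and seed
#' produce byte-identical outputs.
#'
#' Subcommands and their artifacts:
#' * `simulate` — guide library, screen counts and ground truth
#'   (`library.tsv`, `counts.tsv`, `truth.tsv`).
#' * `count` — barcode counts from FASTQ (`counts.tsv`, `qc.json`).
#' * `score` — per-gene FRep scores for one condition (`gene_scores.tsv`
#'   with volcano columns, `barcode_scores.tsv`).
#' * `classify` — responder groups from a wide score table
#'   (`labeled.tsv`, `group_counts.json`).
#' * `condense` — length-normalized transcriptome condensation
#'   (`condensation.tsv`, `group_stats.tsv` when groups are present).
#' * `qpcr` — -ddCt condensation from a Ct table (`ddct.tsv`).
#' * `compare` — screen-versus-screen comparison (`comparison.tsv`,
#'   `comparison.json`).
#'
#' @param subcommand One of `simulate`, `count`, `score`, `classify`,
#'   `condense`, `qpcr`, `compare`.
#' @param config Path to a YAML configuration file, or a named list.
#' @param overrides Named list of `key = value` overrides applied on top of
#'   the file configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
frep_run <- function(subcommand = c("simulate", "count", "score", "classify",
                                    "condense", "qpcr", "compare"),
                     config = list(), overrides = list(), out_dir = ".") {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults(subcommand)
  cfg <- merge_config(defaults, config, subcommand)
  cfg <- merge_config(cfg, overrides, subcommand)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", subcommand,
                  "] ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  logf("start; out_dir=", normalizePath(out_dir))
  t0 <- proc.time()[["elapsed"]]
  paths <- switch(subcommand,
    simulate = run_simulate(cfg, out_dir),
    count = run_count(cfg, out_dir),
    score = run_score(cfg, out_dir),
    classify = run_classify(cfg, out_dir),
    condense = run_condense(cfg, out_dir),
    qpcr = run_qpcr(cfg, out_dir),
    compare = run_compare(cfg, out_dir)
  )
  logf("done in ", sprintf("%.2f", proc.time()[["elapsed"]] - t0), " s; ",
       "artifacts: ", paste(basename(unlist(paths)), collapse = ", "))
  invisible(paths)
}

pipeline_defaults <- function(subcommand) {
  switch(subcommand,
    simulate = c(unclass(sim_config()),
                 list(background = "WT", temp = 30, minutes = 0)),
    count = list(fastq = NULL, library = NULL, flank5 = "ACGGTCTC",
                 flank3 = "GAGACCGT", barcode_length = 12L,
                 max_flank_mismatch = 1L, max_mismatch = 1L),
    score = list(counts = NULL, library = NULL, background = "WT", temp = 30,
                 minutes = 0, pseudocount = 0.5, min_count = 20,
                 window_size = 201L, aggregate = "mean", p_floor = 1e-12,
                 nominal_depth = 2e5),
    classify = list(scores = NULL, hit = 2, basal_cap = 3),
    condense = list(transcripts = NULL, background = "WT", rep = 1L,
                    temps = c(30, 42), bin_size = 100L, pseudocount = 0.5,
                    nominal_depth = 2e6, background_group = "background"),
    qpcr = list(ct = NULL, reference_gene = "ACT1", reference_strain = NULL),
    compare = list(scores_a = NULL, scores_b = NULL, hit_threshold = 2,
                   delta_threshold = 1)
  )
}

merge_config <- function(base, extra, subcommand) {
  if (!length(extra)) return(base)
  if (is.null(names(extra)) || any(!nzchar(names(extra))))
    stop("configuration entries must be named", call. = FALSE)
  unknown <- setdiff(names(extra), names(base))
  if (length(unknown))
    stop("unknown configuration key(s) for '", subcommand, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  base[names(extra)] <- extra
  base
}

require_input <- function(cfg, key) {
  path <- cfg[[key]]
  if (is.null(path))
    stop("configuration key '", key, "' is required", call. = FALSE)
  if (!file.exists(path))
    stop("input file for '", key, "' not found: ", path, call. = FALSE)
  path
}

run_simulate <- function(cfg, out_dir) {
  sc <- do.call(sim_config,
                cfg[setdiff(names(cfg), c("background", "temp", "minutes"))])
  lib <- simulate_guide_library(sc)
  sim <- simulate_screen(lib, sc, background = cfg$background,
                         temp = cfg$temp, minutes = cfg$minutes)
  p <- list(library = file.path(out_dir, "library.tsv"),
            counts = file.path(out_dir, "counts.tsv"),
            truth = file.path(out_dir, "truth.tsv"))
  write_library_table(lib, p$library)
  write_tsv(sim$counts, p$counts)
  write_tsv(sim$truth, p$truth)
  p
}

run_count <- function(cfg, out_dir) {
  fastq <- require_input(cfg, "fastq")
  lib <- parse_library_table(require_input(cfg, "library"))
  layout <- read_layout(cfg$flank5, cfg$flank3, cfg$barcode_length,
                        cfg$max_flank_mismatch)
  res <- count_barcodes(fastq, lib, layout, max_mismatch = cfg$max_mismatch)
  p <- list(counts = file.path(out_dir, "counts.tsv"),
            qc = file.path(out_dir, "qc.json"))
  write_tsv(data.frame(barcode = names(res$counts),
                       count = unname(res$counts)), p$counts)
  jsonlite::write_json(res$qc, p$qc, auto_unbox = TRUE, pretty = TRUE)
  p
}

run_score <- function(cfg, out_dir) {
  counts <- read_count_table(require_input(cfg, "counts"))
  lib <- parse_library_table(require_input(cfg, "library"))
  res <- frep_score_screen(counts, lib, background = cfg$background,
                           temp = cfg$temp, minutes = cfg$minutes,
                           pseudocount = cfg$pseudocount,
                           min_count = cfg$min_count,
                           window_size = cfg$window_size,
                           aggregate = cfg$aggregate, p_floor = cfg$p_floor,
                           nominal_depth = cfg$nominal_depth)
  genes <- res$genes
  genes$neg_log10_p <- -log10(genes$p_value)
  bc <- do.call(rbind, lapply(names(res$barcodes), function(r) {
    cbind(replicate = r, res$barcodes[[r]])
  }))
  p <- list(genes = file.path(out_dir, "gene_scores.tsv"),
            barcodes = file.path(out_dir, "barcode_scores.tsv"))
  write_tsv(genes, p$genes)
  write_tsv(bc, p$barcodes)
  p
}

run_classify <- function(cfg, out_dir) {
  wide <- utils::read.delim(require_input(cfg, "scores"),
                            stringsAsFactors = FALSE)
  res <- classify_all(wide, hit = cfg$hit, basal_cap = cfg$basal_cap)
  p <- list(labeled = file.path(out_dir, "labeled.tsv"),
            counts = file.path(out_dir, "group_counts.json"))
  write_tsv(res$table, p$labeled)
  jsonlite::write_json(as.list(res$counts), p$counts, auto_unbox = TRUE,
                       pretty = TRUE)
  p
}

run_condense <- function(cfg, out_dir) {
  tx <- utils::read.delim(require_input(cfg, "transcripts"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  scored <- score_transcriptome(tx, temps = cfg$temps,
                                background = cfg$background, rep = cfg$rep,
                                bin_size = cfg$bin_size,
                                pseudocount = cfg$pseudocount,
                                nominal_depth = cfg$nominal_depth)
  p <- list(condensation = file.path(out_dir, "condensation.tsv"))
  write_tsv(scored, p$condensation)
  if ("group" %in% names(scored)) {
    gs <- group_comparison(scored$delta_cond_z, scored$group,
                           background = cfg$background_group)
    p$group_stats <- file.path(out_dir, "group_stats.tsv")
    write_tsv(gs, p$group_stats)
  }
  p
}

run_qpcr <- function(cfg, out_dir) {
  ct <- utils::read.delim(require_input(cfg, "ct"), stringsAsFactors = FALSE)
  res <- ddct_condensation(ct, reference_gene = cfg$reference_gene,
                           reference_strain = cfg$reference_strain)
  p <- list(ddct = file.path(out_dir, "ddct.tsv"))
  write_tsv(res, p$ddct)
  p
}

run_compare <- function(cfg, out_dir) {
  a <- utils::read.delim(require_input(cfg, "scores_a"),
                         stringsAsFactors = FALSE)
  b <- utils::read.delim(require_input(cfg, "scores_b"),
                         stringsAsFactors = FALSE)
  res <- compare_screens(a, b, hit_threshold = cfg$hit_threshold,
                         delta_threshold = cfg$delta_threshold)
  p <- list(table = file.path(out_dir, "comparison.tsv"),
            summary = file.path(out_dir, "comparison.json"))
  write_tsv(res$table, p$table)
  jsonlite::write_json(list(pearson_r = res$pearson_r,
                            n_shared = res$n_shared),
                       p$summary, auto_unbox = TRUE, pretty = TRUE)
  p
}
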