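#' Pellet-versus-total log ratio per barcode
#'
#' The raw partitioning statistic behind the FRep score:
#' `log2((pellet/sf_p + pc) / (total/sf_t + pc))` after size-factor
#' normalization, with a symmetric pseudocount that keeps zero-pellet
#' barcodes finite (and strongly negative). The normalized total-fraction
#' count is reported as the barcode's reference abundance, the axis along
#' which the neighbourhood normalization slides.
#'
#' @param pellet_col,total_col Aligned numeric count vectors over the same
#'   barcodes.
#' @param size_factors Numeric length-2 vector `(sf_pellet, sf_total)` or a
#'   named vector containing entries for both columns.
#' @param pseudocount Pseudocount on the normalized-count scale.
#' @param barcode Optional barcode identifiers to carry through.
#' @return Data.frame with `barcode` (if given), `log_ratio`,
#'   `reference_abundance`.
#' @export
barcode_log_ratio <- function(pellet_col, total_col, size_factors = c(1, 1),
                              pseudocount = 0.5, barcode = NULL) {
  if (length(pellet_col) != length(total_col))
    stop("barcode_log_ratio: columns must be aligned on the same barcodes",
         call. = FALSE)
  sf_p <- size_factors[[1]]
  sf_t <- size_factors[[2]]
  p <- pellet_col / sf_p
  t <- total_col / sf_t
  out <- data.frame(
    log_ratio = log2((p + pseudocount) / (t + pseudocount)),
    reference_abundance = t
  )
  if (!is.null(barcode)) out <- cbind(barcode = barcode, out)
  out
}

#' Neighbourhood-normalized scores (NNS)
#'
#' Standardizes each barcode's log-ratio against the distribution of ratios
#' among barcodes of similar abundance: barcodes are sorted by reference
#' abundance, each one's neighbourhood is the symmetric window of
#' `window_size` barcodes around it in that ordering (truncated at the
#' edges), and the score is
#' `nns = (log_ratio - median(window)) / (1.4826 * MAD(window))`.
#' The robust centre/spread make the score a z-like statistic that is
#' insensitive to the heavy tails typical of pooled screens; its magnitude
#' is in units of neighbourhood standard deviations.
#'
#' @param rows Data.frame with columns `barcode`, `log_ratio`,
#'   `reference_abundance` (from [barcode_log_ratio()]).
#' @param window_size Odd window width K (clamped down to the number of
#'   surviving barcodes when larger).
#' @param min_count Barcodes with reference abundance below this are dropped
#'   before scoring; low-count ratios are dominated by Poisson noise.
#' @param scale_floor Lower floor on the neighbourhood scale, guarding
#'   degenerate (constant) windows.
#' @return Data.frame with `barcode`, `reference_abundance`, `log_ratio`,
#'   `nbhd_location`, `nbhd_scale`, `nns`, sorted by reference abundance.
#' @export
neighborhood_normalize <- function(rows, window_size = 201L, min_count = 20,
                                   scale_floor = 1e-8) {
  stopifnot(all(c("barcode", "log_ratio", "reference_abundance") %in%
                  names(rows)))
  rows <- rows[is.finite(rows$log_ratio) &
                 rows$reference_abundance >= min_count, , drop = FALSE]
  n <- nrow(rows)
  if (n < 3L)
    stop("neighborhood_normalize: fewer than 3 barcodes survive the ",
         "min_count filter", call. = FALSE)
  k <- as.integer(window_size)
  if (k %% 2L == 0L)
    stop("neighborhood_normalize: window_size must be odd", call. = FALSE)
  if (k > n) k <- if (n %% 2L == 1L) n else n - 1L
  if (k < 3L) k <- 3L
  ord <- order(rows$reference_abundance, rows$barcode, method = "radix")
  rows <- rows[ord, , drop = FALSE]
  half <- (k - 1L) %/% 2L
  lr <- rows$log_ratio
  loc <- numeric(n)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- lr[lo:hi]
    med <- stats::median(w)
    loc[i] <- med
    sc[i] <- max(1.4826 * stats::median(abs(w - med)), scale_floor)
  }
  rows$nbhd_location <- loc
  rows$nbhd_scale <- sc
  rows$nns <- (lr - loc) / sc
  rownames(rows) <- NULL
  rows[, c("barcode", "reference_abundance", "log_ratio", "nbhd_location",
           "nbhd_scale", "nns")]
}

#' Aggregate barcode NNS to per-gene scores
#'
#' Barcodes are averaged within their guide, then guides within their gene
#' (unweighted by default). Genes none of whose guides retain a scored
#' barcode get `NA`.
#'
#' @param barcode_scores Output of [neighborhood_normalize()] for one
#'   replicate.
#' @param library A `guide_library`.
#' @param aggregate `"mean"` (default) or `"median"`, applied at both the
#'   barcode-to-guide and guide-to-gene steps.
#' @return Data.frame with `gene`, `score`, `n_guides`, `n_barcodes`,
#'   covering every gene in the library.
#' @export
gene_frep_score <- function(barcode_scores, library,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  library <- validate_guide_library(library)
  idx <- match(barcode_scores$barcode, library$barcode)
  if (anyNA(idx))
    stop("gene_frep_score: scored barcode(s) absent from library", call. = FALSE)
  df <- data.frame(
    guide_id = library$guide_id[idx],
    gene = library$gene[idx],
    nns = barcode_scores$nns,
    stringsAsFactors = FALSE
  )
  gsplit <- split(df$nns, df$guide_id)
  guide_score <- vapply(gsplit, agg, numeric(1))
  guide_gene <- library$gene[match(names(gsplit), library$guide_id)]
  per_gene <- split(guide_score, guide_gene)
  genes <- unique(library$gene)
  score <- rep(NA_real_, length(genes))
  n_guides <- integer(length(genes))
  hit <- match(names(per_gene), genes)
  score[hit] <- vapply(per_gene, agg, numeric(1))
  n_guides[hit] <- lengths(per_gene)
  nb <- table(factor(df$gene, levels = genes))
  data.frame(gene = genes, score = score, n_guides = n_guides,
             n_barcodes = as.integer(nb), stringsAsFactors = FALSE)
}

#' Combine per-replicate gene scores into a FRep score table
#'
#' The gene's FRep score is the arithmetic mean of its per-replicate scores;
#' reproducibility is quantified by a two-sided one-sample t-test of the
#' replicate scores against zero. Degenerate cases are flagged rather than
#' silently propagated: genes with fewer than two non-missing replicates get
#' no p-value, and zero replicate variance reports the configured p floor.
#'
#' @param scores Data.frame with a `gene` column and one numeric column per
#'   replicate (NA = missing in that replicate).
#' @param p_floor Smallest reportable p-value for zero-variance genes.
#' @return Data.frame with `gene`, `frep_score`, `t_stat`, `p_value`,
#'   `n_replicates`, `flag` (`"ok"`, `"insufficient_replicates"` or
#'   `"degenerate_variance"`).
#' @export
combine_replicates <- function(scores, p_floor = 1e-12) {
  stopifnot("gene" %in% names(scores))
  m <- as.matrix(scores[, setdiff(names(scores), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  n <- rowSums(!is.na(m))
  mean_ <- rowMeans(m, na.rm = TRUE)
  mean_[n == 0L] <- NA_real_
  sd_ <- apply(m, 1L, stats::sd, na.rm = TRUE)
  t_stat <- mean_ / (sd_ / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE)
  flag <- rep("ok", nrow(m))
  low <- n < 2L
  flag[low] <- "insufficient_replicates"
  t_stat[low] <- NA_real_
  p[low] <- NA_real_
  degen <- !low & !is.na(sd_) & sd_ == 0
  flag[degen] <- "degenerate_variance"
  p[degen] <- p_floor
  data.frame(gene = scores$gene, frep_score = mean_, t_stat = t_stat,
             p_value = p, n_replicates = as.integer(n), flag = flag,
             stringsAsFactors = FALSE)
}

#' Score a fractionation screen end to end
#'
#' Orchestrates the full per-condition scoring: depth-anchored
#' median-of-ratios size factors over the condition's total and pellet
#' columns, per-replicate pellet/total log ratios, neighbourhood
#' normalization, barcode-to-gene aggregation, and replicate combination.
#'
#' @param counts Count table (data.frame with `barcode` plus sample columns
#'   named `<background>_<tempC>_<minutes>_<fraction>_rep<k>`).
#' @param library A `guide_library`.
#' @param background,temp,minutes Condition selector.
#' @param pseudocount,min_count,window_size,aggregate,p_floor Scoring knobs,
#'   see [barcode_log_ratio()], [neighborhood_normalize()],
#'   [gene_frep_score()], [combine_replicates()].
#' @param nominal_depth Absolute depth anchor for normalization, in reads
#'   (see [size_factors()]).
#' @return A list: `genes` (FRep score table from [combine_replicates()]),
#'   `replicate_scores` (wide per-replicate gene scores), `barcodes` (list
#'   of per-replicate barcode score tables), `size_factors`.
#' @export
frep_score_screen <- function(counts, library, background = "WT", temp = 30,
                              minutes = 0, pseudocount = 0.5, min_count = 20,
                              window_size = 201L,
                              aggregate = c("mean", "median"),
                              p_floor = 1e-12, nominal_depth = 2e5) {
  aggregate <- match.arg(aggregate)
  library <- validate_guide_library(library)
  stopifnot("barcode" %in% names(counts))
  meta <- parse_sample_names(setdiff(names(counts), "barcode"))
  sel <- meta[meta$background == background & meta$temp == temp &
                meta$minutes == minutes, , drop = FALSE]
  if (!nrow(sel))
    stop("no samples match condition ", background, "/", temp, "C/", minutes,
         "min; expected columns like ",
         make_sample_name(background, temp, minutes, "total", 1),
         call. = FALSE)
  reps <- sort(unique(sel$rep))
  pair_name <- function(frac, r) {
    nm <- sel$sample[sel$fraction == frac & sel$rep == r]
    if (length(nm) != 1L)
      stop("condition ", background, "/", temp, "C/", minutes, "min lacks a ",
           frac, " column for replicate ", r, "; expected sample name ",
           make_sample_name(background, temp, minutes, frac, r),
           call. = FALSE)
    nm
  }
  sf <- size_factors(counts[, c("barcode", sel$sample)], anchor = "depth",
                     nominal_depth = nominal_depth)
  barcode_tabs <- list()
  rep_scores <- NULL
  for (r in reps) {
    pel <- pair_name("pellet", r)
    tot <- pair_name("total", r)
    lr <- barcode_log_ratio(counts[[pel]], counts[[tot]],
                            c(sf[[pel]], sf[[tot]]), pseudocount,
                            barcode = counts$barcode)
    bs <- neighborhood_normalize(lr, window_size = window_size,
                                 min_count = min_count)
    barcode_tabs[[paste0("rep", r)]] <- bs
    gs <- gene_frep_score(bs, library, aggregate = aggregate)
    if (is.null(rep_scores)) {
      rep_scores <- gs[, "gene", drop = FALSE]
    }
    rep_scores[[paste0("rep", r)]] <- gs$score[match(rep_scores$gene, gs$gene)]
  }
  genes <- combine_replicates(rep_scores, p_floor = p_floor)
  list(genes = genes, replicate_scores = rep_scores, barcodes = barcode_tabs,
       size_factors = sf)
}
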