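#' Transcript condensation score
#'
#' Log2 fold change of transcript abundance in the condensate-enriched
#' pellet fraction relative to the total fraction, after size-factor
#' normalization and with a symmetric pseudocount. Positive values mean
#' pellet (condensate) enrichment.
#'
#' @param total_counts,pellet_counts Aligned count vectors over transcripts.
#' @param size_factors Length-2 numeric `(sf_pellet, sf_total)`.
#' @param pseudocount Pseudocount on the normalized scale.
#' @return Numeric vector of per-transcript condensation log2 fold changes.
#' @export
condensation_score <- function(total_counts, pellet_counts,
                               size_factors = c(1, 1), pseudocount = 0.5) {
  barcode_log_ratio(pellet_counts, total_counts, size_factors,
                    pseudocount)$log_ratio
}

#' Ribosome-association score
#'
#' Same contract as [condensation_score()] with the ribosome fraction in
#' place of the pellet: log2 fold change of ribosome-associated abundance
#' relative to total, a proxy for translational engagement.
#'
#' @param total_counts,ribosome_counts Aligned count vectors.
#' @inheritParams condensation_score
#' @return Numeric vector of per-transcript log2 fold changes.
#' @export
ribosome_association_score <- function(total_counts, ribosome_counts,
                                       size_factors = c(1, 1),
                                       pseudocount = 0.5) {
  condensation_score(total_counts, ribosome_counts, size_factors, pseudocount)
}

#' Length-bin z-scores
#'
#' Longer transcripts sediment into condensate fractions regardless of
#' stress, so raw condensation scores are confounded by transcript length.
#' Transcripts are sorted by length (ties broken by identifier for
#' determinism) and cut into consecutive bins of `bin_size`; each
#' transcript's score is standardized against the mean and (n-1) standard
#' deviation of its own bin. A final partial bin with fewer than
#' `min_last_bin` members is merged into the previous bin to avoid unstable
#' standard deviations.
#'
#' @param scores Numeric per-transcript scores (finite).
#' @param lengths Positive transcript lengths in nt.
#' @param ids Transcript identifiers used for deterministic tie-breaks.
#' @param bin_size Transcripts per bin (default 100).
#' @param min_last_bin Minimum size of the final bin before merging.
#' @return Data.frame (input order) with `bin_index`, `z`, `flag`
#'   (`"ok"` or `"degenerate_bin"` for zero-variance bins, whose members
#'   get z = 0).
#' @export
length_bin_zscore <- function(scores, lengths, ids = seq_along(scores),
                              bin_size = 100L, min_last_bin = 10L) {
  n <- length(scores)
  if (n < 2L) stop("length_bin_zscore: need >= 2 transcripts", call. = FALSE)
  if (length(lengths) != n || length(ids) != n)
    stop("length_bin_zscore: scores, lengths and ids must be aligned",
         call. = FALSE)
  if (any(!is.finite(scores)))
    stop("length_bin_zscore: non-finite score", call. = FALSE)
  if (any(lengths <= 0))
    stop("length_bin_zscore: lengths must be positive", call. = FALSE)
  ord <- order(lengths, ids, method = "radix")
  bin <- (seq_len(n) - 1L) %/% as.integer(bin_size) + 1L
  n_bins <- max(bin)
  if (n_bins > 1L && sum(bin == n_bins) < min_last_bin)
    bin[bin == n_bins] <- n_bins - 1L
  bin_of <- integer(n)
  bin_of[ord] <- bin
  z <- numeric(n)
  flag <- rep("ok", n)
  for (b in unique(bin)) {
    members <- which(bin_of == b)
    s <- scores[members]
    sd_ <- stats::sd(s)
    if (!is.finite(sd_) || sd_ == 0) {
      z[members] <- 0
      flag[members] <- "degenerate_bin"
    } else {
      z[members] <- (s - mean(s)) / sd_
    }
  }
  data.frame(bin_index = bin_of, z = z, flag = flag)
}

#' Change in condensation between conditions
#'
#' Elementwise difference of length-normalized condensation z-scores,
#' heat shock minus basal.
#'
#' @param z_42,z_30 Aligned numeric z-score vectors.
#' @return Numeric vector `z_42 - z_30`.
#' @export
delta_condensation <- function(z_42, z_30) {
  if (length(z_42) != length(z_30))
    stop("delta_condensation: inputs must be aligned", call. = FALSE)
  z_42 - z_30
}

#' Rank-sum comparison of transcript groups against background
#'
#' Two-sample Wilcoxon rank-sum test of each transcript group's values
#' against the background group, with Bonferroni correction across the
#' tested groups. The exact null distribution is used when both groups have
#' at most `exact_max` members and no ties; otherwise the normal
#' approximation with tie correction applies.
#'
#' @param values Numeric vector (e.g. delta condensation z-scores).
#' @param groups Character/factor group labels aligned with `values`.
#' @param background Label of the reference group.
#' @param exact_max Largest group size for which the exact test is used.
#' @return Data.frame with `group`, `n`, `statistic` (rank-sum W),
#'   `shift` (group median minus background median), `p_raw`,
#'   `p_bonferroni`, `flag`.
#' @export
group_comparison <- function(values, groups, background = "background",
                             exact_max = 12L) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  bg <- values[groups == background & is.finite(values)]
  if (!length(bg))
    stop("group_comparison: background group '", background, "' is empty",
         call. = FALSE)
  tested <- setdiff(unique(groups), background)
  res <- lapply(tested, function(g) {
    x <- values[groups == g & is.finite(values)]
    if (!length(x))
      return(data.frame(group = g, n = 0L, statistic = NA_real_,
                        shift = NA_real_, p_raw = NA_real_,
                        flag = "empty_group", stringsAsFactors = FALSE))
    exact <- length(x) <= exact_max && length(bg) <= exact_max
    wt <- suppressWarnings(
      stats::wilcox.test(x, bg, exact = exact, correct = TRUE))
    data.frame(group = g, n = length(x), statistic = unname(wt$statistic),
               shift = stats::median(x) - stats::median(bg),
               p_raw = wt$p.value, flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  k <- sum(out$flag == "ok")
  out$p_bonferroni <- pmin(out$p_raw * k, 1)
  out[, c("group", "n", "statistic", "shift", "p_raw", "p_bonferroni",
          "flag")]
}

#' Length-normalized condensation scoring of a fractionated transcriptome
#'
#' Full transcript-level workflow: depth-anchored size factors over all
#' fraction/condition columns, per-condition condensation (pellet/total) and
#' ribosome-association (ribo/total) log2 fold changes, per-condition
#' length-bin z-scores, and the between-condition deltas.
#'
#' @param tx Data.frame with `transcript_id`, `length`, optional `group`,
#'   and sample columns named `<background>_<tempC>_<minutes>_<fraction>_rep<k>`
#'   with fractions `total`, `pellet` and optionally `ribo`.
#' @param temps Length-2 numeric, basal and heat-shock temperature of the
#'   two conditions to contrast.
#' @param background Genetic background of the columns to use.
#' @param rep Replicate index of the columns to use.
#' @param bin_size,pseudocount,nominal_depth See [length_bin_zscore()],
#'   [condensation_score()], [size_factors()].
#' @return The input data.frame augmented with, per condition `<t>`:
#'   `cond_log2fc_<t>`, `bin_index`, `cond_z_<t>`, `ribo_log2fc_<t>` (when a
#'   ribo fraction is present), plus `delta_cond_z` and `delta_ribo_log2fc`.
#' @export
score_transcriptome <- function(tx, temps = c(30, 42), background = "WT",
                                rep = 1L, bin_size = 100L, pseudocount = 0.5,
                                nominal_depth = 2e6) {
  stopifnot(all(c("transcript_id", "length") %in% names(tx)))
  samples <- setdiff(names(tx), c("transcript_id", "length", "group"))
  meta <- parse_sample_names(samples)
  sf <- size_factors(tx[, c("transcript_id", samples)], anchor = "depth",
                     nominal_depth = nominal_depth)
  col_for <- function(t, frac) {
    nm <- meta$sample[meta$background == background & meta$temp == t &
                        meta$fraction == frac & meta$rep == rep]
    if (length(nm) != 1L)
      stop("score_transcriptome: expected exactly one ", frac, " column at ",
           t, "C for ", background, " rep", rep, call. = FALSE)
    nm
  }
  out <- tx
  has_ribo <- any(meta$fraction == "ribo")
  for (t in temps) {
    tot <- col_for(t, "total")
    pel <- col_for(t, "pellet")
    fc <- condensation_score(tx[[tot]], tx[[pel]], c(sf[[pel]], sf[[tot]]),
                             pseudocount)
    zb <- length_bin_zscore(fc, tx$length, tx$transcript_id, bin_size)
    out[[paste0("cond_log2fc_", t)]] <- fc
    out[["bin_index"]] <- zb$bin_index
    out[[paste0("cond_z_", t)]] <- zb$z
    if (has_ribo) {
      rib <- col_for(t, "ribo")
      out[[paste0("ribo_log2fc_", t)]] <-
        ribosome_association_score(tx[[tot]], tx[[rib]],
                                   c(sf[[rib]], sf[[tot]]), pseudocount)
    }
  }
  t0 <- temps[1]; t1 <- temps[2]
  out$delta_cond_z <- delta_condensation(out[[paste0("cond_z_", t1)]],
                                         out[[paste0("cond_z_", t0)]])
  if (has_ribo)
    out$delta_ribo_log2fc <- out[[paste0("ribo_log2fc_", t1)]] -
      out[[paste0("ribo_log2fc_", t0)]]
  out
}
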