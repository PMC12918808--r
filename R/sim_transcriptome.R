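#' Simulate a fractionated transcriptome with planted condensation effects
#'
#' Generates per-transcript counts for total, condensate-enriched pellet
#' and ribosome fractions at a basal (30C) and a heat-shock (42C) condition.
#' Each transcript's true pellet enrichment is
#' `length_slope * z(log length) + group effect + N(0, bio_sd)`, so raw
#' condensation scores are confounded by transcript length at both
#' temperatures (the structure that length-bin z-scores must remove), while
#' group-by-condition shifts at 42C reproduce the qualitative contrast of
#' heat-shock fractionation data: ribosomal-protein-gene-like transcripts
#' gain condensation and lose ribosome association, Hsf1-target-like
#' transcripts evade condensation and gain ribosome association.
#'
#' @param config A [transcriptome_config()].
#' @param background Background label for the sample names.
#' @return A list with `tx` (data.frame: `transcript_id`, `length`, `group`,
#'   six sample columns) and `truth` (data.frame of the true per-transcript
#'   log2 pellet and ribosome enrichments per condition).
#' @export
simulate_fraction_transcriptome <- function(config, background = "WT") {
  stopifnot(inherits(config, "transcriptome_config"))
  n <- config$n_transcripts
  ids <- sprintf("TX%05d", seq_len(n))
  len <- with_substream(config$seed, "tx_length",
                        round(stats::rlnorm(n, config$length_logmean,
                                            config$length_logsd)))
  len <- pmax(len, 100L)
  group <- rep("background", n)
  gi <- 0L
  for (g in names(config$group_sizes)) {
    k <- config$group_sizes[[g]]
    group[(gi + 1L):(gi + k)] <- g
    gi <- gi + k
  }
  group <- with_substream(config$seed, "tx_groups", sample(group))

  abund <- with_substream(config$seed, "tx_abundance", {
    a <- stats::rlnorm(n, 0, config$abundance_logsd)
    a / sum(a)
  })
  lz <- as.numeric(scale(log(len)))
  eff_of <- function(tab, g) ifelse(g %in% names(tab), tab[g], 0)

  cond30 <- config$length_slope * lz +
    with_substream(config$seed, "bio_cond30", stats::rnorm(n, 0, config$bio_sd))
  cond42 <- config$length_slope * lz + unname(eff_of(config$cond_effect_42, group)) +
    with_substream(config$seed, "bio_cond42", stats::rnorm(n, 0, config$bio_sd))
  ribo30 <- with_substream(config$seed, "bio_ribo30",
                           stats::rnorm(n, 0, config$bio_sd))
  ribo42 <- unname(eff_of(config$ribo_effect_42, group)) +
    with_substream(config$seed, "bio_ribo42",
                   stats::rnorm(n, 0, config$bio_sd))

  draw <- function(mu, label) {
    with_substream(config$seed, label,
                   rnbinom_disp(n, mu, config$nb_dispersion))
  }
  d <- config$depth_per_sample
  tx <- data.frame(transcript_id = ids, length = len, group = group,
                   stringsAsFactors = FALSE)
  tx[[make_sample_name(background, 30, 0, "total", 1)]] <-
    draw(d * abund, "counts_total30")
  tx[[make_sample_name(background, 30, 0, "pellet", 1)]] <-
    draw(d * abund * 2^cond30, "counts_pellet30")
  tx[[make_sample_name(background, 30, 0, "ribo", 1)]] <-
    draw(d * abund * 2^ribo30, "counts_ribo30")
  tx[[make_sample_name(background, 42, 30, "total", 1)]] <-
    draw(d * abund, "counts_total42")
  tx[[make_sample_name(background, 42, 30, "pellet", 1)]] <-
    draw(d * abund * 2^cond42, "counts_pellet42")
  tx[[make_sample_name(background, 42, 30, "ribo", 1)]] <-
    draw(d * abund * 2^ribo42, "counts_ribo42")

  truth <- data.frame(transcript_id = ids, group = group, length = len,
                      cond_log2_30 = cond30, cond_log2_42 = cond42,
                      ribo_log2_30 = ribo30, ribo_log2_42 = ribo42,
                      stringsAsFactors = FALSE)
  list(tx = tx, truth = truth)
}
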