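#' Configuration for the synthetic pooled fractionation screen
#'
#' Bundles every knob of the screen generator: library geometry, sequencing
#' depth, the log-normal baseline barcode abundance, negative-binomial count
#' dispersion (variance = mu + dispersion * mu^2), and the planted
#' condensation effects. Defaults mirror the screen design the package
#' targets: roughly 12 guide RNAs per gene, more than one barcode per guide,
#' and four biological replicates.
#'
#' @param n_genes Number of genes in the simulated library.
#' @param guides_per_gene Guides per gene (default 12).
#' @param barcodes_per_guide Distinct barcodes per guide (default 2).
#' @param barcode_length Barcode length in nucleotides (default 12).
#' @param n_replicates Biological replicates (default 4).
#' @param depth_per_sample Expected total reads per sample column.
#' @param abundance_logmean,abundance_logsd Natural-log mean/sd of the
#'   log-normal baseline barcode abundance (heavy-tailed, as in real pools).
#' @param nb_dispersion Negative-binomial dispersion; 0 gives Poisson counts.
#' @param frac_effect_genes Proportion of genes with a planted condensation
#'   effect.
#' @param effect_logfc_mean,effect_logfc_sd Planted per-gene pellet
#'   enrichment on the log2 scale.
#' @param replicate_sd Per-gene, per-replicate log2 jitter applied to the
#'   pellet fraction (biological replicate noise in partitioning).
#' @param seed Top-level RNG seed; all draws derive labelled substreams
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L,
                       guides_per_gene = 12L,
                       barcodes_per_guide = 2L,
                       barcode_length = 12L,
                       n_replicates = 4L,
                       depth_per_sample = 2e5,
                       abundance_logmean = 0,
                       abundance_logsd = 1,
                       nb_dispersion = 0.05,
                       frac_effect_genes = 0,
                       effect_logfc_mean = 1.5,
                       effect_logfc_sd = 0,
                       replicate_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    barcodes_per_guide = as.integer(barcodes_per_guide),
    barcode_length = as.integer(barcode_length),
    n_replicates = as.integer(n_replicates),
    depth_per_sample = as.numeric(depth_per_sample),
    abundance_logmean = as.numeric(abundance_logmean),
    abundance_logsd = as.numeric(abundance_logsd),
    nb_dispersion = as.numeric(nb_dispersion),
    frac_effect_genes = as.numeric(frac_effect_genes),
    effect_logfc_mean = as.numeric(effect_logfc_mean),
    effect_logfc_sd = as.numeric(effect_logfc_sd),
    replicate_sd = as.numeric(replicate_sd),
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "guides_per_gene", "barcodes_per_guide",
              "barcode_length", "n_replicates")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (cfg$depth_per_sample <= 0)
    stop("sim_config: 'depth_per_sample' must be positive", call. = FALSE)
  if (cfg$frac_effect_genes < 0 || cfg$frac_effect_genes > 1)
    stop("sim_config: 'frac_effect_genes' must lie in [0, 1]", call. = FALSE)
  if (cfg$nb_dispersion < 0)
    stop("sim_config: 'nb_dispersion' must be >= 0", call. = FALSE)
  if (cfg$abundance_logsd < 0 || cfg$replicate_sd < 0 || cfg$effect_logfc_sd < 0)
    stop("sim_config: standard deviations must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Configuration for the synthetic fractionated transcriptome
#'
#' Controls the transcript-level generator that emulates sedimentation
#' RNA-seq: log-normal transcript lengths, a built-in length dependence of
#' condensation (longer transcripts sediment more, regardless of stress),
#' and planted group-by-condition shifts for Hsf1-target-like,
#' Msn2/4-target-like and ribosomal-protein-gene-like transcripts at 42
#' degrees C. Group effects are expressed in log2 pellet-enrichment units.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_logmean,length_logsd Natural-log mean/sd of transcript
#'   length in nucleotides (defaults centred near the yeast median of
#'   roughly 1.6 kb).
#' @param group_sizes Named integer vector of transcripts per planted group;
#'   remaining transcripts are labelled "background".
#' @param length_slope Log2 condensation change per standard deviation of
#'   log-length (the length confound the bin z-score must remove).
#' @param cond_effect_42 Named numeric: planted log2 condensation shift per
#'   group at 42C (background implicitly 0).
#' @param ribo_effect_42 Named numeric: planted log2 ribosome-association
#'   shift per group at 42C.
#' @param bio_sd Transcript-level biological log2 noise on each planted
#'   fraction enrichment.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param depth_per_sample Expected reads per fraction/condition column.
#' @param abundance_logsd Natural-log sd of baseline transcript abundance.
#' @param seed Top-level RNG seed.
#' @return A validated list of class `transcriptome_config`.
#' @export
transcriptome_config <- function(n_transcripts = 5000L,
                                 length_logmean = log(1600),
                                 length_logsd = 0.45,
                                 group_sizes = c(Hsf1 = 100L, `Msn2/4` = 100L,
                                                 RPG = 100L),
                                 length_slope = 1,
                                 cond_effect_42 = c(Hsf1 = -1, `Msn2/4` = -0.5,
                                                    RPG = 1),
                                 ribo_effect_42 = c(Hsf1 = 1, `Msn2/4` = 0.5,
                                                    RPG = -1),
                                 bio_sd = 0.5,
                                 nb_dispersion = 0.02,
                                 depth_per_sample = 2e6,
                                 abundance_logsd = 1,
                                 seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    length_logmean = as.numeric(length_logmean),
    length_logsd = as.numeric(length_logsd),
    group_sizes = group_sizes,
    length_slope = as.numeric(length_slope),
    cond_effect_42 = cond_effect_42,
    ribo_effect_42 = ribo_effect_42,
    bio_sd = as.numeric(bio_sd),
    nb_dispersion = as.numeric(nb_dispersion),
    depth_per_sample = as.numeric(depth_per_sample),
    abundance_logsd = as.numeric(abundance_logsd),
    seed = as.integer(seed)
  )
  if (cfg$n_transcripts < 2L)
    stop("transcriptome_config: need at least 2 transcripts", call. = FALSE)
  if (sum(cfg$group_sizes) > cfg$n_transcripts)
    stop("transcriptome_config: group sizes exceed n_transcripts", call. = FALSE)
  if (cfg$nb_dispersion < 0 || cfg$bio_sd < 0 || cfg$length_logsd < 0)
    stop("transcriptome_config: dispersions/sds must be >= 0", call. = FALSE)
  structure(cfg, class = "transcriptome_config")
}
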