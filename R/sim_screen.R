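#' Simulate barcode counts for a pooled fractionation screen
#'
#' Draws a barcode x sample count table for one condition: for every
#' biological replicate, a `total` and a condensate-enriched `pellet`
#' fraction. Baseline barcode abundances are log-normal (heavy-tailed, as in
#' real pools); counts are negative binomial with mean `depth * relative
#' abundance` and variance `mu + dispersion * mu^2`. A planted condensation
#' effect `e_g` (log2) multiplies the pellet-fraction mean of gene g's
#' barcodes by `2^(e_g + jitter)`, where the jitter is per-gene,
#' per-replicate partitioning noise; the total fraction is untouched, so
#' planted effects model fraction partitioning rather than expression.
#'
#' @param library A `guide_library`.
#' @param config A [sim_config()].
#' @param background,temp,minutes Condition labels baked into the sample
#'   names (see [make_sample_name()]).
#' @return A list with `counts` (data.frame: `barcode` plus one column per
#'   sample) and `truth` (data.frame: `gene`, `effect_log2`; non-modulator
#'   genes have effect exactly 0).
#' @export
simulate_screen <- function(library, config, background = "WT", temp = 30,
                            minutes = 0) {
  stopifnot(inherits(config, "sim_config"))
  library <- validate_guide_library(library)
  n_bc <- nrow(library)
  genes <- unique(library$gene)
  n_genes <- length(genes)

  abund <- with_substream(config$seed, "abundance", {
    a <- stats::rlnorm(n_bc, config$abundance_logmean, config$abundance_logsd)
    a / sum(a)
  })

  effect <- numeric(n_genes)
  n_mod <- round(config$frac_effect_genes * n_genes)
  if (n_mod > 0) {
    with_substream(config$seed, "effects", {
      idx <- sample.int(n_genes, n_mod)
      effect[idx] <- stats::rnorm(n_mod, config$effect_logfc_mean,
                                  config$effect_logfc_sd)
    })
  }
  names(effect) <- genes
  bc_effect <- effect[library$gene]

  counts <- data.frame(barcode = library$barcode, stringsAsFactors = FALSE)
  for (r in seq_len(config$n_replicates)) {
    jitter <- with_substream(config$seed, paste0("jitter_rep", r),
                             stats::rnorm(n_genes, 0, config$replicate_sd))
    names(jitter) <- genes
    mu_total <- config$depth_per_sample * abund
    mu_pellet <- mu_total * 2^(bc_effect + jitter[library$gene])
    tot_name <- make_sample_name(background, temp, minutes, "total", r)
    pel_name <- make_sample_name(background, temp, minutes, "pellet", r)
    counts[[tot_name]] <- with_substream(
      config$seed, paste0("counts_", tot_name),
      rnbinom_disp(n_bc, mu_total, config$nb_dispersion))
    counts[[pel_name]] <- with_substream(
      config$seed, paste0("counts_", pel_name),
      rnbinom_disp(n_bc, mu_pellet, config$nb_dispersion))
  }
  truth <- data.frame(gene = genes, effect_log2 = unname(effect),
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

# NB draws parameterised by dispersion phi: var = mu + phi * mu^2.
# phi = 0 degenerates to Poisson.
rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}
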