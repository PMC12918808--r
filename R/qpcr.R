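#' Simulate a qPCR Ct table for fractionation experiments
#'
#' Ct values follow the idealized amplification model
#' `Ct = intercept - log2(abundance) + Normal(0, ct_sd)`, with three
#' technical replicates per well. Input abundances are given per
#' (target, fraction, condition, strain) well.
#'
#' @param abundances Data.frame with columns `target`, `fraction`,
#'   `condition`, `strain`, `abundance` (> 0).
#' @param intercept Ct of one abundance unit.
#' @param ct_sd Technical noise in cycles.
#' @param n_tech Technical replicates per well.
#' @param seed RNG seed.
#' @return A `ct_table` data.frame with columns `target`, `fraction`,
#'   `condition`, `strain`, `ct1` ... `ct<n_tech>`.
#' @export
simulate_ct_table <- function(abundances, intercept = 30, ct_sd = 0,
                              n_tech = 3L, seed = 1L) {
  req <- c("target", "fraction", "condition", "strain", "abundance")
  stopifnot(all(req %in% names(abundances)))
  if (any(abundances$abundance <= 0))
    stop("simulate_ct_table: abundances must be > 0", call. = FALSE)
  n <- nrow(abundances)
  out <- abundances[, setdiff(req, "abundance")]
  base <- intercept - log2(abundances$abundance)
  with_substream(seed, "ct_noise", {
    for (k in seq_len(n_tech))
      out[[paste0("ct", k)]] <- base + stats::rnorm(n, 0, ct_sd)
  })
  out
}

#' Condensation from qPCR Ct values (-ddCt of pellet versus total)
#'
#' For each (target, condition, strain): the median Ct of the technical
#' replicates is taken per well; delta-Ct relative to the reference gene is
#' computed within each fraction, `dCt_f = Ct_target,f - Ct_ref,f`; and
#' condensation is `-(dCt_pellet - dCt_total)`, the log2-scale pellet
#' enrichment of the target relative to the reference gene (+1 = 2-fold
#' pellet-enriched). Optionally, each strain's condensation is further
#' normalized to a reference strain, reported both as a log2 difference and
#' as a linear fold change.
#'
#' @param ct Data.frame with columns `target`, `fraction` (`"pellet"` /
#'   `"total"`), `condition`, `strain`, and one or more technical-replicate
#'   columns `ct1`, `ct2`, ...
#' @param reference_gene Reference target (default `"ACT1"`).
#' @param reference_strain Optional strain to normalize against.
#' @return Data.frame with `target`, `condition`, `strain`, `condensation`
#'   and, when `reference_strain` is given, `condensation_vs_ref` (log2) and
#'   `fold_vs_ref` (linear).
#' @export
ddct_condensation <- function(ct, reference_gene = "ACT1",
                              reference_strain = NULL) {
  req <- c("target", "fraction", "condition", "strain")
  stopifnot(all(req %in% names(ct)))
  ct_cols <- grep("^ct[0-9]+$", names(ct), value = TRUE)
  if (!length(ct_cols))
    stop("ddct_condensation: no technical-replicate columns (ct1, ct2, ...)",
         call. = FALSE)
  cm <- as.matrix(ct[, ct_cols, drop = FALSE])
  storage.mode(cm) <- "double"
  if (any(!is.finite(cm)) || any(cm <= 0))
    stop("ddct_condensation: Ct values must be finite and > 0", call. = FALSE)
  ct$med_ct <- apply(cm, 1L, stats::median, na.rm = TRUE)

  well_ct <- function(target, fraction, condition, strain) {
    v <- ct$med_ct[ct$target == target & ct$fraction == fraction &
                     ct$condition == condition & ct$strain == strain]
    if (length(v) != 1L)
      stop("ddct_condensation: missing or duplicated well for (", target,
           ", ", fraction, ", ", condition, ", ", strain, ")", call. = FALSE)
    v
  }
  combos <- unique(ct[ct$target != reference_gene,
                      c("target", "condition", "strain")])
  rownames(combos) <- NULL
  combos$condensation <- vapply(seq_len(nrow(combos)), function(i) {
    tg <- combos$target[i]; cd <- combos$condition[i]; st <- combos$strain[i]
    d_p <- well_ct(tg, "pellet", cd, st) - well_ct(reference_gene, "pellet",
                                                   cd, st)
    d_t <- well_ct(tg, "total", cd, st) - well_ct(reference_gene, "total",
                                                  cd, st)
    -(d_p - d_t)
  }, numeric(1))
  if (!is.null(reference_strain)) {
    ref <- combos[combos$strain == reference_strain,
                  c("target", "condition", "condensation")]
    names(ref)[3] <- "ref_condensation"
    combos <- merge(combos, ref, by = c("target", "condition"),
                    all.x = TRUE, sort = FALSE)
    combos$condensation_vs_ref <- combos$condensation - combos$ref_condensation
    combos$fold_vs_ref <- 2^combos$condensation_vs_ref
    combos$ref_condensation <- NULL
  }
  combos
}
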