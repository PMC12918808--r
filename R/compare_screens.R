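#' Compare gene scores between two screens
#'
#' Intersects two per-gene FRep score tables, reports their Pearson
#' correlation, and labels each shared gene's conditional genetic
#' interaction: `shared` when both screens call it a hit, `aggravating`
#' when screen B's score exceeds screen A's by at least `delta_threshold`
#' and is itself a hit, `alleviating` for the symmetric case, and `neither`
#' otherwise. The hit convention (score > 2 neighbourhood standard
#' deviations) follows the screen scoring.
#'
#' @param genes_a,genes_b Data.frames with `gene` and a score column
#'   (`frep_score` or `score`).
#' @param hit_threshold Score above which a gene counts as a hit.
#' @param delta_threshold Minimum between-screen score difference for an
#'   interaction call.
#' @return A list with `pearson_r`, `n_shared`, and `table` (data.frame:
#'   `gene`, `score_a`, `score_b`, `label`).
#' @export
compare_screens <- function(genes_a, genes_b, hit_threshold = 2,
                            delta_threshold = 1) {
  score_col <- function(x) {
    cn <- intersect(c("frep_score", "score"), names(x))
    if (!length(cn)) stop("compare_screens: no score column", call. = FALSE)
    x[, c("gene", cn[1])]
  }
  a <- score_col(genes_a)
  b <- score_col(genes_b)
  names(a) <- c("gene", "score_a")
  names(b) <- c("gene", "score_b")
  tab <- merge(a, b, by = "gene")
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("compare_screens: fewer than 3 shared genes", call. = FALSE)
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  r <- stats::cor(tab$score_a, tab$score_b, method = "pearson")
  lab <- rep("neither", nrow(tab))
  aggra <- tab$score_b - tab$score_a >= delta_threshold &
    tab$score_b >= hit_threshold
  allev <- tab$score_a - tab$score_b >= delta_threshold &
    tab$score_a >= hit_threshold
  shared <- tab$score_a >= hit_threshold & tab$score_b >= hit_threshold
  lab[aggra] <- "aggravating"
  lab[allev] <- "alleviating"
  lab[shared] <- "shared"
  tab$label <- lab
  list(pearson_r = r, n_shared = nrow(tab), table = tab)
}
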