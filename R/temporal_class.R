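#' Classify a FRep-score trajectory over a heat-shock time course
#'
#' Assigns a score trajectory at 0, 10, 30 and 60 minutes of heat shock to
#' one of the responder groups, by strict threshold rules:
#'
#' * `sustained` — score > `hit` at all four time points;
#' * `basal` — score > `hit` at 0 minutes and below `basal_cap` at 10, 30
#'   and 60 minutes;
#' * `early` — score < `hit` at 0 minutes and > `hit` at 10, 30 and 60
#'   minutes;
#' * `time_dependent` — all three consecutive differences (10-0, 30-10,
#'   60-30) strictly positive, with the 60-minute score > `hit`;
#' * `other` — everything else.
#'
#' All comparisons are strict, so scores exactly at a threshold fail it
#' (e.g. `(2, 2, 2, 2)` is `other`). The printed rules overlap
#' (a trajectory can satisfy both sustained and basal, or both early and
#' time-dependent); the `precedence` order resolves the overlap in favour of
#' the stronger phenotype and makes the five labels a partition.
#'
#' @param scores Numeric vector of 4 finite scores (minutes 0, 10, 30, 60),
#'   or a 4-column matrix of trajectories (one per row).
#' @param hit Hit threshold in FRep-score units (default 2).
#' @param basal_cap Upper cap on heat-shock time points in the basal rule
#'   (default 3; set equal to `hit` for the symmetric variant).
#' @param precedence Character vector ordering the four named rules.
#' @return Character label(s) in
#'   `{"basal","sustained","early","time_dependent","other"}`.
#' @export
classify_trajectory <- function(scores, hit = 2, basal_cap = 3,
                                precedence = c("sustained", "basal", "early",
                                               "time_dependent")) {
  if (is.null(dim(scores))) {
    if (length(scores) != 4L)
      stop("classify_trajectory: need scores at exactly 4 time points",
           call. = FALSE)
    scores <- matrix(scores, nrow = 1L)
  }
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L)
    stop("classify_trajectory: need scores at exactly 4 time points",
         call. = FALSE)
  if (any(!is.finite(scores)))
    stop("classify_trajectory: non-finite score", call. = FALSE)
  if (!setequal(precedence, c("sustained", "basal", "early", "time_dependent")))
    stop("classify_trajectory: precedence must order the four named rules",
         call. = FALSE)
  s0 <- scores[, 1L]; s10 <- scores[, 2L]; s30 <- scores[, 3L]
  s60 <- scores[, 4L]
  rule <- list(
    sustained = s0 > hit & s10 > hit & s30 > hit & s60 > hit,
    basal = s0 > hit & s10 < basal_cap & s30 < basal_cap & s60 < basal_cap,
    early = s0 < hit & s10 > hit & s30 > hit & s60 > hit,
    time_dependent = (s10 - s0) > 0 & (s30 - s10) > 0 & (s60 - s30) > 0 &
      s60 > hit
  )
  lab <- rep("other", nrow(scores))
  for (nm in rev(precedence)) lab[rule[[nm]]] <- nm
  lab
}

#' Classify every gene's trajectory in a wide score table
#'
#' @param wide Data.frame with columns `gene`, `frep_0`, `frep_10`,
#'   `frep_30`, `frep_60`. Genes with any missing score are labelled
#'   `other` and flagged.
#' @inheritParams classify_trajectory
#' @return A list with `table` (the input augmented with `label` and
#'   `flag`) and `counts` (named integer vector over the five labels).
#' @export
classify_all <- function(wide, hit = 2, basal_cap = 3,
                         precedence = c("sustained", "basal", "early",
                                        "time_dependent")) {
  req <- c("gene", "frep_0", "frep_10", "frep_30", "frep_60")
  miss <- setdiff(req, names(wide))
  if (length(miss))
    stop("classify_all: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(wide[, req[-1]])
  storage.mode(m) <- "double"
  ok <- apply(is.finite(m), 1L, all)
  lab <- rep("other", nrow(wide))
  if (any(ok))
    lab[ok] <- classify_trajectory(m[ok, , drop = FALSE], hit = hit,
                                   basal_cap = basal_cap,
                                   precedence = precedence)
  out <- wide
  out$label <- lab
  out$flag <- ifelse(ok, "ok", "missing_scores")
  lv <- c("basal", "sustained", "early", "time_dependent", "other")
  counts <- table(factor(lab, levels = lv))
  list(table = out, counts = stats::setNames(as.integer(counts), lv))
}
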