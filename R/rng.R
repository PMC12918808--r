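#' Derive a reproducible substream seed from a top-level seed and a label
#'
#' All stochastic operations in the package draw from independent substreams
#' keyed by a fixed label, so that adding or reordering simulation steps does
#' not perturb the draws of unrelated steps. The label is hashed with a small
#' polynomial string hash and folded into the user's top-level seed.
#'
#' @param seed Integer top-level seed.
#' @param label Character scalar naming the substream (e.g. "abundance").
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

#' Evaluate an expression under a labelled RNG substream
#'
#' Saves and restores the caller's RNG state, so simulation helpers never
#' disturb the global random stream.
#'
#' @param seed Integer top-level seed.
#' @param label Substream label, see [substream_seed()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_substream <- function(seed, label, expr) {
  force(seed) # evaluate before snapshotting RNG state
  force(label)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}
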