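#' Simulate a barcoded guide library
#'
#' Draws `n_genes * guides_per_gene` guides, each linked to
#' `barcodes_per_guide` distinct random DNA barcodes. Barcodes are rejection
#' sampled so that every pair is at Hamming distance >= 3, which makes
#' one-mismatch read assignment provably unambiguous.
#'
#' Two barcodes are at distance <= 2 exactly when their one-mismatch balls
#' intersect, so the sampler keeps a hash of every accepted barcode's
#' one-substitution neighbourhood and rejects candidates that collide with
#' it; accepted libraries therefore satisfy the distance constraint by
#' construction.
#'
#' @param config A [sim_config()].
#' @return A `guide_library` data.frame with columns `barcode`, `guide_id`,
#'   `gene`, `is_control`.
#' @export
simulate_guide_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_bc <- config$n_genes * config$guides_per_gene * config$barcodes_per_guide
  len <- config$barcode_length
  if (4^len < n_bc * (3 * len + 1))
    stop("barcode space too small: ", n_bc, " barcodes of length ", len,
         " cannot satisfy pairwise Hamming distance >= 3; increase ",
         "barcode_length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  ball <- new.env(hash = TRUE, size = as.integer(min(2^22, n_bc * 40)))
  barcodes <- character(n_bc)
  with_substream(config$seed, "guide_library", {
    accepted <- 0L
    misses <- 0L
    while (accepted < n_bc) {
      cand <- paste(sample(bases, len, replace = TRUE), collapse = "")
      nb <- one_mismatch_ball(cand, bases)
      if (any(vapply(nb, exists, logical(1), envir = ball, inherits = FALSE))) {
        misses <- misses + 1L
        if (misses > 5000L)
          stop("barcode space too small: rejection sampling stalled at ",
               accepted, "/", n_bc, " barcodes of length ", len,
               "; increase barcode_length", call. = FALSE)
        next
      }
      misses <- 0L
      accepted <- accepted + 1L
      barcodes[accepted] <- cand
      for (s in nb) assign(s, TRUE, envir = ball)
    }
  })
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  guide_gene <- rep(genes, each = config$guides_per_gene)
  guide_id <- paste0(guide_gene, "_g",
                     rep(seq_len(config$guides_per_gene), config$n_genes))
  lib <- data.frame(
    barcode = barcodes,
    guide_id = rep(guide_id, each = config$barcodes_per_guide),
    gene = rep(guide_gene, each = config$barcodes_per_guide),
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
}

# All strings at Hamming distance <= 1 from `seq` (including itself).
one_mismatch_ball <- function(seq, bases = c("A", "C", "G", "T")) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(1L + 3L * length(chars))
  out[1] <- seq
  k <- 1L
  for (i in seq_along(chars)) {
    for (b in bases[bases != chars[i]]) {
      tmp <- chars
      tmp[i] <- b
      k <- k + 1L
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' Validate a guide library table
#'
#' Checks the structural invariants of a barcode -> guide -> gene map:
#' unique barcodes of a single common length, and a consistent guide-to-gene
#' assignment.
#'
#' @param lib A data.frame with columns `barcode`, `guide_id`, `gene`,
#'   `is_control`.
#' @return The validated data.frame, classed `guide_library`.
#' @export
validate_guide_library <- function(lib) {
  req <- c("barcode", "guide_id", "gene", "is_control")
  miss <- setdiff(req, names(lib))
  if (length(miss))
    stop("guide library is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- lib$barcode[duplicated(lib$barcode)]
  if (length(dup))
    stop("duplicate barcode(s) in guide library: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (length(unique(nchar(lib$barcode))) > 1L)
    stop("guide library barcodes must all have the same length", call. = FALSE)
  g2g <- unique(lib[, c("guide_id", "gene")])
  bad <- g2g$guide_id[duplicated(g2g$guide_id)]
  if (length(bad))
    stop("guide(s) mapped to more than one gene: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  lib$is_control <- as.logical(lib$is_control)
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' All-pairs scan; quadratic, intended for validation and tests.
#'
#' @param barcodes Character vector of equal-length strings.
#' @return Integer minimum pairwise distance (Inf for fewer than 2 barcodes).
#' @export
min_pairwise_hamming <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2L) return(Inf)
  m <- do.call(rbind, strsplit(barcodes, "", fixed = TRUE))
  best <- ncol(m)
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) break
  }
  best
}
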