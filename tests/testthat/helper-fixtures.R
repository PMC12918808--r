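# Shared fixtures: tiny hand-built libraries and brute-force oracles kept
# independent of the package's production code paths.

tiny_library <- function(barcodes, genes = NULL, guides = NULL) {
  n <- length(barcodes)
  if (is.null(genes)) genes <- paste0("G", seq_len(n))
  if (is.null(guides)) guides <- paste0(genes, "_g1")
  validate_guide_library(data.frame(
    barcode = barcodes, guide_id = guides, gene = genes,
    is_control = FALSE, stringsAsFactors = FALSE))
}

# Brute-force Hamming distance between two equal-length strings.
bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force sliding-window anchor search (oracle for extract_barcode).
bf_extract <- function(read, flank5, blen, max_mm) {
  fc <- strsplit(flank5, "")[[1]]
  rc <- strsplit(read, "")[[1]]
  flen <- length(fc)
  last <- length(rc) - flen - blen + 1L
  if (last < 1L) return(NA_character_)
  for (s in seq_len(last)) {
    if (sum(rc[s:(s + flen - 1L)] != fc) <= max_mm)
      return(substr(read, s + flen, s + flen + blen - 1L))
  }
  NA_character_
}

# Independently coded responder-group rules (oracle for the classifier).
# Deliberately written as literal per-rule predicates with explicit
# precedence, not sharing code with classify_trajectory().
bf_classify <- function(v, hit = 2, cap = 3) {
  sustained <- v[1] > hit && v[2] > hit && v[3] > hit && v[4] > hit
  basal <- v[1] > hit && v[2] < cap && v[3] < cap && v[4] < cap
  early <- v[1] < hit && v[2] > hit && v[3] > hit && v[4] > hit
  timedep <- (v[2] - v[1]) > 0 && (v[3] - v[2]) > 0 && (v[4] - v[3]) > 0 &&
    v[4] > hit
  if (sustained) return("sustained")
  if (basal) return("basal")
  if (early) return("early")
  if (timedep) return("time_dependent")
  "other"
}

# Brute-force AUROC by pair counting (oracle for auroc()).
bf_auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
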