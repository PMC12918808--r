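#' Read layout around the 3' UTR barcode
#'
#' Describes where the barcode sits inside a read: a constant 5' flank
#' (anchor), the fixed-length barcode window, and a constant 3' flank. The
#' defaults are 8-nt flanks; they are a package convention for simulated
#' reads, not a property of any particular sequencing design, and real
#' layouts should be supplied explicitly.
#'
#' @param flank5,flank3 Constant DNA sequences flanking the barcode.
#' @param barcode_length Barcode length in nt (>= 6).
#' @param max_flank_mismatch Substitutions tolerated when locating `flank5`.
#' @return A list of class `read_layout`.
#' @export
read_layout <- function(flank5 = "ACGGTCTC", flank3 = "GAGACCGT",
                        barcode_length = 12L, max_flank_mismatch = 1L) {
  if (!nzchar(flank5) || !nzchar(flank3))
    stop("read_layout: flanks must be non-empty", call. = FALSE)
  if (barcode_length < 6L)
    stop("read_layout: barcode_length must be >= 6", call. = FALSE)
  if (max_flank_mismatch < 0L || max_flank_mismatch >= nchar(flank5))
    stop("read_layout: max_flank_mismatch must be in [0, nchar(flank5))",
         call. = FALSE)
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 barcode_length = as.integer(barcode_length),
                 max_flank_mismatch = as.integer(max_flank_mismatch)),
            class = "read_layout")
}

#' Simulate FASTQ reads carrying library barcodes
#'
#' Emits exactly `sum(counts)` reads, each `flank5 + barcode + flank3`, with
#' independent per-base substitution errors at `error_rate`. Qualities are a
#' constant Phred+33 placeholder ("I"). Deterministic for a fixed seed.
#'
#' @param counts Named integer vector: barcode -> read count.
#' @param layout A [read_layout()]; its `barcode_length` must match the
#'   barcodes in `counts`.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param path Optional output FASTQ path; when given, records are written
#'   there (4-line records).
#' @return Invisibly, the character vector of read sequences.
#' @export
simulate_reads <- function(counts, layout = read_layout(), error_rate = 0,
                           seed = 1L, path = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  counts <- counts[counts > 0]
  if (length(counts) &&
      any(nchar(names(counts)) != layout$barcode_length))
    stop("simulate_reads: barcode lengths disagree with layout", call. = FALSE)
  reads <- rep(paste0(layout$flank5, names(counts), layout$flank3),
               times = counts)
  n <- length(reads)
  if (n && error_rate > 0) {
    reads <- with_substream(seed, "read_errors", {
      m <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
      hit <- which(matrix(stats::runif(length(m)) < error_rate, nrow(m)))
      if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        # substitute with one of the three other bases, uniformly
        shift <- sample.int(3L, length(hit), replace = TRUE)
        cur <- match(m[hit], bases)
        m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
      apply(m, 1L, paste, collapse = "")
    })
  }
  if (!is.null(path)) {
    qual <- strrep("I", if (n) nchar(reads[1]) else 0L)
    con <- file(path, open = "wb") # "wb" keeps \n line endings exact
    on.exit(close(con))
    if (n) {
      rec <- character(4L * n)
      rec[seq(1L, by = 4L, length.out = n)] <- paste0("@read", seq_len(n))
      rec[seq(2L, by = 4L, length.out = n)] <- reads
      rec[seq(3L, by = 4L, length.out = n)] <- "+"
      rec[seq(4L, by = 4L, length.out = n)] <- qual
      writeLines(rec, con)
    }
  }
  invisible(reads)
}
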