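#' Parse a guide library table from TSV
#'
#' Expects a tab-separated file with header
#' `barcode  guide_id  gene  is_control`. Rows with the wrong number of
#' fields are rejected naming the offending line; duplicate barcodes and
#' inconsistent guide-to-gene maps are rejected by
#' [validate_guide_library()].
#'
#' @param path Path to the TSV file.
#' @return A `guide_library` data.frame.
#' @export
parse_library_table <- function(path) {
  if (!file.exists(path)) stop("library table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("library table is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  req <- c("barcode", "guide_id", "gene", "is_control")
  if (!all(req %in% header))
    stop("library table header must contain: ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop("malformed library table row at line ", bad[1], " of ", path,
         ": expected ", length(header), " fields, found ",
         lengths(fields)[bad[1]], call. = FALSE)
  body <- fields[-1]
  if (!length(body))
    return(validate_guide_library(data.frame(
      barcode = character(), guide_id = character(), gene = character(),
      is_control = logical(), stringsAsFactors = FALSE)))
  m <- do.call(rbind, body)
  colnames(m) <- header
  lib <- data.frame(
    barcode = toupper(m[, "barcode"]),
    guide_id = m[, "guide_id"],
    gene = m[, "gene"],
    is_control = m[, "is_control"] %in% c("TRUE", "true", "1", "T"),
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
}

#' @rdname parse_library_table
#' @param lib A `guide_library`.
#' @export
write_library_table <- function(lib, path) {
  lib <- validate_guide_library(lib)
  write_tsv(lib[, c("barcode", "guide_id", "gene", "is_control")], path)
}

#' Extract the barcode window from a read
#'
#' Scans for the 5' flank anchor from the left end of the read, tolerating
#' up to `max_flank_mismatch` substitutions, and returns the
#' `barcode_length` window that follows the leftmost acceptable anchor
#' position. Returns `NA` when no anchor is found or the read is too short.
#' N bases count as mismatches.
#'
#' @param read_sequence Character vector of read sequences.
#' @param layout A [read_layout()].
#' @return Character vector of barcodes (`NA` where extraction failed).
#' @export
extract_barcode <- function(read_sequence, layout = read_layout()) {
  stopifnot(inherits(layout, "read_layout"))
  reads <- toupper(read_sequence)
  flen <- nchar(layout$flank5)
  blen <- layout$barcode_length
  out <- rep(NA_character_, length(reads))

  # fast path: exact anchor (leftmost occurrence)
  pos <- regexpr(layout$flank5, reads, fixed = TRUE)
  hit <- pos > 0 & nchar(reads) >= pos + flen + blen - 1L
  out[hit] <- substr(reads[hit], pos[hit] + flen, pos[hit] + flen + blen - 1L)

  if (layout$max_flank_mismatch > 0L) {
    todo <- which(is.na(out) & nchar(reads) >= flen + blen)
    if (length(todo)) {
      fchars <- strsplit(layout$flank5, "", fixed = TRUE)[[1]]
      for (i in todo) {
        rchars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        last_start <- length(rchars) - flen - blen + 1L
        for (s in seq_len(last_start)) {
          mm <- sum(rchars[s:(s + flen - 1L)] != fchars)
          if (mm <= layout$max_flank_mismatch) {
            out[i] <- substr(reads[i], s + flen, s + flen + blen - 1L)
            break
          }
        }
      }
    }
  }
  out
}

#' Match a barcode sequence against a guide library
#'
#' Returns the library record whose barcode is within Hamming distance
#' `max_mismatch` of `seq`, or `NULL` when none qualifies or two or more
#' qualify (ambiguous reads are dropped, never fractionally assigned).
#'
#' @param seq A single barcode-length DNA string.
#' @param library A `guide_library`.
#' @param max_mismatch Maximum Hamming distance.
#' @return A one-row data.frame (the library record) or `NULL`.
#' @export
match_barcode <- function(seq, library, max_mismatch = 1L) {
  library <- validate_guide_library(library)
  blen <- nchar(library$barcode[1])
  if (nchar(seq) != blen)
    stop("match_barcode: query length ", nchar(seq),
         " differs from library barcode length ", blen, call. = FALSE)
  qc <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(library$barcode, "", fixed = TRUE))
  d <- rowSums(m != matrix(qc, nrow(m), blen, byrow = TRUE))
  hits <- which(d <= max_mismatch)
  if (length(hits) != 1L) return(NULL)
  library[hits, , drop = FALSE]
}

# Hash from every sequence within Hamming distance <= max_mismatch (0 or 1)
# of a library barcode to its row index; collisions between different
# barcodes map to 0 (ambiguous). Exact for libraries of any distance.
build_match_index <- function(barcodes, max_mismatch) {
  if (max_mismatch == 0L) {
    keys <- barcodes
    idx <- seq_along(barcodes)
  } else {
    balls <- lapply(barcodes, one_mismatch_ball)
    keys <- unlist(balls, use.names = FALSE)
    idx <- rep(seq_along(barcodes), times = lengths(balls))
  }
  o <- order(keys, method = "radix")
  keys <- keys[o]
  idx <- idx[o]
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  val <- idx[starts]
  multi <- which(r$lengths > 1L)
  for (j in multi) {
    if (length(unique(idx[starts[j]:ends[j]])) > 1L) val[j] <- 0L
  }
  names(val) <- r$values
  val
}

#' Count library barcodes in a FASTQ stream
#'
#' Streams over a FASTQ file in fixed-size chunks (constant memory in the
#' number of reads), extracts the barcode window behind the 5' flank anchor
#' and assigns it to the unique library barcode within `max_mismatch`
#' substitutions. Reads whose window is within range of two or more library
#' barcodes are counted as ambiguous and dropped. The QC partition
#' `assigned + ambiguous + unmatched + no_anchor` always sums to
#' `reads_total`.
#'
#' For `max_mismatch` <= 1 the assignment uses a precomputed hash of every
#' one-substitution neighbourhood of the library (exact and fast); larger
#' radii fall back to per-sequence Hamming scans.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param library A `guide_library`.
#' @param layout A [read_layout()].
#' @param max_mismatch Maximum Hamming distance for assignment (default 1;
#'   unambiguous whenever the library has pairwise distance >= 3).
#' @param chunk_reads Reads per streamed chunk.
#' @return A list with `counts` (named integer vector over all library
#'   barcodes) and `qc` (list: `reads_total`, `reads_assigned`,
#'   `reads_ambiguous`, `reads_unmatched`, `reads_no_anchor`).
#' @export
count_barcodes <- function(fastq, library, layout = read_layout(),
                           max_mismatch = 1L, chunk_reads = 100000L) {
  library <- validate_guide_library(library)
  stopifnot(inherits(layout, "read_layout"))
  if (nrow(library) && nchar(library$barcode[1]) != layout$barcode_length)
    stop("layout barcode_length differs from library barcode length",
         call. = FALSE)
  use_index <- max_mismatch <= 1L
  if (use_index) index <- build_match_index(library$barcode, max_mismatch)

  counts <- integer(nrow(library))
  qc <- c(reads_total = 0L, reads_assigned = 0L, reads_ambiguous = 0L,
          reads_unmatched = 0L, reads_no_anchor = 0L)
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "r") else file(fastq, "r")
  on.exit(close(con))
  repeat {
    lines <- readLines(con, n = 4L * chunk_reads)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at record index ",
           qc[["reads_total"]] + length(lines) %/% 4L + 1L, " in ", fastq,
           call. = FALSE)
    heads <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    bad <- which(substr(heads, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
    if (length(bad))
      stop("malformed FASTQ record at record index ",
           qc[["reads_total"]] + bad[1], " in ", fastq, call. = FALSE)
    seqs <- lines[seq(2L, length(lines), by = 4L)]
    n <- length(seqs)
    qc[["reads_total"]] <- qc[["reads_total"]] + n

    bc <- extract_barcode(seqs, layout)
    no_anchor <- is.na(bc)
    qc[["reads_no_anchor"]] <- qc[["reads_no_anchor"]] + sum(no_anchor)
    bc <- bc[!no_anchor]
    if (!length(bc)) next

    if (use_index) {
      assig <- unname(index[match(bc, names(index))])
      unmatched <- is.na(assig)
      ambiguous <- !unmatched & assig == 0L
    } else {
      ubc <- unique(bc)
      m <- do.call(rbind, strsplit(library$barcode, "", fixed = TRUE))
      lut <- vapply(ubc, function(q) {
        qc_ <- strsplit(q, "", fixed = TRUE)[[1]]
        d <- rowSums(m != matrix(qc_, nrow(m), ncol(m), byrow = TRUE))
        h <- which(d <= max_mismatch)
        if (length(h) == 1L) h else if (length(h) == 0L) NA_integer_ else 0L
      }, integer(1))
      assig <- unname(lut[match(bc, ubc)])
      unmatched <- is.na(assig)
      ambiguous <- !unmatched & assig == 0L
    }
    qc[["reads_unmatched"]] <- qc[["reads_unmatched"]] + sum(unmatched)
    qc[["reads_ambiguous"]] <- qc[["reads_ambiguous"]] + sum(ambiguous)
    good <- assig[!unmatched & !ambiguous]
    qc[["reads_assigned"]] <- qc[["reads_assigned"]] + length(good)
    if (length(good)) {
      tab <- tabulate(good, nbins = nrow(library))
      counts <- counts + tab
    }
  }
  names(counts) <- library$barcode
  list(counts = counts, qc = as.list(qc))
}
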