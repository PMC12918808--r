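#' Compose and parse screen sample names
#'
#' Sample columns of a count table follow the fixed scheme
#' `<background>_<tempC>_<minutes>_<fraction>_rep<k>`, e.g.
#' `WT_42_30_pellet_rep2`.
#'
#' @param background Genetic background label (no underscores).
#' @param temp Temperature in degrees C.
#' @param minutes Heat-shock duration in minutes.
#' @param fraction Fraction label, e.g. "total", "pellet", "ribo".
#' @param rep Replicate index.
#' @return Character vector of sample names.
#' @export
make_sample_name <- function(background, temp, minutes, fraction, rep) {
  if (any(grepl("_", c(background, fraction), fixed = TRUE)))
    stop("background and fraction labels must not contain '_'", call. = FALSE)
  paste0(background, "_", temp, "_", minutes, "_", fraction, "_rep", rep)
}

#' @rdname make_sample_name
#' @param x Character vector of sample names to parse.
#' @return For `parse_sample_names()`, a data.frame with columns `sample`,
#'   `background`, `temp`, `minutes`, `fraction`, `rep`.
#' @export
parse_sample_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  ok <- lengths(parts) == 5L & grepl("^rep[0-9]+$", vapply(parts, `[`, "", 5L))
  if (any(!ok))
    stop("sample name(s) not of the form ",
         "<background>_<tempC>_<minutes>_<fraction>_rep<k>: ",
         paste(x[!ok], collapse = ", "), call. = FALSE)
  data.frame(
    sample = x,
    background = vapply(parts, `[`, "", 1L),
    temp = as.numeric(vapply(parts, `[`, "", 2L)),
    minutes = as.numeric(vapply(parts, `[`, "", 3L)),
    fraction = vapply(parts, `[`, "", 4L),
    rep = as.integer(sub("^rep", "", vapply(parts, `[`, "", 5L))),
    stringsAsFactors = FALSE
  )
}

#' Read or write a barcode/transcript count table
#'
#' Count tables are TSV with a first key column (`barcode` or
#' `transcript_id`) and one non-negative integer column per sample.
#'
#' @param path File path.
#' @return `read_count_table()` returns a data.frame.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2L)
    stop("count table must have a key column plus >= 1 sample column: ", path,
         call. = FALSE)
  x
}

#' @rdname read_count_table
#' @param x Data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
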