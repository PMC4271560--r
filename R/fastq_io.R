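#' Construct a quality dataset
#'
#' A `quality_dataset` holds the per-read quality strings of a FASTQ file as
#' opaque ASCII (no Phred-offset interpretation), together with the read ids
#' and, optionally, the DNA sequences so a complete FASTQ can be re-emitted.
#'
#' @param qualities character vector of quality lines (printable ASCII,
#'   codes 33..126).
#' @param ids character vector of read ids (header line without the leading
#'   `@`); defaults to `read_1 .. read_K`.
#' @param sequences optional character vector of DNA lines, same per-record
#'   lengths as `qualities`.
#' @return An object of class `quality_dataset` with elements `ids`,
#'   `sequences`, `qualities`, `K` (number of reads) and `alphabet` (sorted
#'   unique symbols across all quality lines).
#' @export
quality_dataset <- function(qualities, ids = NULL, sequences = NULL) {
  qualities <- as.character(qualities)
  K <- length(qualities)
  ids <- ids %||% sprintf("read_%d", seq_len(K))
  if (length(ids) != K)
    stop("ids and qualities must have the same length")
  if (!is.null(sequences)) {
    if (length(sequences) != K)
      stop("sequences and qualities must have the same length")
    bad <- which(nchar(sequences) != nchar(qualities))
    if (length(bad))
      stop(sprintf("record %d: sequence and quality lengths differ", bad[1]))
  }
  syms <- sort_symbols(split_chars(paste(qualities, collapse = "")))
  if (length(syms)) {
    codes <- vapply(syms, utf8ToInt, integer(1))
    if (any(codes < 33L | codes > 126L))
      stop("quality symbols must have ASCII codes in [33, 126]")
  }
  structure(
    list(ids = ids, sequences = sequences, qualities = qualities,
         K = K, alphabet = syms),
    class = "quality_dataset"
  )
}

#' @export
print.quality_dataset <- function(x, ...) {
  cat(sprintf("quality_dataset: %d reads, alphabet size %d\n",
              x$K, length(x$alphabet)))
  if (x$K > 0) {
    lens <- nchar(x$qualities)
    cat(sprintf("  read lengths: min %d, max %d\n", min(lens), max(lens)))
  }
  invisible(x)
}

#' Read a FASTQ file into a quality dataset
#'
#' Parses strict 4-line FASTQ (header, sequence, `+`, quality); wrapped
#' multi-line records are rejected. Input may be gzip-compressed. Quality
#' lines are kept verbatim; ids and DNA sequences are carried through so the
#' file can be reconstructed.
#'
#' @param path path to a FASTQ file (optionally `.gz`).
#' @return A [quality_dataset()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4",
                 length(lines)))
  K <- length(lines) %/% 4L
  if (K == 0L) return(quality_dataset(character(0)))
  h <- lines[seq(1L, by = 4L, length.out = K)]
  s <- lines[seq(2L, by = 4L, length.out = K)]
  p <- lines[seq(3L, by = 4L, length.out = K)]
  q <- lines[seq(4L, by = 4L, length.out = K)]
  bad <- which(!startsWith(h, "@"))
  if (length(bad))
    stop(sprintf("record %d: header line does not start with '@'", bad[1]))
  bad <- which(!startsWith(p, "+"))
  if (length(bad))
    stop(sprintf("record %d: separator line does not start with '+'", bad[1]))
  bad <- which(nchar(q) != nchar(s))
  if (length(bad))
    stop(sprintf("record %d: quality length %d != sequence length %d",
                 bad[1], nchar(q[bad[1]]), nchar(s[bad[1]])))
  quality_dataset(q, ids = substring(h, 2L), sequences = s)
}

#' Write a quality dataset as a FASTQ file
#'
#' Emits the standard 4-line dialect: `@id`, sequence, `+`, quality.
#'
#' @param dataset a [quality_dataset()].
#' @param path output path (gzip-compressed if it ends in `.gz`).
#' @param sequences optional DNA lines overriding `dataset$sequences`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(dataset, path, sequences = NULL) {
  stopifnot(inherits(dataset, "quality_dataset"))
  seqs <- sequences %||% dataset$sequences
  if (is.null(seqs) && dataset$K > 0)
    stop("no DNA sequences available; supply `sequences`")
  if (dataset$K > 0) {
    if (length(seqs) != dataset$K)
      stop("sequences and qualities must have the same length")
    bad <- which(nchar(seqs) != nchar(dataset$qualities))
    if (length(bad))
      stop(sprintf("record %d: sequence and quality lengths differ", bad[1]))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (dataset$K > 0) {
    out <- character(4L * dataset$K)
    out[seq(1L, by = 4L, length.out = dataset$K)] <- paste0("@", dataset$ids)
    out[seq(2L, by = 4L, length.out = dataset$K)] <- seqs
    out[seq(3L, by = 4L, length.out = dataset$K)] <- "+"
    out[seq(4L, by = 4L, length.out = dataset$K)] <- dataset$qualities
    writeLines(out, con)
  }
  invisible(path)
}
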