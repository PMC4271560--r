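# Self-contained compressed container. Layout (all multi-byte integers
# big-endian):
#   magic "CQS1" | version u8 | flags u8 (1 ids, 2 sequences, 4 payload)
#   K u32
#   if payload: Huffman model  (nsym u8, nsym x [symbol u8, codelen u8])
#               codebook       (M u16, N u16, nS u8, nS symbol bytes,
#                               M*N vector bytes)
#   per read:   P_k u32 (original length), T_k u32 (packed length),
#               pad_bits u8
#   if ids:       block length u32 + newline-joined id bytes
#   if sequences: block length u32 + newline-joined DNA bytes
#   if payload:   payload bit count u32 + packed payload bytes, where each
#                 read contributes ceil(log2 M) index bits followed by its
#                 serialized edit script (2 bits/op + 8 bits/recorded symbol)

CQS_MAGIC <- charToRaw("CQS1")
CQS_VERSION <- 1L

bits_string_to_raw <- function(bits) {
  n <- nchar(bits)
  if (n == 0L) return(raw(0))
  v <- as.integer(charToRaw(bits)) - 48L
  pad <- (8L - n %% 8L) %% 8L
  if (pad > 0L) v <- c(v, integer(pad))
  packBits(as.integer(v), type = "raw")
}

raw_to_bits_string <- function(bytes, nbits) {
  if (nbits == 0L) return("")
  bits <- as.integer(rawToBits(bytes))
  paste(bits[seq_len(nbits)], collapse = "")
}

write_u <- function(con, x, size) {
  writeBin(as.integer(x), con, size = size, endian = "big")
}

read_u <- function(con, n, size) {
  v <- readBin(con, "integer", n = n, size = size,
               endian = "big", signed = size == 4L)
  if (length(v) != n) stop("corrupted container: truncated header")
  v
}

write_container <- function(path, K, P, T, pad, model = NULL,
                            codebook = NULL, ids = NULL, sequences = NULL,
                            payload_bits = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  has_data <- !is.null(payload_bits)
  flags <- (if (!is.null(ids)) 1L else 0L) +
    (if (!is.null(sequences)) 2L else 0L) +
    (if (has_data) 4L else 0L)
  writeBin(CQS_MAGIC, con)
  write_u(con, CQS_VERSION, 1L)
  write_u(con, flags, 1L)
  write_u(con, K, 4L)
  if (has_data) {
    write_u(con, length(model$symbols), 1L)
    writeBin(as.raw(rbind(vapply(model$symbols, utf8ToInt, integer(1)),
                          as.integer(model$lengths))), con)
    write_u(con, codebook$M, 2L)
    write_u(con, codebook$N, 2L)
    write_u(con, length(codebook$symbols), 1L)
    writeBin(as.raw(vapply(codebook$symbols, utf8ToInt, integer(1))), con)
    writeBin(charToRaw(paste(codebook$vectors, collapse = "")), con)
  }
  if (K > 0L) {
    write_u(con, P, 4L)
    write_u(con, T, 4L)
    write_u(con, pad, 1L)
  }
  for (block in list(ids, sequences)) {
    if (!is.null(block)) {
      b <- charToRaw(paste(block, collapse = "\n"))
      write_u(con, length(b), 4L)
      writeBin(b, con)
    }
  }
  if (has_data) {
    write_u(con, nchar(payload_bits), 4L)
    writeBin(bits_string_to_raw(payload_bits), con)
  }
  invisible(path)
}

read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, CQS_MAGIC))
    stop("not a cqs container (bad magic bytes)")
  version <- read_u(con, 1L, 1L)
  if (version != CQS_VERSION)
    stop(sprintf("unsupported container version %d", version))
  flags <- read_u(con, 1L, 1L)
  has_ids <- bitwAnd(flags, 1L) != 0L
  has_seqs <- bitwAnd(flags, 2L) != 0L
  has_data <- bitwAnd(flags, 4L) != 0L
  K <- read_u(con, 1L, 4L)
  model <- NULL
  cb <- NULL
  if (has_data) {
    nsym <- read_u(con, 1L, 1L)
    tab <- matrix(read_u(con, 2L * nsym, 1L), nrow = 2L)
    model <- rebuild_huffman_model(vapply(tab[1, ], intToUtf8, character(1)),
                                   tab[2, ])
    M <- read_u(con, 1L, 2L)
    N <- read_u(con, 1L, 2L)
    nS <- read_u(con, 1L, 1L)
    symbols <- vapply(read_u(con, nS, 1L), intToUtf8, character(1))
    vec_bytes <- readBin(con, "raw", M * N)
    if (length(vec_bytes) != M * N)
      stop("corrupted container: truncated codebook")
    all_vec <- rawToChar(vec_bytes)
    vectors <- substring(all_vec, (seq_len(M) - 1L) * N + 1L, seq_len(M) * N)
    cb <- new_codebook(vectors, symbols)
  }
  P <- T <- integer(0)
  pad <- integer(0)
  if (K > 0L) {
    P <- read_u(con, K, 4L)
    T <- read_u(con, K, 4L)
    pad <- read_u(con, K, 1L)
  }
  read_block <- function() {
    nb <- read_u(con, 1L, 4L)
    out <- strsplit(rawToChar(readBin(con, "raw", nb)), "\n",
                    fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; restore to K entries
    if (K > 0L) c(out, rep("", K))[seq_len(K)] else out
  }
  ids <- sequences <- NULL
  if (has_ids) ids <- read_block()
  if (has_seqs) sequences <- read_block()
  payload <- NULL
  if (has_data) {
    nbits <- read_u(con, 1L, 4L)
    nbytes <- ceiling(nbits / 8)
    bytes <- readBin(con, "raw", nbytes)
    if (length(bytes) != nbytes)
      stop("corrupted container: truncated payload")
    payload <- raw_to_bits_string(bytes, nbits)
  }
  list(K = K, model = model, codebook = cb, P = P, T = T, pad = pad,
       ids = ids, sequences = sequences, payload = payload,
       has_data = has_data,
       file_bits = 8 * file.size(path))
}

new_compression_report <- function(K, M, N, original_bits, payload_bits,
                                   file_bits, degenerate = FALSE) {
  bpq <- function(bits) if (original_bits > 0) 8 * bits / original_bits
    else NA_real_
  structure(
    list(K = K, M = M, N = N,
         original_bits = original_bits,
         payload_bits = payload_bits,
         total_bits = file_bits,
         header_bits = file_bits - payload_bits,
         BPQ = bpq(payload_bits),
         CR_percent = 100 * bpq(payload_bits) / 8,
         BPQ_total = bpq(file_bits),
         CR_total_percent = 100 * bpq(file_bits) / 8,
         degenerate = degenerate),
    class = "compression_report"
  )
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("compression_report: %d reads", x$K))
  if (!is.null(x$M)) cat(sprintf(", codebook M=%d, N=%d", x$M, x$N))
  cat("\n")
  if (x$degenerate) {
    cat("  degenerate input: no quality symbols to compress\n")
    return(invisible(x))
  }
  cat(sprintf("  original: %d bits (8.00 BPQ)\n", x$original_bits))
  cat(sprintf("  payload:  %d bits (%.2f BPQ, CR %.2f%%)\n",
              x$payload_bits, x$BPQ, x$CR_percent))
  cat(sprintf("  total (with header): %d bits (%.2f BPQ, CR %.2f%%)\n",
              x$total_bits, x$BPQ_total, x$CR_total_percent))
  invisible(x)
}

#' Compress the quality scores of a FASTQ file
#'
#' Runs the full pipeline: parse FASTQ, build one global canonical Huffman
#' model, pack every quality line into 6-bit ASCII, design the codebook by
#' multimodal memetic optimization (or use a supplied one), then encode each
#' packed sequence against the code vector with the minimal exact
#' dynamic-programming bit cost (ties to the lowest index). The container
#' written to `output` is sufficient for exact reconstruction.
#'
#' @param input path to a FASTQ file (optionally gzipped).
#' @param output path for the compressed container.
#' @param seed RNG seed for the codebook design; the output is
#'   byte-reproducible given it.
#' @param fes fitness-evaluation budget of the optimizer.
#' @param M,N codebook size / vector length overrides (defaults
#'   [codebook_size()] and [vector_length()] on the packed corpus).
#' @param codebook an external `codebook` (offline mode); its symbol set
#'   must cover the packed corpus.
#' @param store_reads keep read ids and DNA lines in the container so a
#'   complete FASTQ can be reconstructed.
#' @param verify decompress in memory after writing and stop unless every
#'   quality line matches byte-for-byte.
#' @return A `compression_report`, invisibly. Attribute `"codebook"` holds
#'   the codebook used.
#' @export
compress_fastq <- function(input, output, seed = 1L, fes = 1e4,
                           M = NULL, N = NULL, codebook = NULL,
                           store_reads = TRUE, verify = FALSE) {
  ds <- read_fastq(input)
  ids <- if (store_reads) ds$ids else NULL
  seqs <- if (store_reads) ds$sequences else NULL
  P <- nchar(ds$qualities)
  original_bits <- sum(8L * P)
  if (ds$K == 0L || original_bits == 0L) {
    write_container(output, K = ds$K, P = P, T = integer(ds$K),
                    pad = integer(ds$K), ids = ids, sequences = seqs)
    rep <- new_compression_report(ds$K, NULL, NULL, original_bits, 0,
                                  8 * file.size(output), degenerate = TRUE)
    return(invisible(rep))
  }
  model <- build_huffman_model(ds)
  packed <- lapply(ds$qualities, function(q)
    pack_to_ascii(encode_bits(q, model)))
  H <- vapply(packed, `[[`, character(1), "text")
  pad <- vapply(packed, `[[`, integer(1), "pad_bits")
  T <- vapply(packed, `[[`, integer(1), "n_symbols")
  if (is.null(codebook)) {
    codebook <- design_codebook(H, M = M, N = N, fes = fes, seed = seed)
  } else {
    stopifnot(inherits(codebook, "codebook"))
    corpus_syms <- sort_symbols(split_chars(paste(H, collapse = "")))
    if (!all(corpus_syms %in% codebook$symbols))
      stop("external codebook symbol set does not cover the input")
  }
  ib <- index_bits(codebook$M)
  pieces <- character(ds$K)
  for (k in seq_len(ds$K)) {
    best <- best_vector_cpp(codebook$vectors, H[k])
    script <- align(H[k], codebook$vectors[best[1]])
    pieces[k] <- paste0(int_to_bits(best[1] - 1L, ib),
                        serialize_script(script))
  }
  payload_bits <- paste(pieces, collapse = "")
  write_container(output, K = ds$K, P = P, T = T, pad = pad,
                  model = model, codebook = codebook,
                  ids = ids, sequences = seqs,
                  payload_bits = payload_bits)
  rep <- new_compression_report(ds$K, codebook$M, codebook$N, original_bits,
                                nchar(payload_bits), 8 * file.size(output))
  attr(rep, "codebook") <- codebook
  if (verify) {
    back <- decompress_container(output)
    if (!identical(back$qualities, ds$qualities))
      stop("verification failed: decompressed qualities differ from input")
  }
  invisible(rep)
}

#' Decompress a container back to its quality dataset
#'
#' Per read: the code-vector index and edit script are read from the
#' payload, the script is applied to the code vector to recover the packed
#' sequence, the 6-bit packing is undone with the stored padding, and the
#' Huffman bitstream is decoded with the stored model. The result is
#' byte-identical to the original quality lines.
#'
#' @param input path to a container written by [compress_fastq()].
#' @param output optional path: write the reconstructed FASTQ there
#'   (requires stored DNA sequences).
#' @return The reconstructed [quality_dataset()], invisibly when `output`
#'   is given.
#' @export
decompress_container <- function(input, output = NULL) {
  ct <- read_container(input)
  qualities <- character(ct$K)
  if (ct$has_data) {
    ib <- index_bits(ct$codebook$M)
    pos <- 1L
    n <- nchar(ct$payload)
    for (k in seq_len(ct$K)) {
      qualities[k] <- tryCatch({
        if (pos + ib - 1L > n)
          stop("truncated payload")
        idx <- bits_to_int(substr(ct$payload, pos, pos + ib - 1L)) + 1L
        pos <- pos + ib
        if (idx > ct$codebook$M)
          stop("code-vector index out of range")
        ds <- deserialize_script(substr(ct$payload, pos, n),
                                 c_len = ct$codebook$N, q_len = ct$T[k])
        pos <- pos + ds$n_bits
        H <- apply_script(ct$codebook$vectors[idx], ds$script)
        bits <- unpack_from_ascii(H, pad_bits = ct$pad[k])
        q <- decode_bits(bits, ct$model)
        if (nchar(q) != ct$P[k])
          stop(sprintf("decoded length %d != stored length %d",
                       nchar(q), ct$P[k]))
        q
      }, error = function(e)
        stop(sprintf("read %d: %s", k, conditionMessage(e)), call. = FALSE))
    }
  }
  ds <- quality_dataset(qualities,
                        ids = ct$ids %||% sprintf("read_%d", seq_len(ct$K)),
                        sequences = ct$sequences)
  if (!is.null(output)) {
    if (is.null(ct$sequences))
      stop("container has no stored DNA sequences; cannot emit FASTQ")
    write_fastq(ds, output)
    return(invisible(ds))
  }
  ds
}

#' Compression metrics recomputed from a container
#'
#' Re-reads the container, re-measures the per-read encoded sizes
#' `ceil(log2 M) + 2*P* + 8*R` from the stored edit scripts, and reports
#' bits per quality value `BPQ = sum_k L_C(k) / sum_k P_k` (against the
#' original read lengths) and the compression ratio `CR = 100 * BPQ / 8`,
#' both payload-only and header-inclusive.
#'
#' @param input path to a container.
#' @return A `compression_report`.
#' @export
report_metrics <- function(input) {
  ct <- read_container(input)
  original_bits <- sum(8L * ct$P)
  if (!ct$has_data)
    return(new_compression_report(ct$K, NULL, NULL, original_bits, 0,
                                  ct$file_bits, degenerate = TRUE))
  ib <- index_bits(ct$codebook$M)
  pos <- 1L
  total <- 0L
  for (k in seq_len(ct$K)) {
    pos <- pos + ib
    ds <- deserialize_script(substr(ct$payload, pos, nchar(ct$payload)),
                             c_len = ct$codebook$N, q_len = ct$T[k])
    pos <- pos + ds$n_bits
    total <- total + ib + 2L * ds$script$P_star + 8L * ds$script$R
  }
  stopifnot(total == nchar(ct$payload))
  new_compression_report(ct$K, ct$codebook$M, ct$codebook$N, original_bits,
                         total, ct$file_bits)
}
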