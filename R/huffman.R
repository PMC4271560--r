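# Canonical Huffman preprocessing: quality strings -> prefix-code bitstream
# -> 6-bit printable ASCII (codes 33..96), and the exact inverses.

# Optimal prefix-code lengths for a named frequency vector. O(n^2) merging,
# deterministic: ties broken by (weight, smallest contained symbol code).
huffman_code_lengths <- function(freq) {
  n <- length(freq)
  if (n == 0L) stop("cannot build a Huffman model from an empty alphabet")
  if (n == 1L) return(stats::setNames(1L, names(freq)))
  sym_code <- vapply(names(freq), utf8ToInt, integer(1))
  weights <- as.numeric(freq)
  groups <- as.list(seq_len(n))        # leaf indices under each live node
  minsym <- sym_code                   # deterministic tie-break key
  depth <- integer(n)
  while (length(weights) > 1L) {
    ord <- order(weights, minsym)
    a <- ord[1]; b <- ord[2]
    depth[groups[[a]]] <- depth[groups[[a]]] + 1L
    depth[groups[[b]]] <- depth[groups[[b]]] + 1L
    merged_w <- weights[a] + weights[b]
    merged_g <- c(groups[[a]], groups[[b]])
    merged_m <- min(minsym[a], minsym[b])
    keep <- setdiff(seq_along(weights), c(a, b))
    weights <- c(weights[keep], merged_w)
    groups <- c(groups[keep], list(merged_g))
    minsym <- c(minsym[keep], merged_m)
  }
  stats::setNames(depth, names(freq))
}

# Canonical code assignment: symbols ordered by (length, ASCII code);
# consecutive codes, shifted left when the length grows.
canonical_codes <- function(lengths) {
  sym <- names(lengths)
  ord <- order(lengths, vapply(sym, utf8ToInt, integer(1)))
  codes <- character(length(lengths))
  code <- 0
  prev_len <- lengths[ord[1]]
  if (max(lengths) > 52L) stop("Huffman code length exceeds supported maximum")
  for (i in seq_along(ord)) {
    len <- lengths[ord[i]]
    if (i > 1L) code <- (code + 1) * 2^(len - prev_len)
    codes[ord[i]] <- paste(
      rev(floor(code / 2^(seq_len(len) - 1)) %% 2),
      collapse = "")
    prev_len <- len
  }
  stats::setNames(codes, sym)
}

new_huffman_model <- function(lengths, freq = NULL) {
  syms <- sort_symbols(names(lengths))
  lengths <- lengths[syms]
  structure(
    list(codes = canonical_codes(lengths),
         lengths = lengths,
         frequencies = if (!is.null(freq)) freq[syms],
         symbols = syms),
    class = "huffman_model"
  )
}

#' Build a canonical Huffman model from pooled quality symbols
#'
#' One global model is built from the symbol frequencies of all quality
#' lines pooled together. Codes are canonical -- lengths are optimal for the
#' frequencies and, within a length, assigned in ASCII order -- so the model
#' is fully reconstructible from its code lengths alone
#' (see [rebuild_huffman_model()]). A single-symbol alphabet receives the
#' fixed 1-bit code `"0"`.
#'
#' @param x a [quality_dataset()] or a character vector of quality strings.
#' @return An object of class `huffman_model` with elements `codes`
#'   (symbol -> bitstring), `lengths`, `frequencies` and `symbols`.
#' @export
build_huffman_model <- function(x) {
  qualities <- if (inherits(x, "quality_dataset")) x$qualities else
    as.character(x)
  chars <- split_chars(paste(qualities, collapse = ""))
  if (length(chars) == 0L)
    stop("cannot build a Huffman model: no quality symbols present")
  freq <- table(chars)
  freq <- stats::setNames(as.numeric(freq), names(freq))
  lengths <- huffman_code_lengths(freq)
  new_huffman_model(lengths, freq)
}

#' Rebuild a canonical Huffman model from serialized code lengths
#'
#' @param symbols character vector of symbols.
#' @param lengths integer vector of code lengths, same order as `symbols`.
#' @return A `huffman_model` identical to the one the lengths came from.
#' @export
rebuild_huffman_model <- function(symbols, lengths) {
  new_huffman_model(stats::setNames(as.integer(lengths), symbols))
}

#' @export
print.huffman_model <- function(x, ...) {
  cat(sprintf("huffman_model: %d symbols, code lengths %d..%d\n",
              length(x$symbols), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Huffman-encode a quality string to a bitstring
#'
#' @param q quality string; every symbol must be in the model.
#' @param model a `huffman_model`.
#' @return Concatenated per-symbol codes as a `"0"`/`"1"` string.
#' @export
encode_bits <- function(q, model) {
  stopifnot(inherits(model, "huffman_model"))
  if (nchar(q) == 0L) return("")
  chars <- split_chars(q)
  idx <- match(chars, model$symbols)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("symbol '%s' at position %d is not in the Huffman model",
                 chars[p], p))
  }
  paste(model$codes[idx], collapse = "")
}

#' Decode a Huffman bitstream back to a quality string
#'
#' @param bits a `"0"`/`"1"` string consisting of complete codewords.
#' @param model the `huffman_model` used for encoding.
#' @return The decoded quality string.
#' @export
decode_bits <- function(bits, model) {
  stopifnot(inherits(model, "huffman_model"))
  if (nchar(bits) == 0L) return("")
  lookup <- new.env(parent = emptyenv(), size = 2L * length(model$codes))
  for (i in seq_along(model$codes))
    assign(model$codes[[i]], model$symbols[[i]], envir = lookup)
  maxlen <- max(model$lengths)
  n <- nchar(bits)
  out <- character(0)
  pos <- 1L
  while (pos <= n) {
    hit <- NULL
    for (len in seq_len(min(maxlen, n - pos + 1L))) {
      cand <- substr(bits, pos, pos + len - 1L)
      if (!is.null(sym <- lookup[[cand]])) {
        hit <- sym
        pos <- pos + len
        break
      }
    }
    if (is.null(hit))
      stop("corrupted Huffman stream: dangling bits match no codeword")
    out[length(out) + 1L] <- hit
  }
  paste(out, collapse = "")
}

#' Pack a bitstring into 6-bit printable ASCII
#'
#' Splits the bitstream into big-endian 6-bit groups (the last group
#' zero-padded on the right), maps each value `v` in 0..63 to the character
#' with ASCII code `33 + v` (so all output lies in `!`..`` ` ``, codes
#' 33..96), and records the padding so the packing is exactly invertible.
#'
#' @param bits a `"0"`/`"1"` string (may be empty).
#' @return An object of class `packed_seq`: `text` (the packed string),
#'   `pad_bits` (0..5) and `n_symbols`.
#' @export
pack_to_ascii <- function(bits) {
  n <- nchar(bits)
  pad <- (6L - n %% 6L) %% 6L
  if (pad > 0L) bits <- paste0(bits, strrep("0", pad))
  total <- n + pad
  if (total == 0L) {
    return(structure(list(text = "", pad_bits = 0L, n_symbols = 0L),
                     class = "packed_seq"))
  }
  starts <- seq(1L, total, by = 6L)
  groups <- substring(bits, starts, starts + 5L)
  vals <- strtoi(groups, base = 2L)
  structure(
    list(text = rawToChar(as.raw(33L + vals)),
         pad_bits = pad,
         n_symbols = length(vals)),
    class = "packed_seq"
  )
}

#' Unpack 6-bit ASCII back to the original bitstring
#'
#' Exact inverse of [pack_to_ascii()].
#'
#' @param packed a `packed_seq`, or the packed text string itself.
#' @param pad_bits number of padding bits (taken from `packed` when it is a
#'   `packed_seq`).
#' @return The original `"0"`/`"1"` string with padding stripped.
#' @export
unpack_from_ascii <- function(packed, pad_bits = NULL) {
  if (inherits(packed, "packed_seq")) {
    text <- packed$text
    pad_bits <- packed$pad_bits
  } else {
    text <- packed
    pad_bits <- pad_bits %||% 0L
  }
  if (pad_bits < 0L || pad_bits > 5L)
    stop("pad_bits must be in [0, 5]")
  if (nchar(text) == 0L) {
    if (pad_bits != 0L) stop("corrupted packed sequence: padding without data")
    return("")
  }
  vals <- utf8ToInt(text) - 33L
  if (any(vals < 0L | vals > 63L))
    stop("corrupted packed sequence: character outside ASCII [33, 96]")
  bits <- paste(int_to_bits(vals, 6L), collapse = "")
  substr(bits, 1L, nchar(bits) - pad_bits)
}
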