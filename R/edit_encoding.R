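# Substitutional encoding: a quality sequence is stored as an edit script
# transforming a code vector C into the sequence Q. Ops are U (unchanged),
# I (insertion), D (deletion), S (substitution); I and S record the original
# symbol. Each op costs 2 bits, each recorded symbol 8 bits, and a read
# additionally pays ceil(log2(M)) bits for its code-vector index.

new_edit_script <- function(ops, recorded) {
  ops <- as.character(ops)
  stopifnot(all(ops %in% c("U", "I", "D", "S")))
  needs <- ops %in% c("I", "S")
  if (!identical(needs, !is.na(recorded)))
    stop("recorded symbols must be present exactly for I and S ops")
  structure(
    list(ops = ops, recorded = recorded,
         P_star = length(ops), R = sum(needs)),
    class = "edit_script"
  )
}

#' @export
print.edit_script <- function(x, ...) {
  lab <- ifelse(is.na(x$recorded), x$ops,
                paste0(x$ops, "(", x$recorded, ")"))
  cat(sprintf("edit_script: P*=%d, R=%d\n  %s\n",
              x$P_star, x$R, paste(lab, collapse = " ")))
  invisible(x)
}

#' Optimal edit script of a sequence against a code vector
#'
#' Dynamic programming over the true bit cost (U and D cost 2 bits; I and S
#' cost 2 + 8 bits for the recorded symbol), not unit edit distance: the
#' script returned minimizes `2*P* + 8*R` among all scripts that transform
#' `C` into `Q`. Ties during traceback are broken `U > D > I > S`, so the
#' result is deterministic and biased away from recorded symbols.
#'
#' @param Q target sequence (the original quality string, possibly empty).
#' @param C code vector (possibly empty).
#' @return An `edit_script` with fields `ops`, `recorded` (symbol or `NA`
#'   per op), `P_star` (number of ops) and `R` (number of recorded symbols).
#' @seealso [apply_script()], [exact_cost()]
#' @export
align <- function(Q, C) {
  res <- align_ops_cpp(Q, C)
  ops <- split_chars(res$ops)
  rec_syms <- split_chars(res$recorded)
  recorded <- rep(NA_character_, length(ops))
  recorded[ops %in% c("I", "S")] <- rec_syms
  new_edit_script(ops, recorded)
}

#' Exact encoded size of a read in bits
#'
#' `ceil(log2(M)) + 2*P* + 8*R`: the code-vector index plus 2 bits per edit
#' op plus 8 bits per recorded symbol. `M = 1` needs no index bits.
#'
#' @param script an `edit_script`.
#' @param M codebook size (>= 1).
#' @return Integer bit count.
#' @export
exact_cost <- function(script, M) {
  stopifnot(inherits(script, "edit_script"))
  index_bits(M) + 2L * script$P_star + 8L * script$R
}

#' Raw storage size of a quality string in bits
#'
#' Quality scores are stored in 8-bit ASCII, so the raw size is `8 * P`.
#'
#' @param Q quality string.
#' @return Integer bit count.
#' @export
raw_size <- function(Q) 8L * nchar(Q)

#' Levenshtein distance
#'
#' Minimum number of single-symbol insertions, deletions and substitutions
#' transforming `a` into `b`.
#'
#' @param a,b symbol strings.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) lev_cpp(a, b)

#' Approximate encoded size used as the optimizer's fitness surrogate
#'
#' `ceil(log2(M)) + 2*|Q| + 4*lev(C, Q)`. The Levenshtein term is weighted
#' by 4 because half of the op types (I and S) record an 8-bit symbol, so an
#' edit costs 8 extra bits with probability about one half.
#'
#' @param Q quality string.
#' @param C code vector.
#' @param M codebook size (>= 1).
#' @return Numeric bit count.
#' @export
approx_cost <- function(Q, C, M) {
  index_bits(M) + 2L * nchar(Q) + 4L * lev_cpp(C, Q)
}

#' Apply an edit script to a code vector (decoding)
#'
#' `U` copies the next symbol of `C`; `S` emits its recorded symbol and
#' consumes one `C` symbol; `I` emits its recorded symbol consuming nothing;
#' `D` consumes one `C` symbol emitting nothing. For any `Q`,
#' `apply_script(C, align(Q, C)) == Q`.
#'
#' @param C code vector.
#' @param script an `edit_script` consistent with `C`.
#' @return The reconstructed sequence.
#' @export
apply_script <- function(C, script) {
  stopifnot(inherits(script, "edit_script"))
  cs <- split_chars(C)
  out <- character(0)
  ci <- 0L
  for (i in seq_along(script$ops)) {
    op <- script$ops[i]
    if (op == "U") {
      ci <- ci + 1L
      if (ci > length(cs))
        stop("edit script inconsistent with code vector: C exhausted at U op")
      out[length(out) + 1L] <- cs[ci]
    } else if (op == "S") {
      ci <- ci + 1L
      if (ci > length(cs))
        stop("edit script inconsistent with code vector: C exhausted at S op")
      out[length(out) + 1L] <- script$recorded[i]
    } else if (op == "I") {
      out[length(out) + 1L] <- script$recorded[i]
    } else { # D
      ci <- ci + 1L
      if (ci > length(cs))
        stop("edit script inconsistent with code vector: C exhausted at D op")
    }
  }
  if (ci != length(cs))
    stop(sprintf(
      "edit script inconsistent with code vector: consumed %d of %d symbols",
      ci, length(cs)))
  paste(out, collapse = "")
}

# 2-bit op codes used in the container payload.
.op_bits <- c(U = "00", I = "01", D = "10", S = "11")
.bits_op <- stats::setNames(names(.op_bits), .op_bits)

#' Serialize an edit script to its container bit layout
#'
#' Each op becomes 2 bits (`U=00, I=01, D=10, S=11`); recorded symbols
#' follow their op immediately as 8-bit ASCII. The output length is exactly
#' `2*P* + 8*R`.
#'
#' @param script an `edit_script`.
#' @return A `"0"`/`"1"` string.
#' @export
serialize_script <- function(script) {
  stopifnot(inherits(script, "edit_script"))
  if (script$P_star == 0L) return("")
  pieces <- .op_bits[script$ops]
  has_sym <- !is.na(script$recorded)
  if (any(has_sym)) {
    sym_bits <- int_to_bits(
      vapply(script$recorded[has_sym], utf8ToInt, integer(1)), 8L)
    pieces[has_sym] <- paste0(pieces[has_sym], sym_bits)
  }
  paste(pieces, collapse = "")
}

#' Deserialize an edit script from the container bit layout
#'
#' Ops are read until exactly `c_len` code-vector symbols have been consumed
#' (by U, S, D) and exactly `q_len` target symbols emitted (by U, S, I).
#'
#' @param bits a `"0"`/`"1"` string beginning with a serialized script
#'   (trailing bits are ignored).
#' @param c_len length of the code vector the script applies to.
#' @param q_len length of the target sequence the script reconstructs.
#' @return A list with the `edit_script` and `n_bits`, the number of bits
#'   consumed.
#' @export
deserialize_script <- function(bits, c_len, q_len) {
  pos <- 1L
  n <- nchar(bits)
  ops <- character(0)
  recorded <- character(0)
  consumed <- 0L
  emitted <- 0L
  while (consumed < c_len || emitted < q_len) {
    if (pos + 1L > n)
      stop("corrupted container: truncated edit script")
    op <- .bits_op[[substr(bits, pos, pos + 1L)]]
    pos <- pos + 2L
    sym <- NA_character_
    if (op %in% c("I", "S")) {
      if (pos + 7L > n)
        stop("corrupted container: truncated recorded symbol")
      code <- bits_to_int(substr(bits, pos, pos + 7L))
      if (code < 1L) stop("corrupted container: invalid recorded symbol")
      sym <- intToUtf8(code)
      pos <- pos + 8L
    }
    if (op %in% c("U", "S", "D")) consumed <- consumed + 1L
    if (op %in% c("U", "S", "I")) emitted <- emitted + 1L
    if (consumed > c_len || emitted > q_len)
      stop("corrupted container: edit script overruns its sequence lengths")
    ops[length(ops) + 1L] <- op
    recorded[length(recorded) + 1L] <- sym
  }
  list(script = new_edit_script(ops, recorded), n_bits = pos - 1L)
}
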