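`%||%` <- function(a, b) if (is.null(a)) b else a

# Big-endian fixed-width bitstring for a nonnegative integer (< 2^31).
int_to_bits <- function(v, width) {
  vapply(v, function(x) {
    stopifnot(x >= 0, x < 2^width)
    bits <- integer(width)
    for (i in width:1) {
      bits[i] <- x %% 2
      x <- x %/% 2
    }
    paste(bits, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

bits_to_int <- function(bits) {
  if (nchar(bits) == 0L) return(0L)
  strtoi(bits, base = 2L)
}

# Number of bits needed to store a codebook index: ceil(log2(M)), 0 for M = 1.
index_bits <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M < 1)
    stop("codebook size M must be >= 1")
  if (M == 1) return(0L)
  as.integer(ceiling(log2(M)))
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sort a character vector of single symbols by ASCII code (locale-free).
sort_symbols <- function(syms) {
  syms <- unique(syms)
  if (length(syms) == 0L) return(character(0))
  syms[order(vapply(syms, utf8ToInt, integer(1), USE.NAMES = FALSE))]
}

split_chars <- function(x) {
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1]]
}
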