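# Bridge between the optimizer and the encoder: continuous individuals are
# decoded into discrete code vectors, the compression objective is the
# summed approximate encoded size over the corpus, and the final population
# becomes the codebook.

#' Codebook size from the number of sequences
#'
#' `M = round((log2(ceil(K/10)))^2)` (half-up), clamped to a minimum of 2 so
#' that `ceil(log2(M))` can index anything.
#'
#' @param K number of quality sequences (>= 1).
#' @return Integer codebook size.
#' @export
codebook_size <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1)
    stop("K must be a positive count")
  M <- round_half_up(log2(ceiling(K / 10))^2)
  max(as.integer(M), 2L)
}

#' Code-vector length from the corpus read lengths
#'
#' `N = round((min + max) / 2)` (half-up), minimum 1.
#'
#' @param lengths integer vector of sequence lengths (nonempty).
#' @return Integer code-vector length.
#' @export
vector_length <- function(lengths) {
  if (length(lengths) == 0L) stop("lengths must be nonempty")
  max(as.integer(round_half_up((min(lengths) + max(lengths)) / 2)), 1L)
}

#' Decode a continuous individual into a code vector
#'
#' Coordinate `x_n` maps to symbol `S[ceil(x_n)]` (1-based), with the index
#' clamped into `[1, |S|]` so the mapping is total.
#'
#' @param x numeric vector.
#' @param symbols ordered symbol set (character vector of single symbols).
#' @return The code-vector text, a string of `length(x)` symbols.
#' @export
decode_individual <- function(x, symbols) {
  ns <- length(symbols)
  stopifnot(ns >= 1)
  idx <- pmin(pmax(ceiling(x), 1L), ns)
  paste(symbols[idx], collapse = "")
}

#' Raw compression fitness of an individual
#'
#' Sum over the corpus of the approximate encoded size
#' `ceil(log2(M)) + 2*|Q_k| + 4*lev(C, Q_k)` of every sequence against the
#' decoded code vector (see [approx_cost()]). Smaller is better.
#'
#' @param x numeric vector (an optimizer individual).
#' @param sequences character vector of (packed) quality sequences.
#' @param symbols ordered symbol set used by [decode_individual()].
#' @param M codebook size (for the index-bits term).
#' @return Total approximate encoded size in bits.
#' @export
codebook_raw_fitness <- function(x, sequences, symbols, M) {
  if (length(sequences) == 0L) stop("sequences must be nonempty")
  corpus_approx_cost_cpp(decode_individual(x, symbols), sequences,
                         index_bits(M))
}

new_codebook <- function(vectors, symbols, raw_fitness = NULL, trace = NULL) {
  stopifnot(length(vectors) >= 1)
  N <- unique(nchar(vectors))
  stopifnot(length(N) == 1L)
  structure(
    list(vectors = vectors, M = length(vectors), N = N,
         symbols = symbols, raw_fitness = raw_fitness, trace = trace),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: M=%d vectors of length N=%d over %d symbols\n",
              x$M, x$N, length(x$symbols)))
  invisible(x)
}

#' Design a compression codebook by multimodal memetic optimization
#'
#' Runs [run_ma()] with one individual per code vector (`pop_size = M`),
#' dimension `N`, bounds `(0, |S|)`, niching radius `0.1 * N` and sharing
#' shape `alpha = 50`; every individual of the final population is decoded
#' through [decode_individual()] into one code vector. Duplicated vectors
#' are kept: the codebook is the population. When `M < 4` the optimizer
#' runs with 4 individuals (the DE stage needs them) and the best `M` by
#' raw fitness form the codebook.
#'
#' @param sequences character vector of (packed) quality sequences.
#' @param M codebook size; default [codebook_size()] of the corpus.
#' @param N code-vector length; default [vector_length()] of the corpus.
#' @param fes raw-fitness evaluation budget.
#' @param epsilon niching radius; default `0.1 * N`.
#' @param alpha sharing shape.
#' @param ls_evals per-individual local-search budget per generation;
#'   default `2 * N`.
#' @param seed RNG seed; the design is deterministic given it.
#' @return A `codebook` object (fields `vectors`, `M`, `N`, `symbols`,
#'   `raw_fitness`, `trace`).
#' @export
design_codebook <- function(sequences, M = NULL, N = NULL, fes = 1e4,
                            epsilon = NULL, alpha = 50, ls_evals = NULL,
                            seed = 1L) {
  if (length(sequences) == 0L) stop("sequences must be nonempty")
  symbols <- sort_symbols(split_chars(paste(sequences, collapse = "")))
  if (length(symbols) == 0L)
    stop("cannot design a codebook: sequences contain no symbols")
  M <- as.integer(M %||% codebook_size(length(sequences)))
  N <- as.integer(N %||% vector_length(nchar(sequences)))
  epsilon <- epsilon %||% (0.1 * N)
  ls_evals <- as.integer(ls_evals %||% (2L * N))
  pop <- max(M, 4L)
  # local-search step of one symbol level: the decode map is a ceiling into
  # the symbol set, so 1.0 is the natural quantum of the landscape
  cfg <- ma_config(pop_size = pop, dim = N,
                   lower = 0, upper = length(symbols),
                   max_evals = fes, ls_evals = ls_evals, ls_step = 1,
                   seed = seed)
  shp <- sharing_params(epsilon = epsilon, alpha = alpha)
  ib <- index_bits(M)
  objective <- function(x)
    corpus_approx_cost_cpp(decode_individual(x, symbols), sequences, ib)
  res <- run_ma(objective, cfg, shp)
  keep <- seq_len(M) # population is sorted by raw fitness
  vectors <- vapply(keep, function(i)
    decode_individual(res$population[i, ], symbols), character(1))
  new_codebook(vectors, symbols, raw_fitness = res$raw[keep],
               trace = res$trace)
}
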