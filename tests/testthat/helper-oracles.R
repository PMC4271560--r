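# Independent brute-force oracles (plain recursion, no memoization, no DP)
# and small fixture builders used across the suite.

# Minimum bit cost 2*P* + 8*R over all edit scripts transforming c into q:
# U/D cost 2, I/S cost 10. Recursion over string suffixes.
brute_align_cost <- function(q, c) {
  nq <- nchar(q); nc <- nchar(c)
  if (nq == 0L && nc == 0L) return(0L)
  best <- Inf
  if (nq > 0L && nc > 0L) {
    same <- substr(q, nq, nq) == substr(c, nc, nc)
    best <- min(best, brute_align_cost(substr(q, 1L, nq - 1L),
                                       substr(c, 1L, nc - 1L)) +
                  if (same) 2L else 10L)
  }
  if (nc > 0L)
    best <- min(best, brute_align_cost(q, substr(c, 1L, nc - 1L)) + 2L)
  if (nq > 0L)
    best <- min(best, brute_align_cost(substr(q, 1L, nq - 1L), c) + 10L)
  as.integer(best)
}

# Unit-cost edit distance by the same style of recursion.
brute_lev <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  same <- substr(a, na, na) == substr(b, nb, nb)
  min(brute_lev(substr(a, 1L, na - 1L), substr(b, 1L, nb - 1L)) +
        if (same) 0L else 1L,
      brute_lev(a, substr(b, 1L, nb - 1L)) + 1L,
      brute_lev(substr(a, 1L, na - 1L), b) + 1L)
}

# All strings of length 0..maxlen over an alphabet.
all_strings <- function(alphabet, maxlen) {
  out <- ""
  cur <- ""
  for (len in seq_len(maxlen)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

random_string <- function(alphabet, len) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Write a FASTQ file with the given quality strings (DNA lines are N runs).
write_tiny_fastq <- function(qualities, path = tempfile(fileext = ".fastq"),
                             ids = NULL) {
  ds <- quality_dataset(qualities, ids = ids,
                        sequences = strrep("N", nchar(qualities)))
  write_fastq(ds, path)
  path
}

random_bitstring <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("0", "1"), len, replace = TRUE), collapse = "")
}
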