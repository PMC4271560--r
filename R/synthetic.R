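# Seeded generator of FASTQ fixtures with Illumina-like quality structure:
# a small number of latent per-position templates (high scores early, a
# decaying tail), from which each read is drawn and perturbed by small,
# mostly local, symbol shifts. The point is controllable inter-read
# redundancy -- the signal a codebook compressor exploits -- not platform
# fidelity.

#' Quality-profile specification for the synthetic generator
#'
#' @param read_length read length, or a `c(min, max)` range from which each
#'   read's length is drawn uniformly.
#' @param alphabet ordered character vector of allowed quality symbols;
#'   default is the 40-symbol Phred+33 range `#`..`J` (quality 2..41).
#' @param q_high,q_low 1-based alphabet indices of the mean quality at the
#'   first position and at the asymptotic tail.
#' @param decay_rate exponential decay rate of the positional mean from
#'   `q_high` to `q_low` across the read.
#' @param template_sd per-position jitter (in alphabet steps) used when
#'   drawing each template around the positional mean.
#' @param noise_sd spread (alphabet steps) of the shift applied to a
#'   mutated symbol; shifts of 0 are pushed to +/-1.
#' @param n_templates number of latent templates; more templates mean a
#'   less codebook-friendly corpus.
#' @param template_mutation_rate per-symbol probability that a read's
#'   symbol is perturbed away from its template.
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(read_length = 100L,
                            alphabet = NULL,
                            q_high = 37L, q_low = 26L,
                            decay_rate = 3,
                            template_sd = 1.5,
                            noise_sd = 2,
                            n_templates = 2L,
                            template_mutation_rate = 0.05) {
  alphabet <- alphabet %||%
    vapply(35:74, intToUtf8, character(1)) # Phred+33 quality 2..41
  stopifnot(length(alphabet) >= 1,
            template_mutation_rate >= 0, template_mutation_rate <= 1,
            n_templates >= 1, all(read_length >= 0))
  q_high <- min(max(q_high, 1L), length(alphabet))
  q_low <- min(max(q_low, 1L), length(alphabet))
  structure(
    list(read_length = as.integer(read_length), alphabet = alphabet,
         q_high = q_high, q_low = q_low, decay_rate = decay_rate,
         template_sd = template_sd, noise_sd = noise_sd,
         n_templates = as.integer(n_templates),
         template_mutation_rate = template_mutation_rate),
    class = "quality_profile"
  )
}

#' Generate a synthetic FASTQ file with latent quality templates
#'
#' Each template is a symbol string drawn around a position-dependent mean
#' (high early, decaying tail). Every read picks a template uniformly, then
#' perturbs each symbol independently with `template_mutation_rate`, the
#' perturbation being a small signed shift in the alphabet (`noise_sd`
#' steps, never 0, clamped to the alphabet). DNA lines are uniform A/C/G/T,
#' irrelevant to the compressor. Deterministic and byte-identical given
#' `seed`.
#'
#' @param n_reads number of reads (>= 0).
#' @param profile a [quality_profile()].
#' @param seed RNG seed.
#' @param path output FASTQ path.
#' @return Invisibly, a list with `path`, `templates` (the template quality
#'   strings), `assignment` (template index per read) and `profile` --
#'   the ground truth for niche-recovery checks.
#' @export
generate_fastq <- function(n_reads, profile = quality_profile(),
                           seed = 1L, path) {
  stopifnot(n_reads >= 0)
  with_seed(seed, {
    A <- length(profile$alphabet)
    lr <- profile$read_length
    lmin <- min(lr); lmax <- max(lr)
    # positional means over the longest read
    pos <- seq_len(max(lmax, 1L))
    mu <- if (lmax <= 1L) rep(profile$q_high, length(pos)) else
      profile$q_low + (profile$q_high - profile$q_low) *
        exp(-profile$decay_rate * (pos - 1) / (lmax - 1))
    tpl_idx <- lapply(seq_len(profile$n_templates), function(t)
      pmin(pmax(round(mu + rnorm(length(mu), 0, profile$template_sd)), 1L), A))
    templates <- vapply(tpl_idx, function(ix)
      paste(profile$alphabet[ix], collapse = ""), character(1))
    assignment <- integer(0)
    quals <- character(0)
    seqs <- character(0)
    if (n_reads > 0L) {
      assignment <- sample.int(profile$n_templates, n_reads, replace = TRUE)
      lens <- if (lmin == lmax) rep(lmax, n_reads) else
        sample(lmin:lmax, n_reads, replace = TRUE)
      quals <- vapply(seq_len(n_reads), function(k) {
        L <- lens[k]
        if (L == 0L) return("")
        ix <- tpl_idx[[assignment[k]]][seq_len(L)]
        hit <- runif(L) < profile$template_mutation_rate
        if (any(hit)) {
          shift <- round(rnorm(sum(hit), 0, profile$noise_sd))
          zero <- shift == 0
          if (any(zero))
            shift[zero] <- sample(c(-1L, 1L), sum(zero), replace = TRUE)
          ix[hit] <- pmin(pmax(ix[hit] + shift, 1L), A)
        }
        paste(profile$alphabet[ix], collapse = "")
      }, character(1))
      seqs <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
    }
    ds <- quality_dataset(quals,
                          ids = sprintf("synth_%06d", seq_len(n_reads)),
                          sequences = seqs)
    write_fastq(ds, path)
    invisible(list(path = path, templates = templates,
                   assignment = assignment, profile = profile))
  })
}
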