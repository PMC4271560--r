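---
title: "Codebook-based lossless compression of FASTQ quality scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codebook-based lossless compression of FASTQ quality scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqs)
```

## The problem

A FASTQ record carries, besides the DNA call, one quality symbol per base:
a printable ASCII character encoding the base-calling confidence. Stored
raw, quality data costs 8 bits per quality value (BPQ) and routinely
occupies as much space as the DNA itself, while being harder to compress
because its alphabet is much larger than `{A,C,G,T}`. `cqs` compresses the
quality stream losslessly and without any external reference, leaving read
ids and DNA lines untouched (they are carried through verbatim so the
original FASTQ can be re-emitted byte-identically).

The design treats quality lines as opaque ASCII symbol strings. No
Phred-offset interpretation is performed anywhere: the codec is agnostic to
whether a file uses the +33 or +64 convention.

## The model

Compression proceeds in three stages.

**1. Huffman preprocessing.** One canonical Huffman code is built from the
pooled symbol frequencies of all quality lines. Each line's bitstream is
then cut into big-endian 6-bit groups and each group value $v \in [0, 63]$
is re-expressed as the printable character $\mathrm{chr}(33 + v)$, i.e. a
symbol in `!`..`` ` ``. Because quality distributions are heavily skewed,
the converted string $H_k$ is almost always shorter than the original line
$Q_k$, which shrinks the space the codebook has to model. The number of
zero bits padding the final group (0–5) is recorded per read so the packing
inverts exactly; within each 6-bit window the first bit is the most
significant (the natural big-endian reading; the alternative is equivalent
but must be fixed once). A single-symbol alphabet gets the fixed 1-bit code
`"0"` so encoding stays total.

**2. Codebook design.** A codebook is a set of $M$ code vectors, symbol
strings of common length $N$ over the converted alphabet $S$. Each read is
later stored as the index of one code vector plus an *edit script*
transforming that vector into the read. The codebook is designed by a
memetic algorithm in which **each individual is one code vector** and the
final population *is* the codebook — a multimodal-search formulation: the
population should spread over the distinct quality profiles present in the
file rather than collapse onto one. The corpus-level sizing rules are

$$M = \Big(\log_2 \lceil K/10 \rceil\Big)^2, \qquad
  N = \tfrac12\big(\min_k P_k + \max_k P_k\big),$$

rounded half-up with floors $M \ge 2$, $N \ge 1$ ($K$ = number of reads;
$P_k$ here are the *converted* lengths, since vectors live in the converted
space). An individual is a real vector $x \in (0, |S|)^N$ decoded
position-wise by $s_n = S[\lceil x_n \rceil]$ (1-based, clamped), and its
raw fitness is the corpus-wide surrogate encoded size

$$f_R(x) = \sum_{k} \Big(\lceil \log_2 M \rceil + 2\,|H_k|
  + 4\,\mathrm{lev}(C(x), H_k)\Big),$$

using the Levenshtein distance instead of the exact edit-script cost: an
edit costs 2 op bits always and 8 recorded-symbol bits for about half the
op types, hence the factor 4. The exact dynamic program is reserved for the
final encoding pass.

**3. Edit-script encoding.** For each read the encoder picks, among all
$M$ vectors, the one with the smallest *exact* bit cost (ties to the lowest
index) and stores $\lceil \log_2 M \rceil$ index bits plus the script. A
script is a sequence over `{U, I, D, S}` (unchanged / insertion / deletion
/ substitution); `I` and `S` additionally record the original symbol. With
2 bits per op and 8 per recorded symbol the cost is

$$L_C = \lceil \log_2 M \rceil + 2P^\ast + 8R,$$

where $P^\ast$ is the script length and $R$ the number of recorded
symbols. The aligner minimizes this true bit cost (op weights U = D = 2,
I = S = 10), *not* the unit edit distance — a unit-optimal alignment can
carry more recorded symbols and cost strictly more bits. For the sequence
`CCCGFF` against the vector `CCGHFFC` the optimum has $P^\ast = 8$,
$R = 1$: 24 bits against 48 raw. Traceback ties are broken
`U > D > I > S`, which makes scripts deterministic and biased away from
recorded symbols.

### The optimizer

The global stage is self-adaptive differential evolution with neighborhood
search: two mutation strategies (rand-base
$x_{r1} + F(x_{r2} - x_{r3})$ and best-guided
$x_i + F(x_{best} - x_i) + F(x_{r1} - x_{r2})$) chosen with a
success-adapted probability, the scale factor $F$ drawn from
$|N(0.5, 0.3)|$ or $|\mathrm{Cauchy}(0,1)|$ with an adapted mixing
probability, and binomial crossover whose rate mean is re-estimated from
improvement-weighted successful rates (windows: strategy and mixing
probabilities every 50 generations, crossover mean every 25, per-individual
rates resampled every 5).

Niching uses fitness sharing: with Manhattan distances $d_{ij}$, niching
radius $\varepsilon$ and shape $\alpha$,

$$f_S(x_i) = f_R(x_i) \cdot m_i, \qquad
  m_i = 1 + \sum_{j \ne i,\; d_{ij} \le \varepsilon}
  \Big(1 - \frac{d_{ij}}{\varepsilon}\Big)^{\alpha},$$

so crowded individuals look worse under minimization and isolated ones keep
$f_S = f_R$ exactly (the $+1$ is the self term; the kernel is zero beyond
$\varepsilon$ — the literal alternative of treating distant pairs as
distance 0 would *reward* crowding, the opposite of niching). A trial
replaces its parent only if its shared fitness, with the niche count taken
against the current population, is lower.

Each generation every individual is then refined by a
Davies–Swann–Campey-style derivative-free local search: line searches along
an orthonormal direction set (double the step while it improves, then one
quadratic-interpolation refinement), the set re-orthogonalized by
Gram–Schmidt around the sweep's net progress direction, and the step halved
after sweeps without progress. The refinement never worsens an individual
and every probe counts against the global evaluation budget.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fes` | `1e4` | budget of raw-fitness evaluations (all objective calls count, including local-search probes) |
| `M` | sizing rule above | codebook size = population size |
| `N` | sizing rule above | code-vector length = search dimension |
| bounds | $(0, |S|)$ | per-coordinate box, kept open by a $10^{-9}$ margin (a coordinate of exactly 0 has no symbol under the ceiling map) |
| `epsilon` | $0.1\,N$ | niching radius (Manhattan units) |
| `alpha` | 50 | sharing-kernel shape |
| `ls_evals` | $2N$ | per-individual, per-generation local-search budget |
| `ls_step` | 1 symbol | local-search initial step during codebook design: the decode map is a ceiling into the symbol set, so one symbol level is the landscape's natural quantum |
| `seed` | 1 | every stage is deterministic given it |

When `M < 4` the optimizer runs with 4 individuals (differential evolution
needs distinct donors) and the best `M` by raw fitness form the codebook.

## The container

A compressed file is self-contained: magic/version, the Huffman model as
(symbol, code length) pairs — canonical codes are reconstructible from
lengths alone — the codebook ($M$, $N$, symbol set, vectors), the per-read
original lengths, converted lengths and padding counts, optional id and DNA
blocks, then the payload: per read, $\lceil \log_2 M\rceil$ index bits and
the script (`U=00, I=01, D=10, S=11`, recorded symbols as 8-bit ASCII
immediately after their op). All multi-bit fields are big-endian. The
payload length must equal $\sum_k (\lceil \log_2 M \rceil + 2P^\ast_k +
8R_k)$ exactly; `report_metrics()` re-reads every script and stops if it
does not. Reported metrics follow

$$\mathrm{BPQ} = \frac{\sum_k L_C(k)}{\sum_k P_k}, \qquad
  \mathrm{CR} = 100 \cdot \mathrm{BPQ} / 8,$$

with $P_k$ the *original* read lengths (the interpretable unit: raw ASCII
is 8 BPQ). Both payload-only and header-inclusive variants are reported;
headline numbers quote payload-only, stated as such. A codebook may be
reused across files ("offline" mode): the container stores it explicitly,
so losslessness never depends on which corpus designed it — the symbol set
must merely cover the input.

## What the synthetic generator emulates

`generate_fastq()` draws a small number of latent per-position templates
(mean quality high at the 5' end, decaying exponentially toward the tail,
per-position jitter around that mean) over a 40-symbol Phred+33-style
alphabet, then derives each read from a uniformly chosen template by
perturbing each symbol independently with a given probability; a
perturbation is a small signed shift (Gaussian with 2-level spread, never
zero, clamped), because real quality noise wobbles locally rather than
jumping across the scale. This produces the one property the compressor
needs — inter-read redundancy organized around a few profiles — plus
realistic per-position decay and a bounded alphabet.

It does **not** simulate instrument-specific artifacts, cycle chemistry
effects, paired-end structure or the long-range correlations of real
machines. Passing tests on this generator therefore demonstrate
correctness (losslessness, formula accounting, optimizer behavior) and
*relative* compression signal, not the compression ratios attainable on
real archives.

## Numerical choices and degenerate inputs

* Rounding in the sizing rules is half-up (R's `round()` is half-even);
  both formulas otherwise yield non-integers almost always.
* Huffman ties (equal merge weights) are broken by smallest contained
  symbol code; canonical assignment orders by (length, symbol). The model
  is thus platform-independent and serializable as lengths only.
* The empty file compresses to a valid container with zero reads; a file
  whose reads are all empty is flagged `degenerate` in the report and BPQ
  is `NA` (a 0/0 guard) — both decompress exactly.
* Corruption (bad magic, truncated payload, scripts that overrun their
  sequence lengths, packed symbols outside ASCII 33..96) is detected and
  reported with the failing read index. A `--verify` option re-decodes in
  memory after writing.
* Containers are byte-identical across runs and platforms for a fixed
  seed.

## Known limitations

* **Huffman avalanche.** A single symbol substitution that changes a
  codeword length shifts the entire downstream bitstream, so two reads
  differing by one quality value can have converted strings $H_k$ that
  disagree almost everywhere after the mutation point. This caps how much
  the codebook stage can add on top of the Huffman stage for noisy
  corpora: edit-script savings concentrate in the prefix before the first
  length-changing perturbation.
* **Corpus-summed fitness.** Raw fitness sums a vector's surrogate cost
  over the *whole* corpus. With several balanced quality profiles the
  objective is nearly flat along directions that exchange one profile's
  symbol for another's, so vectors tend toward blends of profiles rather
  than pure ones; the niching radius $0.1N$ is small relative to the
  search box, so sharing separates only nearby individuals. The encoder's
  min-over-vectors step recovers part of the loss, but per-profile
  recovery should be expected to be approximate, not exact.
* **Multiplicative sharing near zero.** Because the niche count
  *multiplies* raw fitness, its penalty vanishes as raw fitness approaches
  0: on objectives whose optima are at 0 a crowded near-optimal trial can
  still undercut an isolated mediocre parent, and the population can
  collapse early. Niches hold once individuals are locked near their local
  optima, so on such objectives the local search should be given enough
  per-generation budget to reach the basins' floors before the global
  stage homogenizes the population. Encoded-size objectives are bounded
  well away from 0, where the kernel behaves as intended.
* The evaluation budget is spent on black-box probes of a
  plateau-with-spikes landscape (the Levenshtein term only rewards exact
  symbol hits), so convergence per coordinate is slow by construction;
  large corpora rely on the Huffman stage plus a partially converged
  codebook.

## Problem sizes used by the test suite

The suite favors many small deterministic cases: the end-to-end
losslessness property runs 1000 seeded files of 4–15 reads × 10–42
symbols with a 60-evaluation design budget (losslessness is independent of
codebook quality, so tiny budgets are sufficient and keep the property
cheap); the alignment oracle is exhaustive over all pairs up to length 3 on
a 3-symbol alphabet plus seeded random pairs up to length 6; the
compression-signal check uses 500 reads × 80 symbols with a 2000-evaluation
budget; multimodal recovery uses the five-peak sine toy (budget 5000) and a
balanced two-template corpus of 60 reads × 12 symbols (budget 6000). These
sizes are the package's own choices for a fast, deterministic suite.
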