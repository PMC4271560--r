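# cqs — codebook-based lossless compression of FASTQ quality scores

`cqs` compresses the quality-score lines of FASTQ files losslessly and
without any external reference. Quality data costs 8 bits per quality value
(BPQ) in raw ASCII and often takes as much space as the DNA calls while
compressing worse, because its alphabet is far larger. The package is aimed
at people building or studying NGS compression pipelines: it exposes every
stage (Huffman preprocessing, codebook design, edit-script encoding, the
container format) as ordinary R functions, plus a small CLI.

## Method

Three stages, all exactly invertible:

1. **Huffman + 6-bit repacking.** One canonical Huffman model over the
   pooled quality symbols; each read's bitstream is repacked into printable
   6-bit ASCII (`chr(33 + v)`, v ∈ 0..63), shrinking the strings the
   codebook has to model.
2. **Codebook design by a multimodal memetic algorithm.** A codebook of
   `M = (log2⌈K/10⌉)²` code vectors of length `N = (minP + maxP)/2`. Each
   optimizer individual *is* one code vector (decoded by
   `s_n = S[⌈x_n⌉]`); the final population is the codebook. Global search:
   self-adaptive differential evolution; niching: fitness sharing
   `f_S = f_R · (1 + Σ (1 − d/ε)^α)` over Manhattan distances; local
   refinement: Davies–Swann–Campey-style derivative-free line searches.
   Fitness is the corpus-wide surrogate encoded size
   `Σ_k (⌈log2 M⌉ + 2|H_k| + 4·lev(C, H_k))`.
3. **Edit-script encoding.** Each read is stored as the index of its
   cheapest code vector plus a `{U,I,D,S}` edit script found by dynamic
   programming over the true bit cost `⌈log2 M⌉ + 2P* + 8R` (2 bits per
   op, 8 per recorded symbol).

See `vignettes/quality-score-compression.Rmd` for the full model,
parameter table, numerical choices and known limitations.

## Worked example

```r
library(cqs)

f <- tempfile(fileext = ".fastq")
generate_fastq(300, quality_profile(read_length = 60, n_templates = 2),
               seed = 42, path = f)

out <- tempfile(fileext = ".cqs")
report <- compress_fastq(f, out, seed = 42, fes = 2000, verify = TRUE)
print(report)
#> compression_report: 300 reads, codebook M=24, N=38
#>   original: 144000 bits (8.00 BPQ)
#>   payload:  93700 bits (5.21 BPQ, CR 65.07%)
#>   total (with header): 301256 bits (16.74 BPQ, CR 209.21%)
```

300 synthetic reads of 60 symbols (144,000 bits raw) compress to a 93,700
bit quality payload: 5.21 bits per quality value, i.e. 65% of the raw
size, after a 2000-evaluation codebook design. `verify = TRUE` re-decodes
the container in memory and stops unless every quality line matches
byte-for-byte. The header-inclusive total is larger than the input here
only because the container also carries the ids and DNA lines verbatim
(they are not compressed by this tool) plus the model and codebook; the
payload line is the quality-compression result. `decompress_container(out,
output = "restored.fastq")` reproduces the original FASTQ exactly.

The encoding primitive on the string pair printed throughout the
documentation:

```r
s <- align("CCCGFF", "CCGHFFC")
print(s)
#> edit_script: P*=8, R=1
#>   I(C) U U U D U U D
raw_size("CCCGFF")   # 48 bits raw
exact_cost(s, 1)     # 24 bits encoded (no index bits when M = 1)
```

The script has 8 operations and one recorded symbol: 2·8 + 8·1 = 24 bits
against 48 bits raw.

## Command line

```sh
cqs synth -o sample.fastq --reads 1000 --length 80 --templates 2 --seed 1
cqs compress sample.fastq -o sample.cqs --seed 1 --fes 10000 --verify
cqs stats sample.cqs
cqs decompress sample.cqs -o restored.fastq
```

`compress` also writes a per-generation convergence trace
(`<out>.trace.tsv`: best raw and best shared fitness) for plotting.

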