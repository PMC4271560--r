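compress_tmp <- function(fastq, ...) {
  out <- tempfile(fileext = ".cqs")
  rep <- compress_fastq(fastq, out, ...)
  list(path = out, report = rep)
}

test_that("compress/decompress is lossless, including ids and sequences", {
  f <- tempfile(fileext = ".fastq")
  generate_fastq(120, quality_profile(read_length = c(35, 45),
                                      n_templates = 2), seed = 21, path = f)
  ds <- read_fastq(f)
  z <- compress_tmp(f, seed = 2, fes = 150, verify = TRUE)
  back <- decompress_container(z$path)
  expect_identical(back$qualities, ds$qualities)
  expect_identical(back$ids, ds$ids)
  expect_identical(back$sequences, ds$sequences)
  out <- tempfile(fileext = ".fastq")
  decompress_container(z$path, output = out)
  expect_identical(readLines(out), readLines(f))
})

test_that("containers are byte-identical across runs with one seed", {
  f <- tempfile(fileext = ".fastq")
  generate_fastq(40, quality_profile(read_length = 30), seed = 13, path = f)
  z1 <- compress_tmp(f, seed = 5, fes = 120)
  z2 <- compress_tmp(f, seed = 5, fes = 120)
  expect_identical(readBin(z1$path, "raw", file.size(z1$path)),
                   readBin(z2$path, "raw", file.size(z2$path)))
})

test_that("a corpus of identical reads compresses below 8 payload BPQ", {
  f <- write_tiny_fastq(rep(strrep("IIIHHGG#", 6), 50))
  z <- compress_tmp(f, seed = 3, fes = 200)
  expect_lt(z$report$BPQ, 8)
  expect_lt(z$report$payload_bits, z$report$original_bits)
})

test_that("degenerate inputs produce valid, flagged containers", {
  # all reads of length zero
  f0 <- write_tiny_fastq(rep("", 4))
  z0 <- compress_tmp(f0)
  expect_true(z0$report$degenerate)
  expect_true(is.na(z0$report$BPQ))
  back <- decompress_container(z0$path)
  expect_identical(back$qualities, rep("", 4))
  # no reads at all
  fe <- tempfile(fileext = ".fastq")
  file.create(fe)
  ze <- compress_tmp(fe)
  expect_true(ze$report$degenerate)
  expect_identical(decompress_container(ze$path)$K, 0L)
})

test_that("corruption is detected", {
  f <- tempfile(fileext = ".fastq")
  generate_fastq(25, quality_profile(read_length = 30), seed = 4, path = f)
  z <- compress_tmp(f, seed = 1, fes = 100)
  bytes <- readBin(z$path, "raw", file.size(z$path))
  # bad magic
  bad1 <- tempfile(); b1 <- bytes; b1[1] <- as.raw(0)
  writeBin(b1, bad1)
  expect_error(decompress_container(bad1), "magic")
  # flipped payload byte: either a structural error or changed output
  orig <- read_fastq(f)$qualities
  bad2 <- tempfile(); b2 <- bytes
  b2[length(b2) - 5L] <- xor(b2[length(b2) - 5L], as.raw(0xFF))
  writeBin(b2, bad2)
  res <- tryCatch(decompress_container(bad2)$qualities, error = function(e) e)
  expect_true(inherits(res, "error") || !identical(res, orig))
  # truncated payload
  bad3 <- tempfile()
  writeBin(bytes[seq_len(length(bytes) - 10L)], bad3)
  expect_error(decompress_container(bad3), "read \\d+|truncated")
})

test_that("an external codebook still gives lossless compression", {
  fA <- tempfile(fileext = ".fastq")
  fB <- tempfile(fileext = ".fastq")
  generate_fastq(60, quality_profile(read_length = 30), seed = 31, path = fA)
  generate_fastq(60, quality_profile(read_length = 30), seed = 32, path = fB)
  zA <- compress_tmp(fA, seed = 1, fes = 150)
  cb <- attr(zA$report, "codebook")
  # the packed alphabet of B may exceed A's: widen the codebook symbols by
  # compressing B against A's codebook only when symbols cover; otherwise
  # the call must fail loudly
  res <- tryCatch(compress_tmp(fB, codebook = cb), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "symbol set")
  } else {
    expect_identical(decompress_container(res$path)$qualities,
                     read_fastq(fB)$qualities)
  }
})

test_that("reported metrics agree with the payload audit", {
  f <- tempfile(fileext = ".fastq")
  generate_fastq(50, quality_profile(read_length = c(25, 35)), seed = 44,
                 path = f)
  z <- compress_tmp(f, seed = 9, fes = 150)
  audit <- report_metrics(z$path)
  expect_identical(audit$payload_bits, z$report$payload_bits)
  expect_identical(audit$original_bits, z$report$original_bits)
  for (r in list(audit, z$report)) {
    expect_equal(r$BPQ, 8 * r$CR_percent / 100)
    expect_equal(r$BPQ_total, 8 * r$CR_total_percent / 100)
  }
})
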