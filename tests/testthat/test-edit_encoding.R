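test_that("the CCCGFF vs CCGHFFC example costs 24 bits with one recorded symbol", {
  s <- align("CCCGFF", "CCGHFFC")
  expect_identical(s$P_star, 8L)
  expect_identical(s$R, 1L)
  expect_identical(2L * s$P_star + 8L * s$R, 24L)
  expect_identical(sum(s$ops == "U"), 5L)
  expect_identical(sum(s$ops == "I"), 1L)
  expect_identical(sum(s$ops == "D"), 2L)
  expect_identical(sum(s$ops == "S"), 0L)
  expect_identical(s$recorded[!is.na(s$recorded)], "C")
  expect_identical(apply_script("CCGHFFC", s), "CCCGFF")
  expect_identical(exact_cost(s, 1), 24L)       # M = 1: no index bits
  expect_identical(exact_cost(s, 64), 30L)      # 6 + 16 + 8
  expect_identical(raw_size("CCCGFF"), 48L)
})

test_that("degenerate alignments behave", {
  id <- align("ABBA", "ABBA")
  expect_identical(id$ops, rep("U", 4))
  expect_identical(id$R, 0L)
  expect_identical(align("", "")$P_star, 0L)
  expect_identical(align("XY", "")$ops, c("I", "I"))
  expect_identical(align("", "XY")$ops, c("D", "D"))
  empty <- align("", "")
  expect_identical(exact_cost(empty, 2), 1L)
  expect_error(exact_cost(empty, 0), "M must be")
  expect_identical(raw_size(""), 0L)
})

test_that("levenshtein matches hand cases and is a metric", {
  expect_identical(levenshtein("", ""), 0L)
  expect_identical(levenshtein("", "XYZ"), 3L)
  expect_identical(levenshtein("CCCGFF", "CCGHFFC"), 3L)
  set.seed(20)
  for (i in 1:40) {
    a <- random_string(c("a", "b", "c"), sample(0:6, 1))
    b <- random_string(c("a", "b", "c"), sample(0:6, 1))
    d <- random_string(c("a", "b", "c"), sample(0:6, 1))
    expect_identical(levenshtein(a, b), levenshtein(b, a))
    expect_identical(levenshtein(a, a), 0L)
    expect_lte(levenshtein(a, d), levenshtein(a, b) + levenshtein(b, d))
  }
})

test_that("approx_cost implements the surrogate formula", {
  expect_identical(approx_cost("CCCGFF", "CCGHFFC", 64), 30L) # 6 + 12 + 12
  expect_identical(approx_cost("AAAA", "AAAA", 2), 1L + 8L)
  expect_identical(approx_cost("", "", 1), 0L)
})

test_that("alignment cost equals the brute-force minimum on short pairs", {
  set.seed(8)
  for (i in 1:60) {
    q <- random_string(c("x", "y", "z"), sample(0:5, 1))
    c <- random_string(c("x", "y", "z"), sample(0:5, 1))
    s <- align(q, c)
    expect_identical(2L * s$P_star + 8L * s$R, brute_align_cost(q, c))
  }
})

test_that("bit-cost alignment never loses to the all-substitute script", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    q <- random_string(LETTERS[1:4], n)
    c <- random_string(LETTERS[1:4], n)
    s <- align(q, c)
    expect_lte(exact_cost(s, 4), cqs:::index_bits(4) + 10L * n)
  }
})

test_that("apply_script inverts align on random pairs and rejects bad input", {
  set.seed(14)
  for (i in 1:60) {
    q <- random_string(LETTERS[1:5], sample(0:15, 1))
    c <- random_string(LETTERS[1:5], sample(0:15, 1))
    expect_identical(apply_script(c, align(q, c)), q)
  }
  s <- align("AB", "AB")
  expect_error(apply_script("ABC", s), "inconsistent")
  expect_error(apply_script("A", s), "inconsistent")
})

test_that("script serialization uses the 2/8-bit layout and round-trips", {
  allU <- align("QQQQ", "QQQQ")
  expect_identical(serialize_script(allU), "00000000")
  worked <- align("CCCGFF", "CCGHFFC")
  expect_identical(nchar(serialize_script(worked)), 24L)
  set.seed(27)
  for (i in 1:40) {
    q <- random_string(c("D", "E", "F"), sample(0:10, 1))
    c <- random_string(c("D", "E", "F"), sample(0:10, 1))
    s <- align(q, c)
    bits <- serialize_script(s)
    expect_identical(nchar(bits), 2L * s$P_star + 8L * s$R)
    back <- deserialize_script(bits, c_len = nchar(c), q_len = nchar(q))
    expect_identical(back$n_bits, nchar(bits))
    expect_identical(back$script$ops, s$ops)
    expect_identical(back$script$recorded, s$recorded)
  }
  s <- align("AAB", "AB")
  bits <- serialize_script(s)
  expect_error(deserialize_script(substr(bits, 1, nchar(bits) - 4L),
                                  c_len = 2L, q_len = 3L),
               "truncated")
})
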