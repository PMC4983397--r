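empty_sidecar <- function() {
  data.frame(pos = integer(0), sym = character(0), stringsAsFactors = FALSE)
}

test_that("an empty dictionary costs 2 bits per residue symbol (idealized)", {
  parsed <- gen_random_dna(100, 61)$symbols
  cb <- cost_breakdown(offline_dictionary(), parsed, input_len = 100)
  expect_identical(cb$total, 200)
  expect_identical(cb$bps, 2)
  expect_identical(cb$vocabulary + cb$positions + cb$mismatch + cb$lengths +
                     cb$type + cb$parsed, cb$total)
  expect_identical(cb$header, 0)
})

test_that("a hand-built single-entry dictionary evaluates exactly", {
  # seed length 10, one occurrence at position 64, no mismatches, d = 1:
  # vocabulary 2*10, positions ceil(log2 64) + ceil(log2 1) = 6, lengths
  # ceil(log2 10) = 4, type 2
  e <- dictionary_entry(strrep("AC", 5))
  e <- add_occurrence(e, occurrence("exact", c = 64, n0 = 10))
  e <- finalize_entry(e, 1)
  attr(e, "working_length") <- 100L
  cb <- cost_breakdown(offline_dictionary(list(e)), parsed = "", input_len = 80)
  expect_identical(cb$vocabulary, 20)
  expect_identical(cb$positions, 6)
  expect_identical(cb$lengths, 4)
  expect_identical(cb$type, 2)
  expect_identical(cb$mismatch, 0)
  expect_identical(cb$parsed, 0)
  expect_identical(cb$total, 32)

  # d participates in the position sum: moving d from 1 to 64 adds 6 bits
  e2 <- dictionary_entry(strrep("AC", 5))
  e2 <- add_occurrence(e2, occurrence("exact", c = 64, n0 = 10))
  e2 <- finalize_entry(e2, 64)
  attr(e2, "working_length") <- 100L
  cb2 <- cost_breakdown(offline_dictionary(list(e2)), parsed = "",
                        input_len = 80)
  expect_identical(cb2$positions, 12)
  expect_identical(cb2$total - cb$total, 6)
})

test_that("a mismatch is charged its canonical triple bits", {
  # seed length 9: width_P = ceil(log2 11) = 4; substitution = 4+2+2 = 8,
  # deletion = 4+2 = 6
  e <- dictionary_entry("AATAACTTG")
  e <- add_occurrence(e, occurrence(
    "approximate", c = 2, n0 = 9,
    list(mismatch_record(7, "substitution", "T"),
         mismatch_record(4, "deletion"))))
  e <- finalize_entry(e, 1)
  attr(e, "working_length") <- 50L
  cb <- cost_breakdown(offline_dictionary(list(e)), parsed = "",
                       input_len = 30)
  expect_identical(cb$mismatch, 14)
})

test_that("actual mode reports the true serialized bits, never below idealized", {
  for (i in 1:12) {
    s <- battery_case(700L + i)
    cont <- compress_dna(dna_sequence(s))
    ideal <- cost_breakdown(cont, mode = "idealized")
    actual <- cost_breakdown(cont, mode = "actual")
    expect_identical(actual$total, as.numeric(length(cont$bytes) * 8L))
    expect_gte(actual$total, ideal$total)
    # the gap is exactly the header plus fixed-width field overhead, which
    # actual mode itemizes
    expect_gte(actual$header, 0)
  }
})

test_that("bps falls as planted-repeat density rises", {
  bps <- vapply(c(0, 0.25, 0.5), function(dens) {
    n <- as.integer(round(4000 * (1 - dens)))
    base <- gen_random_dna(n, rng_seed = 97)
    specs <- seedzip:::.density_specs(n, dens)
    seq <- if (length(specs)) plant_repeats(base, specs, 98)$seq else base
    cost_breakdown(compress_dna(seq), mode = "actual")$bps
  }, numeric(1))
  expect_true(all(diff(bps) < 0))
})
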