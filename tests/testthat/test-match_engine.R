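test_that("variant transforms follow the base-pairing rules", {
  expect_identical(variant_transform("ACGT", "reverse"), "TGCA")
  expect_identical(variant_transform("ACGT", "complement"), "TGCA")
  expect_identical(variant_transform("ACGT", "reverse_complement"), "ACGT")
  expect_identical(variant_transform("AAC", "exact"), "AAC")
  expect_identical(variant_transform("AAC", "approximate"), "AAC")
  expect_identical(variant_transform("AAC", "tandem"), "AAC")
  # involutions
  for (t in c("reverse", "complement", "reverse_complement")) {
    x <- gen_random_dna(31, 5)$symbols
    expect_identical(variant_transform(variant_transform(x, t), t), x)
  }
})

test_that("the mismatch threshold is floor(log2(n0))", {
  expect_identical(mismatch_threshold(1), 0L)
  expect_identical(mismatch_threshold(8), 3L)
  expect_identical(mismatch_threshold(9), 3L)
  expect_error(mismatch_threshold(0), ">= 1")
  # doubly logarithmic mode
  expect_identical(mismatch_threshold(8, "log2_log2_n0"), 1L)
  expect_identical(mismatch_threshold(2, "log2_log2_n0"), 0L)
  expect_identical(mismatch_threshold(65536, "log2_log2_n0"), 4L)
})

test_that("gain_check demands exact look-ahead matches and fails at borders", {
  #        123456789012
  w <- "AACTGAAATTTT"
  #  seed ...ACT|G  repeat ...? compare mismatching pair at 5 (G) vs 9 (T)
  # beyond them: 6..8 = AAA vs 10..12 = TTT -> no
  expect_false(gain_check(w, 5, 9, "right", 3))
  w2 <- "AACTGAAATAAA"
  expect_true(gain_check(w2, 5, 9, "right", 3)) # AAA == AAA
  # boundary: fewer than `lookahead` symbols remain
  expect_false(gain_check(w2, 5, 10, "right", 3))
  expect_true(gain_check(w2, 5, 10, "right", 2))
})

test_that("find_next_match honors scan order, transforms and short inputs", {
  # no 4-mer repeats under any transform
  expect_null(find_next_match("ACGTGCTA", k = 4))
  # k too large for the sequence: a no-search signal, not an error
  expect_null(find_next_match("ACGTACGT", k = 5))
  # 16-symbol homopolymer: adjacent exact match -> tandem at i = 9
  hit <- find_next_match(strrep("A", 16), k = 8)
  expect_identical(hit$seed$a, 1L)
  expect_identical(hit$i, 9L)
  expect_identical(hit$rtype, "tandem")
  # reverse-complement planted: engine must find it where the oracle does
  s <- paste0("ACGTTGCAACGG", "TT", variant_transform("ACGTTGCAACGG",
                                                      "reverse_complement"))
  expect_identical(find_next_match(s, k = 6)[c("i", "rtype")],
                   oracle_find_next_match(s, k = 6)[c("i", "rtype")])
})

test_that("extension recovers planted exact repeats in full", {
  # two copies of a 30-mer in an otherwise repeat-free backbone
  base <- gen_random_dna(200, rng_seed = 501)
  res <- plant_repeats(base, plant_spec("exact", 41, 30, target_offsets = 150))
  s <- res$seq$symbols
  hit <- find_next_match(s, k = 8, seed_start = 41)
  ext <- extend_match(s, hit$seed$a, 8, hit$i, hit$rtype)
  expect_gte(ext$n0, 30L)
  expect_identical(unname(diff(ext$seed_span)) + 1L, ext$n0)
  expect_length(ext$mismatches, 0L)
})

test_that("extension records an interior substitution and keeps extending", {
  # copy with one substitution in the middle, >= 3 matching symbols after it
  base <- gen_random_dna(300, rng_seed = 502)
  res <- plant_repeats(base,
                       plant_spec("exact", 51, 24, target_offsets = 200,
                                  mutations = list(list(offset = 12,
                                                        op = "substitution",
                                                        base = "A"))))
  s <- res$seq$symbols
  hit <- find_next_match(s, k = 8, seed_start = 51)
  ext <- extend_match(s, hit$seed$a, 8, hit$i, hit$rtype)
  if (length(ext$mismatches) > 0) {
    expect_identical(ext$rtype, "approximate")
    expect_true(all(vapply(ext$mismatches, function(m) m$op, character(1))
                    == "substitution"))
  }
  expect_gte(ext$n0, 20L)
})

test_that("a 16-A homopolymer cannot extend past the overlap rule", {
  s <- strrep("A", 16)
  ext <- extend_match(s, 1, 8, 9, "exact")
  expect_identical(unname(ext$seed_span), c(1L, 8L))
  expect_identical(unname(ext$repeat_span), c(9L, 16L))
  expect_identical(ext$n0, 8L)
  expect_length(ext$mismatches, 0L)
})

test_that("extension never overlaps, never exceeds the budget, n0 >= k", {
  for (cs in 1:60) {
    s <- battery_case(cs)
    for (k in c(4L, 8L)) {
      hit <- find_next_match(s, k = k)
      if (is.null(hit)) next
      rt <- if (hit$rtype == "tandem") "exact" else hit$rtype
      ext <- extend_match(s, hit$seed$a, k, hit$i, rt)
      expect_lt(ext$seed_span[["q"]], ext$repeat_span[["c"]])
      expect_gte(ext$n0, k)
      expect_lte(length(ext$mismatches), mismatch_threshold(ext$n0))
      # every mismatch position addresses a real seed coordinate
      L <- ext$seed_span[["q"]] - ext$seed_span[["d"]] + 1L
      for (m in ext$mismatches) {
        expect_lte(m$P, L + (m$op == "insertion"))
        expect_gte(m$P, 1L)
      }
    }
  }
})

test_that("materialize_occurrence applies edits then the transform", {
  mm <- list(mismatch_record(2, "substitution", "G"),
             mismatch_record(4, "deletion"),
             mismatch_record(6, "insertion", "T"))
  # seed ACGTA + {C2->G, del T4, ins T before position 6 (i.e. appended)}
  expect_identical(materialize_occurrence("ACGTA", mm, "exact"), "AGGAT")
  expect_identical(materialize_occurrence("ACGTA", mm, "reverse"), "TAGGA")
  expect_identical(materialize_occurrence("ACGTA", mm, "complement"), "TCCTA")
  expect_identical(materialize_occurrence("ACGTA", mm, "reverse_complement"),
                   "ATCCT")
})
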