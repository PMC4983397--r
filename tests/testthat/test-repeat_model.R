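# The two printed dictionary rows used here are the standard worked fixture:
# entry AATAACTTG with an approximate copy at 5 (length 9) and a reverse copy
# at 20 carrying mismatches "1 10 01" and "8 10 00"; entry AACTTG with a
# reverse copy at 36 and an approximate copy at 73 with mismatch "4 01 10".

test_that("occurrences accumulate on an entry in order", {
  e <- dictionary_entry("AATAACTTG")
  e <- add_occurrence(e, occurrence("approximate", c = 5, n0 = 9))
  expect_length(e$occurrences, 1L)

  rev_mm <- list(mismatch_record(1, "substitution", "C"),
                 mismatch_record(8, "substitution", "A"))
  e <- add_occurrence(e, occurrence("reverse", c = 20, n0 = 9, rev_mm))
  expect_length(e$occurrences, 2L)
  expect_identical(e$occurrences[[2]]$rtype, "reverse")
  expect_identical(format_triple(e$occurrences[[2]]$mismatches[[1]]),
                   "1 10 01")
  expect_identical(format_triple(e$occurrences[[2]]$mismatches[[2]]),
                   "8 10 00")
})

test_that("the mismatch budget and seed coordinates are enforced", {
  # floor(log2(9)) = 3, so 5 mismatches on a length-9 occurrence violate it
  mm5 <- lapply(1:5, function(p) mismatch_record(p, "substitution", "A"))
  expect_error(occurrence("approximate", c = 1, n0 = 9, mm5), "at most 3")

  # a mismatch position beyond the seed (plus one for insertion) is rejected
  e <- dictionary_entry("ACGTACGT")
  bad <- occurrence("approximate", c = 1, n0 = 9,
                    list(mismatch_record(10, "substitution", "A")))
  expect_error(add_occurrence(e, bad), "outside the extended seed")
  ins_end <- occurrence("approximate", c = 1, n0 = 9,
                        list(mismatch_record(9, "insertion", "A")))
  expect_silent(add_occurrence(e, ins_end))
})

test_that("finalization fixes d exactly once", {
  e <- dictionary_entry("AATAACTTG")
  e <- add_occurrence(e, occurrence("approximate", c = 5, n0 = 9))
  e <- finalize_entry(e, d = 17)
  expect_identical(e$d, 17L)
  expect_error(finalize_entry(e, d = 3), "already finalized")
  expect_error(add_occurrence(e, occurrence("exact", c = 1, n0 = 9)),
               "finalized")
})

test_that("deletion records carry no symbol; others require one", {
  expect_error(mismatch_record(4, "deletion", "G"), "no base symbol")
  expect_error(mismatch_record(4, "substitution"), "requires a base")
  m <- mismatch_record(4, "deletion")
  expect_true(is.na(m$sym))
  expect_identical(format_triple(m), "4 01")
})

test_that("the dictionary dump mirrors the printed table layout", {
  e1 <- dictionary_entry("AATAACTTG")
  e1 <- add_occurrence(e1, occurrence("approximate", c = 5, n0 = 9))
  e1 <- add_occurrence(e1, occurrence(
    "reverse", c = 20, n0 = 9,
    list(mismatch_record(1, "substitution", "C"),
         mismatch_record(8, "substitution", "A"))))
  e1 <- finalize_entry(e1, 17)
  dict <- offline_dictionary(list(e1))
  tab <- dump_dictionary(dict)
  expect_identical(names(tab), c("extended_seed", "type", "position",
                                 "length", "mismatch_details"))
  expect_identical(tab$type, c("approximate", "reverse", "seed"))
  expect_identical(tab$position, c(5L, 20L, 17L))
  expect_identical(tab$mismatch_details[2], "(1 10 01, 8 10 00)")
  # the seed row comes last, recording d
  expect_identical(tab$position[nrow(tab)], 17L)
})
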