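# The two-entry dictionary used below reproduces the printed worked fixture
# (seeds AATAACTTG and AACTTG with approximate/reverse occurrences and their
# mismatch triples); d and working-length values are chosen freely since the
# table does not print them.
table_fixture_dict <- function() {
  e1 <- dictionary_entry("AATAACTTG")
  e1 <- add_occurrence(e1, occurrence("approximate", c = 5, n0 = 9))
  e1 <- add_occurrence(e1, occurrence(
    "reverse", c = 20, n0 = 9,
    list(mismatch_record(1, "substitution", "C"),
         mismatch_record(8, "substitution", "A"))))
  e1 <- finalize_entry(e1, 17)
  attr(e1, "working_length") <- 90L
  e2 <- dictionary_entry("AACTTG")
  e2 <- add_occurrence(e2, occurrence("reverse", c = 36, n0 = 6))
  e2 <- add_occurrence(e2, occurrence("approximate", c = 73, n0 = 7,
                                      list(mismatch_record(4, "deletion"))))
  e2 <- finalize_entry(e2, 11)
  attr(e2, "working_length") <- 81L
  offline_dictionary(list(e1, e2))
}

expect_dict_equal <- function(d1, d2) {
  expect_identical(length(d1), length(d2))
  for (ei in seq_along(d1$entries)) {
    a <- d1$entries[[ei]]; b <- d2$entries[[ei]]
    expect_identical(a$extended_seed, b$extended_seed)
    expect_identical(a$d, b$d)
    expect_identical(as.integer(attr(a, "working_length")),
                     as.integer(attr(b, "working_length")))
    expect_identical(length(a$occurrences), length(b$occurrences))
    for (oi in seq_along(a$occurrences)) {
      oa <- a$occurrences[[oi]]; ob <- b$occurrences[[oi]]
      expect_identical(oa$rtype, ob$rtype)
      expect_identical(oa$c, ob$c)
      expect_identical(oa$n0, ob$n0)
      expect_identical(mm_table(oa$mismatches), mm_table(ob$mismatches))
    }
  }
}

test_that("an empty dictionary with a short residue round-trips", {
  params <- extend_params()
  meta <- list(name = "x", l_san = 4L,
               sidecar = data.frame(pos = integer(0), sym = character(0),
                                    stringsAsFactors = FALSE))
  bytes <- serialize_container(offline_dictionary(), "ACGT", params, meta)
  back <- parse_container(bytes)
  expect_identical(length(back$dict), 0L)
  expect_identical(back$parsed, "ACGT")
  expect_identical(back$meta$name, "x")
  expect_identical(back$meta$l_san, 4)
  expect_identical(back$params$k, params$k)
})

test_that("the printed two-entry dictionary round-trips field-for-field", {
  dict <- table_fixture_dict()
  params <- extend_params()
  meta <- list(name = "tab", l_san = 200L,
               sidecar = data.frame(pos = c(3L, 9L), sym = c("N", "R"),
                                    stringsAsFactors = FALSE))
  bytes <- serialize_container(dict, "ACGTACGTAA", params, meta)
  back <- parse_container(bytes)
  expect_dict_equal(back$dict, dict)
  expect_identical(back$parsed, "ACGTACGTAA")
  expect_identical(back$meta$sidecar$pos, c(3, 9))
  expect_identical(back$meta$sidecar$sym, c("N", "R"))
})

test_that("the serialized bit total equals the audited field widths", {
  dict <- table_fixture_dict()
  params <- extend_params()
  meta <- list(name = "audit", l_san = 150L,
               sidecar = data.frame(pos = integer(0), sym = character(0),
                                    stringsAsFactors = FALSE))
  bytes <- serialize_container(dict, gen_random_dna(40, 3)$symbols, params,
                               meta)
  audit <- attr(bytes, "audit")
  expect_identical(unname(sum(audit)), as.numeric(attr(bytes, "nbits")))
  expect_identical(length(bytes) * 8L, as.integer(attr(bytes, "nbits")))
})

test_that("serialize/parse is a bijection over compression runs", {
  for (i in 1:40) {
    s <- battery_case(400L + i)
    cont <- compress_dna(dna_sequence(s, name = paste0("b", i)))
    back <- parse_container(cont$bytes)
    expect_dict_equal(back$dict, cont$dict)
    expect_identical(back$parsed, cont$parsed)
    expect_identical(back$meta$l_san, as.numeric(nchar(s)))
    # re-serializing the parsed structures reproduces the bytes
    bytes2 <- serialize_container(back$dict, back$parsed, back$params,
                                  back$meta)
    expect_identical(as.raw(bytes2), as.raw(cont$bytes))
  }
})

test_that("bad inputs produce typed container errors", {
  expect_error(parse_container(as.raw(c(1, 2, 3, 4, 5, 6, 7, 8))),
               "not a seedzip container")
  expect_error(parse_container(as.raw(rep(0, 100))), "not a seedzip container")

  cont <- compress_dna(gen_random_dna(300, 8))
  # version bump -> unsupported
  tampered <- cont$bytes
  tampered[5] <- as.raw(9)
  expect_error(parse_container(tampered), "unsupported container version")
  # truncation mid-stream -> malformed/truncated
  expect_error(parse_container(cont$bytes[1:20]), "truncated")

  expect_error(serialize_container(
    offline_dictionary(list(dictionary_entry("ACGTACGT"))), "A",
    extend_params(), list(name = "u", l_san = 1L,
                          sidecar = data.frame(pos = integer(0),
                                               sym = character(0)))),
    "unfinalized")
})

test_that("container files round-trip through disk", {
  f <- tempfile(fileext = ".szp")
  cont <- compress_dna(gen_random_dna(500, 12, name = "disk"))
  write_container(cont, f)
  back <- read_container(f)
  expect_identical(as.raw(back$bytes), as.raw(cont$bytes))
  expect_identical(decompress_dna(back)$symbols,
                   decompress_dna(cont)$symbols)
})
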