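test_that("gen_random_dna is seeded, uniform, and leaves the RNG alone", {
  expect_identical(gen_random_dna(0, 1)$symbols, "")
  expect_identical(gen_random_dna(500, 42)$symbols,
                   gen_random_dna(500, 42)$symbols)
  expect_false(identical(gen_random_dna(500, 42)$symbols,
                         gen_random_dna(500, 43)$symbols))
  # base frequencies of a 1e5 draw stay within [0.24, 0.26]
  s <- gen_random_dna(100000, 7)$symbols
  freq <- table(strsplit(s, "")[[1]]) / 100000
  expect_true(all(freq >= 0.24 & freq <= 0.26))
  # caller RNG state is not consumed
  set.seed(99)
  before <- .Random.seed
  invisible(gen_random_dna(100, 5))
  expect_identical(.Random.seed, before)
})

test_that("plant bookkeeping matches the emitted sequence exactly", {
  base <- gen_random_dna(1000, 11)
  res <- plant_repeats(base, plant_spec("exact", 101, 50,
                                        target_offsets = 600))
  expect_identical(seq_length(res$seq), 1050L)
  tr <- res$truth
  expect_identical(tr$rtype, c("source", "exact"))
  # every annotated span is literally the transformed source fragment
  src <- tr[tr$rtype == "source", ]
  cp <- tr[tr$rtype == "exact", ]
  expect_identical(substr(res$seq$symbols, cp$start, cp$end),
                   substr(res$seq$symbols, src$start, src$end))
})

test_that("ground truth describes every transformed, mutated copy", {
  base <- gen_random_dna(2000, 13)
  specs <- list(
    plant_spec("reverse", 101, 40, target_offsets = 900),
    plant_spec("reverse_complement", 301, 40, target_offsets = c(1200, 1500),
               mutations = 1L),
    plant_spec("complement", 501, 40, target_offsets = 1800)
  )
  res <- plant_repeats(base, specs, rng_seed = 5)
  s <- res$seq$symbols
  tr <- res$truth
  for (si in 1:3) {
    rows <- tr[tr$spec == si, ]
    src <- rows[rows$rtype == "source", ]
    for (r in which(rows$rtype != "source")) {
      frag <- substr(s, rows$start[r], rows$end[r])
      back <- variant_transform(frag, rows$rtype[r]) # involution: seed frame
      srcs <- substr(s, src$start, src$end)
      mism <- sum(strsplit(back, "")[[1]] != strsplit(srcs, "")[[1]])
      expect_identical(mism, rows$mutations[r])
    }
  }
})

test_that("overlapping plants are rejected", {
  base <- gen_random_dna(500, 17)
  expect_error(
    plant_repeats(base, list(
      plant_spec("exact", 101, 50, target_offsets = 300),
      plant_spec("exact", 201, 50, target_offsets = 300))),
    "duplicate")
  expect_error(
    plant_repeats(base, plant_spec("exact", 101, 50, target_offsets = 120)),
    "inside a source")
})

test_that("compression recovers planted repeats of every class", {
  # copies >= 24 bp with <= 2 substitutions are recoverable: >= 90% of the
  # planted bases must land inside dictionary occurrences
  base <- gen_random_dna(3000, 23)
  specs <- list(
    plant_spec("exact", 101, 60, target_offsets = c(1600, 1900)),
    plant_spec("approximate", 301, 60, target_offsets = c(2200, 2500),
               mutations = 2L),
    plant_spec("reverse", 501, 60, target_offsets = 2800),
    plant_spec("complement", 701, 60, target_offsets = 2950),
    plant_spec("reverse_complement", 901, 60, target_offsets = 3001,
               mutations = 1L),
    plant_spec("tandem", 1101, 60, target_offsets = 1161)
  )
  res <- plant_repeats(base, specs, rng_seed = 29)
  cont <- compress_dna(res$seq)
  om <- occurrence_map(cont)
  copies <- res$truth[res$truth$rtype != "source", ]
  planted <- sum(copies$length)
  covered <- 0L
  for (r in seq_len(nrow(copies))) {
    span <- copies$start[r]:copies$end[r]
    inside <- rep(FALSE, length(span))
    for (b in seq_len(nrow(om))) {
      inside <- inside | (span >= om$start[b] & span <= om$end[b])
    }
    covered <- covered + sum(inside)
  }
  expect_gte(covered / planted, 0.9)
  # the adjacent copy is recognized as a tandem repeat
  types <- unlist(lapply(cont$dict$entries, function(e)
    vapply(e$occurrences, function(o) o$rtype, character(1))))
  expect_true("tandem" %in% types)
  # a reverse-complement (or equivalent) occurrence covers >= 90% of its span
  rc <- copies[copies$rtype == "reverse_complement", ][1, ]
  rc_cov <- 0L
  for (b in seq_len(nrow(om))) {
    lo <- max(rc$start, om$start[b]); hi <- min(rc$end, om$end[b])
    if (hi >= lo) rc_cov <- rc_cov + (hi - lo + 1L)
  }
  expect_gte(rc_cov / rc$length, 0.9)
})

test_that("make_fixture writes a FASTA and a matching truth table", {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  res <- make_fixture(fa, tsv, n = 800,
                      specs = list(plant_spec("exact", 51, 40,
                                              target_offsets = 500)),
                      rng_seed = 3)
  seq <- read_fasta(fa)
  expect_identical(seq$symbols, res$seq$symbols)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), nrow(res$truth))
  cp <- tab[tab$rtype == "exact", ]
  expect_identical(substr(seq$symbols, cp$start, cp$end),
                   substr(seq$symbols, tab$start[tab$rtype == "source"],
                          tab$end[tab$rtype == "source"]))
})
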