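Package: seedzip
Title: Seed-Based Lossless Compression of DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression of nucleotide sequences by seed-and-extend
    repeat discovery. Exact, approximate, reverse, complemented,
    reverse-complemented and tandem repeats are located by scanning fixed-length
    seeds, extending matches in both directions under a dynamic mismatch budget,
    and excising every profitable occurrence into an offline dictionary whose
    mismatches are stored as bit-packed (position, edit-operation, base)
    triples. The residual sequence and the seed vocabulary are entropy-coded
    with an adaptive order-0 arithmetic coder, and the dictionary plus residue
    are serialized into a self-contained bit-exact container. Includes a cost
    model itemizing the compressed size in bits per component, a deterministic
    synthetic-sequence generator with planted repeats for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
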