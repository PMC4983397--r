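# Cost model: the compressed size itemized in bits, either in the idealized
# accounting (every integer charged its ceil(log2) information content, the
# repeat type charged 2 bits per occurrence, the vocabulary and residue
# charged 2 bits per base) or as the true bits of the serialized container.
# The idealized figure drops all self-delimiting overhead, so it is a lower
# bound on the container size; the difference is the header plus fixed-width
# field overhead.

#' Itemized compression-cost breakdown
#'
#' In `"idealized"` mode the components are: vocabulary `2 * sum(l(i))` over
#' seed lengths; positions `sum(ceil(log2(P)))` over every occurrence
#' position `c` plus each entry's seed position `d`; mismatches the canonical
#' triple bits; lengths `ceil(log2(l(i)))` per occurrence; type 2 bits per
#' occurrence (a reporting convention: two bits cannot index all six repeat
#' classes, and the container actually spends 3); parsed `2 * l(S_final)`.
#' `ceil(log2(1))` is 0. In `"actual"` mode the components are the true bit
#' counts of the serialized container, with all self-delimiting overhead
#' (magic, parameters, name, sidecar, entry counts, padding) reported under
#' `header`, which is 0 in idealized mode.
#'
#' @param dict An [offline_dictionary()], or a `compressed_container` (in
#'   which case `parsed` and `input_len` are taken from it).
#' @param parsed Residue sequence (character scalar).
#' @param input_len Original (sanitized) input length in symbols.
#' @param mode `"idealized"` or `"actual"`.
#' @param params,meta Required for `"actual"` mode when `dict` is not a
#'   `compressed_container` (the container must be re-serialized).
#' @return An object of class `cost_breakdown`: a list of bit counts
#'   (`vocabulary`, `positions`, `mismatch`, `lengths`, `type`, `parsed`,
#'   `header`), their `total`, and `bps` = total / input length.
#' @examples
#' cont <- compress_dna(dna_sequence(strrep("ACGT", 25)))
#' cost_breakdown(cont)
#' @export
cost_breakdown <- function(dict, parsed = NULL, input_len = NULL,
                           mode = c("idealized", "actual"),
                           params = NULL, meta = NULL) {
  mode <- match.arg(mode)
  if (inherits(dict, "compressed_container")) {
    cont <- dict
    dict <- cont$dict
    parsed <- cont$parsed
    input_len <- cont$meta$l_san
    params <- cont$params
    meta <- cont$meta
  }
  stopifnot(inherits(dict, "offline_dictionary"), is.character(parsed),
            is.numeric(input_len))
  if (input_len < nchar(parsed)) {
    stop("input_len must be at least the parsed length", call. = FALSE)
  }

  if (mode == "idealized") {
    vocab <- 0; positions <- 0; mismatch <- 0; lengths <- 0; typebits <- 0
    for (e in dict$entries) {
      l_i <- nchar(e$extended_seed)
      width_P <- as.integer(.celog2(l_i + 2L))
      vocab <- vocab + 2 * l_i
      if (!is.na(e$d)) positions <- positions + .celog2(e$d)
      for (o in e$occurrences) {
        positions <- positions + .celog2(o$c)
        lengths <- lengths + .celog2(l_i)
        typebits <- typebits + 2
        for (m in o$mismatches) {
          mismatch <- mismatch + triple_bits(m, width_P)
        }
      }
    }
    comp <- c(vocabulary = vocab, positions = positions, mismatch = mismatch,
              lengths = lengths, type = typebits,
              parsed = 2 * nchar(parsed), header = 0)
  } else {
    if (is.null(params) || is.null(meta)) {
      stop("actual mode requires params and meta (or a compressed_container)",
           call. = FALSE)
    }
    bytes <- serialize_container(dict, parsed, params, meta)
    audit <- attr(bytes, "audit")
    comp <- c(vocabulary = audit[["vocabulary"]],
              positions = audit[["positions"]],
              mismatch = audit[["mismatch"]],
              lengths = audit[["lengths"]],
              type = audit[["type"]],
              parsed = audit[["parsed"]],
              header = audit[["header"]])
  }

  total <- sum(comp)
  structure(list(vocabulary = comp[["vocabulary"]],
                 positions = comp[["positions"]],
                 mismatch = comp[["mismatch"]],
                 lengths = comp[["lengths"]],
                 type = comp[["type"]],
                 parsed = comp[["parsed"]],
                 header = comp[["header"]],
                 total = total,
                 bps = if (input_len > 0) total / input_len else NA_real_,
                 mode = mode, input_len = input_len),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> mode = %s, input = %d bp\n", x$mode,
              x$input_len))
  for (f in c("vocabulary", "positions", "mismatch", "lengths", "type",
              "parsed", "header")) {
    cat(sprintf("  %-11s %10.0f bits\n", f, x[[f]]))
  }
  cat(sprintf("  %-11s %10.0f bits\n", "total", x$total))
  cat(sprintf("  bits/base   %10.4f\n", x$bps))
  invisible(x)
}

#' @export
as.data.frame.cost_breakdown <- function(x, ...) {
  data.frame(component = c("vocabulary", "positions", "mismatch", "lengths",
                           "type", "parsed", "header", "total"),
             bits = c(x$vocabulary, x$positions, x$mismatch, x$lengths,
                      x$type, x$parsed, x$header, x$total),
             stringsAsFactors = FALSE)
}
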