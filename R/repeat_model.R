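# Domain types for the offline dictionary: repeat types, mismatch records,
# occurrences, dictionary entries. The dictionary is an ordered list of
# entries, one per extended seed, in excision order; decompression replays
# that order in reverse.

#' Repeat type codes
#'
#' The six repeat classes and their fixed 3-bit container codes. The
#' idealized cost model charges 2 bits per occurrence for the type, which
#' cannot index six classes; the container spends 3 bits so the bitstream
#' stays decodable (see [cost_breakdown()]).
#'
#' @format Named integer vector mapping type name to container code.
#' @export
REPEAT_TYPES <- c(exact = 0L, approximate = 1L, reverse = 2L,
                  complement = 3L, reverse_complement = 4L, tandem = 5L)

.check_rtype <- function(rtype) {
  if (!is.character(rtype) || length(rtype) != 1L ||
      !rtype %in% names(REPEAT_TYPES)) {
    stop("unknown repeat type: ", paste(rtype, collapse = ", "), call. = FALSE)
  }
  rtype
}

#' Create a mismatch record
#'
#' A mismatch is a (P, E, S) triple: `P` the 1-based position within the
#' extended seed, `op` the edit operation, and `sym` the base inserted or
#' substituted. `sym` is absent (NA) if and only if the operation is a
#' deletion. For an insertion, `P` may be `seed length + 1` (insertion past
#' the right end).
#'
#' @param P 1-based position within the owning extended seed.
#' @param op `"insertion"`, `"deletion"` or `"substitution"`.
#' @param sym Base symbol `"A"/"C"/"G"/"T"`, or `NA` for deletions.
#' @return An object of class `mismatch_record`.
#' @examples
#' mismatch_record(7, "substitution", "T")
#' @export
mismatch_record <- function(P, op = c("substitution", "insertion", "deletion"),
                            sym = NA_character_) {
  op <- match.arg(op)
  stopifnot(is.numeric(P), length(P) == 1L, P >= 1, P == floor(P))
  if (op == "deletion") {
    if (!is.na(sym)) {
      stop("a deletion record carries no base symbol", call. = FALSE)
    }
  } else {
    if (is.na(sym) || !sym %in% .BASES) {
      stop("op '", op, "' requires a base symbol in {A,C,G,T}", call. = FALSE)
    }
  }
  structure(list(P = as.integer(P), op = op, sym = sym),
            class = "mismatch_record")
}

#' @export
print.mismatch_record <- function(x, ...) {
  cat(sprintf("<mismatch> P=%d %s%s\n", x$P, x$op,
              if (is.na(x$sym)) "" else paste0(" ", x$sym)))
  invisible(x)
}

#' Create an occurrence of a repeat
#'
#' One excised copy of an extended seed: its type, its 1-based start `c` in
#' the working sequence *at the moment of its excision*, its length `n0`,
#' and the ordered mismatch records that transform the seed into the copy.
#'
#' @param rtype Repeat type (one of `names(REPEAT_TYPES)`).
#' @param c 1-based excision-time start position.
#' @param n0 Length of the excised copy (symbols).
#' @param mismatches List of [mismatch_record()]s (possibly empty).
#' @return An object of class `occurrence`.
#' @export
occurrence <- function(rtype, c, n0, mismatches = list()) {
  .check_rtype(rtype)
  stopifnot(is.numeric(c), length(c) == 1L, c >= 1, c == floor(c))
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 >= 1, n0 == floor(n0))
  stopifnot(is.list(mismatches))
  for (m in mismatches) stopifnot(inherits(m, "mismatch_record"))
  if (length(mismatches) > .flog2(n0)) {
    stop("occurrence of length ", n0, " admits at most ", .flog2(n0),
         " mismatches, got ", length(mismatches), call. = FALSE)
  }
  structure(list(rtype = rtype, c = as.integer(c), n0 = as.integer(n0),
                 mismatches = mismatches),
            class = "occurrence")
}

#' Create a dictionary entry for an extended seed
#'
#' @param extended_seed Character scalar over \{A,C,G,T\} (length >= 2).
#' @return An object of class `dictionary_entry` with an empty occurrence
#'   list and no seed position yet; see [add_occurrence()] and
#'   [finalize_entry()].
#' @export
dictionary_entry <- function(extended_seed) {
  extended_seed <- .as_symbols(extended_seed)
  stopifnot(nchar(extended_seed) >= 2L)
  .dna_to_int(extended_seed) # validates the alphabet
  structure(list(extended_seed = extended_seed, occurrences = list(),
                 d = NA_integer_),
            class = "dictionary_entry")
}

#' Append an occurrence to a dictionary entry
#'
#' Occurrence order is the excision order and is preserved; decompression
#' replays it in reverse. Every mismatch position must address a real
#' coordinate of the extended seed (plus one past the end for insertions)
#' and the mismatch count must respect the `floor(log2(n0))` threshold.
#'
#' @param entry A [dictionary_entry()].
#' @param occ An [occurrence()].
#' @return The entry with the occurrence appended.
#' @examples
#' e <- dictionary_entry("AATAACTTG")
#' e <- add_occurrence(e, occurrence("approximate", c = 5, n0 = 9))
#' @export
add_occurrence <- function(entry, occ) {
  stopifnot(inherits(entry, "dictionary_entry"), inherits(occ, "occurrence"))
  if (!is.na(entry$d)) {
    stop("entry is finalized; no further occurrences may be added",
         call. = FALSE)
  }
  L <- nchar(entry$extended_seed)
  for (m in occ$mismatches) {
    lim <- if (m$op == "insertion") L + 1L else L
    if (m$P > lim) {
      stop("mismatch position ", m$P, " outside the extended seed (length ",
           L, ")", call. = FALSE)
    }
  }
  entry$occurrences <- c(entry$occurrences, list(occ))
  entry
}

#' Finalize a dictionary entry with the seed's own excision position
#'
#' The extended seed itself is excised last; its position `d` in the working
#' sequence at that moment is recorded exactly once, after all occurrences.
#' A finalized entry is immutable.
#'
#' @param entry A [dictionary_entry()].
#' @param d 1-based excision-time position of the extended seed.
#' @return The finalized entry.
#' @export
finalize_entry <- function(entry, d) {
  stopifnot(inherits(entry, "dictionary_entry"))
  if (!is.na(entry$d)) {
    stop("entry already finalized (d = ", entry$d, ")", call. = FALSE)
  }
  stopifnot(is.numeric(d), length(d) == 1L, d >= 1, d == floor(d))
  entry$d <- as.integer(d)
  entry
}

#' @export
print.dictionary_entry <- function(x, ...) {
  cat(sprintf("<dictionary_entry> seed %s (%d bp), %d occurrence(s), d=%s\n",
              if (nchar(x$extended_seed) > 30L)
                paste0(substr(x$extended_seed, 1L, 30L), "...")
              else x$extended_seed,
              nchar(x$extended_seed), length(x$occurrences),
              if (is.na(x$d)) "<unset>" else x$d))
  invisible(x)
}

#' Create an (empty) offline dictionary
#'
#' An ordered list of finalized [dictionary_entry()]s; the order is the
#' entry-creation (excision) order, which decompression depends on.
#'
#' @param entries List of dictionary entries.
#' @return An object of class `offline_dictionary`.
#' @export
offline_dictionary <- function(entries = list()) {
  stopifnot(is.list(entries))
  for (e in entries) stopifnot(inherits(e, "dictionary_entry"))
  structure(list(entries = entries), class = "offline_dictionary")
}

#' @export
print.offline_dictionary <- function(x, ...) {
  cat(sprintf("<offline_dictionary> %d entr%s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (e in head(x$entries, 5L)) print(e)
  if (length(x$entries) > 5L) cat("  ...\n")
  invisible(x)
}

#' @export
length.offline_dictionary <- function(x) length(x$entries)

#' Human-readable dictionary dump
#'
#' Flattens an offline dictionary into a data frame mirroring the columns of
#' the on-paper dictionary table: extended seed, type of repeat, position,
#' length, and the mismatch details formatted as space-separated
#' position/op-bits/base-bits triples (see [format_triple()]). The final row
#' of each entry block records the seed's own position `d`.
#'
#' @param dict An `offline_dictionary`.
#' @param path Optional path; when given, the table is written as TSV.
#' @return A data frame (invisibly when `path` is given).
#' @export
dump_dictionary <- function(dict, path = NULL) {
  stopifnot(inherits(dict, "offline_dictionary"))
  rows <- list()
  for (e in dict$entries) {
    for (o in e$occurrences) {
      mm <- if (length(o$mismatches) == 0L) "" else
        paste0("(", paste(vapply(o$mismatches, format_triple, character(1)),
                          collapse = ", "), ")")
      rows[[length(rows) + 1L]] <- data.frame(
        extended_seed = e$extended_seed, type = o$rtype,
        position = o$c, length = o$n0, mismatch_details = mm,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      extended_seed = e$extended_seed, type = "seed",
      position = if (is.na(e$d)) NA_integer_ else e$d,
      length = nchar(e$extended_seed), mismatch_details = "",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(extended_seed = character(0), type = character(0),
               position = integer(0), length = integer(0),
               mismatch_details = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
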