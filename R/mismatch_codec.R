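# Bit-level codec for (P, E, S) mismatch triples.
#
# Field codes (fixed constants): edit operations insertion=00, deletion=01,
# substitution=10 ("11" is unassigned and rejected on decode); bases A=00,
# C=01, G=10, T=11. A triple is written as the position P, then the 2-bit
# operation, then the 2-bit base -- the base field being omitted for
# deletions.
#
# Two position layouts exist. The container always uses `canonical`: P in a
# fixed width of ceil(log2(L+2)) bits for a seed of length L (the +2 admits
# an insertion at position L+1), which is self-delimiting. `minimal` writes
# P in exactly ceil(log2(P+1)) bits -- the smallest width that still
# distinguishes it from zero -- and exists to reproduce worked examples and
# for display; it is never used in the bitstream because it cannot be parsed
# back without knowing P.

.OP_CODES <- c(insertion = 0L, deletion = 1L, substitution = 2L)
.BASE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.bits_chr <- function(value, width) {
  paste(floor(value / 2^((width - 1L):0)) %% 2, collapse = "")
}

#' Number of bits in the canonical encoding of a mismatch triple
#'
#' @param m A [mismatch_record()].
#' @param width_P Fixed bit-width of the position field.
#' @return Integer bit count: `width_P + 2`, plus 2 unless the operation is a
#'   deletion.
#' @export
triple_bits <- function(m, width_P) {
  stopifnot(inherits(m, "mismatch_record"))
  as.integer(width_P + 2L + if (m$op == "deletion") 0L else 2L)
}

#' Encode a mismatch triple as bits
#'
#' @param m A [mismatch_record()].
#' @param width_P Bit-width for the position field (canonical mode). Ignored
#'   in minimal mode, where P is written in `ceil(log2(P+1))` bits.
#' @param mode `"canonical"` (fixed-width, decodable; used in the container)
#'   or `"minimal"` (display/verification only).
#' @return A character scalar of `0`/`1` digits of class `triple_bits`, with
#'   attribute `width_P` giving the position width actually used.
#' @examples
#' encode_triple(mismatch_record(7, "substitution", "T"), mode = "minimal")
#' encode_triple(mismatch_record(7, "substitution", "T"), width_P = 4)
#' @export
encode_triple <- function(m, width_P = NULL, mode = c("canonical", "minimal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "mismatch_record"))
  if (mode == "minimal") {
    width_P <- max(1L, as.integer(.celog2(m$P + 1L)))
  } else {
    if (is.null(width_P)) {
      stop("canonical mode requires width_P", call. = FALSE)
    }
    width_P <- as.integer(width_P)
    if (m$P >= 2^width_P) {
      stop("position ", m$P, " does not fit in ", width_P, " bits",
           call. = FALSE)
    }
  }
  bits <- paste0(.bits_chr(m$P, width_P), .bits_chr(.OP_CODES[[m$op]], 2L))
  if (m$op != "deletion") {
    bits <- paste0(bits, .bits_chr(.BASE_CODES[[m$sym]], 2L))
  }
  structure(bits, class = "triple_bits", width_P = width_P)
}

#' Decode a mismatch triple from bits
#'
#' Inverse of the canonical [encode_triple()]. After the 2-bit operation
#' field, a base field is read if and only if the operation is not a
#' deletion -- except under `dialect = "tolerant"`, where a trailing base
#' field after a deletion is read and discarded (some printed dictionaries
#' carry it).
#'
#' @param bits Character scalar of `0`/`1` digits, or integer 0/1 vector.
#' @param width_P Bit-width of the position field.
#' @param dialect `"strict"` (default) or `"tolerant"`.
#' @return A list with the decoded [mismatch_record()] as `record` and the
#'   number of bits consumed as `nbits`.
#' @export
decode_triple <- function(bits, width_P, dialect = c("strict", "tolerant")) {
  dialect <- match.arg(dialect)
  if (is.character(bits)) {
    bits <- as.integer(strsplit(bits, "", fixed = TRUE)[[1L]])
  }
  stopifnot(all(bits %in% c(0L, 1L)))
  width_P <- as.integer(width_P)
  if (length(bits) < width_P + 2L) {
    stop("malformed triple: stream holds fewer than width_P + 2 bits",
         call. = FALSE)
  }
  P <- sum(bits[seq_len(width_P)] * 2^((width_P - 1L):0))
  opcode <- bits[width_P + 1L] * 2L + bits[width_P + 2L]
  if (opcode == 3L) {
    stop("malformed triple: edit-operation code 11 is unassigned",
         call. = FALSE)
  }
  op <- names(.OP_CODES)[match(opcode, .OP_CODES)]
  used <- width_P + 2L
  sym <- NA_character_
  if (op != "deletion") {
    if (length(bits) < used + 2L) {
      stop("malformed triple: missing base field", call. = FALSE)
    }
    code <- bits[used + 1L] * 2L + bits[used + 2L]
    sym <- names(.BASE_CODES)[match(code, .BASE_CODES)]
    used <- used + 2L
  } else if (dialect == "tolerant" && length(bits) >= used + 2L) {
    used <- used + 2L # printed dialect: discard the redundant base field
  }
  list(record = mismatch_record(P, op, sym), nbits = used)
}

#' Format a mismatch triple in the printed dictionary style
#'
#' Renders a triple as space-separated fields, position in decimal and the
#' operation/base fields as their 2-bit codes, e.g. `"1 10 01"` for a
#' substitution of C at position 1.
#'
#' @param m A [mismatch_record()].
#' @return Character scalar.
#' @export
format_triple <- function(m) {
  stopifnot(inherits(m, "mismatch_record"))
  out <- paste(m$P, .bits_chr(.OP_CODES[[m$op]], 2L))
  if (m$op != "deletion") {
    out <- paste(out, .bits_chr(.BASE_CODES[[m$sym]], 2L))
  }
  out
}
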