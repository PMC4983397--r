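# Adaptive order-0 arithmetic coding over the nucleotide alphabet plus a
# dedicated end-of-stream symbol. Every stream is coded with a fresh model
# (all counts 1), so streams are independently decodable; the container
# interleaves one stream per dictionary seed plus one for the residue.
#
# Streams are self-delimiting: ac_encode prefixes the payload with a 32-bit
# big-endian payload length, so several streams can be concatenated and
# ac_decode can report exactly how many bits each one consumed. Inside the
# payload, decoding still runs until the end-of-stream symbol, which doubles
# as an integrity check.

.AC_NSYM <- 4L # A, C, G, T; EOS handled inside the coder

#' Arithmetic-code a nucleotide fragment
#'
#' @param x A `dna_sequence`, character scalar over \{A,C,G,T\} (may be
#'   empty), or integer vector of codes 1..4.
#' @return Integer 0/1 vector: a 32-bit payload-length prefix followed by the
#'   coded payload (which ends with the end-of-stream codeword).
#' @examples
#' bits <- ac_encode("ACGT")
#' ac_decode(bits)$symbols
#' @export
ac_encode <- function(x) {
  syms <- if (is.numeric(x)) as.integer(x) else .dna_to_int(.as_symbols(x))
  payload <- .ac_encode_core(syms, .AC_NSYM)
  c(.int_bits(length(payload), 32L), payload)
}

.int_bits <- function(value, width) {
  as.integer(floor(value / 2^((width - 1L):0)) %% 2)
}

.bits_int <- function(bits) {
  sum(bits * 2^((length(bits) - 1L):0))
}

#' Decode one arithmetic-coded fragment
#'
#' Exact inverse of [ac_encode()]. Decoding starts at `start` within `bits`,
#' reads the 32-bit length prefix, decodes the payload through its
#' end-of-stream symbol, and reports the bits consumed so that concatenated
#' streams can be decoded in sequence.
#'
#' @param bits Integer 0/1 vector.
#' @param start 1-based offset of the stream within `bits`.
#' @param max_symbols Upper bound on the decoded symbol count (guards
#'   corrupted streams whose end-of-stream marker never appears).
#' @return List with `symbols` (character scalar over \{A,C,G,T\}),
#'   `codes` (integer vector 1..4) and `nbits` (bits consumed, including the
#'   32-bit prefix).
#' @export
ac_decode <- function(bits, start = 1L, max_symbols = 2^26) {
  stopifnot(start >= 1L)
  if (length(bits) < start + 31L) {
    stop("malformed stream: truncated length prefix", call. = FALSE)
  }
  len <- .bits_int(bits[start:(start + 31L)])
  if (length(bits) < start + 31L + len) {
    stop("malformed stream: payload truncated (expected ", len, " bits)",
         call. = FALSE)
  }
  payload <- if (len > 0) bits[(start + 32L):(start + 31L + len)] else integer(0)
  res <- .ac_decode_core(as.integer(payload), .AC_NSYM, max_symbols)
  codes <- as.integer(res$symbols)
  list(symbols = .int_to_dna(codes), codes = codes,
       nbits = 32L + as.integer(len))
}
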