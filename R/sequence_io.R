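#' Construct a DNA sequence object
#'
#' A `dna_sequence` is a validated single nucleotide sequence: a string over
#' the alphabet \{A, C, G, T\} plus a free-text record name. All positions
#' reported anywhere in the package are 1-based and inclusive: position `i`
#' addresses the i-th symbol, `1 <= i <= l`.
#'
#' @param symbols Character scalar over \{A, C, G, T\} (may be empty).
#' @param name Record identifier (free text), default `"seq"`.
#' @return An object of class `dna_sequence` with fields `name` and `symbols`.
#' @examples
#' s <- dna_sequence("ACGT", name = "x")
#' seq_length(s)
#' @export
dna_sequence <- function(symbols, name = "seq") {
  stopifnot(is.character(symbols), length(symbols) == 1L, !is.na(symbols))
  if (nchar(symbols) > 0L) {
    ok <- grepl("^[ACGT]+$", symbols)
    if (!ok) {
      chars <- strsplit(symbols, "", fixed = TRUE)[[1L]]
      bad <- which(!chars %in% .BASES)[1L]
      stop("invalid symbol '", chars[bad], "' at position ", bad, call. = FALSE)
    }
  }
  structure(list(name = as.character(name), symbols = symbols),
            class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  l <- seq_length(x)
  shown <- if (l > 60L) paste0(substr(x$symbols, 1L, 60L), "...") else x$symbols
  cat(sprintf("<dna_sequence> %s (%d bp)\n  %s\n", x$name, l, shown))
  sc <- attr(x, "sidecar")
  if (!is.null(sc) && nrow(sc) > 0L) {
    cat(sprintf("  sidecar: %d non-ACGT symbol(s) recorded for reinsertion\n",
                nrow(sc)))
  }
  invisible(x)
}

#' Length of a DNA sequence
#'
#' @param x A `dna_sequence` or character scalar.
#' @return Integer number of symbols.
#' @export
seq_length <- function(x) {
  nchar(.as_symbols(x))
}

# Accept either a dna_sequence or a plain string everywhere.
.as_symbols <- function(x) {
  if (inherits(x, "dna_sequence")) x$symbols else {
    stopifnot(is.character(x), length(x) == 1L)
    x
  }
}

#' Sanitize a raw nucleotide string
#'
#' Uppercases the input and applies the non-ACGT policy. Under `"reject"`
#' (the default everywhere in the package) any symbol outside \{A, C, G, T\}
#' is an error naming its 1-based position. Under `"strip-record"` such
#' symbols are removed and their positions and identities are recorded in a
#' sidecar table attached to the result, so that decompression can reinsert
#' them and remain lossless on real-world records containing e.g. runs of N.
#'
#' @param raw Character scalar.
#' @param policy `"reject"` or `"strip-record"`.
#' @param name Record name for the resulting sequence.
#' @return A `dna_sequence`; under `"strip-record"` it carries a `sidecar`
#'   attribute: a data frame with columns `pos` (1-based position in the
#'   original string) and `sym` (the removed character).
#' @seealso [reinsert_sidecar()] for the inverse of stripping.
#' @examples
#' sanitize("AcGt")
#' s <- sanitize("ANA", policy = "strip-record")
#' attr(s, "sidecar")
#' @export
sanitize <- function(raw, policy = c("reject", "strip-record"), name = "seq") {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  up <- toupper(raw)
  if (nchar(up) == 0L) {
    out <- dna_sequence("", name = name)
    attr(out, "sidecar") <- data.frame(pos = integer(0),
                                       sym = character(0),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .BASES)
  if (policy == "reject") {
    if (length(bad) > 0L) {
      stop("invalid symbol '", chars[bad[1L]], "' at position ", bad[1L],
           call. = FALSE)
    }
    out <- dna_sequence(up, name = name)
    attr(out, "sidecar") <- data.frame(pos = integer(0),
                                       sym = character(0),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  sidecar <- data.frame(pos = bad, sym = chars[bad], stringsAsFactors = FALSE)
  kept <- if (length(bad) > 0L) chars[-bad] else chars
  out <- dna_sequence(paste(kept, collapse = ""), name = name)
  attr(out, "sidecar") <- sidecar
  out
}

#' Reinsert sidecar symbols removed by `sanitize(policy = "strip-record")`
#'
#' @param symbols Character scalar (the stripped sequence).
#' @param sidecar Data frame with columns `pos`, `sym` as produced by
#'   [sanitize()]. Positions refer to the original (unstripped) string.
#' @return Character scalar with the removed symbols restored.
#' @export
reinsert_sidecar <- function(symbols, sidecar) {
  if (is.null(sidecar) || nrow(sidecar) == 0L) return(symbols)
  chars <- if (nchar(symbols) > 0L) strsplit(symbols, "", fixed = TRUE)[[1L]]
           else character(0)
  total <- length(chars) + nrow(sidecar)
  out <- character(total)
  sidecar <- sidecar[order(sidecar$pos), , drop = FALSE]
  out[sidecar$pos] <- sidecar$sym
  out[setdiff(seq_len(total), sidecar$pos)] <- chars
  paste(out, collapse = "")
}

#' Read the first record of a FASTA file
#'
#' Reads a plain (possibly line-wrapped) FASTA file and returns its first
#' record, sanitized under the given non-ACGT policy. Multi-record files
#' produce a warning and only the first record is used: the compressor treats
#' one sequence at a time.
#'
#' @param path Path to a FASTA file.
#' @param policy Non-ACGT policy passed to [sanitize()].
#' @return A `dna_sequence` (with a `sidecar` attribute under
#'   `"strip-record"`).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, policy = c("reject", "strip-record")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop("cannot read FASTA file: '", path, "' does not exist", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records found in '", path, "'", call. = FALSE)
  }
  if (length(set) > 1L) {
    warning("'", path, "' contains ", length(set),
            " records; using only the first", call. = FALSE)
  }
  nm <- names(set)[1L]
  raw <- as.character(set[[1L]])
  if (nchar(raw) == 0L) {
    stop("FASTA record '", nm, "' is empty", call. = FALSE)
  }
  sanitize(raw, policy = policy, name = nm)
}

#' Write a DNA sequence to a FASTA file
#'
#' @param seq A `dna_sequence` (or character scalar).
#' @param path Output path.
#' @param width Line-wrap width, default 60.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seq, path, width = 60L) {
  stopifnot(width >= 1L)
  symbols <- .as_symbols(seq)
  name <- if (inherits(seq, "dna_sequence")) seq$name else "seq"
  set <- Biostrings::BStringSet(symbols)
  names(set) <- name
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}
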