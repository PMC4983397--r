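# Bit-exact serialization of (offline dictionary, parsed residue) into the
# .szp container, and parsing back. Layout (all multi-bit integers
# big-endian; one bit stream padded to a byte boundary only at file end):
#
#   magic   32 bits  "SZPC"
#   version  8 bits  1
#   k, lookahead, threshold-mode, policy, gain-gate   8 bits each
#   name    16-bit byte count + 8 bits per byte
#   l_san   32 bits  sanitized input length (decompression verifies it)
#   sidecar 32-bit count, then per symbol: 32-bit original position + 8-bit
#           character code
#   n       32 bits  dictionary entry count
#   per entry (creation order):
#     L_w   32 bits  working-sequence length at entry creation; all position
#                    and length fields of the entry use W = ceil(log2(L_w+1))
#                    bits
#     l(i)  W bits   extended-seed length
#     seed  arithmetic-coded stream (self-delimiting, 32-bit length prefix)
#     k(i)  16 bits  occurrence count
#     per occurrence: type 3 bits | c W bits | n0 W bits | mismatch count
#                     5 bits | canonical triples, width_P = ceil(log2(l(i)+2))
#     d     W bits
#   parsed  arithmetic-coded stream
#   zero padding to the next byte boundary

.MAGIC <- utf8ToInt("SZPC")
.VERSION <- 1L
.TMODE_CODES <- c(log2_n0 = 0L, log2_log2_n0 = 1L)
.POLICY_CODES <- c(reject = 0L, `strip-record` = 1L)

#' Serialize a dictionary and parsed residue into container bytes
#'
#' @param dict An [offline_dictionary()] whose entries are all finalized and
#'   carry a `working_length` attribute (as produced by [compress_dna()]).
#' @param parsed Character scalar: the residue sequence.
#' @param params An [extend_params()] object.
#' @param meta List with `name`, `l_san`, `sidecar` (see [compress_dna()]).
#' @return Raw vector with attributes `nbits` (total bits including padding)
#'   and `audit` (named numeric vector of bits per layout component).
#' @export
serialize_container <- function(dict, parsed, params, meta) {
  stopifnot(inherits(dict, "offline_dictionary"),
            inherits(params, "extend_params"))
  bw <- .bit_writer(4096L)
  audit <- c(header = 0, vocabulary = 0, positions = 0, mismatch = 0,
             lengths = 0, type = 0, parsed = 0)
  put <- function(cat, value, width) {
    bw$write_bits(value, width)
    audit[cat] <<- audit[cat] + width
  }
  putvec <- function(cat, bits) {
    bw$write_bitvec(bits)
    audit[cat] <<- audit[cat] + length(bits)
  }

  for (byte in .MAGIC) put("header", byte, 8L)
  put("header", .VERSION, 8L)
  put("header", params$k, 8L)
  put("header", params$lookahead, 8L)
  put("header", .TMODE_CODES[[params$threshold_mode]], 8L)
  put("header", .POLICY_CODES[[params$policy]], 8L)
  put("header", as.integer(params$gain_gate), 8L)

  name_bytes <- as.integer(charToRaw(meta$name))
  if (length(name_bytes) > 65535L) name_bytes <- name_bytes[1:65535]
  put("header", length(name_bytes), 16L)
  for (byte in name_bytes) put("header", byte, 8L)

  put("header", meta$l_san, 32L)
  sidecar <- meta$sidecar
  put("header", nrow(sidecar), 32L)
  if (nrow(sidecar) > 0L) {
    for (r in seq_len(nrow(sidecar))) {
      put("header", sidecar$pos[r], 32L)
      put("header", as.integer(charToRaw(sidecar$sym[r]))[1L], 8L)
    }
  }

  put("header", length(dict$entries), 32L)
  for (e in dict$entries) {
    if (is.na(e$d)) {
      stop("cannot serialize an unfinalized dictionary entry", call. = FALSE)
    }
    L_w <- attr(e, "working_length")
    if (is.null(L_w)) {
      stop("dictionary entry lacks its working_length attribute",
           call. = FALSE)
    }
    W <- .occ_field_width(L_w)
    l_i <- nchar(e$extended_seed)
    width_P <- as.integer(.celog2(l_i + 2L))
    put("lengths", L_w, 32L)
    put("lengths", l_i, W)
    putvec("vocabulary", ac_encode(e$extended_seed))
    put("lengths", length(e$occurrences), 16L)
    for (o in e$occurrences) {
      put("type", REPEAT_TYPES[[o$rtype]], 3L)
      put("positions", o$c, W)
      put("lengths", o$n0, W)
      put("mismatch", length(o$mismatches), 5L)
      for (m in o$mismatches) {
        tb <- encode_triple(m, width_P = width_P, mode = "canonical")
        putvec("mismatch",
               as.integer(strsplit(unclass(tb), "", fixed = TRUE)[[1L]]))
      }
    }
    put("positions", e$d, W)
  }

  putvec("parsed", ac_encode(parsed))

  pad <- (-bw$length()) %% 8L
  if (pad > 0L) putvec("header", integer(pad))
  bytes <- .bits_to_raw(bw$bits())
  attr(bytes, "nbits") <- bw$length()
  attr(bytes, "audit") <- audit
  bytes
}

#' Parse container bytes
#'
#' Exact inverse of [serialize_container()].
#'
#' @param bytes Raw vector.
#' @return List with `dict`, `parsed` (character), `params`, `meta`.
#' @export
parse_container <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 4L || !identical(as.integer(bytes[1:4]), .MAGIC)) {
    stop("not a seedzip container (bad magic bytes)", call. = FALSE)
  }
  bits <- .raw_to_bits(bytes)
  br <- .bit_reader(bits)
  br$skip(32L) # magic, already checked
  version <- br$read_bits(8L)
  if (version != .VERSION) {
    stop("unsupported container version ", version, call. = FALSE)
  }
  k <- br$read_bits(8L)
  lookahead <- br$read_bits(8L)
  tmode_code <- br$read_bits(8L)
  policy_code <- br$read_bits(8L)
  gate <- br$read_bits(8L)
  if (!tmode_code %in% .TMODE_CODES || !policy_code %in% .POLICY_CODES) {
    stop("malformed container: unknown parameter code", call. = FALSE)
  }
  params <- extend_params(
    k = k, lookahead = lookahead,
    threshold_mode = names(.TMODE_CODES)[match(tmode_code, .TMODE_CODES)],
    gain_gate = gate == 1,
    policy = names(.POLICY_CODES)[match(policy_code, .POLICY_CODES)])

  name_len <- br$read_bits(16L)
  name <- if (name_len > 0L) {
    rawToChar(as.raw(vapply(seq_len(name_len), function(i) br$read_bits(8L),
                            numeric(1))))
  } else ""

  l_san <- br$read_bits(32L)
  sc_n <- br$read_bits(32L)
  sc_pos <- integer(sc_n)
  sc_sym <- character(sc_n)
  for (r in seq_len(sc_n)) {
    sc_pos[r] <- br$read_bits(32L)
    sc_sym[r] <- rawToChar(as.raw(br$read_bits(8L)))
  }
  sidecar <- data.frame(pos = sc_pos, sym = sc_sym, stringsAsFactors = FALSE)

  n <- br$read_bits(32L)
  entries <- vector("list", n)
  for (ei in seq_len(n)) {
    L_w <- br$read_bits(32L)
    W <- .occ_field_width(L_w)
    l_i <- br$read_bits(W)
    if (l_i < 2L) stop("malformed container: seed length ", l_i, call. = FALSE)
    seed_dec <- ac_decode(bits, start = br$position(), max_symbols = l_i)
    if (nchar(seed_dec$symbols) != l_i) {
      stop("malformed container: seed stream decoded to ",
           nchar(seed_dec$symbols), " symbols, expected ", l_i, call. = FALSE)
    }
    br$skip(seed_dec$nbits)
    width_P <- as.integer(.celog2(l_i + 2L))
    entry <- dictionary_entry(seed_dec$symbols)
    k_i <- br$read_bits(16L)
    for (oi in seq_len(k_i)) {
      tcode <- br$read_bits(3L)
      if (!tcode %in% REPEAT_TYPES) {
        stop("malformed container: unknown repeat-type code ", tcode,
             call. = FALSE)
      }
      rtype <- names(REPEAT_TYPES)[match(tcode, REPEAT_TYPES)]
      cpos <- br$read_bits(W)
      n0 <- br$read_bits(W)
      mm_n <- br$read_bits(5L)
      mism <- vector("list", mm_n)
      for (mi in seq_len(mm_n)) {
        head_bits <- br$read_bitvec(width_P + 2L)
        P <- .bits_int(head_bits[seq_len(width_P)])
        opcode <- head_bits[width_P + 1L] * 2L + head_bits[width_P + 2L]
        if (opcode == 3L) {
          stop("malformed container: edit-operation code 11", call. = FALSE)
        }
        op <- names(.OP_CODES)[match(opcode, .OP_CODES)]
        sym <- NA_character_
        if (op != "deletion") {
          code <- .bits_int(br$read_bitvec(2L))
          sym <- names(.BASE_CODES)[match(code, .BASE_CODES)]
        }
        mism[[mi]] <- mismatch_record(P, op, sym)
      }
      entry <- add_occurrence(entry, occurrence(rtype, cpos, n0, mism))
    }
    d <- br$read_bits(W)
    entry <- finalize_entry(entry, d)
    attr(entry, "working_length") <- L_w
    entries[[ei]] <- entry
  }

  parsed_dec <- ac_decode(bits, start = br$position(),
                          max_symbols = max(1, l_san))
  br$skip(parsed_dec$nbits)

  list(dict = offline_dictionary(entries), parsed = parsed_dec$symbols,
       params = params,
       meta = list(name = name, l_san = l_san, sidecar = sidecar))
}

.container_from_bytes <- function(bytes) {
  parsed <- parse_container(bytes)
  structure(list(bytes = bytes, dict = parsed$dict, parsed = parsed$parsed,
                 params = parsed$params, meta = parsed$meta,
                 audit = attr(bytes, "audit")),
            class = "compressed_container")
}

#' Write a compressed container to disk
#'
#' @param x A `compressed_container` (or raw vector).
#' @param path Output path (conventionally `.szp`).
#' @return Invisibly, `path`.
#' @export
write_container <- function(x, path) {
  bytes <- if (inherits(x, "compressed_container")) x$bytes else x
  stopifnot(is.raw(bytes))
  writeBin(as.raw(bytes), path)
  invisible(path)
}

#' Read a compressed container from disk
#'
#' @param path Path to a container file.
#' @return A `compressed_container`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read container: '", path, "' does not exist", call. = FALSE)
  }
  bytes <- readBin(path, what = "raw", n = file.size(path))
  .container_from_bytes(bytes)
}
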