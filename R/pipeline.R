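# Compression / decompression orchestration.
#
# Compression loop: scan for the next seed match, extend it, sweep the
# working sequence for every further occurrence of the extended seed
# (excising each at its then-current position), excise the seed itself last
# and record its position d, then restart on the shortened sequence. The
# residue left when no seed matches any more is the parsed sequence.
#
# Decompression replays the record backwards: decode the residue, then for
# each dictionary entry in reverse creation order reinsert the extended seed
# at d and then each of its occurrences, in reverse excision order, at its
# recorded position c.

# All positions in a working sequence of length L_w fit in this many bits.
.occ_field_width <- function(L_w) .field_width(L_w)

# Container bits one occurrence will occupy: 3-bit type + position + length
# + 5-bit mismatch count + canonical triples.
.occ_bits <- function(mismatches, W, width_P) {
  tb <- 0L
  for (m in mismatches) tb <- tb + triple_bits(m, width_P)
  3L + W + W + 5L + tb
}

# Fixed per-entry container overhead: 32-bit working-length field, seed
# length, 16-bit occurrence count, seed position d.
.entry_overhead_bits <- function(W) 32L + W + 16L + W

# Positions (ascending) where the k-length integer pattern occurs in w.
.pattern_positions <- function(w, pat) {
  n <- length(w)
  k <- length(pat)
  if (n < k) return(integer(0))
  hits <- w[seq_len(n - k + 1L)] == pat[1L]
  if (k > 1L) {
    for (j in 2L:k) {
      hits <- hits & (w[j:(n - k + j)] == pat[j])
    }
  }
  which(hits)
}

# Align the whole extended seed (under orientation rtype) against the
# working sequence around an exact k-symbol anchor: target positions
# [tx0, tx0+k-1] match w[ya, ya+k-1] verbatim. The walk proceeds forward to
# the seed's right end and then backward to its left end, admitting
# mismatches under the dynamic threshold (on the working symbols matched so
# far) and a look-ahead window truncated at the seed ends
# (min(lookahead, remaining)): the open-ended extension's strict boundary
# rule would make flank noise on the seed unalignable against later copies.
# The fragment may not start at or before y_min (overlap with the seed).
# Returns NULL on failure, else a list with y0 (fragment start), n0 and
# seed-frame mismatch records.
.align_anchored <- function(w, ya, tx0, seed_v, rtype, lookahead, tmode,
                            y_min) {
  tv <- .transform_int(seed_v, rtype)
  L <- length(tv)
  n <- length(w)
  mirror <- .rtype_mirror(rtype)
  comp <- .rtype_comp(rtype)
  m <- 0L
  matched <- 0L
  mm_op <- integer(0); mm_tp <- integer(0); mm_sym <- integer(0)

  seg_eq_fwd <- function(tfrom, wfrom, len) {
    if (len == 0L) return(TRUE)
    if (tfrom + len - 1L > L || wfrom + len - 1L > n) return(FALSE)
    all(tv[tfrom:(tfrom + len - 1L)] == w[wfrom:(wfrom + len - 1L)])
  }
  seg_eq_bwd <- function(tfrom, wfrom, len) {
    if (len == 0L) return(TRUE)
    if (tfrom - len + 1L < 1L || wfrom - len + 1L <= y_min) return(FALSE)
    all(tv[tfrom:(tfrom - len + 1L)] == w[wfrom:(wfrom - len + 1L)])
  }

  # forward phase: from the anchor start to the seed's right end
  tx <- tx0; y <- ya
  while (tx <= L) {
    if (y > n) return(NULL)
    if (tv[tx] == w[y]) {
      tx <- tx + 1L; y <- y + 1L; matched <- matched + 1L
      next
    }
    if (m + 1L > mismatch_threshold(max(1L, matched), tmode)) return(NULL)
    wsub <- min(lookahead, L - tx)
    if (seg_eq_fwd(tx + 1L, y + 1L, wsub)) {
      mm_op <- c(mm_op, 1L); mm_tp <- c(mm_tp, tx); mm_sym <- c(mm_sym, w[y])
      tx <- tx + 1L; y <- y + 1L; m <- m + 1L; matched <- matched + 1L
      next
    }
    if (seg_eq_fwd(tx + 1L, y, wsub)) {
      mm_op <- c(mm_op, 2L); mm_tp <- c(mm_tp, tx)
      mm_sym <- c(mm_sym, NA_integer_)
      tx <- tx + 1L; m <- m + 1L
      next
    }
    wins <- min(lookahead, L - tx + 1L)
    if (seg_eq_fwd(tx, y + 1L, wins)) {
      mm_op <- c(mm_op, 3L); mm_tp <- c(mm_tp, tx); mm_sym <- c(mm_sym, w[y])
      y <- y + 1L; m <- m + 1L; matched <- matched + 1L
      next
    }
    return(NULL)
  }
  y_end <- y - 1L

  # backward phase: from just before the anchor to the seed's left end
  tx <- tx0 - 1L; y <- ya - 1L
  while (tx >= 1L) {
    if (y <= y_min) return(NULL)
    if (tv[tx] == w[y]) {
      tx <- tx - 1L; y <- y - 1L; matched <- matched + 1L
      next
    }
    if (m + 1L > mismatch_threshold(max(1L, matched), tmode)) return(NULL)
    wsub <- min(lookahead, tx - 1L)
    if (seg_eq_bwd(tx - 1L, y - 1L, wsub)) {
      mm_op <- c(mm_op, 1L); mm_tp <- c(mm_tp, tx); mm_sym <- c(mm_sym, w[y])
      tx <- tx - 1L; y <- y - 1L; m <- m + 1L; matched <- matched + 1L
      next
    }
    if (seg_eq_bwd(tx - 1L, y, wsub)) {
      mm_op <- c(mm_op, 2L); mm_tp <- c(mm_tp, tx)
      mm_sym <- c(mm_sym, NA_integer_)
      tx <- tx - 1L; m <- m + 1L
      next
    }
    wins <- min(lookahead, tx)
    if (seg_eq_bwd(tx, y - 1L, wins)) {
      mm_op <- c(mm_op, 3L); mm_tp <- c(mm_tp, tx + 1L)
      mm_sym <- c(mm_sym, w[y])
      y <- y - 1L; m <- m + 1L; matched <- matched + 1L
      next
    }
    return(NULL)
  }
  y0 <- y + 1L

  n0 <- y_end - y0 + 1L
  if (n0 < 1L || y0 <= y_min) return(NULL)
  if (length(mm_op) > mismatch_threshold(n0, tmode)) return(NULL)

  # convert transformed-frame records to seed coordinates
  mism <- list()
  if (length(mm_op) > 0L) {
    P <- integer(length(mm_op)); sym <- character(length(mm_op))
    for (j in seq_along(mm_op)) {
      if (mm_op[j] == 3L) {
        P[j] <- if (mirror) L - mm_tp[j] + 2L else mm_tp[j]
      } else {
        P[j] <- if (mirror) L - mm_tp[j] + 1L else mm_tp[j]
      }
      sym[j] <- if (is.na(mm_sym[j])) NA_character_ else
        .BASES[if (comp) 5L - mm_sym[j] else mm_sym[j]]
    }
    ops <- c("substitution", "deletion", "insertion")[mm_op]
    ord <- order(P)
    mism <- lapply(ord, function(j) mismatch_record(P[j], ops[j], sym[j]))
  }
  frag <- .materialize_int(seed_v, mism, rtype)
  if (!identical(frag, w[y0:y_end])) {
    stop("internal error: sweep occurrence does not materialize", call. = FALSE)
  }
  list(y0 = y0, n0 = n0, mismatches = mism)
}

# Sweep the working vector for all further occurrences of the extended seed
# located at [d, q], excising each accepted occurrence immediately. Anchors
# are exact k-mer matches of the transformed seed at seed offsets 0 and k
# (the second anchor recovers copies whose leading symbols carry a mismatch,
# e.g. flank noise absorbed into the extended seed). Returns
# list(w, occs, gains).
.sweep_occurrences <- function(w, d, q, params, W, width_P) {
  seed_v <- w[d:q]
  k <- params$k
  L <- length(seed_v)
  offsets <- if (L >= 2L * k) c(0L, k) else 0L
  # anchor patterns: one per (type, offset), with the target index they pin
  pats <- list()
  for (t in .SEARCH_ORDER) {
    tv <- .transform_int(seed_v, t)
    for (off in offsets) {
      pats[[length(pats) + 1L]] <-
        list(rtype = t, tx0 = off + 1L, pat = tv[(off + 1L):(off + k)])
    }
  }
  pref <- match(vapply(pats, function(p) p$rtype, character(1)),
                .SEARCH_ORDER)
  occs <- list()
  gains <- numeric(0)
  ptr <- q + 1L

  repeat {
    anchors <- lapply(pats, function(p) {
      pos <- .pattern_positions(w, p$pat)
      pos[pos >= ptr]
    })
    firsts <- vapply(anchors, function(p)
      if (length(p) == 0L) Inf else as.numeric(p[1L]), numeric(1))
    if (all(is.infinite(firsts))) break
    ya <- as.integer(min(firsts))
    accepted <- FALSE
    # at equal anchor position, prefer exact > reverse > complement >
    # reverse_complement, and the earlier (smaller) seed offset
    for (pi in order(firsts, pref)) {
      if (is.infinite(firsts[pi]) || firsts[pi] != ya) next
      p <- pats[[pi]]
      al <- .align_anchored(w, ya, p$tx0, seed_v, p$rtype, params$lookahead,
                            params$threshold_mode, y_min = q)
      if (is.null(al)) next
      bits <- .occ_bits(al$mismatches, W, width_P)
      gain <- 2 * al$n0 - bits
      if (params$gain_gate && gain <= 0) next
      label <- p$rtype
      if (label == "exact" && length(al$mismatches) > 0L) label <- "approximate"
      if (label == "exact" && al$y0 == q + 1L) label <- "tandem"
      occs[[length(occs) + 1L]] <-
        occurrence(label, c = al$y0, n0 = al$n0, mismatches = al$mismatches)
      gains <- c(gains, gain)
      w <- w[-(al$y0:(al$y0 + al$n0 - 1L))]
      ptr <- al$y0
      accepted <- TRUE
      break
    }
    if (!accepted) ptr <- ya + 1L
  }
  list(w = w, occs = occs, gains = gains)
}

#' Compress a DNA sequence
#'
#' Runs the full seed-and-extend compression loop and returns a
#' self-contained compressed container. Deterministic: identical input and
#' parameters give byte-identical output.
#'
#' @param seq A `dna_sequence`, or a character scalar (sanitized under
#'   `params$policy`).
#' @param params An [extend_params()] object.
#' @return An object of class `compressed_container` with the serialized
#'   `bytes`, the `dict` ([offline_dictionary()]), the `parsed` residue
#'   string, `params` and `meta` (record name, sanitized length, sidecar).
#' @seealso [decompress_dna()], [write_container()], [cost_breakdown()]
#' @examples
#' cont <- compress_dna(dna_sequence("ACGT"))
#' decompress_dna(cont)$symbols
#' @export
compress_dna <- function(seq, params = extend_params()) {
  if (!inherits(seq, "dna_sequence")) {
    seq <- sanitize(.as_symbols(seq), policy = params$policy)
  }
  sidecar <- attr(seq, "sidecar")
  if (is.null(sidecar)) {
    sidecar <- data.frame(pos = integer(0), sym = character(0),
                          stringsAsFactors = FALSE)
  }
  s <- .dna_to_int(seq$symbols)
  l_san <- length(s)
  k <- params$k
  entries <- list()
  rejected <- new.env(hash = TRUE, parent = emptyenv())

  repeat {
    if (length(s) < 2L * k) break
    index <- .kmer_index(s, k)
    if (is.null(index)) break
    L_w <- length(s)
    W <- .occ_field_width(L_w)
    a_max <- L_w - 2L * k + 1L
    committed <- FALSE

    for (a in seq_len(a_max)) {
      key <- index$kv[a]
      if (exists(key, envir = rejected, inherits = FALSE)) next
      hit <- .first_match(index, a)
      if (is.null(hit)) next

      ext <- extend_match(s, a, k, hit$i, hit$rtype, params)
      d <- ext$seed_span[["d"]]; q <- ext$seed_span[["q"]]
      cc <- ext$repeat_span[["c"]]; p <- ext$repeat_span[["p"]]
      L <- q - d + 1L
      width_P <- as.integer(.celog2(L + 2L))

      # a copy immediately adjacent to its (extended) seed is a tandem repeat
      label1 <- ext$rtype
      if (label1 == "exact" && cc == q + 1L) label1 <- "tandem"
      occ1_bits <- .occ_bits(ext$mismatches, W, width_P)
      occ1_gain <- 2 * ext$n0 - occ1_bits
      if (params$gain_gate && occ1_gain <= 0) {
        assign(key, TRUE, envir = rejected)
        next
      }

      w <- s[-(cc:p)]
      occ1 <- occurrence(label1, c = cc, n0 = ext$n0,
                         mismatches = ext$mismatches)
      sw <- .sweep_occurrences(w, d, q, params, W, width_P)
      entry_gain <- occ1_gain + sum(sw$gains) - .entry_overhead_bits(W)
      if (params$gain_gate && entry_gain <= 0) {
        assign(key, TRUE, envir = rejected)
        next
      }

      entry <- dictionary_entry(.int_to_dna(s[d:q]))
      entry <- add_occurrence(entry, occ1)
      for (o in sw$occs) entry <- add_occurrence(entry, o)
      w <- sw$w
      # all sweep excisions lie right of q, so the seed still sits at [d, q]
      w <- w[-(d:q)]
      entry <- finalize_entry(entry, d)
      attr(entry, "working_length") <- L_w
      entries[[length(entries) + 1L]] <- entry
      s <- w
      committed <- TRUE
      break
    }
    if (!committed) break
  }

  dict <- offline_dictionary(entries)
  parsed <- .int_to_dna(s)
  meta <- list(name = seq$name, l_san = l_san, sidecar = sidecar)
  bytes <- serialize_container(dict, parsed, params, meta)
  structure(list(bytes = bytes, dict = dict, parsed = parsed,
                 params = params, meta = meta,
                 audit = attr(bytes, "audit")),
            class = "compressed_container")
}

#' @export
print.compressed_container <- function(x, ...) {
  nb <- length(x$bytes)
  cat(sprintf("<compressed_container> %s: %d bytes, %d dictionary entr%s, %d bp residue\n",
              x$meta$name, nb, length(x$dict),
              if (length(x$dict) == 1L) "y" else "ies",
              nchar(x$parsed)))
  if (x$meta$l_san > 0L) {
    cat(sprintf("  input %d bp -> %.4f bits/base\n", x$meta$l_san,
                8 * nb / x$meta$l_san))
  }
  invisible(x)
}

# Reverse replay shared by decompress_dna() and occurrence_map(). With
# track = TRUE, a parallel label vector identifies which entry/occurrence
# produced every symbol of the restored (sanitized) sequence.
.replay <- function(dict, parsed, track = FALSE) {
  w <- .dna_to_int(parsed)
  lab <- if (track) integer(length(w)) else NULL
  blocks <- list()
  bid <- 0L
  ins <- function(vec, at, frag) {
    n <- length(vec)
    if (at < 1L || at > n + 1L) {
      stop("malformed container: insertion position ", at,
           " outside working sequence of length ", n, call. = FALSE)
    }
    append(vec, frag, after = at - 1L)
  }
  entries <- dict$entries
  for (ei in rev(seq_along(entries))) {
    e <- entries[[ei]]
    if (is.na(e$d)) {
      stop("malformed container: entry ", ei, " has no seed position",
           call. = FALSE)
    }
    seed_v <- .dna_to_int(e$extended_seed)
    w <- ins(w, e$d, seed_v)
    if (track) {
      bid <- bid + 1L
      blocks[[bid]] <- list(entry = ei, occ = 0L, rtype = "seed",
                            len = length(seed_v))
      lab <- ins(lab, e$d, rep(bid, length(seed_v)))
    }
    for (oi in rev(seq_along(e$occurrences))) {
      o <- e$occurrences[[oi]]
      frag <- .materialize_int(seed_v, o$mismatches, o$rtype)
      if (length(frag) != o$n0) {
        stop("malformed container: occurrence length mismatch (recorded ",
             o$n0, ", materialized ", length(frag), ")", call. = FALSE)
      }
      w <- ins(w, o$c, frag)
      if (track) {
        bid <- bid + 1L
        blocks[[bid]] <- list(entry = ei, occ = oi, rtype = o$rtype,
                              len = length(frag))
        lab <- ins(lab, o$c, rep(bid, length(frag)))
      }
    }
  }
  list(w = w, lab = lab, blocks = blocks)
}

#' Decompress a container back to its DNA sequence
#'
#' Exact inverse of [compress_dna()]: decodes the residue, replays the
#' dictionary in reverse creation order (seed first, then its occurrences in
#' reverse excision order), verifies the restored length against the header,
#' and reinserts any sidecar symbols removed at sanitization.
#'
#' @param x A `compressed_container`, a raw vector, or a path to a container
#'   file.
#' @return A `dna_sequence`.
#' @export
decompress_dna <- function(x) {
  x <- .as_container(x)
  rep <- .replay(x$dict, x$parsed)
  if (length(rep$w) != x$meta$l_san) {
    stop("integrity error: restored length ", length(rep$w),
         " does not match recorded length ", x$meta$l_san, call. = FALSE)
  }
  symbols <- reinsert_sidecar(.int_to_dna(rep$w), x$meta$sidecar)
  out <- structure(list(name = x$meta$name, symbols = symbols),
                   class = "dna_sequence")
  out
}

.as_container <- function(x) {
  if (inherits(x, "compressed_container")) return(x)
  if (is.raw(x)) return(.container_from_bytes(x))
  if (is.character(x) && length(x) == 1L) return(read_container(x))
  stop("expected a compressed_container, raw vector, or file path",
       call. = FALSE)
}

#' Map dictionary occurrences back to original coordinates
#'
#' Replays decompression while tracking which dictionary entry produced each
#' restored symbol, and reports every seed and occurrence as a span in the
#' coordinates of the sanitized input sequence. Useful for validating repeat
#' recovery against planted ground truth.
#'
#' @param x A `compressed_container` (or raw vector / path).
#' @return Data frame with columns `entry`, `occ` (0 for the seed itself),
#'   `rtype`, `start`, `end`.
#' @export
occurrence_map <- function(x) {
  x <- .as_container(x)
  rep <- .replay(x$dict, x$parsed, track = TRUE)
  out <- data.frame(entry = integer(0), occ = integer(0),
                    rtype = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  if (length(rep$blocks) == 0L) return(out)
  for (bid in seq_along(rep$blocks)) {
    b <- rep$blocks[[bid]]
    at <- which(rep$lab == bid)
    if (length(at) == 0L) next
    out <- rbind(out, data.frame(entry = b$entry, occ = b$occ,
                                 rtype = b$rtype, start = min(at),
                                 end = max(at), stringsAsFactors = FALSE))
  }
  out[order(out$start), , drop = FALSE]
}

#' Identify the edits between a seed and an approximate repeat
#'
#' Aligns `fragment` against `seed` under the given orientation and returns
#' the mismatch records (positions in seed coordinates) that turn the seed
#' into the fragment. Both strings must be consumed completely. Unlike the
#' extension search, the look-ahead window is truncated near the seed's end,
#' so edits in the final symbols are representable.
#'
#' @param seed Character scalar or `dna_sequence`.
#' @param fragment Character scalar or `dna_sequence`.
#' @param rtype Orientation of the fragment relative to the seed.
#' @param lookahead Look-ahead window (default 3).
#' @param threshold_mode See [mismatch_threshold()].
#' @return List of [mismatch_record()]s (empty when the fragment is the
#'   transformed seed verbatim).
#' @examples
#' sequence_diff("GCACTTACT", "GCACTTTCT") # one substitution at position 7
#' @export
sequence_diff <- function(seed, fragment, rtype = "exact", lookahead = 3L,
                          threshold_mode = "log2_n0") {
  seed_v <- .dna_to_int(.as_symbols(seed))
  frag_v <- .dna_to_int(.as_symbols(fragment))
  al <- .align_anchored(frag_v, 1L, 1L, seed_v, rtype,
                        as.integer(lookahead), threshold_mode, y_min = 0L)
  if (is.null(al) || al$y0 != 1L || al$n0 != length(frag_v)) {
    stop("sequences do not align under the mismatch rules", call. = FALSE)
  }
  al$mismatches
}

#' Compress a FASTA file to a container file
#'
#' @param input Path to a FASTA file (first record used).
#' @param output Path for the compressed container (conventionally `.szp`).
#' @param params An [extend_params()] object; its `policy` governs non-ACGT
#'   symbols.
#' @return Invisibly, the `compressed_container`.
#' @export
compress_fasta <- function(input, output, params = extend_params()) {
  seq <- read_fasta(input, policy = params$policy)
  cont <- compress_dna(seq, params)
  write_container(cont, output)
  invisible(cont)
}

#' Decompress a container file to a FASTA file
#'
#' @param input Path to a compressed container.
#' @param output Path for the restored FASTA file.
#' @param width FASTA line width.
#' @return Invisibly, the restored `dna_sequence`.
#' @export
decompress_fasta <- function(input, output, width = 60L) {
  seq <- decompress_dna(input)
  write_fasta(seq, output, width = width)
  invisible(seq)
}
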