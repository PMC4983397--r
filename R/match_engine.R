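# Seed scanning, variant-transform matching, and bidirectional extension.
#
# The working sequence is held as an integer vector (A=1, C=2, G=3, T=4;
# complement = 5 - code). A seed is the k-mer S[a..b]; the scan looks for the
# first position i > b whose k-mer equals the seed under one of the four
# orientation transforms, then both fragments are extended outward under a
# dynamic mismatch budget. Reverse-family matches pair the seed's left end
# with the repeat's right end, so "seed-left" extension grows the repeat
# rightward for those types.

#' Extension / search parameters
#'
#' @param k Seed length (default 8; sensible range 5..11).
#' @param lookahead Number of symbols after a mismatch that must match
#'   exactly for the mismatch to be worth recording (default 3).
#' @param threshold_mode `"log2_n0"` (default): at most `floor(log2(n0))`
#'   mismatches for an extended repeat of current length `n0`;
#'   `"log2_log2_n0"`: the doubly logarithmic alternative.
#' @param gain_gate When TRUE (default) a dictionary entry is committed only
#'   if the itemized container bits it will occupy are smaller than the
#'   2-bits-per-base it saves; when FALSE every discovered repeat is excised
#'   unconditionally.
#' @param policy Non-ACGT input policy, see [sanitize()].
#' @return A list of class `extend_params`.
#' @export
extend_params <- function(k = 8L, lookahead = 3L,
                          threshold_mode = c("log2_n0", "log2_log2_n0"),
                          gain_gate = TRUE,
                          policy = c("reject", "strip-record")) {
  threshold_mode <- match.arg(threshold_mode)
  policy <- match.arg(policy)
  stopifnot(k >= 2L, lookahead >= 0L)
  structure(list(k = as.integer(k), lookahead = as.integer(lookahead),
                 threshold_mode = threshold_mode,
                 gain_gate = isTRUE(gain_gate), policy = policy),
            class = "extend_params")
}

#' Dynamic mismatch threshold
#'
#' The number of mismatches tolerated in one extended repeat never exceeds
#' `floor(log2(n0))`, where `n0` is the repeat's current extended length; the
#' bound therefore grows as the repeat grows. The doubly logarithmic mode
#' `"log2_log2_n0"` is the stricter alternative.
#'
#' @param n0 Current extended length (>= 1).
#' @param mode `"log2_n0"` or `"log2_log2_n0"`.
#' @return Integer maximum mismatch count.
#' @examples
#' mismatch_threshold(8) # 3
#' mismatch_threshold(9) # 3
#' @export
mismatch_threshold <- function(n0, mode = c("log2_n0", "log2_log2_n0")) {
  mode <- match.arg(mode)
  if (any(n0 < 1)) stop("n0 must be >= 1", call. = FALSE)
  l1 <- .flog2(n0)
  if (mode == "log2_n0") return(as.integer(l1))
  as.integer(ifelse(l1 < 1, 0L, .flog2(pmax(1, l1))))
}

#' Apply a repeat-type transform to a fragment
#'
#' `reverse` reverses the fragment, `complement` complements each base
#' (A<->T, C<->G), `reverse_complement` does both; `exact`, `approximate`
#' and `tandem` return the fragment unchanged.
#'
#' @param fragment A `dna_sequence` or character scalar.
#' @param rtype Repeat type.
#' @return Character scalar.
#' @examples
#' variant_transform("ACGT", "reverse")    # "TGCA"
#' variant_transform("ACGT", "complement") # "TGCA"
#' @export
variant_transform <- function(fragment, rtype) {
  .check_rtype(rtype)
  x <- .as_symbols(fragment)
  .int_to_dna(.transform_int(.dna_to_int(x), rtype))
}

.transform_int <- function(v, rtype) {
  switch(rtype,
         exact = , approximate = , tandem = v,
         reverse = rev(v),
         complement = 5L - v,
         reverse_complement = rev(5L - v))
}

# mirror: seed-left pairs with repeat-right; comp: symbols compare through
# the complement map.
.rtype_mirror <- function(rtype) rtype %in% c("reverse", "reverse_complement")
.rtype_comp <- function(rtype) rtype %in% c("complement", "reverse_complement")

# Orientation search order at equal match position (deterministic tie-break).
.SEARCH_ORDER <- c("exact", "reverse", "complement", "reverse_complement")

# Build the per-pass k-mer lookup: for every seed start a, the first match
# position of each transformed pattern, resolved lazily through an id ->
# positions table. Returns NULL when the sequence is too short.
.kmer_index <- function(s, k) {
  n <- length(s)
  if (n < 2L * k) return(NULL)
  str <- .int_to_dna(s)
  nk <- n - k + 1L
  starts <- seq_len(nk)
  kv <- substring(str, starts, starts + k - 1L)
  keys <- unique(kv)
  id <- match(kv, keys)
  pos_by_id <- split(starts, id) # names are id values as strings

  # Transformed pattern of the seed at a, expressed as an id into `keys`
  # (NA when the pattern does not occur anywhere in the sequence).
  rev_str <- paste(rev(strsplit(str, "", fixed = TRUE)[[1L]]), collapse = "")
  comp_str <- chartr("ACGT", "TGCA", str)
  rc_str <- paste(rev(strsplit(comp_str, "", fixed = TRUE)[[1L]]),
                  collapse = "")
  # reverse(kmer at a) = kmer of rev_str at n-(a+k-1)+1
  rev_kv <- substring(rev_str, n - starts - k + 2L, n - starts + 1L)
  comp_kv <- substring(comp_str, starts, starts + k - 1L)
  rc_kv <- substring(rc_str, n - starts - k + 2L, n - starts + 1L)

  list(
    n = n, k = k, kv = kv,
    pos_by_id = pos_by_id,
    ids = list(exact = id,
               reverse = match(rev_kv, keys),
               complement = match(comp_kv, keys),
               reverse_complement = match(rc_kv, keys))
  )
}

# First match position > b for seed a under each transform; returns
# list(i, rtype) or NULL.
.first_match <- function(index, a) {
  b <- a + index$k - 1L
  best_i <- Inf
  best_t <- NA_character_
  for (t in .SEARCH_ORDER) {
    id <- index$ids[[t]][a]
    if (is.na(id)) next
    pos <- index$pos_by_id[[id]]
    pos <- pos[pos > b]
    if (length(pos) == 0L) next
    i <- pos[1L]
    if (i < best_i) {
      best_i <- i
      best_t <- t
    }
  }
  if (is.infinite(best_i)) return(NULL)
  list(i = as.integer(best_i), rtype = best_t)
}

#' Find the next seed match in a working sequence
#'
#' Scans seeds S[a..b] starting at `seed_start`; for each seed, match
#' positions i run from b+1 upward (the inner loop), and on failure the seed
#' start advances by one (the outer loop). The first position where the
#' k-mer at i equals the seed under some orientation transform is returned;
#' at equal i, exact is preferred over reverse over complement over
#' reverse-complement. An exact match immediately adjacent to the seed
#' (i = b + 1) is labeled `tandem`.
#'
#' @param working A `dna_sequence` or character scalar.
#' @param k Seed length (>= 2).
#' @param seed_start First seed start position `a` to consider.
#' @return `NULL` when no seed has a match (including when the sequence is
#'   shorter than 2k); otherwise a list with `seed` (list `a`, `b`, `k`),
#'   `i` (match position) and `rtype`.
#' @export
find_next_match <- function(working, k = 8L, seed_start = 1L) {
  s <- if (is.numeric(working)) as.integer(working)
       else .dna_to_int(.as_symbols(working))
  k <- as.integer(k)
  stopifnot(k >= 2L, seed_start >= 1L)
  index <- .kmer_index(s, k)
  if (is.null(index)) return(NULL)
  n <- index$n
  a_max <- n - 2L * k + 1L
  if (seed_start > a_max) return(NULL)
  for (a in seed_start:a_max) {
    hit <- .first_match(index, a)
    if (!is.null(hit)) {
      rtype <- hit$rtype
      if (rtype == "exact" && hit$i == a + k) rtype <- "tandem"
      return(list(seed = list(a = a, b = a + k - 1L, k = k),
                  i = hit$i, rtype = rtype))
    }
  }
  NULL
}

#' Look-ahead compression-gain check at a mismatch
#'
#' A mismatch is worth recording only when the `lookahead` symbols beyond it
#' (in the direction of extension, under the occurrence's orientation
#' transform) match exactly; near a sequence boundary where fewer than
#' `lookahead` symbols remain the check fails.
#'
#' @param working A `dna_sequence`, character scalar, or integer code vector.
#' @param seed_cursor Position of the mismatching symbol on the seed side.
#' @param repeat_cursor Position of the mismatching symbol on the repeat
#'   side.
#' @param direction `"left"` or `"right"`: the direction the *seed* is being
#'   extended.
#' @param lookahead Number of symbols that must match exactly (default 3).
#' @param rtype Orientation of the occurrence (default `"exact"`).
#' @return TRUE iff the look-ahead symbols all match.
#' @export
gain_check <- function(working, seed_cursor, repeat_cursor,
                       direction = c("right", "left"), lookahead = 3L,
                       rtype = "exact") {
  direction <- match.arg(direction)
  .check_rtype(rtype)
  s <- if (is.numeric(working)) as.integer(working)
       else .dna_to_int(.as_symbols(working))
  sd <- if (direction == "left") -1L else 1L
  rd <- if (.rtype_mirror(rtype)) -sd else sd
  .la_ok(s, length(s),
         seed_from = seed_cursor + sd, seed_dir = sd,
         rep_from = repeat_cursor + rd, rep_dir = rd,
         lookahead = as.integer(lookahead), comp = .rtype_comp(rtype),
         guard_lo = 0L, guard_hi = 0L)
}

# Core look-ahead comparison: `lookahead` pairs starting at seed_from /
# rep_from, stepping seed_dir / rep_dir; fails at boundaries or when a
# position crosses the guard interval (used for overlap protection).
.la_ok <- function(s, n, seed_from, seed_dir, rep_from, rep_dir, lookahead,
                   comp, guard_lo, guard_hi) {
  if (lookahead == 0L) return(TRUE)
  j <- 0L
  while (j < lookahead) {
    sp <- seed_from + seed_dir * j
    rp <- rep_from + rep_dir * j
    if (sp < 1L || sp > n || rp < 1L || rp > n) return(FALSE)
    if (rp > guard_lo && rp < guard_hi) return(FALSE)
    ss <- s[sp]
    if (comp) ss <- 5L - ss
    if (s[rp] != ss) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

#' Extend a seed match in both directions
#'
#' Starting from a k-symbol match of the seed S[a..b] at `match_start`, both
#' fragments are grown outward, left first and then right (one seed symbol
#' against one repeat symbol per step; for reverse-family orientations the
#' repeat grows on the opposite end). A mismatch is consumed only when the
#' look-ahead gain check passes and the mismatch budget
#' [mismatch_threshold()] at the current extended length admits it; when the
#' budget is full, the direction is suspended and retried after the other
#' direction has grown the repeat. Extension also stops at the sequence
#' boundaries and whenever the two fragments would overlap. Substitutions
#' are tried first at a stalled position; a single-symbol skip on the seed
#' side (deletion) or the repeat side (insertion) is recorded instead when
#' it re-synchronizes the next `lookahead` symbols.
#'
#' @param working A `dna_sequence`, character scalar, or integer code vector.
#' @param seed_start Seed start `a` (1-based).
#' @param k Seed length.
#' @param match_start Match position `i` (the k-mer at i equals the seed
#'   under `rtype`).
#' @param rtype Orientation of the match.
#' @param params An [extend_params()] object.
#' @return A list of class `extension_result`: `seed_span = c(d, q)`,
#'   `repeat_span = c(c, p)`, `n0`, `rtype` (relabeled `approximate` when an
#'   exact match accrued mismatches), and `mismatches` (list of
#'   [mismatch_record()]s with positions in extended-seed coordinates).
#' @export
extend_match <- function(working, seed_start, k, match_start, rtype,
                         params = extend_params(k = k)) {
  s <- if (is.numeric(working)) as.integer(working)
       else .dna_to_int(.as_symbols(working))
  .check_rtype(rtype)
  a <- as.integer(seed_start); k <- as.integer(k)
  i <- as.integer(match_start)
  b <- a + k - 1L
  n <- length(s)
  stopifnot(a >= 1L, b < i, i + k - 1L <= n)
  base_type <- if (rtype %in% c("approximate", "tandem")) "exact" else rtype
  mirror <- .rtype_mirror(base_type)
  comp <- .rtype_comp(base_type)
  la <- params$lookahead
  tmode <- params$threshold_mode

  d <- a; q <- b; cc <- i; p <- i + k - 1L
  m <- 0L
  # mismatch log: op 1=sub, 2=del, 3=ins; abs = absolute seed position (for
  # ins: the seed position the extra symbol precedes); sym in seed frame.
  mm_op <- integer(0); mm_abs <- integer(0); mm_sym <- integer(0)

  thr <- function(n0) mismatch_threshold(n0, tmode)
  # direction states: 1 active, 2 suspended (budget), 3 dead
  st <- c(left = 1L, right = 1L)

  step_dir <- function(dir) {
    # returns TRUE if a symbol pair was consumed; updates state otherwise
    if (dir == "left") {
      sp <- d - 1L
      rp <- if (mirror) p + 1L else cc - 1L
      sdir <- -1L
      rdir <- if (mirror) 1L else -1L
    } else {
      sp <- q + 1L
      rp <- if (mirror) cc - 1L else p + 1L
      sdir <- 1L
      rdir <- if (mirror) -1L else 1L
    }
    # boundary / overlap guards: the repeat lies right of the seed, so the
    # seed may not grow past cc - 1 and the repeat may not grow below q + 1.
    if (sp < 1L || sp > n || rp < 1L || rp > n) { st[dir] <<- 3L; return(FALSE) }
    if (sp >= cc || rp <= q) { st[dir] <<- 3L; return(FALSE) }
    ss <- s[sp]
    cmp_ss <- if (comp) 5L - ss else ss
    advance <- function(seed_too = TRUE, rep_too = TRUE) {
      if (seed_too) { if (dir == "left") d <<- d - 1L else q <<- q + 1L }
      if (rep_too) {
        if ((dir == "left") != mirror) cc <<- cc - 1L else p <<- p + 1L
      }
    }
    if (s[rp] == cmp_ss) {
      advance()
      return(TRUE)
    }
    # mismatch proposed at current extended length
    n0 <- p - cc + 1L
    if (m + 1L > thr(n0)) { st[dir] <<- 2L; return(FALSE) }
    la_args <- function(sfrom, rfrom) {
      # when the repeat steps leftward (toward the seed), its look-ahead
      # positions must stay strictly right of the seed end q
      .la_ok(s, n, seed_from = sfrom, seed_dir = sdir,
             rep_from = rfrom, rep_dir = rdir, lookahead = la, comp = comp,
             guard_lo = 0L,
             guard_hi = if (rdir < 0L) q + 1L else 0L)
    }
    # guard for the seed side growing into the repeat is implicit: seed
    # look-ahead positions approach cc only from the left when dir=right
    seed_guard_ok <- function(sfrom, steps) {
      if (sdir > 0L) sfrom + steps - 1L < cc else TRUE
    }
    # substitution: skip the mismatching pair on both sides
    if (seed_guard_ok(sp + sdir, la) && la_args(sp + sdir, rp + rdir)) {
      mm_op <<- c(mm_op, 1L); mm_abs <<- c(mm_abs, sp)
      mm_sym <<- c(mm_sym, if (comp) 5L - s[rp] else s[rp])
      m <<- m + 1L
      advance()
      return(TRUE)
    }
    # deletion: the seed symbol has no counterpart in the repeat
    if (seed_guard_ok(sp + sdir, la) && la_args(sp + sdir, rp)) {
      mm_op <<- c(mm_op, 2L); mm_abs <<- c(mm_abs, sp)
      mm_sym <<- c(mm_sym, NA_integer_)
      m <<- m + 1L
      advance(seed_too = TRUE, rep_too = FALSE)
      return(TRUE)
    }
    # insertion: the repeat carries an extra symbol before the next seed
    # symbol (seed position d when extending left, q + 1 when extending
    # right, both of which equal the yet-unmatched boundary)
    if (seed_guard_ok(sp, la) && la_args(sp, rp + rdir)) {
      mm_op <<- c(mm_op, 3L)
      mm_abs <<- c(mm_abs, if (dir == "left") d else q + 1L)
      mm_sym <<- c(mm_sym, if (comp) 5L - s[rp] else s[rp])
      m <<- m + 1L
      advance(seed_too = FALSE, rep_too = TRUE)
      return(TRUE)
    }
    st[dir] <<- 3L
    FALSE
  }

  repeat {
    progress <- FALSE
    for (dir in c("left", "right")) {
      while (st[dir] == 1L) {
        if (step_dir(dir)) progress <- TRUE else break
      }
    }
    # revive budget-suspended directions once the repeat has grown enough
    n0 <- p - cc + 1L
    for (dir in c("left", "right")) {
      if (st[dir] == 2L && m + 1L <= thr(n0)) {
        st[dir] <- 1L
        progress <- TRUE
      }
    }
    if (!progress) break
  }

  n0 <- p - cc + 1L
  L <- q - d + 1L
  mism <- .build_mismatches(mm_op, mm_abs, mm_sym, d, L)
  out_type <- rtype
  if (out_type == "exact" && length(mism) > 0L) out_type <- "approximate"
  res <- structure(list(seed_span = c(d = d, q = q),
                        repeat_span = c(c = cc, p = p),
                        n0 = n0, rtype = out_type, mismatches = mism),
                   class = "extension_result")
  .verify_occurrence(s, d, q, cc, p, mism, base_type)
  res
}

# Convert the absolute-position mismatch log into seed-coordinate records,
# sorted by position (insertions at equal P keep log order).
.build_mismatches <- function(mm_op, mm_abs, mm_sym, d, L) {
  if (length(mm_op) == 0L) return(list())
  P <- mm_abs - d + 1L
  ops <- c("substitution", "deletion", "insertion")[mm_op]
  ord <- order(P)
  lapply(ord, function(j) {
    mismatch_record(P[j], ops[j],
                    if (is.na(mm_sym[j])) NA_character_ else .BASES[mm_sym[j]])
  })
}

#' Materialize an occurrence from its seed and mismatch records
#'
#' Reconstructs the excised fragment: the edits are applied to the extended
#' seed in seed coordinates (insertions at position P go before the seed's
#' P-th symbol; P = L+1 appends), then the orientation transform is applied.
#'
#' @param extended_seed Character scalar or integer code vector.
#' @param mismatches List of [mismatch_record()]s.
#' @param rtype Orientation of the occurrence.
#' @return Character scalar: the fragment as it appeared in the working
#'   sequence.
#' @export
materialize_occurrence <- function(extended_seed, mismatches, rtype) {
  v <- if (is.numeric(extended_seed)) as.integer(extended_seed)
       else .dna_to_int(.as_symbols(extended_seed))
  .int_to_dna(.materialize_int(v, mismatches, rtype))
}

.materialize_int <- function(seed_v, mismatches, rtype) {
  .check_rtype(rtype)
  L <- length(seed_v)
  if (length(mismatches) > 0L) {
    out <- integer(0)
    byP_ins <- list(); sub <- rep(NA_integer_, L); del <- rep(FALSE, L)
    for (m in mismatches) {
      if (m$op == "insertion") {
        key <- as.character(m$P)
        byP_ins[[key]] <- c(byP_ins[[key]], match(m$sym, .BASES))
      } else if (m$op == "substitution") {
        sub[m$P] <- match(m$sym, .BASES)
      } else {
        del[m$P] <- TRUE
      }
    }
    for (x in seq_len(L)) {
      ins <- byP_ins[[as.character(x)]]
      if (!is.null(ins)) out <- c(out, ins)
      if (del[x]) next
      out <- c(out, if (!is.na(sub[x])) sub[x] else seed_v[x])
    }
    ins <- byP_ins[[as.character(L + 1L)]]
    if (!is.null(ins)) out <- c(out, ins)
    seed_v <- out
  }
  .transform_int(seed_v, rtype)
}

# Internal invariant: every discovered occurrence must materialize to the
# exact working-sequence fragment it covers. A failure is a programming
# error, never a data error.
.verify_occurrence <- function(s, d, q, cc, p, mismatches, base_type) {
  frag <- .materialize_int(s[d:q], mismatches, base_type)
  if (!identical(frag, s[cc:p])) {
    stop("internal error: occurrence does not materialize to its fragment",
         call. = FALSE)
  }
  invisible(TRUE)
}
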