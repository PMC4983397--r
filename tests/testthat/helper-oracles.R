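# Independent reference implementations used as oracles. These deliberately
# work on character vectors with plain substring comparisons, no k-mer
# indexing, no caching: exhaustive and slow, but direct restatements of the
# search and extension rules.

.oracle_types <- c("exact", "reverse", "complement", "reverse_complement")

.oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_transform <- function(chars, rtype) {
  out <- chars
  if (rtype %in% c("complement", "reverse_complement")) {
    out <- unname(.oracle_comp[out])
  }
  if (rtype %in% c("reverse", "reverse_complement")) out <- rev(out)
  out
}

# Exhaustive first-match scan: all seeds x all positions x all transforms,
# by direct k-mer comparison at every position (no index, no caching).
oracle_find_next_match <- function(s_str, k, seed_start = 1L) {
  n <- nchar(s_str)
  if (n < 2L * k || seed_start > n - 2L * k + 1L) return(NULL)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s_str, starts, starts + k - 1L)
  for (a in seed_start:(n - 2L * k + 1L)) {
    b <- a + k - 1L
    seed <- strsplit(kmers[a], "", fixed = TRUE)[[1L]]
    best_i <- Inf
    best_t <- NA_character_
    for (t in .oracle_types) {
      pat <- paste(oracle_transform(seed, t), collapse = "")
      hits <- which(kmers == pat)
      hits <- hits[hits > b]
      if (length(hits) > 0L && hits[1L] < best_i) {
        best_i <- hits[1L]
        best_t <- t
      }
    }
    if (is.finite(best_i)) {
      rtype <- if (best_t == "exact" && best_i == b + 1L) "tandem" else best_t
      return(list(a = a, b = b, i = as.integer(best_i), rtype = rtype))
    }
  }
  NULL
}

# Reference extension: restates the extension rules directly on character
# vectors. Mismatch records are kept as (op, absolute seed position, symbol)
# and converted at the end.
oracle_extend <- function(s_str, a, k, i, rtype, lookahead = 3L,
                          tmode = "log2_n0") {
  ch <- strsplit(s_str, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  base <- if (rtype %in% c("approximate", "tandem")) "exact" else rtype
  mirror <- base %in% c("reverse", "reverse_complement")
  cmp <- base %in% c("complement", "reverse_complement")
  thr <- function(n0) floor(log2(n0))
  if (tmode == "log2_log2_n0") {
    thr <- function(n0) {
      l1 <- floor(log2(n0)); if (l1 < 1) 0 else floor(log2(l1))
    }
  }
  seedsym <- function(x) if (cmp) unname(.oracle_comp[x]) else x

  d <- a; q <- a + k - 1L; cc <- i; p <- i + k - 1L
  m <- 0L
  recs <- data.frame(op = character(0), abs = integer(0), sym = character(0),
                     stringsAsFactors = FALSE)
  state <- list(left = "active", right = "active")

  # positions of the next seed/repeat pair and step directions for one move
  # in the given seed direction
  geom <- function(dir) {
    if (dir == "left") {
      list(sp = d - 1L, rp = if (mirror) p + 1L else cc - 1L,
           sdir = -1L, rdir = if (mirror) 1L else -1L)
    } else {
      list(sp = q + 1L, rp = if (mirror) cc - 1L else p + 1L,
           sdir = 1L, rdir = if (mirror) -1L else 1L)
    }
  }
  in_bounds <- function(pos) pos >= 1L && pos <= n
  rep_ok <- function(pos) in_bounds(pos) && pos > q
  seed_ok <- function(pos) in_bounds(pos) && pos < cc
  la_match <- function(sfrom, sdir, rfrom, rdir) {
    if (lookahead == 0L) return(TRUE)
    for (j in 0:(lookahead - 1L)) {
      sp <- sfrom + sdir * j
      rp <- rfrom + rdir * j
      if (!seed_ok(sp) || !rep_ok(rp)) return(FALSE)
      if (ch[rp] != seedsym(ch[sp])) return(FALSE)
    }
    TRUE
  }
  do_move <- function(dir, seed_moves, rep_moves) {
    if (seed_moves) {
      if (dir == "left") d <<- d - 1L else q <<- q + 1L
    }
    if (rep_moves) {
      g <- geom(dir)
      if (g$rdir == -1L) cc <<- cc - 1L else p <<- p + 1L
    }
  }

  one_step <- function(dir) {
    g <- geom(dir)
    if (!seed_ok(g$sp) || !rep_ok(g$rp)) {
      state[[dir]] <<- "dead"; return(FALSE)
    }
    if (ch[g$rp] == seedsym(ch[g$sp])) {
      do_move(dir, TRUE, TRUE); return(TRUE)
    }
    n0 <- p - cc + 1L
    if (m + 1L > thr(n0)) {
      state[[dir]] <<- "suspended"; return(FALSE)
    }
    if (la_match(g$sp + g$sdir, g$sdir, g$rp + g$rdir, g$rdir)) {
      recs <<- rbind(recs, data.frame(op = "substitution", abs = g$sp,
                                      sym = seedsym(ch[g$rp]),
                                      stringsAsFactors = FALSE))
      m <<- m + 1L; do_move(dir, TRUE, TRUE); return(TRUE)
    }
    if (la_match(g$sp + g$sdir, g$sdir, g$rp, g$rdir)) {
      recs <<- rbind(recs, data.frame(op = "deletion", abs = g$sp,
                                      sym = NA_character_,
                                      stringsAsFactors = FALSE))
      m <<- m + 1L; do_move(dir, TRUE, FALSE); return(TRUE)
    }
    if (la_match(g$sp, g$sdir, g$rp + g$rdir, g$rdir)) {
      before <- if (dir == "left") d else q + 1L
      recs <<- rbind(recs, data.frame(op = "insertion", abs = before,
                                      sym = seedsym(ch[g$rp]),
                                      stringsAsFactors = FALSE))
      m <<- m + 1L; do_move(dir, FALSE, TRUE); return(TRUE)
    }
    state[[dir]] <<- "dead"
    FALSE
  }

  repeat {
    progress <- FALSE
    for (dir in c("left", "right")) {
      while (identical(state[[dir]], "active")) {
        if (one_step(dir)) progress <- TRUE else break
      }
    }
    n0 <- p - cc + 1L
    for (dir in c("left", "right")) {
      if (identical(state[[dir]], "suspended") && m + 1L <= thr(n0)) {
        state[[dir]] <- "active"
        progress <- TRUE
      }
    }
    if (!progress) break
  }

  mism <- list()
  if (nrow(recs) > 0L) {
    recs$P <- recs$abs - d + 1L
    recs <- recs[order(recs$P), , drop = FALSE]
    mism <- lapply(seq_len(nrow(recs)), function(j) {
      mismatch_record(recs$P[j], recs$op[j], recs$sym[j])
    })
  }
  out_type <- rtype
  if (out_type == "exact" && length(mism) > 0L) out_type <- "approximate"
  list(seed_span = c(d = d, q = q), repeat_span = c(c = cc, p = p),
       n0 = p - cc + 1L, rtype = out_type, mismatches = mism)
}

# Flatten mismatch records for comparison.
mm_table <- function(mism) {
  if (length(mism) == 0L) {
    return(data.frame(P = integer(0), op = character(0), sym = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(P = vapply(mism, function(m) m$P, integer(1)),
             op = vapply(mism, function(m) m$op, character(1)),
             sym = vapply(mism, function(m)
               if (is.na(m$sym)) "-" else m$sym, character(1)),
             stringsAsFactors = FALSE)
}

# Deterministic battery sequence: random backbone, optionally with a planted
# transformed (possibly mutated) copy so matches actually occur.
battery_case <- function(case_seed) {
  n <- 20L + (case_seed * 7L) %% 181L
  base <- gen_random_dna(n, rng_seed = case_seed)
  if (case_seed %% 2L == 0L || n < 60L) return(base$symbols)
  types <- c("exact", "reverse", "complement", "reverse_complement",
             "tandem", "approximate")
  t <- types[(case_seed %/% 2L) %% 6L + 1L]
  len <- min(12L + case_seed %% 20L, n %/% 3L)
  src <- 2L + case_seed %% 5L
  if (t == "tandem") {
    off <- src + len
    t2 <- "exact"
  } else {
    off <- min(n + 1L, src + len + 10L + case_seed %% (n %/% 2L))
    t2 <- if (t == "approximate") "exact" else t
  }
  muts <- if (t == "approximate" && len >= 12L) 1L else 0L
  res <- plant_repeats(base, plant_spec(t2, src, len, target_offsets = off,
                                        mutations = muts),
                       rng_seed = case_seed + 1L)
  res$seq$symbols
}
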