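# Deterministic synthetic-sequence generator: uniform random backbones with
# planted repeat structure (any of the six repeat classes, with optional
# point mutations) plus ground-truth annotations, so repeat recovery and
# losslessness can be validated without external data. All randomness flows
# through one explicit integer seed and the caller's RNG state is untouched.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate an i.i.d.-uniform random DNA sequence
#'
#' @param n Length (>= 0).
#' @param rng_seed Integer seed; identical seeds give identical sequences.
#' @param name Record name.
#' @return A `dna_sequence`.
#' @examples
#' gen_random_dna(10, rng_seed = 1)
#' @export
gen_random_dna <- function(n, rng_seed, name = "random") {
  stopifnot(n >= 0)
  v <- .with_seed(rng_seed, sample.int(4L, n, replace = TRUE))
  dna_sequence(.int_to_dna(v), name = name)
}

#' Describe a repeat to plant into a base sequence
#'
#' A plant spec names a source fragment of the base sequence, an orientation,
#' per-copy point mutations, and the base-coordinate offsets at which the
#' (transformed, mutated) copies are inserted. The number of copies is the
#' number of target offsets.
#'
#' @param rtype Repeat type for the copies.
#' @param source_start,source_len 1-based source fragment in the base
#'   sequence.
#' @param target_offsets Integer vector: base-coordinate positions before
#'   which each copy is inserted (`length(base) + 1` appends). For a tandem
#'   plant use `source_start + source_len` (immediately after the source).
#' @param mutations Either an integer count of random substitutions per copy
#'   (placed away from the copy's ends), or a list of
#'   `list(offset, op, base)` applied to the source fragment before the
#'   orientation transform, with `offset` 1-based within the fragment, `op`
#'   one of `"substitution"`, `"insertion"`, `"deletion"`, and `base` the
#'   seed-frame symbol (ignored for deletions).
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(rtype, source_start, source_len, target_offsets,
                       mutations = 0L) {
  .check_rtype(rtype)
  stopifnot(source_start >= 1L, source_len >= 1L,
            length(target_offsets) >= 1L, all(target_offsets >= 1L))
  if (is.numeric(mutations)) {
    stopifnot(length(mutations) == 1L, mutations >= 0)
    if (mutations > .flog2(max(1L, source_len))) {
      stop("mutation count ", mutations, " exceeds the recoverable bound ",
           .flog2(max(1L, source_len)), " for fragment length ", source_len,
           call. = FALSE)
    }
  }
  structure(list(rtype = rtype, source_start = as.integer(source_start),
                 source_len = as.integer(source_len),
                 target_offsets = as.integer(sort(target_offsets)),
                 mutations = mutations),
            class = "plant_spec")
}

# Apply a mutation list to an integer fragment (seed frame). Returns the
# mutated fragment.
.mutate_fragment <- function(frag, muts) {
  mism <- lapply(muts, function(m) {
    mismatch_record(m$offset, m$op,
                    if (identical(m$op, "deletion")) NA_character_ else m$base)
  })
  .materialize_int(frag, mism, "exact")
}

#' Plant repeats into a base sequence
#'
#' Inserts the transformed (and optionally mutated) copies described by each
#' [plant_spec()] into the base sequence and returns the result together
#' with ground-truth annotations in final coordinates. Copies are pure
#' insertions, processed right-to-left so every target offset refers to the
#' original base coordinates; equal offsets across specs are rejected as
#' overlapping plants.
#'
#' @param base A `dna_sequence` or character scalar.
#' @param specs List of [plant_spec()]s (a single spec is accepted).
#' @param rng_seed Seed used when a spec asks for random mutations.
#' @return List with `seq` (the `dna_sequence` with copies inserted) and
#'   `truth`: a data frame with one row per planted copy (`rtype`, `start`,
#'   `end`, `length`, `mutations`) plus one per source fragment
#'   (`rtype = "source"`), all in final coordinates.
#' @export
plant_repeats <- function(base, specs, rng_seed = 1L) {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  for (sp in specs) stopifnot(inherits(sp, "plant_spec"))
  base_v <- .dna_to_int(.as_symbols(base))
  nb <- length(base_v)

  inserts <- list() # each: offset (base coords), fragment, rtype, nmut, spec
  .with_seed(rng_seed, {
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      if (sp$source_start + sp$source_len - 1L > nb) {
        stop("source fragment of spec ", si, " exceeds the base sequence",
             call. = FALSE)
      }
      src <- base_v[sp$source_start:(sp$source_start + sp$source_len - 1L)]
      for (off in sp$target_offsets) {
        if (off > nb + 1L) {
          stop("target offset ", off, " beyond the base sequence",
               call. = FALSE)
        }
        frag <- src
        nmut <- 0L
        if (is.numeric(sp$mutations)) {
          nmut <- as.integer(sp$mutations)
          if (nmut > 0L) {
            lo <- min(10L, max(2L, sp$source_len %/% 4L))
            hi <- sp$source_len - lo
            if (hi < lo) { lo <- 1L; hi <- sp$source_len }
            at <- sort(sample(lo:hi, nmut))
            for (x in at) frag[x] <- sample(setdiff(1:4, frag[x]), 1L)
          }
        } else {
          frag <- .mutate_fragment(src, sp$mutations)
          nmut <- length(sp$mutations)
        }
        frag <- .transform_int(frag, sp$rtype)
        inserts[[length(inserts) + 1L]] <-
          list(offset = off, frag = frag, rtype = sp$rtype, nmut = nmut,
               spec = si)
      }
    }
  })

  offs <- vapply(inserts, function(x) x$offset, integer(1))
  if (anyDuplicated(offs)) {
    stop("planted copies overlap: duplicate target offsets", call. = FALSE)
  }
  # a copy inserted strictly inside a source fragment would split it
  for (sp in specs) {
    inside <- offs > sp$source_start &
      offs <= sp$source_start + sp$source_len - 1L
    if (any(inside)) {
      stop("target offset ", offs[inside][1L],
           " falls inside a source fragment", call. = FALSE)
    }
  }

  # assemble: insert right-to-left so base offsets stay valid
  out <- base_v
  for (j in order(offs, decreasing = TRUE)) {
    ins <- inserts[[j]]
    out <- append(out, ins$frag, after = ins$offset - 1L)
  }

  # final coordinates: each insertion is shifted by every insertion at a
  # strictly smaller offset
  lens <- vapply(inserts, function(x) length(x$frag), integer(1))
  shift_for <- function(off) sum(lens[offs < off])
  truth <- do.call(rbind, lapply(seq_along(inserts), function(j) {
    st <- offs[j] + shift_for(offs[j])
    data.frame(rtype = inserts[[j]]$rtype, start = st,
               end = st + lens[j] - 1L, length = lens[j],
               mutations = inserts[[j]]$nmut, spec = inserts[[j]]$spec,
               stringsAsFactors = FALSE)
  }))
  # source fragments in final coordinates
  src_truth <- do.call(rbind, lapply(seq_along(specs), function(si) {
    sp <- specs[[si]]
    st <- sp$source_start + sum(lens[offs <= sp$source_start])
    data.frame(rtype = "source", start = st,
               end = st + sp$source_len - 1L, length = sp$source_len,
               mutations = 0L, spec = si, stringsAsFactors = FALSE)
  }))
  truth <- rbind(truth, src_truth)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  name <- if (inherits(base, "dna_sequence")) base$name else "planted"
  list(seq = dna_sequence(.int_to_dna(out), name = name), truth = truth)
}

#' Write a synthetic fixture: FASTA plus ground-truth TSV
#'
#' Generates a random base sequence, plants the given specs, and writes the
#' sequence as FASTA and the ground truth as a tab-separated table with
#' 1-based inclusive coordinates.
#'
#' @param fasta_path,truth_path Output paths.
#' @param n Base-sequence length.
#' @param specs List of [plant_spec()]s (may be empty).
#' @param rng_seed Integer seed.
#' @param name Record name.
#' @return Invisibly, the result of [plant_repeats()].
#' @export
make_fixture <- function(fasta_path, truth_path, n, specs = list(),
                         rng_seed = 1L, name = "fixture") {
  base <- gen_random_dna(n, rng_seed = rng_seed, name = name)
  res <- if (length(specs) > 0L) {
    plant_repeats(base, specs, rng_seed = rng_seed + 1L)
  } else {
    list(seq = base,
         truth = data.frame(rtype = character(0), start = integer(0),
                            end = integer(0), length = integer(0),
                            mutations = integer(0), spec = integer(0),
                            stringsAsFactors = FALSE))
  }
  write_fasta(res$seq, fasta_path)
  write.table(res$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(res)
}
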