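---
title: "Seed-based dictionary compression of DNA sequences: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based dictionary compression of DNA sequences: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedzip)
```

## The problem

A DNA sequence over the four-letter alphabet {A, C, G, T} needs at most 2
bits per base. Genomic sequence is far from random — repeated segments make
up large fractions of most genomes — but the repeats that matter are *long,
infrequent, and imperfect*: copies drift apart by point substitutions and
single-base insertions or deletions, appear reversed, base-complemented, or
reverse-complemented, and sometimes sit immediately next to their source
(tandem repeats). General-purpose text compressors, tuned for short frequent
strings, routinely *expand* DNA. The question this package addresses is how
to spend fewer than 2 bits per base by finding those long variant repeats
explicitly and coding each copy as a reference to a shared dictionary entry
plus a short list of edits.

## The method

Let `S` be the sequence, `l` its length, and `S[i..j]` a substring (all
coordinates in this package are 1-based and inclusive). Compression runs a
seed-and-extend search over a *working sequence* that shrinks as repeats are
excised:

1. **Seed scan.** The seed is the k-mer `S[a..b]`, initially at `a = 1`
   (default `k = 8`). Candidate positions `i > b` are scanned for a k-mer
   equal to the seed under one of four orientations: identity, reverse,
   complement, reverse complement. If the seed has no match anywhere, `a`
   advances by one. At equal `i`, identity wins over reverse over complement
   over reverse complement (a fixed tie-break so output is deterministic).
   An identity match whose copy ends up immediately adjacent to the seed is
   labelled a tandem repeat.
2. **Bidirectional extension.** The seed and its match are grown outward,
   left first and then right, one seed symbol against one repeat symbol per
   step (for mirrored orientations the repeat grows on the opposite end).
   A mismatching pair may be *consumed* as an edit — substitution, or a
   single-symbol skip on one side recorded as an insertion/deletion — but
   only if (a) the next `lookahead` symbols (default 3) match exactly, and
   (b) the running edit count stays within the dynamic budget
   `floor(log2(n0))`, where `n0` is the current extended repeat length.
   When the budget is full, that direction is suspended and retried after
   the other direction has grown `n0`; extension also stops at the sequence
   ends and wherever the two fragments would overlap.
3. **Sweep and excision.** The extended seed becomes a dictionary entry.
   Every further occurrence of it (any orientation, edits under the same
   rules) is excised from the working sequence left to right, each recording
   its type, its position `c` *in the working sequence at the moment of its
   excision*, its length `n0`, and its edits as (P, E, S) triples — position
   within the seed, edit operation, base. Finally the seed itself is excised
   and its position `d` recorded as the entry's last field.
4. **Entropy coding.** When no seed matches any more, the residue (the
   *parsed sequence*) and each dictionary seed are coded with an adaptive
   order-0 arithmetic coder, and everything is serialized into the `.szp`
   container.

Decompression replays the record exactly backwards: decode the residue, then
for each entry in reverse creation order reinsert the seed at `d` and each
occurrence — the transformed, edit-applied seed — at its `c`, in reverse
excision order. Because every position was recorded against the working
sequence as it existed at that step, reverse replay is the unique inverse of
the forward process; `decompress_dna(compress_dna(s))` is an identity the
test suite exercises over hundreds of fixtures.

### Mismatch triples

Edits are stored as (P, E, S): `P` the 1-based position within the extended
seed, `E` the operation (insertion `00`, deletion `01`, substitution `10`;
`11` is unassigned and rejected on decode), `S` the base (A `00`, C `01`,
G `10`, T `11`), omitted for deletions. For seed `GCACTTACT` against repeat
`GCACTTTCT` the single substitution at position 7 encodes — with the
position written in its minimal width — as the 7-bit string `1111011`:

```{r}
m <- sequence_diff("GCACTTACT", "GCACTTTCT")[[1]]
encode_triple(m, mode = "minimal")
```

Minimal-width positions are not self-delimiting, so the container always
uses a fixed per-entry width of `ceil(log2(l(i) + 2))` bits for a seed of
length `l(i)` (the `+2` admits an insertion one past the right end);
minimal mode exists for display and verification of worked examples.

### The cost model

`cost_breakdown()` itemizes the compressed size. In `idealized` mode each
occurrence is charged `ceil(log2 P)` bits for its position (each entry's
`d` is one more position term), `ceil(log2 l(i))` for its length, its
canonical triple bits for edits, and 2 bits for its type; the vocabulary
costs `2 * sum(l(i))` and the residue `2 * l(S_final)`. Bits per symbol
(bps) is the total divided by the input length; 2.0 is the naive baseline.
Two deliberate gaps between this accounting and the real file are reported
rather than hidden:

* the 2-bit type charge cannot index six repeat classes, so the container
  spends 3 bits per occurrence; `idealized` mode keeps the 2-bit convention
  because it is a reporting convention, while the bitstream must decode;
* idealized variable-width fields are not self-delimiting, so the container
  uses fixed widths of `ceil(log2(L_w + 1))` bits against the recorded
  working-sequence length `L_w` of each entry.

`actual` mode therefore reports the true serialized bits, with every
self-delimiting overhead (magic, parameters, record name, sidecar, counts,
padding) under an explicit `header` component; `idealized` is a lower bound
on `actual`, and the test suite audits that `actual` equals the file's exact
bit length on every run.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | seed length, in bases; sensible range 5–11. Short seeds flood the scan with chance matches, long ones miss short repeats; 8 is the default the method was calibrated at. |
| `lookahead` | 3 | exact-match run (bases) required after a consumed mismatch; the compression-gain guard. |
| `threshold_mode` | `log2_n0` | mismatch budget `floor(log2 n0)`; `log2_log2_n0` is the stricter doubly logarithmic alternative, exposed for comparison. |
| `gain_gate` | `TRUE` | commit a dictionary entry only when its itemized container bits undercut the 2 bits/base it saves (see below). |
| `policy` | `reject` | non-ACGT handling; `strip-record` removes such symbols into a sidecar that decompression reinserts, keeping real-world records lossless. |

## Design decisions

**The gain gate.** The literal search loop excises *every* k-mer repeat it
finds. On an i.i.d.-uniform sequence of 100 kb, nearly every 8-mer recurs by
chance, and a short occurrence costs more container bits (position + length
+ type + edits, ~36 bits) than the ~16–24 bits of residue it removes: the
literal loop expands random input several-fold. The method's own principle —
an imperfection is tolerated only when it pays for itself — is therefore
applied at the entry level: an occurrence is swept only if `2·n0` exceeds
its itemized bits, and an entry is committed only if its occurrences'
combined gain exceeds the entry overhead (the seed's coded stream is treated
as a wash against the residue bits its excision saves). With the gate the
dictionary stays empty on random input and bps sits just above 2.0 (the
arithmetic coder's small adaptation cost), while repeat-rich input gains
everything the dictionary can offer. `gain_gate = FALSE` restores the
literal behaviour for study; both paths are lossless and both are tested.

**Seed rejection is cached.** When a seed's entry fails the gate, its k-mer
string is remembered and never re-evaluated, including after later
excisions change the working sequence. In principle an excision could
juxtapose new context that would make a previously rejected seed
profitable; accepting that rare loss keeps the scan near-linear (the cache
is what makes 100 kb random input run in seconds rather than re-extending
tens of thousands of chance matches after every commit).

**Sweep anchoring.** Occurrences of a fixed extended seed are located by
exact k-mer anchors at seed offsets 0 *and* `k`, then aligned outward in
both directions from the anchor. Extension routinely absorbs one or two
flank symbols into the extended seed (they happen to match around the first
copy), so a leading-anchor-only sweep misses every other copy whose context
differs; the second anchor sits inside the repeated material and recovers
them, with the flank noise recorded as ordinary leading edits.

**Look-ahead at the seed's ends.** The open-ended extension requires a full
`lookahead` window after a consumed mismatch and fails the check near
sequence boundaries. A full-seed sweep alignment, by contrast, truncates
the window to `min(lookahead, remaining)`: with the strict rule an edit in
the final one or two seed positions could never be represented, and every
copy behind a flank-absorbed seed end would be lost. `sequence_diff()`
uses the truncated rule for the same reason.

**Arithmetic coder.** Order-0 adaptive over {A, C, G, T} plus a dedicated
end-of-stream symbol; all counts start at 1; counts are halved (rounding up,
so none reaches 0) when the total hits 2^16; 32-bit range coder with
standard underflow (pending-bit) handling, implemented in C++ because the
per-symbol loop is inherently sequential. Order 0 is the minimal faithful
reading of "adaptive arithmetic coding" and keeps the measured gains
attributable to the dictionary rather than to a stronger context model.
Each seed stream and the residue stream use fresh models so streams decode
independently. A binary arithmetic decoder over-reads its 32-bit register,
so end-of-stream detection alone cannot report an exact bit boundary;
`ac_encode` therefore prefixes each stream with a 32-bit payload length,
and the end-of-stream symbol remains as an integrity check inside the
payload. Truncated or corrupt streams raise malformed-stream errors; a
symbol-count cap (the decoder knows each stream's expected length) prevents
corrupt streams from looping.

**Numerical conventions.** "Bits to represent x" is read as `ceil(log2 x)`
for positive integers, with `log2(1) = 0` — the ceiling guarantees a field
wide enough to distinguish values. The mismatch budget uses
`floor(log2 n0)` evaluated at the length *at the moment the mismatch is
proposed* (the budget grows as the repeat grows). All multi-bit container
fields are big-endian; the stream pads to a byte boundary only at file end,
so serialization is bit-exact and byte-identical across runs.

## The synthetic-sequence generator

`gen_random_dna()` draws i.i.d.-uniform bases from one explicit integer
seed (the caller's RNG state is saved and restored). `plant_repeats()`
inserts transformed, optionally mutated copies of chosen source fragments
at chosen offsets and returns ground truth in final coordinates; planted
copies never overlap each other or their sources, and mutation counts are
capped at `floor(log2 length)` so planted structure stays recoverable under
the threshold. The test fixtures cycle through all six repeat classes with
copy lengths of 100 bases, three copies per source, and at most two
substitutions per copy — sizes a curated repeat family in real data might
plausibly show, and comfortably above the ~20-base break-even length of the
cost model.

What the generator deliberately does *not* emulate: GC skew and local
composition bias, nested or overlapping repeat families, transposon-like
hierarchies, microsatellite slippage, and long indel blocks. Passing tests
therefore demonstrate correctness of the search, the coding, and the
container, and effectiveness on idealized repeat structure; they do not
predict compression ratios on real genomic loci, where repeat geometry is
richer and the gains depend on the input.

## Problem sizes in the test suite

The suite validates losslessness over 500+ generated sequences (lengths 0
to 10 kb: mixed planted batteries, plain random, homopolymers, three
repeat densities), checks the entropy coder against its 2-bit bound on a
100 kb uniform sequence, measures effectiveness on ~10 kb fixtures at 0%,
25% and 50% planted density, and cross-checks the search engine against
exhaustive oracles on 1,000 sequences of length ≤ 200. These sizes were
chosen so the full suite completes in about a minute while still covering
every code path at scales where the asymptotics already show.

## Known limitations

* One sequence per container: multi-record FASTA uses the first record
  (with a warning). Cross-sequence dictionaries are out of scope.
* The sweep finds occurrences to the right of the extended seed only
  (matches are discovered at `i > b`, and sweeping rightward keeps the
  seed's own coordinates stable); a copy *upstream* of the first-discovered
  source is picked up later when the scan reaches it, as its own entry.
* A copy whose leading *and* trailing `k` bases are both disrupted has no
  exact anchor and is not swept; it stays in the residue (costing 2
  bits/base, never correctness).
* Indels are single-base: a multi-base gap ends extension rather than
  being recorded as one long edit.
* Greedy, first-match parsing: the dictionary is not globally optimal; a
  later, longer repeat can be shadowed by an earlier, shorter one.
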