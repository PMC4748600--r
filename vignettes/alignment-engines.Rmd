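---
title: "Lane-parallel pairwise alignment: models, engines, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lane-parallel pairwise alignment: models, engines, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanealign)
```

## The model

Pairwise sequence alignment maps the residues of a query `s1[1..m]` onto a
database sequence `s2[1..n]` in an order-preserving way, scoring substitutions
with a matrix (BLOSUM or PAM for proteins, match/mismatch for DNA) and gaps
with an affine penalty. All three classes solve the same dynamic-programming
recurrence over cells `(i, j)`:

```
S[i,j] = T[i-1,j-1] + score(s1[i], s2[j])        (end in a substitution)
D[i,j] = max(T[i-1,j] - open - ext, D[i-1,j] - ext)   (gap in the database)
I[i,j] = max(T[i,j-1] - open - ext, I[i,j-1] - ext)   (gap in the query)
T[i,j] = max(S, D, I)
```

and differ only in boundaries and in where the score is read off:

* **Global (`nw`)** initializes the first row and column with the gap
  function `-(open + k*ext)` and reads `T[m,n]`.
* **Semi-global (`sg`)** initializes the boundaries to zero and takes the
  maximum over the last row and last column, so gaps before the start or
  after the end of either sequence are free.
* **Local (`sw`)** additionally clamps every `T` at zero and takes the
  maximum over all cells.

### Conventions that the recurrence does not fix

* **Gap cost.** A gap of length L costs `open + L*ext`; a length-1 gap costs
  `open + ext`. Under this convention the familiar "open 11, extend 1"
  protein defaults charge 12 for a single-residue gap.
* **Semi-global admits no empty alignment.** The score is the maximum over
  *interior* cells of the last row and column, so two sequences with nothing
  in common get a negative semi-global score rather than zero (an all-end-gap
  "alignment" of nothing is not an alignment). This also keeps end
  coordinates well-defined: they always point at a real cell. Tools that floor
  the overlap score at zero (e.g. `Biostrings::pairwiseAlignment`'s `overlap`
  type) differ from this package exactly when the best non-empty alignment
  scores below zero.
* **Tie-breaks.** Among cells attaining the optimal score, the smallest
  `end_ref` wins, then the smallest `end_query`. Inside a cell, branch
  precedence is S, then D, then I, and a gap-open beats a gap-extend on
  equal values. These choices make every result — including statistics —
  deterministic and comparable across engines.
* **Coordinates.** End positions are 0-based inclusive residue indices.
  Requested tables and last row/column vectors cover interior cells only
  (`i = 1..m`, `j = 1..n`).
* **Empty operands.** `nw` against an empty sequence costs the full gap
  function; `sg` and `sw` return 0 with end indices -1. Vector engines
  delegate these degenerate sizes to the scalar reference.

### Alignment statistics

The library reports `matches` (identical residue pairs), `similar` (pairs
with positive substitution score), and `length` (alignment columns including
gaps) along the tie-broken optimal path. They are computed by an auxiliary
pass that replays the recurrence's maximizing branch over the converged `T`
table under the fixed tie-break rules. Because the pass is a deterministic
function of the table, any engine that reproduces the reference table
reproduces the statistics bit for bit; the substantive cross-engine check is
therefore the table itself. Statistics are bookkeeping integers and are not
clamped to the lane width.

## The vector engines

The three lane-parallel engines emulate a SIMD register of `lanes` integer
elements, each `width` bits wide (`lane_config(width, lanes)`); e.g. 16
lanes of 8 bits emulate a 128-bit register. All lane arithmetic *saturates*:
sums clamp at the representable extremes instead of wrapping.

* **Striped** (`align_striped`) uses the striped query layout: lane `l` of
  segment word `k` holds query position `k + l*t`, `t = ceiling(m/lanes)`.
  A column is computed in one tentative pass that defers the within-column
  vertical dependency, followed by a *lazy-F* loop that re-injects the
  vertical gap contribution across lane boundaries until no retained value
  changes (with per-word early exit). The loop terminates after at most
  `lanes` wrap-around passes, because each wrap shifts the carried gap
  vector by one lane. For local alignment the column holding the running
  maximum is kept by swapping references to an auxiliary column, never by
  copying it.
* **Prefix scan** (`align_scan`) sweeps each column exactly twice — a
  tentative pass ignoring the vertical dependency, then a weighted
  prefix-max propagation of the vertical gap state — so its pass count is
  `2n` for every input, independent of content. That is the source of its
  stable, predictable performance profile.
* **Anti-diagonal** (`align_diag`) evaluates wavefronts `i + j = const`,
  with lanes spanning cells of one anti-diagonal. No query profile is
  needed, and the lane count only chunks the wavefront, so results are
  lane-count-invariant by construction.

### Origin shift (bias) for 8-bit local alignment

Local scores are never negative, so the 8-bit local engines shift the origin
to the unsigned range: the signed floor plus one is treated as zero, making
the full `0..255` range usable, and saturating subtraction prevents
underflow. The ceiling value (255) is reserved for overflow detection. The
shift matters for speed, not correctness: with values resting on a hard
floor at zero, the lazy-F carry dies quickly, while in the signed domain it
decays slowly toward the floor and forces many corrective passes. The
package keeps the unshifted signed mode available (`bias = FALSE`) purely as
a diagnostic; the acceptance suite reports the two mean corrective-pass
counts side by side (about 8 versus about 112 per alignment on the random
protein corpus used there). No such shift is possible for global and
semi-global alignment, whose table values are legitimately negative.

### Overflow detection and the saturation driver

A run is declared *saturated* when any retained table value equals the
domain ceiling (or the floor, for the signed global/semi-global domains), or
when a boundary initialization value is not representable at the current
width. The rule is deliberately conservative: a value that merely *touches*
the ceiling is flagged even if it happens to be exact, so a clipped optimum
can never be returned silently. Internal gap-state values may clamp at the
floor without triggering the flag — a clamped-up candidate either loses the
maximum (harmless) or forces the cell itself to the floor (flagged).

`align_sat` is the escalation driver: it runs at 8 bits and retries at 16
and then 32 bits while the result is saturated. Global alignment at 8 bits
saturates for essentially any realistic input (the boundary alone exceeds
the range), which is why the 16-bit widths are the practical default for
global and semi-global work.

### Query profiles

`build_profile` precomputes, per alphabet symbol, the query's substitution
scores in the striped arrangement at a given width, for reuse across
database sequences (the batch aligner builds one profile per query when the
function name carries the `profile` component). Padding slots beyond the
query length hold the domain floor, so a padded lane can never win a
maximum. The scan engine consumes the same arrangement; the profile's
`layout` tag records the intended engine and is validated at use time.

## Name dispatch

Routines are addressed by underscore-separated function names
(`parse_function_name`, `resolve_function`): class, optional `stats`,
optional `table`/`rowcol`, optional engine, optional `profile`, optional
instruction-set tag, and a trailing width or `sat`. Instruction-set tags are
honoured as lane-geometry presets (register bits / element bits lanes)
rather than hardware requirements — `sse41_128` at width 8 gives 16 lanes,
`knc_512` gives 512-bit geometry, and an omitted tag (`auto`) binds the
widest emulated register, 256 bits. The full registry
(`alignment_function_names()`, ~2300 names) is the domain of the batch
aligner's `-a` option.

## The seed filter

The batch aligner can skip pairs that share no exact substring of at least
`k` residues. The decision structure is a generalized enhanced suffix array:
the sequences are joined with distinct terminator sentinels, suffixes are
sorted lexicographically, and a longest-common-prefix array is attached.
The longest seed shared by two sequences is the maximum, over suffix-array
positions from the two origins, of the minimum LCP between them — computed
in one scan. Construction is by direct comparison sort, chosen for
determinism and simplicity at the corpus sizes this package targets; any
correct suffix-array construction would do, and the test suite pins the
behavior to a quadratic longest-common-substring scan. Sentinels never
participate in a match. The default seed length when the filter is enabled
without an explicit value is `k = 7`, a deliberately small, overridable
default. Seeds are exact residue-index matches after encoding; there is no
substitution-matrix-aware seeding.

## The batch aligner

`run_aligner` (and the `exec/lanealign` script) reads FASTA or FASTQ input
(format auto-detected from the first record character), aligns every query
against every database sequence — or all unordered distinct pairs of a
single file in self-comparison mode — and writes one CSV row per aligned
pair. Output order is sorted by query then database index, so the file is
byte-identical whatever the worker count; parallelism is fork-based with one
task per pair. Throughput is reported in GCUPS (billion table-cell updates
per second, `cells = sum of m*n` over aligned pairs), with the timer
spanning alignment only — sequence loading and index construction are
excluded. The emulated engines execute lane semantics faithfully but in
scalar code, so GCUPS figures here are orders of magnitude below hardware
SIMD implementations; they are accounting, not benchmarks.

## Cross-verification

`cross_verify` is the verification methodology as a first-class harness:
over a seeded random corpus it compares every requested
engine x width x lane-count configuration against the scalar reference —
score, end positions, statistics, and every interior table cell, exactly. A
configuration that saturates at its width is escalated before comparison,
so comparisons always involve representable results. Mismatches are report
content (with the first offending pair and cell), not exceptions.

The random corpus (`random_corpus`) samples residues uniformly over the
matrix alphabet excluding the `'*'` stop symbol, with lengths uniform on a
range that includes zero, so empty and short sequences are always covered.
Uniform sampling exercises the dynamic programming exhaustively but is not
biological: real proteins have skewed residue frequencies, homology
structure, and low-complexity regions, none of which change the cell-exact
equality being verified, but all of which affect throughput and filter
selectivity on real data. Passing the harness demonstrates algorithmic
equivalence, not field performance.

Default problem sizes, chosen to exercise every lane-crossing and
saturation path while keeping a full run inside a few minutes of one CPU:
200 pairs of lengths 0-200 per scoring setting, engines x widths {16, 32} x
lanes {4, 8, 16} (10,800 comparisons per setting), a 1000-pair corpus for
the bias diagnostic, and 500 pairs of lengths up to 64 for the seed-filter
oracle.

## Known limitations

* No tracebacks or CIGAR strings: results are scores, end positions,
  statistics, and tables.
* Only the symmetric both-ends-free semi-global variant is implemented;
  asymmetric (query-only / database-only) free-end variants are not.
* Lane parallelism is emulated for verifiability, not speed; the package is
  a correctness-first implementation of the algorithm family.
* The engines keep the interior table in memory (8 bytes per cell), which
  bounds practical sequence lengths to a few tens of thousands of residues.
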