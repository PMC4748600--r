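# lanealign

Global (Needleman–Wunsch), semi-global, and local (Smith–Waterman)
affine-gap pairwise alignment for protein and DNA sequences, implemented as
a scalar reference engine plus three *lane-parallel* vector engines —
striped, prefix scan, and anti-diagonal — that run over emulated SIMD
registers with saturating fixed-width integer arithmetic. The package is for
people who work on (or teach, or need to verify) vectorized alignment
algorithms: every engine is checked cell-for-cell against the scalar
reference, and the behaviors that make these algorithms subtle — lazy-F
corrective passes, origin-shifted 8-bit arithmetic, overflow detection and
width escalation — are first-class, observable results rather than hidden
implementation details.

## The algorithms

All three alignment classes compute the affine-gap recurrence

    S[i,j] = T[i-1,j-1] + score(q_i, d_j)
    D[i,j] = max(T[i-1,j] - open - ext,  D[i-1,j] - ext)
    I[i,j] = max(T[i,j-1] - open - ext,  I[i,j-1] - ext)
    T[i,j] = max(S[i,j], D[i,j], I[i,j])

with class-specific boundaries: `nw` initializes borders with the gap
function and reads `T[m,n]`; `sg` zeroes the borders and maximizes over the
last row and column (free end gaps); `sw` clamps `T` at zero and maximizes
over all cells. A gap of length L costs `open + L*ext`.

The vector engines evaluate the same recurrence on `lanes` elements of
`width` bits (8/16/32/64) with saturating arithmetic:

* **striped** — Farrar's query layout with a lazy-F loop; 8-bit local mode
  shifts the origin so the full unsigned 0–255 range is usable, which cuts
  corrective passes by an order of magnitude;
* **scan** — exactly two sweeps per column (tentative pass, then weighted
  prefix-max gap propagation), giving input-independent pass counts;
* **diag** — anti-diagonal wavefronts, no query profile needed.

Overflow saturates at the representable ceiling and sets a flag; the `sat`
driver retries at 16 and then 32 bits. Around the engines sit a
Parasail-style function-name dispatcher (`parasail_sw`,
`parasail_sg_stats_scan_avx2_256_sat`, …), an enhanced suffix-array seed
filter, a batch FASTA/FASTQ aligner with GCUPS accounting, and a
cross-verification harness.

## Worked example

```r
library(lanealign)

align_reference("sw", "HEAGAWGHEE", "PAWHEAE", 10, 1, "BLOSUM62",
  want_stats = TRUE)
#> <alignment_result> SW score 17, end (8, 4) [reference engine]
#>   stats: 4 matches, 4 similar, length 5

# the same problem on 16 emulated 8-bit lanes with the origin shift
align_striped("sw", "HEAGAWGHEE", "PAWHEAE", 10, 1, "BLOSUM62",
  config = lane_config(8, 16))
#> <alignment_result> SW score 17, end (8, 4) [striped engine]

# compare all engines against the reference over a seeded random corpus
cross_verify(random_corpus(20, c(0, 100), seed = 42),
  widths = c(16, 32), lanes = c(4, 8))
#> <verification_report> 12 configurations, 720 comparisons over 20 pairs: ALL PASS
```

The local score 17 is the best-scoring subsequence pair (`AW..HE` core);
`end (8, 4)` are 0-based end positions in query and database; the statistics
count identical pairs, positively scoring pairs, and alignment columns along
the optimal path. In the verification report, every configuration's score,
end positions, statistics, and full dynamic-programming table matched the
scalar reference exactly.

Batch use from the shell (self-comparison of one file, seed filter off):

```sh
lanealign -x -a parasail_sw_stats_striped_16 -o 10 -e 1 -m BLOSUM62 \
          -q demo.fasta --output demo.csv
```

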