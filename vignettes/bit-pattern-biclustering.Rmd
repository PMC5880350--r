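---
title: "Bit-pattern biclustering: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-pattern biclustering: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bibitr)
```

## The problem

A bicluster in a binary matrix $M \in \{0,1\}^{m \times n}$ is a pair
$(R, C)$ of row and column subsets such that $M[i, j] = 1$ for every
$i \in R$, $j \in C$ — an all-ones submatrix. In gene-expression work the
rows are genes (attributes), the columns samples, and a one means "this
gene is differentially expressed in this sample"; a bicluster is then a
gene module active in a sample subgroup. The same structure appears in
text mining (word-by-document incidence) and market-basket data.

`bibitr` enumerates biclusters with at least `mnr` rows and `mnc`
columns using the bit-pattern (BiBit) strategy:

1. **Seeding.** For every unordered pair of rows $(r_{i}, r_{k})$ form
   the *joint pattern* $p = r_i \wedge r_k$ (bitwise AND over the $n$
   columns). Keep patterns with at least `mnc` set bits; keep each
   distinct pattern once.
2. **Completion.** For each surviving pattern, collect *all* rows $r$
   with $p \wedge r = p$ — the rows containing the pattern. Discard
   results with fewer than `mnr` rows.
3. **Output.** Each bicluster is the pattern's column set together with
   its containing rows.

Patterns, not row pairs, are the bicluster identity: two pairs with the
same AND pattern would complete to the same bicluster, so duplicates are
dropped at seeding. Deduplication is by *identical* pattern only — a
pattern strictly contained in another reported pattern is still
reported; there is no maximality post-filter. Every reported bicluster
is exact: the method has no noise tolerance, which is why real-valued
data is binarized first.

## Parameters

- `mnr` (rows, $\ge 2$): minimum number of rows per reported bicluster.
  The benchmark convention is 1% of the attributes (e.g. 128 of
  12,800); the CLI accepts `"1%"` directly, resolved as
  `round(pct * m)`.
- `mnc` (columns, $\ge 1$): minimum number of set bits a seed pattern
  needs. `mnc = 0` is rejected: an all-zero pattern is contained in
  every row and describes nothing. The benchmark convention is 2.
- `threshold`: for real-valued input, a cell becomes 1 iff its value is
  *strictly* greater than the threshold (ties to 0). Raising the
  threshold never turns a 0 into a 1.
- `word_width` (32 or 64, default 64): how many columns one machine
  word carries. Patterns over both widths are bit-identical strings, so
  this is purely a performance knob; a dedicated test asserts
  byte-identical output files across widths.
- `workers` ($\ge 1$): worker threads. Output is guaranteed identical
  to the serial run (below).

## The multi-level binarization scheme

For expression matrices with no natural threshold the package follows
the usual pipeline: `standardize()` each gene row to mean zero and unit
variance (population denominator $n$), `discretize_levels()` into
$L = 12$ equal-width bins over the matrix-global range, and
`level_threshold_matrices()` to produce the $L - 1 = 11$ binary
matrices, one per level cut $\ell$: bit one iff level $\ge \ell$. The
matrices are nested, and each is biclustered independently.

Two conventions here were genuinely open and are package decisions:
standardization is per row (the gene-wise convention; a `"column"` axis
is available), and discretization uses equal-width global binning with
the top edge clamped into the last bin. Both are deliberately simple
and documented rather than configurable in depth.

## Encoding and the completion path

Rows are packed least-significant-bit-first into `ceiling(n / W)`
unsigned `W`-bit words (`encode_matrix()`), following base R's
`packBits` byte convention; padding bits are zero. A pair's pattern
then costs `nwords` AND operations plus hardware popcounts.

Seeding enumerates all $\binom{m}{2}$ pairs and deduplicates patterns
in a flat open-addressing hash keyed by the full word sequence, with
chunked arena storage so memory grows smoothly to tens of millions of
distinct patterns.

For completion the package intersects *column-support bitsets* instead
of scanning rows per pattern: for column $j$ let $S_j$ be the set of
rows with a one in column $j$, packed over $\lceil m/W \rceil$ words.
The rows containing pattern $p$ with column set $C$ are exactly
$\bigcap_{j \in C} S_j$, since a row contains $p$ iff it has a one in
every column of $C$. One intersection costs $|C| \cdot \lceil m/W
\rceil$ word operations — far less than testing all $m$ rows against the
pattern — and a popcount of the intersection gives the row count for the
`mnr` filter before any indices are materialized. The direct row-scan
form is kept as `complete_bicluster()`, and a test asserts the two
routes return identical row sets.

## Determinism and the parallel contract

Output order is canonical: biclusters are sorted by pattern, compared
lexicographically on the unpacked column-bit sequence (column 1 first,
`'0' < '1'`). Ties are impossible because patterns are unique. This
single decision makes three stronger properties hold at the byte level
of the output file:

- **Worker invariance.** Seeding workers share one pattern set whose
  membership-test-plus-insert is serialized by a mutex (pattern
  computation and popcount happen outside the critical section);
  completion splits the seed list into near-equal contiguous blocks
  (`partition_range()`, first `total %% workers` blocks one larger)
  with no cross-worker coordination, since completions of different
  patterns are independent.
- **Seed-order invariance.** Which pair first inserts a duplicated
  pattern is scheduling-dependent, but irrelevant: completion
  recomputes the full containing-row set from the pattern alone, and
  that set necessarily includes both seeding rows (their AND contains
  the pattern by construction). `enumeration_order` exists precisely to
  let tests shuffle the pair enumeration and assert nothing changes.
- **Width invariance.** 32- and 64-bit kernels are the same templated
  code over different word types.

The original distributed implementation replicated the encoded matrix
across processes and shipped seed blocks through one-sided
communication; on a single machine both degenerate to shared read-only
memory, and only the partitioning rules and the equivalence contract
are kept.

## The synthetic-data generator

`random_binary_matrix()` draws each cell independently as
Bernoulli($p$) from R's Mersenne-Twister stream (seed required, caller
RNG state restored), then forces optional implanted blocks to one. This
emulates the uniform random benchmark inputs — 12,800 to 51,200
attributes, 100 or 200 samples, 10–15% ones — under an i.i.d. per-cell
reading of "percentage of ones"; an `exact_density` mode places an
exact global count instead for sensitivity checks.

The i.i.d. model makes the benchmark counts predictable. At $p = 0.15$,
$m = 12{,}800$, a fixed column pair is jointly one in a row with
probability $p^2 = 0.0225$, so a 2-column pattern's support is
$\mathrm{Binomial}(12{,}800,\ 0.0225)$ with mean 288 — far above the
`mnr = 128` cut — while any 3-column pattern's support has mean
$12{,}800 \cdot p^3 \approx 43$, far below it. Hence essentially every
one of the $\binom{100}{2} = 4950$ column pairs, and nothing else, is
reported: the expected count is `choose(n, 2)` with overwhelming
probability, and the test suite asserts it exactly for the
12,800×100, 12,800×200 and 25,600×100 configurations. At the critical
density $p = 0.10$ the 2-column support mean *equals* 128, each column
pair clears the cut with probability about one half, and the count must
land near $4950/2 = 2475$; the suite asserts the [2000, 3000] band
rather than a point, since the exact value depends on the RNG stream.

What passing these tests does *not* show: real expression matrices have
correlated rows, blockwise density, and noisy (non-exact) modules. The
generator produces none of these, so recovery on it bounds only the
bookkeeping (enumeration, dedup, filters), not robustness to noise —
which exact-pattern mining intrinsically lacks.

`implant_recovery_case()` builds the sharpest possible recovery
fixture: an all-ones block on an all-zero background, where every
cross-pair pattern is empty and the implant is provably the only
reportable bicluster.

## Numerical and interface decisions

- **ARFF orientation.** Each `@data` line is one biclustering row
  (attribute); each declared ARFF attribute is one sample. A
  `transpose` flag flips this. Only dense numeric or `{0,1}` nominal
  attributes are accepted.
- **Output format.** One line per bicluster:
  `nr;nc;row names...;column names...`, names in ascending index
  order, `\n` line ends, no trailing semicolon.
- **Name synthesis.** Inputs without names get 0-based `"rowI"` /
  `"colJ"`.
- **Degenerate inputs.** Constant rows fail `standardize()` with the
  offending row names; a constant matrix fails `discretize_levels()`;
  non-binary input without a threshold is an argument error (CLI exit
  status 2).
- **Problem sizes in the checks.** The oracle-equivalence suite runs
  200 random matrices up to 40×16 against `bibit_oracle()`, a plain-R
  naive enumerator sharing no code with the packed path; the
  benchmark-scale assertions use the full published dimensions
  (12,800–25,600 × 100–200), which complete in minutes on one core via
  the column-bitset completion.

## A worked example

```{r toy}
x <- rbind(A = c(1, 1, 0, 1), B = c(1, 1, 1, 0), C = c(0, 1, 1, 1),
           D = c(1, 1, 1, 1), E = c(1, 0, 0, 0))
bibit(x, mnr = 2, mnc = 2)
```

The ten row pairs produce six distinct patterns with at least two set
bits, and every one of them completes to at least two rows. Raising
`mnr` to 3 keeps only the three patterns contained in three rows:

```{r toy3}
as.data.frame(bibit(x, mnr = 3, mnc = 2))
```

## Known limitations

- Exact patterns only: one flipped bit splits or destroys a bicluster.
- No maximality filter: subset patterns are reported alongside their
  supersets, matching the reference behavior.
- The seed set is held in memory; extremely dense large matrices (tens
  of millions of distinct patterns) need a few GB.
- Sparse ARFF, string/date attributes and compressed inputs are out of
  scope.
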