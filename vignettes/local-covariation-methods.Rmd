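---
title: "Local covariation for alignment shift-error detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local covariation for alignment shift-error detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locovar)
```

## The model

Covariation statistics were designed to find coevolving residue pairs,
but they are also exquisitely sensitive to a purely artefactual source
of column non-independence: systematic misalignment. When a contiguous
segment of several sequences is shifted by one column, every column in
the shifted region carries, for exactly those rows, the residues of its
left neighbour. Knowing the residue at one shifted column then predicts
the residues at the others, so pairwise covariation rises across the
whole region — while columns flanking the shift, and every pair joining
a shifted column to an unshifted one outside the region, stay at
background. Conservation, the quantity alignment viewers display by
default, barely moves, which is why shift errors survive manual
curation.

`locovar` computes, for each unordered pair of analysis columns:

* **MI** — mutual information of the two columns' residue
  distributions, from plain relative counts (no pseudocounts, no
  sequence weighting);
* **MIp** — MI minus the average-product correction term
  `MI(a,·) · MI(b,·) / mean(MI)`, which removes the background
  component shared through column entropy and phylogeny;
* **Zp** — MIp standardised to zero mean and unit standard deviation
  over all unordered column pairs of the alignment, so scores are
  comparable across alignments.

The **local covariation** of a window of 6 consecutive analysis columns
is the mean Zp over the 15 pairs inside the window. Windows with a
score ≥ 2.0 are peaks; maximal runs of adjacent peaks are regions; an
alignment is categorised by its longest run (`none` / `isolated` /
`adjacent_pair` / `extended`). Averaging over a window suppresses
single-pair excursions (true coevolving contacts typically involve
isolated pairs, often sequence-distant) and amplifies the block
structure a shift produces.

### Assumptions

The statistic assumes columns are identically sampled across rows —
it knows nothing about phylogenetic correlation beyond what APC
absorbs — and it detects *non-independence*, not misalignment per se.
Regions of genuinely coupled positions (e.g. alternative structural
conformations, patch coevolution) also raise local covariation; a peak
is a flag for inspection, not a verdict. This is why the package
provides the curation loop rather than an automatic realigner:
minimising local covariation is not equivalent to correcting the
alignment.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `gap_threshold` | 0 | maximum gap fraction per analysis column. 0 keeps strictly ungapped columns, the conservative reading of "ungapped positions"; configurable because curated alignments with ragged termini may need a small tolerance. |
| `window` | 6 | columns per local-covariation window. |
| `threshold` | 2.0 | peak threshold on the window score (a z-scale quantity). |
| `advisory` | 2.5 | stricter secondary threshold echoed in peak tables; the 2.0 flag is deliberately liberal, 2.5 is the conservative cut. |
| `base` | 2 | MI log base; bits by default. Immaterial to Zp (a z-score is scale-invariant — verified in the tests) but fixes the unit of reported MI. |
| `sd_convention` | `"sample"` | `n − 1` standard deviation in the Zp denominator. With thousands of pairs the choice is numerically irrelevant; it is exposed because the convention is a reporting decision, not a modelling one. |
| `min_identity` | 0.9 | identity floor when mapping an alignment row onto a PDB chain. |

Small alignments (≈10 sequences) have narrower covariation
distributions and can harbour misalignments well below a 2.0 window
score; for such inputs the profile should be read against its own
background rather than the fixed threshold.

## Gap and unknown-residue policy

Ambiguity codes (B, Z, X, U, O, J) are collapsed to a single unknown
symbol. Counting is pairwise-complete: a row enters the count for a
column pair only if it carries a standard residue in both columns.
Under the default strictly-ungapped column filter this matters only
for ambiguity codes; with `gap_threshold > 0` it also governs gaps.
Windows slide over consecutive *analysis* columns, so gap-filtered
columns do not silently break locality; all reported coordinates are
1-based original alignment columns.

Degenerate inputs fail loudly with typed errors: fewer than two
pairwise-complete rows, an all-conserved alignment (mean MI = 0, APC
undefined), zero MIp spread (Zp undefined), fewer analysis columns
than the window (empty profile with a warning, reported as
"too short/too gapped" in screening).

## The synthetic benchmark generator

`simulate_shifted_alignment()` reproduces the planted-shift study
design: a block of 7 columns, each drawing i.i.d. uniformly from a
private 3-letter alphabet chosen so *adjacent* columns share no
letters, prepended to a 200-column host on 200 sequences; a chosen
fraction of rows (3 % = 6 rows, 5 % = 10 rows by default) is shifted
one position to the right across block columns 2–6, leaving flanking
columns 1 and 7 untouched. Ground-truth labels and the pre-shift draw
are recorded.

Two design points deserve emphasis:

* **The vacated column.** Shifting columns 2–6 right by one leaves
  column 2 of a shifted row empty and overwrites the row's original
  column-6 residue. Column 2 is refilled from a reserved *source*
  alphabet disjoint from every column alphabet. Copying column 1
  instead would manufacture covariation between column 1 and the
  shifted region (contradicting the expected flank behaviour), and
  redrawing from column 2's own alphabet would leave column 2
  uncorrelated with the other shifted columns (contradicting the
  expectation that covariation rises between *all* shifted positions).
  The source-alphabet fill is the only rule consistent with both.
  A corollary: because planting destroys one residue per shifted row,
  the exact inverse is not a pure segment shift; the ground-truth
  correcting edit (`correct_planted_shift()`) restores the recorded
  pre-shift content. The general gap-absorbing segment drag for real
  alignments is `apply_shift_edit()`.
* **The host model.** The original demonstration used a curated
  methionine aminopeptidase family as host, which is not
  redistributable; the generator substitutes a synthetic host: each
  column has a dominant residue plus a column-specific set of 3
  tolerated alternatives, and each cell mutates away from the dominant
  residue with probability 0.2. The restricted per-column alphabet is
  the realistic choice — curated family columns admit a handful of
  residues, not an almost-uniform spread over all twenty — and it
  gives the Zp normalisation population (≈21 000 pairs at 207
  columns) a composition resembling a real family. Host columns are
  gap-free and mutually independent.

What the generator does **not** emulate: phylogenetic correlation
between rows, insertions/deletions, multi-column shifts, genuine
coevolving contacts, and gapped regions. Passing the planted-shift
benchmarks therefore demonstrates sensitivity to clean systematic
shifts under idealised sampling, not performance on real families —
on real data the background Zp distribution is heavier-tailed and the
curation loop (clustering, inspection, trial edits) is an essential
part of the method rather than an optional extra.

## Curation machinery

Percent identity over a flagged column range uses pairwise deletion
(gap-vs-anything positions excluded; a pair with no comparable
positions gets distance 1 with a warning — whether gap–gap columns
should count as matches is a viewer-dependent convention, and they are
excluded here). Trees come from classical neighbour joining
(`ape::nj`); negative branch lengths, which NJ can produce on
non-additive matrices, are clamped to zero and flagged. The clade
diagnostic `has_bipartition()` asks whether any internal edge of the
unrooted tree splits exactly the candidate rows from the rest —
deliberately strict, so the post-correction "clade dissolved" check
cannot be satisfied by near-misses.

Segment shift edits require the move to be absorbable by gaps at the
corresponding edge of the edited range, never create or destroy
residues, and keep total width unchanged; blocked moves name the
offending row.

## Numerical choices

The MI matrix is computed via per-symbol indicator cross-products
(an `n × m` indicator per observed residue), which gives exact counts
in vectorised arithmetic; the per-pair sparse counter
(`joint_counts()` + `mutual_information()`) is retained as the
reference path, and the two are held equal to within 1e-12 against a
dense 20 × 20 brute-force tally in the tests. MI values are clipped at
zero to absorb floating-point noise at independence. `0 log 0 = 0`
throughout. NJ ties are resolved by `ape`'s deterministic agglomeration
order; the screening report sorts inputs lexicographically so batch
runs are reproducible.

## Problem sizes in the test suite

The end-to-end checks run the full study condition — 200 sequences ×
207 columns — across 20 replicate seeds at shift fractions
{0, 0.03, 0.05}, with the oracle-equivalence check covering ≈1 000
random column pairs; the whole suite completes in a couple of minutes
on a single CPU. `scripts/acceptance.R` re-runs the same design from
scratch under a user-supplied seed.

## Known limitations

* Covariation needs depth: below a few dozen sequences the Zp
  distribution narrows and the fixed 2.0 threshold loses meaning.
* No sequence weighting: heavily redundant alignments overweight
  their dominant clade in the counts.
* The screening categories count *window* runs, a coarse proxy for
  region extent; two overlapping misalignments merge into one region.
* Structure annotation maps one alignment row to one chain with a
  simple global alignment; it will refuse (identity floor) rather
  than guess when the row and structure diverge.
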