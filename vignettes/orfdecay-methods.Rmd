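---
title: "Methods: inferring de novo gene origin from non-coding homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring de novo gene origin from non-coding homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfdecay)
```

## The inference

A gene is a candidate for *de novo* origin when three things hold at once:
it is a lineage-restricted orphan at the protein level, it has long,
high-identity homology to genomic sequence that does **not** code, and the
non-coding homologs share the same ORF disruptions — evidence that the
common ancestor of gene and homologs was itself non-coding, and that the
coding state is derived. `orfdecay` operationalizes each step so that every
claim is a computation over explicit inputs.

### Candidate filtering

All thresholds are strict inequalities: a protein hit argues against orphan
status when its E-value is at most `e_max` (default `1e-4`) **and** its
percent identity is strictly greater than `identity_min` (default 35); a
genomic fragment is carried forward when its alignment length is strictly
over 4000 bp and its identity strictly over 80. Boundary behaviour is
unit-tested. Identity is evaluated per hit (per-HSP), not over the merged
query coverage; chromosome class (autosome / chrX / chrY) is supplied as an
explicit subject-to-class map, because assembly naming conventions are not
reliable enough to parse.

### Putative-ORF reconstruction

Each reference coding exon is aligned semi-globally (exon global, region
local) against both strands of the candidate region with affine gap costs.
Scoring defaults: match +2, mismatch −3, gap open 5, gap extend 2, where a
gap of length L costs `open + L * extend`; `N` scores 0 against everything,
so unknown bases can neither create nor destroy identity. Placements below
a 60% identity floor are discarded; additional placements (tandem copies)
are found by recursively splitting the region around each accepted
placement, which is deterministic and cannot report overlapping placements
of one exon.

Placements are chained collinearly: all exons of one putative ORF must lie
in consistent order with one shared orientation. Chains are seeded from the
exon-1 placements in reading order and extended greedily with the nearest
unused placement of each following exon — one chain per locus copy. When at
least one chain covers every exon, partial chains are treated as placement
noise and dropped; otherwise the best partial chain is reported with its
missing exons flagged. ORFs are labeled `a`, `b`, ... by region coordinate.

### Disabler scanning and artificial translation

The joined ORF is compared against the reference spliced CDS column by
column. Artificial translation continues through internal stop codons —
the point is to *display* disablement, not to predict a protein — and
codons containing `N`, another ambiguity code or a gap render as `X`.
Coding status is decided from the disabler list, never from the
translation string.

Offset convention: a disabler's `ref_nt_offset` is the 0-based offset of
the affected codon's first base in the reference spliced CDS (start codon
= offset 0). Under this convention in-frame premature stops always sit at
multiples of 3. Positions in the homolog are projected into reference
coordinates through the alignment; positions inside homolog-only
insertions map to the preceding reference base and are flagged. The frame
is tracked through indels as the signed sum of upstream indel lengths mod
3; a premature stop is classified as a *substitution* only in net-frame-0
context at a non-inserted position — anything else is a *frameshift stop*.
Indels with length ≡ 0 (mod 3) preserve frame and are recorded as notes,
not disablers.

Enabler scanning is the same machine run in reverse: the derived coding
sequence defines the frame, the non-coding relative is scanned against it,
and each disabler found corresponds to one enabling change in the derived
lineage. On synthetic data this inverts `disable_locus()` one-to-one.

### Comparative synthesis

Disablers are matched across taxa by `(type, ref_nt_offset)`, exact by
default (a ±3 nt tolerance window is available for diverged real data,
where projection may wobble around indels). Rows present in every column
with known state are flagged ancestral candidates. Gain/loss of coding
ability is reconstructed by small parsimony (Sankoff DP with unit change
cost) on the binary coding/non-coding character; `unknown` and `absent`
taxa are missing data (either state at zero cost) rather than a third
state, since gene *presence* is a different character from coding
*ability*. All minimal labelings are enumerated (capped at 256) and the
events common to every minimal solution are reported separately, so an
ambiguous reconstruction cannot masquerade as a certain one. No dating is
computed; events are rendered relative to user-named splits.

### Phylogenetics

K2P and TN93 distances are computed from their closed forms with pairwise
deletion (columns with a gap or ambiguity in either sequence are excluded
for that pair), which maximizes usable signal on short alignments.
Saturation (a non-positive logarithm argument) is an error, never a silent
`NaN`. Trees are built by canonical neighbor-joining; negative branch
lengths are clamped to zero and the clamped edges recorded. Bootstrap
support resamples alignment columns with replacement under a caller-
supplied seed; replicates whose resample is saturated are skipped and
counted. Distance-NJ is used rather than a likelihood tree search: it is
deterministic, fast enough to test exhaustively, and uses the same distance
family as the simulator, so topology agreement on clean synthetic data is
a meaningful check. The output metadata states the method.

### Dot-plots and synteny

A dot at `(i, j)` means the w-bp windows starting at those (0-based)
positions differ at no more than `max_mismatch` sites. The implementation
scans diagonals with cumulative sums — O(n·m) elementwise, vectorized —
and is tested against a per-window brute-force oracle. Repeat segments
merge same-diagonal runs of off-diagonal dots with a configurable gap
tolerance; because no principled segment-calling rule exists for reading
lengths off a dot-plot, `min_segment` and `gap` are free parameters.
Synteny blocks are maximal runs of shared anchors whose order in the
second list is monotone and whose relative strand pattern matches the run
direction (increasing/equal = forward, decreasing/flipped = inverted);
pseudogene-suffix normalization (`P`/`_P`) is opt-in.

## The synthetic-data generator

The generator emulates the history the pipeline is designed to detect: a
random multi-exon coding locus (ATG ... stop, no internal in-frame stop;
random introns and flanks), disabled by planted minimal edits, evolving
along a tree under a K2P substitution process (`kappa` = 2 by default, the
package's standing choice for primate-scale data) with optional geometric
indels, transposed or duplicated between compartments on designated
branches, and optionally re-enabled on one branch. Branch lengths are
expected substitutions per site; the per-branch substitution probabilities
are the exact K2P transition probabilities, so simulated divergence is
calibrated against the estimator it will be measured with (mean pairwise
K2P at path length 0.2 is unbiased in the test suite).

Design choices that matter for interpretation:

* **Neutral by default.** The root locus and all non-enabled copies evolve
  with no selective constraint. The ORF-integrity rule applies only to
  copies touched by `enable_branch`: reversion restores the planted codons
  (and repairs any other ORF-breaking change accumulated while
  non-coding), and afterwards any mutation that would re-disable the ORF
  is undone. This "purifying selection" is a hard rejection rule, not a
  fitness model — the simplest mechanism guaranteeing that a coding leaf
  exists for positive tests.
* **Indels never straddle exon boundaries** (each segment mutates
  independently), which keeps truth offsets well-defined; enabled copies
  accept indels only outside exons.
* **Truth is recorded at planting time** in reference-CDS coordinates and
  is *not* updated when later substitutions happen to erase a planted
  disabler. At 0.05 substitutions/site a planted stop codon survives with
  probability ≈ 0.89–0.91 (single-codon K2P arithmetic), so recovery
  *including codon survival* plateaus near 0.91–0.94 for the demo mix.
  The package therefore reports two numbers: exact-position recovery
  **conditional on the disabler still being present** (presence decided by
  direct codon inspection, independent of the scanner) — the quantity that
  actually measures scanner accuracy, 1.0 in the shipped validation — and
  the unconditional rate, for transparency.

What the generator does **not** emulate: gene conversion and NAHR between
amplicon copies, codon-usage and GC realism, splice-site evolution,
rate heterogeneity across sites, and population-level processes. Passing
the synthetic validation therefore shows the *inference machinery* is
correct under its own model; it does not certify behaviour on real
Y-chromosome amplicons, where conversion between copies can homogenize
disablers and mimic shared ancestry.

## The demo scenario and problem sizes

The packaged scenario uses five taxa (Hosa, Patr, Gogo, Mamu, Caja) on a
fixed tree, a ~4.4 kb four-exon locus (exons 90/120/90/60 bp, 1.2 kb
introns), four planted disablers (start loss; premature stops at CDS
offsets 42 and 81; stop loss), autosome-to-Y transposition on the
ape+monkey stem, enabling on the ape stem and a tandem Y duplication on
the Hosa branch. Divergence is substitution-only; the indel machinery is
exercised separately in unit tests, because indel-free demo copies make
every truth offset exactly recoverable and keep the alignment stage
honest about what it is being scored on. Validation sizes: 50 seeds for
divergent recovery, 100 seeds of 10 kb loci for NJ topology recovery,
500 bootstrap replicates, 100 random trees (≤ 6 leaves) for the parsimony
oracle, 50 random pairs (≤ 400 bp) for the dot-plot oracle, and 30 random
pairs (≤ 300 bp) for the alignment DP oracle — all chosen so the full
validation runs in about a minute on one CPU while keeping Monte-Carlo
error well below the asserted margins.

## Known limitations

* The exon aligner can, at a few percent divergence, trade a terminal
  mismatch cluster for a short gap and thereby shift an exon-edge disabler
  call (observed for a stop-loss adjacent to the 3' exon boundary). The
  CDS-level global alignment is robust to this; region-level placement is
  scored accordingly in the validation.
* Premature-stop classification inside homolog-only insertions is reported
  as a frameshift-class stop with a note, since there is no reference
  codon to compare against.
* The shared-disabler tolerance default (0 nt) is right for synthetic and
  closely related data; diverged real data with indels near a disabler may
  need the ±3 window, at the cost of occasional over-merging.
* NJ/K2P stands in for a likelihood tree search; on saturated or strongly
  heterogeneous real data a dedicated ML tool should be preferred and its
  tree imported for the comparative stage.
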