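---
title: "Detecting and characterizing exon-skipping events with gess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing exon-skipping events with gess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gess)
```

## The problem

A cassette (middle) exon of a tri-exon arrangement can be spliced into the
mature transcript (the *inclusion isoform*) or skipped (the *skipping
isoform*). Both isoforms usually coexist in one cell, and which one
dominates is regulated by splice-site strength, splicing factors bound
near the exon–intron boundaries, and chromatin features. `gess` finds such
events directly in spliced RNA-seq alignments, without annotation, and
quantifies the isoform balance and its candidate determinants.

## The splice-site link graph

Alignment records are split into two evidence classes. *Spliced reads*
(CIGAR `N` operators) are split at their intron gaps; every gap whose read
anchors at least `min_junction_overhang` (default 6) aligned bases on each
side contributes one support count to a junction. *Constitutive reads*
(no `N`) contribute their aligned span to a per-base coverage track.
Multi-mapped records (secondary flag or `NH > 1`), unmapped records,
low-MAPQ records and reads with too many ambiguous bases are discarded,
with every filter count logged. All internal coordinates are 0-based,
half-open; SAM's 1-based convention is converted exactly once at the I/O
boundary, which removes the off-by-one ambiguity that plagues junction
arithmetic.

Each junction boundary becomes a splice-site node. A junction with support
at least `min_junction_support` (default 8, met *at* 8 — the parameter
names the smallest accepted support) becomes a dotted intron-gap edge,
oriented donor→acceptor by the GT‑AG consensus: `GT..AG` on the forward
strand is `+`, the reverse-complement pattern `CT..AC` is `-`, anything
else is `unknown` and retained but flagged. Splice-site coordinates
partition the chromosome into segments; a segment becomes a solid exon-gap
edge when its mean constitutive coverage is at least
`min_exon_signal_ratio` (default 3.0, inclusive) times the larger of its
two flanking segments' means. Three numerical choices here were genuinely
open and are fixed as follows:

* the background is the *maximum* of the two flank means (conservative:
  a segment must beat its worse neighbour);
* a positive segment over zero-coverage flanks has ratio +∞ and is
  accepted — the limiting case of an isolated expressed exon;
* mean depth (not summed tags) is used, making the ratio invariant to
  segment length; segments longer than `max_exon_length` (default
  5000 bp) are never called exons, which keeps whole-intron coverage
  blobs out of the graph.

Terminal segments use the single available flank, or a window of the
segment's own length outside the node range where one exists. Segment
formation is deliberately permissive about node kinds — donor/acceptor
role consistency is enforced by the event scan, not the graph — so the
graph stays a faithful summary of the evidence and the pattern match
stays strict.

## Event scanning

An exon-skipping event is a six-node sub-graph, in genomic order
`n1 < … < n6`: solid edges `(n1,n2)`, `(n3,n4)`, `(n5,n6)`; dotted edges
`(n2,n3)`, `(n4,n5)` (the flanking introns) and `(n2,n5)` (the skip
junction). Rather than testing all C(n,6) sextets, the scanner seeds from
each dotted edge as a skip candidate and enumerates nested intron pairs
and matching exon edges; equality with exhaustive enumeration is a tested
property (`extents = "all"`), not an assumption. When several solid edges
reach an outer boundary, the default report takes the shortest — the
method reports tri-exon sites, not full transcripts. Events on mixed
known strands are rejected; `unknown`-strand events are reported with
roles assigned as if `+`, flagged rather than discarded. Only
single-middle-exon patterns are emitted; multi-exon skipping is outside
the pattern definition.

## The two-isoform ψ model

Only junction-spanning reads enter the likelihood: inclusion reads span
either flanking junction, exclusion reads span the skip junction.
Middle-exon body reads are excluded deliberately — using them would
require a model of constitutive coverage, and the junction counts already
identify ψ. The two isoforms present different numbers of junction-
spanning start positions: with read length L, overhang v and middle-exon
length m, the skipping isoform offers `L − 2v + 1` positions and the
inclusion isoform up to twice that, less when m is short enough that one
read can span both junctions (such positions count once). Both counts are
obtained by direct enumeration of start positions, capped by the flanking
exon lengths.

Given mixture fraction ψ, a junction read is inclusion-type with
probability `p(ψ) = ψ c_i / (ψ c_i + (1−ψ) c_s)`; the likelihood is
binomial, the prior Beta(α, β) (default uniform), and the posterior is
integrated by trapezoid quadrature on a 16 384-interval grid — fully
deterministic and testable, unlike a sampler, and accurate to below 1e−6
against the conjugate Beta closed form that arises when `c_i = c_s`.
Zero-count events return the prior with a full-width interval; events
with fewer than 10 junction reads are flagged low-confidence rather than
suppressed. Group thresholds are inclusive: ψ ≥ 0.7 → IIDG, ψ ≤ 0.3 →
SIDG.

## Maximum-entropy splice-site strength and competition

Donor sites are 9-mers (3 exonic + 6 intronic bases), acceptor sites
23-mers (20 intronic + 3 exonic). The signal model is the maximum-entropy
distribution matching the training set's positional marginals and all
adjacent-pair marginals (constraint order {1,2}). With these chain-
structured constraints the solution is a first-order heterogeneous Markov
field, so it is fitted by sequential iterative proportional scaling with
exact marginals from forward–backward message passing; the 4^23 acceptor
space is never enumerated, and the fit reaches marginal errors near
machine precision in one or two sweeps. With order-{1} constraints the
model provably factorizes into the positional-marginal product (a PWM),
which is both a fast path and a closed-form correctness check. Scores are
log₂(P_signal/P_background) with probabilities floored at 1e−12;
the background is the position-independent composition of a decoy set
(uniform if none is given). Models are trained from user-supplied site
sets — by default, all sites of the detected events themselves — rather
than shipping fixed parameter tables: the framework, not any particular
weight set, is the method. Richer constraint sets (as used by full
published acceptor models) are accepted through `constraint_order` but
are not the default.

The competition score `S = [s(upI_ss5) − s(dnI_ss5)] + [s(dnI_ss3) −
s(upI_ss3)]` is signed so that weaker middle-exon-flanking sites give
larger S: the outer pair upI_ss5–dnI_ss3 then outcompetes the middle
pairings and favors the skipping isoform. S is invariant to adding a
constant to all four scores. Group comparisons report mean and standard
deviation per site class per group (the dispersion printed in parentheses
in the summary is an SD, not an SE) and a two-sided Mann–Whitney p-value.
For group sizes up to 8 the rank-sum null distribution is computed
exactly by dynamic programming over doubled, tie-averaged ranks — exact
even under ties, where the textbook exact method refuses — and the
two-sided p is `min(1, 2·min(P≤, P≥))`; larger groups use the normal
approximation with tie-corrected variance and no continuity correction.

## Boundary-region profiles

Each event defines eight segments: from every splice site, 50 bp into the
adjoining exon and 100 bp into the adjoining intron, in transcription
orientation. Segments never cross their feature's opposite boundary; when
two segments share a short feature (both middle-exon exonic segments, or
both segments of one intron) the feature is split at its midpoint so
densities stay attributable to one boundary. Signal density is
`count / length × (1e7 / library_size)` — reads-per-ten-million per base —
counting any read that overlaps a segment by at least one base; the
normalization constant cancels in every between-group comparison, and an
identically normalized input control can be subtracted (values may then
be negative). Per factor, the eight per-group mean densities are
standardized within group (mean 0, SD 1) and the Pearson r of the two
Z-profiles measures pattern similarity; factors are ranked by ascending
|r|. Z-scores are computed per factor over the eight segments (not over
events); the event-wise alternative can be built from the returned
densities. Motif-hit tables are consumed from external predictors — motif
scoring itself is out of scope — normalized to hits per base, and tested
per factor × segment with the same Mann–Whitney machinery; heat values
are −log₁₀(p) signed positive toward SIDG enrichment, with optional
Benjamini–Hochberg q-values across the grid.

## The synthetic-data generator

`simulate_locus()` builds a five-exon gene: the tri-exon core plus two
constitutive flanking exons, which are required because the six-node
pattern needs outer splice-site nodes, and nodes only arise from observed
junctions. Defaults model a compact vertebrate-like locus chosen once:
core exons 150/120/150 bp, introns 300 bp, flank exons 150 bp, flank
introns 300 bp, true ψ 0.5, 50× depth, 100 bp reads. Splice sites follow
consensus profiles (donor `CAG|GTAAGT`, acceptor pyrimidine tract +
`…AG|G`) with the invariant GT/AG fixed; "weak" sites keep GT/AG but draw
every other position uniformly, which is how group effects are planted
(low-ψ loci get weak dnI_ss5/upI_ss3 when requested). Reads choose an
isoform with probability proportional to ψ × (start positions on the
inclusion isoform) versus (1−ψ) × (skipping positions), then start
uniformly — exactly the generative model the ψ estimator assumes, so
parameter recovery is a meaningful check of the inference, not of shared
code. Loci are concatenated with ≥1 kb spacers actively scrubbed of GT
and AG dinucleotides; all randomness flows from one seed and identical
seeds give byte-identical FASTA/SAM/TSV output.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: sequencing errors (off by default; alignment
is consumed, not performed), GC and positional coverage bias, fragment-
length distributions for paired ends, overlapping genes, recursive or
non-canonical splicing, and expression-level variation across loci.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 200 simulated loci at 50×
(plus 50 constitutive controls) for exact-boundary recovery; 40 loci per
true-ψ stratum {0.1, 0.3, 0.5, 0.7, 0.9} at 450× so every event carries
at least 500 junction reads; a 100-case count grid for the conjugacy
check; toy sequence spaces up to 4 letters × 3–4 positions for the maxent
oracle; 100 random graphs of up to 14 nodes for the scanner oracle; all
64 group-size pairs up to 8×8 for Mann–Whitney exactness; and 100 loci
per group at 150× for the weak-site competition-direction experiment.
These sizes make every stochastic check comfortably stable under its
stated threshold while keeping a full run in the minutes range on one
core.

## Known limitations

Paired-end mates are treated as independent reads (read-level, not
fragment-level counting). Only single-cassette patterns are detected; the
ψ model is strictly two-isoform. Effective-position counts cap at the
reported flanking exon lengths and do not follow reads across further
junctions, a negligible effect unless flanking exons are shorter than the
read length. The competition analysis assumes the four sites are scored
on a common model per site kind; scores from models trained on different
site sets are not comparable across runs.
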