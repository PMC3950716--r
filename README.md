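# gess — graph-based exon-skipping scanner

`gess` detects cassette-exon (exon-skipping) alternative-splicing events
*de novo* from splicing-aware RNA-seq alignments — no gene annotation
required — and characterizes what drives the choice between the two
isoforms at each event. It is aimed at transcriptomics analysts who have
spliced alignments (TopHat/HISAT-style SAM/BAM with `N` CIGAR operators)
and want, per tri-exon site: exact exon boundaries, the inclusion fraction
ψ, splice-site strengths, and boundary-region signal profiles.

## The method

**Detection.** Spliced reads are split at their intron gaps; each gap
boundary becomes a splice-site node. Two nodes are linked by a *dotted*
(intron-gap) edge when at least 8 spliced reads support the junction
(GT‑AG consensus orients the intron), and by a *solid* (exon-gap) edge
when the mean constitutive-read coverage of the segment between them is at
least 3.0× the flanking background. A skipping event is a six-node
sub-graph: three solid edges (the tri-exon pattern), dotted edges for both
flanking introns, plus a dotted *skip* edge joining the outer exons
directly. Sub-graphs missing any required edge — intron retention,
alternative 5′/3′ sites — never match.

**ψ estimation.** For each event, reads spanning the upstream‑exon/middle
or middle/downstream junctions are *inclusion reads*; reads spanning the
outer‑exon junction are *exclusion reads*. With ψ the fraction of
inclusion transcripts, a junction read is inclusion-type with probability

    p(ψ) = ψ·c_inc / (ψ·c_inc + (1−ψ)·c_skip)

where `c_inc`, `c_skip` count the junction-spanning read start positions
on each isoform (the two-isoform length rescaling). The posterior over ψ
under a Beta prior is integrated on a deterministic grid; events with
ψ ≥ 0.7 form the inclusion-isoform-dominated group (IIDG), ψ ≤ 0.3 the
skipping-isoform-dominated group (SIDG).

**Splice-site competition.** Each event's four sites — upI_ss5, upI_ss3
(upstream intron donor/acceptor), dnI_ss5, dnI_ss3 (downstream intron) —
are scored as log₂-odds under a maximum-entropy sequence model (9-mers for
donors, 23-mers for acceptors; positional and adjacent-pair marginals
constrained) against a background composition. The competition score

    S = Δ_ss5 + Δ_ss3,   Δ_ss5 = s(upI_ss5) − s(dnI_ss5),
                         Δ_ss3 = s(dnI_ss3) − s(upI_ss3)

is larger when the middle-exon-flanking sites are weaker, i.e. when
pairing upI_ss5 with dnI_ss3 — the skipping isoform — is favored. Group
differences are tested with exact (small-n) or tie-corrected Mann–Whitney.

**Region profiles.** Eight segments per event (50 bp into each exon,
100 bp into each intron from every site) carry normalized signal densities
(ChIP-seq-style tracks, input-subtractable), per-factor Z-score profiles
compared between SIDG and IIDG by Pearson r, and Mann–Whitney motif-hit
enrichment with signed −log₁₀(p) heat values.

A seeded simulator generates toy genomes, tri-exon loci with known true ψ,
spliced SAM reads and truth tables, so the whole pipeline is testable
offline.

## Worked example

```r
library(gess)

ds <- simulate_dataset(5, true_psi = c(0.2, 0.4, 0.5, 0.6, 0.8), seed = 42,
                       out_dir = file.path(tempdir(), "demo"))
out <- file.path(tempdir(), "demo_out")
ev  <- run_detect(ds$files[["reads"]], ds$files[["genome"]], out)
#> records: 1800 (spliced 1078, constitutive 722, discarded 0, bad CIGAR 0)
#> graph: 40 nodes, 25 intron edges (of 25 junctions), 19 exon edges
#> events: 5
psi <- run_psi(file.path(out, "events.tsv"), ds$files[["reads"]], out)
psi[, c("event_id", "inclusion_reads", "exclusion_reads", "psi_mean", "group")]
#>   event_id inclusion_reads exclusion_reads psi_mean        group
#> 1  EV00001              24              38    0.248         SIDG
#> 2  EV00002              40              33    0.383 intermediate
#> 3  EV00003              54              25    0.521 intermediate
#> 4  EV00004              60              22    0.577 intermediate
#> 5  EV00005              80              10    0.791         IIDG
```

All five planted loci are recovered with exact boundaries, and the
posterior mean ψ tracks the simulated truth (0.2, 0.4, 0.5, 0.6, 0.8):
the 0.2 locus is called SIDG, the 0.8 locus IIDG, the rest intermediate.
`run_strength()` then scores the four splice sites of each event and
writes the per-event competition score S; `run_profile()` computes the
eight boundary segments and density/Z-score/enrichment tables.

A shell front end wraps the same stages:

```sh
Rscript inst/scripts/gess simulate --out-dir demo --n-loci 5 --seed 42
Rscript inst/scripts/gess detect --alignments demo/reads.sam \
    --genome demo/genome.fa --out-dir demo
```

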