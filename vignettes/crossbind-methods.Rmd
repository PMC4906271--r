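---
title: "Methods: cross-species comparison of ChIP target repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of ChIP target repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbind)
```

## The problem

A Hox transcription factor such as Ultrabithorax (Ubx) specifies
third-thoracic-segment identity across insects, yet the organs it builds
there differ radically — a club-shaped haltere in flies, full hindwings in
bees and silkmoths. One way to ask where that divergence comes from is to
compare the factor's direct target repertoire between species: ChIP peaks
are assigned to putative target genes, the per-species target sets are
projected through ortholog tables onto a common reference gene space, and
the shared versus species-specific parts of the repertoire are profiled
functionally and at the sequence level. `crossbind` implements every
computational step of such a comparison, from file parsing to the anchored
comparison of transcription-factor binding-site arrays around the ChIP
anchors, plus a seeded generator of paired synthetic "species" with known
ground truth for each step.

## Coordinate and parsing conventions

All internal coordinates are 0-based half-open on the genome's forward
orientation. BED input is taken verbatim; GFF3 (1-based closed) is shifted
on read (`start-1`, `end`) and shifted back on write, so both round trips
are bit-exact. An optional seventh BED column carries the peak summit as an
offset from the peak start; a missing summit is replaced downstream by the
interval midpoint `floor((start+end)/2)`. Parsers fail loudly with the
offending line number rather than coercing: sequence residues outside
`A,C,G,T,N`, non-integer coordinates, inverted intervals, and duplicate or
missing gene `ID` attributes are all hard errors, because silent coercion
of coordinates is the classic source of off-by-one drift in cross-format
pipelines.

## From peaks to target sets

**Replicate reconciliation.** A peak is accepted when it is present in
every replicate, presence meaning an overlap of at least `min_overlap_bp`
(default 1). The merged peak is the running intersection interval, its
score the mean of the contributing replicate scores. This is the
conservative choice; a `union` mode is available. The rule is symmetric in
replicate order.

**Nearest-gene assignment.** The distance between a peak and a gene is the
edge-to-edge gap between the peak interval and the gene body (0 when they
overlap or touch), ignoring strand. Gene-body gap rather than TSS distance
is deliberate: in sparsely annotated genomes TSS calls are unreliable while
gene spans are comparatively stable, and a strand-agnostic gap treats
divergently transcribed neighbours symmetrically. Each peak is assigned to
the gene(s) minimising this gap, up to `max_distance_bp` (default 10 kb, a
conventional cis-regulatory reach for compact insect genomes); more distant
peaks stay unassigned and are only counted. Exact distance ties are all
reported, flagged, and ordered lexicographically by gene id — downstream
set construction deduplicates anyway, so reporting ties is free of cost and
avoids an arbitrary winner. Touching intervals (gap 0 without a shared
base) are classified `overlapping` so that "distance 0" and "relation
overlapping" remain synonymous. The implementation is interval-tree based
(overlap hits plus the nearest neighbour on each side, with all
same-distance ties kept); the test suite holds it to exact agreement with
an exhaustive peak-by-gene scan.

## Ortholog projection and set statistics

Species target sets are mapped onto the reference gene space by replacing
each member with the union of its reference orthologs; many-to-one and
many-to-many relations collapse silently and members without an entry are
counted as unmapped. Mapped sets are partitioned into exhaustive Venn
regions (every gene of the union in exactly one region). Overlap
significance is the hypergeometric upper tail
$P(X \ge k) = \sum_{i \ge k} \binom{n_A}{i}\binom{U-n_A}{n_B-i} / \binom{U}{n_B}$
with the universe $U$ defaulting to the number of reference genes that have
at least one ortholog entry — the smallest space in which both sets could
in principle have landed. The fold reported alongside is
$k \, U / (n_A n_B)$, observed over expected overlap.

Functional-category structure is summarised three ways: per-set category
proportions (genes lacking any annotation stay in the denominator, keeping
proportions comparable between differently annotated sets); the fold
over-representation of a category between two sets, $f = p_A / p_B$, with a
two-sided Fisher exact test on the corresponding 2x2 table; and a
hypergeometric enrichment of a set against a universe with
Benjamini-Hochberg correction across the tested categories. When $p_B = 0$
the fold is flagged undefined rather than silently infinite. The fold
statistic is primary and the p-values supplementary, because the
biological claim of interest ("wing-development genes are more than 4-fold
over-represented among shared targets") is a fold statement.

**Expression filter.** The differential-expression filter keeps a gene when
$\max\!\big((v_1+c)/(v_2+c),\,(v_2+c)/(v_1+c)\big) \ge$ `min_fold`
(inclusive, unsigned — "a 2-fold difference" does not say in which
direction). The pseudocount defaults to $c = 1$, the conventional guard
against zero denominators in count-derived tables; rows that are 0/0 under
$c = 0$ are skipped and counted.

## Motif scanning and enrichment

Consensus motifs use the 15 IUPAC codes, matched per position through
4-bit base masks. A sequence `N` carries a fifth bit and therefore matches
*no* code, on either strand — an unsequenced base should never be evidence
for a site. Matrix motifs are regularised with a pseudocount of 0.01 per
cell, row-normalised, and scored by log2-odds against a uniform
background; the hit threshold defaults to 80% of the motif's maximum
achievable score, a common operating point when the matrix's native
threshold is unknown, and is overridable per motif. Reverse-strand hits are
found with the reverse-complemented motif and reported at the forward
coordinate of the match start. Overlapping hits all count; no greedy
masking.

**Fold-enrichment against non-coding background.** The foreground density
is hits per kb over the concatenated foreground (peak) sequences. Each of
`n_draws` (default 200) background draws is a *length-matched* set — the
same multiset of lengths as the foreground — sampled uniformly from
scaffold positions outside gene bodies and free of `N`; length matching
removes the dominant density bias, and drawing whole sets rather than
single sequences makes each draw an exchangeable replica of the foreground.
The fold is foreground density over mean background density, and the
empirical p-value is $(1 + \#\{draws \ge fg\}) / (n_{draws} + 1)$, which
can never reach 0 from a finite simulation. Because the empirical p has a
discrete support of $n_{draws}+1$ values, uniformity diagnostics need
draws counts well above the spec of the diagnostic; the calibration
experiment in the test suite uses 60 draws per run, making the
discreteness bias of the Kolmogorov-Smirnov statistic about 0.016,
an order of magnitude below the 0.15 acceptance bound.

**k-mer over-representation.** As a deliberately simple stand-in for
de-novo discovery, k-mers (4-12 bp) are counted in canonical form (the
lexicographic minimum of a k-mer and its reverse complement) per kb in
foreground and background, a pseudo-frequency of 0.5 occurrences is added
to the background to keep folds finite, and k-mers are ranked by fold with
lexicographic tie-breaks.

**Anchored arrays.** Around each anchor (peak summit if present, else the
interval midpoint) every library motif is scanned on both strands and hits
within ±`window_bp` (default 500 bp — roughly an enhancer-sized
neighbourhood) are reported as signed offsets, sorted. Two arrays are
compared at the TF level (shared / A-only / B-only), with nearest-offset
pairings for shared TFs; the unit of comparison is the TF, not the motif,
so two species can share a MAD1 site realised by different sequence
variants.

The bundled default library contains documented IUPAC approximations (the
Hox core `TAAT`, the extended Ubx site `ATAATS` with S = G/C, Adf-1
`TGGCTGCCGTCGCGAT`, the fly and bee MAD1 sites `GCCGTCGC` and
`GCTGCCCGCCGC`, and the GAGA-factor repeat `GAGAG`); users supply real
matrices for serious scans.

## The synthetic-data generator

The generator emulates the processed shape of a two-species Ubx ChIP
comparison, scaled to desk size. Defaults: 4 scaffolds of 600 kb per
species, 300 genes of 1-2 kb, 150 reproducible peaks of 200-400 bp (two
replicates, jittered by at most 5% of the peak length so replicate pairs
overlap by >= 90%), a shared-target fraction of 0.2 (the study-scale
observation that 15-20% of targets are shared), ortholog coverage 0.85 of
non-target genes (mirroring the ~85% ortholog coverage of hindwing
targets), a wing-development-like category planted at 4-fold
over-representation in shared targets on a 5% base rate, 5% of genes
planted with a >= 2-fold expression difference, and peak sequences carrying
MAD1/Adf-1 sites at ~5-fold their background density while the Ubx site
sits at background rate — the study's striking negative result that the
factor's own motif is not what distinguishes its bound regions.

Three construction decisions make ground truth exact rather than
approximate, so end-to-end tests can assert equality instead of bands:

* **Geometry.** Each gene occupies its own slot `[3 kb pad][2 kb peak
  zone][gene body]`; the planted peak sits 100-1500 bp upstream of its gene
  start inside the zone. Every other gene is therefore >= 3 kb away and the
  nearest-gene convention provably recovers the intended target, jitter
  included. An ambiguity knob would only test tie handling, which has its
  own dedicated tests on constructed cases.
* **Exact-count planting.** Category annotations are planted per disjoint
  subset (shared / A-specific / B-specific / other reference genes) with
  exact counts `round(rate * size)` assigned to random members, not by
  per-gene coin flips: at realistic set sizes (hundreds), binomial sampling
  noise on a proportion ratio would exceed the ±0.5 recovery band the fold
  statistic is held to, and the quantity under test is the statistic, not
  the sampling noise of the annotation. The same principle fixes the
  ortholog structure: coverage trims non-target genes only, so exactly
  `round(shared_target_fraction * n_peaks)` reference genes are shared.
* **Separated expression ratios.** Non-DE genes draw condition ratios in
  [1, 1.4], DE genes in [2.2, 8] (random direction) on baselines >= 50, so
  the inclusive 2-fold filter recovers exactly the planted set under
  pseudocounts 0 and 1 alike.

Background genome composition is uniform over `A,C,G,T`. One caveat is
inherent to the design: peak intervals are part of the non-coding space
that background draws sample from, so planted foreground sites leak
slightly into the background estimate and measured motif folds sit a few
percent below the planted `fg_per_kb / bg_per_kb` ratio (about 4.2 observed
for a planted 5 at the default geometry). The controlled planted-ratio
recovery experiments therefore plant background at a known genome-wide
rate and foreground on top of drawn sequences, where the expectation is
exact.

What passing tests on this generator do **not** show about real data: real
genomes are GC-skewed and repeat-rich (motif null distributions are wider
than uniform-composition ones), real orthology is many-to-many and
incomplete in a correlated way, real peaks include noise peaks far from any
gene and genes with multiple peaks, and real DE tables have dispersion
structure no two-point ratio construction mimics. The generator validates
the *machinery* — conventions, statistics, bookkeeping — not biological
effect sizes.

## Determinism and problem sizes

Every stochastic step takes an explicit seed (`with_seed` restores the
caller's RNG state), generation is byte-identical under a fixed
configuration, and the pipeline writes a MANIFEST naming completed stages
so a failed run is distinguishable from a complete one. The test suite runs
the scanner-oracle comparison on 100 random 1 kb sequences x 10 motifs, the
nearest-gene oracle on 200 random instances, null calibration on 200
seeded enrichment runs of 50 kb foreground x 60 draws, planted-ratio
recovery on 50 seeds per ratio, and end-to-end truth recovery on 60-gene /
40-peak configurations — sizes chosen to give the property checks
comfortable statistical headroom while staying desk-sized. The analysis
drivers and the acceptance script use the full default configuration.

## Known limitations

Assignment is gene-body based and blind to enhancer-promoter looping;
replicate reconciliation assumes congruent peak calls rather than modelling
signal; the hypergeometric universe is a configurable convention, not an
estimate; consensus-mode scanning weights all matching words equally; and
the anchored-array comparison treats TF presence/absence within a fixed
window, without alignment of the two regions.
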