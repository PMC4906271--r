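# crossbind

Cross-species comparison of a transcription factor's ChIP target
repertoires, built for the kind of question posed by Hox biology: Ubx
patterns the third thoracic segment in flies, bees and moths alike, yet
builds a haltere in one and hindwings in the others. Given called ChIP
peaks, gene models, an ortholog table, category annotations and an
expression table for two species, `crossbind` answers: which putative
targets are shared once projected onto a reference gene space, which
functional categories distinguish shared from species-specific targets,
which motifs are over-represented in the bound sequences relative to
random non-coding background, and how the arrays of transcription-factor
binding sites around the ChIP anchors differ between species.

It is aimed at comparative regulatory genomicists working downstream of
peak calling: the pipeline consumes peak BED files, never reads.

## What it computes

* **Targets** — replicate peak sets are reconciled by intersection and each
  reproducible peak is assigned to the gene(s) minimising the edge-to-edge
  gap to the gene body (strand-agnostic, default cutoff 10 kb, exact ties
  all reported).
* **Shared vs specific** — target sets are mapped through an ortholog table
  (many-to-many collapses to the union of reference ids), partitioned into
  exhaustive Venn regions, and the overlap is scored by the hypergeometric
  upper tail P(X >= k) with fold k·U/(n_A·n_B) over a universe U of
  reference genes with ortholog entries.
* **Category structure** — per-set category proportions; the fold
  over-representation f = p_shared / p_specific with a two-sided Fisher
  exact test; hypergeometric enrichment against the universe with
  Benjamini-Hochberg correction.
* **Expression** — an unsigned, pseudocounted fold-change filter
  (max ratio >= 2 by default) intersected with the target sets.
* **Sequence level** — IUPAC/PWM motif scanning (sequence N matches
  nothing); motif fold-enrichment of peak sequences against length-matched
  random non-coding draws with empirical p = (1 + #{draws >= fg})/(n+1);
  canonical k-mer over-representation; and anchored binding-site arrays:
  all library motifs within ±500 bp of each peak anchor, compared between
  species at the TF level (shared / A-only / B-only).
* **Synthetic data** — a seeded generator producing paired two-species
  datasets (FASTA, GFF3, replicate BEDs, ortholog/annotation/expression
  TSVs, motif JSON) with exact ground truth for every stage.

## Worked example

```r
library(crossbind)

# generate a paired synthetic dataset: 300 genes and 150 peaks per species,
# 20% shared targets, a wing-development-like category planted at 4-fold
# over-representation among shared targets
cfg <- synthetic_config(seed = 1)
sim <- simulate_dataset(cfg, "results/data")

# run the full comparison
rc <- run_config(
  species_a = list(genome = sim$paths$genome_a, genes = sim$paths$genes_a,
                   peaks = c(sim$paths$peaks_a_rep1, sim$paths$peaks_a_rep2),
                   label = "bee"),
  species_b = list(genome = sim$paths$genome_b, genes = sim$paths$genes_b,
                   peaks = c(sim$paths$peaks_b_rep1, sim$paths$peaks_b_rep2),
                   label = "moth"),
  orthologs = sim$paths$orthologs, annotation = sim$paths$annotation,
  expression = sim$paths$expression_b, motifs = sim$paths$motifs,
  n_draws = 60, seed = 2)
report <- run_pipeline(rc, "results/run")
report
#> comparison_report (seed 2 )
#>   targets: bee = 150, moth = 150
#>   ortholog-mapped: 150 and 150; shared reference targets: 30
#>   DE genes (filter): 15, of which 5 are targets
```

The 150 reproducible peaks per species each recover their planted target
gene; 30 reference genes (the planted 20%) are shared after ortholog
mapping; 15 genes pass the 2-fold expression filter (the planted 5%), 5 of
them hindwing targets. The planted category fold is recovered exactly:

```r
subset(report$category_folds, category_id == "CAT-WING",
       c(comparison, proportion_a, proportion_b, fold))
#>                       comparison proportion_a proportion_b fold
#>     shared_vs_species_a_specific          0.2         0.05    4
#>     shared_vs_species_b_specific          0.2         0.05    4
```

and the motif table shows the planted sequence signature — MAD1/Adf-1
sites ~4-fold enriched in peaks, the Ubx site itself at background rate:

```r
report$motif_enrichment[, c("species", "motif_id", "fold", "empirical_p")]
#>  species motif_id fold empirical_p
#>      bee MAD1_fly 4.04       0.016
#>      bee     Adf1 4.55       0.016
#>      bee  UbxSite 0.99       0.541
#>      ... (moth rows analogous)
```

The nested-site worked example — the fly MAD1 site `GCCGTCGC` sits at
offset +5 inside the Adf-1 sequence `TGGCTGCCGTCGCGAT`:

```r
scan_motif(motif_model("MAD1_fly", "MAD1", iupac = "GCCGTCGC"),
           "TGGCTGCCGTCGCGAT", both_strands = FALSE)
#>   motif_id tf_name position strand score
#> 1 MAD1_fly    MAD1        5      +     1
```

The numbered drivers under `analysis/` run the same stages as standalone
narrative scripts (`01_simulate.R` ... `05_motif_arrays.R`), writing their
tables under `results/`.

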