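# cistrotype

Integrative cistrome–transcriptome analysis for a ligand-activated
nuclear receptor studied in a 2×2 genotype × ligand design (wild-type and
receptor-null cells, each with and without a synthetic agonist). The
package is aimed at analysts who have ChIP-seq tag positions and a
factorial expression matrix for such a design and want to go from raw
tags to a classified, annotated set of direct target genes with one
reproducible pipeline — or who want to benchmark that pipeline on
synthetic data with a known ground truth.

## What it computes

**Hotspot peak calling.** Tag enrichment in a 150 bp target window is
scored against a 200 kb local background window with a binomial model.
Each window gets a success probability

    p = (uniquely mappable bp in the 150 bp window) /
        (uniquely mappable bp in the 200 kb window)

and, with `N` tags in the background window, `mu = N p`,
`sigma = sqrt(N p (1 - p))`, the score

    z = (n - mu) / sigma

where `n` is the input-subtracted tag count in the window (input tracks
are first rescaled to the ChIP library size). Windows with `z > 60` are
retained and merged; peaks overlapping a peak called in the receptor-null
ChIP by more than 1 bp are excluded as non-specific.

**Response typing.** Per gene, three Welch contrasts on log2 expression
(ligand response in wild-type, knockout vs wild-type, ligand response in
knockout) are thresholded at fold change ≥ 1.3 and BH FDR ≤ 0.25 and
combined into eight response types: constitutive repression (I) or
activation (II), ligand-dependent activation (III) or repression (IV) —
requiring no response in the knockout — and their four combinations
(V–VIII).

**Integration and annotation.** Peaks are assigned to their nearest TSS
(midpoint distance, strand-aware sign); differentially expressed genes
with a peak within ±10 kb of the TSS form the direct-target sets with and
without ligand, reported with their full set algebra. Peaks are also
annotated by genomic feature (UTRs, coding exons, introns, 1/2/3 kb
upstream and downstream rings, intergenic) and chromosome, with exact
binomial enrichment against genome baseline fractions.

**Motifs.** A DR1-type PPRE position-frequency matrix is built from
aligned site sequences, reduced to an IUPAC consensus, and scanned (log2
odds, both strands) over 400 bp regions around peaks; motif co-occurrence
fractions are corrected against receptor-null regions, and motif
similarity is summarized as an average-linkage tree in newick form.

A bundled synthetic-data generator (`sim_config()`, `simulate_genome()`,
`simulate_tags()`, `simulate_expression()`) produces a toy genome,
annotation, mappability mask, tag libraries with planted 150 bp sites,
knockout artifact sites, planted motifs and a planted response type per
gene, together with a ground-truth manifest, so the whole pipeline is
testable offline.

## Worked example

```r
library(cistrotype)

cfg <- pipeline_config(seed = 42, out_dir = "demo_out")
run <- run_pipeline(cfg, verbose = FALSE)
print(run)
print(run$classification)
str(run$summary$truth_recovery)
```

prints

```
cistrotype run (seed 42)
  peaks:  chip_wt_veh 56, chip_wt_lig 94, chip_null_veh 15, chip_null_lig 15
  direct targets: |A|=25 |B|=41 union=49
  consensus: GGGNCAAAGGTCA
Response-type classification: 97 differentially expressed of 150 genes (fc >= 1.3, q <= 0.25)
   I   II  III   IV    V   VI  VII VIII none
  31   48    8    3    3    2    1    1   53
List of 6
 $ recall_without       : num 1
 $ recall_with          : num 0.92
 $ artifact_peaks_before: int 29
 $ artifact_peaks_after : int 0
 $ type_accuracy        : num 0.932
 $ n_planted_de         : int 103
```

Reading this: four ChIP conditions were peak-called (the two knockout
samples contribute only non-specific artifact peaks, all 15 of them);
after null subtraction, 25 differentially expressed genes carry a peak
within ±10 kb of their TSS without ligand (set A) and 41 with ligand
(set B), 49 in the union — the direct-target sets. The classifier found
97 differentially expressed genes and the per-type counts below them.
Against the generator's ground truth, every planted unliganded site and
92% of liganded sites were recovered at `z > 60`, all 29 wild-type peaks
that fell on artifact sites were removed by the knockout subtraction, and
93% of the 103 planted genes got their planted response type. The derived
PPRE consensus is `GGGNCAAAGGTCA`. Stage outputs (peak BEDs, response and
assignment TSVs, enrichment tables, motif co-occurrence, newick tree,
`summary.json`) land under `demo_out/`.

A thin command-line front end with per-stage subcommands (`simulate`,
`callpeaks`, `classify`, `integrate`, `annotate`, `scan-motifs`, `run`)
is installed at `inst/scripts/cistrotype`.

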