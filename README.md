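# barcodeaudit

Audit tools for COI DNA barcode reference libraries, written for the
people who curate them: entomologists and molecular ecologists building
regional species-identification libraries (wild bees being the
motivating case), who need to know — before anyone identifies a
specimen against their library — which sequences are suspect, which
species are cleanly diagnosable, and which are split across deep
mitochondrial lineages or share barcodes with a sibling species.

The package runs the standard audit end to end on plain tibbles:

* **Record QC** — FASTA + specimen-TSV ingestion into a validated
  library; length tiers (`full` ≥ 500 bp, eligible for clustering;
  `partial` 300–499 bp, used in distances and haplotypes only).
* **Numt screen** — reading-frame detection and stop-codon counting
  under the invertebrate mitochondrial code (table 5; TAA/TAG stops,
  TGA = Trp), plus internal frameshift-gap flags on aligned input.
* **K2P distances** — Kimura 2-parameter distances with pairwise
  deletion,
  `d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q)`
  with `P`/`Q` the transition/transversion proportions; explicit
  saturation and low-overlap states; rank-stratified summaries over
  mutually exclusive conspecific / congeneric / confamilial pairs.
* **Barcode gap** — per-species mean/max intraspecific distance
  against the minimum distance to the nearest heterospecific
  neighbour, with gap flags and exceedance reports.
* **Clustering & concordance** — single-linkage partition at
  `τ = 0.022` (connected components under `d ≤ τ`, local clusters,
  deliberately *not* registry BINs) and per-species categories:
  MATCH / SPLIT / MERGE / MIXTURE / UNASSESSED.
* **Haplotypes** — species-scoped haplotype collapsing and Nei's
  diversity `Hd = n/(n−1)·(1 − Σ pᵢ²)`.
* **NJ tree** — neighbour-joining over the K2P matrix with
  deterministic Newick output.
* **Simulator** — a K2P sequence-evolution generator with planted
  deep splits, merged species pairs, partial-length records and
  frameshift numts, returning the truth tables the test-suite and
  acceptance checks evaluate against.

## A worked example

```r
library(barcodeaudit)

sim   <- simulate_library(sim_config(seed = 42))  # known truth
audit <- run_audit(sim, out_dir = "audit_out")

glance(audit)
#> # A tibble: 1 × 12
#>   n_specimens n_species n_clusters n_match n_split n_merge n_mixture
#>         <int>     <int>      <int>   <int>   <int>   <int>     <int>
#> 1         217        36         39      31       3       2         0
#> # i 5 more variables: n_unassessed <int>, mean_within_species_pct <dbl>,
#> #   mean_within_genus_pct <dbl>, total_haplotypes <int>, n_numt_suspect <int>

audit$rank_divergence
#> # A tibble: 3 × 8
#>   level          n_seqs n_taxa n_comparisons min_pct mean_pct max_pct  se_pct
#>   <chr>           <int>  <int>         <int>   <dbl>    <dbl>   <dbl>   <dbl>
#> 1 within_species    210     30          1011  0        0.2777   9.859 0.03069
#> 2 within_genus      216      9          1680  0.1521  12.93    23.56  0.06210
#> 3 within_family     216      3          5386 15.23    20.69    29.45  0.03330

audit$gap_report
#> <gap_report> threshold 2% K2P
#>   species exceeding threshold: 3
#>     Genus08 species031 (9.86%), Genus02 species005 (9.28%), ...
#>   mean intra range: [0.04, 6.56]%
#>   NN distance range: [0.15, 17.94]%
#>   species without barcode gap: 1
```

Reading this: of 36 named species, 31 map one-to-one onto a local
cluster, the three species simulated with deep conspecific lineages
split into multiple pure clusters, and the planted near-identical
species pair merges into a shared cluster — exactly what
`truth_eval(audit, sim$truth)` confirms (100% category recovery).
Conspecific divergence averages ~0.28% against ~13% between congeners:
a clear barcode gap, with the one gap failure belonging to a planted
deep-split species whose lineages diverge more than its distance to
its nearest neighbour. `run_audit()` writes the per-species table,
cluster assignments, haplotype table, Newick tree, `summary.json` and
an audit log into `audit_out/`.

Real libraries enter the same way:

```r
lib <- assemble_library(read_specimen_table("specimens.tsv"),
                        read_barcode_fasta("barcodes.fasta"))
audit <- run_audit(lib, out_dir = "audit_out")
```

A small synthetic example library ships in `inst/extdata/`
(`synthetic_bees.fasta` / `synthetic_bees.tsv`), and
`inst/scripts/barcode-audit.R` wraps `validate` / `run` / `simulate`
for shell use.

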