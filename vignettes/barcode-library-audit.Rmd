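---
title: "Auditing COI barcode reference libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing COI barcode reference libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(barcodeaudit)
```

## The problem

A DNA barcode reference library links voucher specimens with taxonomic
names to cytochrome c oxidase subunit I (COI) sequences, so that later
specimens — often mass-trapped insects in poor condition — can be
identified by sequence comparison alone. Before such a library can be
trusted it has to be audited: are the sequences genuine mitochondrial
COI rather than nuclear copies (numts)? Is intraspecific variation
clearly separated from interspecific divergence (the "barcode gap")?
Do algorithmically delimited sequence clusters correspond one-to-one to
named species, or do some species split into deep conspecific lineages
while others share barcodes with close relatives?

`barcodeaudit` implements that audit as a set of pipe-friendly stages
over plain tibbles, plus a simulator that generates libraries with
known truth so every stage can be exercised and calibrated without any
external data.

## The audit model, stage by stage

### Records and length tiers

A library is the join of a FASTA file of (optionally aligned) barcodes
and a tab-separated specimen table. Records are tiered by ungapped
length: `full` (>= 500 bp), `partial` (300-499 bp) and `reject`.
The 500 bp bound is the conventional minimum for cluster ("BIN"-style)
assignment; both bounds are inclusive at the lower edge of their tier
so there are no off-by-one surprises at exactly 500 or 300 bp.
Partial-tier records take part in distance and haplotype computations
but are never clustered — this mirrors the common curation practice of
keeping short Sanger fragments informative without letting them drive
cluster delineation. Records with an empty species label (unnamed
taxa awaiting identification) are retained for clustering and tree
building but excluded from all per-species statistics.

### Numt screening

Nuclear pseudogene copies of COI are typically betrayed by reading-frame
disruptions. `detect_frame()` translates the gap-stripped sequence in
the three forward frames under the invertebrate mitochondrial genetic
code (translation table 5: TGA encodes tryptophan, only TAA and TAG are
stops) and takes the frame with the fewest internal stops; ties go to
the lowest frame index. Codons containing ambiguity codes are skipped,
and the terminal codon is not counted — a trailing stop is legitimate.
Sequences are assumed delivered in barcode (5'→3' coding) orientation;
a `try_revcomp` rescue mode exists but is off by default. In aligned
input, an internal gap run whose length is not a multiple of three is
flagged separately as a putative frameshift indel (`indel_suspect`);
terminal gap runs are treated as missing data, since 3'-truncated
partial reads would otherwise all be false positives.

A structural point worth knowing: a single-base frameshift is *not*
always detectable from stop codons alone. One reading frame of the
shifted sequence re-aligns with the clean reading downstream of the
indel, so a stop must occur both in the shifted downstream segment and
in the off-frame upstream segment before every frame shows a stop.
Deletions near either end of the barcode therefore escape the
stop-codon signal with appreciable probability (roughly a third of
uniformly placed deletions at 658 bp under uniform base composition).
The combined screen — stop codons *or* an internal frameshift gap —
is what the audit reports as `flagged`, and it catches essentially all
planted single-base indels; the stop-only rate is reported alongside.
Suspects are flagged, never removed: removal is a decision for the
curator, not the screen.

### K2P distances

Pairwise distances use the Kimura 2-parameter model,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

with `P` and `Q` the transition and transversion proportions over the
compared sites. Sites with a gap or ambiguity code in either sequence
are excluded (pairwise deletion — with 300 bp records in the library,
complete deletion would discard most columns). Pairs with fewer than
`min_overlap = 100` comparable sites, and pairs where an argument of a
logarithm is non-positive (saturation), carry `d = NA` and are excluded
from all summaries, never silently zeroed. Inputs of unequal length are
an error: alignment is out of scope, and an implicit alignment would be
worse than a refusal.

Rank-stratified summaries use mutually exclusive levels: conspecific
pairs, congeneric pairs *of different species*, and confamilial pairs
*of different genera*. Exclusivity matters — a "within genus" band that
included conspecific pairs would have a minimum of zero by construction
and would be useless for gap assessment. Distances are reported in
percent; the standard error is over comparisons.

### Barcode gap

For each named species the audit reports the mean and maximum
intraspecific distance and the distance to the nearest heterospecific
neighbour, where "nearest" means the *minimum* pairwise distance to any
member of another named species (minimum, not mean: the identification
failure mode is the closest heterospecific barcode, not the typical
one). Ties between neighbour species are broken alphabetically. The
local barcode gap holds for a species when its maximum intraspecific
distance lies below its nearest-neighbour distance. Species with fewer
than two records have undefined intraspecific statistics and an
unassessable gap; the reporting subset for distribution plots and
exceedance lists is species with at least three records. Because the
per-species mean of intraspecific distances and the global
per-comparison mean answer different questions, the package computes
both (the per-species means in the gap table, the per-comparison mean
in the rank summary) and labels them accordingly.

### Clustering and concordance

Cluster delineation is plain single linkage at a fixed threshold: the
connected components of the graph joining full-tier sequences with a
valid distance `d <= tau`, with `tau = 0.022` — the conventional seed
threshold for barcode clusters. The refinement step that registry
systems apply within seed clusters is deliberately not implemented:
registry BINs depend on a global, versioned database and are not
reproducible offline, so the package produces *local clusters*
(`LC:000001`, ...) and never calls them BINs. Cluster ids are assigned
in order of each cluster's lexicographically smallest member, making
the partition stable under input reordering. Invalid (saturated or
low-overlap) pairs contribute no edge.

Each named species is then classified against the partition: `MATCH`
(one cluster, no other named species in it), `SPLIT` (several pure
clusters — deep conspecific lineages), `MERGE` (one cluster shared
with another species), `MIXTURE` (several clusters, at least one
shared), `UNASSESSED` (no full-tier record). Unnamed records never
render a cluster impure; they are pending taxa, not conflicts.

### Haplotypes

Within each species, alignment columns containing a gap or ambiguity
code in any member are removed before collapsing identical sequences
into haplotypes — the complete-site convention of standard
population-genetic software, configurable in principle but a sensible
default for mixed-length libraries. Haplotype diversity is Nei's

$$H_d = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

computed in the integer-count form `(n^2 - sum(c_i^2)) / (n (n - 1))`
whenever the frequencies are exact counts, so the boundary identities
(`Hd = 0` for a single haplotype, `Hd = 1` when all sequences differ)
hold exactly rather than to rounding. Diversity values are displayed
for species with more than ten sequences; below that the estimate is
too noisy to be worth printing, though it is still computed. Haplotypes
are species-scoped — identical sequences in different species are
different haplotypes — and the library-level total is reported both as
the sum of per-species counts and as a global string collapse; the two
differ only when identical sequences cross species boundaries (e.g.
a merged species pair).

### Tree

A neighbour-joining tree over the K2P matrix provides the structural
view of divergence. By default one leaf per species-scoped haplotype
keeps the tree at desk scale; `all` and `species-medoid` policies
exist. Negative intermediate branch lengths, an occasional NJ artefact,
are clamped to zero and counted. Newick output uses six significant
digits and alphabetically rotated children, so identical analyses give
byte-identical files.

## The simulator: what it emulates, and what it does not

`simulate_library()` generates an aligned library down a
family → genus → species hierarchy. Every branch applies a Poisson
number of substitution events per site; each event is a transition
with probability $\kappa/(\kappa+2)$ and each transversion with
probability $1/(\kappa+2)$, so multiple hits happen and the K2P
correction is actually exercised rather than vacuously verified.
Individuals radiate from their species ancestor on a star genealogy at
`theta_intra / 2` each.

Because clean COI must stay translatable, the generator avoids creating
frame-0 stop codons: an event whose target codon would be TAA/TAG is
redirected to a non-stop target base. Crucially the event is redirected,
not discarded — discarding would silently shrink realized divergence by
a few percent and bias every parameter-recovery check; redirection
keeps the substitution count, and therefore the expected distance,
exactly as configured. This emulates purifying selection on the reading
frame at the cost of a slight local distortion of the
transition:transversion ratio (a few percent of events are redirected).

Default conditions, chosen once to emulate a desk-scale multi-family
wild-bee library: `L = 658` bp, `kappa = 3`, 3 families × 3 genera ×
4 species, geometric(mean 8) individuals per species, `theta_intra =
0.002` (≈ 0.2% conspecific divergence), species/genus/family branches
of 0.06/0.04/0.05 expected substitutions per site (≈ 12% congeneric and
≈ 20% confamilial K2P), three planted deep splits at `delta = 0.08`
(≈ 8% of species, matching the frequency of deep conspecific lineages
reported in regional bee libraries), one planted congeneric pair at
`eps = 0.002` (a barcode-sharing species pair), a 1.1% partial-length
tier truncated from the 3' end, 2% single-base frameshift numts
(represented as a one-column gap so the alignment is preserved), and
one unnamed specimen. The first individual of each species and of each
planted lineage is never truncated, so every species keeps at least one
cluster-eligible record and planted anomalies are always observable.

What the simulator does *not* model, and what that means for the tests:
no coalescent structure within species (the star genealogy produces the
right divergence scale but no haplotype genealogy), no rate variation
across sites or lineages, no base-composition bias (real COI is AT-rich,
which raises the stop-only numt detection rate above what uniform
composition gives), no insertions/deletions beyond the planted
frameshifts, and no sequencing error. Passing tests therefore
demonstrate that the *methods* are implemented correctly and behave as
designed under their own assumptions — not that real libraries are this
clean.

## Numerical choices

* Saturation (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) and low overlap are
  explicit states, never `NaN`s propagated into means.
* Clustering uses exact threshold comparison (`d <= tau`, inclusive);
  partitions refine monotonically in `tau`.
* NJ ties on the Q-criterion are resolved by the underlying
  agglomeration deterministically; negative branches are clamped to 0.
* All iteration is over sorted keys; re-running an audit on identical
  input produces byte-identical output files.
* Percentages are printed to 2 decimal places in the TSV reports and
  kept at full precision in `summary.json`.

## Problem sizes used by the test-suite

The suite validates K2P against a brute-force site-loop oracle on 1000
random pairs (tolerance 1e-12), single linkage against union-find on
random matrices up to n = 50, NJ on random additive trees up to 12
taxa, and parameter recovery on 20 simulated libraries of 100 sequences
at L = 2000, where the mean conspecific and congeneric K2P estimates
must sit within three Monte-Carlo standard errors of the configured
values and all planted splits/merges must classify correctly. These
sizes give stable Monte-Carlo behaviour on a single CPU in a couple of
minutes while exercising every code path.

## A worked run

```{r}
sim <- simulate_library(sim_config(seed = 42))
sim
audit <- run_audit(sim)
glance(audit)
audit$rank_divergence
percentage_summaries(audit)
truth_eval(audit, sim$truth)
```

```{r, fig.width = 6, fig.height = 4}
autoplot(audit)
```

## Known limitations

* Clusters are local to the library at hand; they are not registry
  BINs, and per-species cluster multiplicities can legitimately differ
  from registry values that include records from other datasets.
* Alignment is assumed, not performed. Different aligners can shift
  pairwise distances in the third decimal; distance summaries should be
  compared across pipelines only to ~0.02 percentage points.
* The numt screen detects frame disruptions; a numt that preserves the
  reading frame is invisible to it, as it is to any stop-codon screen.
* `pearson_corr()` is a convenience for the audit's sampling-effort
  checks, not a general correlation toolkit.
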