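---
title: "netkda: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netkda: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkda)
```

## What the workflow computes

`netkda` validates a candidate network key driver in three linked stages.
First, a six-genotype mouse RNA-seq design (wild type; driver
heterozygote and knockout; an amyloid model; and the amyloid model crossed
onto each driver genotype) yields per-contrast differential-expression
tables and directional signatures. Second, signatures are intersected
pairwise — the critical comparison being genes *up* in the amyloid
genotype versus genes *down* when the driver is knocked out on that
background — with one-sided Fisher exact tests and fold enrichments.
Third, the reversal signature is projected onto a directed causal gene
network: the candidate driver's downstream neighborhood is layered by
shortest directed distance, each layer is scored for signature enrichment,
and every network node is ranked genome-wide by the enrichment of its
cumulative downstream neighborhood. A co-expression module stage
(adjacency → topological overlap → clustering → module enrichment)
mirrors the module-level interpretation of the same signatures.

## Differential expression model

Counts are filtered to genes with at least 1 count per million in at
least one sample, with CPM computed on raw library sizes and the boundary
inclusive. TMM scaling factors (30% trim on M-values, 5% on A-values,
precision weights from the binomial asymptotic variance, reference sample
chosen by the upper-quartile rule) are computed by edgeR, which implements
exactly the published recipe; the test suite checks the factors against an
independently hand-coded version of the formula to 1e-6. Expression is
log2-CPM with a prior count of 0.5 on TMM-effective library sizes.

Each gene gets a group-means linear model over the six genotypes. The
residual variances are shrunk by empirical Bayes: `limma::fitFDist`
moment-matches the log residual variances to a scaled F distribution
(digamma/trigamma equations) to give the prior degrees of freedom d0 and
prior variance s0², and the posterior variance is
(d0·s0² + dg·s²g)/(d0 + dg). We assemble the moderated t, its d0 + dg
degrees of freedom, and two-sided p-values in-package so that the d0 = 0
(no moderation) and d0 = ∞ (full pooling) limits are available as explicit
settings; the estimated-d0 path is cross-checked against `limma::eBayes`
in the tests. This is the untrended log-CPM variant of the moderated
linear model — the simplest member of that family; a precision-weighted
(voom-style) variant is a possible extension but is not implemented, since
at the simulated depths (8–12 million reads) the mean–variance trend is
mild.

BH adjustment is applied within each contrast, because DEG counts are
reported per contrast; signatures take FDR ≤ 0.05 inclusive. The six
contrasts are fixed to the reported design: het vs WT, KO vs WT, amyloid
vs WT, amyloid×KO vs amyloid, amyloid×KO vs WT, amyloid×KO vs KO.

## Enrichment statistics

All overlap tests are one-sided hypergeometric upper tails — the
enrichment direction of Fisher's exact test — because every reported use
pairs the test with a fold enrichment above 1. The tail is accumulated by
logsumexp over the log pmf, so p-values down to the smallest normalized
double survive; the suite checks exact agreement with exhaustive draw
enumeration for universes up to 12.

The universe N is a genuine free parameter: published overlap tables
rarely state it. Our default is the set of genes surviving the expression
filter (for signature–signature tests) or network nodes intersected with
expressed genes (for network tests), and every result row carries
`overlap, n1, n2, N` so any p-value can be recomputed. For the reported
86/181/116 mouse counts the implied universe can be recovered by inverting
FE = overlap·N/(n1·n2), giving N* = 18579, at which the fold enrichment
reproduces 76.1 and the FET p is ~1e-156 — the order of magnitude of the
published figure, which cannot be matched exactly without the original N.

## Key-driver analysis

Neighborhood layering is plain breadth-first search over outgoing edges:
layer i is the set of nodes at shortest directed distance i from the seed,
so it is well defined on any digraph, including the cyclic unions that
arise when cohort-level DAGs are merged (`union_network` keeps both
directions of oppositely oriented edges and merges cohort tags on
duplicates). Per-layer enrichment is the default because reported
first-layer counts read as per-layer sets; cumulative unions are a flag,
and the identity "cumulative layer k = enrichment of the union of layers
1..k" is asserted in the tests. The genome-wide ranking scores every node
with a non-empty downstream neighborhood within `max_depth = 4` (four
layers), BH-adjusts across candidates, and breaks ties deterministically
by fold enrichment, then neighborhood size, then name. No
neighborhood-size bounds are imposed on candidates; with the defaults the
planted driver is recovered at rank 1 in 20/20 simulation replicates, so
bounds were left out rather than tuned.

## Co-expression modules

The construction is a standard unsigned weighted analysis: adjacency
|r|^β with β = 6, topological overlap
TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage
clustering of 1 − TOM, and a static cut. The static cut height default is
0.95: with β = 6, within-module TOM for realistically correlated genes
(|r| ≈ 0.7) sits near 0.15 (dissimilarity ≈ 0.85) while between-module
dissimilarity is ≈ 1, so 0.95 separates the two regimes with margin. A
cut at the frequently quoted 0.25 belongs to a different scale — the
module-eigengene *merge* height — and would leave every gene unassigned
under a static cut on 1 − TOM. Clusters below `min_size = 30` are labelled
"unassigned". Merge-height ties can produce sub-epsilon non-monotone
heights in average linkage; heights are made monotone (cummax) before
cutting.

## What the simulators emulate — and what they do not

`simulate_counts` reproduces the study conditions: 24 samples in groups
of 4/3/4/4/4/5; a 100-gene planted module with log2FC 2 (4-fold) in the
amyloid genotypes; 80% of that shift removed by driver knockout and half
of the removal in heterozygotes (`het_effect = 0.5`; a silent-het setting
`het_effect = 0` mirrors the observation that one driver allele changes
almost nothing); negative-binomial noise with a single dispersion of 0.1 —
a typical within-genotype value for inbred mouse brain — and log-normal
baseline abundances at 8–12 million reads. Dispersion is shared across
genes by default (simplest recoverable model); it does not emulate
per-gene dispersion trends, outlier samples, batch structure, or GC/length
biases, so passing recovery tests demonstrate correctness of the
statistical machinery, not robustness to those artefacts.

`simulate_causal_network` plants the structure the network stage is meant
to detect: 1000 nodes, driver layers of 25/50/100/150 with planted-module
fractions 0.6/0.45/0.3/0.2 (≈97 of the 100 module genes land in the four
layers), at least one previous-layer parent per layer node plus Poisson(0.5)
extras, and background nodes that attach only to earlier background nodes
or the deepest layer. Edges always point from earlier to later positions
in a fixed topological order, so the graph is acyclic and the planted
layers are exactly the driver's BFS layers by construction. Layer-1 nodes
head genuine sub-trees, so the layering signal does not trivially leak:
competitors see only a subset of the enriched layers, which is what makes
driver identification non-degenerate. It does not emulate estimated-network
error (false/reversed edges); the printed human-network enrichment
magnitudes are not reproducible without those networks and are treated as
structural anchors only.

`simulate_coexpression` draws five 60-gene single-factor modules
(loadings U(0.7, 0.95), noise sd 0.5, within-module |r| ≈ 0.65–0.8) plus
200 unit-variance background genes over 50 samples — enough samples that
background correlations (≈0.11) vanish under β = 6. It does not emulate
overlapping modules, module–module correlation, or eigengene–trait
structure.

The count and network generators draw the planted module membership as
their first RNG action from the shared seed, so a single
`simulation_config` yields a consistent truth across both.

## Problem sizes and numerical choices

The test suite and the acceptance script use the default sizes above:
5000 × 24 count matrices, 1000-node networks, 500 × 50 expression
matrices, with 20 replicates per recovery experiment, 500 enumeration
cases, 200 random digraphs, and 10,000 Gaussian replicates for the Grubbs
calibration; the full suite runs in about a minute on one core. Other
fixed choices: Grubbs uses the exact two-sided critical value
((n−1)/√n)·√(t²/(n−2+t²)) with t the upper α/(2n) t-quantile on n−2 df and
removes at most one point per call (iteration policy is deliberately not
automated); power is computed exactly from the noncentral t with
ncp = d·√(n1n2/(n1+n2)), two-sided by default; ΔΔCt assumes exact base-2
amplification efficiency; ortholog mapping defaults to case-folded symbol
identity with ambiguous one-to-many rows dropped and reported, since
symbol case conventions distinguish mouse and human and an explicit
two-column map can always be supplied.

## Known limitations

* Bayesian network *structure learning* is out of scope: networks are
  consumed as edge lists (TSV or SIF) and emulated by the simulator.
* The moderated model has no voom-style precision weights; very shallow
  or very uneven libraries would favour adding them.
* Module detection uses a static tree cut, not dynamic tree cutting; very
  unequal module sizes may need the cut height adjusted.
* Reported human-cohort enrichment magnitudes (70-fold first layer, etc.)
  depend on unavailable networks and universes; the workflow reproduces
  the *procedure* and validates it by planted-truth recovery instead.
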