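---
title: "Forest graphical models and functional node activities for tumor proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest graphical models and functional node activities for tumor proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`proteoforest` analyzes protein × sample log2-intensity matrices from
multi-tissue tumor cohorts: preprocessing, a forest-structured Gaussian
graphical model over proteins, functional-node activities, subtype discovery
with a differential-protein signature, external classification, and mixed
linear models for tissue-progression contrasts. This vignette explains the
statistical model behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-cohort generator does and does
not emulate, and the numerical and design choices made where the methodology
left room.

## Preprocessing

Raw intensities are log2-transformed (matrices already on the log2 scale pass
through). A protein is retained when at least `min_valid_fraction` (default
0.75, inclusive comparison: "at least 75%") of its values are observed in at
least one tissue group (NT, P, T, LN); groups without samples are skipped
rather than divided by. Filtering runs **before** imputation, so imputation
only ever sees proteins with substantial observed support.

Missing proteomic intensities are predominantly left-censored: a value is
absent because it fell below the detection limit, not at random. The imputer
therefore draws each missing cell in sample *s* from
N(μ̂ₛ − d·σ̂ₛ, (w·σ̂ₛ)²), where μ̂ₛ and σ̂ₛ are the sample's observed mean and
standard deviation. The defaults d = 1.8 and w = 0.3 are the de facto
standard parameterization of downshifted-normal imputation in proteomics
practice, applied per sample (column-wise); both parameters and the mode are
configurable (`preprocess_config()`). Imputation is deterministic under the
configured seed, touches exactly the missing cells, and requires at least two
observed values per sample.

## The forest graphical model

For proteins *i*, *j* with Pearson correlation *r* over *n* samples, adding
the edge (*i*, *j*) to a Gaussian forest model improves the model deviance by
−n·ln(1 − r²). Penalizing each edge by ln n (BIC; an AIC penalty of 2 is
available via `penalty = "aic"`) gives the weight

w(i, j) = −n·ln(1 − r²) − ln n.

The acyclic model minimizing BIC is the maximum-weight spanning forest over
the edges with positive weight, found by Kruskal's algorithm
(`learn_minimal_bic_forest()`, or the `forest_pgm()` front end). Properties
worth noting:

* **Forest, not tree.** Edges with non-positive penalized weight are
  excluded, so proteins without a sufficiently correlated partner stay
  isolated and the model may have several components.
* **Determinism.** Weight ties are broken by the lexicographic index pair.
* **Degenerate inputs.** Zero-variance proteins are rejected by name
  (their correlation is undefined); r² is clipped at 1 − 10⁻¹² so duplicated
  proteins get a large finite weight and rank first rather than producing an
  infinite weight.

`split_into_branches()` decomposes the forest into branches: while any
connected component exceeds `max_size` (default 300), that component's
minimum-weight edge is deleted; components below `min_size` (default 10) are
kept but flagged unassignable. This size-bounded weakest-edge cutting is an
explicit, reproducible surrogate for the visual branch delimitation common in
published network analyses; the defaults produce on the order of 10–20
annotatable branches from a ~2300-protein forest, matching the granularity at
which functional nodes are usually reported.

## Functional nodes and activities

Each assignable branch is tested for gene-set overrepresentation against the
background of quantified proteins (the filtered matrix — not the genome; this
is the conservative background choice). The p-value is the exact
hypergeometric upper tail P(X ≥ k), fold enrichment is (k/m)/(K/N), and
Benjamini–Hochberg correction is applied within each branch, since branches
are annotated independently. The branch's *main function* is the passing term
with minimum q (ties: larger overlap, then term id; thresholds q ≤ 0.05 and
overlap ≥ 3 by default); branches where nothing passes are carried as
function-free nodes, which do occur in real cohorts.

Tightly co-regulated processes can travel together in one branch. When a
branch additionally contains at least `secondary_coverage` (default 0.8) of a
*second* term's background members — that term also passing the q and overlap
thresholds, and its proteins mostly distinct from the primary function —
`functional_nodes()` emits a secondary node for it. This mirrors the
dual-function nodes reported in practice (a single branch carrying, say, both
a secretion and a metabolism module) while keeping each node's activity
tied to one process: the activity of a node in a sample is the arithmetic
mean of the log2 intensities of *its* main-function proteins. Activity is
affine-equivariant in the matrix, and repeated term names are disambiguated
("adhesion", "adhesion 2", ...).

## Subtypes, signature and external classification

Tumor samples are clustered on correlation distance (1 − Pearson r computed
across the full filtered protein set) with average (UPGMA) linkage, and the
dendrogram is cut at exactly k clusters (default 3). Labels T1..Tk are
assigned by decreasing cluster size (ties: first appearance), making the
labeling deterministic; Pearson distance makes the clustering invariant to
per-sample affine rescaling.

The differential signature comes from a multiclass SAM: per protein,

d = sqrt( (Σnₖ / Πnₖ) · Σₖ nₖ(x̄ₖ − x̄)² ) / (s + s₀),

where s is the pooled standard error and s₀ the exchangeability constant
(default: the median of s across proteins), so that for two balanced groups d
reduces to |mean difference| / (SE + s₀). The null distribution is obtained
by permuting class labels (`n_perm` ≥ 100; the pipeline default is 1000).
For each candidate threshold Δ the estimated FDR is
π̂₀ · median_b #{d* ≥ Δ} / #{d ≥ Δ}, with π̂₀ estimated as the fraction of
observed scores inside the interquartile range of the permuted scores
(capped at 1). The selected signature is the largest set whose estimated FDR
does not exceed `target_fdr` (default 0.05). Everything is deterministic
under the seed.

`build_centroids()` averages the signature proteins within each subtype;
`classify_by_centroid()`/`predict()` assign a sample to the subtype whose
centroid it matches best over the signature proteins present — Pearson
correlation by default (shift- and scale-invariant, the standard choice for
single-sample subtype predictors; Euclidean available). At least
`min_fraction` (default 0.8) of the signature must be present, reflecting
external cohorts where only part of a protein signature maps to measured
genes; an identifier map (protein → gene) can be supplied. Exact score ties
resolve to the lexicographically first label and are flagged.

## Group statistics

Node activities are compared between tissues with a linear mixed model:
tissue as fixed effect (cell-means coding) and a random intercept per
patient, because the cohort design is paired — several tissues, sometimes
several punches, per patient. Fits use REML (`lme4`); each requested contrast
(default NT→T, P→T, T→LN) is a linear combination of the fixed effects with
a two-sided Wald z-test. Wald rather than likelihood-ratio tests keep the
procedure fast and deterministic; with dozens of samples per fit the normal
approximation is accurate. When the random-intercept fit is singular (or the
response is degenerate) the model falls back to fixed effects only and the
row is flagged `model = "fixed"`; in the balanced two-tissue case with no
between-patient variance the estimate then equals the raw group mean
difference. Contrasts naming an absent tissue are skipped with a warning. No
multiple-testing correction is applied across nodes by default, mirroring the
plain p < 0.05 reporting convention for node activities; a BH option exists
in `summarize_differential_nodes()`.

Between-subtype comparisons of node activities use two-sided Mann–Whitney
tests: exact when both groups have at most 8 tie-free samples, otherwise the
normal approximation with continuity and tie correction (the two branches
agree to about 0.011 in p at n₁ = n₂ = 8, the crossover point). Significance
tiers follow the standard star convention (\*\*\*\* < 0.0001, \*\*\* < 0.001,
\*\* < 0.01, \* < 0.05). Clinical associations use Pearson chi-squared tests
without continuity correction, reporting expected counts and flagging tables
with expected counts below 5.

The pipeline (`run_pipeline()`) executes the stages in the fixed order
io → preprocess → network → annotation → subtyping → group_stats, derives
per-stage seeds deterministically from the global seed, snapshots the
configuration as JSON, logs each stage, and halts with the stage name on
failure. Reruns with the same configuration are bit-identical. Per-subtype
tissue contrasts reuse the cohort-wide functional nodes by default so that
node definitions are comparable across subtypes (and the run stays fast);
`per_subtype_networks = TRUE` instead re-learns a forest and nodes within
each subtype's samples, which is closer to publishing one network per subtype
but makes node identities subtype-specific.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the analysis
assumes, at the scale of the motivating study: 52 patients, all with a tumor
sample and with non-tumor, PanIN and lymph-node samples available with
probabilities 47/52, 43/52 and 31/52; 2311 proteins in 10 functional blocks
whose sizes are log-uniform between 50 and 500; per-protein baselines
N(22, 1.5²) log2 units. Within each block a random spanning tree defines a
tree-structured Gaussian with adjacent-protein correlation ρ = 0.6 (scaled by
the residual sd of 0.5); three latent subtypes shift their characteristic
blocks by 1.0 log2 units in *all* of a patient's samples (the molecular
identity is present from the earliest lesion); tissue-progression shifts of
±0.8 log2 units per step follow a map with clear rises and falls along
NT→P→T→LN (secretion and immune/adhesion blocks peak in the tumor,
nucleoplasm rises monotonically, ECM falls, mitochondria/metabolism and
translation peak in the preneoplastic lesion); patients get a N(0, 0.3²)
random intercept. The shift magnitudes are ordinary one- to two-fold protein
changes; 0.8 equals 1.6 residual standard deviations, comfortably above the
1.5-sd detectability margin used in the recovery checks. Missingness is
missing-not-at-random: the probability of censoring is logistic in the true
intensity (steepness 1.5 per log2 unit), with the midpoint calibrated by
root-finding so the expected missing fraction equals the configured target
(default 10%) — the left-censoring structure that downshifted-normal
imputation presumes. The generator returns the ground truth (block
membership, tree edges, subtype labels, shift maps) so every downstream stage
can be scored.

What the generator does **not** emulate: peptide-to-protein roll-up and
protein-specific measurement error, batch or run-order effects, non-Gaussian
heavy tails, overlapping or hierarchically redundant annotation terms (each
block maps to one synthetic term, plus random decoy sets), correlations among
clinical covariates, and any survival structure. Passing tests therefore
demonstrate that the pipeline recovers planted structure under its own model
assumptions — not that those assumptions hold for any particular real
dataset.

Two structural consequences of the generative model are worth understanding.
First, subtype and tissue shifts induce correlation *between* blocks that are
shifted together; the maximum-weight forest can then route co-shifted blocks
(for example the two blocks raised in the same subtype) through one branch
whose combined size stays below `max_size`, so the smaller block's term ranks
second rather than first in that branch — exactly the situation the
secondary-function mechanism addresses, and the reason end-to-end function
recovery is asserted as "every planted term is assigned to some node" rather
than "every plurality branch ranks its term first". Second, the tree
correlation decays as ρ^distance within a block, so distant same-block pairs
are weakly correlated and large blocks shed small fragments below `min_size`;
those fragments are deliberately left unassigned.

`generate_clinical_table()` draws independent categorical covariates from
configurable marginals typical of a resected PDAC cohort (60/40 gender,
76% head location, two-thirds moderate grade, and so on), and
`generate_external_cohort()` draws samples from trained subtype centroids
with independent noise, removes a random fraction of signature features
(default 9%, emulating a signature that only partially maps onto an external
platform) and translates identifiers through a synthetic protein→gene map.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise the methods at realistic
scale while completing quickly: the end-to-end recovery checks use one
default-scale cohort (2311 proteins, 52 patients, ~170 samples); forest
learning is verified against exhaustive enumeration on all instances up to 6
vertices; tree-structure recovery uses 20 replicates of a 20-vertex tree at
n = 2000; SAM calibration uses 20 cohorts of 500 proteins × 60 samples with
10% true signals and 200 permutations; the mixed-model operating
characteristics use 500 null replicates of a 40-patient incomplete design
(type-I error) and 100 replicates of a complete 52-patient paired design
(recovery of a +2.0 effect at residual sd 0.5, where the contrast's sampling
sd of ≈ 0.1 makes the ±0.2 recovery band attainable; under the incomplete
design the sampling sd is ≈ 0.13 and no correct implementation meets that
band).

## Known limitations

* A forest cannot represent cyclic conditional-dependence structure; it is a
  sparse organizational scaffold, not a full Gaussian graphical model.
* Branch delimitation by size bounds is a surrogate for expert curation; the
  `max_size`/`min_size` defaults control granularity, not biology.
* The SAM FDR is an estimate (permutation-based, π̂₀-adjusted); its accuracy
  degrades with strong inter-protein correlation.
* Wald p-values from mixed models are mildly anti-conservative for very few
  patients; the type-I simulations bound this at the cohort sizes intended.
* Downshifted-normal imputation assumes left-censoring; applying it to data
  whose missingness is not intensity-dependent biases low.
* No between-sample normalization is applied; matrices are expected to be
  normalized upstream.
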