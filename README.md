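# proteoforest

Forest-structured graphical models and functional-node analysis for
multi-tissue tumor proteomics cohorts.

## The problem

Deep proteomic profiling of tumor cohorts produces a protein × sample matrix
of log2 intensities with substantial left-censored missingness. Beyond
single-protein statistics, a systems view asks: how do proteins organize into
co-expressed functional modules, do tumors fall into molecular subtypes, and
which biological processes change along disease progression — from non-tumor
tissue (NT) through preneoplastic lesions (P) to primary tumor (T) and lymph
node metastasis (LN) — within each subtype?

`proteoforest` implements that full workflow for cohorts of patients
contributing paired tissue samples (the motivating setting is pancreatic
ductal adenocarcinoma, but nothing is organ-specific):

1. **Preprocessing** — log2 transform; retain a protein only if ≥ 75% of its
   values are observed in at least one tissue group; impute the remaining
   missing values per sample from a *downshifted normal*
   N(μ̂ₛ − 1.8·σ̂ₛ, (0.3·σ̂ₛ)²), the standard treatment for intensities
   censored below the detection limit.
2. **Network** — learn a forest-structured Gaussian graphical model over
   proteins with no prior biological information. Every protein pair gets the
   penalized deviance weight *w*ᵢⱼ = −n·ln(1 − r²ᵢⱼ) − ln n (BIC penalty per
   edge); the maximum-weight spanning forest over the positive-weight edges —
   Kruskal's algorithm — is the acyclic model minimizing BIC.
3. **Functional nodes** — split the forest into branches of bounded size by
   repeatedly deleting the weakest edge of oversized components; assign each
   branch its most overrepresented gene-set term (exact hypergeometric test
   against the quantified background, Benjamini–Hochberg within branch); the
   *functional node activity* of a sample is the mean log2 intensity of the
   node's main-function proteins.
4. **Subtyping** — hierarchical clustering of tumor samples (correlation
   distance, average/UPGMA linkage) cut at k = 3; a multiclass SAM
   (moderated between-group statistic with exchangeability constant s₀ and
   label-permutation FDR) defines the differential-protein signature;
   per-subtype centroids over the signature classify external samples by
   Pearson correlation, tolerating partial signature coverage.
5. **Group statistics** — linear mixed models (tissue fixed effect, patient
   random intercept; REML, Wald tests) for the NT→T, P→T and T→LN contrasts
   of each node activity; Mann–Whitney tests between subtypes; chi-squared
   tests against clinical covariates; and a compact progression table listing
   the significant nodes per subtype and contrast with direction arrows.

A synthetic-cohort generator (`generate_cohort()`) reproduces the statistical
structure this analysis assumes — block-correlated proteins (tree-structured
Gaussian within blocks), three latent subtypes with block-specific shifts,
tissue-progression shifts, patient random effects, and intensity-dependent
(MNAR) missingness — so every stage is testable end to end without access to
a real cohort.

## Worked example

A small synthetic cohort (24 patients, 300 proteins in 5 functional blocks),
run through the whole pipeline:

```r
library(proteoforest)

cfg <- simulation_config(n_patients = 24, n_proteins = 300, n_blocks = 5,
                         block_size_range = c(30, 100), seed = 7)
coh <- generate_cohort(cfg)

x <- preprocess_matrix(coh$matrix, coh$manifest, preprocess_config(seed = 1))
#> 300 -> 285 proteins survive the 75% valid-value rule

fit <- forest_pgm(x)
summary(fit)
#> Forest graphical model
#>   vertices:   285
#>   edges:      284
#>   components:1 (largest 285)
#>   edge weights: [12.78, 148.1]

branches <- split_into_branches(fit, max_size = 120, min_size = 5)
nodes <- functional_nodes(branches, coh$annotation, rownames(x))
nodes[[1]]
#> functional_node (120 proteins): adhesion [SYN:01], 84 main-function proteins, q = 7.56e-19

mf <- match_manifest(x, coh$manifest)
tumor <- mf$sample_id[mf$tissue == "T"]
subtypes <- hcl_subtypes(x[, tumor], k = 3)
subtypes
#> subtype_assignment over 24 samples:
#> T1 T2 T3
#>  8  8  8

sam <- sam_multiclass(x[, tumor], subtypes, n_perm = 200, seed = 2)
model <- build_centroids(x[, tumor], subtypes, sam$selected)
ext <- generate_external_cohort(model, n = 100, feature_dropout = 0.09, seed = 3)
pred <- predict(model, ext$matrix, idmap = ext$idmap)
mean(as.character(pred) == as.character(ext$labels))
#> [1] 1

acts <- node_activity_matrix(x, nodes)
ct <- tissue_contrast_table(acts, coh$manifest)
head(ct[order(ct$p), ], 5)
#>           node contrast estimate     se        p direction model
#> 1     adhesion    NT->T    0.894 0.0432 5.07e-95        up mixed
#> 2     adhesion     P->T    0.799 0.0447 1.84e-71        up mixed
#> 3     adhesion    T->LN   -0.790 0.0474 2.73e-62      down mixed
#> 10 nucleoplasm    NT->T    0.785 0.0533 3.57e-49        up mixed
#> 12 nucleoplasm    T->LN    0.847 0.0585 1.31e-47        up mixed
```

The planted tissue shifts in this toy cohort are ±0.8 log2 units; the mixed
models recover them with the right sign and near-nominal magnitude (adhesion
rises into the tumor and falls in lymph nodes; nucleoplasm rises
monotonically), and the centroid classifier recovers every external sample's
subtype despite 9% of the signature being absent. In this small cohort 3 of
the 5 blocks carry subtype shifts, so most proteins are genuinely
differential and SAM selects nearly all of them; on the full-scale default
cohort the signature is a subset.

One call runs everything and writes the stage products, a log and a config
snapshot into a directory:

```r
run_pipeline(pipeline_config(out_dir = "run1",
                             simulate = simulation_config(), seed = 5))
```

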