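# clinclust

Robustness evaluation for unsupervised patient stratification from classical
blood biomarkers.

## What this is for

Clustering people by routine laboratory values (blood counts, lipids,
glucose, ...) is a candidate route to patient stratification: clusters may
be enriched for diseases, complications or lifestyle traits. Before such
clusters can be trusted, two robustness questions need answers:

- **Methodological robustness** — do the clusters (and their quality) depend
  on how markers were pre-processed and which clustering algorithm was used?
- **Cohort robustness** — do the clusters, and the clinical traits enriched
  in them, reappear when the scheme is projected onto an independent cohort?

`clinclust` implements the full evaluation grid: 4 pre-processing variants
× 3 clustering algorithms, cluster-quality scoring with dropout resampling,
classifier-based projection of training clusters onto a validation cohort,
and cross-cohort validated-enrichment accounting. A synthetic cohort-pair
generator with planted truth (subgroups, age effects, trait associations)
makes the whole pipeline testable end to end.

## The statistics at the core

- **Cluster quality**: homogeneity minus separation,
  `H_A − S_A`, where `H_A` is the mean Pearson similarity of each clustered
  sample to its cluster centroid and
  `S_A = Σ_{i<j} n_i n_j sim(c_i, c_j) / Σ_{i<j} n_i n_j`
  over centroid pairs. Reported as mean ± sd over 10 reruns with 3% of
  samples dropped; pipelines are compared by Student's t on those lists.
- **Graph clustering (CLICK-style)**: pairwise similarities are modeled as a
  mates/non-mates normal mixture (EM, pooled variance); edges carry the
  log-likelihood-ratio weight and components are split along minimum-weight
  cuts until every kernel's cuts have positive total weight; adoption,
  merging, and a reassignment polish follow. Samples that never fit a kernel
  stay `UNCLASSIFIED`.
- **Enrichment**: per (cluster, trait) hypergeometric upper-tail test,
  `P(X ≥ k)`, with enrichment factor `(k/n) / (K/N)`; a *validated
  enrichment* is significant in both cohorts for the same (projected)
  cluster.

## Worked example

```r
library(clinclust)

# a synthetic cohort pair: 3 subgroups, 12 markers, 4 traits
# (traits 1..3 planted at odds ratio 8, one per subgroup)
spec <- generator_spec(n_train = 300, n_valid = 300, n_subgroups = 3,
                       n_markers = 12, separation = 6,
                       skewed_markers = integer(0),
                       marker_scales = rep(1, 12),
                       marker_offsets = rep(0, 12),
                       age_slopes = rep(0, 12), n_traits = 4,
                       planted_odds = data.frame(subgroup = 1:3,
                                                 trait = 1:3, odds = 8),
                       seed = 42)
pair <- generate_cohort_pair(spec)

ppt <- preprocess(pair$train, "zscore")
cl  <- click_cluster(ppt$cohort, click_params(seed = 1))
cl
#> <clustering> click: 300 samples, K = 3, 20 unclassified
adjusted_rand_index(cl$labels, pair$truth$train_labels)
#> [1] 1

# project the validation cohort onto the training clusters
ppv <- preprocess(pair$valid, "zscore")
pj  <- train_projector(ppt$cohort, cl, seed = 2)
vcl <- project(pj, ppv$cohort)

# cross-cohort validated enrichment
tr  <- enrich_clusters(cl, pair$train_traits, min_positives = 20)
va  <- enrich_clusters(vcl, pair$valid_traits, min_positives = 20)
validate_enrichments(tr, va)
#> <validation_report> valid 3/3, distinct 3/3, clusters 3/3, factor 2.07
```

The three planted (subgroup, trait) associations are recovered as validated
enrichments — significant in the training clusters and again in the same
(projected) clusters of the validation cohort — with an average enrichment
factor of 2.07 for the three most significant, i.e. those traits are about
twice as frequent in their cluster as in the cohort overall.

The full 12-cell grid, with Table-style CSV reports:

```r
cfg <- experiment_config(generator = generator_spec(seed = 1),
                         seed = 1, out_dir = "out")
res <- run_experiment(cfg)   # quality_table.csv, validation_table.csv,
                             # trait_grid.csv, enrichment_records.csv, run_log.txt
```

A command-line front end with `synth` / `run` / `quality` / `enrich` verbs is
installed at `inst/cli/clinclust.R`.

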