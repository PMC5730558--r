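# gliomaTME

Immune microenvironment profiling of experimental rat C6 gliomas, as a
tested, reusable R pipeline. The package re-implements the computational
backbone of a typical rat-glioma immunoprofiling study — flow-cytometry
population quantification, microarray differential expression, rank-based
Gene Ontology enrichment, M1/M2 marker-panel scoring, and cross-species
glioblastoma-subtype similarity — and couples it to a seeded synthetic-data
module that generates every input with planted ground truth, so the whole
pipeline can be exercised and validated end-to-end without any external
download.

It is intended for computational biologists who want a transparent,
scriptable version of these analyses: every estimator is a plain R function
with tests against independent brute-force oracles, and every synthetic
study records its ground truth in a sidecar the estimators never see.

## What it computes

**Quadrant-gate flow cytometry.** Positivity cutoffs are the 99th percentile
of the matched isotype-control intensities, per channel; the CD45 low/high
separator is the minimum-density point between the two dominant modes of
log-intensity among CD45-positive events. Events are classified as microglia
(CD11b⁺CD45^low), blood-derived macrophages (CD11b⁺CD45^high), leukocytes
(CD11b⁻CD45^high), Treg/Th/Tc (FOXP3⁺/CD4⁺/CD8a⁺) or MDSC (CD11b⁺Gr1⁺), and
reported as fractions of all gated events. Group differences use Welch's
t-test followed by a two-sided Mann–Whitney U test (exact by enumeration for
combined n ≤ 20, ties included).

**Differential expression.** Per gene, Welch's t statistic
t = (x̄_T − x̄_C)/√(s²_T/n_T + s²_C/n_C) with Welch–Satterthwaite degrees of
freedom; discoveries at a uniform level α get the plug-in false discovery
rate estimate FDR̂ = m·α/k (expected false positives over observed
discoveries), plus per-gene Benjamini–Hochberg q-values. Helpers produce the
control-centred log2-ratio matrix for heatmaps, top-K strongest-regulation
lists, and M1/M2/GAM marker-panel reports with signed linear fold changes.

**GO enrichment.** Genes ranked by signed log2 fold change; each term's
member ranks are compared with the remaining genes by a two-sided rank-sum
(Mann–Whitney) test, BH-corrected across terms; annotations are consumed
flat (GMT or term/gene TSV).

**Cross-species subtype similarity.** Human tumors are assigned to subtypes
(Proneural, Neural, Classical, Mesenchymal) by a one-sample
Kolmogorov–Smirnov statistic on the normalized within-sample ranks of each
subtype's signature genes, signed toward high expression. Rat genes are
mapped to human orthologues (one-to-one filtered), per-replicate
tumor/normal log2 fold-change vectors are built, and subtypes are ranked by
Spearman correlation between the rat vectors and subtype-mean human
references, with pairwise two-sided Mann–Whitney tests.

## Worked example

```r
library(gliomaTME)

# a day-21 tumor-bearing-brain myeloid panel with planted fractions
sim <- generate_event_panel(myeloid_panel_config("glioma", day = 21,
                                                 n_events = 50000, seed = 7))
th <- derive_thresholds(sim$stained, sim$isotype, pos_quantile = 0.99)
classify_myeloid(sim$stained, th)
#> <population_fractions> n = 50000
#>   microglia       14057   28.11%
#>   macrophage       2017    4.03%
#>   leukocyte        9940   19.88%
#>   unclassified    23986   47.97%
```

The planted truth (recorded in `sim$truth`, never inside the event table)
was 28% microglia, 4% macrophages, 20% leukocytes: the isotype-derived
quadrant gates recover all three to within binomial sampling error.

```r
# cross-species subtype ranking on a simulated cohort
cohort <- generate_human_cohort(cohort_sim_config(seed = 1))
ass <- assign_subtypes(cohort$human, cohort$signature)
mapped <- map_orthologs(rownames(cohort$rat$expr), cohort$orthologs)
similarity_ranking(fold_change_vector(cohort$rat),
                   fold_change_vector(cohort$human), ass, mapped)
#> <similarity_result> 1820 mapped genes, mode 'rat'
#>   Mesenchymal  mean rho = +0.178 (sd 0.005)  <- winner
#>   Classical    mean rho = -0.010 (sd 0.011)
#>   Proneural    mean rho = -0.017 (sd 0.004)
#>   Neural       mean rho = -0.026 (sd 0.009)
```

The cohort was generated with a Mesenchymal-like rat study (attenuated
centroid, 660 of 840 signature genes surviving the ortholog map); the
ranking recovers it.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study on
simulated data and write their tables under `results/`:

1. `01_flow_cytometry.R` — myeloid quadrants (sham vs day-21 glioma),
   accumulation kinetics at days 8/14/21, T-cell and MDSC panels, per-animal
   group comparisons.
2. `02_bulk_differential_expression.R` — hemisphere differential expression
   (4 control vs 3 tumor), plug-in FDR, top-50 list, centred heatmap matrix.
3. `03_go_enrichment.R` — rank-based GO enrichment of the hemisphere
   fold-change profile, top-30 up/down term lists.
4. `04_microglia_profile.R` — sorted-microglia differential expression and
   M1/M2/GAM marker-panel reports.
5. `05_subtype_similarity.R` — KS subtype assignment, ortholog mapping and
   Spearman similarity ranking.

Each is run as `Rscript analysis/<script>` from the repository root.

## Vignette

`vignettes/glioma-immune-profiling.Rmd` documents the models, the tunable
parameters and their defaults, what the simulator does and does not emulate,
the numerical conventions (tie handling, degenerate inputs, threshold
boundaries), and known limitations.
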