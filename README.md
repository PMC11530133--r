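# apucnet

Second-order gene-association networks, signature scoring, and survival
analysis for androgen-pathway gene modules in prostate cancer RNA-seq
cohorts.

## The problem

In advanced prostate cancer, a handful of genes governing androgen
production, uptake and conversion (APUC) — canonically the six-gene module
*HSD3B1*, *HSD3B2*, *CYP11A1*, *CYP11B1*, *CYP17A1*, *CYP3A43* ("APUC-6") —
can act together, and tumors driven by this ligand-production program behave
differently from tumors driven by androgen-receptor (*AR*) overexpression.
Detecting such a *coalescent module* needs more than pairwise co-expression:
two genes belong together when they relate to the **whole transcriptome** in
the same way. `apucnet` implements that second-order measure and everything
around it needed to go from an expression matrix to survival curves for
expression-defined patient groups.

For genes $i, j$, with $C$ the gene-by-gene Spearman correlation matrix
across samples, the association is

$$A_{ij} = \mathrm{cor}\big(C_{i,\,-\{i,j\}},\ C_{j,\,-\{i,j\}}\big), \qquad A_{ii} = 1,$$

the Pearson correlation of the two genes' correlation profiles with the self
columns removed. The *coalescence score* of a gene set is the mean
off-diagonal $A_{ij}$ among its members; tracked across benign → primary →
metastatic cohorts it quantifies stage-dependent module formation.

On top of this the package provides: TPM harmonization (counts/FPKM → TPM,
log transform, zero-gene filtering, duplicate-id handling), sum-log and
mean-z signature scoring with strict-above percentile stratification
(HIGH/LOW/MID and four-way APUC-6 × AR groups), per-stratum correlation
panels with Benjamini–Hochberg adjustment, Mann–Whitney quartile-contrast
differential expression, from-scratch permutation GSEA (ES/NES/FDR, gene-set
or phenotype permutation), Kaplan–Meier/log-rank/Cox group comparison, the
">100-day claims gap" death-imputation rule for real-world survival data,
and a synthetic multi-cohort simulator with planted ground truth.

## Worked example

Simulate a three-stage study with the module correlation staged at
0.1 / 0.4 / 0.8, then run the analysis end to end:

```r
library(apucnet)

cfg <- sim_config(n_samples = c(benign = 100, primary = 150, metastatic = 208),
                  seed = 11)

# stage-wise coalescence of the planted module
sapply(names(cfg$n_samples), function(st)
  coalescence_score(alan_matrix(generate_expression(cfg, st)), cfg$module_genes))
#>     benign    primary metastatic
#>      0.063      0.552      0.949
```

The module's mean second-order association rises from near zero in benign
tissue to ~0.95 in the metastatic cohort — the coalescence signature.
Scoring and stratifying the 208 metastatic samples:

```r
met  <- generate_expression(cfg, "metastatic")
apuc <- scale_0_100(sumlog_score(met, cfg$module_genes, "APUC6"))
table(stratify_extremes(apuc, 0.25))
#> HIGH  LOW  MID
#>   52   52  104
```

Strict-above type-7 quantile cuts give exactly 52 HIGH and 52 LOW of 208 at
the quartile threshold (and 21 at the 90th percentile). Crossing with an AR
score and comparing survival of the two discordant groups:

```r
ar     <- sumlog_score(met, "AR", "AR")
groups <- four_group_labels(apuc, ar, 0.25)
clin   <- generate_clinical(cfg, groups)
compare_groups_os(clin, groups, c("APUC6hi_ARlo", "APUC6lo_ARhi"))
#>                    contrast n_a n_b    hr ci_lo ci_hi logrank_p median_a median_b
#> 1 APUC6hi_ARlo:APUC6lo_ARhi  20  17 0.444 0.201  0.98    0.0408     30.6     21.7
```

The planted protective group (module-high/AR-low, simulated at half the
hazard of module-low/AR-high) comes out with HR < 1 and a longer median OS,
as designed. `generate_study_bundle()` writes the whole fixture (expression
TSVs per stage, clinical table with claim dates, gene-set GMT) for file-based
workflows.

## Documentation

The methods vignette (`vignettes/apucnet-methods.Rmd`) describes the model
and its assumptions, every pinned convention (quantile type, tie policy,
logFC definition, claims-rule boundaries, tie handling in Cox models), what
the simulator does and does not emulate, and known limitations.
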