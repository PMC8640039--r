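# sbmie

Diet-corrected gut-content metabolomics for soybean-meal-induced enteritis
(SBMIE).

Replacing fish meal (FM) with soybean meal (SBM) in carnivorous fish diets
induces enteritis of the distal intestine (DI). Untargeted LC-MS metabolomics
of the DI *contents* (digesta) is an attractive non-lethal window on this
process, but it has a confound that tissue metabolomics does not: a metabolite
that differs between dietary groups in the digesta may simply have been eaten,
not produced or absorbed by an inflamed gut. `sbmie` implements the downstream
analysis chain for this design, for three compartments (diet, DI contents, DI
tissue) measured in positive and negative ion modes across an ordered dose
ladder (e.g. `FM < SBM20 < SBM40`, 20%/40% substitution):

1. **Differential analysis** per feature: log2 fold change
   `log2FC = log2(mean_trt / mean_ctl)`, a Welch *t* (or Student/Wilcoxon)
   test on log2 intensities, and the PLS-DA **variable importance in
   projection**, `VIP_j = sqrt( p * Σ_a SS_a (w_ja/‖w_a‖)² / Σ_a SS_a )`
   from a NIPALS PLS1 fit (so `Σ_j VIP_j² = p`). Metabolite significance is
   `P < 0.05` and `VIP ≥ 1`; the DEG rule `|log2FC| > 1 & P < 0.05` is also
   available, as are strict monotone dose-trend profiles (A: rising, B:
   falling).
2. **Diet-background filtration**: content-differential metabolites that are
   also diet-differential are kept only when the trends are contrary or the
   log2FC variation range exceeds 2 — otherwise they are treated as dietary
   carry-over and removed.
3. **Biomarker screening**: top-10 VIP per ion mode, cross-mode
   deduplication by metabolite name, intersection across substitution levels
   into "core biomarkers", and validation by z-scores against the control,
   ROC AUC (Mann–Whitney `U/(n₁n₂)`, ties ½) and significance-masked Pearson
   correlation.
4. **Exchange analysis**: metabolites differential in *both* contents and
   tissue with strictly opposite trends are classified as
   `content_up_tissue_down` / `content_down_tissue_up` — candidate
   lumen↔mucosa transfers.
5. **Pathway over-representation** (hypergeometric upper tail) and
   **alpha diversity** (observed species, Shannon, Gini–Simpson, classical
   Chao1, ACE, Good's coverage) for companion 16S OTU tables.
6. A **seeded synthetic-data generator** that emulates the whole design
   (3 groups, n = 12 content/tissue samples per group, ~2,000 positive- and
   ~1,100 negative-mode log-normal features) with planted differential,
   diet-derived and exchanged features plus ground-truth labels, so every
   stage is testable without any raw data.

All user-facing functions take plain tibbles (a feature table =
`feature_id`, optional `feature_name`, one numeric column per sample;
metadata = `sample_id`, `group`, `compartment`, `ion_mode`) and return
tibbles, so stages chain with the pipe. `plsda()` fits come with broom-style
`tidy()`/`glance()` methods; `plot_volcano()`, `plot_zscores()`,
`plot_correlation()` and `plot_alpha_diversity()` give ggplot2 graphics.

## Worked example

```r
library(sbmie)
library(dplyr)

sim <- simulate_metabolome(sim_spec(n_features = c(positive = 600, negative = 400),
                                    seed = 42))

content <- diff_features(sim$tables$content_positive, sim$metadata, "FM", "SBM40") |>
  classify_differential()
count(content, trend)
#>   trend     n
#> 1 down     42
#> 2 none    511
#> 3 up       47
```

47 features rise and 42 fall significantly in SBM40 digesta (the generator
planted 27 true up- and 27 true down-shifts in this table; the remainder are
the expected false positives at raw `P < 0.05`). Now remove the dietary
background:

```r
diet <- diff_features(sim$tables$diet_positive, sim$metadata, "FM", "SBM40") |>
  classify_differential()
flt <- apply_diet_filter(diet, content)
lengths(flt$partition)
#> content_only    diet_only co_contained
#>           72           20           17
count(flt$decisions, decision)
#>   decision                n
#> 1 keep_contrary_trend     9
#> 2 remove                  8
```

Of 17 metabolites differential in both diet and contents, 9 show contrary
trends (kept: the intestine actively reversed the dietary signal) and 8 share
the diet's trend within a log2FC range of 2 (removed as carry-over) — exactly
the planted diet-derived structure. Screen biomarkers across both ion modes
and validate:

```r
neg <- diff_features(sim$tables$content_negative, sim$metadata, "FM", "SBM40") |>
  classify_differential()
scr <- screen_biomarkers(content, neg, k = 10)
length(scr$panel); scr$co_contained_modes
#> [1] 19
#> [1] "SharedMetab_2"

roc_auc_table(sim$tables$content_positive, sim$metadata, "FM", "SBM40",
              features = scr$top_positive$feature_id)$auc |> range()
#> [1] 1 1
```

The 10+10 per-mode panels merge to 19 biomarkers (one metabolite detected in
both modes), and every panel member separates the groups perfectly
(AUC = 1 at these planted effect sizes). Finally, the content↔tissue
exchange classification:

```r
tissue <- diff_features(sim$tables$tissue_positive, sim$metadata, "FM", "SBM40") |>
  classify_differential()
ex <- exchange_classify(content, tissue)
count(ex, exchange_class)
#>   exchange_class             n
#> 1 content_down_tissue_up     6
#> 2 content_up_tissue_down     6
#> 3 none                     588
rank_representatives(ex, "content_up_tissue_down", k = 3)
#>   feature                  content_log2FC content_p tissue_log2FC tissue_p ...
#> 1 Metabolite_positive_0046           1.88  1.92e-10         -1.84 2.66e-14
#> 2 Metabolite_positive_0047           2.15  2.07e-13         -2.08 7.63e-10
#> 3 Metabolite_positive_0043           2.06  1.00e-12         -1.90 7.20e-10
```

Both planted exchange classes are recovered in full (6 + 6), and the
representatives table mirrors the published layout: opposite log2 fold
changes, significant in both compartments.

The package also ships the published worked-example tables
(`sbmie_example("vip_top10")`, `"level_panels"`,
`"exchange_representatives")`): merging the printed per-mode top-10 VIP lists
gives the 17-metabolite panels with 3 cross-mode duplicates, intersecting the
two level panels gives the 14 "core biomarkers" plus 3 level-specific
metabolites each, and the 20 printed representative metabolites classify
10/10 into each exchange class.

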