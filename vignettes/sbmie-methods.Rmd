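---
title: "Methods: diet-corrected gut-content metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-corrected gut-content metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sbmie)
library(dplyr)
```

## The problem and the model

Soybean-meal-induced enteritis (SBMIE) is studied by feeding fish a control
fish-meal (FM) diet and diets with increasing soybean-meal substitution
(SBM20, SBM40), then profiling three compartments by untargeted LC-MS:
the diets themselves, the distal-intestine (DI) contents (digesta), and the
DI tissue, each in positive and negative electrospray modes. The content
metabolome is the compartment of interest — it can be sampled repeatedly and
non-lethally — but it is contaminated by the dietary background: a metabolite
differential between groups in the digesta may have been *eaten* rather than
produced, absorbed or secreted by the intestine. The pipeline therefore runs
in four stages: per-feature differential analysis, diet-background
filtration, VIP-based biomarker screening with validation, and content/tissue
exchange classification.

Intensities are modeled as log-normal with multiplicative group effects, so
effects are additive on the log2 scale and the natural effect statistic is
`log2FC = log2(mean_treatment / mean_control)` computed on (normalized) raw
group means — matching how group means are reported in published intensity
tables.

## Per-feature differential analysis

For each feature we compute:

* **log2FC** on normalized raw group means. A zero group mean is replaced by
  a configurable pseudo-mean (`pseudo_mean`), and is an error when none is
  configured: silently inventing a fold change for an absent feature is worse
  than failing.
* a **two-sided univariate test** on log2 intensities. Welch *t* is the
  default: intensity variance is rarely equal between a control and an
  inflamed gut, and on log-normal data the log transform makes the *t* model
  exact. Student *t* and the Wilcoxon rank-sum test are options. Degenerate
  inputs follow fixed conventions (both groups constant and equal: p = 1;
  constant but different: p = 0).
* the **PLS-DA VIP**. We fit NIPALS PLS1 with the class coded 0/1 and
  autoscaled features, and compute
  `VIP_j = sqrt(p * Σ_a SS_a (w_ja/‖w_a‖)² / Σ_a SS_a)` with `SS_a` the
  response variance explained by component `a`. The normalization identity
  `Σ VIP_j² = p` holds exactly and is asserted in the test suite, which also
  checks the scores against an independently coded brute-force PLS
  implementation to 1e-8. Two components are fitted by default; the
  algorithm reduces the count with a warning when the residual rank is
  exhausted, and constant features are excluded from autoscaling (VIP 0).

A metabolite is called **significant** when `P < 0.05` and `VIP ≥ 1` (raw P,
no multiple-testing correction by default, matching the convention of
reporting raw `P < 0.05` in this literature; Benjamini–Hochberg is available
via `p_adjust = "BH"`). For transcript-style data the DEG rule
`|log2FC| > 1 & P < 0.05` is provided. Dose-trend profiles across the full
ladder (`A` strictly rising, `B` strictly falling) additionally require a
significant extreme-group test; the trend software used in the original
analyses leaves its criterion unstated, so the extreme-dose pairwise test is
our declared convention.

## Normalization

Missing cells are imputed per feature with half the minimum positive value
(the common metabolomics default for left-censored missingness); dropping the
feature is the alternative policy. Before analysis, samples are normalized by
**probabilistic quotient normalization** (PQN): each sample is divided by the
median of its feature-wise ratios to the median reference spectrum. We
initially used total-intensity scaling, but under the generator's own study
conditions it is demonstrably biased: baseline abundances are heavy-tailed
(log-sd 1.5), so a single abundant differential feature shifts a sample's
total and drags a spurious opposite-direction fold change onto every null
feature. PQN's scaling factor is the median ratio, driven by the unchanged
majority, and is insensitive to that minority; `"total"` and `"none"` remain
available (`normalize =`). The PLS-DA input is then log2-transformed and
autoscaled.

## Diet-background filtration

Differential sets are matched across tables by exact, case-sensitive
metabolite display name (`feature_name`, falling back to `feature_id`) — the
published tables intersect named metabolites, and name matching is what makes
cross-mode and cross-compartment comparison possible at all. The Venn
partition of diet-differential vs content-differential names yields
`content_only`, `diet_only` and `co_contained` sets. A co-contained
metabolite is kept iff its diet and content log2FCs have strictly opposite
signs (*contrary trend* — the intestine reversed the dietary signal) or the
log2FC variation range exceeds 2. The "variation range" is interpreted as
`|log2FC_content − log2FC_diet|` (the difference between the two contrasts);
the alternative reading `|log2FC_content| > 2` is selectable via
`range_definition = "content_abs"`. Trend signs are taken from the log2FC of
records already significant in both tables, so no second significance gate is
applied. The filter is idempotent, never adds features, and reduces to the
identity when the diet-differential set is empty.

## Biomarker screening and validation

Per ion mode, the panel is the top 10 significant features by VIP (ties:
smaller p, then lexicographic id). Panels merge across modes by metabolite
name, duplicates counted once; panels intersect across substitution levels
into the **core biomarkers**, with per-level set differences as
level-specific markers. Validation uses:

* **z-scores** against the control group, `(x − mean_ctl)/sd_ctl` (n−1 sd);
* **ROC AUC** computed as the Mann–Whitney statistic `U/(n₁n₂)` with ties
  counted ½, auto-oriented so AUC ≥ 0.5 with the orientation recorded. This
  rank form is invariant under monotone transforms and equals the pairwise
  counting definition, which the tests verify exhaustively for all class
  sizes up to 8. No AUC confidence interval is computed by default: the
  original analyses mention a 95% interval without stating its method.
* a **significance-masked correlation matrix** (Pearson default, Spearman
  optional), with p-values from `t = r√(n−2)/√(1−r²)` and pairs with
  `p > 0.05` blanked in the display.

## Exchange classification

Metabolites differential in both DI contents and DI tissue whose log2FCs have
strictly opposite signs are classified `content_up_tissue_down` or
`content_down_tissue_up`; everything else is `none`. "Differential" defers
to the upstream classifier: when the input records carry a `significant`
column (the normal pipeline path, where significance may include the VIP
criterion) it is used; otherwise `p < alpha` on each side is the fallback.
Representatives of a class are ranked by `min(content_p, tissue_p)`
ascending, ties by `|content log2FC|` descending — the published tables do
not state their ranking rule, so this convention is declared and
configurable in code. Swapping the compartment inputs mirrors the classes
exactly; the two class counts always sum to the total exchanged set.

## Enrichment and alpha diversity

Pathway over-representation is the hypergeometric upper tail `P(X ≥ k)` with
the annotated-feature universe as background, one count per feature per
pathway, records only for pathways with `k ≥ 1`, raw-P significance at 0.05
(BH optional). Alpha diversity implements observed species, Shannon (base 2
by default — consistent with published index magnitudes of ~2–6 for
communities of hundreds of OTUs; natural log via `base =`), Gini–Simpson
`1 − Σp²`, **classical** Chao1 `S + F1²/(2F2)` with the `F1(F1−1)/2` fallback
at `F2 = 0`, ACE with rare-taxon threshold 10 (ACE = S_obs with no rare taxa;
Chao1 substituted when every rare taxon is a singleton, where ACE is
undefined), and Good's coverage `1 − F1/N`. vegan's `estimateR()` uses the
*bias-corrected* Chao1, so the test suite cross-checks Shannon, Simpson and
ACE against vegan but Chao1 against hand-computed fixtures. Optional seeded
rarefaction to a fixed depth precedes the indices when requested; none is
applied by default.

## The synthetic-data generator

`simulate_metabolome()` emulates the study conditions: 3 groups on the dose
ladder, 12 content and 12 tissue samples per group (6 replicate diet
measurements), ~2,000/~1,100 features per mode, log-normal baselines
(meanlog 12, sdlog 1.5 — intensities spanning the 1e3–1e8 range of published
tables), within-group CV 30%, and planted classes at a full-dose log2 effect
of 2: differential (up/down), diet-derived (same-trend with a planted
content−diet gap of 1 < the filter range 2, hence removed; or contrary,
hence kept; content baselines attenuated by a passage factor of 0.5),
and exchanged (opposite content/tissue shifts). Intermediate doses carry
half the effect, making planted group means strictly monotone along the
ladder. Three planted metabolite names are shared verbatim between modes to
exercise cross-mode deduplication. Labels partition the feature set and are
returned as ground truth. Where the study protocol states no value (effect
sizes, CV, fractions, diet replication), the defaults above are our one-time
choices of realistic values and are config-exposed, not claims about the
study. `simulate_otu()` draws multinomial reads from geometrically decaying
taxon probabilities; a larger dysbiosis gradient flattens the decay, giving
richer, more even communities, emulating the observed diversity increase
with substitution level.

What the generator does **not** emulate: chromatographic drift, batch
effects, missing-not-at-random dropout, correlated metabolite modules,
isotope/adduct redundancy, and compositionality of closed-sum acquisition.
Passing the synthetic recovery suites therefore shows the *algorithms* are
correct under the declared model, not that the biological conclusions of any
particular feeding trial are reproducible from raw spectra.

## Problem sizes and determinism

The test and acceptance workloads run at reduced but statistically meaningful
sizes chosen as part of the package design: 300–510 features per simulated
table, 20 seeds for Monte-Carlo properties (type-I error within 3 binomial
SDs of 0.05; planted-biomarker AUC ≥ 0.9 in ≥ 95% of seeds), and 6 seeds for
the faster unit-level properties. All generators are seeded and bit-exactly
reproducible; `scripts/acceptance.R` derives its per-iteration seeds from a
single `--seed` argument.

## Known limitations

* PLS1 with a 0/1 response is the two-class case only; multi-level
  discrimination is handled pairwise against the control.
* VIP values depend on the declared normalization; comparing VIPs across
  differently normalized runs is not meaningful.
* The hypergeometric test treats annotations as fixed and independent;
  topology-aware or set-enrichment methods are out of scope.
* Exchange classification is correlational: an inverse trend is consistent
  with absorption/secretion but does not establish transport direction or
  mechanism.
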