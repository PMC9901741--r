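---
title: "Methods: the adaptive-to-innate immune ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive-to-innate immune ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airatio)
library(dplyr)
```

## The problem and the model

Bulk tumour RNA-seq mixes signal from cancer cells and from the immune
cells infiltrating the tumour microenvironment. A tumour's prognosis and
its response to checkpoint-inhibitor immunotherapy depend not only on how
much immune infiltrate is present but on its composition: a specific,
adaptive response (T and B lymphocytes) acts against the tumour, while a
dominant innate response (macrophages, neutrophils, mast cells, dendritic
and NK cells) can accompany unresolved inflammation and poorer outcome.

`airatio` quantifies this balance from bulk expression in three steps.

**1. Marker-gene cell-type scores.** Each of 14 immune cell types is
represented by a small set of marker genes (the packaged default uses the
Danaher et al. 2017 definitions; `default_panel()`). The score of cell
type $c$ in sample $i$ is the plain mean of marker log-expression,

$$ s_{ic} = \frac{1}{|G_c|} \sum_{g \in G_c} \log_2(\mathrm{TPM}_{gi} + 1), $$

with no per-gene standardisation — marker genes for a cell type are
already selected to co-vary with its abundance, and a plain mean keeps
zero TPM at score zero. The total TIL (tumour-infiltrating leukocyte)
score of a sample is the mean of all its cell-type scores.

**2. Cohort-relative scaling.** Cell types differ widely in marker
expression levels, so raw scores are not comparable across cell types.
Scores are mapped back to the linear scale ($2^{s}-1$) and each cell type
is min–max scaled over the analysis cohort:

$$ \tilde s_{ic} = \frac{x_{ic} - \min_i x_{ic}}{\max_i x_{ic} - \min_i x_{ic}}, \qquad x_{ic} = 2^{s_{ic}} - 1 . $$

Every cell type then spans $[0,1]$ with at least one sample at each
extreme. The statistic is deliberately *cohort-relative*: adding a sample
with a new extreme rescales everyone, so ratios are comparable within one
dataset but not across datasets scaled separately.

**3. Compartment means and the ratio.** The adaptive score $A_i$ is the
mean scaled value over the seven adaptive cell types (CD8 T cells,
B cells, CD45, cytotoxic cells, T cells, Th1 cells, Tregs) and the innate
score $I_i$ the mean over the six innate types (dendritic cells,
macrophages, mast cells, neutrophils, NK and NK CD56dim cells). The
adaptive-to-innate ratio is $A_i / I_i$. A ratio above 1 means the scaled
adaptive signal dominates.

A rank-based check (`rank_genes()`, `compare_tumour_vs_cellline()`)
guards the interpretation: within each sample all genes are ranked by
expression (lowest = 1, ties averaged), and the mean percentile rank of
the immune marker genes is compared between tumours and cancer cell
lines, which carry no infiltrate. Marker ranks clearly higher in tumours
support that the immune signal originates from infiltrating cells rather
than from cancer cells expressing immune genes.

## Parameters that matter

* **`transform`** (`linear_tpm` / `log2p1`, no default): the declared
  scale of the input matrix. It is never guessed — a silent
  misdetection would corrupt the reverse-log step, which assumes scores
  are on the log2(TPM+1) scale. Linear input is converted before scoring,
  so the scaling chain is identical either way.
* **`coverage_threshold`** (default 0.5): minimum fraction of a cell
  type's markers present in the matrix. Below it the join fails (a score
  over a near-empty marker set is meaningless); between 0.5 and 1 the
  coverage report carries a warning.
* **`scope` of min–max scaling** (default: whole cohort): extremes can
  instead be taken per cancer type. The default scales once per dataset;
  per-cancer-type scaling is exposed because within-type comparisons may
  prefer it.
* **`split_scope` of median splits** (default: per gender): "high" means
  strictly above the median of the sample's scope group; ties are "low",
  deterministically. `female_median_reference()` additionally labels
  males against the *female* median of their stratum, for gender-gap
  analyses.
* **`epsilon`** in `ai_ratio()` (default 0): a sample whose innate score
  is exactly 0 gets a missing ratio rather than an epsilon-inflated
  near-infinity; users who need a complete column can opt into a small
  positive denominator offset.

## Downstream statistics

Survival models are Cox proportional-hazards fits (`survival::coxph`,
Efron tie handling — the least biased of the common approximations);
median-split groups are compared by Kaplan–Meier curves and the log-rank
test. Per-cancer-type hazard ratios are combined by fixed-effect
inverse-variance meta-analysis on the log-HR scale (weights $1/SE^2$); a
DerSimonian–Laird random-effects variant is available behind
`method = "random"` for sensitivity analysis, since with few strata the
between-stratum variance is poorly estimated. Nested Cox models are
compared by a likelihood-ratio chi-square on $2\Delta\ell$. Group
comparisons use the two-sided Wilcoxon rank-sum test, exact by
enumeration when both groups have at most 8 observations and no ties.
Quadrant-vs-response association uses Fisher's exact test (two-sided,
point-probability method). The "below diagonal" fraction counts samples
with $I > A$ strictly; $A = I$ is not below, so membership is
deterministic. Per-stratum p-values are reported raw, with a
Benjamini–Hochberg adjustment available via `p.adjust` where users need
it; all tests are two-sided unless a function's contract states
otherwise (the tumour-vs-cell-line rank test is one-sided by design).

For regression, age enters linearly in years and tumour stage as the
ordinal 1–4 encoding of the major stage (substages such as "IIIb"
collapse to "III"; unknown stage is missing and drops the sample from
complete-case fits).

## What the synthetic cohort emulates

`simulate_cohort()` generates the structure the analysis assumes, with
recorded ground truth, so every stage is testable without external data:

* a latent per-patient **adaptive skew** $s \sim N(\mu_\text{gender}, 1)$,
  with the female mean shifted by `adaptive_skew_effect` (default 0.5) —
  this encodes a gender difference in immune balance;
* a per-sample **infiltration budget** (log-normal around
  `infiltration_scale` = 0.15, a realistic mean immune fraction of tumour
  mass) split across cell types by skew-tilted weights
  $\mathrm{logit}^{-1}(\pm s)$, so the adaptive share rises with $s$
  while total infiltration varies independently;
* marker-gene TPM = shared log-normal background (median ≈ 5 TPM, one
  log10 of spread) + 200 TPM per unit infiltration fraction of the cell
  type, under multiplicative log-normal noise (sd 0.3 on the natural-log
  scale, a typical bulk RNA-seq technical spread); 500 background genes
  carry background only. Setting `infiltration_scale = 0` gives
  cell-line mode, where marker genes are statistically indistinguishable
  from background;
* **survival**: exponential event times with log-hazard
  $\beta_{AI}\,(s - \bar s)$ (default $\beta_{AI} = -0.7$: higher
  adaptive balance is protective), baseline median OS of 3 years,
  independent exponential censoring at ≈ 30%; progression-free times
  share the event-time truth scaled earlier by a fixed factor 0.6;
* **response**: a proportional-odds draw on $s$ with cutpoints chosen to
  give a realistic checkpoint-inhibitor mix (≈ 45% PD, 25% SD, 20% PR,
  10% CR); SD is generated deliberately so the response-evaluable filter
  has something to remove;
* an immunohistochemistry-style **phenotype** (inflamed / excluded /
  desert) as noisy tertiles of total infiltration.

One root seed expands into independent per-stage substreams, so changing
the response model does not perturb the expression draws, and a fixed
seed reproduces the cohort byte-identically.

**What it does not emulate** — and hence what passing tests do not show
about real data: gene–gene correlation beyond shared cell-type membership,
cancer-type-specific expression programs or frequencies, cancer cells that
themselves express immune genes (leukaemia/lymphoma-like), non-proportional
hazards, informative censoring, and response driven by anything but the
immune balance (in particular, total infiltration does not directly drive
response in the generator, so quadrant enrichments are weaker than in
real immunotherapy cohorts).

## Numerical choices and degenerate inputs

* Duplicate gene rows collapse by arithmetic mean on the stored scale
  (deterministic and symmetric); duplicate sample ids are an error.
* A cell type constant across a scope group scales to all-zeros with a
  warning rather than 0/0.
* An all-constant innate compartment yields all-missing ratios, not a
  crash; missing ratios are excluded from medians and labelled `NA`.
* Median ties go to "low" ("above median" read strictly).
* Cox non-convergence or separation is flagged on the result
  (`converged = FALSE`), not raised, so cancer-type sweeps skip
  degenerate strata instead of aborting; the per-gender meta-analysis
  additionally requires a minimum number of events per stratum
  (default 5).
* Meta-analysis excludes strata with non-finite estimates or zero SE
  with a warning and requires at least two usable strata.
* Sample matching is exact string match after whitespace strip; no
  barcode truncation heuristics are applied, so cohort-specific id
  harmonisation is the caller's responsibility.

## Design choices where the design was open

* **TIL mean vs ratio cell types.** The total TIL score averages *all*
  panel cell types, while the ratio uses only the 13
  compartment-assigned types; the 14th type (Exhausted CD8 in the
  default panel) carries `compartment = excluded`. This reconciles a
  13-type ratio with a 14-type score panel without dropping information,
  and the panel file makes the choice user-configurable.
* **Scaling scope.** Min–max extremes default to the whole dataset
  (pan-cancer within one cohort), with per-cancer-type scaling exposed;
  cross-cohort comparisons should scale each dataset separately.
* **Median-split scope.** The default split is per gender, since the
  gender-stratified survival contrast is the analysis's centrepiece; a
  pooled split is one argument away.
* **Meta-analysis model.** Fixed-effect inverse variance is the default;
  the random-effects variant is for sensitivity only.
* **Continuous vs binary exposure.** Per-cancer-type univariate Cox fits
  can use the continuous ratio, while KM and the meta-analysis use the
  median-split binary; both entry points are exposed
  (`fit_cox` with `ai_ratio` vs `ai_high`).

## Problem sizes used by the test suite

The packaged checks run the scaling chain against a brute-force oracle on
a 10-sample, 13-cell-type cohort (tolerance 1e-12); the ranking against a
sort-based oracle on 1,000 random tied vectors (exact); Fisher's test
against hypergeometric enumeration on all 2×2 tables with $n \le 20$ and
the exact Wilcoxon against full permutation enumeration for group sizes
up to 8. Calibration uses 400 null replicates at $n = 300$ (log-rank
rejection rate inside the exact binomial 95% band around 0.05) and 200
replicates for likelihood-ratio p-value uniformity; recovery uses 20
seeds at $n = 1000$ (rank correlation of latent skew with the computed
ratio ≥ 0.7 in every seed, protective median-split hazard ratio, female
median above male) and 20 seeds at 50 samples per arm for the
tumour-vs-cell-line rank separation. These sizes were chosen so each
property is measured with comfortable statistical margin on a single CPU.

## Known limitations

The ratio is cohort-relative by construction: its absolute value is not
transportable between datasets scaled separately. Marker-mean scoring
assumes marker genes are expressed predominantly by their cell type; in
cancers of immune origin the assumption fails (such cohorts should be
excluded, as immune-system cancers were from the motivating analyses).
No proportional-hazards diagnostics or competing-risks models are
provided, and the package performs no gene-identifier conversion —
expression matrices must already use the panel's gene symbols.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n_samples = 400, seed = 11))
cohort <- join_cohort(sim$expr, sim$clinical)
profile <- immune_profile(score_cell_types(cohort))
outcome <- outcome_table(cohort, profile, ai_scope = "gender")

km <- km_logrank(outcome, outcome$ai_group, endpoint = "os")
autoplot(km)

meta <- meta_by_gender(outcome, endpoint = "os")
meta$combined
```
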