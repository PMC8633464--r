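---
title: "Mining MRI feature rules for the epileptogenic zone in TSC"
author: "tscez"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MRI feature rules for the epileptogenic zone in TSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscez)
```

## The problem and the data model

Tuberous sclerosis complex (TSC) produces many dysplastic cortical lesions,
and in epilepsy-surgery candidates the epileptogenic zone (EZ) must be
identified among them. The workflow implemented here assumes rater-scored
data: each patient's brain is partitioned into 22 predefined cortical
regions of interest (11 per hemisphere: five frontal, two temporal, two
parietal and two occipital subregions), and each ROI is scored by one or
more neuroradiologists for six binary dysplastic features — tubers, cysts,
calcifications, increased cortical thickness, gray-white matter (GWM)
junction blurring and the transmantle sign. Per scan, the single ROI judged
to contain the largest FCD-affected area is additionally designated. The EZ
is not a rater judgment: it is operationalized as the resected area of
patients who were and remained seizure-free (at least two years of
follow-up), so it is a study-level label attached per (patient, ROI) and
identical across raters. Patients who did not become seizure-free may be
carried in a cohort file but are excluded from every EZ-referenced
analysis, because an incomplete resection leaves the EZ unknown.

`TscCohort` encodes these contracts as a `SummarizedExperiment` with one
logical assay per feature, and its validity method enforces the ones that
are easy to get wrong in tabular data: complete 22-ROI grids per (patient,
rater), no missing feature values, EZ consistency across raters, at least
one EZ ROI per seizure-free patient, and the largest-area rule — at most
one designation per scan, exactly one whenever any FCD-like feature
(thickness, blurring, transmantle sign) is scored. The last rule is a
design choice: the scoring convention only says the largest affected ROI
"is denoted", and requiring uniqueness makes the designation well defined.
The EZ may span several ROIs (lobar and multilobar resections), so it is
stored per ROI rather than as a single region.

All collections are keyed by (patient, rater, ROI); row order of an input
CSV never influences any result, and this is tested as a hard contract.

## Statistics

**Percentages.** All reported percentages are rounded half-away-from-zero
(one decimal for prevalence, integers for diagnostic metrics); full
precision is retained internally. Counts, not printed percentages, are
always the authority.

**Cohen's kappa** quantifies inter-rater agreement per feature:
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_o$ the observed agreement
proportion and $p_e$ the chance agreement from the marginal rates. When
$p_e = 1$ the statistic is undefined and returned as `NA` rather than a
number.

**Kendall's tau-b** measures feature–EZ association and inter-rater
correlation. Plain tau-a is degenerate for heavily tied binary data, so the
tie-corrected tau-b is used; for paired binary vectors it reduces to the
phi coefficient of the 2×2 table, $\;(ad-bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$,
and for the derived abnormality-count variants (0–7 scale) it is computed
by concordant/discordant pair counting over the joint contingency table.
Pooling follows the source analysis exactly: the 22 ROIs of every
seizure-free patient are concatenated into one vector (330 observations
for 15 patients). Within-patient clustering is deliberately ignored — this
reproduces the published analysis design and is a known statistical caveat,
not an option.

**P-values.** The default is a label-permutation test (10,000 seeded
shuffles of one vector, two-sided on $|\hat\theta|$, with the standard
$(1+\text{hits})/(B+1)$ estimator); a large-sample normal approximation is
available by flag (Fleiss's null variance for kappa, the tie-corrected
variance of Kendall's $S$ for tau). The permutation test on heavily tied
binary data is discrete and therefore conservative; the tests characterize
this rather than pretending uniformity. The two methods agree closely at
the pooled-cohort scale ($n \approx 330$).

**Diagnostics.** Each feature is also treated as a binary EZ flag and
summarized by accuracy $(tp+tn)/n$, positive predictive value
$tp/(tp+fp)$ and false discovery rate $fp/(tp+fp)$, pooled (Table-style)
and per patient (denominator exactly 22). PPV and FDR are complements
whenever defined. When a feature flags nothing for a patient, PPV and FDR
are reported as `NA`, never as 0 or 100 — silently coding undefined cases
would bias per-patient summaries, which routinely contain them. The
largest-area designation is treated as a seventh binary feature here.

## The rule search

The hypothesis family is "flag an ROI when at least $t$ of feature set $S$
are present", $S$ a non-empty subset of the seven features, $1 \le t \le
|S|$. The search is exhaustive — $\sum_k \binom{7}{k} k = 448$ rules for
the full pool — which is the entire point of the brute-force design: no
heuristic can miss the optimum. A rule is "perfect" in a patient when it
flags at least one ROI and every flagged ROI lies inside the EZ, i.e. 100%
within-patient PPV; with a multi-ROI EZ any flagged EZ ROI counts as a
true positive. This is the weakest reading consistent with "identifies at
least one ROI correctly with 100% PPV"; a stricter variant requiring a
unique flagged ROI is exposed as `perfect = "unique"`. The objective is the
number of perfect patients only; total EZ coverage is reported but not
optimized.

Rules are ranked by perfect-patient count, then smaller feature sets, then
larger thresholds (parsimony, then specificity), then lexicographically so
that rankings are reproducible and independent of patient order. Among the
top rules, the reduced frontier drops any rule dominated by one using a
strict subset of its features with identical flag sets patient-for-patient
— such a rule adds features without adding information. Cysts stay in the
default pool: excluding the one feature known to carry no EZ association
would bake the expected answer into the search.

## The synthetic-cohort generator

No rater score sheets are published for this kind of study, so the
generator is a first-class module: it defines the study conditions under
which everything downstream is validated.

Per patient, an EZ of 1–4 ROIs is drawn (sizes weighted 18:5:4:1,
matching the observed mix of focal, lobar, multilobar and hemispheric
resections) and placed uniformly among the 22 ROIs; spatial contiguity is
not modelled because no downstream statistic depends on adjacency. Latent
features are independent Bernoulli draws: baseline per-ROI prevalences
default to the whole-cohort ROI positivity rates of a 28-patient surgical
TSC cohort (tubers 30.3%, cysts 1.8%, calcifications 2.1%, increased
thickness 5.5%, GWM blurring 17.9%, transmantle sign 10.6%), and inside
the EZ the odds are multiplied by a per-feature odds ratio — an odds
ratio, not a risk ratio, so probabilities cannot leave $[0,1]$. Default
odds ratios (tuber 4, blurring 4, transmantle 6, thickness 10,
calcification 12, cysts 1) were chosen once to reproduce the qualitative
association pattern reported for such cohorts — every feature positively
associated with the EZ except cysts — and are the package's own defaults,
not published estimates; no per-feature EZ prevalences exist to calibrate
against. Features are independent given EZ status: no co-occurrence
structure is reported for such data, so none is invented.

Raters then mis-score each latent feature independently with per-rater
false-positive and false-negative rates (defaults 2%/12% and 3%/18%,
giving fair-to-substantial kappa at these prevalences); agreement targets
are reached by calibrating flip rates, never by specifying kappa directly.
The largest-area ROI is re-derived per scan as the argmax of the FCD-like
feature count, ties broken by a seeded draw. All simulated patients are
seizure-free, since non-seizure-free patients contribute nothing to any
EZ analysis and incomplete resections are out of scope. Identical config
and seed give a bit-identical cohort.

`plantRule()` supports recovery experiments: it edits the latent features
minimally so the rule holds exactly on the EZ (on in EZ ROIs until the
threshold is met, off in non-EZ ROIs until below it, touching only the
rule's own features, in name order), then re-applies rater noise under a
seed derived from the config seed. Only the six lesion features can be
planted: the largest-area designation is a derived per-scan property, so a
per-ROI guarantee for it cannot be enforced by feature edits, and rules
naming it are rejected as infeasible.

What passing tests on synthetic cohorts do **not** show: that real raters'
errors are independent across features and ROIs (real disagreement is
likely spatially and feature-correlated), that real lesions are spatially
unstructured, or that real feature co-occurrence is absent. The generator
validates the *machinery* — accounting, statistics, search — under known
truth, not the clinical effect sizes.

## Numerical choices and degenerate inputs

- Undefined statistics (constant vectors, $p_e = 1$, nothing flagged) are
  `NA` with the metric's context preserved, never silently coerced.
- Rounding is half-away-from-zero throughout; base R's round-half-even is
  never used for reported figures.
- Zero baseline prevalence stays zero inside the EZ (the odds-ratio map is
  degenerate at 0 and 1).
- Largest-area ties are broken by a seeded draw so cohorts are exactly
  reproducible.
- The pipeline fans one top-level seed out to per-stage seeds with a fixed
  affine splitter, so stages can be re-run in isolation; all outputs except
  the manifest's timestamp are byte-stable across runs.

Problem sizes in the test suite were chosen for statistical sharpness at
desk scale: closed-form equivalences are exhausted over all 2×2 tables
with $n \le 12$; search correctness is cross-checked against an
independent naive enumerator on fifty 10-patient cohorts; Monte-Carlo
prevalence and agreement calibration use 200-patient cohorts (4,400 ROIs
per rater) over ten seeds, with 3-standard-error bands from closed-form
expectations (binomial for prevalence; the Fleiss–Cohen–Everitt variance
for kappa).

## Known limitations

- Pooled association ignores within-patient clustering (by design, to
  match the published analysis); GEE-style corrections are out of scope.
- Rule performance is in-sample: the search reports the optimum on the
  cohort it is given, with no cross-validation of generalization.
- Printed diagnostic tables from clinical studies of this design cannot be
  reproduced without the raw score sheets; the package reproduces the
  arithmetic and the method, and its own numbers come from synthetic or
  user-supplied cohorts.
- No confidence intervals on PPV/FDR and no ROC analysis; features arrive
  pre-scored, and image processing is explicitly out of scope.
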