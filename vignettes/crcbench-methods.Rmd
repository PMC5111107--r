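---
title: "Cross-validating colon cancer subtype classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validating colon cancer subtype classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcbench)
```

`crcbench` re-implements the statistical machinery needed to compare many
published colon cancer molecular subtype classifiers on one patient cohort:
a harmonized expression database, the classifiers themselves (declarative
rules and re-trainable engines), agreement analytics, a relapse-free
survival (RFS) benchmark, cell-line subtype assignment, and a synthetic
cohort generator that plants known truth so every stage can be verified.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish about real data.

## The cohort database

Classifiers are compared on a pooled log2-scale expression matrix (genes ×
samples) carrying a dataset-of-origin tag per sample. The package consumes
already-normalized matrices (MAS5/RMA flavor is metadata, not computation)
in plain TSV or the GEO series-matrix text dialect. Three harmonization
steps matter for a pooled analysis:

* **Probe collapse.** Array platforms measure a gene with several probe
  sets. Where a curated "best probe" designation is available (JetSet-style
  annotation) that probe is used; otherwise the probe with the highest mean
  expression represents the gene. Unmapped probes are dropped and counted.
  A row already named like a gene maps to itself, which makes the collapse
  idempotent.
* **Centering.** Several average-expression classifiers specify
  median-centred input; `center_values()` centers each gene's median to 0,
  pooled or per dataset.
* **Redundancy removal.** Public repositories contain re-uploaded samples.
  Identical sample accessions are always merged; beyond that, two samples
  are treated as the same tumor when their expression correlates at
  Pearson r ≥ 0.99 over the shared genes (configurable). The threshold is
  a deliberate design choice: technical replicates of one RNA extraction
  correlate above 0.99 on these platforms, while distinct tumors almost
  never do. The first-encountered sample is kept and every removal is
  reported. Missing values are excluded pairwise from medians and
  correlations.

## Declarative rule classifiers

Most published classifiers are fully determined by a gene list plus a small
rule; `crcbench` stores them as `crc_signature` objects (gene symbols,
per-gene risk direction and optional weight, rule kind and parameters,
output labels with prognosis annotation, optional housekeeping panel and
training-set tags). Rule kinds:

* **Weighted linear score with cutoffs.** `score = intercept + Σ w·expr`.
  The five-term hypoxia score ships built in (intercept 1.301, weights
  0.543, −0.416, 0.596, 0.538, −0.177; high risk above 4.526). The source
  description calls it a six-gene model but prints five gene terms plus an
  intercept; the printed five-term formula is implemented. Cutoffs can be
  fixed, cohort-median, or tertiles.
* **Delta-Ct pre-transform.** RT-PCR-style classifiers are emulated from
  array data via `ΔCt(g) = −15 − (log2 mean(housekeeping) − log2 g)`. The
  housekeeping mean is arithmetic on the linear scale (matching
  `log2(mean(·))`; geometric available). The recurrence-score rule cuts at
  30 and 40 with both boundaries intermediate ("between 30 and 40"); the
  seven-gene relapse hazard score cuts at 0 with housekeeping panel ACTB,
  HMBS, RPL13A.
* **Product-ratio score.** `|BMI1·VEGFA/H3F3B| − |ETV6·H3F3B/RPS10|` after
  subtracting the mean of five housekeeping genes (B2M, GUSB, POLR2L,
  PSMB6, UBC); a zero denominator leaves the sample unclassified. The
  median split replaces the originally published cutoffs, following the
  validation setup this package mirrors.
* **Per-gene tallies.** A gene scores positive above its cohort reference
  (up-risk genes) or below it (down-risk genes); references are per-gene
  medians or the 80th/20th percentiles. The 13-gene rule calls high risk at
  ≥5 positives, the 7-gene rule poor prognosis at ≥3, and the three-gene
  rule uses the count itself (0/1/2/3) as the label. "Overexpressed" is
  strict (`>` the median): the original description does not state the
  boundary, and a strict inequality keeps ties in the non-risk group,
  consistent with all other ties here.
* **Group-mean comparison.** The BRAF-mutant-like surrogate compares the
  means of two gene partitions; ties go to wild-type-like.
* **Dual-median.** Two weighted sub-scores; high risk only when both exceed
  their own cohort medians.

**Tie policy (global design decision).** Every cohort-relative boundary —
medians, percentiles, midpoints — sends ties to the lower/non-risk group.
Risk calling is conservative and the choice is applied uniformly so no rule
has a private boundary convention. The fixed recurrence-score boundaries
are the one documented exception, because the published rule states the
closed interval explicitly.

**Three-group splits.** The 95-gene and stem-cell-signature classifiers
divide patients into three groups around the mean signature expression
without published boundaries; tertiles of the signature-mean score are used
and exposed as a config knob, since equal-sized groups are the only
boundary-free reading.

**Coverage floor.** A signature runs only when ≥80% of its genes are
measurable (configurable). The floor acknowledges that published
classifiers are routinely run on reduced probe sets when platforms differ —
classification then proceeds on the shared subset — while below 80% a call
no longer reflects the published rule. Non-evaluable signatures yield
explicit all-NA calls, never silent drops.

Signatures whose gene lists were published only as supplementary material
(the 25-gene instability signature, the 95-gene network signature, the
13-gene relapse rule, ...) are supplied by the user via the YAML bundle
schema (`write_signature_config()` / `load_signature_config()`); the engine
is list-agnostic.

## Trainable engines

Centroid-style classifiers are re-trained from any labeled matrix:

* **Nearest centroid** — per-class gene means; prediction by Euclidean or
  one-minus-Pearson distance. Correlation distance is the default
  convention for consensus-subtype-style centroid predictors; Euclidean
  elsewhere. The original descriptions do not state metrics or priors, so
  these defaults are explicit assumptions, configurable per signature.
* **Nearest shrunken centroid (PAM)** — class-vs-overall centroid
  contrasts are standardized by the pooled within-class SD plus a
  stabilizing offset `s0` (the median of those SDs), soft-thresholded by
  the shrinkage Δ, and classification uses the standardized squared
  distance with uniform priors; posteriors are exposed as confidences. At
  Δ = 0 the engine reduces exactly to nearest centroid in standardized
  space (a tested identity). Uniform priors are deliberate: subtype
  prevalences differ between training sets and a pooled cohort, so
  training-set priors would import a bias.
* **Compound covariate predictor** — two-class; per-gene two-sample
  t-statistics are the weights, the decision threshold is the midpoint of
  the class-mean scores, and a sample exactly at the midpoint goes to the
  reference class.
* **Meta-gene linear discriminant** — meta-gene features (means of member
  genes) feed a multiclass linear discriminant with the pooled within-class
  covariance ridged by 1e-6 (default), so singular covariances — common
  when features outnumber samples — stay invertible. Uncovered and
  constant meta-genes are dropped with warnings.
* **Reference engines** — deterministic KNN (majority vote; an even split
  is broken toward the label with the smaller aggregate neighbour distance,
  and a residual tie is NA) and a linear maximum-margin classifier (fit as
  a large-cost linear SVM; the separating hyperplane is extracted to a
  plain weight vector, so serialization stays text-only).

Exact prediction ties are NA everywhere — the benchmark tolerates
unclassified samples by design, and a coin-flip would break determinism. A
per-model confidence floor suppresses low-confidence calls; the
90%-posterior scoring rule of the 163-probe classifier is
`confidence_floor = 0.9`. Models serialize to YAML (engine kind, labels,
centroid/weight tables at 15 significant digits) and reload with agreeing
predictions.

## Concordance and gene scores

Agreement between two classifiers is Cramér's V,
`sqrt(χ²/(n·(min(r,c)−1)))`, computed from the contingency table of
pairwise-complete calls with the uncorrected χ² — the textbook convention,
and exactly reproducible by hand on small tables. Samples unclassified by
either classifier are excluded pairwise. Per-prognosis-label agreement
restricts each classifier to the indicator "carries its good (or bad)
label" and applies Cramér's V to the indicators; because V is unsigned and
agreement on a label is directional, a negative association (observed
co-occurrence below the independence expectation) is clamped to 0. The
statistic restricted to one label is not defined in the source material;
this sign-clamped indicator V is the package's documented choice, isolated
behind one function.

Gene-list overlap is row-normalized
(`100·|G_i ∩ G_j|/|G_i|`, asymmetric), and each gene's score is
`(number of signatures containing it) × Σ (1/signature size)` over those
signatures, ranked descending with alphabetical tie order.

## Survival benchmark

All comparisons use Cox proportional hazards with the Efron approximation
for ties (month-resolution follow-up makes ties common) and Wald confidence
intervals and p-values. For a classifier with more than two labels, the
benchmark compares the best- and worst-outcome cohorts. "Best/worst" is
operationalized as the extremes of the per-label one-vs-rest log hazard —
the source states the selection but not the criterion; a ranking by KM
median survival is available as an alternative reading, but the log-hazard
ranking uses all events rather than one quantile. Intermediate and
unclassified samples are excluded, as are each classifier's original
training datasets (per-signature `training_sets` tags; the consensus
subtype classifier is exempted via config because its training pool already
spanned the validation data). Stage filtering (typically II–III, the
clinically actionable group) is applied before the fit.

The univariate screen splits the cohort at each gene's median (ties low)
and reports per-signature proportions of genes significant at 0.05/0.01,
plus the Spearman correlation between those proportions and the hazard
ratios the classifiers achieve. Multivariate adjustment fits the
(two-level) classifier term together with MSI status, gender, and
MKI67/CDX2 expression, with listwise deletion (reported), a ≥50%
covariate-availability requirement, and an explicit error naming exactly
collinear covariates.

## Cell-line assignment

Replicate arrays of one cell line are collapsed by consensus: the modal
label wins when it reaches at least 60% of the arrays, inclusive — so 2 of
3 (66.7%) is assigned and 1 of 2 (50%) is not. The source phrases the same
rule both as "at least 60% identical" and as "more than 40% different";
at an exact 60/40 split the inclusive reading assigns, and that reading is
adopted. Cohort-relative references (medians, percentiles) are computed
within the cell-line panel itself, which is classified as a standalone set
— patient-cohort cutoffs would be meaningless for cultured lines.
Mutation annotations (KRAS, BRAF, PIK3CA, PTEN, TP53, APC; M/WT/NA) join by
cell line, with conflicting duplicate rows rejected. The prevalence table
pairs patient label proportions (NA as its own category) with model counts
and flags subtypes that lack any cell-line model.

## Synthetic cohorts: what they emulate, and what they do not

The generator produces the statistical structure the analysis assumes:

* log2 expression background Normal(7, 1) — the typical location and
  spread of normalized microarray intensities; a heavier-tailed option
  (t, 5 df, variance-matched) exercises robustness;
* planted subtypes with specified proportions; signature genes shifted by
  ±`effect_size` (by gene direction), graded by subtype hazard rank so the
  lowest-hazard subtype is the unshifted background;
* exponential RFS with rate `baseline_rate × hazard_map[subtype]` —
  exactly proportional hazards, so Cox recovery is a clean oracle. The
  default `baseline_rate = 0.016`/month gives a median RFS of ≈43 months
  at unit hazard, matching the observed median of the pooled patient
  cohorts this package targets;
* independent uniform censoring on `[0, horizon]`, with the horizon solved
  numerically (`mean(pmin(T, τ))/τ = rate`) so the expected censored
  fraction equals the requested rate (default 20%) while censoring stays
  non-informative;
* clinical covariates drawn to match the pooled cohort's aggregates
  (57.4% male, ~74% stage II/III, 15% MSI, age ≈ N(69, 10)).

Every generator is a pure function of its parameters and seed.

Problem sizes used in the shipped validation: cohorts of 200–600 samples
with a few hundred genes, 200 replicates for CI coverage, and 1000
simulated cell lines for the consensus rule — sizes at which the planted
effects are identifiable yet the whole suite runs in seconds.

What passing tests do **not** show about real data: the generator has no
platform or batch structure, no probe-level effects, no correlation between
background genes, no non-proportional hazards, and planted subtypes that
align perfectly with one signature at a time. Recovery on synthetic cohorts
therefore validates the *machinery* (formulas, boundaries, exclusions,
estimators), not the clinical performance of any classifier. One visible
consequence: fixed-cutoff classifiers calibrated to their original assay's
scale (the hypoxia score's 4.526, the recurrence-score 30/40) classify a
synthetic cohort one-sidedly, because the synthetic background is not on
that scale — cohort-relative rules are unaffected.

A related sensitivity worth knowing: a median-referenced tally can only
label the full risk group when that group is a minority; if more than half
the cohort is shifted, the per-gene median moves into the risk group and
sensitivity drops by construction. The shipped recovery tests plant a 40%
risk group for sensitivity checks, and the end-to-end hazard-recovery test
uses 50/50 (where the best-vs-worst contrast is unaffected).

## Numerical choices and degenerate inputs

* Ties: lower/non-risk group at every cohort-relative boundary; NA for
  exact prediction ties; recurrence-score boundaries closed into the
  intermediate interval.
* Constant genes: never score positive in tallies (warned), are excluded
  from discriminant features (warned), and yield NA in the univariate
  screen (excluded from proportion denominators).
* Zero denominators in product-ratio scores: NA call, warned, logged.
* Quantiles: R type-7 (the default) everywhere; tertile splits of 9
  distinct scores give exact 3/3/3 groups.
* PAM stabilization: `s0` = median of pooled within-class SDs; ridge 1e-6
  on the discriminant covariance.
* Cramér's V: χ² without continuity correction; vectors with a single
  level after NA removal return NA with a warning rather than 0.
* Fewer than two distinct scores under a cohort-relative cutoff: all NA,
  warned.

## Known limitations

* Raw CEL-file normalization, cross-platform batch correction, and
  automated repository retrieval are out of scope; the package consumes
  normalized matrices.
* Externally published model weights (recurrence-score weights, the
  inflammatory-score and relapse-hazard-score coefficients, consensus
  centroids) are config-supplied, not curated here.
* The survival benchmark covers two-cohort contrasts of RFS; competing
  risks, time-varying covariates, and overall survival are not modeled.
* The redundancy criterion behind any particular published duplicate count
  is not reproducible from the outside; the correlation threshold here is
  principled but its removal counts are its own.
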