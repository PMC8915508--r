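---
title: "Network features for length-of-stay prediction at admission: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network features for length-of-stay prediction at admission: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(losnet)
```

## The problem

Hospital managers want a length-of-stay (LOS) estimate the moment an elderly
patient is admitted, when the only available information is demographic data,
hospital attributes, the diagnoses flagged at the point of admission (PoA)
and whatever the system knows about the patient's past stays. Elderly
inpatients are overwhelmingly multimorbid — they carry several chronic
conditions at once — and the way those conditions co-occur carries signal
about how long a stay will be. `losnet` turns administrative discharge
records into that signal: it builds a disease co-occurrence network and a
patient-similarity network, derives four groups of admission-time features
from them, and evaluates how much each group adds to a regression model of
LOS.

Everything operates on a plain admissions table (one row per
hospitalization, up to 16 three-character ICD-10 codes with PoA flags), so
the package applies to any discharge-record extract with that shape. Because
real hospital data is access-restricted, the package ships a synthetic
cohort generator with *planted*, known structure; every claim the test suite
makes is checked against that ground truth or against an independent oracle.

## Cohort definition

`apply_inclusion_criteria()` reproduces the standard cohort filter for this
setting, in a fixed order so the exclusion tally is well defined: LOS
present and non-negative; admission date inside the study window; patient
alive; age at least 65; LOS at most an outlier cutoff; and at least one
*chronic* diagnosis flagged at the PoA. Chronicity is a catalog lookup — an
exact string match on the three-character code — and the catalog is always
an explicit input, because the chronic/acute classification is an external
editorial product, not something derivable from the data.

The LOS outlier cutoff is recomputed from the data as the nearest-rank 99%
quantile rather than hard-coded: any fixed day count is a property of one
cohort's tail, and synthetic cohorts have different tails. A fixed override
(`los_cutoff`) is available for exact reproduction of a published cohort.

## The multimorbidity network

Patients are aggregated into a sparse binary patient-disease matrix `M`
(`build_disease_matrix()`): entry `(p, d)` is 1 if any of patient `p`'s
era records lists chronic disease `d` in any diagnosis position, PoA or
in-hospital. The network deliberately sees the full comorbid burden — the
point of the structure is to let an admission-time diagnosis borrow
information from diseases that tend to be discovered later.

Pair counts come from the sparse cross product `t(M) M`, whose diagonal
holds the per-disease patient counts `C_i` and off-diagonal cells the pair
counts `C_ij`. The edge weight between diseases *i* and *j* is the relative
risk of co-occurrence

$$RR_{ij} = \frac{C_{ij}\,N}{C_i\,C_j},$$

the observed joint count relative to what independence would predict among
the `N` patients. Its uncertainty is summarized by a multiplicative
interval, $RR \cdot e^{\pm z\sigma}$ with $z = 2.58$ for a nominal 99%
level, built from the dispersion sum

$$s_{ij} = \frac{1}{C_{ij}} + \frac{1}{C_i C_j} - \frac{1}{N} - \frac{1}{N^2}.$$

### Two dispersion conventions

`katz_ci()` exposes a deliberate fork. The formula above is widely printed
with $\sigma = s_{ij}$ directly, and `sigma_mode = "as_printed"` implements
exactly that; it is the default of `katz_ci()` for fidelity to the printed
form. But $s_{ij}$ is a variance-scale quantity — the log-scale standard
error of a count ratio is the *square root* of such a sum — so an interval
built from $s_{ij}$ directly is far too narrow wherever $s_{ij} < 1$
(i.e. whenever $C_{ij} > 1$). At typical counts ($C_{ij} \approx 20$,
$s \approx 0.05$, true $\mathrm{sd}(\log RR) \approx 0.2$) the "99%"
interval from the printed form has a one-sided false-positive rate around
25%, which makes it useless as an edge-significance test.
`sigma_mode = "sqrt"` applies the square root, recovering a calibrated
log-scale interval. **Edge retention in `build_mn()` therefore defaults to
the `"sqrt"` mode**, and the package's null-calibration test (ten
independent-disease cohorts, at most 3% of candidate pairs retained, nominal
about 1%) passes only under that mode — which is precisely the argument for
the default. Both modes are available everywhere the interval is computed.

### Edge retention and centrality

The retention rule itself is configurable because no single convention is
canonical: `"ci_low_gt_1"` (default; the pair co-occurs significantly more
than chance at the 99% level), `"rr_gt_1"`, or `"all"` with a minimum pair
count. Node importance is eigenvector centrality — the principal
eigenvector of the RR-weighted adjacency (`weight_mode = "binary"` is
available, since either reading of a "weighted" network is defensible) —
computed by power iteration with an all-ones start, a small diagonal shift
(5% of the maximum absolute row sum) so bipartite components cannot
oscillate, enforced non-negativity, an L1 tolerance of 1e-10 and a 10,000
iteration cap. Disconnected components are solved independently and each
normalized to unit Euclidean norm; isolated nodes score 0. The suite checks
the result against a dense eigendecomposition to 1e-6 on random weighted
graphs.

## The patient-similarity network

Within blocks of identical sex and five-year age band (65-69 through 90+),
the similarity between two admissions is the Jaccard index of their chronic
PoA diagnosis sets. Each admission's feature signal is the LOS distribution
of its top-`k` (default 100) most similar *training* admissions:
mean, standard deviation, median, min, max.

Three retrieval decisions matter and are all deliberate:

* **Zero-similarity candidates are dropped** even when fewer than `k`
  neighbours remain — a neighbour sharing no disease carries no information,
  and the network reading of similarity implies shared conditions.
* **A patient's own other admissions are excluded by default**
  (`exclude_same_patient = TRUE`): a patient's past LOS reaches the model
  through the historical features, where it belongs; letting it also enter
  through the "similar patients" channel would disguise autocorrelation as
  network signal. The flag can be turned off to mimic setups that do not
  separate the two.
* **Ties break by ascending record id**, making retrieval reproducible.

Only the exact blocked backend is shipped. At the scale this package
targets, sparse intersection counting retrieves exact top-100 lists in
seconds, so an approximate index would add a recall contract without buying
anything; the brute-force all-pairs comparison in the test suite confirms
the exact backend is exact.

## Feature groups

Four groups, tagged per column so ablations are column selections:

* **Baseline (69 columns)**: admission year/month/day-of-week, age,
  hospital affiliation, admission status, both address codes and their
  equality flag, hospital level, the PoA diagnosis count; one-hot sex,
  admission source, ethnic group, job (13 levels) and marital status; the
  31 Elixhauser comorbidity flags and their van Walraven-weighted score.
  The published column count implies a two-column encoding of hospital
  level; we emit the ordinal grade plus a top-grade indicator. The
  Elixhauser code-to-category map is a pluggable input (the published maps
  are external products); `synthetic_eci_map()` provides a deterministic
  many-to-few stand-in for synthetic cohorts.
* **Historical (8)**: count, mean, SD, median, min, max of the same
  patient's LOS over admissions in the three-year window before the current
  one, plus days since the last discharge and the last LOS. A stay
  admitted exactly three years earlier is inside the window; one day
  earlier is not. No history means all zeros.
* **Network (centrality vocabulary + 4)**: a multi-hot vector over the
  centrality vocabulary with ones replaced by the disease's eigenvector
  centrality, and four aggregates (count, max, mean, sum) of per-disease
  *risk scores* — centrality times the disease's mean training LOS — over
  the admission's PoA set.
* **Similarity (5)**: the neighbour-LOS statistics above.

Missing values do not exist in the assembled table: every "no data" case
(no history, no neighbours, no covered disease) is zero-filled, and
`assemble_features()` refuses tables with residual `NA`s. Standard
deviations use the population convention with the single-observation value
defined as 0, so singleton histories are deterministic.

### Leakage discipline

Every statistic a row's features could leak through is computed from
training rows only: the per-disease mean LOS, the similarity index, the
discriminant projection — and also the centrality-feature *vocabulary*,
which we restrict to network diseases observed at PoA among training rows.
The era-based reading ("diseases seen in the modeling period") would let a
single held-out admission add a column to every row's feature block; the
train-only reading makes the no-leakage property provable, and the suite
asserts it literally by deleting held-out rows and recomputing.

## Discriminant compression

The centrality block is wide and sparse, so it is compressed with Fisher
linear discriminant analysis using the distinct integer LOS day values as
classes (LOS is discrete, so the class-based construction applies
directly; at most `K - 1` components exist for `K` distinct values). The
within-class scatter is ridge-regularized (1e-6 of its mean diagonal)
because multi-hot blocks are routinely rank-deficient, and the
eigenproblem is solved by symmetric whitening, with unit-norm columns and
a deterministic sign convention. The output dimension is selected on the
validation split: one projection per candidate (default grid 8, 16, 32,
64, infeasible entries dropped), scored by the validation MAE of a fixed
small boosted-tree probe, smallest dimension on ties. Only the centrality
block is compressed; the other groups pass through untouched.

## Ablation harness

`run_ablation()` mirrors the standard experimental design: an 80/20
train/test split with 20% of the training rows held out for validation;
five feature-subset combinations (baseline; baseline plus each other group;
all four); grid search per cell; refit on the training rows; test-set MAE,
RMSE and $R^2$ (computed around the observed mean, so a mean forecast
scores exactly 0). "Repeated ten times" is interpreted as ten *reseeded
splits* (`base_seed + r`), since the spread being reported is split
variability; a fixed-split variant is a one-line plan change. All
split-dependent features are recomputed inside every repeat.

Model internals are delegated behind a uniform fit/predict/importance
surface (`model_spec()`): gradient-boosted trees (xgboost, the default),
random forest (ranger) and a linear SVM (e1071, inputs standardized to
training mean/sd). The package's contribution is everything upstream of
the regressor, so re-implementing regressors would add risk without value.
A feed-forward network branch is not shipped: its published architecture is
tied to one dataset's encoded width, and no torch runtime is assumed.
Feature importances are summed within groups, and the top-k table reports
min-max relative importance so the leading feature scores 1.

## The synthetic generator

`generate_cohort()` emulates the *structure* of a multi-year elderly
discharge cohort: persistent per-patient chronic disease sets with
Bernoulli marginals (default prevalence 0.1 over 20 diseases); optional
planted pairwise co-occurrence, sampled from the exact 2x2 joint table with
`P(both) = RR * p_i * p_j`, so the population relative risk of a planted
pair is its target by construction (feasibility is validated); one or more
admissions per patient over 2015-2019 (negative-binomial counts, mean 1.8);
and an integer LOS built as `base + disease effects + age slope + patient
frailty + noise`, floored at one day (defaults: base 7 days, effects
cycling 0-4 days, 0.05 days/year above 65, frailty SD 2, noise SD 2).
Carried diseases are flagged at the PoA with probability 0.9, and the
principal diagnosis is the highest-effect PoA disease. Demographics follow
an elderly inpatient shape (48.7% male, 99.6% majority ethnic group,
five-year age bands with decreasing mass).

What it does **not** emulate: real marginal prevalences or their age
structure, coding noise and up/down-coding, mortality, transfers,
seasonality, or hospital-level effects on LOS. Passing tests therefore
demonstrate that the machinery recovers structure *that is present by
construction* — correctness of the pipeline, not clinical performance on
real data. Named presets (`make_fixture()`: tiny 50, small 2,000,
medium 20,000 patients, fixed seeds, two planted pairs at RR 5 and 3) give
the test suite stable surfaces; the medium preset is the size at which the
end-to-end ablation direction check (all four groups beating baseline in at
least 9 of 10 reseeded repeats) is run, a size chosen to give that check
stable signal while keeping the whole suite interactive.

## Numerical and degenerate-case conventions

* Nearest-rank quantile for the LOS cutoff (`sort(x)[ceiling(q n)]`).
* Population SD everywhere a spread of LOS values is a feature; `n = 1`
  gives 0.
* Jaccard of two empty sets is an error, not 0 — admissions enter the
  similarity stage only with at least one chronic PoA diagnosis.
* Relative risk with `C_ij = 0` is 0; its interval is undefined (error).
* Power iteration: diagonal shift against bipartite oscillation,
  non-negativity enforced, per-component normalization, isolated nodes 0.
* Unknown categorical levels one-hot to an all-zero block with a warning
  rather than erroring or adding a reserved column, preserving the fixed
  69-column schema.
* One global seed fans out to stage seeds by a stable string hash
  (`stage_seed()`), so stage-level reproducibility is independent of
  execution order; all fitted models run single-threaded with explicit
  seeds.

## Known limitations

* The edge-retention rule that produced any particular published network
  size is not reconstructible from counts alone; the package makes the rule
  explicit and configurable instead of guessing.
* Historical features use a single fixed three-year window; multi-scale
  windows are out of scope.
* The LOS tail is hard for every regressor here; no resampling of long
  stays is attempted.
* No classification mode (prolonged/short LOS), no network clustering, no
  visualization layouts; exports are plain edge/node tables.
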