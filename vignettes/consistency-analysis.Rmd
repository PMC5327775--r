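---
title: "Risk-score consistency analysis in chronic myeloid leukemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-score consistency analysis in chronic myeloid leukemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmlrisk)
```

## The problem

Four baseline prognostic scoring systems are in routine use for chronic
myeloid leukemia: Sokal, Hasford (Euro), EUTOS and ELTS. Each maps a
handful of diagnosis-time variables — age, palpable spleen size (cm below
the costal margin; 0 means non-palpable), platelet count (×10⁹/L), and
peripheral blast, eosinophil and basophil percentages — through fixed
published coefficients to a continuous score, and the score to a risk
category through published cut-offs. Sokal, Hasford and ELTS use three
categories (low / intermediate / high); EUTOS uses two.

Applied to the same patient the systems often disagree. This package
implements the scores and a consistency analysis that evaluates them
against a binary molecular endpoint, major molecular response (MMR:
BCR-ABL1 transcript level ≤ 0.1% on the international scale, assessed at
12 months): which scores agree, how often they conflict, and which score
predicts MMR best when they conflict.

## Score implementation and boundary conventions

The score equations are implemented exactly as published, with two
structural readings that deserve comment because careless typesetting of
the originals can suggest otherwise:

* **Sokal**: the exponential applies to the *whole* linear predictor,
  `exp(0.0116(age − 43.4) + 0.0345(spleen − 7.51) + 0.188((platelets/700)² −
  0.563) + 0.0887(blasts − 2.10))`. This is the original hazard-ratio form
  and the only reading under which the 0.8 / 1.2 cut-offs partition the
  score's actual range; attaching `exp` to the age term alone produces
  values near 1 + small terms for which those cut-offs are meaningless.
* **Hasford**: the ×1000 applies to the whole sum, not to the platelet
  indicator alone; otherwise the 780 / 1480 cut-offs are unreachable.

Category boundaries are closed/open as follows. Sokal: low < 0.8,
intermediate ∈ [0.8, 1.2], high > 1.2. Hasford is published with integer
cut-offs (≤ 780 / 781–1480 / ≥ 1481), which leaves the open intervals
(780, 781) and (1480, 1481) unaddressed for the non-integer scores that
real inputs produce; we use low ≤ 780, intermediate ∈ (780, 1480], high >
1480 — continuous, gap-free, and agreeing with the integer cut-offs
wherever they apply. EUTOS: low < 87, high ≥ 87. ELTS: the value 1.5680 is
printed in both the low and intermediate ranges; we assign it to low
("low-risk score ≤ 1.5680"), making intermediate the half-open interval
(1.5680, 2.2185] and high everything above. ELTS uses age in completed
years, so fractional ages are floored for that score only; the Hasford age
indicator uses the raw age.

Validation is strict by default (finite values, percentages in [0, 100],
platelets strictly positive — the ELTS platelet term is a −0.5 power, so
zero is a singularity) with a documented opt-out, because out-of-range
inputs corrupt scores silently rather than loudly.

## Dichotomization, accuracy, and the consistency partition

Two strategies collapse the three-level systems to two levels: strategy 1
merges intermediate with low; strategy 2 merges intermediate with high.
EUTOS is unaffected by either. Accuracy treats the dichotomized label as a
binary classifier of MMR — high predicts *failure to achieve* MMR, the
merged low group predicts achievement — and is the percentage of patients
whose label matches their outcome, computed from the 2×2 label × MMR
contingency table. Accuracies are computed at full precision and rounded
half-up to two decimals; on the reference cohort strategy 1 dominates
strategy 2 for every three-level system, which is why the partition is
defined on strategy-1 labels.

With four dichotomized systems there are 2⁴ = 16 joint label patterns,
enumerated in a fixed order (Sokal most significant; lowish before high).
Patients whose four labels all agree form the consensus group; the rest
form the conflict group. Per-system accuracy is then computed in the whole
cohort and within each group; because the groups partition the cohort, the
whole-cohort agreement count decomposes exactly into the consensus and
conflict agreement counts.

One reporting subtlety: conventionally quoted whole-cohort accuracies pair
Sokal, EUTOS and ELTS strategy-1 figures with a Hasford figure that
corresponds to the *strategy-2* dichotomization (58.95 rather than the
strategy-consistent 67.37 on the reference cohort). The report therefore
exposes both: `subgroup_accuracies` is strategy-consistent (and satisfies
the decomposition identity), while both strategies' full contingency
tables and accuracies sit in `strategy_tables`. Similarly, the
consensus-group misclassification count is reported against both natural
denominators (share of the whole cohort and share of the consensus group),
since the two percentages answer different questions.

## The synthetic cohort generator

`generate_cohort()` exists so that every analysis stage is testable
without access to patient data. Each baseline variable is drawn from a
truncated distribution whose *truncated* median is calibrated (by
root-finding on the location parameter) to the published summary value:

| Variable | Median | SD | Range | Family |
|---|---|---|---|---|
| Age (yr) | 40.21 | 15.13 | 18–74 | truncated normal |
| Spleen (cm) | 8.33 | 7.53 | 0–25 | truncated normal |
| Platelets (×10⁹/L) | 510.97 | 439.88 | 4.42–2876 | truncated lognormal |
| Basophils (%) | 1.32 | 1.10 | 0–7 | truncated normal |
| Eosinophils (%) | 0.83 | 1.24 | 0–7 | truncated normal |
| Blasts (%) | 1.50 | 1.39 | 0–10 | truncated normal |

Platelets get a lognormal family because the published summary is strongly
right-skewed (median 511 with SD 440 and a range to 2876); the log-scale
spread is set from the SD/median ratio of the untruncated lognormal and
the log-location is then calibrated as above. The eosinophil range is
published as 0–0.07, which contradicts its own median of 0.83; we treat it
as 0–7, symmetric with the basophil range, and flag the discrepancy here.
All rows are overridable through `cohort_config(variables = ...)`.

MMR is assigned by a logistic model: each patient's four score values are
z-standardized within the cohort, averaged, and re-standardized into a
composite (`risk_composite()`), and `logit P(MMR) = logit(baseline) −
a·composite` with baseline rate 0.65 (the reference cohort's 62/95) and
association `a` defaulting to 0.5, a moderate prognostic signal. `a = 0`
gives outcome-independent risk; the generator's slope is recoverable by
logistic regression of MMR on the composite (verified at n = 10,000 within
three standard errors).

What the generator deliberately does **not** emulate: correlations between
baseline variables (real splenomegaly co-occurs with basophilia and
thrombocytosis; variables here are independent draws), longitudinal
BCR-ABL1 kinetics (MMR is a single binary endpoint), and any
treatment-response mechanism beyond the single logistic link. Passing
tests on generated cohorts therefore validate the *analysis machinery*,
not clinical claims about real populations.

## Cohort reconstruction from aggregate tables

`reconstruct_cohort()` inverts the analysis: given the 16 combination-row
counts (split by MMR) plus per-system strategy-2 marginals, it builds a
patient-level cohort that reproduces them exactly. The steps:

1. **Slots.** One slot per patient, carrying its pattern row and an MMR
   flag; MMR flags are assigned deterministically to match each row's
   split (the targets fix them exactly, so sampling them would only add
   noise).
2. **Intermediates.** The number of intermediate-category patients per
   three-level system equals its strategy-2 high count minus its
   strategy-1 high count, per MMR status. These are placed greedily in
   slot order among that system's lowish slots. On the reference targets
   every intermediate fits inside the all-lowish consensus row, and since
   the targets constrain only per-system marginals, the placement choice
   cannot affect any reported table.
3. **Rejection search.** For each pattern, patient baselines are drawn
   from broad uniform clinical ranges (age 18–80, spleen 0–30, blasts
   0–15, eosinophils 0–10, basophils 0–12; platelets log-uniform on
   10–3000) until the *scored* three-level categories match the slot's
   targets. Platelets are log-uniform because several patterns (high
   Sokal or ELTS with low Hasford) live in the clinically real but
   numerically narrow low-platelet regime that a linear-scale uniform on
   a range reaching 3000 essentially never visits. Each pattern uses its
   own PRNG stream derived from the seed and the pattern index, so
   patterns are reproducible independently; the default budget is 2×10⁷
   candidate draws per pattern, after which the pattern is reported as
   unsatisfiable by name (some patterns genuinely are — e.g. low Sokal
   with high Hasford, since every Hasford-high route inflates the Sokal
   exponent within these ranges; all such patterns have zero counts in
   the reference targets).
4. **Verification.** The finished cohort is re-scored with the score
   engine and every slot's categories checked; the search's bookkeeping
   is never trusted.

Reconstructed patients are *aggregate-equivalent* stand-ins, not estimates
of the real patients: only their score categories and MMR flags are
constrained, so their raw baseline values should not be interpreted
clinically.

## Numerical and testing choices

Accuracy rounding is half-up at two decimals (base R's `round()` is
round-half-even, which is the wrong convention for reported clinical
percentages). Published accuracy figures mix rounding and truncation at
the second decimal (62.10 vs 62.105…; 63.15 and 63.16 for the same
60/95), so reproduction tests compare at an absolute tolerance of 0.01
percentage points rather than demanding digit identity. Cohort CSVs are
written with 17 significant digits so a write–read round trip is
bit-exact. Problem sizes used by the test suite: 10,000-patient simulated
cohorts for distribution and association checks, 100 random label cohorts
for the patient-level vs aggregated accuracy equivalence, and the 95-patient
reconstructed cohort for the end-to-end reproduction; the whole suite runs
in well under a minute.

## Limitations

The package makes no survival or time-to-event claims (no OS/EFS
endpoints), does not re-derive any score's regression coefficients, and
implements no meta-model for resolving conflicts between scores — it
quantifies the conflict and the per-score accuracy within it, nothing
more. Accuracy against a binary MMR endpoint is a deliberately simple
figure of merit: it ignores calibration, class imbalance and the cost
asymmetry between over- and under-treatment.
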