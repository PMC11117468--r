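---
title: "The urine light chain/eGFR quotient: model, calibration and validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The urine light chain/eGFR quotient: model, calibration and validation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcquotient)
```

## The clinical problem and the rule

About one fifth to two fifths of multiple myeloma patients develop
kidney failure from light-chain nephropathy, and cast nephropathy (CN)
is its most aggressive form: precipitated monoclonal free light chains
obstruct the tubules, and without rapid treatment the patient ends up on
dialysis. Proving CN requires a kidney biopsy, which high light-chain
concentrations themselves make riskier (platelet interaction, bleeding).

CN has a biochemical signature that no single routine value captures:
*more* severe filtration loss than the other paraprotein kidney diseases
(AL amyloidosis, monoclonal immunoglobulin deposition disease, light-chain
proximal tubulopathy, ...) combined with *higher* urinary excretion of
the involved light chain. The quotient

$$Q = \frac{\mathrm{LC}_{\mathrm{urine}}}{\mathrm{eGFR}}
\qquad \left[\frac{\mathrm{mg/dL}}{\mathrm{mL/min/1.73\,m^2}}\right]$$

amplifies both effects. The decision rule is isotype-specific:

| involved LC | positive (CN predicted) iff |
|---|---|
| lambda | $Q > 2$ |
| kappa | $Q > 5$, **or** $1 < Q \le 5$ and proteinuria $< 8\,$g/24 h |

The kappa branch needs proteinuria because kappa light chains more often
cause unspecific tubulointerstitial damage with moderately elevated
quotients; heavy proteinuria in that mid-range argues for a glomerular
process rather than CN.

### Boundary conventions

The rule has been stated in two printed forms — "$Q > 1$ and proteinuria
$< 8$ g/24 h, or $Q > 5$" and "$Q > 5$, or $Q$ 1–5 and proteinuria
$< 8$ g/day". Whether "1–5" includes its endpoints is never stated. We
adopt **strict comparisons everywhere** (`>` for quotient cuts, `<` for
proteinuria) and realise the interval as $1 < Q \le 5$. Under this
convention the two phrasings are logically identical, which the test
suite verifies by exhaustive grid enumeration around the cut points. A
patient sitting exactly on a cut is negative; the source material never
exhibits a boundary case, so the convention is ours and is documented
here. Thresholds are configuration (`rule_thresholds()`), not constants,
so sensitivity analyses over the cuts are possible; the defaults are the
published ones.

The quotient is undefined in anuria: `lc_egfr_quotient()` raises a
domain error for non-positive eGFR rather than returning an infinity.
Kappa patients with missing proteinuria and a quotient in the
branch-sensitive range $(1, 5]$ are *unclassifiable*; `apply_rule()`
excludes them with a machine-readable reason instead of guessing.
Lambda patients never need proteinuria.

## eGFR: which CKD-EPI?

The validation cohort reports "the CKD-EPI formula" without a version.
We implement the 2009 creatinine equation as the default with the race
coefficient fixed at 1.0 — the typical European laboratory practice
during the 2019–2023 enrolment window — and make the 2021 race-free
refit selectable (`ckdepi_params("2021")`). The choice shifts eGFR by a
few percent and can move borderline quotients across a cut, which is why
the version is explicit configuration rather than a hidden constant.
Body-surface indexing is left as reported (per 1.73 m²).

The inverse map `creatinine_from_egfr()` is the exact closed-form
inversion of the piecewise power law; the branch is selected by
comparing the target eGFR with its value at the sex-specific knot
(creatinine 0.7 mg/dL female / 0.9 mg/dL male), where the two branches
meet continuously. The inverse exists so that simulated patients carry a
serum creatinine consistent with their sampled eGFR; cohort validation
checks that consistency (default relative tolerance 5%) on real files
too, completing eGFR from creatinine when only the latter is supplied.

## The virtual-cohort generator

Raw patient data underlying the validation cohort are not deposited, so
the package ships a generator (`cohort_spec()`, `generate_cohort()`)
that emulates the cohort's *marginal* per-histology summaries. It is
first-class, tested code: every pipeline stage runs against it.

**Distribution family.** eGFR, involved serum FLC, involved urine LC and
proteinuria are positive and right-skewed (published group means sit far
above the medians), so each variable in each group is log-normal. A
log-normal with median $m$ and log-scale standard deviation $\sigma$ has
IQR $2m\sinh(z\sigma)$ with $z = \Phi^{-1}(0.75)$, giving the closed-form
calibration

$$\sigma = \mathrm{asinh}\!\left(\frac{\mathrm{IQR}}{2m}\right)/z,$$

implemented in `sigma_from_median_iqr()` and verified by plug-back to
$10^{-9}$. The default spec encodes the published median (IQR) of each
variable for the four groups (CN $n=18$, ALA $n=13$, MIDD $n=3$, Others
$n=33$).

**Proteinuria** has no published IQR, only group means (3929 mg/24 h in
CN, 2565 mg/24 h in the rest), so it uses a log-normal with log-scale
sigma fixed at 1.0 and median $\mathrm{mean}\cdot e^{-\sigma^2/2}$. It
is the weakest-calibrated variable; only the kappa mid-branch consults
it.

**Composition.** Group sizes, the CN kappa fraction (11/18) and the
overall kappa/lambda split (38/29, hence 27/49 kappa in each non-CN
group — only the overall non-CN split is published), sex (24 female of
67) and the histology mix inside "Others" are allocated by deterministic
largest-remainder counts, so the default cohort reproduces the published
composition *exactly* at any seed while scaled cohorts keep the
proportions. Age uses a Beta(3, 1.745) draw scaled to [38, 90], whose
median sits at 72 — a right-weighted, range-respecting choice; the exact
family is unconstrained by the source summaries.

**Independence.** eGFR and urine LC are sampled independently within a
patient (no joint statistics are published). A log-scale correlation
hook exists for sensitivity analyses
(`cohort_spec(log_cor_egfr_urine = ...)`), clearly an extrapolation.
Under independence the generated quotient is itself log-normal with
median equal to the *ratio of medians* — e.g. $171.5/7.5 \approx 22.9$
in CN — which is not the same quantity as the published *median of
ratios* (33.1 in CN). Both are far above every cut, and the generated
group ordering CN > MIDD > ALA ≥ Others mirrors the published one, but
this is the main sense in which the generator emulates margins rather
than the joint distribution.

**What passing tests therefore show.** On generated cohorts the rule's
sensitivity is high (the CN quotient mass sits far above the cuts) and
specificity lands near the published value — but the published
specificity emerges from tail overlap in real patients that marginal
calibration cannot claim to reproduce. The test suite consequently
asserts only conservative bounds on synthetic operating characteristics
(sensitivity ≥ 0.90, specificity ≥ 0.70 at 10,000 draws per class) and
exact agreement where exactness is meaningful: the accuracy metrics
recomputed from the published 2×2 counts. MIDD, calibrated from a
three-patient summary with an enormous serum-FLC IQR, participates in
ordering checks but not in tight recovery tolerances.

## Statistical machinery and numerical conventions

* **Accuracy metrics** come from the four-field table with
  Clopper–Pearson exact intervals (95% default). The source prints no
  intervals; exact intervals are the conservative standard at these
  denominators and are labelled as a package extension. Zero-denominator
  metrics are reported as undefined (`NA`), never coerced.
* **ROC/AUC**: ties are grouped into single operating points and credited
  ½ in the AUC, computed as the normalised Mann–Whitney rank statistic;
  the trapezoidal area of the polyline is equal by construction and both
  are tested against exhaustive pair enumeration (and pROC). The kappa
  rule is a *compound* of quotient and proteinuria, so its operating
  point is evaluated as a point and not forced onto the single-score
  ROC; for lambda the rule is a pure threshold and its point lies on the
  ROC polyline (tested).
* **Group comparisons**: Kruskal–Wallis with tie correction
  (delegated to `stats::kruskal.test`), Dunn's post hoc on pooled
  mid-ranks with the tie-corrected standard error and two-sided normal
  p-values (sidedness is unstated in the source; two-sided is the
  conservative default), Benjamini–Hochberg adjustment via
  `stats::p.adjust` with the family being the six pairwise comparisons
  of *one* variable, matching per-variable reporting. For two groups
  Dunn's $z^2$ equals $H$, verified to $10^{-10}$.
* **t-test/ANOVA**: the CN-vs-other-kidney-disease contrasts use the
  Welch form (group variances are clearly unequal); the pooled variant
  exists and supplies the classical $t^2 = F$ identity test.
* **Quartile convention**: linear interpolation between order statistics
  (`quantile` type 7) everywhere, fixed because IQRs feed the generator
  calibration.
* **Determinism**: `generate_cohort()` is a pure function of
  (spec, seed); it pins the RNG kind and restores the caller's RNG
  state.

## Problem sizes in the shipped tests

Oracle-equivalence checks run on hundreds of small random instances
(≤ 30 points each); calibration recovery uses 100,000 draws per group
(2% tolerance); operating-characteristic bounds use 10,000 draws per
class; the Kruskal–Wallis null simulation uses 2,000 replicates of four
groups of 15. The full suite completes in well under a minute on one
CPU.

## Known limitations

* The rule is undefined in anuria; biopsy remains the only option there.
* 24-h urine collection errors propagate linearly into $Q$; the package
  treats the collected value as exact.
* False positives concentrate in light-chain proximal tubulopathy, which
  shares the low-eGFR/high-LC$_{urine}$ signature; the rule cannot
  separate it from CN, which is why it is a rule-*out* (NPV-driven)
  tool. The alternative urinary-albumin-fraction criterion (≤ 10%
  albumin) is out of scope beyond this note.
* The generator emulates marginal summaries only (see above); it does
  not model longitudinal progression or treatment response.
* One source passage gives the CN isotype split as 10 kappa / 8 lambda
  while the tabulated counts give 11/7; the package follows the
  tabulated counts (11/7) and records the discrepancy here rather than
  resolving it.
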