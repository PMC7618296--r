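---
title: "A decision-analytic model of ovarian cancer triage in primary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of ovarian cancer triage in primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatriage)
```

## The problem

Women presenting in UK primary care with symptoms of possible ovarian cancer
(OC) are currently triaged with a CA125 blood test; if CA125 is at or above
35 U/mL a pelvic ultrasound scan (USS) follows, and an abnormal scan leads to
urgent referral. Because OC risk varies strongly with both the CA125 level
and age, risk models (Ovatools) that convert CA125 and age into a 12-month
invasive-OC probability — or equivalent age-adjusted CA125 thresholds —
allow risk-based triage instead of the single cut-off. `ovatriage`
implements a decision-analytic evaluation of six triage pathways:

1. **P1** (current practice): CA125 ≥ 35 U/mL, then USS.
2. **P2**: Ovatools risk < 1% reassure; 1–3% USS; ≥ 3% direct urgent referral.
3. **P3**: as P2 with age-adjusted CA125 thresholds accuracy-matched to the
   same risk levels.
4. **P4**: CA125 and USS concurrently; refer if Ovatools risk ≥ 3% *or* USS
   abnormal.
5. **P5**: as P4 with the age-adjusted threshold.
6. **P6**: concurrent, refer if CA125 ≥ 35 U/mL *or* USS abnormal.

Each pathway is scored by detection and referral rates, lifetime discounted
QALYs and costs per 1000 women, and incremental cost-effectiveness ratios
(ICERs), separately for women under and over 50 (test accuracy differs
sharply between the two groups).

## The decision tree

The tree classifies each woman into one of four classes — true positive
(invasive OC detected and referred), false negative (OC missed), true
negative, false positive (no OC but referred) — under conditional
independence of the blood test and USS given disease status. Specificity is
defined against "no invasive OC", so women with other cancers sit in the
negative class. Closed forms per mode (s = sensitivity, q = specificity):

* sequential single cut: `P(detect|OC) = s_blood * s_USS`,
  `P(refer|no OC) = (1-q_blood) (1-q_USS)`;
* sequential banded: `P(detect|OC) = s_high + (s_mod - s_high) s_USS`,
  `P(refer|no OC) = (1-q_high) + (q_high - q_mod)(1-q_USS)`;
* concurrent: `P(detect|OC) = 1 - (1-s_blood)(1-s_USS)`,
  `P(refer|no OC) = 1 - q_blood q_USS`.

With the published accuracy table and stratum prevalences (0.2% under 50,
1.05% at 50+) these forms reproduce all printed detection/referral
percentages to printed rounding, which is the package's decision-tree
acceptance surface. The tests additionally check the closed forms against a
brute-force enumeration of every joint (disease, blood band, USS) atom.

Age-adjusted CA125 pathways (P3/P5) default to Ovatools accuracy at the
matched risk level — their defining property — so the package reproduces the
Ovatools pathways' operating characteristics for them; a threshold-specific
accuracy table can be loaded to override this.

### Stage shift

Earlier detection is translated into benefit through staging: cancers
detected by the new pathway but missed by current practice have their
probability of late-stage (III/IV) diagnosis multiplied by a relative risk
of 0.836 (95% CI 0.737–0.950, screen-detected vs clinically detected
symptomatic women), i.e. a 16.4% reduction; the displaced mass is diagnosed
early. All other cases keep usual-care staging, and a pathway that detects
*fewer* cancers than current practice triggers no reverse shift — missed
cases simply revert to usual-care staging. The shift is always computed
against pathway 1 on the same stratum.

### Primary and secondary care costs

Branch costs accumulate the stated sequences (2022 GBP): GP face-to-face
consultation £40, nurse blood draw £9, CA125 test £10; a follow-on USS adds
a £20 telephone follow-up and the £204 scan; any referral is preceded by one
further £40 consultation. Concurrent pathways bundle the USS into the
initial visit. The source costing does not detail the concurrent
consultation structure or the direct-referral branch; we adopt the minimal
extension of the sequential rules (one extra consult before referral in
both cases).
False negatives repeat the full diagnostic process once, costed as the same
branch twice, and enter the Markov model with usual-care staging in year 1.
False-positive referrals without any cancer incur either benign-disease
surgery (probability 0.75, £3,994) or an outpatient workup
(£181 + £10 + £204), an expected £3,094.25.

## The Markov model

Five states — no cancer, early-stage cancer, late-stage cancer (entry
states), cancer death and non-cancer death (absorbing) — with annual cycles
until age 110. Cancer-death risk in the first 8 years after diagnosis
(scenario: 15) comes from stage-specific survival models; beyond the horizon
it is the life-table cancer mortality at current age, as is all mortality
for women without cancer. There are no early↔late transitions: progression
is subsumed in the stage-specific death risk. Competing risks within a cycle
are combined on the hazard scale, with the joint-death overlap allocated
proportionally to the hazards; this reduces exactly to the single-risk form
when one hazard is zero, and matches closed-form exponential survival to
1e-8 under constant hazards (a test).

Discounting uses `(1+r)^(-t)` with `t = 0` for the first cycle, r = 3.5%/yr
for both QALYs and costs (scenario 1.5%). No half-cycle correction is
applied in the base case (the source analysis does not state one; a config
switch enables it) — pathway comparisons, being differences, are unaffected
to first order.

### Synthetic parametrization

The registry-fitted inputs (flexible parametric survival models, two-part
GLM cost models, the UK Biobank EQ-5D regression, national life tables) are
outside this package's scope; `synthetic_profile()` supplies calibrated
deterministic stand-ins with the same interfaces, so synthetic and
user-supplied inputs are interchangeable:

* **Survival**: exponential models pinned exactly to one anchor each.
  Ovarian cancer uses the published 5-year survival of 95% (stage I → early)
  and 16% (stage IV → late), giving hazards 0.0103/yr and 0.3665/yr. The
  model's stages are I/II vs III/IV, so using the stage-I and stage-IV
  figures brackets the true early/late survival; the anchor table is
  configurable (e.g. Weibull-like shapes can be approximated by re-anchoring).
  Other cancer types (lower GI, uterine, lung, pancreatic, other) carry
  documented synthetic anchors with late ≤ early survival.
* **Life table**: Gompertz–Makeham female all-cause mortality
  (A = 2e-4, B = 1.8e-5, C = 0.1/yr, approximating UK female rates),
  partitioned into cancer/non-cancer by a smooth age-dependent cancer share
  peaking near age 66.
* **Utility**: the published female EQ-5D age function
  (0.9508566 − 0.0002587·age − 0.0000332·age²), cancer decrements with two
  recency levels (within vs beyond one year of diagnosis), a late-stage
  extra decrement of 0.046 applied in every cycle spent in the late state
  (its duration is not stated at source; diagnosis-year-only is the obvious
  alternative, and scenario values 0.06 and 0 are supported), and
  benign-surgery effects −0.04 in the surgery year and +0.008/yr thereafter,
  applied to the 75% of no-cancer false positives who undergo surgery.
* **Costs**: step-function annual inpatient costs per type × stage over
  years 0–4+ since diagnosis (late year-0 ≥ early), plus a £450/yr
  background inpatient cost.
* **Population**: strata reproduce the cohort headers exactly (under 50:
  n = 112,081, prevalence 0.2%, 46% late; 50+: n = 164,746, 1.05%, 72%
  late); integer-age weights follow a truncated normal (mean 54.6,
  SD 15.8 — the cohort's age distribution) restricted to each stratum;
  cohort-wide other-cancer prevalences are split across strata by an age
  gradient (under-50 carries half the cohort-wide rate) that preserves the
  overall rates.

The synthetic stand-ins reproduce the *structure* of the published analysis
— the sign pattern of incremental QALYs and costs and the dominance
relations — but not its absolute magnitudes, which depend on the fitted
registry internals. Passing tests therefore demonstrate mechanism
correctness, not calibration to the source cohort: with printed unit costs
alone, the false-positive referral delta already puts the 50+ sequential
pathway's incremental cost well above the published £34.9k per 1000.

Women with other cancers traverse the Markov model with their own synthetic
curves and are pathway-invariant in the base case; an optional scenario
applies a stage-shift analog to them, scaled by the pathway's incremental
ovarian detection with a user-supplied relative risk (no other-cancer
accuracy data exist at source, so this is deliberately a hook, not an
estimate).

## Economic analysis

Per-pathway results are scaled to 1000 women. Incremental analysis differs
each pathway against current practice. The ICER frontier sorts options by
cost, removes strictly dominated options, then iteratively removes options
whose pairwise ICER sequence is non-increasing until the ladder strictly
increases (standard extended-dominance pruning; equivalence with an
exhaustive net-benefit search over all ≤ 6-option inputs is a test). The
Ovatools pathway and its age-adjusted twin are never compared with each
other: each option is evaluated in a frontier containing, from every other
twin group, only the lowest-id member, and is reported against the shared
lower neighbour. Fed the published incremental table, this flags pathways 4
and 5 as extendedly dominated in both age groups and reconciles the printed
frontier ICERs within 0.5% (exact reproduction is impossible from rounded
inputs).

### Probabilistic sensitivity analysis

1000 parameter sets by default. The source describes bootstrap/Monte-Carlo
parameter sets; without the source data, parametric Monte Carlo from the
printed 95% CIs is used: beta distributions (method of moments) for every
sensitivity/specificity, a lognormal matched to its CI for the stage-shift
relative risk (draws above 1 are capped, with a warning), normals for the
two benign-surgery QoL deltas, and fixed values for parameters printed
without uncertainty. Drawn Ovatools operating points are clamped to respect
ROC ordering across thresholds. CEACs report, at each willingness-to-pay
value (default grid £0–50,000 by £1,000; the source axis convention is not
fully specified), the fraction of draws in which each pathway attains the
maximal net benefit, ties split equally.

Because the drawn parameters enter the Markov layer only through class
weights and the analytic surgery-QoL term, the per-age Markov component
outcomes are computed once and reused across draws, keeping a 1000-draw PSA
in seconds.

### Threshold sweep

Ovatools accuracy between the printed 1% and 3% operating points is not
reported; we interpolate on a binormal ROC curve,
`TPR = Φ(a + b·Φ⁻¹(FPR))`, fitted exactly through the two printed operating
points per age group, with the operating point indexed linearly in
`Φ⁻¹(FPR)` against log risk threshold. This two-parameter form is standard
in diagnostic-accuracy modelling, anchors exactly, and is monotone over the
sweep range (0.6%–4%); it is our choice — the source does not state an
interpolation — and any user-supplied (threshold, sensitivity, specificity)
table overrides it. The sweep grid re-evaluates the banded sequential
pathway against current practice for each (moderate, high) threshold pair;
the (1%, 3%) cell equals the base case exactly, and the incremental cost is
non-increasing in the moderate threshold (fewer scans and referrals), the
mechanism behind the reported ICER drop when the USS threshold rises.

## Numerical and design choices

* Degenerate inputs: zero prevalence reports detection as `NA`; ROC anchors
  on the unit-square boundary, equal-FPR anchors and non-positive thresholds
  are errors; exact QALY/cost ties on the frontier keep the lower pathway id
  and flag the tie.
* Occupancy conservation is enforced at 1e-10 in tests; closed-form
  agreement under constant hazards at 1e-8.
* Problem sizes: the shipped analyses run two strata × six pathways over
  integer-age grids (32 and 50 ages), a 1000-draw PSA and sweep grids of a
  few hundred cells — a full base case in a few seconds and the PSA in
  well under a minute on one core.

## Known limitations

* Survival, cost and utility stand-ins are synthetic: absolute QALY/cost
  levels (and hence synthetic-default ICERs) are not estimates of the
  published ones.
* Test accuracy is age-group-specific, not per-year-of-age, and
  stage-invariant by default (a stage-stratified accuracy table is accepted
  via configuration).
* One-time testing: repeat presentation beyond the single false-negative
  re-entry is not modelled, and the cohort is closed to new cancers after
  the index year (cancer deaths among undiagnosed women enter through
  cause-specific life-table mortality).
* The late-stage utility decrement is applied for the whole time in state;
  if the true effect is transient the QALY benefit of the stage shift is
  overstated in proportion.
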