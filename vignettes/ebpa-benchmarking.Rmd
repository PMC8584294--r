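---
title: "Benchmarking personalised scoliosis treatment against randomised trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking personalised scoliosis treatment against randomised trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebpabench)
```

## The problem

Adolescent idiopathic scoliosis (AIS) at high risk of progression —
curves of 11–45° Cobb with Risser maturity 0–2 — is treated
conservatively with a graded arsenal: observation, scoliosis-specific
exercises, elastic bracing, and rigid or very rigid bracing at
increasing daily dosages. Randomised controlled trials (RCTs) have each
tested one treatment at one fixed intensity. An evidence-based
personalised approach (EBPA) instead selects, within guideline bounds
and through shared decision-making, a different intensity for each
clinical situation. The question this package operationalises: how does
an EBPA-treated cohort, followed to the end of growth, compare with
the published arms of those RCTs, both in results and in burden of
care?

The comparison machinery has four layers, each a module of the package:

1. **Cohort model** (`read_cohort()`, `apply_study_filters()`): a wide
   one-row-per-patient table with baseline and end-of-observation
   fields, validated, filtered by the study's inclusion and exclusion
   criteria with a deterministic attrition ledger.
2. **Rule engine** (`classify_*()`, `adherence_matrix()`): per-patient
   labels — change category, guideline aims, over-/under-treatment —
   plus per-trial eligibility and success.
3. **Effect measures** (`relative_risk()`, `number_needed_to_treat()`,
   `chi_square()`, `t_test_from_summaries()`): 2×2 comparative
   statistics under efficacy and worst-case intent-to-treat analyses.
4. **Synthetic cohort generator** (`generate_cohort()`): a seeded
   simulator with the statistical structure the analysis assumes, so
   the whole pipeline is testable without access to any clinical
   database.

## The classification rules

All rules key on the Cobb angle of the largest curve and the
radiographic measurement error of 5°.

**Change.** A patient *improved* if the angle fell by strictly more
than 5°, *progressed* if it rose by strictly more than 5°, otherwise
*stable*. The strictness matters at the boundary: a 5° change is
stable.

**Aims.** The severity at the start sets the target at the end of
growth. Starts of 11–20° aim below 20° (primary) and below 45°
(minimal); starts of 21–40° aim below 30° and below 45°; severe starts
of 41–45° aim below 45° and below 60°, the threshold beyond which
surgery is considered unavoidable.

**Under-treatment** is progression the applied therapy failed to
prevent, judged against the 30° adulthood threshold: starts below 30°
are under-treated when they end above 30°; starts of 30–40° when they
progress by more than 5° — unless intensity 6 (very rigid brace,
22–24 h/day) was already applied, since nothing stronger existed;
severe starts only when they cross 60°. A configuration switch
(`any_progression`) implements the stricter reading in which any
progression of a 30–40° start counts, with no intensity exemption.

**Over-treatment** is unnecessary improvement: more correction than the
30° threshold required. For starts up to 20°, any improvement beyond
the 5° measurement error. For starts of 21–40°, improvement must exceed
`5 + (cobb_start − 20)/2` — the measurement error plus half the excess
over 20° — *and* the end must lie below 30°. We read the printed
formula this way because it makes the margin grow smoothly from 5.5° at
a 21° start to 15° at 40°, consistent with its purpose; the 41–45°
band has no over-treatment rule (no improvement of a severe curve is
unnecessary). These two definitions are mutually exclusive by
construction, which the test suite verifies exhaustively on the full
integer grid of start × end × intensity against an independent
transcription of the band rules.

Band edges are closed on the printed integers and decimals fall in the
enclosing interval: bands are `[11,20]`, `(20,30]`, `(30,40]`,
`(40,45]`. The under-treatment dichotomy at 30° uses `cobb_start < 30`
versus `≥ 30` as the rules state it, so a start of exactly 30° follows
the progression rule.

## Benchmarks and effect measures

Each benchmark (`benchmarks.yaml`) carries an RCT's inclusion criteria,
its protocol intensity on the 0–6 scale, its outcome definition, and
its published arm summaries. Eligibility is recomputed per patient;
records missing an optional field used by a criterion (menarche status,
apex level) pass by default and are excluded under
`missing_policy = "strict"` — neither choice can be validated against
the original cohort, whose field completeness was never published.

Success follows each trial's failure definition complemented: below 50°
at the end (plastic bracing), below 45° (elastic bracing, the
definition behind the published risk ratios; the protocol reading,
progression ≤ 5°, is also available), progression ≤ 3° (exercises).

The *efficacy* analysis uses patients who completed treatment; the
worst-case *intent-to-treat* analysis keeps dropouts in the denominator
as failures. Patients still in treatment at data close are excluded
from both. The cohort arm is then compared with a published arm whose
counts are reconstructed by nearest-integer rounding of proportion × n
(residuals are logged, since printed proportions are themselves
rounded):

- relative risk of success with the Katz log-method interval — chosen
  because it reproduces the published 1.7–2.5 interval from the printed
  inputs; the published analysis never names its method;
- NNT as the reciprocal risk difference, with bounds from the inverted
  Wald interval reported in ascending order (an interval spanning zero
  leaves the upper bound unbounded);
- Pearson chi-square without Yates correction (samples are large; no
  correction is stated in the published analysis);
- pooled-variance Student t for baseline comparability from summary
  statistics — pooled, not Welch, because pooled reproduces the printed
  height p-value (0.0003 vs Welch's 0.0013 against a printed 0.0002).

Comparisons with printed one-decimal values round half away from zero
(`round_to_printed()`). Zero success cells in the reference arm are an
error unless the optional Haldane–Anscombe 0.5 correction is enabled;
no reconstructed published table needs it.

`published_benchmark_table()` recomputes the whole efficacy table and
the burden-of-care shifts from the packaged summaries alone. Published
intent-to-treat rows are not recomputed: their subgroup-specific
dropout denominators were never reported, so any reconstruction would
be a guess. The elastic-bracing rows are recomputed but carry a caveat:
the published efficacy entries for that trial appear internally
transposed between the control and treated comparisons, so they are not
used as a correctness reference anywhere in the tests.

## The synthetic generator

`generate_cohort()` draws, per patient: sex (83% female), age
(normal, 12.7 ± 1.3 y, untruncated — truncation would bias the mean the
moment-recovery tests pin down), baseline Cobb (normal 24 ± 8°
truncated to the 11–45° inclusion range — the simplest shape matching
the reported subgroup moments; no full-cohort distribution was
published), Risser stage (56/22/22% over 0/1/2, independent of Cobb by
default — the data to quantify their correlation was never
published; the policy table is the override hook), and a treatment
intensity drawn from the (Cobb band × Risser) policy whose default is
the published full-population adherence pattern, normalised cell-wise
to sum to one (several printed columns sum to 99 or 101).

The end-of-growth angle is `start + effect(intensity) +
Normal(0, outcome_sd)`, floored at zero, with default mean effects
(+6, +3, +1, −2, −3, −4, −6)° for intensities 0–6 and `outcome_sd = 6°`.
These effects are **calibration knobs chosen to be ordered and
plausible, not estimates about scoliosis**: tests use them only through
analytic identities (with `outcome_sd = 0`, exactly the intensity-6
patients improve and exactly the intensity-0 patients progress).
An optional pure measurement-error term (sd ≈ 2.5° corresponds to the
conventional ±5° reading error) can be added independently to both
recorded angles. Dropout (11%) is independent of outcome — the published study
notes dropouts did not differ at their last visit — and dropouts keep
their last observed angle but no end Risser stage; an
`in_treatment_prob` knob (0 by default, 0.14 to mimic the published study's
attrition diagram) marks patients excluded from analysis.

What the generator does *not* emulate: visit-by-visit growth and
treatment switching, compliance, informative dropout, multi-curve
anatomy, and any real correlation structure between maturity, curve
size and treatment choice beyond the policy table. Green tests
therefore certify the *machinery* — filters, rules, effect measures,
analyses — on data with known structure; they are not evidence about
clinical effect sizes.

## Numerical and design choices

- Filters run in a fixed order (Cobb range, Risser, in-charge visits,
  braced-at-first, radiograph window) so the attrition ledger is
  deterministic; the published methods state no order.
- The expected-intensity ranges behind `frac_outside_expected` ship as
  an editable configuration (`expected_intensity.yaml`) whose defaults
  are the modal intensities per band; the published marking of expected
  options is not machine-readable, so these figures are
  configuration-dependent and never asserted against it.
- The protocol intensity of the plastic-brace trial maps to level 3
  (rigid brace ≤ 21 h/day): its orthosis was prescribed from 18 h/day,
  and this mapping reproduces the published 48%/24% burden shift from
  the published subgroup distribution. The elastic-brace and exercise
  trials map to levels 2 and 1.
- Problem sizes in the test suite — 20,000 patients for moment
  recovery, 50,000 for policy recovery, 10,000 replicates for interval
  coverage, all 2×2 tables with row margins ≤ 30 for the chi-square
  closed form — were chosen so each check resolves its preregistered
  tolerance while the whole suite stays fast.
- Policy recovery is checked per matrix entry against a four-standard-
  error binomial band rather than a fixed percentage: with 12 cells
  sharing 50,000 patients, sparse severe-band cells hold a few hundred
  patients and a fixed 1-point band would be narrower than one sampling
  standard error there, making the test uninformative about generator
  correctness.

## Limitations

Everything quantitative about real cohorts requires real data; this
package ships none. The reproduction layer
(`published_benchmark_table()`) rests on printed summaries, so its
inputs inherit their rounding; reconstructed counts can differ from the
originals by one patient per arm, which moves the chi-square statistic
visibly (it is reproduced in magnitude, not to the decimal) while
leaving RR and NNT stable at one decimal. Cohort-level outcome
percentages (improved, progressed, over-/under-treated) depend on a
real case mix and are computed but never asserted against published
values.
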