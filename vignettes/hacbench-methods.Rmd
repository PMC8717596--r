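---
title: "Benchmarking hospital safety from hospital-acquired complications: models and design choices"
author: "hacbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking hospital safety from hospital-acquired complications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacbench)
```

## The problem

A hospital-acquired complication (HAC) is an adverse condition — a
pressure injury, a healthcare-associated infection, acute renal failure,
delirium, and so on — whose onset falls inside an admitted-patient
episode. HACs are largely preventable, and they are expensive: admissions
with a HAC kill more often, stay far longer, and cost several times more
than comparable admissions without one. Administrative admission data
record, for every diagnosis on an episode, both the ICD-10 code and a
*condition-onset flag* (COF): COF = 1 means the condition arose during the
episode; COF = 2 means it was present on admission. Together with a
grouping of ICD-10 codes into 16 national HAC classes, that flag lets a
complication be detected without chart review.

`hacbench` implements an episode-level analysis pipeline around this
definition:

1. **Cohort building** — exclusion of same-day admissions and
   private-sector hospitals, derivation of 30-day readmission from dates.
2. **HAC classification** — code + COF + position rules, per episode.
3. **Comorbidity and complexity** — the Charlson comorbidity index (CCI)
   per episode via the Quan ICD-10 algorithm, aggregated into a
   hospital-level complexity index.
4. **Benchmarking** — output-oriented data envelopment analysis (DEA) of
   hospitals against regional ("group") and state-wide ("meta")
   best-practice frontiers, with peers, targets and bootstrap intervals.
5. **Peer network** — the directed learn-from graph implied by the DEA
   peer structure.
6. **Outcome models** — logistic models for the odds of HAC, in-hospital
   death and 30-day readmission, and log-link GLMs for cost and length of
   stay (LOS).

Because the linked administrative data such analyses run on are not
public, the package also ships a **synthetic cohort generator** with
known ground truth, which turns the whole pipeline into something that
can be validated by parameter recovery.

## HAC classification rules

A diagnosis on an episode contributes a HAC group iff all four gates
pass:

* it is **not the principal diagnosis** (the first-listed code describes
  the reason for admission, not an acquired condition);
* its **COF equals 1**;
* its code **longest-prefix matches** an entry of the HAC mapping (codes
  are compared upper-cased with dots stripped; a longer prefix beats a
  shorter one, the standard grouper behaviour, so `T81.4` resolves to the
  infection group even though `T81` as a family belongs to the surgical
  complications group);
* the matched group is **not excluded**. Groups 5 (unplanned ICU
  admission — not identifiable from diagnosis codes), 15 and 16
  (maternity and neonatal groups, irrelevant in a cardiovascular cohort)
  are excluded by default.

The episode-level outcome is the dummy `hac` — at least one contributing
diagnosis — plus the set of groups. An episode with complications in two
groups counts once in prevalence and once per group in the
group-frequency table.

The shipped mapping is a deliberately reduced, versioned reference list
(at least three representative code families per included group). The
full national ICD-10-AM HAC list is licensed material; any CSV with
columns `code_prefix`, `hac_group_id`, `group_name` can be substituted.

## Charlson score and the complexity index

The CCI is computed per episode from that episode's diagnosis list with
the Quan ICD-10 prefixes for the 12 conditions that carry non-zero weight
in the updated, mortality-calibrated index (weights 1–6). Each condition
counts once; hierarchy pairs (mild vs moderate/severe liver disease, any
malignancy vs metastatic solid tumour) score only the severe member. No
lookback window across prior episodes is applied.

DEA needs one hospital-level "case-mix difficulty" input. The analysis
this package operationalises describes its complexity index only as
"constructed from the CCI and the ICU admission rate, ranging 0 to 1";
the exact construction is not public. We therefore implement a
documented, configurable stand-in:

$$\mathrm{complexity}_h \;=\; w_{\mathrm{cci}} \cdot
\min\!\left(\frac{\overline{\mathrm{CCI}}_h}{\mathrm{cap}},\, 1\right)
\;+\; w_{\mathrm{icu}} \cdot \mathrm{ICUrate}_h,
\qquad w_{\mathrm{cci}} = w_{\mathrm{icu}} = \tfrac12,$$

with `cap` defaulting to the cohort's 97.5th percentile of episode-level
CCI. This respects the stated unit range, uses both stated ingredients,
and is monotone in each. It is a stand-in: every report produced by the
package carries a caveat line saying so, and both the weights and the cap
are exposed. The *simplicity index* `1 - complexity` is what enters DEA,
so that all inputs relate positively to the safety output.

## Output-oriented DEA

Each hospital (decision-making unit, DMU) is described by inputs
$x = (\text{beds}, \text{simplicity})$ and the single output
$y = \text{safety rate} = 100 - 100\cdot\text{HAC rate}$ (percent).
Against a frontier set $J$, the radial output-expansion LP is

$$\max_{\varphi, \lambda}\ \varphi \quad \text{s.t.}\quad
\sum_{j \in J} \lambda_j x_j \le x_0,\qquad
\sum_{j \in J} \lambda_j y_j \ge \varphi\, y_0,\qquad
\lambda \ge 0,$$

plus $\sum_j \lambda_j = 1$ under variable returns to scale (VRS).
Technical efficiency is $TE = 1/\varphi \in (0, 1]$: the fraction of the
frontier-feasible safety rate the hospital actually achieves at its input
bundle. Output orientation is the right frame here — a hospital cannot
realistically shed beds or make its patients simpler, but it can improve
its safety rate.

Design choices, all of which were genuinely open:

* **Returns to scale.** Not stated by the source analysis. Default VRS,
  because hospitals in such cohorts differ in scale by two orders of
  magnitude and CRS would let tiny remote hospitals be scaled up
  fictitiously; CRS remains available (`rts = "crs"`) and every output
  labels the assumption. Because the RTS and interval method behind the
  original efficiency tables are unknown, those published scores are not
  treated as reproduction targets anywhere in the package.
* **Two-phase solution.** After maximising $\varphi$, a second LP
  maximises total slack at fixed $\varphi$. This makes peers and
  projected targets deterministic under the degenerate optima DEA is
  prone to. Peers are the frontier units with $\lambda > 10^{-6}$,
  reported in ascending id order.
* **Solver.** Both the envelopment LP and its dual multiplier form are
  solved by a package-internal dense two-phase simplex with Bland's
  anti-cycling rule. The problems are tiny (tens of variables), and
  having both formulations available lets the test suite assert
  envelopment–multiplier agreement to $10^{-7}$ on hundreds of random
  instances, alongside the closed-form single-ratio oracle for
  1-input/1-output CRS.
* **Positivity.** A zero safety rate is replaced by 0.1 (percent scale)
  and a zero simplicity by $10^{-6}$, with warnings — radial expansion
  requires positive data.
* **Group vs meta frontier.** Every hospital is scored against its own
  remoteness region's DMUs and against all DMUs pooled. The pooled
  feasible set contains the regional one, so $TE_{meta} \le TE_{group}$
  must hold; the suite asserts it with tolerance $10^{-7}$ on every
  generated cohort. The metatechnology ratio $TE_{meta}/TE_{group}$ is
  reported per DMU. Singleton regions score themselves efficient, with a
  logged caveat.
* **Averages and intervals.** The "average" row is a weighted mean over
  DMUs, weighted by retained episode counts by default (the weighting
  behind published averages of this kind is typically unstated; uniform
  weights are a config switch). Intervals are naive percentile bootstraps
  over DMUs resampled with replacement ($B = 1000$, seed-deterministic).
  Smoothed DEA bootstraps (Simar–Wilson) are deliberately out of scope;
  the naive intervals understate frontier-estimation uncertainty and are
  labelled as resampling intervals only.

The peer network turns the DEA solution into a directed graph: an edge
runs from each radially inefficient hospital to each of its peers with
weight $\lambda$, so under VRS the out-weights of an inefficient node sum
to 1. In-degree is a best-practice hospital's peer count — its influence.
Exports (edge CSV, GraphML) can pseudonymise hospital ids with a stable
salted hash, since the point of such maps is usually publication without
identifying hospitals.

## Outcome models

The descriptive stage reports HAC rates by stratum with Pearson
chi-squared tests (no continuity correction) and mean cost/LOS/death/
readmission by HAC status. The modelling stage fits, on the episode
level:

* logistic regressions (IRLS via `stats::glm`, binomial) for the odds of
  HAC, in-hospital death and 30-day readmission, the latter two including
  the HAC dummy;
* Gamma GLMs with log link for cost and LOS, so exponentiated
  coefficients are multiplicative effects on the conditional mean. A
  quasi-Poisson option exists for LOS.

Reference levels are fixed to the conventional bases (age < 45, SEIFA
Q1, divorced/separated, born in the Americas, major-city hospitals, no
comorbidity). Intervals are Wald on the exponentiated scale. Constant
outcomes are refused; apparent separation (non-convergence or any
log-odds coefficient beyond ±10) flags the fit rather than silently
reporting it. No patient-level clustering correction is applied — the
episode-level specification is deliberately plain, mirroring the analysis
it implements; repeated episodes per patient mean the nominal SEs are
mildly optimistic.

## The synthetic cohort generator

The generator emulates the *structure* of a linked state-wide
cardiovascular admissions cohort; no generative model is published for
the real data, so the generator uses exactly the model families the
analysis stage fits, making parameter recovery well-posed:

* **Hospitals.** 30 by default, five remoteness regions (probabilities
  0.25/0.25/0.25/0.15/0.10), 20% private, beds uniform on 20–800.
  Episodes are allocated to hospitals proportionally to beds. Each
  hospital carries a latent safety inefficiency
  $u_h = |N(0, \sigma)|$, $\sigma = 0.5$, added to the HAC log-odds —
  a half-normal, so the truth is a known efficiency ordering that DEA
  should recover.
* **Patients and episodes.** Seven age bands centred on an elderly
  cardiovascular mix; episode counts per patient $1 +
  \mathrm{Pois}(3)$; 65% same-day episodes; ICU rate 5.6% and acute rate
  86.8% (both back-derived from the published marginal HAC rates by
  stratum); comorbidity burden category 0/1/2+ with probabilities
  0.5/0.25/0.25, realised as actual Charlson codes (COF 2) on the
  diagnosis list so the scoring code path is exercised. Hierarchy pairs
  are never co-inserted, and the burden category is derived pre-hierarchy,
  so generated and fitted categories coincide. Diagnosis lists also carry
  a principal cardiovascular code and unmapped filler codes, which the
  classifier must tolerate.
* **Effect sizes.** The default coefficient vectors encode the published
  study-scale estimates as generating truth: ICU→HAC odds ratio 10.07,
  HAC→death 2.54, HAC→readmission 0.53, cost multiplier 3.10, LOS
  multiplier 2.93, plus the full covariate profiles and model constants
  (0.04, 0.04, 0.02, \$3,669, 4.48 days). Costs are Gamma on the log
  scale (shape 2).
* **LOS integerisation.** Stays are whole days, and overnight stays are
  at least one day. Drawing a Gamma and rounding with a floor of 1
  biases the mean of short stays upward and hence the recovered LOS
  multiplier downward by about 2%. Overnight LOS is therefore drawn as
  $1 + \mathrm{NegBin}(\mathrm{size}=1.5,\ \mu = e^{x'\beta} - 1)$,
  which keeps $E[\mathrm{LOS}\mid x] = e^{x'\beta}$ exactly — the
  log-link mean model holds and the Gamma GLM estimating equations
  remain consistent for $\beta$.
* **Readmission via dates.** The generator does not write a readmission
  flag; it draws the *next-admission gap* (within 0–30 days with the
  model's probability, otherwise 31+ geometric), and the cohort builder
  re-derives `readmit30` from dates — deliberately exercising that
  derivation. Consequence: sequence-final episodes, including every
  death-truncated sequence, can never show a readmission, so the
  recovered HAC→readmission odds ratio is attenuated relative to its
  generating value. This is a property of deriving readmission from
  observed admissions (real cohorts share it), and it is why the
  recovery suite pins death, cost and LOS — whose generation is not
  censored — and not readmission.
* **Death truncation.** An in-hospital death ends the patient's episode
  sequence.

Everything is deterministic given the seed, and `export_truth()` writes
the generating coefficients and the $u_h$ ranking to a JSON file that no
pipeline stage reads.

What passing tests on this generator do **not** show about real data:
real administrative cohorts have coded-field noise, transfers and nested
episodes, seasonal admission patterns, cost micro-components, and
case-mix correlation structures (age–comorbidity–hospital) far richer
than the generator's independent draws. The generator validates the
*pipeline machinery* — exclusion accounting, classification gates, index
arithmetic, LP correctness, estimator consistency — not the
epidemiology of any particular health system.

## Problem sizes and numerical conventions

* Desk-scale default: 30 hospitals, 5,000 patients, ~20,000 raw episodes
  — runs the full pipeline in a few seconds and is the scale of the unit
  suite's shared fixture (800 patients for the smallest).
* Evaluation scale (`study_scale_config()`): 22,000 patients, sized so
  that roughly 20,000 episodes survive the same-day and private-sector
  exclusions; used for effect-recovery checks (20 replicate seeds;
  95% Wald coverage of the generating HAC effects in at least 15 of 20)
  and for the inefficiency rank-recovery check (Spearman correlation
  between $u_h$ and $1 - TE_{meta}$ above 0.5 under homogeneous
  covariates).
* The 30-day window is inclusive of day 30 and measured from the
  separation date; a readmission starting on the discharge day (gap 0)
  counts. Same-day means separation date equals admission date.
  Same-day exclusion is accounted before the private-sector exclusion.
* LP tolerances: simplex pivot tolerance $10^{-9}$, peer threshold
  $\lambda > 10^{-6}$, meta-dominance assertion $10^{-7}$. Ties in peer
  sets break by ascending DMU id.

## Known limitations

* The complexity index is a stand-in; hospital rankings can be sensitive
  to its weights and cap, which is why they are configurable and every
  report repeats the caveat.
* Naive bootstrap intervals for mean efficiency ignore the frontier
  estimation bias that smoothed DEA bootstraps address.
* No transfer/episode-bundling logic: overlapping episodes only raise a
  warning.
* The shipped HAC and Charlson maps are reduced reference lists, adequate
  for validation and demonstration, not for production coding against a
  full ICD-10-AM corpus.
* Episode-level models without clustering corrections understate standard
  errors in multi-episode cohorts.
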