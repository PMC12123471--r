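---
title: "Intersectional versus marginal debiasing: models, design choices, and what the synthetic study does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersectional versus marginal debiasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Admission prediction models for emergency departments are trained to rank
visits by the probability of inpatient admission. Two fairness notions
matter for this task and cannot both be satisfied exactly when admission
rates differ across groups:

* **Sufficiency** — patients with the same risk score should experience
  the outcome at the same rate regardless of group membership. Its
  operational form here is *group-level calibration*.
* **Separation** — patients with the same outcome should receive similar
  scores regardless of group. Its operational relaxation here is keeping
  *subgroup false-negative rates* (falsely discharged patients) low, with
  the emphasis on the worst-off subgroup.

Both can be enforced with respect to *marginal* groups (one protected
attribute at a time) or *intersectional* groups (joint cells of all
protected attributes). A model can satisfy a marginal constraint while
violating it badly on intersections — fairness gerrymandering — so the
package's central comparison axis is: how much subgroup performance is
recovered by intersectional constraints that marginal constraints miss?
Evaluation is therefore always carried out over the intersectional
collection, whatever groups the intervention itself used.

## The two interventions

### Multicalibration boosting

Scores $s$ are $\alpha$-multicalibrated over a collection $C$ of subgroups
and a binning of $[0,1]$ if, for every group $g \in C$ and bin $b$ whose
cell holds at least a fraction $\gamma$ of all records,
$\lvert \mathrm{E}[y \mid g, b] - \mathrm{E}[s \mid g, b] \rvert \le \alpha$.
`fit_multicalibration()` sweeps cells — groups in canonical label order,
bins ascending — recomputing each cell against the *current* scores, and
adds the cell's residual (damped by `step`) to its members, clipping to
$[0,1]$, until a full sweep makes no update. Convergence therefore
certifies, by construction, that the fit-set audit
(`audit_multicalibration()`) is violation-free.

Key parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | per-cell calibration bound (probability scale) |
| `gamma` | 0.001 | minimum cell prevalence, against the full sample, for a cell to be audited/repaired; prevents overfitting groups of a handful of visits |
| `n_bins` | 10 | equal-width prediction bins $[k/10,(k+1)/10)$, last closed |
| `max_sweeps` | 100 | hard cap; hitting it warns and flags non-convergence |
| `step` | 1.0 | damping; 1 zeroes a cell's residual before clipping |

Design points that were genuinely open:

* **Sweep order.** The underlying algorithm family allows arbitrary or
  random cell order. A fixed canonical order was chosen so fits are
  deterministic and the recorded update list is replayable bit-for-bit.
* **Update form.** Additive on the probability scale (matching the
  residual's own scale), with clipping. A logit-space variant was
  considered and rejected for v1: the additive form makes the one-update
  repair exact and hand-checkable.
* **Replay semantics.** `apply_postprocessor()` replays updates in
  recorded order, recomputing bins against the evolving scores. A record
  moved out of a bin by an earlier update is *not* touched by a later
  update aimed at the old bin. This is the contract that makes replay on
  the fit data reproduce the fitted scores exactly, and it is what the
  test suite asserts.
* **Fit data.** Updates are learned on the training split and replayed on
  test. Learning them on a separate calibration holdout is supported by
  passing that split's scores instead; the train-fit default mirrors the
  usual postprocessing workflow.
* **ECE aggregation.** Reported expected calibration error is the
  count-weighted mean over nonempty bins of the absolute outcome/score gap
  — the standard definition; per-group rows are computed on member records
  only.

### Fairness-oriented multiobjective training

`fomo_optimize()` searches over per-group sample-weight multipliers
$w \in [0.1, 10]^{|C|}$ for the base learner. Each genome is expanded to
per-record weights (records in several groups multiply their groups'
entries; records in none keep weight 1), the learner is fitted on an
internal 75% of the training data, and two objectives are measured on the
held-out 25% (stratified by outcome): $1 - {}$balanced accuracy overall,
and the maximum FNR over intersectional subgroups (groups with no
positives are excluded — an undefined rate is data absence, not evidence).
The search is a standard elitist multiobjective evolutionary loop:
nondominated sorting with crowding-distance diversity, binary-tournament
selection, simulated binary crossover ($\eta_c = 15$), polynomial mutation
($\eta_m = 20$, rate $1/d$), population 50 × 50 generations by default.
The all-ones genome is always injected into the initial population, so the
unweighted baseline is a candidate the search can never lose from its
nondominated set.

**Solution selection.** The selection rule is not a settled convention, so
three deterministic policies ship: `min_fairness` (smallest worst-case
FNR), `knee` (closest to the ideal point after min–max normalization), and
the default `guarded`: smallest worst-case FNR among solutions whose
*validation AUROC* is within 0.01 of the all-ones baseline's. The guarded
rule was made the default because desk-scale experiments showed that both
other policies can hand back solutions that trade several AUROC points for
their FNR gain at some seeds; guarding on AUROC encodes, as the selection
criterion itself, the requirement that debiasing must not degrade overall
discrimination. Validation AUROC is recorded per solution as bookkeeping;
it is not an optimization objective, and the front's nondominance
invariant is defined on the two objectives only.

After selection, the winning weighting is refitted once on the full
training split before test evaluation.

## The synthetic cohort generator

The real cohorts this line of work studies are credentialed or private, so
the package ships a generator whose statistical structure makes every
downstream claim testable without any data download:

* **Protected attributes** drawn from an explicit joint distribution over
  intersectional cells. The adult preset pins the smallest cell at 0.1%
  prevalence and the largest at 31.4%, with ethnoracial marginals
  0.3/3.7/26.2/10.0/59.8% — the documented composition of a large adult
  ED cohort. The pediatric preset uses three attributes (race, ethnicity,
  gender) under an independence joint.
* **Features** limited to normal, lognormal, and ordinal families (age,
  vitals-like measurements, triage acuity 1–5, prior-visit counts): enough
  to give the learner honest signal without modeling real vitals.
* **Outcome** drawn from a logistic model whose linear predictor combines
  feature effects, per-level main-effect log-odds offsets, and per-cell
  *interaction* offsets. The logistic probability is stored as
  `true_risk`: a perfectly calibrated oracle that lets tests assert
  calibration properties against a planted truth.
* **Interaction offsets are the bias dial.** The `adult_ed_biased` preset
  adds log-odds offsets of roughly ±0.25 to ±1.2 at intersectional cells.
  The study's learners see protected attributes only as main-effect
  dummies, so they can absorb marginal structure but not these offsets:
  intersectional miscalibration exists by construction, marginal
  debiasing can repair only part of it, and the intersectional-versus-
  marginal gap is guaranteed to be present for the harness to detect.
* **Seeding.** One master seed; attributes, each feature, and outcomes
  draw from independent derived substreams with sequential uniform
  consumption, so the first $m$ rows are identical for any $n \ge m$ and
  adding a feature never reshuffles another column.
* Preset intercepts were frozen from a one-off Monte Carlo root-solve so
  overall admission rates sit near the documented 29.5% (adult) and 16.3%
  (pediatric).

What the generator deliberately does **not** emulate: repeated visits per
patient (rows are independent, so row-wise splits are exact here — with
real data one would split by patient), missing demographics, temporal
structure, and site-specific feature sets. Passing tests on this cohort
demonstrate that the algorithms do what they claim under a known
generative truth; they do not demonstrate effect sizes on any real
population.

## The experiment harness

One trial = one seeded 50/50 row split; hyperparameters tuned on the
training half by successive halving over the learner's grid (logistic:
penalty ∈ {l1, l2} × C ∈ {0.01, 0.1, 1, 10}; forest: 100 trees, depth 4)
with stratified 3-fold CV scored by balanced accuracy; the scenario's
intervention applied (calibration task: fit on train, replay on test; FNR
task: optimize, select, refit, score test); metrics computed on the test
half over the γ-filtered intersectional collection, which is built on the
full data *before* splitting so the group list is identical across trials.
Trial $t$ of every scenario shares split seed `base_seed + t` — the paired
design the signed-rank tests require. Degenerate single-class splits are
retried on a documented seed offset stream.

`wilcoxon_signed_rank()` drops zero differences, midranks ties, reports
$\min(W^+, W^-)$, and computes the exact null by convolution for up to 25
nonzero pairs (doubling midranks to lattice points), switching to a
tie-corrected, continuity-corrected normal approximation beyond.
`holm_bonferroni()` is the standard step-down adjustment; the correction
family defaults to all scenario pairs within one report, and is as wide or
narrow as the pair list the caller passes — the appropriate family scope
is a judgment the package does not make silently.

### Operating point

Metric functions default to a 0.5 classification threshold. The preset
*study* runs at 0.3, approximately the overall admission rate. At 0.5 the
desk-scale baseline operates so deep in the low-sensitivity regime that
entire subgroups have FNR = 1, the two FOMO objectives improve together
(no genuine trade-off for the front to map), and worst-case-FNR numbers
saturate; at the prevalence threshold the study sits in the regime of
meaningful FNRs where the fairness–accuracy trade-off is real. This is the
standard threshold choice for imbalanced risk models and is configurable
per scenario.

### Problem sizes

The shipped study conditions are 20 000-visit cohorts, 20 paired trials
for the calibration comparison, and a 50 × 50 optimizer budget for the
FNR task; the per-cell bias planted by the preset is large enough that the
base-versus-intersectional comparison has essentially full power at these
sizes. All of it is configurable upward.

## Known limitations

* Multicalibration with overlapping (marginal) groups can in principle
  cycle; the sweep cap turns this into a reported non-convergence rather
  than an error, and it has not been observed under the presets.
* The genome is one multiplier per group — the smallest search space that
  expresses group-targeted reweighting. Per-record weights or richer
  parameterizations are out of scope.
* Undefined subgroup FNRs (no positives) are excluded from means and
  maxima. An optional prior-smoothed FNR for tiny groups is a natural
  extension and is not implemented in v1.
* Proportional multicalibration (residuals relative to the outcome rate)
  is not implemented.
* `run_experiment()` executes trials serially; at the shipped sizes the
  full calibration study runs in a couple of minutes on one core.
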