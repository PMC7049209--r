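---
title: "Identifying the ruptured aneurysm: model, score and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the ruptured aneurysm: model, score and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miascore)
```

## The clinical problem

Roughly one in five patients with aneurysmal subarachnoid hemorrhage (SAH)
harbors more than one intracranial aneurysm, yet exactly one of them is the
bleeding source. When the hemorrhage pattern on CT does not point to a single
aneurysm, the neurovascular team must still decide which lesion to secure
first. `miascore` implements a per-aneurysm prediction score for this
setting: a linear combination of the three aneurysm-specific characteristics
that are readily available from angiographic imaging — maximum diameter,
vascular region, and shape — whose within-patient maximum designates the
predicted bleeding source.

## The model

Each aneurysm is one observation with a binary rupture outcome. The model is
a logistic regression

$$\operatorname{logit} P(\text{rupture}_{ij}) =
  \beta_0 + \underbrace{\beta_s\, \text{size}_{ij}
  + \beta_{\ell(ij)} + \beta_{irr}\,\mathbb{1}[\text{irregular}_{ij}]}_{\text{aneurysm-specific score}}
  + \mathbf{z}_i^\top\gamma + b_i,$$

where $i$ indexes patients, $j$ aneurysms, $\ell(ij)$ is one of five vascular
regions (anterior cerebral/anterior communicating as reference; posterior
communicating; posterior circulation; middle cerebral; internal carotid
without the PcomA segment), $\mathbf{z}_i$ collects patient-level covariates
(age, smoking, hypertension, aneurysms per patient, additional aneurysms in
the same region) and $b_i$ is a patient random intercept that absorbs
within-patient dependence.

The coefficients are not estimated by maximum likelihood but by
*component-wise gradient boosting* of the binomial deviance
(`boost_fit()`): the additive predictor starts at the empirical log-odds; at
every iteration the negative gradient $y - p$ is fitted by each candidate
base learner — one simple linear learner per centered covariate and one
ridge-penalized patient-intercept learner — and only the best-fitting
component (smallest residual sum of squares) is added, scaled by the step
length $\nu$. This performs variable selection and coefficient shrinkage in
one pass; the number of iterations $m_{stop}$ is the regularization
parameter and is tuned by patient-level inner cross-validation
(`select_mstop()`).

Because the patient-level terms and the random intercept are constant within
a patient, they cancel from within-patient comparisons; `extract_score()`
therefore re-expresses only the aneurysm-specific part, with the reference
region and regular shape pinned at zero, and `rank_patients()` predicts the
within-patient argmax of that score. The published coefficients are available
as `published_coefficients()`:

```{r}
published_coefficients()
```

## Tunable parameters

* `nu` (default 0.1) — boosting step length. Standard practice for
  component-wise boosting: small enough that selection is nearly greedy-path
  stable, large enough to converge within ~10^3 iterations.
* `max_iterations` (default 1000) — the search space for $m_{stop}$.
* `inner_cv_folds` (default 10) — inner patient-level folds tuning
  $m_{stop}$.
* `random_effect_df` (default 4) — effective degrees of freedom of the
  ridge-penalized patient-intercept learner. The penalty $\lambda$ is solved
  from $\sum_g n_g/(n_g+\lambda) = \mathrm{df}$. The source model cites a
  random-effects boosting formulation without stating its penalty; the df is
  our declared choice and is exposed in `boost_control()`.
* `threshold` (default 0.5) — cut-point of the deterministic
  single-logistic-regression shape imputation (`impute_shape()`); the
  boundary case is assigned *irregular*. The rupture outcome is included
  among the imputation covariates ("conditional on all other variables" —
  the outcome is a variable of the analysis table).
* `bin_size` (default 50) — calibration interval size; the remainder of the
  ordered observations is appended to the last interval
  (`calibration_table()`).

## Centering

Covariates are centered on the training sample inside `boost_fit()`; the
centering constants travel with the fit, and held-out data are centered with
the *training* constants. Centering only shifts the intercept, so the
extracted score coefficients are on the raw covariate scale either way.
Whether the original analysis centered its covariates is not stated;
coefficient *paths* (and thus fits at finite $m_{stop}$) depend on that
choice even though the converged solution does not. This is documented, not
resolved.

## Numerical choices

* **Rounding.** Printed score values carry 4 decimals; comparisons use
  rounding half away from zero (`round_half_up()`). Internal arithmetic is
  never rounded. Every self-consistent printed value we checked is
  consistent with this convention; exact half-way cases are unverifiable
  from 4-decimal output.
* **Ties.** The argmax set is computed by exact equality on unrounded
  scores. Two identical aneurysms (the prospective cohort's patient 21 —
  two 5 mm regular MCA aneurysms) tie exactly. Three accounting policies are
  offered: `report`/`non_strict` counts a patient correct when the ruptured
  aneurysm lies in the argmax set (the only reading under which the
  prospective cohort can be scored fully correct); `fractional` credits
  $|\text{argmax} \cap \text{ruptured}|/|\text{argmax}|$, the expected
  correctness of a uniform random pick among the tied maxima; `first` and
  `error` are strict alternatives. The fractional policy matters for null
  calibration: a model with no aneurysm-specific signal may legitimately
  select only patient-level covariates, tying *all* of a patient's scores —
  non-strict counting then credits every patient, whereas fractional
  counting recovers exactly the $1/k$ random-guessing baseline.
* **Degenerate inputs.** An all-0 or all-1 outcome aborts; a constant
  covariate silently receives zero slope and can never be selected;
  separation needs no special handling because early stopping is itself the
  regularizer.
* **Deviance guard.** Log-likelihood terms clamp probabilities at
  $10^{-12}$ to keep held-out deviance finite under extreme predictions.

## The synthetic cohort generator

The derivation cohort (252 patients, 619 aneurysms) is not publicly
deposited, so `sample_cohort()` generates cohorts with its published
structure: aneurysm-count frequencies 2:174, 3:49, 4:22, 5:6, 6:1; location
frequencies ACOM/AA 119, PcomA 85, posterior 72, MCA 234, ICA 109;
irregular-shape prevalence 107/619; hypertension 0.44; smoking 0.35; age
normal(53, 12.8) truncated at 18. Size is log-normal with median 6 mm and
`sdlog = 0.622` (solved so the SD is about 5 mm, matching the reported
"6 ± 5" while keeping sizes positive and right-skewed), truncated to
(0, 40] — the range of the published score heatmap. The reported
aneurysm-count percentages are inconsistent with their own counts; the
generator uses the counts.

Rupture is assigned by a one-per-patient conditional logit:
$P(\text{aneurysm } j \text{ ruptures}) \propto
\exp(s \cdot \text{score}_j + \varepsilon_j)$ with `signal_scale` $s$ and
optional noise $\varepsilon_j$. This enforces the single-bleeding-source
invariant by construction, and patient-level terms cancel exactly as in the
model. `signal_scale = 0` is the random-guessing null; large `signal_scale`
concentrates rupture on the score argmax.

What the generator does **not** emulate: within-patient correlation of
sizes and locations (real mirror aneurysms are common), measurement error in
size, reader variability in shape, hemorrhage-pattern information, and any
covariate effects absent from the generating score. Passing recovery and
calibration tests therefore demonstrates the *pipeline's* correctness under
the stated structure, not clinical performance on real cohorts.

## Evaluation design

`cross_validate()` performs patient-level ten-fold cross-validation:
patients (never single aneurysms) are split into folds whose sizes differ by
at most one; each learning sample tunes $m_{stop}$ by its own inner
ten-fold loop, so no held-out patient influences fitting or tuning. Held-out
patients are ranked by the extracted score; accuracy is reported overall and
stratified by aneurysm count against the exact $1/k$ baseline. AUC is the
rank-based Mann–Whitney statistic (ties one half), reported as the
fold-average (the published summary) and additionally pooled; random
intercepts are excluded from predicted probabilities so held-out and
training aneurysms are scored on the same terms. A complete-data fit
supplies the complete-data AUC and the calibration table.

The original derivation data being unavailable, the published derivation
metrics (test AUC 80.89%, accuracy 68.58%) are not reproduction targets;
the machinery is instead validated by property-based experiments at chosen
problem sizes: oracle equivalence against `glm` IRLS on 200 aneurysms
(coefficient agreement $10^{-3}$ with a joint learner, 5% on the selected
slope component-wise), sign/ordering recovery on 2000-patient cohorts,
null-accuracy calibration on 300-patient cohorts, and binned calibration on
5000 self-consistent probabilities using 500-observation bins (with 50 per
bin the per-bin binomial noise, SD ≈ 0.07, would swamp a 0.05 discrepancy
band; 500 per bin puts it near 0.02).

One caveat from the recovery experiments: the PcomA offset of the published
score (−0.0104) is an order of magnitude smaller than its sampling error
even at 2000-patient cohorts (the maximum-likelihood standard error of that
offset is ≈ 0.11 at ~4900 aneurysms), so its *sign* — and the ordering of
the two top regions — is not recoverable at realistic cohort sizes. The
corresponding acceptance expectations fail honestly and are documented as
such; all separations larger than their sampling error are recovered.

## The packaged prospective cohort

`table2_cohort()` ships the full published 34-patient prospective validation
cohort (83 aneurysms) with the printed per-aneurysm scores as an auxiliary
reference column. Recomputing all 83 scores (`reproduce_table2()`)
reproduces 80 exactly at 4 decimals; the remaining three printed values
contradict the published formula itself (the same size/region/shape pattern
appears elsewhere in the table with the recomputed value, and two of the
three print *different* scores for the *same* pattern), so they are treated
as printing errata:

```{r}
rep <- reproduce_table2()
rep$mismatches[, c("patient_id", "site", "size_mm", "shape",
                   "published_score", "recomputed")]
```

Ranking the cohort finds the surgically or expert-confirmed bleeding source
at the within-patient maximum for 33 of 34 patients:

```{r}
rep$n_correct
subset(rep$ranking, correct == 0)
```

The single discordant patient is the published cohort's own contradiction:
its narrative reports the surgically confirmed source (a 10 mm MCA
aneurysm, score 0.0215) while the co-existing basilar-tip aneurysm scores
higher (0.6118). The fixture encodes the surgical finding as ground truth
and the discrepancy is reported rather than reconciled.

## Limitations

* Single-center derivation and validation; no external cohort is packaged,
  and the synthetic generator cannot substitute for one.
* The score is a decision support, not a decision rule: it encodes only
  size, region and shape, and deliberately ignores hemorrhage-pattern
  information (it is designed for exactly the cases where that information
  is uninformative).
* The boosting formulation pins the random-effect learner's flexibility by
  a fixed effective degrees of freedom rather than estimating a variance
  component; fits with very few patients per fold inherit that choice.
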