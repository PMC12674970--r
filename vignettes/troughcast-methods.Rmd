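---
title: "Methods: trough forecasting, feature engineering, and dose search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trough forecasting, feature engineering, and dose search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the pharmacokinetic
model behind the synthetic cohort, the prediction task and its feature
representation, the sequence regressor and how it is trained, the evaluation
statistics, and the dose-recommendation search — together with the design
decisions that were genuinely open and how they were resolved.

## The prediction task

One observation unit is an eligible ICU *patient-day*: the model sees
clinical data up to the end of that day and predicts the steady-state
vancomycin trough concentration that will be measured about two days later,
given the doses planned in between. Forecasting two days ahead is what makes
the task clinically useful — it leaves time to change the regimen before the
next level is drawn — and what makes it hard: vancomycin clearance follows
kidney function, and serum creatinine reacts to a kidney insult with a lag of
one to three days, so part of the outcome depends on physiology that has not
yet surfaced in the observables.

## Synthetic cohort: what is emulated

Real trough-prediction cohorts are protected health data, so the package
ships a seeded simulator whose outputs exercise every downstream stage.

**Pharmacokinetics.** One compartment, first-order elimination, zero-order
intermittent infusions. For a dose $D$ infused over $T$ hours into volume
$V$ with elimination rate $k = \mathrm{CL}/V$:

$$
C(t) =
\begin{cases}
\dfrac{D}{TVk}\left(1-e^{-kt}\right) & 0 \le t \le T\\[6pt]
C(T)\, e^{-k (t-T)} & t > T,
\end{cases}
$$

and concentrations from successive doses superpose linearly
(`concentration_at()`). Troughs are this closed form evaluated 0–60 minutes
before a scheduled dose, plus Gaussian noise (`residual_sd`, default
1 mg/L — assay error plus the rounding of values documented in notes).
Clearance is linked to kidney function by
$\mathrm{CL} = \theta_0 + \theta_1\,\mathrm{CrCl}$ with CrCl from
Cockcroft–Gault, defaults $\theta_0 = 0.05$ L/h and $\theta_1 = 0.75$
(CrCl expressed in L/h), which give a normal-renal-function adult a
clearance near 4–5 L/h; the distribution volume is 0.7 L/kg. These are
standard adult values, configurable in `cohort_config()`, and they stand in
for the unpublished population model of any specific health system.

**Kidney function.** Each encounter has a baseline creatinine (log-normal,
median 0.63 mg/dL) and, with probability 0.4, one acute kidney injury
episode: a piecewise log-linear rise to a peak ratio drawn by KDIGO stage
(stage mix ≈ 67/27/6 % conditional on AKI), a plateau, and a slow
resolution. The *true* clearance used for each trough follows the mean CrCl
over the preceding 48 h of this trajectory.

**The prescriber.** Initial doses are chosen to hit the middle of the goal
range at steady state — but using kidney function estimated from the
*baseline* creatinine (plus a small log-normal idiosyncratic error,
sd 0.10). True clearance follows the *current* creatinine. The gap between
the two is the clinically documented creatinine-lag phenomenon and is the
main observable driver of off-target troughs in the simulator. After each
measured trough the dose is re-titrated proportionally toward the target,
and markedly supratherapeutic levels (more than 5 mg/L above the goal
ceiling) trigger a dose hold until the projected level decays into range —
without the hold the simulator produced multi-day accumulations no ICU
would allow. Goal ranges are 15–20 mg/L for severe-sepsis patients (and a
random 10 % of the rest), 10–15 mg/L otherwise, mirroring indication-driven
goal selection.

**What is *not* emulated.** Multi-compartment kinetics; clearance covariates
beyond age/sex/weight/creatinine; pharmacodynamics; drug removal by kidney
replacement therapy (KRT days exist only so the eligibility filter has work);
informative sampling (labs are missing at random, not
because-the-patient-is-sick); and free-text documentation. Tests passing on
this cohort therefore demonstrate that the machinery is correct and that the
model can extract genuinely present PK signal — not that the model would
reach any particular accuracy on real EHR data.

A deliberately mis-specified "pharmacist" predictor (clearance slope biased
to 0.9× truth, 1 mg/L noise) populates the benchmark column so the paired
*t*/McNemar machinery has non-trivial input; it is a stand-in, not a model
of Bayesian dosing software.

## Eligibility and data hygiene

Days are whole 24 h blocks from ICU admission (day 1 = hours [0, 24)); the
prediction time is the end of the day. A patient-day is eligible if the
patient is an adult with at least 24 h in the ICU, the day is within the
first 14 days, no continuous infusion that day, no KRT that day or in the
previous 7 days, at least one IV dose that day, and a trough drawn 36–60 h
after the prediction time. The 36–60 h window (nominal 48 h) avoids brittle
exact-hour joins; the earliest trough in the window is the target, and later
troughs seed their own patient-days. Train/test splitting is at the
*encounter* level so no patient contributes to both sides.

## Feature representation

Observations are binned hourly (median within the hour), carried forward up
to 24 h, then mean-imputed with training-set means; the observation mask is
retained, which makes imputation idempotent. Each instance becomes a
24 × F matrix — the prediction day's hourly values, a derived
Cockcroft–Gault CrCl channel, the vancomycin dose given in each hour, each
variable's 72 h OLS slope and mean, and broadcast statics — plus a 4-vector
of dose features (prediction-day dose, interval dose through the trough
draw, time since last dose, most recent prior trough) that skips straight to
the output layer.

Numerical choices: concentration-like quantities (creatinine, CrCl, WBC,
doses, prior trough) are `log1p`-transformed before z-scoring, because they
are right-skewed and enter the kinetics multiplicatively; z-scoring uses
training-set statistics only, with standard deviations floored at $10^{-6}$;
binary flags stay 0/1; a missing prior trough is mean-filled and flagged by
a broadcast indicator; slopes with fewer than two points of history are 0 by
convention.

## The regressor

The 24-step sequence feeds an LSTM with 16 hidden units returning all hidden
states; two-head self-attention (key dimension 64) mixes them across the
time axis; the attention outputs are mean-pooled over time; the pooled
vector is concatenated with the dose skip vector and a single linear unit
emits the prediction. Both the forward pass and backpropagation are written
in the package and checked against central finite differences (relative
error ~1e−7 in tests, asserted at 1e−4).

Open points resolved as follows:

- **All hidden states feed the attention layer** (not only the final one);
  the pooling step between attention and the dense unit is unstated
  upstream, so it is isolated behind one switch (`pooling = "mean"`,
  `"last"`, `"max"`). Empirically the three are nearly indistinguishable
  here because the attention output is almost constant across time steps;
  mean is the default.
- **Log-scale target.** Troughs are strictly positive and multiplicative in
  dose and clearance, so training regresses standardized log-troughs and
  exponentiates predictions (`log_target = TRUE`; the raw linear-scale path
  is kept behind the flag). The loss is mean squared error either way, and
  exponentiating the log-scale conditional mean yields the conditional
  median — the right point estimate for absolute-error metrics.
- **Regularization scope.** Weight decay is applied to *every* kernel
  matrix (biases exempt). Restricting it to the dense and recurrent kernels
  left the attention projections — three quarters of the parameters —
  unregularized, and the model memorized patients (train MAE 2.4 vs held-out
  4.0 at ~700 training instances). `l2_lambda = 0.1` is large by deep
  learning conventions but is what a seeded random search selected at this
  sample size.
- **Optimization.** Adam (minibatch 128), plateau-based learning-rate
  halving down to 2e−4, early stopping on a 15 % encounter-level validation
  slice with patience 30, best-validation weights restored; a stochastic
  weight average of the near-optimal epochs replaces them only if it
  validates better. Glorot-uniform initialisation, forget-gate bias 1.
  Everything is deterministic given `seed`. Hyperparameters (learning rate,
  decay, batch size) can be re-searched with `tune_model()`, a seeded random
  search standing in for more elaborate Bayesian optimisation.
- **Output clipping.** Under the raw-scale path, negative predictions are
  clipped to zero at reporting time with the raw value retained in an
  attribute.

Gradient×input relevance is computed by one backward pass per batch (samples
are independent, so a per-sample unit pullback yields all input gradients at
once); under log-target training the chain rule multiplies each sample's
gradient by its own prediction. A feature that is identically zero has
exactly zero relevance.

## Evaluation statistics

MAE, RMSE and MAPE use their standard definitions with MAPE on the 0–100
scale; observed troughs below 0.5 mg/L are excluded from MAPE (with a
warning) to avoid ratio blow-up. Therapeutic classification against each
instance's own goal range treats both bounds as inclusive — the clinical
reading of "10–15". Bland–Altman reports the mean difference, its sample SD,
and mean ± 1.96 SD limits. The paired comparison runs a paired *t*-test on
absolute errors (undefined, and reported as such, when the differences are
constant) and McNemar's test on the 2×2 correct/incorrect table — the
continuity-corrected statistic $(|b-c|-1)^2/(b+c)$ is always reported, with
the p-value taken from the exact binomial form when fewer than 25 discordant
pairs exist.

## Dose recommendation

The line search enumerates every candidate change to the interval dose in
250 mg steps up to ±1500 mg, clipped so the dose never goes negative,
re-predicts the trough for each candidate by updating the interval-dose skip
feature (optionally also scaling the prediction-day dose), and keeps the
candidate with the highest reward. The default reward is 0 inside the goal
range and minus the distance (mg/L) to the nearest bound outside; it is
injectable. Ties are broken by predicted trough closest to the range
midpoint, then by smallest absolute dose change — which makes the exhaustive
search order-independent and exactly reproducible by brute-force
enumeration (a property the tests assert against randomized stub
predictors). The distance–reward curve bins (actual − recommended) dose to
the nearest 250 mg and reports each bin's mean reward (computed on the
*measured* trough against its own range; a flag switches to predicted
troughs), standard error, and count.

## Problem sizes and runtime

The test suite builds all fixtures in code: unit tests use toy encounters
and cohorts of 25–60 encounters; the end-to-end statistical checks use one
500-encounter cohort (~850 patient-days) with three training seeds, which
keeps a full run of the suite in the minutes range on one CPU. The same
500-encounter study backs `scripts/acceptance.R`.

## Known limitations

- The network's advantage over a mean-only baseline on the synthetic cohort
  is real but modest (roughly 10–25 % MAE reduction depending on the cohort
  draw). Two causes, in order of importance. First, a large share of trough
  variance under these study conditions is *irreducible from prediction-day
  data*: AKI that evolves during the two-day interval, the prescriber's
  idiosyncratic error, and assay noise are all invisible to any feature the
  model is allowed to see. Second, bounded recurrent units extrapolate
  poorly into the supratherapeutic tail, where absolute errors are largest —
  a sparse log-linear probe on the same inputs does somewhat better there,
  and the residual gap between the two is the honest cost of the sequence
  architecture at this sample size (~700 training instances; the gap narrows
  with more encounters). High error on supratherapeutic levels is also the
  regime reported as hardest in the clinical literature on this task.
- The dose search moves ±1500 mg around interval doses that typically total
  several grams over two days, so its leverage on the predicted trough is a
  few mg/L; with an accurate model the recommendation saturates at the grid
  edge for clearly off-target patients. The search honors the grid bounds
  rather than extrapolating beyond what was explored.
- The simulator's missingness is non-informative and its vitals carry almost
  no PK signal by construction, so feature-importance rankings beyond the
  dose/kidney block mostly reflect noise suppression, not physiology.
- `classify_aki_stage` implements only the creatinine-ratio arm of the KDIGO
  criteria (no urine-output or absolute-rise arms).
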