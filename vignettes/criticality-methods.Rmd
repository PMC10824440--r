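---
title: "Dynamic criticality modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic criticality modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidyn)
```

## The problem

Hospitalized children rarely die, so pediatric severity modeling uses a more
common surrogate outcome: whether the child will be receiving ICU-level or
routine-ward care in a specified future window. `cidyn` implements a
multi-horizon version of this idea. Each hospital course is discretized into
consecutive 6-hour periods; for every period with at least one new data
element, four independent classifiers predict the care location in the
windows >6–12, >12–18, >18–24 and >24–30 hours ahead. Raw classifier
outputs are recalibrated to probabilities (the dynamic criticality index),
audited for calibration, and examined at clinically motivated operating
points (fixed sensitivities 0.85–0.99 for detecting impending ICU need,
fixed specificities for ICU discharge readiness).

The package's headline experiment mirrors the external-validation question:
a model set trained at a *reference* site is transported to a *local* site
whose clinical practice differs (which therapies its ICU uses, how readily
it admits neurologically impaired children), and is compared against a model
set redeveloped locally with identical variables and methodology. Because no
public pediatric EHR extract exists for this problem, the package ships a
synthetic-cohort generator whose population structure matches the published
study sample; all pipeline claims are therefore claims about recovery of
known structure from synthetic data, not about real hospitals.

## The synthetic cohort generator

### Latent severity and care-location trajectories

Each admission carries a latent severity score $s_t \in (0,1)$ sampled
hourly from a discrete-time mean-reverting process

$$ s_{t+1} = s_t + \theta\,(\mu - s_t) + \sigma\,\varepsilon_t, $$

with reversion rate $\theta = 0.12\,\mathrm{h}^{-1}$ in stable phases,
innovation scale $\sigma = 0.03$, and phase-dependent asymptote $\mu$
(routine 0.30, ICU 0.80). Transfers are *emergent threshold crossings with
hysteresis*: a routine patient moves to the ICU when the simulated trace
crosses 0.65; an ICU patient moves out when it crosses 0.50. The gap
between the two thresholds prevents rapid oscillation.

Hitting four published population targets at once — 19.2 % direct-to-ICU
admissions, 3.0 % routine-to-ICU transfers, 78.1 % of ICU admissions later
transferred out, and 20.8 % of periods in the ICU — is impossible with
free-running crossings, so the generator plans each transfer time (a Beta
fraction of the stay) and calibrates the *drift rate* of a short ramp phase
so the expected crossing lands on the planned time: a hold-then-ramp
design. The transfer event is still the actual first crossing of the noisy
trace (setting the volatility to zero and keeping asymptotes away from the
thresholds yields exactly zero transfers), and the ramp aims slightly past
the threshold so discharge censoring of planned transfers is negligible.
Planned transfer times keep a 9-hour margin before discharge.

Lengths of stay are log-normal per admission path (routine-only median 2.4
days, ICU-ever median 4.2 days), chosen so the mixture median is ~2.7 days
and, combined with Beta transfer fractions with mean ≈ 0.61 (ICU share of a
transferred-out stay), the ICU share of 6-hour periods lands at ≈ 0.208.
Ages are log-normal (median 68 months, IQR ≈ 15–157, capped at 21 years);
sex and race are categorical draws used only descriptively.

### Observables

Thirty laboratory analytes, six vital signs and an integer coma score
(3–15) are sampled in location-dependent *rounds* (vitals roughly 4-hourly
on the ward and hourly in the ICU; labs roughly daily on the ward and
6-hourly in the ICU, with each analyte included in a draw with probability
0.7). This sparse non-ICU sampling is the reason 6-hour windows are the
discretization unit, and it makes the new-data gate meaningful: a few
percent of routine windows contain no data at all. Observed values are
linear in the current latent severity plus Gaussian noise, clipped to
configured plausibility ranges. The noise scale (0.8–0.9 of the reference
span) was chosen so that single-site discrimination lands in a realistic
0.95-ish AUROC range rather than saturating at 1.

Medication administrations follow per-class Poisson start rates with
log-normal durations; roughly a third of the 143 synthetic classes are
ICU-leaning (infusion-like: frequent starts, ~10-hour runs), a third
ward-leaning, a third neutral. Class usage depends only on current location
and severity, so medication exposure is an honest practice signature.

A fraction (12 %) of patients carries a persistent downward coma-score
offset independent of systemic severity — chronically neurologically
impaired children. Their care location is decided by *practice*: a site
admits to the ICU any child whose admission coma score falls below the
ward's tolerated floor (`coma_icu_threshold`). Such practice-forced ICU
stays keep routine-like physiology and are time-limited rather than
severity-threshold-limited. This is the central device that makes the
transported-model experiment meaningful: where the floor is low, these
children are ward patients; where it is high, the same physiology is an
ICU outcome.

### What the generator does not emulate

Individual analyte time series have no organ-system structure, diagnoses
are absent, medication classes have no real vocabulary mapping, and
observation timing has no circadian or workflow pattern. Passing tests
therefore demonstrate that the pipeline recovers known structure under the
stated noise model — not clinical performance on real EHR data.

## Episode processing

Windows are half-open $[6k, 6k+6)$ hours from admission; the final partial
window is kept and labeled by its segment (configurable off). A window
containing a location change in its interior is labeled `transition` and
excluded from training and evaluation — the strictest reading of
transition exclusion; a change exactly on a window boundary is clean.
Horizon $j$ of origin window $k$ targets window $k+1+j$ (offsets
$(6j, 6j+6]$ hours from the end of the origin window); outcomes are
undefined past discharge or on transition targets and such rows are
dropped.

Features per window: min/max/mean for each lab, vital and the coma score;
exposure fraction-of-time and administration count per medication class;
the same summaries for up to four preceding windows (per-slot lookback was
chosen over pooled 24-hour summaries as the richer reading). A "new data
element" is any raw lab, vital, coma or medication start/stop event — the
broadest event-based reading. Imputation is last-observation-carried-forward
within the encounter (past-only, so a leakage test can perturb future
events and observe unchanged features), then age-band normal-reference
midpoints for variables never observed; the defaults live in the variable
panels and the strategy is a replaceable object. Medication features are
structural zeros, never imputed. Patients are split 75/13/12 by
largest-remainder rounding under a seed.

## Horizon models and the growth protocol

Each horizon model is a fully connected feed-forward network (ReLU hidden
layers, logistic output) trained to minimize binary cross-entropy with
Glorot-uniform initialization and RMSprop (full-scale initial learning rate
2e-4, minibatches of 10,000 rows). Training starts with one hidden layer
and grows the width along a geometric schedule while monitoring MCC,
sensitivity, specificity, precision and NPV at cut points 0.15/0.5/0.9 on
the training and validation partitions. A fit whose training-minus-
validation MCC at 0.5 exceeds the drift tolerance counts as overfit and is
retried with progressively stronger L1/L2/dropout; when width stops
helping, a layer is added (up to five); growth stops when regularization no
longer rescues overfitting; the best non-overfit validation-MCC model is
kept. MCC of a degenerate confusion matrix is defined as 0. Scores equal
to a cut point classify as routine (strict inequality).

Two departures from the full-scale protocol matter at desk scale and are
deliberate. First, the desk protocol (`ci_protocol_desk()`) shrinks the
schedule (widths 8/16, depth ≤ 2, ~10–15 epochs), shrinks minibatches to
`n/10`, and raises the learning rate to 3e-3 so RMSprop converges within
the small step budget. Second, its drift tolerance is 0.12 rather than the
full-scale 0.02: with a few thousand training rows a generalization gap of
that order is irreducible, and the validation MCC itself has sampling noise
of a few hundredths. If no candidate meets the tolerance at all, the
least-drift candidate is kept with a warning and an `overfit_fallback`
flag rather than failing the pipeline.

## Calibration

Raw scores are mapped to risk by logistic regression on a cubic B-spline
basis with five interior knots at empirical quantiles of the validation
scores, boundary-clamped so the map is defined on all of (0,1); the map is
fitted on the validation partition only and is not constrained to be
monotone. The audit sorts records by calibrated risk and forms equal-count
intervals of exactly 200 records (the last absorbs the remainder) —
equal-count was chosen because published interval counts imply near-equal
occupancy. Per interval it compares observed outcome rate with expected
(mean) risk via an exact binomial test (no multiplicity correction,
matching raw per-interval significance reporting) and Cohen's
$h = |2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}|$; the summary regresses
expected on observed (ideal: slope 1, intercept 0, $R^2$ 1, ≥95 % of
intervals with $h < 0.2$).

With outcomes drawn Bernoulli(risk), the audit's regression slope is
attenuated below 1 by binomial noise in the observed proportions
(regression dilution); at 200-record intervals and uniformly spread risks
the attenuation is below 0.02, well inside the acceptance band — a reason
the interval size floor matters.

## Evaluation suite

AUROC is the rank-sum concordance probability with a DeLong large-sample
interval; AUPRC is trapezoidal integration of the precision-recall curve
with a logit-scale normal interval. Operating points report sensitivity,
specificity, precision, NPV, accuracy, F1 (harmonic mean of precision and
sensitivity), MCC and NNE = 1/precision, with Wilson intervals for the
proportion metrics; the algebraic identities among them hold exactly by
construction and are regression-tested to 1e-12. Fixed-sensitivity
(-specificity) searches return the largest (smallest) threshold reaching
the target, which maximizes the complementary rate; ties from discrete
scores mean the reported rate can exceed the target.

Transfer-cohort accuracy evaluates only patients who actually moved: for a
transfer at time $T$ with first fully-post-transfer window $w$, horizon $j$
predicts from origin window $w-(1+j)$, and the patient enters horizon $j$'s
denominator only if that window lies entirely inside the pre-transfer
residence and carries new data — so 12 hours of residence admit only the
>6–12 h model and ≥30 hours admit all four. Thresholds are fixed globally
on the full test partition (fixed sensitivity for routine-to-ICU, fixed
specificity for ICU-to-routine), never refit per cohort.

## Local importance

Local explanations perturb a record (Gaussian jitter scaled by training
standard deviations; Bernoulli flips for binary features), score the
perturbations with the model, weight by an exponential kernel on
standardized distance (width $0.75\sqrt{d}$), and fit a weighted ridge
surrogate; covariates are ranked by absolute surrogate weight with ties
broken by name. The protocol constants for the frequency comparison are a
calibrated-risk band of 0.245–0.255 and top-30 membership; profiles from
two model sets are compared per covariate by frequency difference, Wilson
intervals, Cohen's h, and a practical-difference flag requiring both
non-overlapping intervals and $h > 0.2$. Kernel width, perturbation count
(default 1000; 250–500 in pipeline runs) and ridge strength are declared
defaults, not inferred values. The ridge solve uses the dual form when
perturbations are fewer than features.

Two desk-scale accommodations apply in the pipeline. Frequencies are
counted at the covariate level (lookback slots of one variable-summary
pooled via `groups`), because top-30 membership over ~2,000 raw columns is
dominated by ranking noise; the published protocol ranks covariates at
variable granularity. And when the narrow risk band contains no test
records — the desk-scale risk distribution is sharply bimodal — the band
is widened symmetrically until both model sets have enough cases, with
the band actually used recorded in the output. A caveat follows from the
same noise analysis: two independently trained networks on
same-distribution cohorts already disagree substantially about mid-tier
covariates, so the top-30 *non-overlap between sites* is a descriptive
statistic at this scale, not a test statistic; the practical-difference
flagging mechanism itself is validated on constructed scorers with a known
injected usage shift.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full two-site pipeline
at 800 admissions per site with the desk protocol (~20,000 6-hour periods
per site, ~2,000 feature columns), the generator-fidelity checks at 20,000
admissions without observation streams, and the calibration-audit recovery
at 100,000 records — sizes chosen so the whole suite completes on one CPU
in minutes while leaving the directional contrasts (local vs transported
AUROC, horizon decay) many standard errors wide. Every stochastic step
takes an explicit integer seed; stage seeds are derived from one master
seed, and identical configuration plus seed reproduces cohorts
byte-identically and training to numerical tolerance.

## Known limitations

The transported-vs-local AUROC gap is a scaled-down directional analog: at
desk scale the absolute transported AUROC stays well above the published
multi-institutional range because the synthetic feature space is far
smaller than a real EHR's and the severity signal is shared across sites by
construction. Fixed-specificity transfer accuracy for the shortest horizon
is pessimistic when the local model is nearly separable (the 95 %
specificity threshold collapses toward zero risk). The imputation defaults
are reference-range midpoints, not values fitted to any real population.
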