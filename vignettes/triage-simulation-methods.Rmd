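---
title: "Methods: multimodal SSI risk modelling and triage pathway simulation"
author: "ssitriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal SSI risk modelling and triage pathway simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Remote postoperative wound monitoring asks patients to submit structured
symptom questionnaires (PROMs) and wound photographs during the first 30
days after surgery. Each submission is triaged by a clinician as low,
moderate or high risk of surgical-site infection (SSI), and the prediction
target of interest is whether an SSI is confirmed in person within 48 hours
of the submission. Reviewing every response is the bottleneck: at roughly
two minutes per response, a monitoring service's triage workload grows
linearly with adoption. The question this package addresses is *how much of
that workload an automated risk model can absorb, and at what cost in missed
infections*.

`ssitriage` implements the full chain as reusable, tested components: a
synthetic cohort generator that reproduces the statistical structure of such
monitoring data; the tabular, image and fused risk models; grouped
stratified evaluation; and the implementation-strategy simulator that
converts model probabilities into routing decisions, diagnostic accuracy,
failure rates, staff-hours and full-time-equivalent (FTE) workload, with a
threshold sensitivity analysis. The repository is organised as an analysis
workflow: the numbered scripts under `analysis/` narrate the pipeline
(simulate, train, simulate pathways, sweep thresholds); every computation
they perform lives in the package and is exercised by the test suite.

# The synthetic cohort generator

Real patient-generated wound data are access-restricted, so the generator
is a first-class module: it defines the study conditions under which every
downstream claim is tested.

**Responses.** Each of `n_patients` patients is an intervention non-user
with probability 0.25; active patients submit a zero-truncated Poisson
number of responses (mean 5) on postoperative days 1–30. Each response
carries a confirmed-SSI-within-48-h indicator drawn at rate `p_ssi48`
(default 0.037 per response, the observed event rate in the motivating
studies' pooled responses).

**Symptoms.** Eight binary PROM items are used: pain, erythema, oedema,
warmth, discharge/pus, fever, wound opening, general unwellness. The
8-item set matches the 8-wide model input; the exact study questionnaire
wording is not public, so items are named for the cardinal signs of
infection. Non-SSI responses follow an explicit none / isolated /
multiple-symptom mixture whose weights are solved in closed form so the
*marginal* symptom-free and isolated-symptom fractions equal their targets
(0.719 and 0.168) exactly in expectation. SSI responses draw all eight items
independently at effect-shifted rates
`plogis(qlogis(base) + effect)`; the default effects make erythema and
discharge the strongest markers (log-odds +2.2 and +2.6) and oedema the
weakest (+0.3), mirroring which symptoms are typically independently
associated with confirmed SSI. Symptom-free SSI responses remain possible
(probability ≈ 0.9%), as observed in practice. Present symptoms carry a
trend sub-answer (new/worse/same/better) which is generated but collapsed to
presence/absence for modelling by default, since it is not established that
trends entered the original 8-feature array.

**Triage labels.** Clinician triage is modelled as a latent severity
score, `eta = s*(2*ssi + 0.8*n_symptoms) + logistic noise`, cut at two
thresholds. The calibration solves three one-dimensional root problems
against exact expectations over the discrete (SSI, symptom-count)
distribution: the informativeness scale `s` and lower threshold jointly
match P(SSI | low triage) = 0.014 *and* the marginal suspected-SSI fraction
(default 0.150); the upper threshold then matches
P(SSI | high triage) = 0.240. The moderate-risk conditional rate is left to
emerge (≈ 0.11 in expectation) rather than being forced to a geometric
interpolation (≈ 0.058): with the latent-threshold mechanism and three
calibrated targets there is no remaining freedom, and overriding it would
break the threshold model's coherence. Only the two printed extremes are
treated as calibration truth.

**Images.** Each response carries 0–3 images (default probabilities
0.45/0.30/0.15/0.10). An image is a parametric rendering at 256×256×3: a
uniform skin tone drawn per patient from a wide configurable range, a dark
curvilinear incision (random position, orientation, curvature), an
erythema halo whose intensity is Beta-distributed with SSI-dependent shapes
(mean 0.27 for non-SSI, 0.73 for SSI wounds), and 0–3 purulent spots with
SSI-dependent counts. The wound mask (incision plus periwound band) covers
1–40% of pixels by construction. Pixels are rendered lazily from stored
truth parameters with a per-image derived seed, so cohorts stay small in
memory and rendering is order-independent and exactly reproducible. Images
without a visible wound are never generated, matching the manual curation
step applied to real data before modelling.

**What the generator does not emulate.** Within-patient correlation of the
outcome beyond shared skin tone and the grouped split (each response's SSI
indicator is independent); temporal evolution of symptoms across a
patient's submissions; photographic nuisance (lighting, blur, occlusion,
background clutter); and any real anatomy. Tests passing under these
conditions demonstrate that the pipeline's statistics and mechanics are
correct, not that the models would attain any particular accuracy on real
wounds.

# Tabular models

PROMs are one-hot encoded; because every item is binary, one indicator
column per item is kept, preserving the 8-wide input. Missing answers are
imputed as "symptom absent" *before* encoding, the assumption a clinician
would make for a partially completed questionnaire. Columns are centred and
scaled with statistics learned on the training partition only; the stored
encoder is reused verbatim for any new data.

The MLP is a sequential 8→16→8→1 network (rectified hidden layers, sigmoid
output) trained with Adam (learning rate 1e-3) for up to 200 epochs with
early stopping on the training loss (patience 10) and best-weight restore.
Class weights default to inverse prevalence, which keeps training stable at
a 3.7% event rate; the architecture beyond the input width is a desk-scale
choice recorded in the model's training metadata. Because training-loss
early stopping under heavy class weighting otherwise memorises rare
symptom patterns, the dense engine applies L2 weight decay (default 0.03,
on weights only); this keeps held-out discrimination in line with the
logistic comparator across cohort seeds and keeps the MLP's output
probabilities moderate enough for downstream stacking. The comparator is a
multivariable logistic regression on the same inputs, fitted by
`stats::glm` with tightened convergence (deviance epsilon 1e-12) so it
agrees with an independent IRLS implementation to 1e-6; the tests enforce
that agreement.

No deep-learning framework is assumed anywhere: the dense and convolutional
engines are implemented in the package on base-R matrix algebra, with
finite-difference gradient checks in the test suite.

# Image model

Input images are standardised to 256×256×3 by bilinear-resizing the short
side and centre-cropping the long side (the resize dialect is a documented
choice; only the target size is fixed by convention). Training-batch
augmentation is restricted to label-preserving rigid/similarity transforms
— flips, integer translations, rotation, isotropic scaling — never shear or
elastic warps, which would deform wound shape. Evaluation is always
augmentation-free.

The desk-scale backbone is a small CNN: a 4× average-pooling stem (working
resolution 64×64), four 3×3 same-padded convolution blocks of 8/16/16/32
filters with 2×2 max-pooling after the first three, global average pooling
and one sigmoid unit. It trains from scratch with RMSprop in batches of 10
for up to 30 epochs; the training binary cross-entropy is evaluated every
10 optimisation steps with a patience of 10 evaluations and best-weight
restore. Early stopping monitors the full training loss (not the last
batch's), because batch-level loss under inverse-prevalence weighting is
too noisy to detect sustained improvement. A VGG-style pretrained backbone
unfrozen at its third pooling stage is the natural full-scale alternative;
since no trained weights ship with the package it is exposed only as an
explicit `backbone_weights` option and is not used by any test.

**Class-activation heatmaps** use gradient weighting at the last
convolutional stage. With a global-average-pool + linear head the spatial
mean of the score gradient for map *k* is exactly `w_k / (map area)`, so the
heatmap is the rectified weighted sum of the last feature maps, upsampled
bilinearly to the input and max-normalised. If rectification leaves no
positive evidence anywhere the map is returned as uniform — "nothing to
localise" — which also gives untrained baselines a well-defined
localisation score (the wound-mask area fraction, in expectation). The
localisation statistic is the fraction of heatmap mass inside the dilated
wound mask; tests require a trained model to beat an untrained one of the
same architecture on held-out synthetic wounds.

# Late fusion

Each response's PROMs probability is fused with each of its image
probabilities; the response-level risk is the maximum over images, and
responses without images keep the PROMs prediction unchanged (exact
equality, enforced by test). The default head is a 2-input logistic stacker
on the unimodal probabilities — reproducible across frameworks and
monotone whenever both learned weights are positive; a parameter-free
average and a small neural head are alternatives. Following standard
stacked generalisation, the pipeline fits the stacker on *cross-fitted*
PROMs probabilities (5 patient-grouped folds, `crossfit_proms()`): fitting
it on in-sample MLP outputs, which are over-confident, quasi-separates the
stacking regression and degrades the fused ranking. The max rule is applied
*after* per-image fusion (max of fused risks, not fusion of the max image
score): "highest predicted risk" is read as the per-response risk. Both
orderings coincide for monotone heads, which all defaults are.

# Evaluation

Responses are split 4:1 with all of a patient's responses in one partition
(zero leakage) and allocation stratified by patient-level outcome: within
each stratum patients are shuffled and assigned to the test side until its
response count best matches 20%. AUC uses the midrank concordance
definition (ties count half) with a DeLong placement-value interval; the
point estimate is checked against brute-force pairwise enumeration to
1e-12 and against an established ROC implementation. Discrimination bands
follow the usual convention — 0.5–0.59 poor, 0.6–0.69 moderate, 0.7–0.79
good, ≥0.8 excellent — lower-inclusive, with values below 0.5 labelled
below-chance.

# Pathway simulation

Three implementation strategies are simulated over a labelled, predicted
cohort:

* **Full clinical assessment** — every response is clinician-reviewed; the
  recorded triage label decides (moderate/high → in-person review).
* **Hybrid rule-out** — responses with fused risk ≤ threshold are cleared
  automatically and never seen by a clinician; survivors are
  clinician-reviewed and decided by their triage label. A clinician can
  therefore still downgrade a model-flagged response to low risk.
* **Full automation** — the threshold decides alone; zero clinician
  reviews.

"Low risk" means predicted probability *at or below* the threshold (the
convention is `<=`, fixed and documented). Positivity is routing to
in-person review; truth is confirmed SSI within 48 h. The failure rate —
the proportion of low-risk-stratified responses with confirmed SSI — is
computed *identically* as 1 − NPV. Metrics with empty denominators are
reported as undefined rather than zero. Proportion intervals default to
Wilson score; Wald intervals are available because clinical reports often
print them, and the printed-count regression tests use that option.

One deliberate inconsistency is worth recording. An idealised invariant —
"a perfect predictor makes the hybrid pathway failure-free at any interior
threshold" — does not hold under the hybrid semantics above, because
surviving true-SSI responses can still be clinician-labelled low; the
published hybrid arithmetic (false negatives rising from 17 under full
automation to 26 under hybrid review) confirms that downgrading happens.
The test suite therefore asserts the consistent form (perfect model *and*
faultless clinician labels give zero failures) in the module tests, and
retains the idealised form in the acceptance suite, where its failure
documents the contradiction rather than a defect of the implementation.

**Workload.** A clinician review costs 2 minutes; automated assessment is
real time (0 minutes). Staff-hours = reviews × 2/60; the percentage
reduction is relative to the full-clinical baseline. Annual FTE per
1000-patient caseload annualises study-period hours by 12/9 (a nine-month
collection window), scales from the 200 monitored patients to the
caseload, and divides by 1950 h (37.5 h/week × 52). These defaults
reproduce the reference workload figures exactly (51.5 h → 0.176 FTE for
full review of 1545 responses; 9.1 h → 0.031 for hybrid); every factor is
an explicit, overridable `staffing_model()` parameter. The threshold sweep
re-simulates a strategy over a sorted grid and reports accuracy, failure
rate and workload per threshold; review counts are monotone non-increasing
in the threshold by construction of the ≤ rule.

# Numerical and scale choices

Problem sizes are chosen for a single desk CPU and are stated where used:
the calibration-recovery checks use 2000-patient cohorts (≈7500 responses);
the end-to-end model-sanity check uses 400 patients with the default
(strong) generative effects, a 240-image training cap for the CNN (all
SSI-positive images kept, negatives subsampled) and the full 30-epoch
recipe; the acceptance script runs 200 patients. Monte-Carlo tolerances are
3 binomial standard deviations around the calibrated targets. All
randomness flows through explicit seeds (data, split, model), each consumed
via an internal scoped-seed helper so no function disturbs the caller's RNG
stream; derived seeds stay within 32-bit range. Degenerate inputs are
handled explicitly: a zero SSI rate skips conditional calibration and
calibrates the marginal triage mix instead; single-class training data,
crossed calibration targets, empty threshold grids and zero-denominator
metrics all raise or flag rather than silently produce numbers.

# Known limitations

The generator's independence assumptions (responses within patient, images
within response) understate real clustering, so confidence intervals on
simulated cohorts are, if anything, slightly narrow. The image domain is
cartoon-like by design; image-model accuracies on synthetic wounds say
nothing quantitative about photographic wounds. The FTE annualisation is a
linear scaling and ignores queueing, review batching and out-of-hours
effects. Fusion operates on output probabilities; joint fine-tuning of both
branches is out of scope.
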