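---
title: "Nocturnal-breathing biomarkers for Parkinson's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nocturnal-breathing biomarkers for Parkinson's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Parkinson's disease (PD) lacks practical biomarkers for diagnosis and for
tracking severity. Breathing is disturbed early in the disease, and a full
night of respiratory effort — from a chest belt during polysomnography (PSG)
or from contactless radio sensing — can be recorded repeatedly at home with
no burden on the patient. `breathpd` implements a complete pipeline that
takes one night of breathing (a 1D signal at $f_b = 10$ Hz, $T$ seconds
long), produces a PD probability and an MDS-UPDRS severity estimate, and
evaluates both the way longitudinal biomarker studies require: multi-night
aggregation, test–retest reliability, and progression statistics.

## Preprocessing

Each raw night is screened and normalized:

* nights shorter than 2 h are dropped;
* nights with a constant signal are dropped as absent;
* a night is called *distorted* when more than 20% of samples sit at the
  clip bound, when more than 25% of 30-s windows are flat (window s.d.
  below 5% of the median window s.d.), or when the Welch-averaged spectrum
  (60-s segments) has no peak in the respiratory band 0.1–0.5 Hz exceeding
  3× the 1–5 Hz noise floor. These three rules are this package's
  operationalization of "distorted or nonexistent"; they are configurable
  via `distortion_config()`.
* surviving nights are clipped to $[-6, +6]$ raw units, then centred and
  divided by the **population** (divide-by-$n$) standard deviation of the
  clipped signal. The order — clip, then normalize — matters and is fixed.

## The network

The model is a multitask network built from five parts (all shapes are
(time × channels) matrices):

* **Breathing encoder $E$** — a stride-5 convolutional stem followed by
  eight 1D bottleneck residual blocks (1×1 reduce, 3×1 conv, 1×1 expand,
  per-channel time normalization after every convolution, ReLU, projection
  shortcut where stride or width changes; stride 2 at blocks 1, 3, 5, 7)
  and three simple recurrent unit (SRU) layers. The total temporal stride
  is $S = 80$ samples, so features arrive at 0.125 Hz — one step per 8 s.
  SRUs are used because their matrix products are time-parallel; only an
  elementwise recurrence is sequential.
* **PD encoder $G$** — two stride-1 convolutions score every feature step;
  a softmax over time converts scores into attention weights $a_t \ge 0$,
  $\sum_t a_t = 1$; the global feature is the attention-weighted time
  average $g = \sum_t a_t f_t \in \mathbb{R}^d$.
* **PD classifier $M$** — three fully connected layers and a sigmoid;
  diagnosis is `score > 0.5`.
* **Severity predictor $N$** — four fully connected layers, linear output
  on the MDS-UPDRS scale. Subpart heads (I–IV) replace the total head with
  identical structure.
* **qEEG predictor $F$** — three ×2 deconvolution blocks (zero-stuffed
  upsampling followed by convolutions; three deconvolution layers with
  normalization, ReLU and a residual join per block), UNet-style skip
  connections that concatenate upsampled SRU-layer outputs, two fully
  connected output layers, and a per-second softmax over the four bands.
  Three ×2 blocks turn the 0.125 Hz features into exactly the 1 Hz label
  rate.

Widths default to 6→8→12 channels with bottleneck expansion 2, SRU hidden
size and global dimension $d = 12$. This is deliberately narrow: the
layer*count* structure above is fixed, but widths were chosen so that the
full bench experiments in the test suite train in minutes on one CPU core.
Wider plans are one `model_config()` call away.

There is no dropout and the normalization layers compute their statistics
from the input itself (per-channel over time), so evaluation is exactly
deterministic: two forward passes of the same night are bit-identical, and
a saved and reloaded model (`save_model()` / `load_model()`) reproduces
predictions bit-identically.

The forward/backward machinery is implemented in this package directly —
Rcpp/Armadillo kernels for convolution, the SRU recurrence and fused
normalization, with a small reverse-mode tape in R composing them. Every
kernel's gradient is validated against central finite differences in the
unit tests.

## qEEG auxiliary labels

One PD label per ~8 h night is sparse supervision. Nights recorded in a
sleep laboratory also carry EEG, from which a per-second summary is
computed: relative spectral power in the δ (0.5–4 Hz), θ (4–8), α (8–13)
and β (13–30 Hz) bands of the C4-M1 channel. `compute_band_powers()` uses,
for each second, a 4-s window centred on that second, analyzed by Welch's
method with 2-s Hann sub-windows at 50% overlap; band edges are half-open
$[lo, hi)$ so boundary frequencies count once; the normalizer is the sum
over the four bands only. The 0.5 Hz sub-window resolution is the smallest
that resolves the lower δ edge while giving a 1 Hz label rate; none of
these Welch parameters is externally prescribed, so they are package
choices exposed as arguments.

## The training objective

A training step processes all nights of one subject that fall within a
one-month window (the paper-style regime samples one full night per step;
grouping a subject's in-window nights is this package's choice, needed so
the transductive consistency term — which compares nights of one subject —
has something to compare). The total loss sums the available terms:

* weighted cross-entropy for PD classification (class weights = inverse
  class frequency of the training split);
* weighted squared error for MDS-UPDRS regression (per-sample
  inverse-domain-frequency weights), weight 0.05 — the initially planned
  0.01 left the severity head visibly undertrained at bench scale;
* an L2 loss on the predicted qEEG relative powers (padded label seconds
  are masked out);
* an adversarial domain term: a discriminator $D_{PD}$ distinguishes belt
  from wireless features of PD subjects, $D_{Control}$ does the same for
  controls (two discriminators so that removing the domain gap cannot
  remove class information when prevalence differs across domains). The
  encoder is driven through a gradient-reversal layer ($\lambda = 1$), and
  three discriminator-only refinement steps per batch on detached pooled
  features keep the discriminators strong — the standard alternating
  realization;
* the transductive consistency term: the population variance of one
  subject's per-night severity predictions inside the window.

A term whose label is absent is excluded exactly — the corresponding head
is never even evaluated, so its parameters receive no gradient (checked by
finite differences in the tests). Optimization is Adam; the package default
learning rate is $10^{-3}$ (the clinical-scale reference value is
$10^{-4}$, which undertrains at tens-of-subjects bench sizes). Training is
deterministic given the seed.

## Calibration and ensembling

Belt and wireless cohorts have very different PD prevalence, so raw scores
are not comparable against a fixed 0.5 threshold. The training subjects are
split into four subsets; each rotation trains on three and fits Platt
scaling on the fourth: two scalars $(A, B)$ minimizing the cross-entropy of
$\sigma(A z + B)$, where $z$ is the classifier's **pre-sigmoid logit**
(probability-input Platt cannot express the identity map, so the logit
convention is used and documented). The fit is a damped Newton iteration on
the convex 2-parameter problem, run to gradient norm $10^{-8}$. The final
model averages the four members' calibrated scores.

## Evaluation methodology

* **ROC/AUC** via midranks (equal to the Mann–Whitney concordance
  probability with ties counted ½; verified against exhaustive pair
  enumeration).
* **Sensitivity/specificity** from the confusion counts at threshold 0.5,
  with Clopper–Pearson exact 95% CIs (Wilson available); the exact bounds
  are verified against a binomial-tail bisection oracle.
* **Pearson correlation** in the summation form
  $R = (N\sum uv - \sum u \sum v) / \sqrt{(N\sum u^2-(\sum u)^2)(N\sum v^2-(\sum v)^2)}$.
* **Multi-night aggregation**: the subject-level value is the median of
  nightly values (mean-of-middle for even counts), optionally inside the
  month following a visit.
* **Test–retest reliability**: one-way random-effects single-measurement
  ICC(1,1) from variance components,
  $\mathrm{ICC} = (MS_B - MS_W)/(MS_B + (k_0-1) MS_W)$, treating
  non-overlapping windows of $w$ nights (aggregated by median) as
  interchangeable repeated measurements; CIs by subject-level bootstrap.
  Windows come only from the month after baseline, when severity can be
  assumed static.
* **Cross-validation** is always subject-level (all nights of a subject
  share a fold); 4-fold stratified by class and domain, leave-one-out,
  cross-institution and external-holdout schemes are provided.
* **Group comparisons** delegate to the standard one-tailed Wilcoxon
  rank-sum, Kruskal–Wallis and one-tailed one-sample signed-rank tests
  (exact small-sample distributions where tie-free), verified against
  exhaustive enumeration. An all-zero difference vector returns $p = 1$.
  No multiple-testing adjustment is applied.
* **Progression**: per subject, the median severity prediction over the
  month after baseline and the month after the month-6/12 visit; change =
  later − baseline (positive = worsening), tested with the one-tailed
  signed-rank test. A single-night variant quantifies what aggregation
  buys.

## Attention interpretation

Attention steps (8 s each) are spread uniformly over the seconds they
cover. Each second is assigned its 30-s hypnogram stage, or its argmax
relative-power EEG band (ties resolved toward the lower-frequency band —
a rule this package fixes since none is externally given). Per-category
scores are the attention mass in the category, renormalized over the
categories present in the night. Cohort contrasts pick the direction of
the PD–control median difference per category and report the one-tailed
rank-sum p-value in that direction.

## The simulator

`simulate_cohort()` generates everything the pipeline consumes, with the
generating truth stored alongside:

* **Breathing**: an amplitude-modulated quasi-sinusoid whose instantaneous
  rate follows an Ornstein–Uhlenbeck process around 0.25 Hz
  (AR(1)-discretized exactly); disease raises the rate-variability s.d.,
  the amplitude irregularity and the hourly rate of arousal bursts
  (10–20 s excursions of rate and amplitude placed inside Wake/N1 epochs),
  each scaled linearly by severity/100.
* **Hypnograms**: a five-stage Markov chain at 30-s epochs, blended toward
  a Wake/N1-bound fragmentation matrix as severity grows.
* **qEEG**: stage templates on the band simplex, perturbed per second by
  Dirichlet noise, with δ reduced and β elevated in proportion to severity.
* **Domains**: belt nights are clean and carry qEEG labels (as PSG nights
  would); wireless nights are 7-sample smoothed with added AR(1) coloured
  noise and carry no EEG. The wireless signature is strong enough that the
  acquisition domain is recoverable from the raw normalized signal — a
  prerequisite for studying domain-adversarial transfer at all.
* **Longitudinal structure**: baseline, month-6 and month-12 visits with a
  configurable severity drift in points/year.

Severities are uniform over 20–80 MDS-UPDRS for PD and 0–10 for controls;
`effect_scale = 0` removes every disease effect and provides the leakage
control. Defaults (rates, gains, noise levels) were fixed once during
development so that the standard bench experiments are learnable, and are
documented in `?sim_config`.

What the simulator does *not* emulate: real respiratory pathophysiology
(apneas, periodic breathing), EEG microstructure, inter-subject anatomy, or
label noise in clinician scores. Passing the bundled experiments therefore
shows that the implementation is correct and that the method behaves as
designed on data with the assumed statistical structure — it does not
certify clinical performance, which requires restricted clinical cohorts.

## Bench problem sizes

The test suite and `scripts/acceptance.R` run everything end to end at
sizes chosen for a single CPU core: 30-minute nights, 40+40 subjects ×
3 nights (30 epochs, 4-fold) for detection, 60 subjects × 6 nights for
severity, 100 replicate cohorts for progression power, and 16–34-subject
cohorts for the transfer and consistency checks. Full-length (8 h) nights and
wider networks are configuration changes, not code changes.

## Known limitations

* At these model widths, an encoder trained on a class-balanced two-domain
  cohort prunes acquisition-domain information on its own (an untrained
  encoder's pooled features reveal the domain to a logistic probe at
  ~0.72–0.75 accuracy; after class training this falls to near chance even
  without any adversarial term). A strong probe-based contrast between
  adversarially and plainly trained encoders therefore only appears when
  prevalence confounding gives the classifier an incentive to keep the
  domain shortcut — and in that regime the class-mediated association puts
  a floor (~0.76 here) under any class-preserving probe accuracy. The
  adversarial term still demonstrably shrinks the feature-space domain gap
  (group centroid distance roughly 3× smaller in every run).
* Severity estimates compress toward the cohort mean at the extremes, as
  L2-trained regressors do; subpart heads share this behaviour.
* The ICC bootstrap resamples subjects only; with very few subjects the
  interval is optimistic.
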