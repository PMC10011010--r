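---
title: "Methods: functional data analysis of multiple brief exercise bouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional data analysis of multiple brief exercise bouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Children's spontaneous physical activity looks nothing like a laboratory
ramp test: it is a sequence of short, intense efforts separated by brief
rests. The multiple-brief-exercise-bout (MBEB) protocol mimics this — up to
ten 2-minute constant-work-rate cycling bouts, each followed by a 1-minute
rest, at an intensity set as a fraction (typically 40% or 80%) of the peak
work rate from a prior ramp test. At high intensity roughly half of healthy
children decline to start some later bout ("task failure"). The scientific
question this package operationalizes: can the second-by-second heart rate
(HR), respiratory rate (RR), oxygen uptake (VO2) and carbon dioxide output
(VCO2) trajectories over just the **first four bouts (720 s)** — which every
participant completes — predict who will eventually fail?

The package implements the full analysis chain as reusable, tested
components: a synthetic cohort generator (the original cohort data are not
public), preprocessing and quality control, penalized B-spline smoothing,
continuous curve registration, functional permutation t-tests and bootstrap
functional ANOVA, and FPCA-based supervised classification with a
generalized spectral additive model (GSAM) plus six baseline classifiers.

## The synthetic cohort generator

Because no raw data are deposited, `generate_cohort()` is a first-class,
tested module, not a fixture. It emulates the stated world of the protocol:

* **Kinetics.** Each signal follows piecewise first-order dynamics over the
  square wave: within a bout the noise-free trajectory relaxes toward
  `baseline + amplitude` with time constant `tau_on`; in the rest after
  bout *k* it relaxes toward `baseline + drift_per_bout * k` with
  `tau_off`. The per-segment solution is the exact exponential
  `y(t) = target + (y0 - target) exp(-(t - t0)/tau)`, propagated
  analytically across segment boundaries, so the noise-free trajectory is
  continuous and an independent closed-form oracle can check it to 1e-10.
* **Defaults** (simulation choices, not physiological estimates): HR
  baseline 80, amplitude 70 beats/min, tau 30/45 s, the cleanest signal
  (noise sd 1.5); RR baseline 20, amplitude 20 breaths/min, the noisiest
  (sd 4); VO2/VCO2 baseline 300, amplitude 1200 mL/min, tau_on 25/35 s,
  sd 80/90. These reproduce the qualitative appearance of the signals
  (bouts obvious in HR, hard to discern in RR).
* **Group structure.** Failures receive an amplitude shift (higher mean
  response) plus a positive end-of-rest drift per completed bout
  (incomplete recovery). The effect enters the *level*, not the time
  constants, because the empirical finding being emulated is a higher mean
  function in failures, not different kinetics. Both knobs are
  configurable; tests that need a null world set them to zero.
* **Sampling.** Breath-by-breath measurement is emulated by exponential
  inter-sample gaps (mean 1 s for HR, 2 s for RR and gas exchange),
  truncated at four times the mean: real inter-breath intervals do not
  reach the 10-s QC gap threshold, and an untruncated exponential would
  trip it several times per session. A final sample is logged at test end,
  as a metabolic cart does.
* **Labels and quitting.** Cohorts are balanced (39/39 at full scale).
  Failures quit uniformly after 4–9 bouts; the study reports only a mean
  (~6.2 bouts) and that everyone finished at least four, so the uniform
  choice is a stand-in, not an inference. Completers finish all bouts.
* **Randomness.** One RNG stream per participant, split by signal, all
  derived from the single config seed: adding a signal never perturbs
  another's draws, and the cohort is a pure function of its config.
* Between-participant variability (8% fractional sd on baseline and
  amplitude) is a generator choice at the scale of biological variation in
  pediatric exercise responses.

What a green test on this generator does **not** establish: realism of
breathing noise spectra, motion artifacts, cart dropout patterns, or the
physiological coupling between signals (each signal is simulated
independently given the group). Conclusions about the *method* transfer;
conclusions about children do not.

## Preprocessing

Raw irregular series are linearly interpolated to integer seconds
(`interpolate_to_seconds()`): linear interpolation matches common CPET
practice and cannot overshoot before smoothing. No extrapolation beyond a
1-s constant edge hold is allowed; series starting after t = 1 s or ending
more than 1 s early fail QC rather than being extrapolated. The module
fixes interpolate-then-truncate order; the two operations commute on
covered windows (property-tested), so nothing hinges on it.
`qc_screen()` flags inter-sample gaps > 10 s, values outside physiological
ranges (HR 25–250 beats/min, RR 2–120 breaths/min, VO2 0–6000, VCO2
0–7000 mL/min), and flatlines longer than 60 s — conservative,
config-exposed stand-ins for the study's informal removal of technically
corrupted records. A participant is excluded iff any of their four signals
is excluded.

## Smoothing

Curves are represented in an order-6 B-spline basis with breakpoints every
second: on [0, 720] that is 719 interior breakpoints + 6 = **725 basis
functions**, an interpolation-grade basis whose flexibility is controlled
entirely by the roughness penalty. The penalty is the harmonic-acceleration
operator

\[ L = \omega^2 D + D^3, \qquad R_{jk} = \int (L\phi_j)(L\phi_k)\,dt, \]

whose null space {1, sin(ωt), cos(ωt)} is unpenalized. The package default
is ω = 2π/180 rad/s — one cycle per 180-s bout+rest period — so oscillation
at the protocol's driving frequency is never penalized; ω is a config knob
because the original choice is not recorded. R is computed by composite
Simpson quadrature (default step = spacing/4).

For data y on grid t, `penalized_smooth()` solves
(Φ'Φ + λR)c = Φ'y, with df = tr(Φ(Φ'Φ+λR)⁻¹Φ') and
GCV = n·SSE/(n−df)² (Craven–Wahba). `select_lambda()` scans a λ grid
(default 41 points, log-spaced 1e-2…1e6) and returns the GCV minimizer
along with the full (λ, df, GCV) trace for the classic GCV-vs-DoF
inspection plot. `smooth_sample()` selects **one λ per signal** (minimizing
the summed per-curve GCV), matching tuning per curve-set; per-curve
selection sits behind a flag.

Numerical choices worth knowing:

* Moderate λ uses a Cholesky solve of the normal equations; when
  λ‖R‖/‖Φ'Φ‖ exceeds 1e6 the solver switches to QR on the augmented system
  rbind(Φ, √λ·R^{1/2}), which stays accurate where the normal equations
  lose half their digits.
* Ties in GCV (e.g. a noise-free null-space signal, where every λ fits
  exactly) break to the **largest** λ — the smoothest fit.
* sin/cos belong to the spline span only to O(h⁶), so for λ ≳ 1e10 (at 1-s
  spacing) the penalized fit converges to the *discrete* null space rather
  than the analytic one; the limiting-behaviour tests are pinned at the
  largest λ where the analytic premise holds (1e8–1e10).
* λ = 0 with fewer observations than basis functions is a singular system;
  the error message says to use a positive λ rather than silently
  regularizing.

## Registration and the phase/amplitude decomposition

Bout onsets are synchronized by the protocol, so phase variation is small
but not zero. `register_to_mean()` performs continuous registration:
iteratively compute the cross-sectional mean, warp each curve toward it,
update the mean. Warps are parameterized as exponentiated B-spline
integrals h(t) = T·∫₀ᵗe^{W}/∫₀ᵀe^{W} (W a spline with ~5 coefficients), so
h(0)=0, h(T)=T and h'>0 by construction; the misalignment criterion is
penalized least squares to the running mean — the simplest criterion
consistent with near-aligned data (the minimum-eigenvalue criterion is a
known alternative; it matters when amplitude and phase are badly
confounded, which the protocol precludes).

The variance decomposition follows the Kneip–Ramsay construction with

\[ C = \frac{\operatorname{mean}_i \int x_i^2}{\operatorname{mean}_i \int y_i^2},\quad
   \text{MSE}_\text{amp} = C\,\operatorname{mean}_i\!\int (y_i-\bar y)^2,\quad
   \text{MSE}_\text{phase} = C\!\int \bar y^2 - \int \bar x^2 , \]

(x unregistered, y registered). With C computed this way the additivity
identity MSE_total = MSE_phase + MSE_amp is *algebraically* exact whatever
quadrature is used — the tests assert it to 1e-6 relative and observe
~1e-14. The phase ratio is clamped to [0,1]; a single-curve sample has
ratio 0 by convention. Downstream code accepts registered and unregistered
samples through the identical `fd_sample` contract.

## Inference

`permutation_ttest()` computes the pointwise Welch t between two groups of
curves, then permutes group labels (default 200 permutations) recording
both the pointwise |t| quantiles (for plotting) and the distribution of
max_t|t|. The familywise decision uses the **max-statistic** null — times
where observed |t| exceeds the permutation 95th percentile of the maximum
form the rejection regions. Quantiles use the ceiling index, keeping the
test conservative at finite permutation counts; the suite verifies the
familywise level empirically over 200 replicate null cohorts. A seed is
mandatory — resampling results without one are not reproducible, so the
functions refuse to run.

`fanova()` tests equality of group mean functions with an integrated F
ratio (between-group sum of squares of mean curves over within-group
variability, with the usual degrees of freedom). The null distribution
bootstraps group-centered residual curves (pooled, labels fixed, resampled
with replacement), preserving within-group covariance under H0; p-values
use the add-one rule (1 + #{F* ≥ F})/(1 + B), default B = 500 (the
calibration studies in the acceptance suite reduce B to 200 for speed).
The asymptotic version of the functional F-test is out of scope; the
bootstrap path is primary.

## Classification

Curves enter classifiers through FPCA: the covariance operator is
eigen-decomposed in coefficient space via the basis Gram matrix, scores are
L2 inner products with the (orthonormal) eigenfunctions. The component rule
is the smallest K reaching 95% cumulative variance, capped at 10. Inside
cross-validation **FPCA is re-estimated on each training fold** and test
curves are projected onto the training fold's eigenfunctions — no leakage;
smoothing, being unsupervised and label-blind, is done once globally.

The GSAM is an additive logistic model: one spline smooth (fixed 3
effective df — not inner-loop tuned, which would be optimistic at n ≈ 78)
per retained FPC score of each functional input, plus linear terms for
binary sex/puberty. Body mass is off by default (it did not help
classification in the motivating analysis) and flag-enabled, entering
standardized by training-fold statistics. Perfect separation falls back to
ridge-penalized logistic regression with a logged warning, never a crash.

Six baselines (LDA, CART, random forest, linear SVM, single-hidden-layer
neural net, KNN) consume the identical (scores, scalars) design — the
choice to give all models FPC-score features is fixed and documented here,
since raw-evaluation inputs would confound the model comparison with a
representation change. LDA uses MASS; the other five are compact
in-package implementations (Gini CART; bagged CART with random feature
subsets; squared-hinge linear SVM with Platt-scaled probabilities;
tanh-hidden-layer net with weight decay fit by BFGS; plain KNN) because the
usual back-end packages are not assumed available. They follow the
standard constructions and are property-tested (e.g. 1-NN memorizes, LDA
separates 4σ Gaussian clouds), but are not feature-complete ports.

Cross-validation is stratified by label (default 10-fold), all specs in a
battery share one master seed and hence identical folds (paired rankings),
the decision threshold is 0.5 with ties assigned to the completer class,
and the pooled confusion matrix yields accuracy, precision, recall and
F1 = 2PR/(P+R), with F1 ≡ 0 when P + R = 0. Battery rankings are
descriptive; no multiplicity correction is applied.

## Pipeline

`cmd_simulate()` and `cmd_analyze()` (or the `mbeb_cli()` subcommand
wrapper in `inst/cli/mbeb.R`) chain the stages: QC → interpolate →
truncate → smooth → (optionally) register → FANOVA per signal → classifier
battery, writing `fanova.json`, `battery.csv/json`, `report.json`, a log
with every λ, df, GCV, phase ratio and seed, and a config snapshot from
which the run can be reproduced byte-for-byte. `--no-register` skips
registration (phase ratios disappear from the report; the schema is
otherwise unchanged). Stage failures abort with the stage name; partial
artifacts stay on disk.

## Known limitations

* The generator's independence across signals means multivariate ("full"
  model) gains are structurally smaller than in real data, where the four
  signals share latent physiology.
* Registration optimizes a penalized least-squares criterion with BFGS from
  the identity warp; severe misalignment (beyond anything the protocol can
  produce) may need more iterations or a larger warp basis.
* The asymptotic functional F-test, landmark/elastic (SRVF) registration,
  Fourier/wavelet bases, derivative-domain testing and the image-encoding
  neural comparison are deliberately out of scope.
* Whether the motivating subgroup t-tests were run on curves or their first
  derivatives is ambiguous in the record; the package tests curve levels
  and exposes `deriv` in evaluation functions without asserting either
  choice.

All empirical statements above (calibration of the permutation and
bootstrap tests, oracle agreement of the smoother, decomposition
additivity, classifier recovery and null behaviour) are computed by the
test suite, not quoted from elsewhere.
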