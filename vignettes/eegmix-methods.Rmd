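---
title: "Mixture-model source analysis of lower-limb motor EEG: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model source analysis of lower-limb motor EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`eegmix` analyses high-density EEG recorded while a seated subject performs
discrete lower-limb exercises: isometric and isotonic knee and ankle
flexion/extension at two effort levels, in repetitions of roughly 3 s
separated by 5 s pauses. The analysis chain has four scientific stages:

1. **Mixture ICA.** The multichannel EEG is modelled as a mixture of `M`
   complete linear ICA models. Model `h` explains a sample `x` as
   `x = A_h s + c_h` with independent sources `s_i` following adaptive
   generalized-Gaussian densities
   `log q(s) = log(rho / (2 beta Gamma(1/rho))) - |s/beta|^rho`,
   optionally extended to a mixture of scale components per source. Models
   compete for samples through posterior responsibilities; maximum
   likelihood fits the unmixing matrices, biases, density parameters and
   model priors jointly. With `M = 2`, the two models capture the two
   spatial regimes that knee and ankle tasks are expected to produce
   (somatotopy of the medial sensorimotor cortex): the posterior model
   probability of a trial's samples classifies it as a knee or an ankle
   trial.
2. **Source localization.** Each independent component's scalp map is
   explained by an equivalent current dipole in a single homogeneous
   conducting sphere. Components whose dipole leaves more than 15% of the
   scalp-map variance unexplained are discarded; remaining components are
   screened with ocular and myogenic rules and clustered across subjects
   by k-means on weighted dipole-location plus scalp-map features.
3. **Time-frequency ERD analysis.** Component activations are decomposed
   with complex Morlet wavelets on a 220-bin log frequency grid from 3 to
   150 Hz; single-trial spectrograms are time-locked to mechanically
   detected trial onsets, baseline-normalised (log power minus the mean of
   a -1.0 to -0.5 s pre-onset window), linearly time-warped to a common
   trial duration and masked by a bootstrap significance test.
   Event-related desynchronization (ERD) appears as significant negative
   dB values in the alpha (8-12 Hz) and beta (12-30 Hz) bands.
4. **Decoding.** Normalized spectrograms are reduced 10-fold in time and
   frequency; the union over conditions of bootstrap-significant reduced
   grid points defines the feature set; a linear (pooled-variance)
   Gaussian naive-Bayes classifier with stratified 10-fold
   cross-validation decodes the four conditions (isometric/isotonic x
   high/low effort), summarised by grand-average normalized confusion
   matrices.

# The forward model

The scalp potential of a dipole at eccentricity `b` inside a homogeneous
sphere of radius `R` and conductivity `sigma` is the truncated Legendre
series

$$V = \frac{1}{4\pi\sigma}\sum_{n\ge1}\frac{2n+1}{n}\frac{b^{n-1}}{R^{n+1}}
 \left[n\,q_r P_n(\cos\gamma) + q_t P_n^1(\cos\gamma)\right],$$

truncated when a term's relative contribution drops below `1e-10` (cap 200
terms), mean-referenced across electrodes. A single homogeneous sphere
(rather than a three-shell or boundary-element model) is used because the
package needs *internal consistency* between the simulator and the inverse
fit, not anatomical accuracy; all coordinate statements inherit this
ceiling, and no template-brain coordinates are reported. The inverse fit
is nonlinear least squares over the location only (the moment enters
linearly and is solved in closed form), seeded from a deterministic 5 mm
grid inside the brain sphere with the best `n_restarts` nodes refined by
Nelder-Mead; ties break toward the lexicographically smallest location.
Noiseless forward-then-invert recovery is better than 1 mm on a
64-electrode cap; with 10% RMS topography noise the median location error
is a few millimetres.

# Fitting the mixture

One iteration alternates (a) per-sample responsibilities from the
prior-weighted per-model log-likelihoods, (b) a responsibility-weighted
Newton-preconditioned relative-gradient update of each unmixing matrix
(using the integration-by-parts moments `kappa_i = E[phi_i^2]` and
`E[(phi_i s_i)^2]`, falling back to the plain natural gradient where the
curvature estimate is indefinite), (c) closed-form scale updates and a
bounded line search for each density shape `rho_i` in `[0.5, 4]`, and (d)
the prior update. The total log-likelihood is monotone by construction:
steps that decrease it are rejected and the learning rate halved; ten
consecutive rejections abort. A mild prior floor (`0.2/M`) prevents a
model from shrinking onto a tiny outlier niche (e.g. blink pulses) before
it can specialise.

Three design choices deserve comment because the design space was
genuinely open:

* **Initialisation and schedule.** Random-start EM on two regimes that
  differ in a single source column almost never finds the regime split.
  The default `"blocks"` initialisation therefore (i) fits one shared
  model, (ii) clusters 8 s data blocks by their second-order structure
  (the vectorised covariance of the whitened data) with k-means, (iii)
  refines a copy of the shared model on each cluster, drawing the
  refinement samples equally from amplitude sub-states of the cluster so
  neither model fits one task state better than the other, and (iv)
  consolidates densities and priors on the full data with the unmixing
  matrices frozen. A post-seeding joint unmixing competition is available
  (`joint_iter`) but defaults to off: protocols like this one contain a
  second, stronger nonstationarity -- the trial/pause alternation of
  oscillatory power and myogenic activity -- and an unconstrained
  competition reliably abandons the spatial-regime split for that
  amplitude-state split, which carries more likelihood but no somatotopic
  information. On stationary sources (the unmixing-recovery fixtures) the
  competition is purely beneficial and is switched on there
  (`joint_iter = 60`). The likelihood remains monotone in every phase.
* **Trial classification.** Two separately refined models inevitably
  carry a small constant per-sample fit offset (one model is slightly
  sharper everywhere); such an offset is not identifiable from the
  mixture priors, and summed over a 1500-sample trial it can outweigh the
  regime evidence of exactly those trials whose limb-specific source is
  desynchronized (sustained-ERD trials). `classify_trials_by_model()`
  therefore calibrates, by default, a decision threshold on the per-trial
  mean log-likelihood ratio by maximising agreement with the trial labels
  -- the same labelled-agreement principle that already chooses the
  model-to-joint mapping -- and also reports the plain argmax-posterior
  accuracy for comparison.
* **Scale-mixture densities.** With a single generalized Gaussian per
  source, state-dependent source variance (desynchronization, bursts) is
  unmodelled and the two mixture models are drawn to explain it. Three
  scale components per source (`n_scale = 3`, the pipeline default) let
  each model absorb amplitude states inside its densities, so the model
  competition is driven by mixing geometry. The plain single-component
  density remains the `mixica()` default and is what the unmixing-recovery
  tests use.
* **Dimensionality.** Data are PCA-whitened to `n_components` (default 16
  of 64 synthetic channels) before fitting; scalp maps are mapped back
  through the reduction. Fitting optionally subsamples to
  `max_samples` evenly spaced samples (default 100k in the pipeline);
  prediction and classification always use all requested samples.

# The synthetic study

Because no public recording of this protocol exists, validation runs on a
synthetic study whose defaults *are* the study conditions: 8 subjects, 7
exercises x 2 efforts x 20 repetitions (isotonic knee flexion excluded),
lognormal 3 s trials (CV 0.1), 5 s pauses, 64 electrodes on a Fibonacci
cap, 512 Hz EEG and 1000 Hz mechanical channels.

Sources are dipoles in the forward model above: seven cortical generators
(supplementary motor area, left/right dorsal premotor, posterior
cingulate, posterior parietal, anterior cingulate, visual), one ocular and
one neck-muscle generator. Each cortical source is band-limited Gaussian
noise in the alpha and beta bands (baseline scalp amplitudes 2-4 uV per
band) whose instantaneous amplitude is `a(t) = a_base (1 - d m(t))`;
because amplitude, not power, is modulated, the designed power ERD in dB
is exactly `20 log10(1 - d)`. The window `m(t)` is mode-specific: 600 ms
raised-cosine bumps at onset and offset for isometric trials, a plateau
with 300 ms cosine ramps for isotonic trials -- the task-locked pattern
contrast the analysis is meant to recover. Depths are effort-dependent
(supplementary motor area 0.50 high / 0.30 low, smaller in the premotor
and parietal sources, none in the anterior cingulate and visual sources)
with per-trial jitter (SD 0.05); the 0.6 low-to-high depth ratio was
calibrated once so the effort contrast is detected consistently across
the 8 simulated subjects, mirroring a small-but-reliable effect. A pink background 10 dB below the alpha
baseline, Poisson blinks (0.2/s, 300 ms biphasic, with a continuous
low-frequency ocular baseline), and 20-150 Hz myogenic bursts during
trials (atop a resting tone) complete the source set. The knee and ankle
regimes share all sources except the supplementary-motor one, whose
location shifts 15 mm posteriorly for ankle tasks; inter-trial samples
follow the upcoming trial's regime.

Sensor-level noise comprises white noise (1 uV RMS), 60 Hz line
interference (0.5 uV), a per-channel random walk (removed by the 1 Hz
high-pass), and -- important for realism -- a diffuse background of six
deep random dipoles carrying pink noise (8 uV at the strongest
electrode), emulating volume-conducted ongoing cortical activity. Without
that background every channel is dominated by its private white noise
during pauses and the neighbour-correlation rejection rule (correctly)
discards most of the cap; with it, retention matches what the rule is
designed to leave on real high-density recordings. The ocular and
myogenic baselines similarly prevent the artifact sources from becoming
degenerate outliers of the fitted source densities.

The generator's amplitudes and noise levels are not reported by any
experiment; they were chosen once so that the pipeline stages meet their
recovery properties at desk scale, and are all exposed in the
configuration. What passing tests show is therefore *internal
consistency* -- each stage recovers what the generator planted under
realistic interference -- not performance on real EEG, which has richer
artifact structure, inter-subject variability and no ground truth.

# Numerical choices

* Morlet wavelets use a fixed 500 ms Gaussian envelope (+-3 sigma) at all
  frequencies, i.e. frequency-proportional cycles, and are L2-normalised;
  power is `10 log10 |conv|^2`. The 25 ms column step reads the sliding
  windows as overlapping by 475 ms; epoch extraction snaps to the column
  grid so all trials share exact column latencies.
* Time-warping maps `[onset, offset]` linearly onto `[0, target]` (the
  median trial duration), keeps 1 s of unwarped context on each side on
  the same column grid, and uses two-point linear interpolation.
* The bootstrap mask draws, per frequency, one random baseline column per
  trial per resample (single columns, not blocks), thresholds the
  trial-mean dB at the empirical `alpha/2` and `1-alpha/2` percentiles,
  and sets non-significant grand-average values to 0 dB. No
  multiple-comparison correction is applied (the masks are pointwise by
  design). In pattern summaries, a time column counts as showing ERD only
  when at least 20% of the alpha/beta rows are significantly suppressed;
  isolated pointwise false positives (5% of points under the null) cannot
  reach that level, whereas genuine band-wide desynchronization does.
  Onset/offset neighbourhoods are measured at the analysis resolution: a
  column at time `t` integrates signal from `t` plus/minus half the
  500 ms window, so a 600 ms neighbourhood spans 850 ms in column time.
* Channel rejection applies its three rules in order (amplitude,
  kurtosis, windowed neighbour correlation), with the kurtosis statistics
  computed once on the rule-1 survivors and "nearby" meaning the 4
  nearest electrodes in 3-D; the correlation rule uses 1 s windows since
  a per-sample correlation is undefined. Mechanical trial-bound detection
  uses a 10% of peak-to-baseline threshold with 2% hysteresis, falling
  back to nominal bounds (with a warning) on flat auxiliary signals.
* Decoding uses the union (not intersection) of per-condition
  significance masks; feature selection runs inside each training fold by
  default (no test-set leakage); a `paper_mode` switch reproduces the
  subject-level mask selection computed before cross-validation for
  comparison. "Linear naive Bayes" is implemented as the pooled-variance
  Gaussian classifier -- the construction that is simultaneously naive
  Bayes and linear; per-class variances sit behind a flag. Per-fold
  confusion matrices are aggregated as counts and then normalised so all
  16 cells sum to 100%.
* Components are clustered per ICA model; location coordinates are
  z-scored and weighted 3, scalp maps are interpolated to a common
  64-point spherical grid (subjects retain different channel subsets),
  reduced to 10 principal components, z-scored and weighted 1. Clusters
  need components from at least 75% of subjects (6 of 8) to be retained.
  Records are canonically ordered before k-means so the partition is
  invariant to input order at a fixed seed.

# Problem sizes

The bundled tests and the acceptance script run, by choice, at desk
scale: the unmixing-recovery fixture uses 16 dimensions and 100k samples
(the two regime mixings share 8 of 16 source columns); trial
classification uses one full default subject (280 trials, 64 channels,
fitting on 100k subsampled points); dipole recovery uses 25-50 random
dipoles on the 64-electrode cap; mask calibration uses 200 null trials
per replicate; the ERD and decoding studies use all 8 subjects at 20
repetitions, with spectrograms computed on the generator's ground-truth
cortical activations (the ICA stage is validated separately by the
recovery and classification fixtures). `run_pipeline()` executes the full
chain -- simulation, preprocessing, mixture ICA, localization,
clustering, ERD statistics and decoding -- end to end and is exercised in
the tests on a reduced configuration.

# Known limitations

* The homogeneous sphere bounds localization realism; no
  anatomical/template coordinates are produced.
* The block-seeded initialisation assumes regimes occupy contiguous
  stretches much longer than 8 s, which holds for blocked exercise
  protocols but not for rapidly interleaved designs.
* The scale-mixture densities capture per-source amplitude states but not
  their co-switching across sources; a strong co-modulated state can
  still attract the model competition, which is why the competition phase
  is capped after a successful seeded start.
* The synthetic generator does not emulate electrode drift over sessions,
  cardiac artifact, or volume-conducted EMG spectra with realistic
  coloration; conclusions about real-data decoding accuracy must come
  from real data.
* EDF support is limited to what the package writes (16-bit, one-second
  records, per-signal rates); BDF/BrainVision/FIF are out of scope.
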