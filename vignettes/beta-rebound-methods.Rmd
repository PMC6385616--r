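---
title: "Simulating and testing the post-movement beta rebound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing the post-movement beta rebound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betarebound)
```

## The scientific problem

Passive (proprioceptive) movement of a limb produces a stereotyped response
in the sensorimotor mu/beta rhythms (8--30 Hz): oscillatory power drops
during the movement (event-related desynchronization, ERD) and then
transiently overshoots its baseline once the movement ends (event-related
synchronization, the *beta rebound*). In Parkinson's disease the rebound to
proprioceptive input is strongly attenuated relative to healthy controls,
while the ERD is largely preserved — a candidate marker of impaired
cortical processing of afferent feedback that is not restored by
dopaminergic medication.

Testing such an effect end-to-end requires a chain of standard but
error-prone steps: epoching and artifact rejection, isolating the induced
(non-phase-locked) response, wavelet time-frequency decomposition,
channel-pair combination and selection, baseline normalization,
cluster-based permutation inference, and default-prior Bayesian tests for
the cohort-level questions. `betarebound` implements this chain together
with a synthetic-data generator that reproduces the statistical structure
the analysis assumes, so every stage — and the pipeline as a whole — can be
validated without access to raw MEG recordings.

## The generative model

`sim_config()` fixes the study conditions. Defaults mirror a two-group,
two-session passive-movement protocol:

* 12 patients (`pd`) and 16 controls (`hc`), two sessions each;
* 90 events per session, separated by a silent period drawn uniformly from
  3.5--4.0 s, sampled at 1000 Hz;
* 10 orthogonal planar-gradiometer-like channel pairs, one EMG channel, and
  a 3-axis accelerometer.

Each session's sensor signal is built as

\[
x_c(t) = w_c \Big[ \sum_j A_j \, e(t)\, \sin(2\pi f_j t + \phi_j)
          + v(t) \Big] + \sigma_n \, \eta_c(t),
\]

where \(f_j \in \{10, 20\}\) Hz are the mu and beta carriers with baseline
amplitudes \(A_j = 20\) (arbitrary gradiometer-like units), \(e(t)\) is the
event-locked amplitude envelope, \(v(t)\) is a phase-locked evoked
transient (Gaussian bump peaking 80 ms after each event, within the 50--110
ms window used for channel selection), \(w_c \sim U(0.3, 1)\) are per-channel
mixing weights (members of a pair get independent weights), and
\(\eta_c\) is unit-variance \(1/f\) noise with \(\sigma_n = 15\).

The envelope `make_envelope()` is 1 in the baseline, descends to
\(1 - d\) over the ERD window ([0, 0.5] s), rises to \(1 + g\) over the
rebound window ([0.5, 1.5] s), and returns to 1, with raised-cosine ramps
of 0.1 s starting at each window edge (published schematics constrain only
the plateau structure, so the ramp shape and duration are package
conventions). The level holds at \(1-d\) between the two windows if they do
not abut. The group effect lives in the rebound gain: by default
\(g = 0.8\) for controls and \(g = 0.15\) for patients in both sessions
("almost absent" rebound), with equal ERD depth \(d = 0.5\) everywhere.
Amplitudes are arbitrary-unit conventions — published figures report only
log-ratios — chosen so that single-trial band amplitude differences are
visible but single-subject statistics still require trial averaging.

Phase handling deserves a note. In the standalone trial generator each
trial's carriers get an independent uniform phase. In the continuous
session generator the carriers run with a single session phase; because
the inter-event interval is jittered by 0.5 s (5 and 10 carrier cycles at
10 and 20 Hz), the carrier phase at each event is effectively uniform, so
across-trial averaging cancels the oscillation while the fixed-latency
evoked transient survives — exactly the property the induced/evoked
separation relies on, and what the generator's tests assert. Degenerate
configurations (an ITI grid commensurate with a carrier period) would
phase-lock the carriers; the defaults are far from that regime.

The \(1/f\) noise is white noise spectrally shaped by a cascade of
first-order pole/zero sections with log-spaced corners (three per decade
between 0.5 Hz and 40% of Nyquist), a staircase approximation whose fitted
log-log slope is within ~0.2 of the target exponent; the cascade runs in
compiled code because it is applied to ~20 channels x 340 s per
subject-session. EMG is broadband noise plus a 50 Hz line component and
optional injected bursts; the accelerometer carries a biphasic
contraction/extension profile within 200 ms of each event, plus optional
0.3 s "accidental movement" transients at 5x the stimulus peak, at a
uniform latency outside the stimulus window, so detection is unambiguous.

What the generator does *not* model: sensor physics (no forward model, no
SQUID noise spectra, no head geometry), ocular/cardiac artifacts, and any
tSSS/ICA cleaning residue. Channels are abstract pair members with random
gains. Consequently, passing tests demonstrate the *analysis chain* is
correct and calibrated under the assumed signal structure — not that it is
robust to every artifact class of real recordings.

## Preprocessing conventions

* Epochs span \([-1.5, 3.5]\) s around each event, closed intervals sampled
  inclusively (5001 samples at 1 kHz). Events without full support are
  skipped and logged, never fatal.
* Peak-to-peak rejection uses strict `>` against per-channel-type
  thresholds (2000 fT/cm for gradiometer-type channels, 10 pT for
  magnetometer-type); equality keeps the trial. The simulator's arbitrary
  units sit far below these limits, so the rule is exercised with scaled
  fixtures in the tests.
* Accidental movements: the accelerometer axes are band-passed 1--195 Hz
  (zero-phase Butterworth), collapsed to the Euclidean norm, and z-scored
  per session. A trial is rejected when \(|z| > 3\) persists for at least
  20 ms outside [0, 0.5] s. The window comes from the protocol; the
  threshold and duration are package conventions (flagged in the
  configuration) because no published values exist.
* The evoked response (across-trial mean of kept trials) is subtracted
  from every trial before decomposition, isolating the induced response.
* EMG: 50 Hz suppression is implemented as a zero-phase IIR notch
  (48--52 Hz stop band). The published description names a DFT filter; the
  package asserts equivalence at the level that matters — at least 40 dB
  suppression of the line component — rather than filter identity. PSDs
  use Hann-windowed periodograms of the non-rectified signal.

## Time-frequency decomposition

`morlet_tfr()` uses complex Morlet wavelets with a fixed width of 5
cycles, i.e. temporal SD \(\sigma_t = 5 / (2\pi f)\) (39.8 ms at 20 Hz),
on 2--40 Hz in 1 Hz steps. Coefficients are evaluated in the frequency
domain — the epoch spectrum is multiplied by the wavelet's Gaussian
transfer function and inverted only at the requested output times — which
permits the 50 ms output grid from \(-1.25\) to 2.5 s directly (76 bins)
and costs far less than full-rate convolution. The wavelet is normalized
so a unit-amplitude sinusoid at a grid frequency has power 1 at its
carrier. Output bins whose support (3 temporal SDs each side) exceeds the
epoch are set to `NA`, not zero-padded; all downstream statistics ignore
missing bins symmetrically across groups. Per-trial power is averaged
across trials *before* the log transform.

Pair combination is root-sum-of-squares in the amplitude domain and a
plain sum in the power domain (equivalent, and orientation-invariant).
The analysis pair per subject is the one with the highest mean combined
evoked amplitude within 50--110 ms, after averaging all trials of both
sessions and low-pass filtering at 90 Hz; ties break toward the lowest
pair index and are flagged.

Baseline correction is \(\log_{10}\) power minus the per-frequency mean
log power over \([-1.25, -0.2]\) s. Any log base is affine-equivalent;
base 10 is used so a 10-fold change reads as +1. Non-positive power is an
error unless an explicit floor is supplied; simulated data never needs
one. The statistical band is 8--30 Hz (23 rows), covering both the mu and
beta sensorimotor rhythms, whose separation is confounded by the mu
harmonic.

## Cluster-based permutation inference

Point-wise two-tailed t statistics (pooled-variance independent, or
one-sample on paired differences) are thresholded at parametric
\(p < 0.05\) two-tailed; supra-threshold bins of equal sign are clustered
under 4-connectivity (frequency and time neighbours; time-only in 1-D)
and summed into cluster masses. The published description states the
threshold explicitly only for the EMG tests; the package adopts the same
threshold for the time-frequency tests, matching the common practice of
the toolbox family this analysis style comes from.

The null distribution records, per permutation, the extreme positive and
negative cluster masses (independent designs permute group labels
preserving sizes; paired designs flip difference signs). Each observed
cluster is referred to its own-sign extreme distribution and flagged
significant at \(\alpha/2 = 0.025\) per sign, the two-tailed convention;
Monte-Carlo p-values carry the +1 correction \((b+1)/(n_{perm}+1)\), which
guarantees validity and is asymptotically identical to the raw
proportion. When the design space is small (at most 20,000 assignments or
sign patterns) exhaustive enumeration replaces sampling and p-values are
exact proportions (the identity assignment included, so \(p \ge 1/N\)).
A numerical tolerance of \(10^{-9}\) relative on mass comparisons keeps
the identity assignment from being lost to round-off.

The medication question uses a pseudo-2x2 design: per subject,
session-1 minus session-2 difference grids are re-baselined (their own
mean over \([-1.25, -0.2]\) s per frequency) and compared between groups
with the independent test. A retest effect common to both groups cancels
exactly; only a group-specific session effect — medication, in the
design's logic — survives.

The permutation loops are vectorized: all permuted t-maps come from two
matrix products, and the per-permutation max-mass extraction runs in
compiled code. A pure-R reference labeller (`label_components_ref()`) is
kept and cross-checked against the compiled one in the tests, so the
inference path never rests on a single implementation.

## Bayes factors

Subject variables use the Jeffreys-Zellner-Siow t-test Bayes factor: a
Cauchy prior with scale \(\sqrt{2}/2\) on the standardized effect,
integrated numerically over the variance mixture. The implementation
integrates over the g-mixture; the tests check it against an independent
route (the noncentral-t likelihood marginalized directly over the Cauchy
prior) to \(10^{-6}\) relative, including \(t = 0\).

The sex-ratio test is the closed-form Dirichlet-multinomial contingency
Bayes factor (independent symmetric Dirichlet(1) priors per group under
H1, a shared vector under H0). The concentration is a convention the
source method family does not pin down; it is exposed as an argument.

Regression comparisons (baseline-power models H0/H1/H2 and the
kept-trial-count "Bayesian ANOVA") use the Zellner-Siow mixture-of-g
nested-model Bayes factor, computed by one-dimensional quadrature of
\((1+g)^{(n-p_0-p_1)/2} (1+g(1-R^2))^{-(n-p_0)/2}\) against the scaled
inverse-gamma prior on g. Subject intercepts enter as fixed nuisance
columns (a random-effect treatment is not determined by the source
description); columns made redundant by the nuisance space (e.g. group
within subject dummies) are dropped by pivoted QR, and rank deficiency of
the *tested* columns is an error that names them. A BIC-based
approximation is provided as a cross-check mode. For a single balanced
two-level regressor the regression Bayes factor reduces exactly to the
two-sample JZS t-test Bayes factor (with the prior scale mapped as
\(r_{reg} = r_t / 2\) for a ±1/2-coded contrast), which the tests verify
to \(10^{-6}\) — a deliberate consistency anchor between the two Bayes
routes. Exact reproduction of published cohort-table Bayes factors is not
attempted: they were computed from raw subject data that is not printed;
the documented check is order-of-magnitude agreement from the printed
summaries (the reconstructed motor-score contrast lands within a factor
of ~1.4 of the published 5.36e6).

## Orchestration and problem sizes

`extract_study_features()` streams one subject-session at a time
(simulate, preprocess, select, decompose, reduce, discard), so the default
28-subject study needs a few hundred MB rather than the several GB a
materialized study would take. `run_study()` adds the three analyses and
the Bayes layer and serializes a JSON report plus a human-readable
summary; identical configuration and seed reproduce the files
byte-for-byte. Seeds for subject-sessions and permutation draws are
derived deterministically from the master seed.

Validation problem sizes were chosen once as the smallest that still
measure what they claim: the permutation-oracle check enumerates all 70
assignments of a 4-vs-4 design on an 8x10 grid; type-I calibration uses
200 replicate null grid studies (8 vs 8 subjects) per design, with the
binomial 95% CI required to cover 0.05; effect recovery runs 20 seeded
replicates of the full pipeline at the study's own scale (12 vs 16
subjects, 90 trials, 10 pairs, 1 kHz) and requires the rebound cluster in
at least 80% of them with no spurious ERD-phase cluster in the majority.
The null-calibration generator draws white-noise grids — calibration of an
exchangeability-based test needs exchangeability, not realism — while
effect recovery exercises the full generative model.

## Known limitations

* Sensor-level only; no source model, no spatial clustering across pairs
  (the analysis runs on one selected pair, as in the protocol).
* The cluster-forming threshold for the time-frequency tests and the
  two-tailed split are conventions where the source description is silent;
  both are arguments, not constants.
* The accidental-movement detector's threshold/duration and the EMG notch
  realization are conventions, asserted at the level of behaviour.
* The generator's amplitudes and gains are arbitrary-unit conventions; no
  published physical-unit effect sizes exist to calibrate against.
* The generator couples baseline band power to the baseline-corrected
  rebound through the signal-to-noise ratio: subjects with larger mixing
  weights have both more baseline carrier power and less noise dilution of
  the log-ratio. The baseline-power regression comparison therefore tends
  to find a real (positive) relationship on simulated studies. That is a
  property of this generative model, not a claim about real cohorts, where
  the corresponding comparison can favour the no-relationship model.
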