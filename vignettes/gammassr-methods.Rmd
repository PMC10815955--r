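---
title: "Methods: gamma-band ASSR phase locking, spontaneous gamma power and behavioral endpoints"
author: "gammassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band ASSR phase locking, spontaneous gamma power and behavioral endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammassr)
```

## What the package computes

`gammassr` implements the EEG-biomarker analysis used in preclinical
pharmacology studies of NMDA-receptor-antagonist ("schizophrenia-like")
rodent models, together with a synthetic-data generator that makes every
stage testable against closed-form expectations. The chain has four
endpoint families:

1. **ASSR phase locking.** A 30-min session presents 1500 auditory
   stimuli, each a 500-ms click train at 50 Hz followed by 700 ms of
   silence. The continuous EEG is cut into 1.5-s epochs covering
   $[-500, +1000]$ ms around each stimulus onset; each epoch is
   offset-corrected by subtracting its median, and epochs with any sample
   strictly beyond $\pm 300\,\mu V$ are rejected. Per retained epoch a
   complex Morlet time–frequency transform is computed on
   $[48, 52]$ Hz, and the phase-locking factor (PLF, also called
   inter-trial coherence) at each (time, frequency) cell is

   $$\mathrm{PLF}(t, f) \;=\; \Bigl|\; \tfrac{1}{N}\sum_{j=1}^{N}
   \frac{c_j(t, f)}{|c_j(t, f)|} \;\Bigr| \in [0, 1],$$

   the magnitude of the average unit phasor across epochs. The scalar
   endpoint per channel is the mean PLF over the post-stimulus region of
   interest ($[0, 500]$ ms) minus the mean over the baseline
   ($[-500, 0]$ ms), both windows trimmed by 100 ms at both ends.

2. **Spontaneous gamma power.** A 1-h stimulation-free recording is split
   into non-overlapping 4-s epochs; epochs with peak-to-peak amplitude
   strictly above $400\,\mu V$ are excluded; each remaining epoch gets a
   Hanning-windowed periodogram (0.25-Hz bins), and the gamma band power
   is the sum of bins with $32 \le f \le 80$ Hz, averaged over epochs.

3. **Behavior.** Horizontal activity counts summed over a scoring window
   (90 min by default) per subject, and social-interaction time per pair
   of animals (the pair is the statistical unit).

4. **Group statistics.** Within each arm, values strictly beyond two
   sample standard deviations from the arm mean are removed in a single
   pass; endpoints are normalized to percent of the reference-arm mean
   for reporting; a one-way fixed-effects ANOVA on the raw values is
   followed by Dunnett's two-sided many-to-one comparisons against the
   reference arm (single-step multivariate-$t$ adjustment, via
   **multcomp**), with significance tiers $0.05/0.01/0.001/0.0001$.

## The generative model

The simulator is designed so that each analysis stage has an analytic
target, not to be biophysically detailed. A recorded channel is the sum of:

- **Evoked component**: a sinusoid at the 50-Hz train rate, active on
  $[0, 500)$ ms after each onset, whose phase is redrawn each trial from a
  von Mises distribution with concentration $\kappa$. The population PLF
  of this component is the mean resultant length
  $A(\kappa) = I_1(\kappa)/I_0(\kappa)$, so $\kappa$ is the single
  phase-synchrony knob with a closed-form answer
  (`plf_population()`, inverted by `kappa_from_plf()`). A trial-jittered
  sinusoid was chosen over a superposition of click-evoked transients
  because validation needs this analytic target. Trial phases are shared
  across channels (both cortical sites entrain to the same stimulus);
  background noise is independent per channel.
- **Background**: $1/f^{\alpha}$ noise (spectral synthesis, exact slope by
  construction; default $\alpha = 1$, RMS 8 µV) plus a band-limited
  32–80 Hz component of RMS `gamma_scale` µV (default 15). Doubling
  `gamma_scale` multiplies expected gamma band power by exactly 4, which
  is how drug arms with elevated spontaneous gamma are built
  (amplitude ratio $\sqrt{4.06}$ yields a ~406% band-power arm).
- **Artifacts**: biphasic 200-ms transients (one positive, one negative
  100-ms lobe, peak $\pm 600$ µV by default, peak-to-peak twice the peak)
  with Poisson timing. The shape deliberately exercises both rejection
  rules: the $\pm 300$ µV sample rule and the 400 µV peak-to-peak rule.
- **Behavior**: activity counts are negative-binomial around a per-bin
  mean profile (dispersion 0.4 by default — chosen so the between-subject
  scatter of 90-min totals matches the standard errors reported for this
  kind of assay, roughly SD ≈ 730 counts at a mean of ~3300); social
  times are normal truncated to $[0, 600]$ s.

**Between-subject heterogeneity.** Arms built with `study_arm(plf_mean =,
plf_sd =)` draw each subject's population PLF from a truncated normal
(default SD 0.07) and invert it to $\kappa$; background gamma amplitude
gets a mean-preserving log-normal jitter with CV 0.25. These defaults
were set so that simulated percent-of-reference group SEMs at $n = 8$
land in the 3–8 point range typical of published telemetry studies of
this design; without them the pipeline recovers group effects with
unrealistically small standard errors.

The canonical two-arm design (`default_assr_study()`) encodes a
vehicle arm (population PLF 0.85, activity ≈ 287 counts/90 min, social
≈ 57 s) against an MK-801-like arm (population PLF ratio 0.4, gamma
amplitude ratio $\sqrt{4.06}$, activity ≈ 3334 counts, social ≈ 13.9 s).

### What the generator does *not* emulate

No biophysical circuit (PING/interneuron) dynamics, no pharmacokinetics,
no volume conduction or multi-electrode spatial structure, no line noise,
no movement or state (sleep/wake) nonstationarity, and independent
sessions rather than a Latin-square repeated-measures schedule. Passing
tests therefore demonstrate that the *estimators* behave as specified on
signals with the assumed statistical structure — they do not validate the
pipeline against the full complexity of telemetry EEG.

## Numerical choices

- **Morlet definition.** Gaussian-windowed complex exponential with total
  support $n_c / f$ seconds for $n_c$ cycles, so the half-length is
  $n_c/(2f)$ — 93.75 ms for 9 cycles at 48 Hz, the constant the region
  trim of 100 ms rounds up from. The Gaussian $\sigma_t$ is support/7, so
  the envelope is essentially zero at the truncation points; kernels are
  unit-energy normalized with odd length. Cells where the kernel overhangs
  the epoch are flagged invalid and excluded from all region means.
- **PLF reading.** "Unit-normalize each epoch's coefficient, average
  across epochs, take the magnitude" — i.e. the standard inter-trial
  coherence, with the magnitude taken *after* epoch averaging and region
  aggregation done on the epoch-averaged map. Zero-magnitude cells are
  excluded from the average. The alternative reading (averaging
  magnitudes of normalized amplitudes) is degenerate (identically 1) and
  was discarded.
- **Frequency/time grid.** 0.5-Hz steps over $[48, 52]$ (9 frequencies),
  every time sample.
- **Window trim.** Both baseline and ROI are trimmed by 100 ms at *both*
  ends (effective windows $[-400, -100]$ and $[100, 400]$ ms): symmetric
  protection against kernel smearing across the stimulus transition and
  the epoch edges.
- **Rejection conventions.** Both thresholds are strict ("exceeds"):
  samples exactly at $\pm 300$ µV and epochs at exactly 400 µV
  peak-to-peak are retained. An epoch bad on either channel is dropped
  for both (conservative; per-channel screening is available). The order
  is fixed as extract → offset-correct → reject. Events whose window
  leaves the recording are dropped, not zero-padded, because padding
  would corrupt wavelet edges.
- **Periodogram scaling.** One-sided, energy-normalized:
  $P_k = 2\lvert X_k\rvert^2 / (N \sum_n w_n^2)$ (half that at DC and
  Nyquist). This makes the spectrum Parseval-consistent (bins sum to the
  windowed mean square) and gives a bin-centered unit-amplitude sinusoid
  a total leaked band power of $A^2/2$ regardless of the window. With a
  coherent-gain ($\bigl(\sum w\bigr)^2$) normalization the same tone's
  3-bin leakage sum would be $1.5 \times A^2/2$, breaking both
  properties, which is why energy normalization is used. No detrending
  beyond the window; no 50-Hz notch (the gamma band includes 50 Hz —
  flagged because on real recordings mains contamination would sit in
  band).
- **Band endpoints.** 32 and 80 Hz are both included ("within the band
  32–80 Hz"); band power is additive over any split of the discrete grid
  under this convention. Session aggregation is the mean over retained
  epochs.
- **Outlier rule.** Single pass (a one-line rule cannot support
  iteration), group-wise mean and sample SD ($n-1$) including the
  candidate, strict threshold. With $k = 2$ an arm needs at least 6
  values before any removal is even possible (the maximum achievable
  z-score in an arm of $n$ values is $(n-1)/\sqrt{n}$), which the tests
  document as small-$n$ masking.
- **Scale of testing.** ANOVA and Dunnett run on raw endpoint values;
  percent-of-reference is reporting-only. If the reference-arm mean is
  not positive, normalization is flagged and raw values are reported.
- **Activity windows** must align with bin edges; no pro-rating, so
  endpoints stay exact. The pair is the unit for the social endpoint
  (one score per couple).
- **EDF I/O** is written directly (16-bit, physical microvolts, 1-s
  records, zero-padded final record with the true length stored in the
  reserved header field), with round-trip error bounded by one
  quantization step.

## Estimator bias and the attenuation design

The finite-trial PLF estimate is positively biased: $N$ uniform phases
give an expected resultant of $\sqrt{\pi}/(2\sqrt{N})$ (≈ 0.023 at
1500 trials; `rayleigh_plf_expectation()`), and baseline cells sit at
this floor (slightly above it, because consecutive 1.5-s epochs of a
1.2-s cycle share 0.3 s of signal). The ROI-minus-baseline contrast
subtracts this floor from both arms, so the percent-of-reference of a
drug arm with population ratio $r$ converges to a value slightly below
$100r$; at 1500 trials the residual bias is roughly 1–3 points. The
package's attenuation-recovery checks therefore (i) use the design the
property is stated for — two arms identical in everything except the
trial-phase concentration — and (ii) judge the recovered percentage
against the studies' own simulated standard errors. In the combined
phenotype design, the drug arm's elevated gamma background additionally
lowers its wavelet-band signal-to-noise ratio and drags the recovered
percentage a few points further down; that design is checked
qualitatively (direction and magnitude class of all four endpoints), not
against $100r$.

## Simulation sizes

Simulation studies in the test suite and the acceptance script run at
reduced, stated sizes chosen as the package's own verification scale:
sampling rate 500 Hz (ample for a 50-Hz response and an 80-Hz band edge;
the 1000-Hz default matches the 0.25-Hz × 0–500 Hz spectral grid of the
full protocol), one simulated channel, the full 1500-stimulus protocol
for attenuation recovery, 8 subjects per arm, five replicate studies for
the power check, 2000 replicate null studies for the Dunnett family-wise
error check, and a 10-min spontaneous recording for band-power endpoints
(150 four-second epochs per subject). Closed-form checks (Bessel-ratio
recovery, Rayleigh floor) use noise-free jittered sinusoid epochs, where
Monte-Carlo standard errors are known.

## Known limitations

- The PLF contrast is a biased estimate of the population contrast at
  small trial counts; cross-study comparisons should hold the retained
  epoch count roughly constant (the report logs per-stage counts for
  this reason).
- The generator's artifact model is a fixed biphasic shape; real
  telemetry artifacts are heterogeneous, so rejection rates on real data
  will differ.
- The 2-SD outlier rule is ineffective below $n = 6$ per arm and can
  mask single extreme values at small $n$; it is implemented as
  specified, not as recommended practice.
- Dunnett p-values use quasi-Monte-Carlo multivariate-$t$ integration
  (accuracy ~$10^{-3}$); exact ties at the significance tiers are
  resolved by that integration, not analytically.
- The telemetry implant's true sampling rate and hardware filters are
  not modeled; the 1000-Hz default is inferred from the spectral grid
  (0.25-Hz resolution, 0–500 Hz range with 4-s epochs implies 1 kHz).

## A worked miniature

```{r example, eval = FALSE}
library(gammassr)

# two-arm study, scaled down for a quick run
cfg <- pipeline_config(
  fs = 500, channels = "auditory_cortex",
  protocol = list(n_stimuli = 300L),
  qeeg = list(duration_s = 300)
)
study <- run_study(default_assr_study(seed = 5, n_per_arm = 8), cfg)
study$report
plot_report(study$report)

# the fitted statistics layer is broom-friendly
fit <- anova_dunnett(study$endpoints$assr_plf, reference = "vehicle")
tidy(fit)
glance(fit)
```
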