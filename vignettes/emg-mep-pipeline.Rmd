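---
title: "Quantifying evoked and voluntary forelimb EMG after cervical spinal cord injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evoked and voluntary forelimb EMG after cervical spinal cord injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepkit)
```

## The measurement problem

After a cervical (C7) contusion injury, forelimb muscle function in the
rat can be followed longitudinally with intramuscular differential EMG
from the biceps. Two complementary read-outs are used:

* **Motor evoked potentials (MEPs)** — responses of the biceps to
  epidural electrical stimulation of the motor cortex, recorded while
  the animal moves freely. Stimulation is delivered as short trains
  (five 0.2 ms biphasic pulses at 500 Hz) every 2 s; 60 stimulus-locked
  sweeps are acquired at 20 kHz and the 20 with the least spontaneous
  activity are averaged. The response is quantified on the averaged,
  rectified trace as its area under the curve (AUC, mV·ms) and its
  duration between onset and offset.
* **Maximum voluntary contraction (MVC)** — biceps activity during a
  grip-strength pull, three timestamped ~8 s trials per forelimb. Each
  trial's trace is low-pass filtered, the timestamped portion rectified
  and integrated; trial AUCs are averaged per limb and then across the
  two forelimbs.

Group comparisons follow the study design: one-way ANOVA with Tukey or
Bonferroni post-hoc tests at single time points, a two-way
repeated-measures (split-plot) ANOVA with Greenhouse–Geisser correction
for the weekly panels, and exact Mann–Whitney U tests for the small
anatomical groups of the motor-neuron pool mapping.

Because the underlying raw recordings are not publicly deposited, the
package ships a seeded synthetic-session generator whose statistical
structure matches the assumptions of the analysis, with full ground
truth for every simulated quantity. All pipeline guarantees quoted
below are measured on that generator; the per-animal motor-neuron
count table is real published data and is packaged as a plain-text
fixture.

## Signal conditioning

The MEP chain applies, per sweep and in this order: full-wave
rectification, a centred 5-point moving average, a zero-phase low-pass
filter at 230 Hz, and DC-offset correction against the pre-stimulus
baseline window. The MVC chain deliberately differs: the raw trace is
low-pass filtered *first* and the timestamped portion rectified
afterwards. Both orders are locked by tests on a zero-mean tone, where
they give very different results (rectification creates a DC component
proportional to the tone amplitude; filtering first removes the tone
entirely).

The low-pass step of this protocol calls for a very steep cutoff at
230 Hz; we implement a zero-phase (forward–backward) Butterworth of
configurable order, default 8 per pass. The filter is
realised as a cascade of second-order sections rather than a single
transfer function: at a normalised cutoff of 230 Hz / 20 kHz a
high-order transfer function loses several digits to coefficient
rounding, while the biquad cascade passes a constant with an error
below 1e-12. Edges are handled by reflection padding sized to ~25
filter time constants, so short sweeps are not contaminated by filter
transients. A companion high-pass is provided for band-limiting in the
generator.

Stimulus-aligned epochs default to (−50, +100) ms around each train
onset (the source does not state a window). The first 3 ms after the
stimulus are blanked (replaced by the sweep's pre-stimulus mean) to
remove the stimulus artifact. The manual selection of "clean" sweeps is
automated as the `k` sweeps with the lowest pre-stimulus rectified RMS,
with ties broken by acquisition order; only pre-stimulus samples enter
the score, so the selection can never be influenced by the response
itself.

## Response detection and its operating point

A response is declared when the preprocessed average exceeds a
threshold relative to the pre-stimulus baseline — the classic "15%
deviation from baseline" criterion — sustained for a minimum run
length. Two practical guards are needed to make this rule operational:

* Because the DC correction zeroes the baseline window, the measured
  baseline of a preprocessed average is close to zero, and a purely
  relative criterion (1.15 × baseline) degenerates. The detection
  threshold is therefore `max(baseline * 1.15, baseline +
  abs_floor_mV)`.
* The residual noise of a 20-sweep average at the default background
  level (0.05 mV RMS, 20–1000 Hz) has a standard deviation of about
  0.0025–0.003 mV after the 230 Hz low-pass, and its correlation time
  is a few milliseconds. An absolute floor of 0.005 mV (≈2σ) combined
  with a 1 ms run requirement fires on essentially every noise-only
  average. The defaults are therefore set at `abs_floor_mV = 0.01`
  (≈4σ of the averaged residual) and `min_run_ms = 3` (longer than the
  filter's correlation time, so a single noise swing cannot qualify as
  "sustained"). With this operating point, noise-only averages tested
  negative in 30/30 seeded sessions while responses at the default
  burst amplitude are detected in every seed.

Onset is the start of the first qualifying suprathreshold run in the
post-stimulus search window (default 3–100 ms), offset the end of the
last one; AUC is integrated between these bounds, so duration and AUC
always refer to the same interval. On noiseless synthetic
MEPs the pipeline recovers onset and offset within ±1 ms (typically
±0.1 ms) and AUC within 2% of the closed-form envelope integral. At
the default noise level, onset remains within ±1 ms; the *offset*
crossing sits on the shallow tail of the burst envelope, where
threshold-level noise moves the crossing by up to ±2.5 ms — a known
limitation of any level-crossing offset definition, documented rather
than hidden. AUC, which is dominated by the burst core, stays within a
few percent.

The stimulation threshold of an animal is the smallest current of an
ascending recruitment series whose analysed session is scored as a
response. Non-monotone detection across currents is reported with a
warning but still returns the smallest detected current.

## The synthetic-session generator

The generator produces `raw_session` bundles (CSV signal + JSON
sidecar) indistinguishable in structure from real acquisitions:

* **Background EMG**: band-limited Gaussian noise (20–1000 Hz, RMS
  0.05 mV), synthesised spectrally with the exact zero-phase amplitude
  response of the band-limiting Butterworth cascade and normalised to
  the nominal RMS per realisation, so closed-form expectations hold
  exactly.
* **MEP bursts**: a gamma-shaped envelope (shape 4; latency 8 ms;
  duration 15 ms, defined as the width at 10% of the peak) multiplying
  a 400 Hz carrier, phase-locked to each stimulus on the channel
  contralateral to stimulation. Stimulation at or above the animal's
  threshold evokes the burst with amplitude `amp_mV ×
  group-week multiplier × min(current/threshold, 2)`; below threshold
  nothing is evoked. A 1 ms biphasic transient at each train onset
  models the stimulus artifact (the per-pulse artifacts of the 500 Hz
  train are collapsed into this single transient, since they fall
  inside the blanking window by design).
* **Movement artifacts**: 2–10 Hz bursts (0.3 mV, ~0.5 s) at a Poisson
  rate of 0.1/s on both channels — the contamination that the
  clean-sweep selection and averaging are there to suppress.
* **MVC trials**: amplitude-modulated band-limited noise under a
  raised-cosine envelope covering 70% of each ~8 s trial, three trials
  per limb; grip-force readings share only a weak factor (0.15) with
  the EMG amplitude, so the dissociation between apparatus force and
  muscle activity can be reproduced and analysed.
* **Effect profiles**: per-group, per-week multipliers on burst
  amplitude. The defaults encode baseline parity (multiplier 1 at
  week −1), an acute post-injury drop to 0.4, a rise in the
  triple-treatment group beginning at week 4 and a plateau at 1.0 from
  week 6 through week 11, with untreated (0.40) and single-treatment
  (0.45) groups flat after injury.

Ground truth travels with each session. For MEP sessions the truth
contains the expected preprocessed average computed in closed form:
the rectified cycle-mean of the carrier burst plus Gaussian noise
(`E|A sinφ + N(0,σ)|`, averaged over carrier phase, minus the
rectified-noise mean removed by DC correction), its threshold
crossings, and its integral. For MVC sessions the expected trial AUC
is `∫ sqrt(2/π) · sqrt(ρ(σ² + a²env²)) dt`, where ρ is the variance
pass-ratio of the 230 Hz analysis filter on the generator's noise
band, computed deterministically from impulse responses. Recovery
tests compare pipeline output against these expectations — the ratio
of *expected AUCs* is the configured truth for cohort effect
recovery, because the raw amplitude-multiplier ratio ignores the
additive background floor that any rectified-AUC measure necessarily
carries.

What the generator does **not** emulate: motor-unit action-potential
trains (the burst is noise-like, not a sum of MUAPs), conduction
delays and their variability, electrode impedance drift, and
cross-talk between channels. Passing recovery tests on this generator
therefore demonstrates that the *analysis* is correct and calibrated
under its stated assumptions, not that those assumptions exhaust real
recordings.

## Statistics

All tests are implemented from first principles and cross-checked in
the test suite against independent routes (`aov` with error strata,
`TukeyHSD`, `multcomp`'s multivariate-t Dunnett, `wilcox.test`, and
hand-coded sums-of-squares and enumeration oracles):

* One-way fixed-effects ANOVA; with identical group means and no
  within-group variance, F is defined as 0 and p as 1.
* Tukey–Kramer and Bonferroni pairwise post-hocs on the pooled
  within-group mean square.
* Dunnett-style many-to-one comparisons with critical values from a
  seeded Monte-Carlo of the max-|t| null (2×10⁵ draws by default,
  ≈0.003 accuracy on p) — a deliberate choice to stay self-contained
  rather than depend on multivariate-t quadrature at run time.
* Split-plot repeated-measures ANOVA: the group effect is tested
  against subjects-within-groups, time and group×time against the
  within-subject residual. The Greenhouse–Geisser epsilon is computed
  from the pooled within-group covariance through orthonormal
  contrasts, clamped to its algebraic range [1/(k−1), 1], and applied
  unconditionally when requested (the non-integer degrees of freedom
  reported in this literature imply correction without a Mauchly
  gate). Only complete balanced panels are accepted — the longitudinal
  design uses complete cases with no missing time points.
* Exact Mann–Whitney U: mid-ranks for ties, two-tailed p as the
  fraction of all `choose(n1+n2, n1)` group assignments whose U
  deviates from `n1·n2/2` at least as much as observed. An enumeration
  guard (≤10⁶ assignments) directs larger samples to a normal
  approximation elsewhere. At 5 vs 3 animals every p is a multiple of
  1/56, which is exactly how the published values (.7857, .3928,
  .1428, and p < .05 at the lesion epicenter) arise.

## Motor-neuron pool mapping

The packaged count table (5 naïve, 3 injured animals × spinal levels
C2–T2) is analysed with per-level means and n−1 standard deviations,
per-animal totals, exact Mann–Whitney tests per level (levels with
all-zero counts in both groups are reported as non-testable), and a
group × level matrix of mean counts for heat-map display. A
negative-binomial count simulator with per-level means supports
power-style experiments around this analysis.

## Numerical and design choices

* All stored times are seconds; all reported analysis quantities are
  milliseconds and mV·ms. The conversion happens in one place.
* Weeks are coded numerically (baseline −1, post-injury 1–11, terminal
  12) so panels sort correctly without string tricks.
* Trigger counts are configurable (reported acquisition protocols vary
  between 30 and 60 acquired and 10–20 averaged); the default is
  acquire 60, select 20.
* Sweep cleanliness ties break toward earlier sweeps; selection and
  every simulation are deterministic given a seed, with derived
  sub-seeds below 2³¹ for portability. Seeded helpers restore the
  caller's RNG state.
* Scaled problem sizes used by the test-suite and the acceptance
  script: MEP property checks run at 4–20 kHz with 8–24 triggers;
  cohort calibration runs 200 replicates of 3 groups × 6 animals × 4
  weeks of single-trial MVC sessions at 800 Hz, and effect recovery 50
  replicates of 2 groups × 6 animals × 7 weeks. When sweep counts are
  scaled below the 60/20 design, the acquire/select ratio (3:1) is
  kept and the background RMS is scaled by `sqrt(k/20)` so the
  averaged residual noise — the quantity the detection operating point
  is calibrated against — matches the full design.

## Known limitations

* Offset timing at realistic noise carries a few-ms uncertainty (see
  above); duration measures inherit it.
* The Dunnett adjustment is Monte-Carlo based; p-values jitter at the
  third decimal across seeds.
* The exact Mann–Whitney is limited to small samples by construction.
* The generator's closed-form MVC expectation treats the contraction
  envelope as slowly varying relative to the analysis filter; at trial
  durations well below ~0.5 s that approximation would degrade.
* Movement artifacts make session AUCs mildly heavy-tailed, so the
  longitudinal group F test runs slightly hot (measured ≈6–7% rejection
  at nominal 5% on scaled 0.8 s trials, where an artifact carries about
  ten times the relative weight it has in a full 8 s trial). The MVC
  chain has no artifact-rejection step — trials are defined by their
  behavioural timestamps — so this is a property of the analysis, not a
  bug in the test.
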