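---
title: "Models and methods behind mbceus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbceus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbceus)
```

# Scope

`mbceus` quantifies three ultrasound readouts of antiangiogenic response
in small-animal tumour models — differential targeted enhancement (dTE)
from destruction-replenishment exams with VEGFR2-targeted microbubbles,
non-perfused tumour area at peak arterial enhancement, and tumour-to-pad
strain ratios — and provides the growth arithmetic and nonparametric
statistics used to compare treatment arms. A synthetic generator
produces every input the analysis consumes, so each stage is testable
without instrument data.

# Display compression and linearization

Scanners show echo power on a logarithmic scale. We model the display as

$$D = \mathrm{round}\Big((L-1)\,\mathrm{clamp}\big(1 +
\tfrac{10\log_{10}(E/e_{ref})}{dr},\,0,\,1\big)\Big)$$

with $L = 256$ levels, dynamic range $dr$ in dB and full-scale power
$e_{ref}$ (a.u.), and *linearization* as its exact inverse
$E = e_{ref}\,10^{dr(D/(L-1)-1)/10}$. Quantification must run on
linearized values: means of display values are not proportional to
bubble counts, means of powers are.

Numerical conventions, chosen so the error bound is exact:

- rounding is half-away-from-zero, making the worst-case round-trip
  relative error exactly $10^{dr/(10\cdot 2\cdot 255)} - 1$
  (`roundTripTolerance()`; about 0.32% at 7 dB, 1.8% at 40 dB);
- zero power maps to level 0 (the log is clamped, never an error);
  out-of-range powers clamp to the scale ends.

The contrast protocol we emulate ran at 7 dB displayed dynamic range — an
unusually narrow setting — so the law is configurable everywhere and the
simulator defaults to 40 dB, which keeps a realistic spread of tissue and
contrast levels on the display. Every quantitative test pins its own law.

# Kinetic model of the simulated exam

The generator's purpose is to produce data with the statistical structure
the window-subtraction analysis assumes, with every assumption explicit
and breakable.

Circulating concentration is a gamma-variate first pass

$$g(t) = A\,(t/t_p)^{\alpha} e^{\alpha(1-t/t_p)}$$

(unimodal, peak $A$ at $t_p$; the standard perfusion bolus kernel) plus a
recirculating pool $A f_{rec}(1-e^{-t/\tau_{rec}})e^{-t/\tau_w}$ that
sustains the circulating signal at the 6-minute exam point. Defaults:
$A = 100$ a.u., $t_p = 12$ s, $\alpha = 2$, $f_{rec} = 0.1$,
$\tau_{rec} = 60$ s.

The washout constant $\tau_w$ defaults to infinity: the dTE analysis
attributes the entire difference between its two windows (27 s apart) to
bound bubbles, i.e. it assumes clearance is negligible on that timescale.
The generator adopts that null structure as its default so that the
zero-binding control is exactly zero up to quantization; a finite
$\tau_w$ is available to measure the clearance bias of the window
subtraction, which the default deliberately excludes.

Binding accumulates as $B(t) = \rho\,k_{on}\int_0^t C(s)\,ds$ (cumulative
trapezoid; $\rho$ receptor density, $k_{on} = 0.03$ /(a.u. s) by default,
placing dTE in the few-hundred-a.u. range typical of such exams while
keeping peak pixel power inside the default display range). The
1-second flash at 360 s zeroes both in-plane pools; circulating signal
relaxes back to its unflashed trajectory with $\tau_{repl} = 2$ s
(out-of-plane blood), while the bound pool does not re-form within the
remaining 24 s of the exam — re-binding on that timescale is negligible
compared with the accumulated pre-flash pool, and modelling it as zero
makes the true dTE exactly the pre-flash bound signal.

Rendering: perfused tumour pixels carry
$E = \mathrm{gain}(C + B\,\rho_{map})$, necrotic and extra-tumoural
pixels a tissue background (1 a.u.); multiplicative Gaussian noise of
configurable sd stands in for speckle; flash frames are rendered
saturated, as on real systems. The exam timeline is two 30-second clips
(0–30 s arterial, 355–385 s bracketing the flash) at 10 Hz, matching a
protocol with a second clip from 5 min 55 s and an 18-second
replenishment assessment after the 6-minute flash.

# dTE quantification

`computeDTE()` averages the curve over $[t_f - 2, t_f)$ and
$[t_f + 15, t_f + 25)$ seconds, with $t_f$ the flash *onset*, and
subtracts. Decisions a reader should know:

- **Onset, not end, anchors the windows.** The protocol's wording ("the
  10 seconds following the 15th second after the flash") does not say
  which; measured from onset the post window is exactly the last 10 s of
  the second clip, measured from flash end it would overrun the
  recording. Onset is the only self-consistent reading.
- **Windows are half-open** $[start, end)$, frames assigned by
  timestamp; flash frames are excluded from both windows (saturated,
  non-physical).
- **TE is the mean, not the sum,** of per-pixel linearized power, so dTE
  is comparable across tumours of different ROI sizes.
- **Negative dTE is not clamped**; the downstream statistics are
  rank-based and unaffected, and clamping would bias noise studies.
- `detectFlash()` trusts metadata when present; otherwise it takes the
  maximal run of frame means above median + 6 MAD of all frame means, and
  errors when nothing qualifies rather than guessing.

# Non-perfused area

The original scoring was visual: two blinded readers grade the
non-enhanced fraction at peak arterial enhancement on a 10% step scale,
disagreements resolved by discussion. The package operationalizes this
as: peak frame = maximum of the linearized ROI curve within the first
30-second clip (ties to the earliest frame); a pixel is non-enhanced when
its power is below `thresholdFactor` (default 2) times the median power
outside the ROI; quantization is to the nearest multiple of 10 with
halves rounding up; and consensus of two discordant quantized readings is
the quantized mean of the raw fractions — a deterministic stand-in, since
consensus-by-discussion is not reproducible. The two simulated readers
differ by their threshold factors (2.0 and 2.5 in `runStudy()`). A
degenerate background (no pixels outside the ROI, or zero median) is an
error, never silently scored.

# Elastography

Strain images are taken as given — scanners compute them internally from
tissue deformation under manual compression, and that processing is out
of reach. The elasticity ratio is mean tumour strain over mean
reference-pad strain; because the pad has constant consistency, the ratio
cancels the unmeasured compression force (scale invariance, asserted in
the tests, is exactly the property that makes manual compression
acceptable). Three replicate measurements per examination are averaged
(`triplicateMean()`), replicates retained for audit. The generator gives
the pad uniform strain and tumour pixels the pad level times the true
ratio plus zero-mean noise, replicates differing only by noise.

# Growth cohorts and statistics

Volumes use the xenograft convention height x width x thickness / 2.
The generator grows volumes day-by-day piecewise-exponentially: untreated
rate 0.075/day (about +79% over 8 days, matching placebo-arm regrowth),
on-drug rate 0.01/day (near arrest), and after a *permanent* stop the
untreated rate times a rebound multiplier (default 1.05, making regrowth
after definitive withdrawal comparable to placebo — the study's headline
observation); a temporary interruption grows at the plain untreated rate.
Per-animal lognormal noise enters the baseline volume (sd 0.45,
reproducing the several-fold spread of starting volumes) and a per-animal
rate multiplier (sd 0.15, giving within-group delta spreads like the
published ranges). Diameters are reported as a cube-root triple with
fixed anisotropy (1.1, 1, 1/1.1) — per-axis statistics were never
published, so any fixed anisotropy is equally defensible and this one
reconstructs the volume exactly.

Response deltas are computed **per animal, then summarized**
(median-of-deltas). The distinction matters: group medians moving from
143 to 706 mm^3 suggest +394% while the median per-animal delta of the
same arm is +197%; the tests pin a fixture where the two differ.

Statistics follow the conventions of the original analyses, two-sided
throughout, no multiple-testing correction (none was applied), animals
lost before reassessment excluded listwise:

- **Kruskal-Wallis** delegates to `stats::kruskal.test` (tie-corrected H,
  chi-square reference); all-identical data return p = 1 by convention.
- **Mann-Whitney** is exact by default for groups of up to 10 (the study
  arms had 4–6 animals): with no ties via the closed-form null
  (`stats::pwilcox`), with ties by enumerating all assignments of the
  observed multiset. The asymptotic mode uses the tie-corrected normal
  approximation *without* continuity correction, so its p squares to the
  two-group Kruskal-Wallis — an identity the tests assert. Note the
  published p = 0.019 for the group 1 vs 3 perfusion comparison is not
  reachable by exact enumeration (complete separation of 4 vs 4 gives
  2/70 = 0.029); the original SPSS setting is unknown, and the package
  documents rather than chases the discrepancy.
- **Wilcoxon signed-rank** drops zero differences (all-zero pairs:
  p = 1), enumerates all $2^n$ sign assignments of midranks for
  n <= 15, otherwise uses the tie-corrected normal approximation.
- **Spearman** uses midranks; exact permutation p for n <= 8,
  t-approximation beyond.

# What the generator does and does not emulate

Emulated: bolus wash-in and recirculation, receptor-proportional binding,
flash destruction and circulating-only replenishment, log-compressed
8-bit display, multiplicative noise, central necrosis as an exact pixel
count, three treatment schedules, lognormal animal heterogeneity,
replicate strain measurements. Everything is a pure function of
(parameters, seed) — byte-identical reruns are an acceptance property.

Not emulated: acoustic wave propagation, beamforming, spatially
correlated (Rayleigh) speckle, probe or respiratory motion (the modelled
protocol fixed the probe mechanically), attenuation and time-gain
compensation (treated as identity), sorafenib pharmacokinetics, and
absolute microbubble counts (only relative a.u.; injected doses were
reported per gram but animal masses were not). Passing tests therefore
demonstrate correctness of the quantification arithmetic and its
statistical behaviour under the stated model, not robustness to motion,
attenuation or speckle correlation in real recordings.

# Problem sizes and runtime choices

Tests and the acceptance script run cine simulations at 24–48 px frames,
10 Hz (5 Hz in the end-to-end study runs), 600 frames per exam; Monte
Carlo checks use 20 seeds (dTE linearity, perfusion noise), 300–500
replicates (strain recovery) and 100 seeds (Mann-Whitney power). These
sizes give the assertions comfortable margins while keeping the whole
suite in the tens of seconds on one CPU; all scale linearly if larger
checks are wanted.

# Known limitations

- The compression law of any given scanner is proprietary; ours is a
  convention, and dTE values are comparable only within one law.
- The perfusion threshold (2x background median) is an operationalization
  of a visual call; absolute agreement with human readers is untested.
- Group-level effect sizes in `studyConfig()` (receptor densities,
  necrotic fractions, strain ratios per arm) are calibrated to reproduce
  *directions* of published effects, not their unpublished per-animal
  magnitudes; direction-of-effect tests are the appropriate strength of
  claim.
- Exact tests enumerate; with ties and more than ~10 per group the
  Mann-Whitney exact mode refuses and points to the asymptotic mode.
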