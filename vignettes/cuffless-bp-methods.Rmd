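---
title: "Estimating blood pressure from local pulse wave velocity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from local pulse wave velocity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufflessbp)
```

## The measurement problem

A pressure pulse launched by each heartbeat travels along the arterial tree
at a speed — the pulse wave velocity (PWV) — set by the vessel wall's
stiffness, and wall stiffness rises with distending pressure.  If two
sensors sit on the radial artery a fixed distance $L$ apart (3 cm here),
the transit time (PTT) of each beat between them gives a *local* PWV,
$\mathrm{PWV} = L/\mathrm{PTT}$, and a hemodynamic model can convert that
speed into pressure without any per-subject cuff calibration.  This package
implements the full software chain of such a device — waveform synthesis,
analog-front-end design calculators, FIR pre-filtering, beat detection,
transit-time estimation, model inversion and agreement statistics — so that
every stage is testable against known ground truth.

## The hemodynamic model

Two relations are composed:

* **Moens–Korteweg**: $\mathrm{PWV} = \sqrt{E_{inc} h / (D \rho)}$ with
  lumen diameter $D$, wall thickness $h$ and blood density $\rho$
  (1060 kg/m³);
* **exponential wall stiffening** (Hughes-type law):
  $E_{inc} = E_0 e^{\xi P}$, with defaults $E_0 = 1428.7$ and
  $\xi = 0.031$.

Composing and solving for pressure gives the closed form implemented in
`mk_inverse()`:
$P = \ln\!\left(\mathrm{PWV}^2 \rho D / (h E_0)\right) / \xi$.
The returned pressure is interpreted as mean arterial pressure (MAP).

**Units.** $E_0$ and $\xi$ are taken on the mmHg pressure scale and the
modulus is converted to Pa (133.322 Pa/mmHg) before the square root, with
$D$, $h$ in meters.  No units are stated alongside the literature values of
$E_0$ and $\xi$; this reading is adopted because it is the only one that
produces arterial wave speeds of the right order (roughly 10–30 m/s for a
radial artery between 70 and 110 mmHg).  A regression test pins the
conversion-order convention (`test-hemo.R`).

**Sensitivity.** Since $dP/d\mathrm{PWV} = 2/(\xi\,\mathrm{PWV})$, a 1 %
velocity error moves MAP by $\approx 0.02/\xi \approx 0.645$ mmHg
irrespective of geometry.  Conversely the one-sample quantization of PTT
bounds the MAP error by $(2/\xi)\,\Delta\mathrm{PTT}/\mathrm{PTT}$ — the
yardstick used by the recovery tests.

**MAP split.** The device convention `split_map()` maps MAP to a
systolic/diastolic pair through a factor $k = 0.76$:
$\mathrm{DBP} = k\,\mathrm{MAP}$,
$\mathrm{SBP} = \mathrm{MAP} + (1-k)\mathrm{DBP}$.  This pair does *not*
invert the cuff approximation $\mathrm{MAP} = (\mathrm{SBP} +
2\,\mathrm{DBP})/3$; the package implements the convention as stated,
documents the inconsistency in a test, and offers
`method = "consistent"` ($\mathrm{SBP} = 3\,\mathrm{MAP} -
2\,\mathrm{DBP}$) behind a flag.  The default follows the device.

## Signal chain

### FIR pre-filter

`design_bandpass()` builds the Kaiser-window FIR bandpass: a windowed ideal
bandpass impulse response, $N + 1$ taps centered at $N/2$ (so the group
delay is the integer $N/2$ samples), digital angular frequencies
$\omega_c = 2\pi f_c / f_s$, and the singular center sample replaced by its
limit $(\omega_{c2}-\omega_{c1})/\pi$.  Defaults: $N = 128$,
passband 0.6–5 Hz at $f_s = 10$ kHz — i.e. 36–300 beats/min, bounding the
detectable heart rates.  $\beta$ defaults to 6 (roughly 60 dB sidelobes);
the device's own $\beta$ is not public, and no test depends on a specific
$\beta$ beyond the passband/stopband contracts.

An important structural observation, verified numerically in the tests: at
the default $N/f_s = 12.8$ ms the kernel is far too short to resolve a
0.6 Hz edge (that requires a support of order $1/f_{c1} \sim$ seconds).
All 129 taps come out positive and the realized response is a gain
$\approx 0.056$ smoothing kernel that **retains the signal mean**.  The
design equations are implemented faithfully and the nominal
passband/stopband properties (DC gain below $10^{-3}$ of the passband,
$\ge 40$ dB contrast between 2 Hz and 50 Hz) are asserted on a *resolved*
configuration ($f_s = 200$ Hz, $N = 2000$, a 10 s kernel) where a true
bandpass is realizable.  The DC-retaining behaviour of the default filter
is not an implementation defect — it is load-bearing for the detector
below.

Because the taps are symmetric, filtering both channels with the same
coefficients delays every feature by the same $N/2$ samples, so transit
times are invariant to the filtering; the group delay is reported in trace
metadata rather than trimmed.

### Dynamic-gradient beat detector

`detect_features()` is a single-pass, constant-memory peak/trough detector.
Per sample it maintains the trailing-window ($M$ samples) mean, RMS and
standard deviation with two running accumulators plus the eviction stream —
the retained state is eight numbers regardless of trace length — and forms
the hysteresis threshold

$$\mathrm{gradient} = \mathrm{RMS}\cdot\frac{CV}{100}\cdot gain,
\qquad CV = 100\,\frac{\sigma}{|\mu|},$$

with the uncentered window variance $\sigma^2 = \sum (x_k-\mu)^2/M$.  (The
coefficient of variation is the textbook reading of the threshold's
"rate-of-change" factor; a literal transcription of the printed dispersion
formula collapses to zero because deviations from the mean sum to zero.)
A zero window mean is treated as a flat signal: $CV = 0$, gradient 0.  The
threshold scales linearly with the signal, so detection is invariant to
amplitude re-scaling — different subjects' pulse amplitudes need no
per-subject tuning.

The state machine (`detector_step()`) tracks a running local maximum and
minimum.  In emission state, when the value falls below
$\text{local max} - \text{gradient}$, the stored maximum is emitted as a
peak and the minimum is reset to it; out of emission state, a rise above
$\text{local min} + \text{gradient}$ emits the stored minimum as a trough
and resets the maximum.  Kinds therefore strictly alternate.  Numerical
choices, each fixed and tested:

* **Initialization**: local max $-\infty$, local min $+\infty$, emission
  state *on* — the first excursion registers correctly for either polarity.
  A consequence: the first event of any finite recording is a peak, so an
  $n$-beat recording yields $n$ peaks and $n-1$ feet.
* **Ties**: strict inequalities, so plateaus keep the first sample's index.
* **Warm-up**: no emissions until $0.1\,M$ samples have been seen; until a
  full window is available the statistics use all samples so far.
* **Window**: $M = f_s$ (one second) by default; $M = f_s/2$ tracks
  strongly alternating rhythms, which the tests exercise with a 50/100 bpm
  alternating train.
* **Gain** 1.1; on low-SNR traces a larger gain produces no more events
  than a smaller one (false-positive suppression, asserted at ~6 dB peak
  SNR).

The detector's threshold statistics assume a signal with nonzero mean
(unipolar baseline), which is exactly what the default short FIR delivers.
A genuinely DC-free bandpass would drive $|\mu| \to 0$, $CV \to \infty$ and
suppress all events — one more reason the device's under-resolved filter
and its detector must be understood as a matched pair.

The streaming implementation is verified *exactly* (event-for-event)
against an offline oracle that recomputes the window statistics from
scratch at every sample and replays the state machine in R.

### Pairing, PTT and PWV

`pair_beats()` matches each proximal event with the earliest subsequent
distal event of the same kind within `max_ptt` (default 50 ms, a loose
physiologic bound: $\ge 0.6$ m/s over 3 cm), non-crossing, dropping and
counting the unpaired.  For beat trains whose spacing exceeds `max_ptt` —
always true physiologically — this equals the total-lag-minimizing
non-crossing assignment, which the tests confirm against an exhaustive
dynamic-programming oracle on small random trains with dropouts.

The default pairing mode is **peak-to-peak**: the transit time of the
device chain is defined between the peaks of the two channel outputs, and
only peaks exist in equal number to beats (see the initialization note
above — feet number one fewer on a finite recording, so a 30 s, 60 bpm
recording yields its 30 transit samples only from peaks).  Foot-to-foot
pairing remains available via `mode = "ff"` for waveforms whose crests are
distorted by reflections.

`compute_ptt()` is the index difference over $f_s$ — resolution one sample
(0.1 ms at 10 kHz); no sub-sample interpolation is applied by default, so
quantization is the dominant noise-free error term.  Beat-wise PWV values
are aggregated by the **median** (`aggregate_pwv()`), which tolerates
corruption of any minority of beats.

## The synthetic generator

`generate_dual_channel()` emulates what the device records and nothing
more:

* a quasi-periodic train of asymmetric gamma bumps
  $g(\tau) = (\tau/t_p)^a e^{a(1-\tau/t_p)}$ (unit peak at
  $t_p = 0.12$ s, shape $a = 2$; template support capped at
  $\min(6 t_p, \text{beat interval})$, last partial beat truncated) — a
  single dominant crest per beat with fast rise and slow decay, which is
  the morphology the detector needs and all it assumes;
* channel 2 as an integer-sample shift ($\mathrm{round}(\mathrm{PTT}\cdot
  f_s)$) of channel 1's clean train — the ground truth is quantized to the
  sample grid because that is the resolution of the measuring chain itself;
* shared per-beat amplitude jitter (a beat is the same size at both
  sensors), independent per-channel sinusoidal baseline wander and white
  noise.  Defaults (amplitude 300 mV, jitter 2 %, wander 20 mV at 0.3 Hz,
  noise 5 mV) were chosen once as plausible for an amplified piezoelectric
  pulse signal; recordings of the real device are not public, so these are
  stand-ins, stated here and not revisited.

What the generator deliberately does **not** model: dicrotic notches and
reflection peaks, motion artifacts, arrhythmia beyond explicit beat-time
lists, sensor coupling drift.  Passing tests therefore demonstrate
correctness of the *algorithms* under their stated assumptions, not
clinical performance on real skin-coupled recordings.

`generate_subject()` and `generate_cohort()` supply hemodynamic ground
truth: MAP drawn from 70–110 mmHg, lumen diameter 2.0–3.0 mm, wall
thickness 0.2–0.4 mm (plausible radial values; the clinical cohort's
per-subject numbers are not published, and the ranges are overridable).
Each subject's PWV/PTT follow from the forward model, so the whole chain
closes: synthesize at the subject's true PTT, measure, invert, compare.

## Analog front end

The calculators implement the design equations directly: load resistance
$R_1 = 1/(2\pi f C_p)$ (15–28 MΩ for the 8 nF ± 30 % sensor at 1 Hz),
Sallen-Key natural frequency $f_c = 1/(2\pi\sqrt{R_a C_a R_b C_b})$
(high-pass 0.55 Hz, low-pass 10 Hz), the adiabatic cavity pressure law and
the film-on-gas resonance $\sqrt{\gamma S P_A/(\rho V L)}$ (about 1.3 kHz
for the default geometry — comfortably above the pulse band).  The optional
software simulation (`simulate_afe_chain()`) discretizes the two
second-order sections by the bilinear transform at the trace's sampling
rate — a standard, stable mapping; the hardware is analog and prescribes no
digital form — applies the gain stage as a non-inverting scalar (sign does
not affect timing), and is validated against the analytic transfer-function
magnitudes (agreement within 1 % at 2 and 50 Hz) and an ODE integration of
the cavity oscillator (0.1 %).

## Agreement statistics

`pair_references()` implements the alternating clinical protocol (4
reference, 3 device readings; device reading $i$ compared against the mean
of reference readings $i$ and $i+1$).  `iso_stats()` returns the mean
difference and the *uncentered* root-mean-square of differences exactly as
the standard's formula prints it (divisor $n$); because reported clinical
"standard deviations" may follow either convention, the centered $n-1$
standard deviation is returned alongside, clearly labelled, and the
identity $\mathrm{std}^2 = \mathrm{var}_n + \mathrm{md}^2$ is asserted
numerically.  `passes_iso()` applies the inclusive headline bounds
$|\mathrm{md}| \le 5$, $\mathrm{std} \le 8$ mmHg.  `bland_altman()` uses
$1.96\,\mathrm{sd}$ limits of agreement and emits the plotting coordinates.

## Problem sizes and verification scope

The test suite and the acceptance script run entirely on synthesized data:

* the beat-yield check uses the full stated condition — 30 s, 60 bpm,
  10 kHz, 5 ms delay — and must find exactly 30 transit samples;
* detector/oracle equivalence runs on 100 short random traces (300–400
  samples, $M = 40$–50) of three signal families;
* cohort recovery uses 32 subjects at 30 s each; with the default
  constants their PTTs over 3 cm are 1.0–2.4 ms (12–24 samples at 10 kHz),
  so quantization alone bounds each subject's MAP error by about
  2–3 mmHg, and the cohort-level statistics land near
  $|\mathrm{md}| \lesssim 0.5$, $\mathrm{std} \approx 1.3$ mmHg — inside
  the asserted 1 and 2 mmHg bounds with margin.

## Known limitations

* The split factor $k$ is population-level; pulse pressure varies between
  individuals, and MAP-proportional splitting inflates SBP/DBP errors
  relative to MAP errors.
* $E_0$, $\xi$, $\rho$ are literature defaults; arterial stiffness is
  individual, and the closed-form inversion inherits any bias in them.
* With the default constants, radial PWV is fast enough that PTT over 3 cm
  is only 10–25 samples at 10 kHz; one-sample quantization is then a
  2–3 mmHg MAP effect, which is why the beat-wise median (not single
  beats) is the subject-level estimate.
* The synthetic morphology is a single smooth crest; algorithms that must
  cope with dicrotic notches or motion artifacts need evidence beyond this
  package's tests.
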