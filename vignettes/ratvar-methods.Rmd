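---
title: "Autoregressive spectral analysis of rat cardiovascular variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoregressive spectral analysis of rat cardiovascular variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratvar)
```

## The problem

Beat-to-beat fluctuations of heart period and arterial pressure carry
information about autonomic cardiovascular control. In the conscious rat,
the pulse-interval series (tachogram) and the systolic-pressure series
(systogram) extracted from a continuous arterial-pressure recording
oscillate in characteristic frequency bands: very-low-frequency activity
below 0.2 Hz, low-frequency (LF) Mayer-wave activity between 0.2 and
0.75 Hz reflecting sympathetic vasomotor modulation, and high-frequency
(HF) activity between 0.75 and 3.0 Hz coupled to respiration and, on the
heart period, largely vagal. `ratvar` implements the complete analysis
chain for such recordings — beat detection, stationary-fragment selection,
parametric spectral decomposition, band powers and the composite indices
(LF/HF sympathovagal balance and the baroreflex alpha index) — together
with the 2x2 factorial statistics used to compare groups of diabetic
and/or renal-denervated spontaneously hypertensive rats (SHR), and a
synthetic-data generator that makes every stage verifiable without animal
data.

## The spectral model

Each stationary fragment of about 300 beats is mean-centred and modelled
as an autoregressive (AR) process
$x_t = \sum_{i=1}^{p} a_i x_{t-i} + e_t$, $e_t \sim (0, \sigma^2)$.
Coefficients are estimated by the Burg lattice recursion, whose reflection
coefficients have modulus below one, so the fitted model is stable by
construction; the recursion also yields the innovation variance at every
intermediate order in a single pass, which is what the order selector
uses. The model order is chosen by AIC,
$\mathrm{AIC}(p) = n\log\hat\sigma^2_p + 2p$, over a default range of
8–20, ties resolved toward the smaller order. The estimator and range are
exposed in the configuration because published analyses of rat recordings
rarely state them; 8–20 comfortably brackets the two oscillatory pairs
plus broadband structure seen in 300-beat fragments.

The fitted spectrum is then resolved into discrete components by factoring
the AR characteristic polynomial. Every real root contributes one
component and every complex-conjugate pole pair one oscillatory component
whose central frequency is the pole angle mapped to Hz through the
fragment's mean beat interval $\Delta t$ (s):
$f = |\arg z| / (2\pi \Delta t)$. This beat-domain-to-Hz mapping is the
standard convention for beat-sampled cardiovascular series and is what
makes the fixed band edges in Hz meaningful across animals with different
heart rates; doubling the mean interval halves every central frequency, a
property checked in the test suite. Component powers are the residues of
the spectral density at the poles (doubled for conjugate pairs), so they
sum to the process variance; the suite verifies the sum against numerical
quadrature of the AR density to well below 0.5%. Components whose poles
sit very close to the unit circle (modulus > 0.999) are flagged with a
warning: they are legitimate for strongly periodic inputs but their
individual powers become ill-conditioned. Residue powers of heavily
damped components can in principle be slightly negative; they are kept
as-is so that energy conservation remains exact, and band sums are
reported unclipped.

Band powers assign each component to the band containing its central
frequency. Intervals are half-open at the lower edge and closed at
3.0 Hz — a deterministic tie-break for components that land exactly on an
edge. Components above 3.0 Hz count toward the total but no band.
Normalized units are percentages of LF + HF power, so
`lf_nu + hf_nu = 100` holds identically whenever both are defined. Total
HRV and SAPV are reported as the fragment variance rather than the AR
power sum: the two agree within the energy-conservation tolerance, and
the variance is the conventional definition of total variability.

## Fragments, indices and aggregation

Stationarity is screened with a thirds test: a sliding window of the
target length qualifies when, split into three equal sub-windows, the
sub-window means differ by less than `k_mean` x the window SD (default
0.5) and the sub-window variances by less than `k_var` x the window
variance (default 1.0), on the tachogram and the coincident systogram
simultaneously. Qualifying windows are accepted greedily from the start
of the series, so fragments are non-overlapping and share beat indices
across the two series. The thresholds are configuration-exposed: they are
a design choice, not a published criterion, and the defaults were picked
so that a genuinely stationary 300-beat white-noise or
sinusoid-plus-noise window passes while windows straddling a several-SD
mean shift fail.

The composite indices are computed per fragment and then averaged per
animal: LF/HF is the ratio of absolute tachogram band powers, and the
alpha index is $\alpha_{LF} = \sqrt{LF_{HRV} / LF_{SAPV}}$ (ms/mmHg), an
estimate of spontaneous baroreflex sensitivity. Ratios are never formed
from group-mean powers — the mean of per-animal ratios differs from the
ratio of means by a Jensen gap, and the per-animal convention is the only
one consistent with group tables in which the mean LF/HF is far from the
ratio of the mean band powers. When a recording yields several
qualifying fragments they are analyzed independently and averaged before
any group statistic, fixing the aggregation level at the animal. A zero
HF power makes LF/HF missing (never infinite), and a zero systogram LF
power makes the alpha index missing; missing values are excluded
field-wise with counts reported.

## Beat extraction

The paper-level description of the source recordings is a continuous
pressure trace sampled at 2 kHz, analyzed beat-to-beat; no detection
algorithm is standard enough to assume. `detect_beats()` uses
adaptive-threshold local-maximum detection: the threshold sits 55% of the
way between the 1st and 99th amplitude percentiles (hence invariance to
constant offsets), a refractory period of 0.4 x the median candidate
spacing suppresses secondary maxima at rat heart rates of 300–450 bpm,
and each accepted peak is refined to sub-sample accuracy by parabolic
interpolation through its three surrounding samples. Pulse intervals are
defined systolic-peak-to-systolic-peak so that tachogram and systogram
share beat indexing. Diastolic minima are located between successive
peaks, and the per-beat mean pressure is the time average of the samples
in the cycle — not the diastolic + pulse-pressure/3 approximation —
because the quantity of interest is the directly measured mean pressure.
Heart rate obeys the exact unit contract `hr x mean(PI) = 60000`.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture: it
emulates the study conditions so that every downstream stage has a known
right answer.

* **Beat series.** Pulse intervals are a mean plus one LF and one HF
  sinusoid plus white Gaussian noise, with beat times accumulated from
  the successive intervals; the systolic series is built the same way
  around its own mean. A sinusoid of amplitude $A$ contributes exactly
  $A^2/2$ to the series variance, which is the analytic oracle used
  throughout the tests. Default oscillation frequencies are 0.45 Hz (mid
  LF band) and 2.0 Hz (HF band). Each diastolic value follows the smaller
  of its flanking systolic values at 70% amplitude around its own mean —
  a phenomenological coupling that keeps every cycle's pulse pressure
  near its configured mean; no closed-loop baroreflex
  dynamics are modelled, so simulated PI–SAP coherence carries no
  physiological meaning. Non-positive interval draws are clipped at
  10 ms with a warning. White noise is spectrally flat, so a band also
  receives the noise power falling inside it: simulated absolute band
  powers sit above the pure-sinusoid targets by the in-band noise share.
  This is intentional — the analytic sinusoid checks use low-noise specs,
  and no test asserts that simulated cohorts reproduce published band
  powers.
* **Waveforms.** Each cycle decays from its systolic peak toward the
  diastolic level with the C1-smooth kernel $e^{1-\sqrt{1+x^2}}$
  (rescaled to land exactly on the diastolic value at the foot of the
  next upstroke) and rises to the next peak with a half-cosine upstroke
  occupying 15% of the cycle. Morphology is deliberately minimal: only
  the extrema and their timing matter downstream, and the zero-slope
  peaks keep the parabolic refinement of the detector accurate. At 2 kHz
  the simulate→detect round trip recovers the beat count exactly and
  every interval within 1 ms.
* **Cohorts.** The default 2x2 design (group sizes 7, 6, 6, 5) draws
  every scalar outcome from per-group Gaussians calibrated to published
  group summaries for the diabetic/renal-denervated SHR model; urinary
  albumin is log-normal, parameterized from its printed median and
  bracketed interval. Whether the brackets are a min–max range or an
  interquartile range is not stated in the source literature, so both
  interpretations are config options (`albumin_interval`); the default
  reads them as the observed range of a sample of the group's size, using
  the expected normal range for that n on the log scale. Initial
  (48-hour) glycemia in diabetic groups is drawn truncated above the
  300 mg/dL induction threshold — the study design only labels animals
  diabetic above it — so default cohorts pass the inclusion filter
  unchanged; the 45-day glycemia is untruncated and keeps its configured
  centre. One group's published systogram variability components exceed
  its published total, which no additive noise variance can reconcile;
  for that group the generator targets the component powers and floors
  the systogram noise SD at 1 mmHg. Systolic/diastolic draws are redrawn
  until pulse pressure is at least 10 mmHg.

What the generator does *not* emulate: 1/f baseline drift, transients and
artifacts, respiratory frequency wander, closed-loop coupling, and
non-Gaussian beat noise. Passing tests therefore demonstrate correctness
of the algorithms under stationary additive-sinusoid conditions, not
robustness to every feature of real recordings.

## Statistics

Group comparisons use the unbalanced two-way factorial ANOVA
(diabetes x denervation) with Type-III sums of squares under sum-to-zero
contrasts — the convention of the commercial package named in the source
study's methods. In the 2x2 design every effect has one degree of
freedom, so the raw-data route fits `lm(y ~ denervation * diabetes)` with
sum contrasts and squares the coefficient t. A second, closed-form route
(`anova_from_summary()`) reconstructs the identical table from cell
means, SDs and sizes, which are sufficient statistics for the factorial
model: main-effect sums of squares are unweighted cell-mean contrasts
$SS = L^2 / \sum c_{ij}^2/n_{ij}$ and the residual sum of squares is
$\sum (n_{ij}-1) s_{ij}^2$. The equivalence of the two routes to 1e-9 on
random data is a standing test, and the summary route is what lets the
package verify published p-values (e.g. a baseline-weight interaction
near 0.73) directly from printed tables.

Post-hoc comparisons use the Student–Newman–Keuls procedure: means are
ranked, a span of r means is tested against the studentized range
quantile `qtukey(1 - alpha, r, df)` with the one-way residual MSE, and a
non-significant span is homogenized so that no significant pair can be
nested inside it. With unequal group sizes each comparison uses the
harmonic mean of the two group sizes — the textbook extension, under
which the two-group case reduces exactly to the pooled two-sided t-test.
Urinary albumin is natural-log transformed before testing and displayed
as median [range]. Dispersion in reports is labelled SD by default (a
config flag switches the label to SEM): published dispersion magnitudes
for this model are consistent with SDs even where methods text says SEM,
and the report layer states what it shows rather than guessing intent.
No multiplicity correction is applied across outcomes, matching the
source analysis. One further naming ambiguity in the source results
("HRD", presumably the renal-denervated hypertensive group) is noted
here rather than resolved.

## Numerical choices and degenerate inputs

* Burg reflection update with mean-centring; zero-variance fragments are
  rejected explicitly, as are fragments shorter than twice the order.
* Root finding uses `polyroot`; a root on or outside the unit circle (not
  reachable from Burg fits, but possible for hand-built models) raises an
  explicit instability error.
* Flat waveforms raise a "no beats detected" error distinct from the
  NaN-sample error; series shorter than the fragment length raise a
  short-input error distinct from "no stationary fragment".
* All ratio indices report missing (`NA`) rather than infinity at zero
  denominators.
* Every simulation is reproducible: a design/spec seed determines the
  output bytes, and per-animal seeds are derived from the cohort seed.

## Problem sizes used in validation

The bundled tests and the acceptance script validate at sizes chosen to
keep sampling error well inside the asserted tolerances: 300-beat
fragments (the conventional fragment length), 200 seeded replicates for
the LF sinusoid-recovery Monte Carlo, 200 simulated cohorts at 50
animals/group for power of the diabetes main effects, 1000 null cohorts
for the type-I error rate, and 10,000-animal groups for
law-of-large-numbers checks of the generator. Coefficient-recovery
checks against the exact Yule-Walker solution use 50,000-sample series,
where the Burg estimator's sampling SD is an order of magnitude below the
asserted ±0.01.

## Known limitations

* The AR decomposition attributes broadband (noise) power to whichever
  band a component's centre falls in; narrow-band indices from short
  fragments are therefore noisy, as they are in practice.
* The stationarity screen is a heuristic; it bounds first- and
  second-moment drift across thirds of a window but cannot detect all
  nonstationarity.
* No cross-spectral coherence is computed; the alpha index is reported
  without a coherence gate, matching the source analysis.
* The statistical layer covers the 2x2 between-animal design only — no
  repeated measures, no mixed models.
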