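---
title: "Quantifying presynaptic homeostatic plasticity: models, estimators and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic homeostatic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synhomeo)
```

## The scientific problem

At the *Drosophila* larval neuromuscular junction (NMJ), blocking a fraction
of postsynaptic glutamate receptors — pharmacologically with philanthotoxin
(PhTX) or genetically — reduces the postsynaptic response to a single
vesicle (the *quantal size*, read out as the miniature EPSP/EPSC amplitude).
Within minutes the presynaptic terminal compensates by releasing more
vesicles per action potential, so the evoked EPSC recovers to its original
amplitude. This compensation is presynaptic homeostatic plasticity (PHP).
Whether a genotype expresses PHP is decided entirely through quantal
arithmetic: quantal size from miniature events, *quantal content* (vesicles
per action potential) as evoked amplitude over quantal size, and the size of
the readily releasable vesicle pool (RRP) from depression during
high-frequency trains.

`synhomeo` implements that quantification chain — and the statistics used to
screen many genotypes with it — together with generators that simulate each
data type with known ground truth, so every estimator in the package can be
validated against the construction that produced its input.

## The simulators and what they emulate

### Miniature-event traces

`simulate_minis()` draws event onsets from a Poisson process, gives each
event a biexponential waveform

$$w(t) = \left(1 - e^{-t/\tau_r}\right) e^{-t/\tau_d},$$

peak-normalized and scaled by a lognormal amplitude, and adds white Gaussian
noise. Defaults: rate 2 events/s, $\tau_r$ = 0.5 ms, $\tau_d$ = 5 ms,
sampling 10 kHz, amplitude mean 1 with CV 0.1, noise SD 0.2 (signal-to-noise
5). The lognormal is chosen for its positive support and right skew,
matching physiological mini-amplitude histograms; the distribution family is
a modeling choice, not a measured property.

Two defaults deserve comment.

* **Amplitude CV (0.1).** Template-matching detection at criterion
  threshold 4 has an intrinsic amplitude gate: the Clements–Bekkers
  criterion at the true lag is approximately amplitude/noise SD, so at
  signal-to-noise 5 events below roughly 0.8× the mean amplitude fall under
  a threshold of 4 regardless of implementation quality. The default
  dispersion is therefore deliberately modest — a near-uniform quantal
  population in which fewer than ~6% of events sit under the gate — so that
  detection performance reflects the detector rather than the amplitude
  tail. Physiological event-to-event dispersion is larger (CV ~0.2–0.4);
  at CV 0.3 the same detector recovers only about two thirds of events at
  these settings, an amplitude-selection effect users should expect on real
  data. `amp_cv` is a first-class parameter.
* **Noise SD.** No recording-noise figure is available for the original
  data; the default fixes the canonical signal-to-noise ratio of 5 used
  throughout the calibration experiments.

### Stimulus trains

`simulate_trains()` implements a two-line depletion–replenishment model of
60 Hz trains (60 stimuli, 5 trains per cell):

$$A_i = q\,p_r\,N_i\,(1+\epsilon_i), \qquad
  N_{i+1} = N_i(1-p_r) + k\,\Delta t\,\bigl[N_0 - N_i(1-p_r)\bigr],$$

with $N_1 = N_0$, $\Delta t = 1/60$ s, clipping to $[0, N_0]$ and
multiplicative Gaussian trial noise $\epsilon_i$. Replenishment is
first-order recovery toward the resting pool applied after each stimulus;
during sustained stimulation this converges to a constant-replenishment
steady state, which is exactly the regime the cumulative-amplitude RRP
method assumes. With $k = 0$ the amplitudes are geometric,
$A_i = qp_rN_0(1-p_r)^{i-1}$, which provides closed-form oracle values used
in the tests.

### Screen tables

`simulate_screen()` emulates a PhTX screen: per line, a handful of NMJs
with mean mEPSP and mean EPSC values. PhTX acts purely as a quantal-size
scale (default 0.6, i.e. the ~40% mini reduction seen experimentally);
PHP-competent lines multiply quantal content by the reciprocal so their
EPSC is conserved, PHP-deficient lines do not, so their EPSC falls to 0.6×.
Receptor kinetics are not modeled. NMJ counts per line are drawn as
3 + a geometric(1/2) excess capped at 12 — mean ≈ 4, range 3–12, mode 3 —
reflecting small screening cohorts. Wild-type anchors (0.8 mV mEPSP, 70 nA
EPSC, 16 NMJs per reference group, between-NMJ CV 0.15) are typical
two-electrode voltage-clamp values at this synapse. The two WT reference
groups (with and without PhTX) are always emitted.

`simulate_php_experiment()` generates the paired design used for PHP
normalization — one genotype, untreated and PhTX-treated arms — under the
same construction rules. Its between-NMJ CV defaults to 0.1: the
quantal-content ratio of a two-arm design combines four independent group
means, so its sampling error is about $\mathrm{CV}\cdot\sqrt{4/n}$, and a
CV of 0.1 at 20 NMJs per arm puts the conventional ±10% acceptance band at
roughly two standard errors. The screen generator keeps the larger CV of
0.15 typical of heterogeneous screening cohorts.

### Bouton point patterns and images

`simulate_boutons()` places a reference channel uniformly inside a bouton
polygon and couples a configurable fraction of target points to reference
points through an isotropic Gaussian tether (re-drawn until inside the
polygon); the rest of the target channel is completely spatially random
(CSR). The default polygon is a radially modulated circle of mean radius
1 µm; default counts (12 reference, 15 target) are in the range of
punctum counts per bouton seen in super-resolution images of
vesicle-associated proteins. `render_puncta_image()` rasterizes a geometry
through a Gaussian PSF (default SD 30 nm, pixel 20 nm, matching gSTED
acquisition settings).

What the generators do **not** emulate: correlated (pink) recording noise,
stimulus artifacts, receptor saturation or desensitization, z-structure in
images, chromatic offsets, and bouton-to-bouton heterogeneity of punctum
density. Passing calibration on these simulations therefore demonstrates
correctness of the estimators under their stated assumptions, not
robustness to every property of real recordings.

## The estimators

### Event detection

`cb_detect()` slides a biexponential template along the trace; at each lag
the template is fitted by least squares with free scale and offset, and the
detection criterion is the fitted scale divided by the SD of the fit
residuals. The offset term absorbs DC shifts, and the criterion is
invariant to joint rescaling of trace and noise — both properties are
tested. Numerical choices:

* **One event per suprathreshold excursion.** The criterion stays elevated
  along an event's decay, so taking every local maximum above threshold
  would duplicate events; each contiguous above-threshold segment
  contributes exactly one event at its criterion peak.
* **Minimum separation** defaults to the template rise time + 2 ms and is
  enforced greedily in descending criterion order; it replaces the manual
  post-hoc inspection of the original workflow with a deterministic rule.
* **Edges:** lags needing samples beyond the trace end are skipped, so no
  events are reported within one template length of the end.
* Threshold default 4 criterion units, the conventional operating point for
  this detector.

`match_events()` scores detections against ground truth by greedy
one-to-one nearest-time matching (default tolerance 1.5 ms). Under the
default calibration conditions (SNR 5, 2 Hz, 60 s) the detector reaches
~92% sensitivity with <1% false discovery and ~2% amplitude bias.

### Quantal content and PHP normalization

Group quantal analysis follows screening convention: the group mini mean is
the unweighted mean of per-NMJ mean amplitudes (`group_mean_mepsc()`), and
each evoked-response NMJ's quantal content divides its mean EPSC by that
group mini mean (`quantal_content()`) — minis and evoked responses come
from *different* NMJs, and no driving-force correction is applied for the
different holding potentials, faithfully reproducing the field's
convention. `php_ratio()` normalizes treated quantal contents to the mean
untreated quantal content; a ratio near $1/0.6 \approx 1.67$ with a
conserved EPSC is the signature of intact PHP.

### RRP, release probability, paired-pulse ratio

`cumulative_profile()` averages amplitudes across trains per stimulus
index, then `rrp_from_cumulative()` fits an ordinary least-squares line to
the last 15 cumulative amplitudes against time and back-extrapolates to
$t = 0$. The intercept over the group mini mean is the RRP in quanta;
`pr_and_ppr()` derives $p_r = A_1/\text{intercept}$ and
$\text{PPR} = A_2/A_1$.

* **Abscissa.** The fit uses time in seconds with $t_1 = 0$. Fitting
  against stimulus index instead rescales only the slope; the intercept —
  and hence every derived quantity — is identical. This equivalence is
  documented here because the original description does not fix the
  choice; it is numerically exact, not approximate.
* **Bias is reproduced, not corrected.** With nonzero replenishment the
  back-extrapolated intercept is biased relative to $qN_0$. Under the
  first-order recovery used here the bias is *downward*: replenishment
  between stimuli shallows the depletion, the late train releases
  $A_\infty$ per stimulus, and the intercept works out to
  $A_\infty + (A_1 - A_\infty)/(1-\rho)$ with
  $\rho = (1-p_r)(1-k\Delta t)$, which is below $qN_0$ whenever $k > 0$
  and equal to it in the $k \to 0$ limit. The estimator is required (and
  tested, to $10^{-9}$) to agree with a brute-force simulation of the
  recurrence followed by the same fit; correcting the bias would change
  the estimator away from the method it reimplements.
* Negative intercepts are flagged with a warning, never clamped; $p_r$
  outside $[0,1]$ likewise.

In the noise-free geometric regime the estimator recovers $N_0$ and $p_r$
to better than $10^{-4}$ across $p_r \in \{0.3, 0.5, 0.7\}$,
$N_0 \in \{200, 500\}$ (the residual error is the truncated geometric tail,
$(1-p_r)^{45}$ at worst). With 10% trial noise and 5 trains the median RRP
error stays under 10%.

### Screen statistics

`volcano_screen()` pools every line's evoked amplitudes with the
PhTX-treated WT reference in a single one-way ANOVA and applies Tukey HSD
against the reference. A single pooled model (rather than per-batch models)
is used because the original analysis reports one familywise p-axis for the
whole screen; the choice is configurable upstream by subsetting the table.
Lines are flagged `smaller`/`larger` at adjusted $p \le 0.01$.

`twoway_php_test()` uses type-II sums of squares (via `car::Anova`) because
the group sizes in these designs are unequal and no interaction-ordering
argument favors type III here, with Tukey HSD on the cell means. A design
with zero total variance is degenerate and reported as $p = 1$ with a
warning rather than an error, so screen loops do not abort.

`compare_two()` encodes the gated two-group convention: Shapiro–Wilk on
each group, then classical (mean-centered) Levene; failure of normality
routes to Mann–Whitney, failure of variance homogeneity alone to Welch's
t-test, otherwise Student's t-test. The gate level is fixed at 0.05 (the
original description states the gates but not their level), and the Welch
branch is an interpolation of what "after a Levene's test" implies — both
choices are recorded in the result object. Zero-variance groups make
Shapiro–Wilk undefined and fall to Mann–Whitney with a warning.

`min_n_power()` returns the smallest per-group n whose two-sided
two-sample t-test power, evaluated with the noncentral t distribution,
reaches the target (default 0.8 at $\alpha = 0.05$); n = 2 is the smallest
admissible design. Reference points: d = 1.0 → 17, d = 0.8 → 26,
d = 0.5 → 64 per group.

### Proximity analysis

`find_maxima()` implements a prominence-based peak finder: flooding the
image from the brightest pixel downward (8-neighborhood), a peak survives
only if it stands more than `noise_tolerance` above the saddle connecting
it to a brighter region — one maximum per punctum, emulating a
"Find Maxima"-type operator whose internal parameters are not published.
`nnd_set()` computes reference-to-target nearest-neighbor distances;
distances are measured *from* the channel of interest *to* the partner
channel, and the direction is the caller's choice.

`mc_nnd_test()` is the Monte-Carlo null: per bouton, both channels are
re-placed uniformly inside the bouton polygon (same counts) `n_rand` times
and the per-bouton randomized mean NND is averaged across repetitions;
observed and randomized per-bouton means are then compared with a
two-sided Student's t-test. Defaults and their rationale:

* `n_rand = 100` with averaging reduces the null's Monte-Carlo variance;
  `n_rand = 1` reproduces a single-randomization design exactly.
* The test is **unpaired** by default, matching the generic "Student's
  t-test" of the original analysis; a paired version is available and is
  more powerful when boutons are heterogeneous.
* Calibration: over 200 simulated datasets of 10 NMJs × 13 boutons under
  CSR, the rejection rate at $\alpha = 0.05$ stays near nominal (0.03 to
  0.08 across runs); under coupling (80% of target points tethered at
  50 nm) essentially every dataset rejects at $p < 0.001$.

`costes_test()` builds a correlation null by permuting PSF-sized blocks of
one channel (equal-size blocks permuted within their size class, edge
remainders among themselves) and reports
$p = (1 + \#\{r_\text{null} \ge r_\text{obs}\})/(n_\text{scramble} + 1)$,
so the smallest attainable p is $1/(n_\text{scramble}+1)$ and the null p
distribution is uniform under independence (verified by a KS check).
A block that covers the whole mask, or a constant channel, is rejected as
degenerate.

### Morphometry

`preprocess_projection()` max-projects a stack, subtracts a rolling-ball
background — implemented as grayscale opening with a ball structuring
element of the stated physical radius (default 1 µm); the ball's height is
in intensity units scaled by `ball_aspect`, and exact parity with any
particular legacy implementation is not promised — and returns both a
3 × 3 median-filtered projection (for masks) and the unfiltered one (for
intensity measurement). `threshold_mask()` keeps pixels at or **at or
above** the stated fraction of the image maximum (inclusive comparison;
the original description does not fix strictness); 15% and 35% are both
first-class values and results should be reported per threshold — note
that object counts are *not* monotone between the two thresholds (masks
are nested, components can merge or vanish), which is why the tested
invariant is mask nesting, not count ordering. `count_and_measure()`
labels 8-connected components (no minimum size filter by default),
normalizes the count to the marker-mask area in µm², and measures
per-punctum mean intensity on the unfiltered corrected projection.

## Pipeline and reproducibility

`run_pipeline()` executes configured stages in dependency order; each stage
derives its seed from the global seed through a stable string hash, so
adding a stage never shifts another stage's random stream, and a rerun of
the same config is byte-identical. Outputs are plain text (CSV/JSON);
rendered images can be exported as TIFF with a JSON pixel-size sidecar.

## Problem sizes used in validation

The shipped validation suite uses: 60 s traces at 10 kHz over 20 seeds for
detection calibration; the 6-point $(p_r, N_0)$ grid plus 100 noisy seeds
for RRP; 20 NMJs per arm for PHP discrimination; 200 CSR datasets and 50
coupled datasets of 130 boutons for the NND test; 50 null and 50
planted-hit screens of 100 lines; and 1000 simulated null designs for the
two-way interaction calibration. These sizes were chosen so that binomial
or Monte-Carlo error is small relative to each acceptance band.

## Known limitations

* The detector fits a single template; overlapping events within one
  excursion are merged, and kinetic heterogeneity (variable rise/decay)
  is not modeled or fitted.
* The RRP method inherits the cumulative approach's replenishment bias by
  design; it should be read as an upper bound on $qN_0$ when
  replenishment is fast.
* The NND null randomizes within the manually drawn bouton boundary only;
  structured sub-bouton exclusion zones (e.g. mitochondria) would make
  the CSR null liberal on real data.
* The rolling-ball background is a morphological idealization; pixel-exact
  agreement with specific legacy software is out of scope.
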