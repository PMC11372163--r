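---
title: "Methods: detecting specific quadratic phase coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting specific quadratic phase coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qpcoupling)
```

This vignette is the package's account of its science: the generative model,
the two detection arms, the significance machinery, every tunable parameter
that matters, and the numerical choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The three-channel model

`simulate_condition()` generates three stochastic processes on epochs of
duration $T$ sampled at $f_s$:

$$X_1 = I_1 + \xi_1, \qquad X_2 = I_2 + \xi_2, \qquad
  X_3 = W X_1 X_2 + I_3 + \xi_3,$$

where $I_1$ is a triangular wave $2\,\mathrm{asin}(\sin(2\pi F_1 t +
\omega_1))$ with range $[-\pi,\pi]$, $I_2$ a rectangular wave in
$\{-1,+1\}$ (positive when $(2\pi F_2 t + \omega_2) \bmod 2\pi \in
[0,\pi)$), $I_3$ a cosine, and the $\xi_i$ are i.i.d. Gaussian
(`noise_sd`, default 1). Phases $\omega_i(\nu)$ are redrawn uniformly on
$[0, 2\pi)$ for every epoch $\nu$, which makes epochs independent
realisations and — crucially for the bispectral arm — leaves only genuinely
phase-locked structure coherent across Welch segments. The non-sinusoidal
carriers give the two input channels a spread harmonic content closer to
physiological spectra than pure tones, and make the channel SNRs available
in closed form (`expected_snr()`):
$\pi^2/3$, $1$, and $(2\pi^2/3 + 2)W^2 + 1/2$.

Defaults are the study conditions throughout: $f_s = 100$ Hz, 5-second
epochs, 128 epochs (64 000 samples), unit noise, and the carrier set
$\{70, 80, 120, 150, 230\}/2\pi$ and $50 - 10/2\pi$ Hz (`study_frequencies()`),
chosen so that no carrier or carrier sum falls on a rational grid. The
carrying frequency $F_3$ must differ from $F_1$, $F_2$ and $F_1+F_2$, else
the output carrier would be confounded with the coupling line; the
constraint is overridable for exploration. Randomness derives from one seed
per condition: phases (3 × epochs) are drawn first, then the noise array,
in a single stream — epochs remain independent draws and every realisation
is bit-reproducible.

What the simulator does **not** emulate: coloured or non-Gaussian noise,
drifting carriers, volume conduction, more than three channels, or
non-stationarity. Passing tests therefore demonstrate correctness of the
estimators under stationary multiplicative coupling with white noise, not
robustness on real EEG/MEG records.

## 2. Empirical signal-to-noise ratio

The SNR of a channel is the ratio of the power carried by its declared
harmonic structure to the broadband noise power. The default estimator
(`empirical_snr(method = "projection")`) least-squares-projects each epoch
onto the sine/cosine pair of every declared line — odd harmonics $kF_1$
(triangular, amplitudes $\propto k^{-2}$), odd harmonics $lF_2$
(rectangular, $\propto l^{-1}$, truncated at 99.9% of the waveform power),
the single $F_3$ line, and for the coupled channel with $W > 0$ the
intermodulation lines $|kF_1 \pm lF_2|$ — all folded into $(0, f_s/2]$ by
aliasing. Explained power is corrected by the exact least-squares
degrees-of-freedom identity ($E[\mathrm{ESS}] = n P_{\mathrm{sig}} +
p\sigma^2$), and noise power is the residual variance.

This projection form was preferred over summing periodogram excess at the
harmonic bins (available as `method = "periodogram"`): with 500-sample
rectangular-window epochs and carriers roughly half a bin off the Fourier
grid, spectral leakage removes 5–10% of line power from any reasonable bin
window — a systematic bias that replication cannot average away — whereas
the projection estimator is leakage-free and reproduces the analytic limits
for the two input channels. The two estimators agree on which behaviour
matters for the coupled channel: the broadband part of $W X_1 X_2$
(noise×carrier and noise×noise products) raises the noise floor while only
the discrete carrier×carrier lines count as signal, so the empirical SNR of
$X_3$ falls below its analytic expectation and the shortfall grows with
$W$ — the "SNR efficiency" (empirical/expected) the study tracks.

## 3. Welch segmentation and the bifrequency grid

Records are segmented with 50% overlap across the concatenated epochs
(`segment_series()`); 128 five-second epochs yield $L = 255$ segments of
500 samples. Each segment is mean-removed and variance-normalised (the
estimators below are invariant to per-segment rescaling in any case), then
truncated to the DFT length and transformed without taper. No taper is
applied because the per-epoch random phases already decorrelate segments;
the rectangular window keeps the estimator exactly the sample form of the
defining equations.

The bifrequency grid step is the *fractional power of two closest to the
experimental resolution* $f_s/\mathrm{segment}$: for 500 samples at 100 Hz,
$\Delta f_{\exp} = 0.2$ Hz and the rule (`bispectral_resolution()`) selects
$\Delta f = 0.25$ Hz, realised by truncating segments to
$f_s/\Delta f = 400$ samples. Frequencies are bin centres at integer
multiples of $\Delta f$; the sum index $f_1+f_2$ addresses the full-length
DFT directly, so sums beyond the Nyquist frequency alias onto their
conjugate fold automatically. The single corner bin whose sum aliases onto
DC is excluded from the principal domain (its denominator is exactly zero
after mean removal) and flagged.

Sectors partition the square $(0, f_{\mathrm{Nyq}}]^2$: $Q_I$ where
$f_1+f_2 \le f_{\mathrm{Nyq}}$ (boundary included), $Q_{II}$ above the
anti-diagonal with $f_1 > f_2$, $Q_{III}$ otherwise. A coupling whose sum
frequency exceeds the Nyquist frequency is observed in $Q_{II}$/$Q_{III}$
through aliasing, which is why the sector of the carrier bifrequency is the
natural denominator region for the specificity index.

## 4. Cross-bicoherence and its null

`cross_bicoherence()` estimates

$$\hat b^2_{ijk}(f_1,f_2) =
  \frac{\left|\left\langle \tilde X_i(f_1)\tilde X_j(f_2)
        \tilde X_k^*(f_1+f_2)\right\rangle\right|^2}
       {\left\langle |\tilde X_i(f_1)\tilde X_j(f_2)|^2\right\rangle
        \left\langle |\tilde X_k(f_1+f_2)|^2\right\rangle},$$

with $\langle\cdot\rangle$ the average over Welch segments; the
Cauchy–Schwarz inequality bounds it in $[0,1]$. (The numerator averages the
complex cross-bispectrum *before* taking the squared magnitude — the form
with the magnitude inside the average has no null decay and does not
measure phase locking.) Under the null of zero true bicoherence,
$2L\hat b^2$ is approximately $\chi^2_2$; the test suite verifies this in
distribution (Kolmogorov–Smirnov at $\alpha = 0.01$, $L = 200$) and checks
the vectorised estimator against a naive triple-loop oracle to $10^{-10}$.

Significance (`fit_null_mixture()`) follows an empirical-Bayes two-class
mixture $F = p_0 F_0 + (1-p_0) F_A$ fitted to the raw map values: the
values are histogrammed at bin width $\Delta = 0.001$, the mode located
after 3-bin moving-average smoothing (ties towards the smaller statistic),
and the null component — the $\chi^2_2$ family with a free scale, i.e. an
exponential on the raw scale — is fitted by a count-weighted log-linear
regression over the null bulk to the right of the mode, down to $e^{-3}$ of
the mode height (≈95% of an exponential's mass). The intercept at the mode
gives $p_0$, box-constrained to $[0, 0.9]$; the slope gives the null rate,
whose theoretical value is $L$. A mode on the right edge of the histogram,
or a non-negative fitted slope, falls back to the theoretical
$\chi^2_2$ null with a warning. Right-tail FDR q-values are
$q(x) = \min_{t \le x} p_0 S_0(t)/\hat S(t)$ (cumulative-minimum form, so q
is monotone non-increasing in the statistic); `significance_map()` keeps
$\overline{b^2} = \hat b^2$ where $q < 0.05$ and zero elsewhere. The
threshold 0.05 and the $p_0$ box are parameters, not constants.

## 5. R_BQPC

`r_bqpc()` sums $\overline{b^2}$ over the closed neighborhood
$G(f_1,f_2;d)$ — bin centres within $\pm d$ of each carrier, default
$d = 0.5$ Hz, clipped to the sector of the centre so $G \subset Q$ — and
divides by the sum over the whole sector (which includes $G$ itself, hence
the ratio is bounded by 1). A sector with no significant mass gives an
*undefined* flag, deliberately distinct from 0; ratios exactly 0 or 1 are
flagged as boundary outliers so that the study aggregation can exclude
them, mirroring the outlier rule of the simulation study.

## 6. Bivariate spectral Granger causality

The Granger arm (`bgcs()`) forms the product process $U = X_i X_j$ and
measures the spectral causality $U \to X_k$ via Geweke's decomposition of a
bivariate VAR: with transfer function $H(f)$ and residual covariance
$\Sigma$, after the standard rotation that removes the instantaneous
residual correlation,

$$\mathrm{BGCS}(f) = \ln \frac{S_{kk}(f)}
  {|\tilde H_{kk}(f)|^2 \Sigma_{kk}} \ \ge 0 .$$

The VAR order is selected once on the whole record by the Schwarz criterion
with an anti-overfitting margin: the smallest order $l$ with
$\mathrm{SC}(l) \le \mathrm{SC}_{\min} + 0.05\,|\mathrm{SC}_{\min}|$
(`select_lag()`, `lag.max` default 50). The margin is applied on the
$|\mathrm{SC}_{\min}|$ scale so it preserves its intent whether SC is
positive or negative; by construction the choice never exceeds the arg-min.
The time-domain identity $\int$BGCS$= \ln(\sigma^2_{\mathrm{red}} /
\Sigma_{kk})$ is verified to 5% on VAR(2) systems in the tests.

With `mode = "welch"` (the default, matching the study design) the spectrum
is the point-wise *median* of per-segment VAR spectra across all Welch
segments; `mode = "single"` fits one VAR on the whole record and is the
fast option. Segments with singular fits are skipped (an error if more than
half are).

Significance (`bootstrap_significance()`) resamples residuals of the
*reduced* model — $X_k$ regressed on its own past only — to resimulate
$X_k$ under the no-causality null, recomputes the same BGCS estimator
`nboots` times (rule: $\sqrt{\Delta f_{\exp}} \times 1000$, i.e. 447 for
0.2 Hz), and forms per-frequency p-values
$(1 + \#\{\mathrm{boot} \ge \mathrm{obs}\})/(\mathrm{nboots}+1)$. Q-values
come from `qvalues()`: Storey's pFDR with $\lambda = 0.5$, falling back to
Benjamini–Hochberg when the p-value sample is numerically constant (as
happens with too few bootstrap resamples). The causal-dependency threshold
$\theta$ is the smallest observed BGCS among the $q<0.05$ frequencies, and
$\theta$ *determines* the significant values: the retained spectrum
$\overline{\mathrm{BGCS}}$ is the curve at or above the $\theta$ line. This
threshold-line rule (rather than keeping only the $q<0.05$ bins themselves)
is what the framework's reference figures draw — the dashed threshold with
the shaded area of the curve above it — and it is what gives the Granger
index its characteristic broad denominator; with no significant frequency
$\theta$ is undefined and nothing is retained, so null calibration is
unaffected. The aliased spectral interval of interest is
$[(f_1{+}f_2) - 2d,\ (f_1{+}f_2) + 2d]$, with centre $f_s - (f_1+f_2)$
when the sum exceeds the Nyquist frequency (the fold of the sum line),
clipped to $(0, f_{\mathrm{Nyq}})$; `r_gqpc()` is the ratio of retained
mass inside the interval to the whole band, with the same undefined/0/1
flagging as R_BQPC.

## 7. The simulation study and problem sizes

`build_condition_grid()` enumerates unordered carrier pairs with every
admissible $F_3$; with the study frequency set this yields **58**
conditions (two pair sums, $70/2\pi + 80/2\pi$ and $80/2\pi + 150/2\pi$,
fall back inside the set and remove one $F_3$ choice each). The realized
count is always logged; medians across conditions are the aggregate, so
they are robust to the enumeration detail. `run_study()` derives one seed
per condition from a master seed, so results are independent of execution
order; `aggregate_medians()` applies the outlier rule (drop undefined, 0
and 1 ratios) before taking per-coupling medians.

Problem sizes used by the shipped tests were chosen to keep the whole suite
within a desk-scale run while preserving the study conditions where they
matter:

* the bicoherence arm runs the **full** 58-condition grid at all six
  coupling strengths with the full 128-epoch records (≈3 minutes);
* the Granger arm uses a stratified subset (every 10th condition), three
  coupling strengths, full 128-epoch records, the rule-determined
  `nboots = 447`, `lag.max = 12`, and recomputes bootstrap medians over
  every 3rd segment (≈9 minutes). Bootstrap segment subsampling widens the
  null spread slightly, i.e. errs conservative. The bootstrap count is kept
  at the full rule value because discrete bootstrap p-values interact
  sharply with pFDR: with `nboots` bootstraps the smallest attainable
  p-value is `1/(nboots+1)`, and a q-value below 0.05 requires on the order
  of twenty frequencies sitting at that floor simultaneously.
* `scripts/acceptance.R` (≈30 s) reruns the worked-example ratios, the
  parameter rules, the 20-replicate SNR recovery and the full-grid median
  R_BQPC at $W = 0.05$.

What the suite finds on this grid: the median R_BQPC is ≈0.50 at
$W = 0.050$ and falls steeply for strong coupling (spurious carrier-axis
ridges inflate the sector denominator); the median R_GQPC decreases
monotonically over the couplings where the Granger arm has power (≈0.10 at
$W = 0.150$, ≈0.03 at $W = 0.750$); R_BQPC exceeds R_GQPC wherever both are
defined; and the X3 SNR efficiency is below 1 in nearly all conditions and
decreases with $W$. Two caveats belong here rather than in the test log.
First, at the very weakest coupling ($W = 0.025$) the bispectral index
comes out *more* specific (median ≈0.59) than at $W = 0.050$, so the
realized R_BQPC median curve is monotone decreasing rather than peaked at
$W = 0.050$; the weak-coupling group is sensitive to exactly how liberal
the empirical-null fit is, the least pinned-down ingredient of the
framework (Section 4), and we chose not to tune it against any expected
curve shape. Second, at $W = 0.025$ the Granger arm detects nothing: under
the null-resimulation bootstrap only a few frequencies ever beat all
bootstrap replicates, too few for any q-value to clear 0.05, so $\theta$
and R_GQPC are undefined for that group. A confidence-band bootstrap of
the estimator itself would be more powerful there, at the price of relying
on the estimator's own bias; we keep the resimulated null because its
false-positive behaviour is directly verifiable (Section 6).

## 8. Numerical choices and degenerate inputs

* Zero-denominator bicoherence bins are reported as 0 with a flag, never
  NaN; the DC-aliased corner bin is excluded from the principal domain.
* A constant (degenerate) statistic sample, or fewer than 500 values, is an
  error in `fit_null_mixture`; a right-edge mode falls back to the
  theoretical null with a warning.
* Ties in the histogram mode go to the smaller statistic; ties in p-value
  ranks share the largest rank of the run.
* Records shorter than `2 * lag.max` reduce `lag.max` with a warning;
  records shorter than one segment are an error.
* `nboots < 100` warns (reduced-precision p-values); the p-value floor is
  $1/(\mathrm{nboots}+1)$, never 0.
* Harmonic lines closer than $10^{-8}$ Hz after aliasing are merged; lines
  within $10^{-9}$ Hz of DC are dropped.

## 9. Known limitations

* The Granger arm's absolute θ and lag depend on the estimator mode
  (whole-record fits run far less biased per segment than 500-sample fits);
  ratios are comparable across modes but θ is not.
* The empirical-null fit assumes the null bulk dominates the histogram mode
  (enforced by the $p_0 \le 0.9$ box); maps that are mostly coupled would
  need a different null.
* Conditions whose entire significant mass is inside (or outside) the
  neighborhood produce the boundary flags rather than information about
  specificity; they are excluded from medians, as in the study's own
  outlier rule.
* Only stationary, white-noise, three-channel multiplicative coupling is in
  scope; wavelet/multitaper variants and conditional (trivariate) causality
  are not implemented.
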