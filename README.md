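# qpcoupling

Detection of **specific quadratic phase coupling (QPC)** in trivariate time
series by cross-bicoherence and bivariate spectral Granger causality.

## The problem

When two oscillatory signals $X_1$ and $X_2$ (carrier frequencies $F_1$,
$F_2$) interact multiplicatively into a third channel,

$$X_3(t) = W\,X_1(t)\,X_2(t) + I_3(t) + \xi_3(t),$$

the product term creates a component at the sum frequency $F_1+F_2$ whose
phase is locked to the sum of the carrier phases — quadratic phase coupling.
Higher-order spectral estimators detect this, but in noisy data they also
flag *spurious* bifrequencies (e.g. ridges along the carrier axes), and the
stronger the coupling the more spurious detections appear. For applications
such as EEG/MEG connectivity one needs to know whether detected QPC is
*specific* to the carrier bifrequency. This package implements two
specificity indices:

* **R_BQPC** — the sum of significant magnitude-squared cross-bicoherence
  $\overline{b^2_{ijk}}(f_1,f_2)$ over a neighborhood
  $G(f_1,f_2;d)$ of the carrier bifrequency, divided by the sum over the
  whole bifrequency sector $Q(f_1,f_2)$ containing it;
* **R_GQPC** — the sum of significant bivariate Granger-causality spectrum
  values $\overline{\mathrm{BGCS}}_{ij\to k}(f)$ over the spectral interval
  around the (possibly aliased) sum frequency, divided by the sum over the
  whole band $(0, f_{\mathrm{Nyq}})$.

Both indices live in $[0,1]$; values near 1 mean the detected coupling is
concentrated where the physics says it should be. Significance is decided by
an empirical-Bayes two-class mixture fit (mode matching of a
$\chi^2_2$-family null on the $2L\hat b^2$ scale, right-tail FDR, $q<0.05$)
for the bispectral arm, and by a residual bootstrap of the no-causality null
with Storey pFDR q-values (Benjamini–Hochberg fallback) for the Granger arm.

The package also ships the three-channel simulator the indices were
validated on (triangular/rectangular/cosine carriers with per-epoch uniform
random phases plus unit Gaussian noise), its analytic signal-to-noise ratios

$$\mathrm{SNR}_{X_1}=\tfrac{\pi^2}{3},\qquad \mathrm{SNR}_{X_2}=1,\qquad
\mathrm{SNR}_{X_3}=\left(\tfrac{2\pi^2}{3}+2\right)W^2+\tfrac12,$$

and a batch driver that reproduces the simulation study (a grid of carrier
conditions crossed with coupling strengths
$W \in \{0.025, 0.05, 0.075, 0.15, 0.3, 0.75\}$, aggregated as per-coupling
medians).

## Worked example

```r
library(qpcoupling)

cond <- condition_spec(F1 = 120 / (2 * pi), F2 = 70 / (2 * pi),
                       F3 = 80 / (2 * pi), W = 0.05, seed = 3)
sim <- simulate_condition(cond)   # 128 epochs x 5 s at 100 Hz
fit <- qpc(sim, gc_mode = "welch", nboots = 100, lag_max = 20)
fit
```

```
Quadratic phase coupling analysis at (f1, f2) = (19.099, 11.141) Hz, d = 0.5 Hz
R_BQPC(19.099, 11.141; 0.5) = 0.8961 / 1.933 = 0.464  [sector Q_I]
  [GC arm: VAR(18), nboots = 100, theta = 0.01444805]
R_GQPC = 0.823 / 7.554 = 0.109  [interval [29.2, 31.2] Hz]
```

Reading the output: of all statistically significant cross-bicoherence mass
in sector Q_I, 46% sits within ±0.5 Hz of the true carrier bifrequency
(R_BQPC = 0.464); the Granger arm localises 11% of the significant causal
mass of $X_1 X_2 \to X_3$ in the interval around the sum frequency. At this
weak coupling the bispectral index is markedly more specific than the
Granger index, the study's central finding. `plot(fit)` draws the
significance map; `plot(fit, "gc")` the median BGCS spectrum with its
threshold $\theta$.

The simulation study itself:

```r
grid <- build_condition_grid()          # 58 conditions from the 6-frequency set
tab <- run_study(grid, couplings = 0.050,
                 config = within(default_config(), arms <- "bicoherence"))
aggregate_medians(tab)                  # median R_BQPC ~ 0.51 at W = 0.05
```

A command-line wrapper with `simulate`, `bicoherence`, `granger`, `qpc` and
`study` subcommands is installed at `inst/cli/qpctool.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/qpctool.R", package="qpcoupling"))')" \
    simulate --seed 1 --W 0.05 --out sim.tsv
```

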