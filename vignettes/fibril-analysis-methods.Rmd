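---
title: "Models and methods behind fibrilscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrilscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilscape)
```

fibrilscape implements the quantitative backbone of a multi-technique
characterisation of huntingtin exon-1 (polyQ) fibril formation and its
modulation by small-molecule inhibitors such as curcumin: SAXS modelling
and fitting of bundled fibrils, polyQ core geometry, ThT aggregation
kinetics, 1D ssNMR window integration, and TEM width morphometrics. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The SAXS model for bundled rod-like fibrils

A 1D scattering profile of a concentrated ensemble of long rod-like
fibrils is modelled as

$$I(q) = A\,\Big[\int_0^\infty P(q, r, L)\, N(r)\, dr\Big]\, S(q, d, \nu)
  + \frac{B}{q^n} + C,$$

with

* $P(q,r,L)$ the orientation-averaged form factor of a cylinder of radius
  $r$ and length $L$, normalised to $P(q\to 0) = 1$;
* $N(r)$ a log-normal distribution of the cross-section radius with median
  $r$ and log-space width $\sigma_r$ — fibril cross-sections are
  heterogeneous, and a log-normal keeps radii positive and right-skewed;
* $S(q,d,\nu)$ a PRISM-style (liquid-state) structure factor encoding the
  short-ranged lateral correlation between bundled fibrils at average
  distance $d$ with interaction strength $\nu$;
* $B/q^n + C$ a smooth background from everything not part of the
  fibrillar domains.

`model_intensity()` composes these; `cylinder_form_factor()`,
`lognormal_weights()` and `prism_structure_factor()` expose the parts.

### Orientation quadrature

The cylinder form factor is an integral over the angle between the rod
axis and the scattering vector. After substituting $t = \cos\alpha$ the
integrand contains $\mathrm{sinc}^2(qLt/2)$, which for $L = 1000$ nm
oscillates hundreds of times across the unit interval. We integrate with
panelised fixed-order Gauss–Legendre quadrature whose panel edges are
aligned to the sinc zeros $t_k = 2k\pi/(qL)$ (plus a uniform subdivision
for the slower Bessel factor). Eight nodes per half-oscillation panel make
the rule effectively exact; the test suite holds it to $10^{-4}$ relative
agreement against a 10,000-point trapezoid oracle, and in practice it
agrees to ~$10^{-10}$. The quadrature is fully vectorised over radii,
which is what makes polydisperse model evaluation affordable in R.

### Why the interaction kernel looks the way it does

The structure factor is $S(q) = 1/(1 + \nu\,\Omega(qd'))$ with the damped
oscillatory kernel $\Omega(x) = \sin(x)/x$. The literature form leaves the
kernel's argument scaling open, so we calibrate it: $d' = (x_1/2\pi)\,d$
with $x_1 \approx 4.4934$ the location of the kernel's first minimum. This
places the first maximum of $S$ exactly at $q_{\max} = 2\pi/d$, so the
fitted $d$ obeys the same Bragg-like convention,
$d_{\text{f-f}} = 2\pi/q_{\max}$, that one uses when reading a correlation
peak off a curve. Without this calibration the fitted "distance" would be
a kernel-dependent quantity ~40% away from the peak-derived one. The
calibration is contract-tested: for $\nu \in [0.5, 3]$ and
$d \in [10, 40]$ nm the argmax of $S$ stays within 2% of $2\pi/d$.

$\nu \ge 0$ is enforced; the attractive regime is not modelled.

### Polydispersity

The radius integral is discretised on a 41-point log-spaced grid spanning
$\pm 4$ log-SD around the median, with trapezoidal weights renormalised to
sum to one. A refinement test against a 2001-point grid keeps the
discretisation error below 0.5%. $\sigma_r < 10^{-4}$ is treated as
monodisperse (the log-normal collapses to a delta faster than any grid can
resolve).

### Fitting

`fit_model()` minimises log-space residuals,
$\sum_i \big[(\log I^{\text{obs}}_i - \log I^{\text{model}}_i)/w_i\big]^2$,
because SAXS intensities span four decades and linear residuals would fit
only the low-q plateau. When the profile carries per-point uncertainties,
$w_i = \sigma_i / I^{\text{obs}}_i$ (the relative error, which is the SD of
$\log I$ to first order); otherwise unit weights. Minimisation is
Levenberg–Marquardt with box bounds ($r \in [1, 20]$ nm, $d \in [5, 60]$
nm, $\nu \in [0, 10]$, $n \in [0, 4]$, $\sigma_r \in [0.01, 0.5]$), run
from five starts — the supplied or data-derived init plus four seeded
log-uniform ±30% perturbations of it — with best-of selection, because the
$(A, r, \sigma_r)$ and $(\nu, d)$ directions are correlated enough for a
single start to stall. When no init is supplied, the data-derived guess is
first refined by a coarse grid scan over $(r, \sigma_r)$ with the scale
$A$ profiled out in closed form: the Guinier-based radius guess is biased
low on strongly bundled curves (the rising structure factor masks the
cross-section decay), and without the scan all five perturbed starts can
inherit that bias and settle in a wrong basin. The rod length $L$ is structurally unidentifiable
in the probed q-range (it only sets the unobserved low-q roll-off) and is
always fixed, at 1000 nm by default.

During fitting the form factor is evaluated from a precomputed table on a
dense log-radius grid (4-point cubic Lagrange interpolation in log–log
space, interpolation error ~$2\times10^{-4}$ relative), built once per q
grid; the public `model_intensity()` default path uses exact quadrature.

Standard errors come from the scaled Gauss–Newton Hessian at the optimum
via an SVD pseudo-inverse; a parameter pinned at a bound reports `NA`
rather than a fabricated uncertainty. Noiseless self-generated curves are
recovered to ~$10^{-4}$% in the structural parameters; at 2% noise the
median error of $r$ and $d$ over random ground truths is below 5% and the
±2SE intervals cover the truth in well over 80% of runs (both are test
assertions).

### Derived analyses and their conventions

* `powerlaw_slope()` — OLS of $\log I$ on $\log q$; the negated slope is
  the exponent $\alpha$ of $I \propto q^{-\alpha}$. Long rods give
  $\alpha = 1$ in the window $2\pi/L \ll q \ll 1/r$. (The inequality is
  stated here in the physically meaningful direction: the rod regime sits
  *above* $2\pi/L$, not below it.)
* `find_correlation_peak()` — the raw curve of a bundled sample is often
  monotone, the "peak" being a shoulder on a decaying background.
  Detection works on the lowess-smoothed log–log curve: a genuine interior
  local maximum with side-valley prominence above 2% counts as a peak; a
  monotone curve is probed for a shoulder via a rise of the smoothed
  log–log slope (a pure decay has a monotonically falling slope, so any
  slope rise above 0.1 marks correlation-induced bending). Detection
  borrows up to half a decade of data below the search window as the
  pre-shoulder baseline. The apex is refined with a local quadratic on the
  raw curve, which is unbiased under any smooth local power-law trend;
  `d_eff = 2*pi/q_max` exactly. Reading a shoulder is intrinsically
  convention-laden: on full synthetic profiles the shoulder position
  corresponds to a distance within ~10% of the ground-truth $d$, while on
  pure structure-factor traces it is exact to <0.1%; the quantitative $d$
  should come from `fit_model()`.
* `cross_section_guinier()` — for rods, $\ln(qI)$ vs $q^2$ has slope
  $-R_c^2/2$; for a homogeneous cylinder $r = R_c\sqrt{2}$. The window is
  shrunk from the high-q side until $q_{\max} R_c \le 1.3$, the standard
  validity bound; non-linearity ($R^2 < 0.98$) sets a warning flag instead
  of failing. Against exact cylinder curves the implied radius is within
  ~3% (the residual bias of the finite window).
* `segment_regions()` — the conventional region boundaries (0.12,
  0.3 nm⁻¹) by default; detection reads them off the smoothed log–log
  slope instead: `q*` is where the slope first departs by more than 0.25
  from its low-q trend, and the upper bound is where it then drops below
  that trend into the steep high-q fall. (A free RSS-optimal piecewise-
  linear breakpoint fit was tried first and rejected: it spends its
  breakpoints on the strongly curved high-q fall and misses the gentle
  rod-to-intermediate bend entirely.) A pure power law — no slope change
  anywhere — reports "no breakpoint" and falls back to the defaults, with
  the method recorded in the result either way.

## PolyQ core geometry

The geometry module is deliberately plain arithmetic, because that is what
the structural argument is: each residue of an extended β-strand adds
~3.5 Å along the strand, so a strand of $n$ residues spans $0.35n$ nm.
A monomer contributing $s$ strands connected by turns of $t$ residues has
$(Q - (s-1)t)/s$ residues per strand, and filaments stack additively.
The default turn length is 4 residues (a canonical β-turn); it also
reproduces the hairpin arithmetic $(32-4)/2 = 14$ residues → 4.9 nm.
Whether a β-arc consumes a different residue count is deliberately left
as a parameter (`turn_len`) rather than decided. Widths are
polyQ-core-only: negative stain penetrates the disordered flanking
segments, so TEM widths are read as core widths.

`enumerate_architectures()` scans strand/filament combinations against an
observed width — e.g. ~10 nm Q32 fibrils admit either an extended
single-filament (11.2 nm) or a hairpin double-filament (9.8 nm) model,
which is exactly the ambiguity TEM alone cannot resolve.

## ThT kinetics

Preprocessing follows the plate-reader protocol: subtract the dye-only
control (interpolated onto the sample grid if the grids disagree), clip
negatives, normalise to the maximum observed signal. The ThT and curcumin
fluorescence channels are treated as one signal, since both gain
fluorescence on fibril formation.

The lag phase has no universal operational definition; we use the
tangent-intercept construction standard in amyloid kinetics: the steepest
5-point sliding linear fit defines the maximum growth rate, and the lag is
where that tangent (anchored at the observed centre point of the steepest
window) meets the pre-transition baseline (median of the points before
the steepest window, so the construction is shift-equivariant). `t50` is
the first half-amplitude crossing, linearly interpolated. Curves that
never cross half-amplitude report "no transition" rather than erroring.
Mechanistic nucleation-model fitting is out of scope.

The synthetic generator uses a logistic centred at `lag + 2/rate`, which
makes the generator's `lag_h` *exactly* the tangent-intercept lag of the
noiseless curve — the generator/extractor pair round-trips within one
sampling interval (0.25 h, one reading per 15 minutes). Lag and growth
steepness are independent knobs, since inhibitors can lengthen the lag and
change the growth steepness separately.

## ssNMR window integration

1D CP-spectrum areas are trapezoidal integrals on the native ppm grid
(no resampling, no default baseline correction) over named windows; window
edges are included by linear interpolation, making adjacent windows
exactly additive. Two window schemes ship as presets, matching the two
fibril batches digit for digit (batch 1: PCα 68.31–60.68, QCα 60.68–53.40,
PCδ 53.40–47.78 ppm; batch 2: 66.70–58.99, 58.99–51.79, 51.79–46.01 ppm).
Areas are normalised by the *point maximum* of the intensity inside the
QCα window — whether a fitted peak height would be preferable is an open
question; the point maximum is what is implemented and it is scale-exact
on clean spectra. Error bars are propagated from the noise SD of a
user-nominated signal-free region as `sd * step * sqrt(n_points)`.

## TEM morphometrics

Width samples are summarised on half-open `[lo, hi)` 1-nm bins anchored at
0 (the bin origin is unverifiable from published histograms; 1 nm is the
apparent granularity and the default). Condition comparisons report the
difference of means with a seeded 1000-resample bootstrap CI, Cohen's d,
and a two-sided Mann–Whitney p-value — a rank test because measured width
distributions are skewed. Both pooled-measurement and per-fibril-average
modes are supported (`collapse_fibrils()`), since several measurements are
typically taken along each fibril and the published choice between the two
modes is unknown.

## Synthetic data: what it does and does not emulate

The generators produce data with the *statistical structure* each analysis
assumes: Eq.-1 curves with multiplicative noise (2% Gaussian by default —
instrument noise characteristics are not published, so this is a
stand-in), truncated-normal width samples (floor 0.5 nm; the published
histograms do not identify a distribution family), logistic ThT curves,
and Gaussian/Lorentzian line spectra on a flat baseline. The default
untreated-like SAXS condition is 2r = 12 nm, d = 24 nm, σ_r = 0.25, ν = 1,
with scale A = 1 and a small background (B = 1e-5, n = 1, C = 2e-6,
roughly 10–40% of the fibrillar signal at the high-q end — backgrounds
larger than the signal would make any recovery claim vacuous); the
treated-like condition is 2r = 8 nm, d = 20 nm.

What passing tests on these data show: the model, fitter, extractors and
statistics are self-consistent, unbiased at realistic noise, and
deterministic under seeding. What they do not show: robustness to
instrument artefacts absent from the generators — smearing, detector
counting statistics, baseline drift and phasing errors in spectra,
fibril-picking bias in TEM, or real polymorph heterogeneity within one
sample. Every generator is a pure function of its parameters and seed, and
generators restore the caller's RNG state.

## Pipeline and reproducibility

`run_pipeline()` validates a config (stage names, parameter keys, input
paths) before anything runs, fans one run seed out into per-stage child
seeds by stable string hashing of the stage name (so adding or reordering
stages never changes another stage's draws), and writes write-once JSON
outputs plus a plain-text summary. The `demo` stage runs the synthetic
end-to-end comparison — simulate the untreated/treated pair, fit both,
flag the reduced cross-section — and is byte-deterministic given a seed.

Problem sizes used in the shipped tests and demonstration (200-point
profiles, 20-fit recovery studies, 100-replicate kinetics ensembles,
1000-resample bootstraps) were chosen as the smallest sizes at which the
statistical assertions are comfortably stable under the fixed seeds.

## Known limitations

* The PRISM kernel is a calibrated $\mathrm{sinc}$ form, not the exact
  published liquid-state expression (whose parameterisation is not in the
  public text); the calibration contract pins the one observable property
  (peak position ↔ distance convention) that the downstream analyses use.
* No instrument smearing or absolute-intensity calibration; no 2D
  detector reduction; no mechanistic kinetics fitting; no FID processing
  or 2D NMR; no micrograph segmentation.
* Reading $d$ from a shoulder on a full profile carries a ~10% convention
  bias (see above); use the fit.
* The unified exponential/power-law description of isolated single
  fibrils is approximated by the modified cross-sectional Guinier
  analysis, which is the piece of that description the width comparison
  actually needs.
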