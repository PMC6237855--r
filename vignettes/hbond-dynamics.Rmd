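---
title: "Hydrogen-bond rearrangement dynamics and echo observables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond rearrangement dynamics and echo observables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdyn)
```

`hbdyn` post-processes liquid-water molecular-dynamics output into
hydrogen-bond (HB) rearrangement observables.  The chain it implements is

1. instantaneous OH stretch frequencies $\omega(t)$ per mode, by a
   continuous wavelet transform (CWT) of the bond phase-space signal;
2. per-pair HB metrics consumed from energy-decomposition output: the
   donor$\to$acceptor stabilization energy $\Delta E_{D\to A}$ (kJ/mol,
   negative = stabilizing) and charge transfer $\Delta CT_{D\to A}$ (a.u.),
   plus the derived local solvent reorganization index (LSRI)
   $O_h = D_{Acc} + A_{Don} - D_{Don} - A_{Acc}$;
3. least-squares linear maps $y = b + m\,\omega$ between frequency and each
   metric, with their RMSE;
4. time-correlation functions (TCFs) of the fluctuations of each quantity
   — FTCF, HBCF, CTCF, LSRI-TCF — plus the continuous HB survival
   $S_{HB}(t)$ and the HB-number correlation $N_{HB}(t)$, each summarized by
   a bi-exponential fit
   $f(t) = a_0 e^{-t/\tau_0} + (1 - a_0)\,e^{-t/\tau_1}$ with 3-block
   standard errors;
5. third-order echo observables in the second-order cumulant
   approximation: the lineshape function $g(t)$ (double time-integral of the
   unnormalized FTCF), the integrated three-pulse echo intensity
   $I(t_1, t_2)$, and its short-time slope S3PE
   $S(t_2) = \partial I/\partial t_1 |_{t_1=0}$, normalized to
   $C(t_2) = S(t_2)/S(0)$.

Units are Angstrom, femtosecond, amu, cm$^{-1}$ and kJ/mol throughout, and
all molecule/atom indices are 1-based (both in the R API and in the TSV
formats; a single convention avoids off-by-one translation errors).

## The wavelet frequency tracker

The mother wavelet is the Morlet–Grossman form
$\psi(t) = (\sigma^2\pi)^{-1/4} e^{2\pi i \lambda t} e^{-t^2/2\sigma^2}$
with defaults $\lambda = 1$, $\sigma = 2$, the values in common use for
time-frequency analysis of MD series; both are configurable.  The signal
analysed for each OH mode is the mean-removed complex pair
$f(t) = \delta r(t) - i\,\delta p(t)/(\mu\bar\omega)$, where $r$ is the O–H
bond length, $p = \mu\,\dot r$ the reduced-mass relative momentum projected
on the instantaneous bond axis, and $\bar\omega$ a fixed scaling frequency
taken at the centre of the admissible window.  This scaling makes the two
parts commensurate, so for a harmonic mode the signal rotates uniformly at
$+\omega$ and a positive-frequency wavelet localizes it; the recovered
argmax is insensitive to moderate mis-scaling of $\bar\omega$.

The transform $L_\psi f(a,b) = a^{-1/2}\int f(t)\,\bar\psi((t-b)/a)\,dt$ is
evaluated by FFT cross-correlation per scale, with the wavelet truncated at
$|t-b| > 4a\sigma$; analysis times where that support is clipped by the ends
of the record are flagged `edge`.  Scales form a geometric grid (default
256 points) spanning 2800–4000 cm$^{-1}$, the OH stretch band of ambient
water, giving sub-5-cm$^{-1}$ resolution; a scale maps to wavenumber
$\nu = \lambda/(a\,\Delta t\,c)$.

One numerical choice matters here: the scale is selected by maximizing the
*amplitude-normalized* modulus $|L|/\sqrt{a}$ rather than $|L|$ itself.
The $a^{1/2}$ prefactor that $|L|$ carries for a pure tone shifts its argmax
by a relative $1/(2\sigma^2(2\pi\lambda)^2) \approx 0.3\%$ — two to three
grid steps at the default resolution — whereas the normalized modulus is an
unbiased Gaussian in $a\omega$.  With this choice a pure tone is recovered
within one grid step, and halving the grid step halves that bound.  An
argmax landing on the boundary of the scale grid is flagged (`boundary`),
never silently clipped: it usually signals a mis-configured window or a
degenerate (zero-amplitude) signal.

## The LSRI sum convention

For a bonded pair (D, A), the four terms of $O_h$ sum the signed
$\Delta E$ over *all* bonds of the molecule in the given role, including
the pair's own bond; `exclude_self_bond = TRUE` implements the alternative
reading.  Energies enter with their sign (stabilization negative), so an
isolated dimer with $\Delta E = -20$ kJ/mol has
$O_h = 0 + 0 - (-20) - (-20) = +40$ kJ/mol — this dimer value fixes the
sign convention.  Reversing every bond of a graph maps each molecule's
donated sums onto its accepted sums, so the index of a pair followed
through the reversal is invariant, while evaluating with the pair's
donor/acceptor slots held fixed flips its sign.  No energy threshold is
imposed on pair membership — the pair table defines it — but an optional
cutoff exists because energy-decomposition codes emit near-zero entries
for marginal contacts.

## Linear maps and the reference coefficients

Maps are ordinary least squares of the observable on frequency ("simple"
least squares, not total least squares), with
RMSE $=\sqrt{\overline{r^2}}$.  The package primarily *fits* maps from
data.  The stored reference coefficients for ambient water,

```{r}
water_frequency_maps()
```

place the small-magnitude coefficient as the slope (per cm$^{-1}$) and the
large one as the intercept, with signs chosen so that the HB weakens (both
$|\Delta E|$ and $\Delta CT$ shrink) as the frequency rises and the
magnitudes are physical at 3400 cm$^{-1}$ ($\Delta E \approx -17$ kJ/mol,
$\Delta CT \approx 0.011$ a.u., LSRI $\approx 12.7$ kJ/mol).  A bare pair
of numbers does not identify which is slope and which is intercept, so
this placement is a documented interpretation fixed by those physical
constraints, not a recovered convention.

## Time-correlation functions

The TCF engine pools all (entity, origin) products per lag — the literal
ensemble average — using FFT autocorrelations per contiguous segment;
absent stretches (a pair that is not bonded) contribute nothing rather
than being zero-filled, which would fabricate decay.  Fluctuations are
taken about the **pooled ensemble mean** by default.  The alternative,
subtracting each entity's own sample mean, is available
(`center = "entity"`) but biased for records only a few tens of
correlation times long: the sample mean absorbs the slow components and
depresses the TCF tail by roughly $2\bar\tau/T$, which at 24 ps and
$\tau_1 \approx 1$ ps drags the fitted long constant down by about 25%.
The ensemble mean over 128 statistically equivalent modes carries none of
that bias.  Curves are normalized by $C(0)$ on request, and per-lag block
standard errors use contiguous thirds of the record (the 3 × 8 ps division
appropriate to a ~1 ps decay on a ~24 ps record).

When an observable is a linear image of the frequency plus
frame-uncorrelated measurement scatter, its TCF is
$m^2 C_\omega(t)$ everywhere except lag 0, where the scatter adds a
"nugget" $\sigma^2$.  A bi-exponential fit of the normalized raw curve
then misreads the nugget as an ultrafast component and blends the true
components into one intermediate timescale.  `denoise_lag0()` replaces
$C(0)$ by the quadratic extrapolation of lags 1–3 back to zero,
recovering the dynamical variance; the pipeline applies it to the
synthetic HBCF/CTCF/LSRI-TCF before fitting and before the cumulant
conversion.

$S_{HB}(t)$ uses the strictly continuous definition (no transient breaks;
an `allowance` in frames exists, default 0).  Its estimator restricts time
origins to $t_0 \le T - t_{max}$, which makes the curve exactly
non-increasing, bounded in [0, 1], and free of end-of-record censoring.
$N_{HB}(t)$ counts donated plus accepted bonds per molecule and normalizes
by the fluctuation variance, so $C(0) = 1$ identically; a constant count
(zero variance) is an error, not a silent NaN.

The bi-exponential fitter is Levenberg–Marquardt with a multistart grid
($\tau_0 \in \{0.02, 0.05, 0.1\}$ ps, $\tau_1 \in \{0.5, 1, 2\}$ ps,
$a_0 \in \{0.3, 0.7\}$), bounds $a_0 \in [0,1]$, $\tau > 0$, SSE tolerance
$10^{-14}$, and $\tau_0 \le \tau_1$ ordering after the fit.  The default
window, 0 to min(4 ps, 40% of the lag range), avoids the noisy far tail.
On noiseless bi-exponential input the parameters are recovered to
$10^{-6}$ relative.  Two degeneracies are handled explicitly:
single-exponential input drives one amplitude to 0 or 1 (the active branch
carries the timescale), and on noisy curves the slow branch sometimes
parameterizes a flat noise floor with an absurd $\tau_1$ and small
amplitude.  `biexp_long_time()` therefore reports $\tau_1$ only when its
amplitude exceeds 0.05 *and* it is resolved within five fit-window spans;
otherwise the active branch.  For processes known to be single
relaxations — the two-state Markov oracles behind $S_{HB}$ and
$N_{HB}$ — a bi-exponential is ill-posed, and `fit_exp()` is the
appropriate summary.

## Cumulant echo observables

Frequency fluctuations are treated as Gaussian, so everything follows from
$g(t) = \int_0^t\!\!\int_0^{t'} C(t'')\,dt''\,dt'$ with $C$ the
unnormalized FTCF converted to angular units by $(2\pi c)^2$.  The
classical (high-temperature) treatment drops the imaginary solvation part
of $g$, the conventional choice when the input is a classical fluctuation
statistic.  The double integral is reduced exactly to
$g(t) = t\int_0^t C - \int_0^t sC(s)\,ds$ and evaluated by
endpoint-corrected (Euler–Maclaurin) trapezoids on a spline-refined 1 fs
grid: a plain trapezoid is only $O(\Delta t/\tau_c)$ accurate *relative to
g* near $t = 0$ where $g \sim t^2$, while the corrected form matches the
static ($g = \Delta^2 t^2/2$) and Kubo
($g = \Delta^2\tau_c^2(e^{-t/\tau_c} + t/\tau_c - 1)$) closed forms to
better than $10^{-4}$.

The three rephasing pathways are taken in the Condon, two-level cumulant
form, all sharing the envelope
$\exp[-g(t_1) + g(t_2) - g(t_3) - g(t_1{+}t_2) - g(t_2{+}t_3) +
g(t_1{+}t_2{+}t_3)]$; the 1$\to$2 anharmonic pathway, vibrational
lifetime, non-Condon weighting and finite pulses are out of scope.  S3PE
depends only on the shape of this envelope, which is why the approximation
suffices: in the static limit the integrand rephases symmetrically about
$t_3 = t_1$ and the normalized slope stays at 1, while under fast
modulation ($\Delta\tau_c \to 0$) the echo disappears and
$I \propto e^{-2\Delta^2\tau_c t_1}$ — both limits are tested against
closed forms.  $I(t_1,t_2)$ integrates the squared envelope over $t_3$ by
trapezoid (default $dt_3 = 2$ fs to 2 ps); if the integrand tail exceeds
$10^{-3}$ of its peak the surface carries a truncation warning, and absent
that warning doubling $t_3^{max}$ moves $I$ by less than 0.1%.  The slope
at $t_1 = 0$ uses the one-sided second-order stencil
$(-3I_0 + 4I_1 - I_2)/2\Delta t_1$ with $\Delta t_1 = 2$ fs.

To drive the same pipeline with HB-strength or charge-transfer
fluctuations, the observable TCF is divided by the squared slope of its
fitted frequency map (so $C_y \to C_\omega$ in cm$^{-2}$), after nugget
removal.  How such a conversion should be done is genuinely open; this
choice is linear, explicit, and flagged in the output metadata.

## What the synthetic generators emulate

The generators define the study conditions; they are first-class, tested
code, not fixtures.

* `gen_frequency_process()`: stationary Gaussian tracks whose
  autocorrelation is exactly the bi-exponential target, realized as the sum
  of two Ornstein–Uhlenbeck processes with variances $a_0\Delta^2$ and
  $(1-a_0)\Delta^2$ — exact, trivially seeded, no spectral filtering.
  Defaults: mean 3400 cm$^{-1}$, $a_0 = 0.6$, $\tau_0 = 0.1$ ps,
  $\tau_1 = 1.01$ ps, $\Delta = 100$ cm$^{-1}$.  The long constant is the
  reported ambient-water FTCF value; $a_0$, $\tau_0$ and $\Delta$ are not
  reported anywhere and are fixed here once at values typical of ambient
  water OH-stretch dephasing (sub-100-fs librational component carrying
  somewhat more than half the variance, ~100 cm$^{-1}$ inhomogeneous
  width).
* `gen_coupled_observables()`: $\Delta E$, $\Delta CT$ and LSRI as linear
  images of the frequency plus Gaussian scatter matching the reference
  RMSEs (7.27 kJ/mol, 0.004 a.u.; 5 kJ/mol for LSRI, whose scatter no
  reference value pins — chosen comparable to the $\Delta E$ scatter on
  the LSRI scale).  The scatter is white by construction, which is exactly
  what the nugget correction above addresses.
* `gen_markov_hbonds()`: independent two-state chains started from
  equilibrium with per-step survival $e^{-k\,\Delta t}$, so continuous
  bonded intervals are geometric with mean exactly $1/k_{break}$, the
  indicator autocorrelation relaxes with $1/(k_{break}+k_{form})$, and the
  bonded fraction is $k_{form}/(k_{form}+k_{break})$.  The pipeline preset
  uses $1/k_{break} = 1.2$ ps with $k_{form}$ chosen so the relaxation is
  0.74 ps — both reported values planted in one ensemble.
* `gen_oscillator_trajectory()`: a single O–H with
  $r = r_0 + A\cos\phi(t)$, $\dot\phi = 2\pi c\,\omega(t)$ and analytic
  velocities, for closed-loop wavelet tests.

What they do *not* emulate: the short-time oscillatory (librational) beat
of the real HBCF, non-Gaussian frequency statistics, cross-correlation
between modes, cooperative bond switching, or any real HB-network
geometry.  Passing the planted-recovery suite therefore shows the
*estimators* are correct and unbiased at realistic record lengths; it does
not validate the Gaussian or Markov assumptions against real water.

## Problem sizes and reproducibility

The shipped analyses use 128 modes × 24 ps at 5 fs for frequency-driven
quantities, 500 bonds × 25 ps for the Markov ensembles, lags to 6.2 ps,
fits on 0–2.5 ps (40% of the lag range), and echo grids
$\Delta t_1 = \Delta t_3 = 2$ fs, $t_3 \le 2$ ps, $t_2 \le 4$ ps — the
scale of the original study, where the estimators resolve a ~1 ps constant
to roughly 5% (one seed's draw).  Every generator takes an explicit
integer seed and is byte-reproducible; `run_pipeline()` is fully
determined by its `run_config()` plus seed, and writes a config hash into
its summary.

## Known limitations

* The cumulant echo module is not a 2D-IR simulator: no anharmonic
  pathways, populations, or polarization conditions.
* The HB geometric criterion (default $r_{OO} \le 3.5$ Å, angle
  $\le 30°$) is the standard lifetime-literature choice but is exposed as
  configuration because no single criterion is canonical.
* Wavelet tracks at the record edges ($|t - b| < 4a\sigma$ clipped) are
  flagged rather than corrected; downstream statistics should drop them.
* The bi-exponential model is summary, not truth: where a decay is single
  exponential its $\tau_1$ is reported from the active branch, and
  stretched or tri-exponential behaviour is out of scope.
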