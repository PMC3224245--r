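---
title: "Signal and noise propagation in the chemotaxis pathway: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal and noise propagation in the chemotaxis pathway: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemnoise)
```

## The model

`chemnoise` models the chemotaxis signalling pathway of *Escherichia
coli* from ligand binding at cooperative chemoreceptor complexes to the
switching of the flagellar rotary motor, with every step treated as a
stochastic process. The pathway is described by Langevin equations:
deterministic kinetics plus additive Gaussian white noise whose
intensity equals the sum of the one-way reaction fluxes of the
corresponding process at the adapted state (for a process at
steady-state balance, twice the one-way flux).

**Receptors.** `N` receptor dimers (a mix of Tar and Tsr) form one
signalling complex that switches rapidly between an active and an
inactive conformation. Its mean activity is the two-state (MWC) form
$A = N/(1 + e^{F})$ with free energy

$$F(c, M) = N\epsilon_0 - \tfrac{M}{2} +
  N\left[\nu_a \ln\frac{1 + c/K_a^{off}}{1 + c/K_a^{on}} +
         \nu_s \ln\frac{1 + c/K_s^{off}}{1 + c/K_s^{on}}\right],$$

so each methyl group contributes $-1/2\,k_BT$ while the offset and the
ligand term are additive over the `N` receptors. Two consequences are
used repeatedly: $\partial A/\partial M = N A_r (1 - A_r)/2$ and
$\partial A/\partial c \propto N^2$ at fixed per-receptor activity
$A_r = A/N$ — complexes amplify ligand changes in proportion to their
size. A cell carries $N_C = N_{tot}/N$ complexes that signal
independently.

**Adaptation.** Methylation by CheR acts on inactive receptors at rate
$\gamma_R (N - A)$; demethylation by phosphorylated CheB acts on active
receptors at rate $\gamma_B [B_p]^2 A$ (the quadratic CheB-P dependence
reproduces the strongly activity-dependent demethylation seen in
adaptation time courses). In the simplified single-complex model the
demethylation rate is taken as $\gamma_B^{(s)} A^3$, whose adapted
per-receptor activity solves the cubic $A_r^3 + \beta A_r - \beta = 0$,
$\beta = \gamma_R/\gamma_B^{(s)} N^2$, a function of the rate ratio
alone (`adapted_activity_simplified()`).

**Phosphorylation.** Active receptors drive CheA autophosphorylation;
CheA-P transfers its phosphoryl group to CheY (motor control) and CheB
(adaptation feedback); CheY-P and CheB-P are dephosphorylated at
first-order rates, with CheZ-catalysed hydrolysis absorbed into the
effective CheY-P rate. Copy numbers, not concentrations, are the state
variables; the cell volume converts between the two.

**Motor.** The motor is a two-state (CW/CCW) system. Its
occupancy-averaged switching rates as a function of CheY-P follow a
cooperative 26-subunit ring model in `mwc` mode; for all spectral and
SNR computations the default is the `linearized` mode parameterised
directly by the steady-state rates $k_+^*, k_-^*$ and their CheY-P
slopes, because those operating-point numbers are experimentally
anchored while the ring-model constants are not (the shipped `mwc`
constants are a reconstruction that reproduces the same operating
point: equal rates — CW bias 1/2 — at 3.2 uM CheY-P, and wild-type
rates 1.05 and 1.06 1/s there). The Langevin representation of the
two-state motor is exact, and the package cross-validates it against an
event-driven telegraph simulator.

## Calibration of the operating point

The package's wild-type defaults pin the adapted state at per-receptor
activity $A_r^* \approx 1/3$ and CheY-P $\approx 3.2$ uM (the
concentration at which the calibrated motor has CW bias 1/2). With the
shipped totals and rate constants, those anchors fix the CheA
autophosphorylation constant at $k_A = 10\,\mathrm{s^{-1}}$: solving
the four steady-state balances jointly then yields $A_r^* = 0.333$,
CheA-P $= 0.026$ uM, CheB-P $= 0.062$ uM and CheY-P $= 3.30$ uM, and
the motor frequency $\omega_X = k_+^* + k_-^* = 2.11\,\mathrm{s^{-1}}$.
A much faster autophosphorylation constant (values up to
$10^3\,\mathrm{s^{-1}}$ circulate for the isolated enzyme) would drive
the adapted CheY-P close to saturation and the adapted activity far
below 1/3, inconsistent with these anchors; `k_A` remains a config
parameter for users who want that regime.

```{r steady-state}
params <- pathway_params()
solve_steady_state(params, c0 = 0)
```

## Frequency-domain analysis

Linearising around the adapted state and Fourier transforming gives the
response function per observable, $\hat{\chi}_R(\omega)$, and the noise
power spectrum $S_R(\omega)$ (two-sided, in rad/s, with
$\langle \delta R^2\rangle = \frac{1}{2\pi}\int S_R\,d\omega$). For the
simplified pathway these are closed forms: the receptor activity is a
high-pass filter

$$\hat\chi_{A_c}(\omega) =
  \frac{-i\omega\, N_C\, \partial A/\partial c}{\omega_M - i\omega},$$

with adaptation frequency $\omega_M = \omega_1 \partial A/\partial M$,
$\omega_1 = \gamma_R (3 - 2A_r^*)/A_r^*$, and the motor adds a low-pass
filter $\omega_2/(\omega_X - i\omega)$. The activity spectrum collects
receptor-switching, ligand-diffusion and methylation noise, each
filtered by adaptation; the motor spectrum adds the dominant switching
Lorentzian $Q_X/(\omega^2 + \omega_X^2)$,
$Q_X = 2k_+^*k_-^*/(k_+^* + k_-^*)$.

For the full pathway no closed form is transcribed; instead a generic
linear-noise matrix engine (`linearize_full()`, `response_full()`,
`spectrum_full()`) assembles the Jacobian analytically, routes each
elementary white-noise source through
$(-i\omega I - J)^{-1} G$ and sums $|\cdot|^2 Q_s$ per source. Shared
phosphotransfer noises (CheA-P to CheY-P, CheA-P to CheB-P) enter the
donor and acceptor equations with opposite signs through a single
source column, which is what correlates their fluctuations. The
closed-form simplified model is the regression oracle for this engine:
with `reduce = TRUE` the matrix system collapses to the two-variable
high-pass/low-pass cascade and reproduces the closed forms to machine
precision (a construction identity, verified in the tests).

State variables of the linear system: the total activity $A_c$
(relaxing at the fast switching rate $k_1 + k_2$ towards the MWC
activity, with $k_1 = k_2 A_r^*/(1 - A_r^*)$ so that the fast
equilibrium reproduces the adapted activity), the ligand count in a
complex-sized sensing volume (exchange rate $k_D = D/2s^2$, complex
diameter $s = \sqrt{N} s_R$), the mean complex methylation, the three
phosphorylated copy numbers and the motor bias. Per-complex noise
sources are independent across complexes and enter the aggregate with
$\sqrt{N_C}$ (incoherent) scaling, while a concentration stimulus
drives all complexes coherently ($N_C$) — this asymmetry is the origin
of the optimal-amplification results below. A `ligand_correlated`
switch makes the ligand noise coherent across the whole cluster
instead.

**Ligand noise.** The diffusion constant `D` of the attractant is not
part of the measured pathway set; the default is a typical
small-molecule value, $10^3\,\mathrm{\mu m^2 s^{-1}}$, and every
ligand-noise output carries the value used. The intensity is
$Q_L = 2 D s c_0$ (with $c_0$ as a number density), consistent with the
twice-the-one-way-flux convention; `ql_factor` exposes the
single-flux alternative. The zero-frequency concentration spectrum
then evaluates to $8 c_0/(D s)$ in number-density units — the
diffusion-limited (Berg–Purcell-type) sensing floor up to the
prefactor, which the package reports as computed rather than forcing a
particular constant.

## Time-domain engines

Deterministic responses use plain forward Euler with the receptor
activity recomputed from the current ligand concentration and
methylation at each step (default $\Delta t = 10^{-3}$ s; halving the
step changes an impulse-response peak by under 0.5%). Stochastic runs
use Euler–Maruyama at $\Delta t = 10^{-4}$ s with noise intensities
frozen at the adapted state (additive noise), so the simulated
fluctuations linearise exactly onto the analytic spectra. One
refinement: the receptor-activity state relaxes at
$k_1 + k_2 \approx 1.5\times10^3\,\mathrm{s^{-1}}$, where a plain
Euler–Maruyama step inflates the stationary variance by
$\sim k_{12}\Delta t/2$; this single stiff state therefore uses the
exact Ornstein–Uhlenbeck update (exponential relaxation towards the
MWC target plus the exact stationary increment). The ligand
concentration noise relaxes at $k_D \sim 10^7\,\mathrm{s^{-1}}$, far
above any simulated band, and is sampled as its white low-frequency
equivalent. With every noise source disabled the stochastic engine
reproduces the deterministic integrator bit for bit.

For spectral estimation the engine can record block means over the
sampling interval (a boxcar anti-aliasing filter); plain decimation
would fold the fast receptor-switching spectrum into the analysis band
and bias the comparison with the analytic spectra by tens of percent.
Binary motor traces are recorded as instantaneous states, as a
tethered-cell camera would.

The motor can be simulated either as a continuous Langevin bias (the
Gaussian approximation, exact at the level of second-order statistics)
or as a discrete telegraph process driven by the instantaneous rates;
`simulate_telegraph()` additionally provides the exact event-driven
simulator (exponential dwell times; Ogata thinning with a bound
refreshed every 0.01 s when the rates vary in time).

## Signal-to-noise analyses

The integrated squared response
$\Delta R^2 = \frac{1}{2\pi}\int |\hat\chi_R \hat{\Delta c}|^2 d\omega$
and the band-limited variance
$\frac{1}{2\pi}\int_{-\tau^{-1}}^{\tau^{-1}} S\,d\omega$ define the
SNR at the motor (`snr_at_motor()`). Conventions:

* The variance band edge is $\tau^{-1} = 1$ rad/s by default (the
  range relevant for motor switching is of order 0.1–1 Hz;
  `tau_band` exposes the choice, and results in this range are not
  sensitive to it at the reported qualitative level).
* The transmitted variance counts receptor switching, ligand
  diffusion, methylation and phosphorylation; the motor's own
  switching noise is excluded unless `include_motor_noise = TRUE`.
* A step stimulus is 10% of the background concentration. Its
  spectral density is the pure-step $h^2/\omega^2$ regularised below
  $1/T_w$ by a finite observation window ($T_w = 10^3$ s by default);
  quadrature uses the oscillation-averaged envelope. For asymptotic
  scaling studies the window is lengthened to
  $\max(10^3, 100/\omega_M)$ s so the integrated response attains its
  adaptation-limited value.

Quadratures are trapezoidal on dense logarithmic grids (about 150
points per decade), validated in the tests against closed forms (the
step response against
$(N_C \partial A/\partial c)^2 (\alpha c)^2 / 2\omega_M$, band
variances against flat and Lorentzian integrals).

**Scaling laws.** At the receptor level the module recovers, by
log-log regression over explicit grids: integrated step response
$\propto N$; receptor-switching variance independent of $N$; ligand
variance $\propto N^{5/2}$ (incoherent addition, $N^2$ amplification,
$\sqrt N$ sensor size); methylation variance approximately
$\propto N$; and for small $\gamma_R$, response
$\propto \gamma_R^{-1/3}$ and switching variance
$\propto \gamma_R^{1/3}$, hence the switching-noise-limited SNR
$\propto \gamma_R^{-2/3}$. One caution discovered while verifying
these laws numerically: evaluated exactly, the methylation variance
scales as $\gamma_R^{2/3}$ (not $\gamma_R^{1}$, the rate often quoted
from a cruder estimate) and, with the wild-type constants, dominates
the transmitted variance at every accessible $\gamma_R$, so the SNR
built on the *total* transmitted variance scales as
$\gamma_R^{-1}$. The package therefore reports the $-2/3$ law for the
quantity it actually describes — the SNR against the
receptor-switching noise floor — and exposes all per-source variances
so either convention can be computed.

**Complex-size sweep.** With the totals fixed, increasing $N$ raises
the coherent signal amplification linearly while the ligand noise
grows as $N^{5/2}$, so the SNR must eventually peak at a finite
optimal complex size. Where that optimum falls depends strongly on
the ligand-noise magnitude, i.e. on $D$: with the physical
$D = 10^3\,\mathrm{\mu m^2 s^{-1}}$ the methylation and
phosphorylation variances (both growing $\approx$ linearly, like the
signal) still exceed the ligand term by two to three orders of
magnitude for all $N \le 100$, so over that range the computed SNR
rises monotonically and the optimum sits far beyond biologically
reported cooperativities (it moves into the tens-of-units range only
for $D$ of order $1\,\mathrm{\mu m^2 s^{-1}}$, e.g. strongly hindered
transport near the cluster). The package reports what the equations
give at the stated $D$ rather than tuning $D$ to place the optimum;
`sweep_complex_size()` exposes every component so the dependence can
be examined.

**Adaptation-rate sweep.** The asymmetry between the two adaptation
enzymes is reproduced: lowering $\gamma_R$ slows adaptation faster
than it quenches the response, so the integrated response and the SNR
grow as $\gamma_R \to 0$; lowering $\gamma_B$ saturates the adapted
activity ($A_r^* \to 1$), quenching response, transmitted noise and
SNR once $\gamma_B$ falls a few orders below its wild-type value. Both
saturation limits quench the transmitted variance.

**Fluctuation–response.** Sweeping $\gamma_R$, $\gamma_B$ or the CheY
total shifts the adapted CheY-P concentration; the total CheY-P
variance (full integral of the analytic spectrum) is maximal when
about half of CheY is phosphorylated (adapted CheY-P near 5 uM with
the wild-type total of 9.7 uM), while the variance normalised by the
squared adapted value decreases with adapted CheY-P except at the
smallest values. The adaptation time is reported as $1/\omega_M$. On
the short-adaptation-time side of the variance peak, adaptation time
and CheY-P variance rise together — an approximate
fluctuation–response relation — while the long-time branch reverses
it, tracing the non-monotonic variance.

## What the synthetic data emulate

The generator produces: triangular attractant impulses (peak
$10^{-3}$ mM, 0.02 s, on a zero background — small-signal by
construction against $K_a^{off} = 0.02$ mM), steps of 10% of
background, sinusoids for in-silico frequency scans, stationary noisy
trajectories of every pathway species, and tethered-cell-like binary
motor traces (video-rate sampling at 1/60 s, default length
$10^3$ s). Every dataset carries its generating parameters and seed.
Deliberately *not* emulated: bead/tether measurement artefacts
(Brownian wobble, tracking error), ligand rebinding corrections,
receptor-cluster heterogeneity between cells, and gene-expression
noise in protein totals. Passing tests on these data therefore
demonstrate internal consistency of the model and estimators — e.g.
that a $10^4$ s trace suffices to recover $\omega_X$ to 5% — not that
real tethered-cell records are this clean.

Parameter-recovery fixtures pair a deterministic impulse response with
a long motor trace. The impulse response decays back at the full
model's slow relaxation eigenvalue, which the CheB-P feedback makes
about 14% faster than the bare methylation estimate
$\omega_M = \omega_1 \partial A/\partial M$; the fixture's ground
truth is that eigenvalue (both values are recorded).

## Numerical choices and degenerate inputs

* Copy numbers round to the nearest integer; all internal balances use
  the rounded totals consistently, so steady-state residuals are below
  $10^{-9}$.
* $N_C$ rounds to at least 1; $N_{tot}^{eff} = N_C N$ is used
  throughout so complexes and receptors stay consistent.
* Steady states are found by nested bracketed root solves
  (per-receptor activity outer, CheA-P inner), tolerance $10^{-14}$;
  the bracket covers $(0, 1)$ so saturated adaptation limits remain
  solvable.
* Free energies are evaluated through `plogis`, safe for $|F|$ of
  hundreds; `log1p` forms avoid cancellation at small concentrations.
* Phases are unwrapped cumulatively; magnitudes and phases come from
  one complex response object, so cascades retain sign conventions
  (negative response to attractant appears as a phase of $\pi$ at high
  frequency).
* Degenerate inputs error early with the offending field named:
  negative rates or concentrations, zero-background steps,
  out-of-range adaptation targets, bands wider than the computed
  spectrum.

## Problem sizes used in the shipped checks

The test suite exercises the stochastic engines at the scales the
statistics require and no further: the ensemble comparison of
simulated against analytic spectra uses 200 replicates of $10^3$ s at
$\Delta t = 10^{-4}$ s; telegraph statistics use single $10^4$–$10^5$ s
traces; parameter-recovery uses one $10^4$ s trace. Sweeps use grids
of 5–33 points per axis with 600–1600 frequency points. These sizes
were chosen so that Monte-Carlo error sits well inside the asserted
tolerances (binned spectral ratios within 10%, variance closures
within 2%).

## Known limitations

* Methylation is tracked as one aggregate level per representative
  complex (scaled fluctuations), not per-site or per-complex states.
* Noise intensities are frozen at the adapted state (additive-noise
  Langevin); far-from-adapted transients carry approximate noise.
* CheY-P/CheZ complex formation, CheR/CheB localisation kinetics and
  gene-expression noise are outside the model.
* The `mwc` motor constants are a reconstruction of an operating
  point, not a fit to rate-vs-CheY-P data; quantitative motor-rate
  curves away from the operating point should not be read off them.
* Parameter fitting to experimental response or spectral data is out
  of scope; shipped parameter sets are forward-model configurations.
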