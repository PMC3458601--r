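---
title: "Ion track structure and microdosimetry with iontrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion track structure and microdosimetry with iontrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontrack)
```

`iontrack` is a single-interaction Monte Carlo simulator for the passage of
therapeutic ions (protons through oxygen and carbon) through slab targets,
with the observables of experimental microdosimetry and multiple-scattering
benchmarks: projected-angle distributions and their Gaussian-core widths,
radial dose profiles of individual ion tracks, depth--dose curves, and
lineal-energy spectra in micrometer tissue-equivalent sites. This vignette
describes the physics models, the numerical choices behind them, and what
the simulated conditions do and do not capture about real beamlines.

## Transport model

Primary ions are transported event by event rather than by a condensed
random walk. A track alternates two kinds of steps:

* **Continuous energy-loss substeps.** The electronic stopping power is the
  Bethe formula with the full kinematic maximum energy transfer
  $T_{\max}$ and no shell, density, or Barkas corrections — a documented
  few-percent systematic at the benchmark energies (all $\geq 2.57$
  MeV/u). Substeps are 1% of the residual CSDA range, capped at 100 µm and
  floored at 0.1 µm so the step count stays bounded at the end of range.
  Gaussian (Bohr) energy-loss straggling is applied per substep and is on
  by default. Ions reaching the 1 MeV/u validity floor are stopped and
  deposit their residual energy locally.

* **Discrete elastic collisions.** Elastic scattering off target nuclei
  uses the screened Rutherford cross section
  $d\sigma/d\Omega \propto (1 - \cos\theta + 2\eta)^{-2}$ with the Molière
  screening parameter $\eta = \tfrac14 (\hbar / p\,a_{TF})^2$,
  $a_{TF} = 0.885\,a_0 Z^{-1/3}$. Collision-free path lengths are
  exponential with mean $1/(n\,\sigma(>\theta_{\min}))$ from the
  closed-form integrated cross section, and polar angles are sampled by
  the exact inverse CDF, conditioned on $\theta > \theta_{\min}$.

Energy is conserved exactly per track: entry kinetic energy equals the sum
of all deposits plus delta-ray energies at creation plus the exit kinetic
energy, to floating-point rounding (the test suite asserts $10^{-9}$
relative).

### The discrete-collision cutoff

$\theta_{\min}$ is the one genuinely numerical parameter of the
multiple-scattering model: deflections below it are ignored, not
condensed. The Gaussian core of a multiple-scattering distribution is
built by the central limit theorem from very many small collisions, so
the cutoff must be low enough that thousands of collisions contribute.
The default is $\theta_{\min} = 0.001°$, which gives of order $10^4$
collisions per track for the proton benchmarks; the variance carried by
the ignored sub-cutoff collisions is then negligible against the fitted
core width. A coarser cutoff (e.g. comparable to the 0.03° scoring bin)
leaves only tens of collisions per track and visibly destroys the
Gaussian core. `theta_min_convergence()` re-runs a benchmark with the
cutoff halved and reports the width change in units of the combined fit
uncertainty; at the default the change is consistent with statistical
noise (about 1 sigma), which is the package's convergence criterion.

### Delta electrons

The Coulomb collisions with target electrons above a production threshold
`Tcut` (default 1 keV; 0.5 keV in the nanometer-scale presets) are
sampled as discrete delta rays from the free-electron $1/T^2$ spectrum
between `Tcut` and $T_{\max}$, with binary-encounter emission angles
$\cos^2\theta = T_\delta / T_{\max}$. The continuous loss then uses the
restricted stopping bracket $\tfrac12\ln(2 m_e c^2 \beta^2\gamma^2
T_{cut}/I^2) - \beta^2$, so the split reproduces the total Bethe loss in
expectation, and the Gaussian straggling variance is scaled by
$T_{cut}/T_{\max}$ where deltas are explicit (the sampled deltas *are*
the close-collision fluctuations).

Delta electrons themselves use a deliberately simple model: a straight
segment along the emission direction whose length is the practical range
$R = 4.0\times10^{-6}\,T_{keV}^{1.75}$ g/cm² shortened by an exponential
detour factor (mean 0.5, truncated at 1) for path tortuosity, with the
energy deposited uniformly along the segment. This is a model choice, not
a transport of electron interaction cross sections. It preserves the
first-order radial structure of the track: the simulated penumbra of a
fast ion falls off as $1/r^2$ (fitted log--log slope $-2.0$ over
10--100 nm for 300 MeV/u carbon), which is the expected behaviour of the
delta-ray halo, and conserves each electron's energy exactly. What it
cannot reproduce is electron backscatter, angular straggling detail, or
condensed-phase track-end structure below a few nanometers.

Where delta transport is disabled — or outside a configured transport
window — the delta energy is deposited at its production point; this
changes no track-level energy accounting and is used to keep long-range
runs affordable (see the Bragg-peak protocol below).

## Scoring

* **Projected angles.** Exit angles are histogrammed as
  $\theta_x = \arctan(d_x/d_z)$ in uniform bins (default 0.03°) centred
  on zero, the convention of proton multiple-scattering benchmarks.
* **Radial dose.** Deposits are binned into coaxial cylindrical shells
  (default 40 log bins per decade from 0.3 nm to 10 µm) and divided by
  the shell mass; 1 keV in 1 g is $1.602\times10^{-13}$ Gy. The innermost
  shell is the singular track-core region and is best reported
  separately.
* **Depth dose.** Deposits are binned in z either from the stored stream
  or by an in-transport tally (used for long water-phantom runs).

## Analytic multiple-scattering reference

`highland_width()` implements the parameterized approximation to Molière
theory,
$$\theta_0 = \frac{14.1\,\mathrm{MeV}}{p\beta c}\, z\, \sqrt{x/X_0}
\left[1 + \tfrac19\log_{10}(x/X_0)\right],$$
evaluated once for the full thickness (the single-evaluation variant;
the step-summed variant differs at the few-percent level and the choice
is documented rather than hidden). Radiation lengths are compiled from
the PDG approximate elemental formula, mass-combined for compounds.

`fit_gaussian_core()` fits $A\,e^{-\theta^2/2\sigma^2}$ to the histogram
core, restricted to $|\theta| \le 2.5\,\hat\sigma$ with
$\hat\sigma$ an interquartile-range estimate, iterated once. Core
restriction excludes the single-scattering Rutherford tail; fitting the
full range gives a systematically larger width (asserted as a property
test). On pure-Gaussian synthetic data the fit is unbiased within two
standard errors over 100 replicates.

For the 158.6 MeV proton benchmarks the simulated fitted widths are
0.287° (0.66 cm beryllium; measured reference 0.30°) and 0.27° (0.30 cm
graphite; references 0.26--0.28°), with Highland values 0.304° and
0.272°. A note on the graphite target: the simulated width scales with
the square root of the target's areal density, and the package uses the
PDG graphite density 2.21 g/cm³ in its material table; benchmark targets
of lower-density carbon would scale the expected width down accordingly.

## Microdosimetry

Lineal energy is $y = \varepsilon / \langle l \rangle$, with
$\varepsilon$ the energy imparted to the site in one event (one primary
plus all of its delta rays, the standard single-event convention) and
$\langle l \rangle$ the mean chord length, $4V/S$ for a convex site and
$2d/3$ for a sphere. Spectra are built on 40 log bins per decade over
0.01--1000 keV/µm: $f(y)$ from event counts, $d(y) = y f(y)/\bar y$
normalized with the binned first moment so that both densities integrate
to one exactly, and $y\,d(y)$ as the display quantity per logarithmic
interval. The moments $y_F$ and $y_D$ are computed from the event list,
never from binned values; $y_D \ge y_F$ is asserted as an invariant.

`tepc_site_scaling()` converts a tissue-equivalent proportional counter
cavity to its tissue-equivalent diameter by ideal-gas density scaling;
with the manufacturer cavity diameter of 12.7 mm for the LET-1/2 preset
(a documented assumption — only the gas pressure is usually quoted) and
propane-based TE gas at 120 mbar this gives 2.70 µm, consistent with the
quoted equivalence at the few-percent level.

`poisson_hit_stats()` converts an ion fluence and a target
cross-sectional area to the Poisson distribution of traversal counts.
At the fluence $3\times10^6$ ions/cm² and a 100 µm² nucleus cross
section the mean is 3 traversals and the zero-traversal fraction is
$e^{-3} = 4.98\%$, just under the 5% often used as a design bound in
cell-irradiation experiments.

### Bragg-peak site protocol

The carbon benchmark transports a monoenergetic 300 MeV/u pencil beam in
water (CSDA + Bohr straggling, $10^4$ primaries) in two phases: first a
depth--dose tally (0.2 mm bins over 1.15 CSDA ranges) locates the dose
maximum; then the beam is re-run with a 2.7 µm tissue-equivalent sphere
on the axis at that depth. Delta electrons are transported inside a
±60 µm window around the site — chosen from the kinematic reach of the
deltas that exist near the Bragg depth — and deposited locally elsewhere,
where they cannot influence the site; within ±8 µm of the site the
substep cap tightens to 0.05 µm so a chord is resolved by ~50 continuous
deposits. This windowing is a cost/variance technique, not a physics
approximation for the scored quantity.

**Known limitation.** Under these conditions (a truly monoenergetic
pencil beam, primaries only) the range spread at the peak is the Bohr
straggling alone, $\sigma_R \approx 0.4$ mm, so the ions crossing the
site at the depth--dose maximum are a few hundred micrometers from the
end of their range, with stopping powers around 150--200 keV/µm; the
computed $y\,d(y)$ mode is correspondingly high (about 190--210 keV/µm,
as the acceptance script reports). Measured spectra at carbon Bragg
peaks put the primary-ion peak near 131 keV/µm, i.e. ions about 1 mm
from stopping: real beamlines add momentum spread (and fragmentation and
positioning effects) that widen the stopping-depth distribution well
beyond Bohr straggling and soften the LET mix at the measured maximum.
Neither beamline momentum spread (not part of the beam contract) nor
nuclear fragmentation (out of scope by design) is modelled, and the
package reports its honestly computed mode rather than tuning toward the
measured value.

## Randomness and reproducibility

The compiled transport core uses the xoshiro256** generator. Every
primary owns three named sub-streams (elastic, straggling, delta),
seeded from (master seed, primary index, stream tag) via splitmix64, so
results are bit-reproducible from the master seed, independent of
execution order, and toggling one physics process does not perturb the
sequences of the others — switching elastic scattering off leaves the
identical delta-ray history, which makes paired on/off comparisons
(e.g. the track-core dose reduction) exact common-random-number designs.

## Problem sizes

The shipped benchmarks use $2\times10^4$ protons for each scattering
target, $10^4$ carbon ions per phase of the Bragg-peak protocol, and
1000 oxygen ions (in batches of 100) for the radial-dose study; each runs
in seconds to tens of seconds on one core. The test suite re-runs scaled
versions of all of them plus the property checks. These sizes give fit
uncertainties of ~0.002° on scattering widths and a few percent on
spectrum modes — well inside the benchmark tolerances, so larger runs
buy nothing for validation purposes.

## What the simulated conditions do not include

No nuclear reactions (fragment production or attenuation), no neutrons,
no beamline momentum spread or divergence, no magnetic fields, no
water radiolysis or chemistry, bare projectile charge (no effective-
charge scaling for slow ions), and a deliberately simple delta-electron
model. Consequently, observables dominated by fragments (e.g. the
low-lineal-energy fragment peak of measured carbon TEPC spectra, or
off-axis spectra) are out of reach by design, and the primary-ion peak
position at a Bragg maximum carries the systematic discussed above.
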