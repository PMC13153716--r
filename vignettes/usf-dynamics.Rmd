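---
title: "Dynamic models of ultrasound-switchable fluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic models of ultrasound-switchable fluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usfdyn)
```

## The model chain

`usfdyn` computes the time-resolved signal a camera or detector records in
ultrasound-switchable fluorescence (USF) imaging. Four physical stages are
composed; each is a module with its own container class, and each stage's
output is the next stage's input.

**Acoustic focus.** The complex pressure amplitude of a focused beam is
evaluated from a closed-form two-term expression parametrized by a source
scale $P_a$, a lateral beam parameter $\bar a$, and the Rayleigh-like
distance $z_d = k\bar a^2/2$. The expression has removable singularities
where $D_\mp = x^2+y^2+(z \mp i z_d)^2$ vanishes; we substitute the limit
$\sin(k\sqrt D)/\sqrt D \to k$ whenever $|D| < 10^{-20}\,\mathrm{m^2}$, and
the output is invariant under the complex square-root branch because
$\sin(s)/s$ is even. With $\bar a = 0.5$ mm at 2.5 MHz the simulated focus
has lateral/axial FWHMs of 0.855/4.495 mm — deliberately the *model's*
focal size, which differs from the quoted hardware FWHM of the physical
transducer the parameters emulate.

*Attenuation.* The unattenuated formula gives $|P_1| = P_a$ at the focal
center. Tissue absorption is applied as a plane-wave factor; the default is
the axially varying form $e^{-\alpha (z+d)}$ ($d$ = focus depth, $z$ = 0 at
the focus), with a depth-uniform $e^{-\alpha d}$ variant as an option. The
axial form is the default because it is what reproduces both the attenuated
focal peak (1.58 MPa for $P_a$ = 2.4 MPa at $d$ = 10 mm,
$\alpha = 58/8.686 \cdot 2.5^2$ Np/m) *and* the 4.495 mm axial FWHM; the
uniform variant yields 4.417 mm. The conversion from the customary
dB m$^{-1}$ MHz$^{-1}$ specification uses the power law $\alpha f^y$ with
$y = 2$.

**Bioheat.** The ultrasound-induced temperature rise obeys the Pennes
equation with the perfusion sink acting on $\Delta T$ (the steady state is
subtracted, which eliminates metabolic and baseline perfusion terms). The
solver is explicit forward-time central-space with a 7-point Laplacian,
zero-gradient (mirror) faces and $\Delta T(r, 0) = 0$. The explicit scheme
is the simplest correct choice here: the stability-limited step on the
default 50 × 50 × 175 µm³ grid is ≈4 ms, so a full 0.8 s simulation costs
only ≈200 sweeps of a 1.2 M-voxel volume (seconds in vectorized R). The
step is shortened locally so every requested snapshot time and the exposure
edge are hit exactly; no temporal interpolation is ever done. Heating is
active on $[0, \Delta t)$ at 100% duty cycle.

*Grid economy.* The pressure formula is smooth at the 50 µm scale near the
focus, so the heating field is evaluated directly on the thermal grid; the
paper-resolution 12.5 × 12.5 × 43.75 µm³ sampling is used only for the 1-D
profiles from which beam FWHMs are measured
(`pressure_axis_profile`), avoiding a $10^8$-voxel volume. Domain extents
default to ±3 mm laterally and ±7 mm axially — more than 3× the focal
FWHMs, which makes the zero-gradient boundaries indistinguishable from an
infinite medium over sub-second horizons (halving the time step or
enlarging the box changes the focal peak by <0.5%).

**Switching.** The nanoagent quantum yield is a smooth step in temperature
built from the complementary error function, rising from $Q_0$ to $Q_0R_0$
around the midpoint $T_M$ with Gaussian-width $\sigma$. Its derivative is a
Gaussian whose FWHM defines the transition bandwidth
$T_{BW} = T_{sa} - T_{th}$; this FWHM convention is one of several possible
bandwidth definitions, and it is fixed here because every printed parameter
value in the reference parameter set uses it. Validity requires
$1 < R_0 < 1/Q_0$, enforced at construction rather than by clamping
outputs. `characterize_curve` recovers $(T_{th}, T_{sa}, T_M, \sigma)$ from
a measured fluorescence-versus-temperature curve by numerically
differentiating and reading the half-maximum points; on a 0.01 °C grid the
recovered threshold is 38.42 °C for the canonical agent (the exact analytic
value; coarser derivative estimates can shift it by ±0.01 °C).

**Photon diffusion.** Excitation and emission propagate diffusively in a
semi-infinite medium. The excitation source is a point buried one transport
mean free path $z_{tr} = 1/(\mu_s' + \mu_a)$ below the surface, and the
extrapolated-zero-boundary (EZB) condition is imposed with a mirror image
source across the plane offset $z_b = \frac{1+R_{eff}}{1-R_{eff}} \cdot
\frac{2}{3(\mu_a + \mu_s')}$ outside the surface. Two unit conventions
matter and are fixed deliberately:

* the diffusion coefficient uses the light speed *in the medium*,
  $v = c/n$ with $n = 1.333$ — this is what reproduces the tabulated
  $D_{ex} = 4.95\times10^4$ and $D_{fl} = 4.38\times10^4$ m²/s at 808/830
  nm to three significant figures;
* $z_b$ uses the length-form coefficient $D/v$, the standard EZB
  convention, giving $z_b \approx 1.24$ mm for the excitation medium.

Excitation (808 nm) and emission (830 nm) each carry their own $z_b$ and
hence slightly different mirror planes; a `shared_ezb` switch forces both
onto the excitation plane for sensitivity studies.

*The image term.* The USF signal subtracts an image-volume term so the
emission fluence vanishes on the EZB. We implement the standard
image-emitter construction: each emitting voxel is mirrored across the
emission EZB with *unchanged* strength
($G_{ex}(r)\,C\,Q \cdot G_{fl}(r_i, r_D)$, subtracted), which is exactly
equivalent to replacing the emission kernel by the two-term semi-infinite
Green's function $G_{fl}(r, r_D) - G_{fl}(r_i, r_D)$. Evaluating the
*two-term excitation kernel itself* at the image point instead would flip
the sign of the image term (by the mirror-swap identity
$\phi_{ex}(r_i) = -\phi_{ex}(r)$) and violate the emission boundary
condition, so that reading is rejected. Note the image terms are not small
when the detector sits on the surface: the image emitter is only
$2(z_{tr}+z_b)$ ≈ a few mm farther, so the image/direct ratio is tens of
percent — the construction matters quantitatively.

## Signal, velocity, and the quantities derived from them

The signal is a midpoint-rule sum over the thermal-grid voxels of
$K\,G_{ex}(r)\,C(r)\,Q(T(r,t))\,G_{fl}(r,r_D)$ minus the image term, with
$K = v^2 M_0 \varepsilon_{fl} / ((4\pi)^2 D_{ex} D_{fl})$. The integration
support is the whole grid: outside the heated region
$Q(T) - Q(T_{BG}) \approx 0$, so no explicit "focal volume" needs to be
delimited. The background (pre-ultrasound) fluorescence is subtracted as
$\phi(t) - \phi(0)$; subtracting $Q_0$ inside the integrand instead would
differ only by $Q(T_{BG}) - Q_0$, which is ~$5\sigma$ into the erfc tail at
37 °C.

The velocity is by default the central-difference derivative of the sampled
signal; an analytic mode evaluates the derivative integral directly with
$dQ/dT$ and the solver's $dT/dt$ and is kept as a cross-validation (the two
agree within 3% on a 10 ms cadence). The default cadence for dynamics runs
is 10 ms over $[0, 1]$ s — the velocity pulse is ~40–60 ms wide, so it is
resolved by ≥4 samples; two-point delays use sub-sample parabolic peak
localization. Time series are plotted normalized per curve, since the
prefactor constants ($M_0$, $\varepsilon_{fl}$, $C$, …) cancel in any
normalized measurement.

Sensitivity matrices exploit linearity in $C$: the weight of voxel $j$ is
the single-voxel signal at unit concentration, evaluated in one vectorized
pass (`sensitivity_kernel`); a literal scan that fills one voxel at a time
(`sensitivity_scan`) is retained as the brute-force oracle and agrees to
$10^{-10}$. The default normalization is global (one scale across voxels
and times), preserving the growth of sensitivity with time; per-frame
normalization is available since published weight maps are often shown with
per-frame color scales. Ring thicknesses in `support_metrics` are
thresholded against the maximum along the measured ray rather than the
frame maximum: the optical kernels vary by an order of magnitude across the
focal volume, so a frame-global threshold would measure depth weighting,
not shell geometry.

## Closed-form analytics and their limits

Under thermal confinement (exposure ≪ diffusion and perfusion time scales)
the heating rate is time-independent, $dT/dt = 2\alpha I(r)/(\rho_0 C_t)$,
and threshold-crossing times are simply $(T_x - T_{BG})/\mathrm{rate}$.
This yields the velocity pulse width $\Delta t_v = T_{BW}/\mathrm{rate}$,
the two-point delay $\Delta t_{X12} = t_M(\mathrm{rate}_2) -
t_M(\mathrm{rate}_1)$, and the separation limit
$\Delta X = 1/\{|\nabla I/I| \cdot [(T_{th}-T_{BG})/(T_{BW}/2) + 1]\}$.
These are re-derivations from the stated confinement logic; the delay/width
ratio linearized in the separation equals 1 at exactly *twice* $\Delta X$
(the bracket uses the half-bandwidth), a factor the tests pin down
explicitly. For the canonical parameters the improvement factor in the
bracket is 7 at $(T_{th}-T_{BG}, T_{BW}) = (3, 1)$ °C. The 0.4 s exposure
is comfortably confined: the perfusion time constant is ≈59 s (0.7% loss
over the exposure) and the conduction length $\sqrt{4\alpha_{th}\Delta t}
\approx 0.45$ mm is below the focal dimensions — though not negligibly so,
which is why the finite-difference focal peak (3.34 °C) is appreciably
below the confinement bound (5.7 °C) and why the closed forms are treated
as bounds and orderings, not predictions.

## What the scenario generator emulates — and what it does not

`nanoagent_map`/`make_fixture` produce the study conditions: a single
filled voxel at the focal center, two voxels separated by 0.3 mm (the
canonical two-point experiment), a uniform fill, and seeded random blobs
for phantom studies, all at a nominal concentration of
$4.4\times10^{-11}$ mol/L (which cancels in normalized outputs). Real
tissue adds heterogeneous optical and thermal properties, perfusion
hotspots, agent pharmacokinetics, photobleaching, hysteresis between
heating and cooling branches of the switching curve, and measurement
noise — none of which are modeled. Passing tests therefore demonstrate
correctness of the coupled forward physics under idealized semi-infinite,
homogeneous conditions, not predictive accuracy for any particular tissue.

## Numerical choices and problem sizes

* Pressure evaluation: complex arithmetic throughout; the
  $e^{kz_d}/\sinh^2(kz_d)$ prefactors stay within double range for
  practical $k z_d \lesssim 700$ (here 13).
* Bioheat: stability safety factor 0.9 by default; the step is also capped
  at $\tau/10$ so strong-perfusion scenarios stay accurate.
* Kernels: distances below a configurable clamp (disabled by default) are
  floored for robustness; no geometry in the standard scenarios places a
  source or detector inside the integration volume.
* Dynamics and sensitivity studies run on a decoupled focal-region grid
  (0.1 mm lateral / 0.35 mm axial over ±1.5 × ±4 mm, ~22 k voxels), which
  resolves the thermal focus adequately for shape and ordering studies
  while keeping the brute-force sensitivity scan and the test suite fast;
  the headline thermal quantities are always computed on the full 50 µm
  grid (1.19 M voxels, ~15 s per 0.7 s simulation).
* Degenerate inputs: empty concentration maps, non-monotone temperature
  samples, unresolved velocity pulses, and out-of-grid placements raise
  informative errors rather than returning silent zeros.

## Known limitations

Single exposure at a fixed focal position (no scan-pattern assembly, no
pulse-repetition effects); linear acoustics with a parametric beam (no
transducer aperture diffraction, nonlinearity, or standing waves); constant
tissue properties (no temperature dependence, no vasculature); semi-infinite
optics only (no slabs or multi-layer media, no time-resolved diffusion);
and no inverse problem — the sensitivity matrices are exported for use by
reconstruction codes, but no reconstruction is performed here.
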