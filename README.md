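# usfdyn

Forward simulator for **ultrasound-switchable fluorescence (USF)** imaging in
deep tissue.

USF beats the millimeter-scale resolution limit of diffuse near-infrared
fluorescence imaging by encapsulating NIR fluorophores in thermosensitive
nanoagents that are dark below a threshold temperature T_th and bright above
a saturation temperature T_sa. A focused ultrasound pulse heats the focal
volume by a few degrees, switching agents on only there; the spatial
resolution becomes that of the acoustic/thermal focus (~0.5–0.8 mm) instead
of the optical diffusion blur (~5 mm). `usfdyn` simulates the full chain of
coupled physics behind the measured signal, for people designing USF systems,
agents, or tomographic reconstruction schemes:

1. **Acoustic focus** — analytic focused-beam pressure amplitude

   P1(x,y,z) = Pa·z_d / (2 sinh²(k z_d)) · [ e^{k z_d} sin(k√D₋)/√D₋ −
   e^{−k z_d} sin(k√D₊)/√D₊ ],  D∓ = x² + y² + (z ∓ i z_d)²,

   with plane-wave tissue absorption (α converted from dB m⁻¹ MHz⁻¹ via
   α = dB/8.686 · f^y), intensity I = |P1|²/(2ρ₀c₀) and volumetric heating
   H = 2αI.
2. **Bioheat** — the Pennes equation ρ₀C_t ∂ΔT/∂t = k_t∇²ΔT − ω_bρ_bC_bΔT + H
   solved by explicit finite differences (zero-gradient boundaries, zero
   initial condition) on a 50 × 50 × 175 µm³ voxel grid.
3. **Switching** — temperature-gated quantum yield
   Q(T) = Q₀{1 + [(R₀−1)/2]·erfc[−(T−T_M)/(√2σ)]}, whose derivative is a
   Gaussian of FWHM T_BW = T_sa − T_th.
4. **Photon diffusion** — semi-infinite medium with extrapolated zero
   boundary (EZB) image sources for excitation (808 nm) and emission
   (830 nm).
5. **USF signal and velocity** — volume integral of
   G_ex·C·Q(T(r,t))·G_fl minus its EZB image term, background-subtracted;
   the velocity (time derivative) forms a narrow pulse whose timing encodes
   sub-focal structure, giving the two-point separation limit
   ΔX = 1 / { |∇I/I| · [ (T_th−T_BG)/(T_BW/2) + 1 ] }.
6. **Sensitivity matrices** — per-voxel, per-time weights of signal and
   velocity for configurable source–detector placements (the Jacobian for
   tomographic reconstruction).

## Worked example

```r
library(usfdyn)

cfg <- usf_config()          # canonical soft-tissue / liposome parameter set
obj <- config_objects(cfg)

# acoustic focus at the fine sampling
px <- pressure_axis_profile(obj$spec, obj$alpha_np, "axial", "x", 12.5e-6, 3e-3)
profile_fwhm(px$coord, px$value) * 1e3   # lateral FWHM, mm
#> [1] 0.8549967
max(px$value) / 1e6                      # attenuated focal peak, MPa
#> [1] 1.581115

# 0.4 s exposure, thermal snapshots during heating and cooling
grid  <- usf_grid(50e-6, 50e-6, 175e-6, 3e-3, 3e-3, 7e-3)
field <- evaluate_pressure(grid, obj$spec, obj$alpha_np)
src   <- heating_source(field, obj$alpha_np, 1064, 1540, exposure = 0.4)
th    <- solve_bioheat(src, obj$tissue, grid, c(0.149, 0.397, 0.521, 0.708))
summary(th)
#>       time_s peak_dT_K focal_dT_K lateral_fwhm_mm axial_fwhm_mm
#> 0.149  0.149  1.658185   1.658185       0.6810679      2.918719
#> 0.397  0.397  3.338851   3.331250       0.7659380      3.316592
#> 0.521  0.521  2.539655   2.526101       0.8889451      3.868408
#> 0.708  0.708  1.854206   1.839962       1.0461789      4.589539
```

The peak focal heating of ≈3.34 °C near the end of the exposure is what
switches the nanoagents (T_th − T_BG = 1.41 °C); the thermal focus is
narrower than the 0.855 mm acoustic focus during heating and broadens by
diffusion afterwards.

Canned end-to-end pipelines (`run_preset`) produce the dynamic signal and
velocity curves, two-point separability experiments, and sensitivity
matrices:

```r
two <- run_preset("fig5", cfg)    # two voxels 0.3 mm apart in the focus
c(dt_X12 = two$dt_X12, dt_v = two$dt_v)
#>    dt_X12      dt_v
#> 0.1337714 0.0650450
```

The delay between the two velocity pulses (134 ms) exceeds the pulse width
(65 ms), so the two points — unresolvable in the spatial USF image — separate
cleanly in time.

A thin command-line front end lives at `inst/cli/usf.R`
(`Rscript inst/cli/usf.R preset fig5`).

## Scope

The package simulates the forward problem for a single ultrasound exposure
at a fixed focal position. Tomographic inversion, localization-based
super-resolution, acoustic streaming, full-wave acoustic solvers, and
pulse-repetition effects are out of scope.
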