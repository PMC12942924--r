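# phototherm

Coupled light-transport / bioheat finite-element simulation of laser
photothermal therapy in axisymmetric heterogeneous tissue, for researchers
modeling nanoparticle-assisted tumor hyperthermia and for anyone who needs a
self-contained, validated delta-P1 solver with a Monte Carlo reference.

## What it computes

Photothermal therapy couples two transport problems on a cylindrical
geometry reduced to the (r, z) half-plane:

**Light.** The fluence rate φ (W m⁻²) is computed by one of three models:

- **Beer–Lambert (BL):** ray attenuation with the total extinction
  μₜ = μₐ + μₛ;
- **Standard diffusion (SDA):** −D∇²φ + μₐφ = S with
  D = 1/(3(μₐ + μₛ′)), μₛ′ = (1−g)μₛ, and the partial-current laser boundary
  condition φ + 2AD ∂φ/∂n = 4P₀(r);
- **delta-P1:** the phase function is split into a forward delta spike
  (f = g², g\* = g/(1+g), μₛ\* = (1−g²)μₛ); the collimated component decays
  with μₜ\* = μₐ + μₛ\* along the beam, the diffuse component solves
  ∇²φ_d − μ_eff² φ_d = −3μₛ\*(μ_tr + g\*μₜ\*) φ_c with
  μ_eff = √(3μₐμ_tr), and φ = φ_c + φ_d.

**Heat.** The Pennes bioheat equation
ρC_p ∂T/∂t = ∇·(k∇T) + Q_m + W_bC_b(T_a − T) + μₐφ,
discretized with r-weighted P1 triangles and backward-Euler stepping, with
convection, fixed-temperature and insulated boundaries.

A compiled voxel Monte Carlo photon-transport oracle (Henyey–Greenstein
scattering, implicit capture, Russian roulette, Fresnel surface reflection,
track-length fluence estimator with batch standard errors) serves as the
in-package reference, and an analytical semi-infinite delta-P1 solution
(Hankel-transform construction) validates the FEM solver independently.
Validation metrics — cylindrical region-averaged temperature, relative
error, r-volume-weighted RMS error — plus mesh-convergence and
optical-property sweep drivers round out the toolkit. See the methods
vignette (`vignettes/phototherm-methods.Rmd`) for the full account.

## Worked example

The Gaussian-beam gel phantom preset: an agar cylinder (radius 15 mm, depth
30 mm) with a gold-nanoparticle-loaded inclusion (radius 5 mm, 3 mm below
the surface), 7 mm FWHM / 1.1 W beam, 706 s of irradiation.

```r
library(phototherm)

case <- ptt_case2()
case$mesh
#> Axisymmetric triangle mesh: 9196 nodes, 18000 triangles ( 75 x 120 cells )
#>   domain: r in [0, 0.015 ] m, z in [0, 0.03 ] m
#>   regions: gel (16000), gnp (2000)

sol <- solve_fluence(case$mesh, case$optics, case$beam, model = "deltap1")
sol
#> fluence solution (deltap1): max 2.996e+04 W/m^2

run <- run_bioheat(case$mesh, case$thermal, case$thermal_bc,
                   dt = case$dt, t_end = case$duration, T0 = case$t0,
                   optics = case$optics, phi = sol$phi, probes = case$probes)
run
#> bioheat run: 353 steps (dt = 2 s) to t = 706 s; final T in [25.523, 32.633] C

c(gel = average_temperature(run$final, "gel"),
  gnp = average_temperature(run$final, "gnp"))
#>      gel      gnp
#> 26.71846 30.09289
```

After 706 s the loaded region has warmed ~5.1 °C above the 25 °C ambient
(volume average), the surrounding gel ~1.7 °C; the hottest point (32.6 °C)
sits inside the inclusion under the beam axis. The built-in Monte Carlo
oracle provides an independent fluence reference:

```r
mc <- run_mc(case$mesh, case$optics_raw, case$beam, photons = 2e5, seed = 1)
mc
#> Monte Carlo fluence: 200000 photons on 60 x 120 voxels (0.25 mm)
#>   weight: launched 200000 = absorbed 42065.1 + escaped 157935 + roulette 0

rms_error(sol$phi, interpolate_to_mesh(mc, case$mesh))
#> [1] 519.9799   # W/m^2, ~2 % of the peak fluence
```

Fields export as legacy VTK (`write_field_vtk()`), probe traces as CSV, and
a thin command-line wrapper ships in `inst/cli/phototherm.R`
(`run`, `compare`, `validate-carp`, `case1`, `case2` subcommands).

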