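---
title: "Methods: delta-P1 light transport coupled to Pennes bioheat finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-P1 light transport coupled to Pennes bioheat finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the physics it implements, the
numerical choices it makes, and what its validation suite does and does not
demonstrate.

## The problem

Laser photothermal therapy heats nanoparticle-loaded tissue with a
near-infrared beam. Predicting the temperature field requires coupling two
transport problems: light transport through a turbid (absorbing and
scattering) medium, which yields the fluence rate $\phi$ (W m$^{-2}$), and
heat transport, where the absorbed optical power $\mu_a \phi$ (W m$^{-3}$)
acts as a volumetric source. Both problems are posed on axisymmetric
geometries — nested cylinders of tissue, tumor, gel, or nanoparticle-loaded
inclusions — and reduced to the $(r, z)$ half-plane with every integral
weighted by $r$.

## Light transport models

The radiative transfer equation is approximated at three levels, all sharing
one optical property set per region ($\mu_a$, $\mu_s$, anisotropy $g$,
refractive index ratio $n$):

* **Beer–Lambert (BL).** Pure ray attenuation of the incident beam with the
  total extinction $\mu_t = \mu_a + \mu_s$. Valid when absorption dominates;
  ignores scattered light entirely.
* **Standard diffusion (SDA).** $-D\nabla^2\phi + \mu_a\phi = S$ with
  $D = 1/(3(\mu_a + \mu_s'))$, $\mu_s' = (1-g)\mu_s$. The laser enters
  through the partial-current Robin condition
  $\phi + 2AD\,\partial\phi/\partial n = 4P_0(r)$ on the illuminated
  surface, where $A$ encodes internal Fresnel reflection. Valid when
  $\mu_s' \gg \mu_a$.
* **delta-P1.** The phase function is split into a forward delta spike of
  weight $f = g^2$ plus a smooth part with first moment $g^* = g/(1+g)$ and
  scattering $\mu_s^* = (1-f)\mu_s$. The fluence separates into a collimated
  part $\phi_c$, attenuated along the beam with $\mu_t^* = \mu_a + \mu_s^*$,
  and a diffuse part $\phi_d$ solving
  $\nabla^2\phi_d - \mu_{e\!f\!f}^2\phi_d =
  -3\mu_s^*(\mu_{tr} + g^*\mu_t^*)\phi_c$ with
  $\mu_{tr} = \mu_a + \mu_s'$ and
  $\mu_{e\!f\!f} = \sqrt{3\mu_a\mu_{tr}}$. The total fluence is
  $\phi = \phi_c + \phi_d$. This retains BL's accuracy in absorption-dominated
  media and the SDA's in scattering-dominated ones.

Note one notational trap the code resolves explicitly: in the SDA literature
the "starred" coefficient means the *reduced* scattering $(1-g)\mu_s$, while
in the delta-Eddington literature it means $(1-g^2)\mu_s$. The package keeps
both as distinct fields (`mu_s_red`, `mu_s_star`) and uses the reduced one in
the diffusion coefficient.

### Boundary conditions and sign conventions

The delta-P1 conservation condition at an exterior surface couples $\phi_d$
to $\phi_c$. Deriving it from partial currents with the delta-P1 diffuse flux
$\vec j_d = -\tfrac{1}{3\mu_{tr}}\nabla\phi_d +
\tfrac{g^*\mu_s^*}{\mu_{tr}}\phi_c\,\hat s_0$ gives, with the *outward*
normal,
$$\phi_d + A h \frac{\partial\phi_d}{\partial n}
  = -3 A h g^* \mu_s^* (\hat s_0\cdot\hat n)\,\phi_c, \qquad
  h = \frac{2}{3\mu_{tr}},$$
which reduces to the familiar slab form on the irradiated top surface
($\hat s_0\cdot\hat n = -1$). The sign of the normal matters: the same
condition written with an inward normal looks like it has the opposite sign
on the derivative term, and taking the printed slab form literally with an
outward normal would produce a non-coercive (ill-posed) Robin term. The
package always uses the outward-normal, coercive form above, and its
correctness is checked end-to-end against an independent analytical solution
(below). Non-illuminated exterior boundaries receive the homogeneous variant
($\phi_c \approx 0$ there); the axis $r = 0$ is a natural symmetry boundary
because the $r$-weight vanishes.

The Fresnel parameter $A(n)$ uses the standard cubic fit
$A = -0.13755 n^3 + 4.3390 n^2 - 4.90466 n + 1.6896$ with $n$ = tissue/air
index ratio, fitted over $n \in [1.0, 1.6]$. $A(1) = 0.987$, within the fit
tolerance of the physical no-mismatch limit $A = 1$; the test suite also
cross-checks the cubic against direct numerical integration of the Fresnel
reflection moments ($R_1$, $R_2$, $A = (1+R_2)/(1-R_1)$) to better than 1 %.

## Discretization

**Finite elements.** All elliptic solves use P1 triangles on structured
crossed-diagonal meshes of the $(r,z)$ rectangle (each grid quad split along
one diagonal). Every volume/surface integral carries the factor $r$; for P1
basis functions these integrands are polynomials and the assembly rules are
exact (no quadrature error). The heterogeneous delta-P1 and SDA problems are
assembled in flux-continuous form — the stiffness coefficient is the
per-region diffusion coefficient — so interfaces conserve flux. Elliptic
systems are solved by sparse direct factorization (relative residual checked
against $10^{-10}$); a Jacobi-preconditioned conjugate-gradient path
(tolerance $10^{-8}$) is available for repeated solves.

**Collimated transport.** $\partial\phi_c/\partial s = -\mu_t^*\phi_c$ is
integrated down each vertical node column with classical RK4. For a
piecewise-constant coefficient an RK4 step is exactly multiplication by the
quartic Taylor polynomial of $e^{-\mu\Delta z}$, so the integration reduces
to cumulative products; steps are subdivided so that $\mu\Delta z \le 0.05$
per substep, making the result match the layered closed-form exponential to
better than $10^{-6}$ relative. Only normal incidence along $-z$ is
supported (both validation geometries use it). No specular reduction is
applied to the incident beam by default (`specular = 1`), consistently in
the deterministic solvers and the Monte Carlo launch.

**Bioheat.** The Pennes equation
$\rho C_p \partial T/\partial t = \nabla\!\cdot\!(k\nabla T) + Q_m +
W_b C_b (T_a - T) + \mu_a\phi$
is stepped with backward Euler; the perfusion sink is inside the matrix
(implicit) and the perfusion/metabolic supplies on the right-hand side, so
the scheme is unconditionally stable and reduces to plain conduction when
perfusion and metabolism are zero. Convection
($-k\,\partial T/\partial n = h_{conv}(T - T_{ref})$), fixed-temperature and
insulated boundaries are supported per facet tag. The system matrix is
factorized once per (mesh, dt) and reused across steps and across runs that
differ only in the source — including an adjoint-mode evaluation of the
final-time region averages used to propagate Monte Carlo batch noise through
the transient without re-running it. The optical source enters as the exact
weak projection $\int \mu_a \phi\, v\, r\, dA$ with the per-region
(element-wise) $\mu_a$.

One known finite-element artifact is documented rather than hidden: with the
consistent mass matrix, backward Euler can overshoot a sharp initial
boundary layer by a fraction of a percent of the data range before decaying;
the tests bound this at 0.5 % and verify the late-time solution respects the
data bounds to $10^{-6}$.

**Monte Carlo reference.** The package carries its own compiled voxel Monte
Carlo oracle: photons propagate in 3D with free paths sampled in optical
depth and marched voxel-by-voxel (exact ray/cylinder-shell and ray/plane
intersections, so heterogeneity introduces no step bias), implicit-capture
weighting, Henyey–Greenstein scattering, Russian roulette (threshold
$10^{-4}$, survival 0.1), Fresnel reflection (including total internal
reflection) at the air interface, and absorbing lateral/bottom faces.
Fluence is scored with the track-length estimator directly on annular
$(r,z)$ voxels — the azimuthal average is built into the tally — and
normalized to the source power, giving steady-state W m$^{-2}$. The
generator is a dedicated xoshiro256++ stream seeded from the user's integer
seed, so fixed seeds are bit-reproducible across platforms. Photons are run
in batches (default 10) whose spread provides standard errors for any
functional of the fluence; every comparison against the MC reference carries
these errors. Weight bookkeeping satisfies
launched = absorbed + escaped + roulette-net exactly, where roulette-net is
the (zero-expectation) running imbalance of the roulette game.

## Validation cases and the choices behind them

Three shipped case setups drive the validation suite. Their parameters are
the package's fixed study conditions; where the underlying benchmark
literature was not available to quote, values were chosen once, on physical
grounds, and are documented here.

**Semi-infinite medium (analytical benchmark).** A homogeneous half-space
with $\mu_s'/\mu_a = 100$ ($\mu_a = 10$ m$^{-1}$, $\mu_s' = 1000$ m$^{-1}$,
$g = 0.9$, $n = 1.4$) under Gaussian beams with $1/e^2$ waists of 1, 10 and
100 transport lengths $l^* = 1/\mu_{tr}$. The reference is the classical
analytical construction for this geometry: Hankel transform in $r$,
closed-form 1D solution per spatial frequency (written in a
cancellation-free form so the $\nu \to \mu_t^*$ resonance is harmless),
numerical inverse transform on the axis. The FEM box is 30 $l^*$ deep and at
least 30 $l^*$ (or 3 waists) wide at 240 cells per direction; on-axis totals
agree with the analytical solution to within 1.4 % over depths 1–15 $l^*$,
comfortably inside the 10 % acceptance band, with the residual dominated by
finite-box truncation.

**Flat-beam heterogeneous benchmark (`ptt_case1()`).** A tumor of 20 mm
diameter and 5 mm depth, uniformly loaded with gold nanorods, inside a
40 mm × 10 mm healthy-tissue cylinder. The benchmark literature this
geometry follows states the layout but the present package had to fix the
property values itself; they were chosen once to put the baseline in the
absorption-dominated regime that the original benchmark assumes (it treats
BL as its forward model): tumor $\mu_a = 800$, healthy $\mu_a = 30$, both
$\mu_s = 80$ m$^{-1}$, $g = 0$, $n = 1.37$; flat beam of radius 10 mm at
5000 W m$^{-2}$; thermal $\rho = 1050$, $C_p = 3639$, $k = 0.5$,
$Q_m = 420$, $W_b = 0.5$, $C_b = 3840$, $T_a = 37\,^\circ$C; 37 °C Dirichlet
right/bottom walls, convective top ($h = 10$ W m$^{-2}$K$^{-1}$,
$T_{ref} = 25\,^\circ$C), 300 s at dt = 1 s. The default mesh (122 × 62
cells, 15 128 triangles) aligns the tumor interfaces with grid lines so the
labeled area is exact.

Two studies run on this case. The *mesh-convergence study* compares each
model's fluence field against one fixed fine-voxel MC reference
(r-volume-weighted RMS). Because the reference is a different physical model,
the RMS error saturates at the model discrepancy once discretization error
falls below it; the study therefore uses levels (10×5, 20×10, 40×20 cells)
where discretization still dominates, and the monotone decrease is asserted
within MC batch noise. The *absorption-to-scattering sweep* holds the total
extinction at 1000 m$^{-1}$ with $g = 0.5$ and varies
$\mu_a/\mu_s \in \{0.01, 0.1, 1, 10\}$ homogeneously; the relative
(percent, volume-weighted) fluence error against MC shows delta-P1 matching
the better of SDA/BL at each extreme and strictly beating both at the
intermediate ratios.

**Gaussian-beam gel phantom (`ptt_case2()`).** An agar gel cylinder with an
embedded nanoparticle-loaded cylinder, irradiated by a Gaussian beam of
7 mm FWHM and 1.1 W total power for 706 s (dt = 2 s), top-surface convection
5 W m$^{-2}$K$^{-1}$, all other thermal boundaries insulated, no metabolic or
perfusion terms, thermal properties of water, initial and ambient
temperature 25 °C (the source experiment does not state it; this is the
package's default, configurable). Optics: gel $\mu_a = 2$, $\mu_s = 176$;
loaded region $\mu_a = 31$, $\mu_s = 289$ m$^{-1}$; these tabulated values
come without an anisotropy factor, so they are treated as reduced
coefficients ($g = 0$), $n = 1.33$. The phantom's exact dimensions are only
available as a drawing; the package's reconstruction — gel radius 15 mm,
depth 30 mm, inclusion radius 5 mm with its top face 3 mm below the surface
and height 10 mm — is configurable in `case2.yaml`. The default mesh is
75 × 120 cells (18 000 triangles, the structured generator's nearest size to
the original study's 17 241), again with interfaces on grid lines.

The headline check sweeps the relative nanoparticle concentration from 10 %
to 100 % (optical coefficients interpolate linearly between the gel at 0 %
and the loaded region at 100 %), runs identical bioheat transients driven by
the delta-P1 and the MC fluence, and compares region-averaged temperatures
$T_{av} = \int_{\Omega_R} T r\,dV / \int_{\Omega_R} r\,dV$ at 706 s. With
$10^6$ photons per concentration the maximum discrepancy over both regions
and all ten concentrations is about 0.15 °C, against an acceptance bound of
0.6 °C plus the MC standard error.

## What the validation does and does not show

The MC oracle shares the axisymmetric voxelized geometry, the beam model and
the surface Fresnel treatment with the deterministic solvers, so
model-vs-MC comparisons isolate the transport approximation itself. They do
not probe: oblique incidence, index mismatches between interior tissue
regions, wavelength dependence (all properties are single-wavelength
inputs), temperature-dependent tissue properties, or thermal damage
kinetics — all outside the package's scope. Boundary treatment of escaping
photons (matte-black lateral/bottom faces) is one explicit convention among
several used by external MC codes; region-average comparisons are
insensitive to it at the shipped geometry sizes, but near-boundary
point-wise fluence is not.

## Problem sizes

Default runs use the meshes above (9 000–19 000 nodes); the test suite
exercises the same code paths at reduced sizes ($10^5$–$10^6$ photons,
meshes up to 240 × 240) so the complete suite runs in about a minute, and
the acceptance script's full concentration sweep at $10^6$ photons per point
takes a couple of minutes on one core. All stochastic assertions carry the
MC batch standard errors rather than fixed fudge factors.
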