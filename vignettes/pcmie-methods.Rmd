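---
title: "Partially coherent Mie image formation for TXM: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partially coherent Mie image formation for TXM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the image-formation
models it implements, the parameters that matter, the numerical choices
behind the implementation, and what the tests do and do not demonstrate.

## The physical setting

A full-field transmission X-ray microscope illuminates the sample through a
condenser that produces a hollow cone of light over a narrow polar-angle
range (0.83–1.18 degrees here), and images it with a Fresnel zone plate
whose first diffraction order acts as a thin lens. The test object is a
solid gold nanosphere of diameter about 60 nm imaged at 510 eV
(lambda = 2.431 nm). The sphere's optical response is set by the complex
refractive index n = 1 − delta + i beta: beta attenuates (Beer's law),
delta shifts phase. Because the condenser NA is far below the objective NA,
the illumination is partially coherent, and the image is neither the
incoherent blur of the absorption map nor a fully coherent hologram.

## Conventions

* Lengths in nm, energies in eV; angles are degrees in configuration
  objects and radians in the imaging operations (`deg2rad()` is the single
  conversion site).
* Waves propagate as `exp(+ikz)`; the scattered wave is
  `S(psi)/(-ik) * exp(ik r)/r`. Under this convention the forward
  scattering amplitude of a weakly refracting sphere has a negative
  imaginary part, and the extinction theorem reads
  `Q_ext = (4/x^2) Re S(0)`.
* Defocus `z > 0` moves the sphere *away* from the zone plate ("above
  focus"). With this sign the model's axial contrast reversal appears below
  focus and the slow axial decay above, matching the orientation in which
  through-focus measurements of such spheres are usually described.
* Reported angles are rounded half-up to two decimals (1.005 prints as
  1.01).

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| delta, beta (gold, 510 eV) | 3.6e-3, 2.6e-3 | Representative of crystalline gold in the water window; gives a 63 nm sphere a central transmission of 0.43. Optical constants are user inputs: the package deliberately ships no tabulation database, and quantitative work on other materials should supply values from the user's preferred source. `density_fraction` scales both. |
| theta_m | (0.83 + 1.18)/2 = 1.005 deg | Arithmetic mean of the annulus; reproduces the printed 1.01 degrees. `mean_annular_angle()` accepts a weight function for other conventions (e.g. annulus-area weighting), because the "mean angle" of an annular condenser is a convention, not a law. |
| p_phi | 1 deg | Azimuthal coherence-patch size. Each patch contributes one plane wave; intensities add across patches. Small patches reproduce measured stacks; large ones leave visible coherent ringing. |
| Zone plate | N = 900 zones, dr_n = 25 nm | Diameter 4 N dr_n, f = diameter dr_n / lambda, NA = r_zp / R_f (about lambda / 2 dr_n = 0.0486). These are derived defaults from the zone-plate design, not measured distances. |
| Magnification | 3600 | Sets R_f = f (1 + 1/M) and z_cam = f (1 + M) via the thin-lens equation; validated to 1e-6 relative at construction. |
| Camera | 5.5 nm pixels (sample plane), 40 nm z-steps | The acquisition geometry of the measured focal series this package emulates. |
| omega_tilt | 0 (0.26 deg in the tilt studies) | Misalignment of the beam-condenser axis; estimated from the lateral asymmetry of measured stacks. |

## Scattering amplitudes

`mie_amplitudes()` implements the Mie series with the Wiscombe truncation
`n_max = ceil(x + 4 x^(1/3) + 2)`, a downward-recurrence logarithmic
derivative and upward Riccati–Bessel recurrences. Non-finite coefficients
raise an error rather than propagate. Two independent summations of the
same coefficients (the efficiency sum and the forward amplitude) must agree
to 1e-6 — a series-consistency check, tested.

`ada_amplitude()` evaluates the anomalous-diffraction integral with
adaptive Gauss–Legendre quadrature (node doubling until 1e-8 relative).
Its psi = 0 value has a closed-form antiderivative (substitution
u = sqrt(a^2 − xi^2)) used as an oracle. `ea_amplitude()` differs only by
the exponent factor (n^2 − 1) versus 2(n − 1); for gold at 510 eV the three
amplitudes agree to a few tenths of a percent, which is what licenses the
scalar (S1 = S2) treatment used by the imaging chain. Outside the validity
regime (2a not ≫ lambda, or |n − 1| not ≪ 1) the functions warn and
compute anyway.

Amplitudes are tabulated on an angle grid (2048 points spanning at least
1.5 NA, extended automatically to cover the aperture plus illumination
angle) and interpolated with cubic splines in the real and imaginary parts
separately; interpolation error is verified to be far below the quadrature
tolerance.

## The imaging chain

Dropping constants common to both paths, the camera fields in sample-plane
coordinates are

* plane wave: a Lommel-type integral over the aperture with the residual
  quadratic phase −k r'^2/(2 R_f) and the oblique tilt; it reduces to
  `A(u, v) = ∫_0^1 J0(v ρ) e^{iuρ²/2} ρ dρ` with `u = k r_zp²/R_f` (about
  5.7e3) and `v = k r_zp |sin θ n̂ − x_s/R_f|`;
* scattered wave: the Fourier transform of the pupil
  `S_θ(x′,y′) e^{−ikz r′²/(2R_f²)}`, with the spherical-wave prefactor
  `1/(−ik (R_f + z))` and the incident-phase factor `e^{ikz(1−cos θ)}`.

`A(u, v)` is evaluated by a convergent series obtained by integrating the
tail of the infinite-aperture integral by parts: a "geometric" term
`(i/u) e^{−iv²/2u}` plus an aperture-edge series `Σ (−iv/u)^m J_m(v)`. It
converges geometrically for v/u < 0.75 (the operating regime is v/u < 0.5)
and is cross-checked against direct Simpson quadrature (the `"quad"`
backend), which refuses to run below 8 samples per 2π of local phase.

The scattered-wave pupil is sampled on an FFT grid whose spacing is fixed
by the requested camera pixel (`Δ′ = 2π R_f /(k n_fft Δx)`), with the
aperture edge anti-aliased by area weighting and a Nyquist check on the
defocus phase. The paraxial defocus phase `k z r′²/(2R_f²)` follows from
expanding the sphere-to-aperture distance R_M to second order; the quartic
term (about 1.7 rad at the rim) is dropped consistently in both paths, as
is standard for this microscope model. Correctness of the combined
prefactors is audited by properties rather than absolute radiometry: with
S ≡ 0 the background is exactly the plane-wave image; with S ≡ 1 and z = 0
the scattered path is an Airy pattern with its first zero at 0.61 lambda/NA;
at theta = 0 the FFT field matches an independent radial-quadrature oracle
to better than 1%; and in focus the recovered absorption matches Beer's law
(below).

## Partially coherent synthesis and normalization

For each z-plane the single-patch intensity is computed at azimuth 0 and
summed over patch azimuths. Two exact shortcuts keep this fast:

* the field for illumination azimuth φ is the azimuth-0 field rotated by φ
  (rotational symmetry of sphere plus circular aperture), so only unique
  polar angles require field computations — one for the untilted model,
  181 for the tilted model at 1-degree patches;
* for a single polar angle and a dense even azimuth set (at least 180
  patches) the discrete rotation sum is indistinguishable from the exact
  azimuthal mean, which radial binning of the single-patch image computes
  directly. Sparse azimuth sets keep the explicit (bilinear) rotation sum
  so that the residual ringing of large coherence patches is preserved.

Each patch intensity is divided by the matching blank (no-sphere)
plane-wave intensity before the azimuthal sum. This per-patch flat-field
mirrors what a microscopist does with an empty-field reference image, and
it matters numerically: the single-patch background carries a few percent
of aperture-edge Fresnel ringing, and normalizing summed images by summed
blanks (a ratio of sums) instead of flat-fielding each patch leaves a
several-percent bias in the area-integrated absorption. The flat-fielded
chain was validated against an independent ideal band-limited-imaging
oracle computed entirely in object space (agreement to ~0.1% in the
integrated absorption for a pure absorber). After the sum, the stack is
scaled so the border-annulus median is exactly 1.

With omega_tilt = 0 the tilted engine receives bit-identical inputs to the
untilted one, so `pc_image_tilted()` reduces exactly to `pc_image()`. For
omega_tilt > 0 the illumination directions lie on a cone of half-angle
theta_m about the tilted axis: theta(phi) =
acos(cos theta_m cos omega − sin theta_m sin omega cos phi), with the exact
per-direction azimuth used for the rotation (first order:
theta_m ± omega at phi = 0, π).

## The inc-BL comparison model

The Beer's-law absorption density
`D(r, z′) = μ e^{−μ(z′ + √(a²−r²))}` (μ = 2kβ inside the sphere) is
convolved laterally with the objective's PSF slice `h(·, z − z′)` and
integrated through the sphere (trapezoid, 48 slices). Each PSF slice is
normalized to unit lateral integral analytically (Hankel–Parseval), so the
delta-PSF limit reproduces chord-by-chord Beer transmission exactly up to
the z′ discretization — the end-to-end oracle for the machinery. Because
the defocus parameter changes by only k NA² a ≈ 0.2 rad across the sphere
depth, slices are grouped (default 5 groups) and each group convolved with
one PSF; the error is far below the slicing error. The `"annular"`
apodization uses the condenser's footprint on the pupil,
[sin θ_min, sin θ_max]/NA, as the default annulus. By construction the
inc-BL image never exceeds the background — it cannot produce the contrast
reversals of the partially coherent model.

## Analysis choices

* Best focus: the minimum-intensity voxel of the background-normalized
  stack; ties break to the smallest z index, then row-major order. A stack
  whose minimum is not below background − 3 sd is "no object". Sub-pixel
  centre refinement exists behind a flag, off by default.
* Radial profiles: one-pixel bins by default; empty bins are missing (NA),
  never zero.
* Absorption endpoints: 8 endpoints evenly spaced over 3a–8a. The
  integration must start beyond the central inverted peak *and* its bright
  contrast-reversal rim: inside ~2a the integral A(r_end) still swings by
  ±5–12%, which would defeat the endpoint-averaging that the procedure
  uses to estimate a robust mean and spread; beyond 3a it has stabilized
  (spread across endpoints ~1.5% of the mean for the model stacks). For
  clean-versus-corrupted comparisons of the *same* stack the package's
  tests use 1.5a–4a instead: there the endpoint systematics cancel in the
  ratio and the smaller integration area keeps photon noise of the
  estimate (which grows with the integration area) well below the
  comparison tolerance.
* Axial asymmetry: `axial_asymmetry()` = Σ|I(z) − I(−z)| / Σ|I − 1|. The
  denominator is the total deviation from background, making the metric
  independent of how much empty field surrounds the object (a raw-ΣI
  denominator would pin any stack's value near zero). Measured on
  ±3 µm stacks: ≈1.0 for the full-δ gold model, ≈0.04 for δ = 0 — the
  factor-of-~25 separation is the quantitative form of "the phase term
  causes the axial contrast reversal". The δ = 0 value is small but not
  zero: the scattered wave interferes with the complex Fresnel-ringing
  phase of the aperture-limited plane wave, which is not z-symmetric.

## Synthetic acquisition

`corrupt_stack()` emulates the degradations seen in measured focal series:
per-plane multiplicative source flicker (log-normal, default sd 5%,
typical of storage-ring intensity drift between planes), integer-pixel
stage jitter (uniform within ±3 pixels, circular shifts so registration is
exactly invertible), and Poisson photon counting at `photon_scale`
expected counts per unit intensity. The photon budget of a real exposure
is not derivable from first principles here, so `photon_scale` is a free
parameter; 1e4 is the default working point. Read noise and detector MTF
are deliberately omitted. `register_stack()` (integer cross-correlation
against the central plane, with a featureless-plane guard) and
`deflicker_stack()` (plane sums scaled to the stack median — valid because
a small absorber conserves the absorbed flux across defocus) are the
matching corrections. What passing the end-to-end recovery test shows is
that the measure-and-correct chain is unbiased against *these* noise
processes; real data add drift, partial-pixel jitter and background
structure that this generator does not emulate.

## Problem sizes

The shipped tests and the acceptance script run at reduced but
representative sizes chosen by the package: scattering checks on 600–800
angle grids; field oracles on 64² cameras; model-structure stacks at
160² × 13 planes (±3 µm, 500 nm steps); absorption comparisons at
192² × 9 planes (±1 µm, 250 nm steps, pupil FFT 1024²); the synthetic
pipeline at 96² × 7 planes. Full acquisition-scale stacks (512² × 301
planes) use identical code paths and scale linearly in planes and unique
polar angles.

## Known limitations

* The condenser is a set of discrete plane waves at the mean polar angle;
  the full annular range, the spiral scanning of the condenser spot, and
  any measured coherence function are not modelled.
* The zone plate is an ideal thin lens: no struts, no diffraction
  efficiency, no other orders (their effect on the first-order focus is
  quantified as small by `zoneplate_airy_check()`).
* Scalar fields (S1 = S2 holds to 0.04% in this regime); no polarization,
  no Zernike phase-contrast mode; a single homogeneous sphere.
* Light scattered beyond the objective NA is lost, so the area-integrated
  intensity deficit taken to infinity exceeds pure absorption by a few
  percent (for these optical constants ~4% of A_BL, mostly δ-driven
  scattering); over the finite 3a–8a endpoints of the standard procedure,
  with the flat-field normalization, the measured model-to-Beer ratio is
  1.000 ± 0.015. Radiometrically absolute predictions (exposure-level
  intensities) are out of scope — all stacks are background-normalized.
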