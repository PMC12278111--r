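# Shared fixtures: the reference gold nanosphere and microscope of the
# simulated experiments, plus small grids sized for fast tests.

gold_sample <- function(diameter = 63.2, delta = 3.6e-3, beta = 2.6e-3,
                        density_fraction = 1) {
  sphere_sample(diameter = diameter,
                optics = optical_constants(energy = 510, delta = delta, beta = beta),
                density_fraction = density_fraction)
}

ref_config <- function(...) {
  microscope_config(wavelength = wavelength_from_energy(510), ...)
}

small_grid <- function(nx = 96, z_planes = 0, pixel = 5.5) {
  camera_grid(nx = nx, pixel_size = pixel, z_planes = z_planes)
}

# uniform-amplitude "scatterer" (S == 1) for pupil-transform checks
unit_amplitude <- function(psi_max = 0.08, n = 512) {
  scattering_amplitude(seq(0, psi_max, length.out = n), rep(1 + 0i, n),
                       method = "ada")
}

# analytic radial profile object (bypasses pixelation) for analysis oracles
analytic_profile <- function(r, I) {
  structure(data.frame(r = r, intensity = I, n_pixels = 1),
            bin_width = diff(r[1:2]),
            class = c("radial_profile", "data.frame"))
}
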