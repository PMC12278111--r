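# Core domain types and unit conventions.
#
# Unit conventions used throughout the package:
#   * all lengths in nanometres (nm), including focal lengths and camera
#     distances;
#   * photon energies in electron-volts (eV);
#   * angles in degrees at the user-facing API (configuration objects),
#     converted to radians in one place (`deg2rad`) for internal use.

HC_EV_NM <- 1239.841984  # h*c in eV nm

#' Degree/radian conversion
#'
#' Configuration objects store angles in degrees; the imaging operations
#' take radians. These helpers are the single conversion site.
#' @param x Angle(s).
#' @return Converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

#' Photon wavelength from energy
#'
#' Converts photon energy to vacuum wavelength via \eqn{\lambda = hc/E} with
#' \eqn{hc = 1239.841984} eV nm.
#'
#' @param energy Photon energy in eV. Must be positive.
#' @return Wavelength in nm.
#' @examples
#' wavelength_from_energy(510)   # ~2.431 nm soft X-rays
#' @export
wavelength_from_energy <- function(energy) {
  if (!is.numeric(energy) || any(energy <= 0)) {
    stop("photon energy must be positive (eV)")
  }
  HC_EV_NM / energy
}

#' Photon energy from wavelength
#'
#' Inverse of [wavelength_from_energy()].
#'
#' @param wavelength Wavelength in nm. Must be positive.
#' @return Photon energy in eV.
#' @export
energy_from_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || any(wavelength <= 0)) {
    stop("wavelength must be positive (nm)")
  }
  HC_EV_NM / wavelength
}

#' Round half away from zero
#'
#' Plain "half-up" rounding used when reporting angles, where R's default
#' banker's rounding would be surprising (e.g. 1.005 -> 1.01).
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Mean annular illumination angle
#'
#' The condenser illuminates the sample over an annular range of polar angles
#' \[theta_min, theta_max\]. The partially coherent models replace the range
#' by a single representative polar angle; by default the arithmetic mean
#' (theta_min + theta_max)/2. A weight function can be supplied for other
#' conventions (e.g. annulus-area weighting).
#'
#' @param theta_min,theta_max Annulus limits in degrees, 0 < min <= max.
#' @param weight Optional weight function w(theta); if given, the weighted
#'   mean \eqn{\int \theta w(\theta) d\theta / \int w(\theta) d\theta} over
#'   the annular range is returned.
#' @return Mean angle in degrees.
#' @examples
#' mean_annular_angle(0.83, 1.18)  # 1.005, reported as 1.01 at two decimals
#' @export
mean_annular_angle <- function(theta_min, theta_max, weight = NULL) {
  if (!(theta_min > 0) || theta_max < theta_min) {
    stop("need 0 < theta_min <= theta_max")
  }
  if (is.null(weight)) {
    return((theta_min + theta_max) / 2)
  }
  if (theta_max == theta_min) return(theta_min)
  num <- stats::integrate(function(t) t * weight(t), theta_min, theta_max)$value
  den <- stats::integrate(weight, theta_min, theta_max)$value
  num / den
}

#' Optical constants of the sample material
#'
#' Bundles photon energy/wavelength with the refractive-index decrement
#' `delta` and absorption index `beta` of the complex refractive index
#' n = 1 - delta + i beta, and the vacuum wave number k = 2 pi / lambda.
#' Exactly one of `energy` or `wavelength` must be supplied.
#'
#' @param energy Photon energy in eV.
#' @param wavelength Photon wavelength in nm.
#' @param delta Refractive-index decrement (dimensionless).
#' @param beta Absorption index (dimensionless, >= 0).
#' @return An object of class `optical_constants` with fields `energy`,
#'   `wavelength`, `delta`, `beta`, `n` (complex) and `k` (1/nm).
#' @examples
#' au <- optical_constants(energy = 510, delta = 3.6e-3, beta = 2.6e-3)
#' au$n
#' @export
optical_constants <- function(energy = NULL, wavelength = NULL,
                              delta, beta) {
  if (is.null(energy) == is.null(wavelength)) {
    stop("supply exactly one of `energy` or `wavelength`")
  }
  if (is.null(wavelength)) wavelength <- wavelength_from_energy(energy)
  if (is.null(energy)) energy <- energy_from_wavelength(wavelength)
  stopifnot(is.numeric(delta), length(delta) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (beta < 0) stop("beta must be >= 0 (absorbing or transparent)")
  structure(
    list(energy = energy, wavelength = wavelength,
         delta = delta, beta = beta,
         n = complex(real = 1 - delta, imaginary = beta),
         k = 2 * pi / wavelength),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf(
    "<optical_constants> E = %.6g eV (lambda = %.6g nm)\n  n = 1 - %.4g + %.4gi,  k = %.6g 1/nm\n",
    x$energy, x$wavelength, x$delta, x$beta, x$k))
  invisible(x)
}

#' Representative optical constants of gold at 510 eV
#'
#' Convenience default for the water-window imaging experiments simulated by
#' this package: gold at a photon energy of 510 eV (lambda ~ 2.43 nm).
#' Tabulated optical-constant databases are deliberately outside the scope of
#' the package; these values are representative of crystalline gold in the
#' water window (they give a 63 nm sphere a central transmission of ~0.43)
#' and should be replaced by the user's preferred tabulation for quantitative
#' work on other materials or energies.
#'
#' @param density_fraction Scale factor applied to both delta and beta
#'   (1 = bulk crystalline gold).
#' @return An [optical_constants] object.
#' @export
gold_optical_constants <- function(density_fraction = 1) {
  optical_constants(energy = 510,
                    delta = 3.6e-3 * density_fraction,
                    beta = 2.6e-3 * density_fraction)
}

#' Beer's-law transmission along a ray
#'
#' Intensity transmission exp(-2 k beta t) of a ray of path length `t`
#' through a homogeneous absorber; `1 - beer_transmission(t, optics)` is the
#' corresponding absorption.
#'
#' @param t Path length in nm (>= 0), vectorised.
#' @param optics An [optical_constants] object.
#' @return Transmission in (0, 1].
#' @export
beer_transmission <- function(t, optics) {
  stopifnot(inherits(optics, "optical_constants"))
  if (any(t < 0)) stop("path length must be >= 0")
  exp(-2 * optics$k * optics$beta * t)
}

#' Spherical nanoparticle sample
#'
#' The scatterer: a homogeneous sphere of radius `a` with the given optical
#' constants. The regime of validity of the scattering approximations used
#' downstream is the large-sphere limit; a warning is raised when the size
#' parameter x = k a falls below 10.
#'
#' @param radius Sphere radius in nm (alternative: `diameter`).
#' @param diameter Sphere diameter in nm.
#' @param optics [optical_constants]; default [gold_optical_constants()].
#' @param density_fraction Nominal density relative to the bulk material;
#'   scales delta and beta (default 1 = crystalline gold).
#' @return Object of class `sphere_sample` with fields `a` (radius, nm),
#'   `optics` (density-scaled), `density_fraction`, `x` (size parameter).
#' @examples
#' s <- sphere_sample(diameter = 63.2)  # Dataset #2 sphere
#' s$x                                  # size parameter k a >> 1
#' @export
sphere_sample <- function(radius = NULL, diameter = NULL,
                          optics = gold_optical_constants(),
                          density_fraction = 1) {
  if (is.null(radius) == is.null(diameter)) {
    stop("supply exactly one of `radius` or `diameter`")
  }
  if (is.null(radius)) radius <- diameter / 2
  stopifnot(inherits(optics, "optical_constants"))
  if (!(radius > 0)) stop("sphere radius must be positive")
  if (density_fraction != 1) {
    optics <- optical_constants(energy = optics$energy,
                                delta = optics$delta * density_fraction,
                                beta = optics$beta * density_fraction)
  }
  x <- optics$k * radius
  if (x < 10) {
    warning(sprintf(
      "size parameter x = k a = %.3g < 10: outside the large-sphere regime of the anomalous-diffraction model",
      x))
  }
  structure(list(a = radius, optics = optics,
                 density_fraction = density_fraction, x = x),
            class = "sphere_sample")
}

#' @export
print.sphere_sample <- function(x, ...) {
  cat(sprintf("<sphere_sample> a = %.4g nm (2a = %.4g nm), x = k a = %.4g\n",
              x$a, 2 * x$a, x$x))
  print(x$optics)
  invisible(x)
}

#' Microscope geometry and illumination configuration
#'
#' Describes the TXM: the condenser's annular illumination range, the
#' zone-plate objective approximated by a thin lens of focal length `f`
#' (first diffraction order), the in-focus sample distance `R_f`, the
#' camera distance `z_cam` and the magnification `M = z_cam / R_f`.
#'
#' When only the zone-plate design (`n_zones`, `dr_n`) and magnification are
#' given, the remaining geometry is derived: the zone-plate diameter is
#' 4 N dr_n, its first-order focal length f = diameter dr_n / lambda, the
#' numerical aperture NA = r_zp / R_f (~ lambda / (2 dr_n)), and R_f, z_cam
#' follow from the thin-lens equation 1/R_f + 1/z_cam = 1/f at the requested
#' magnification. These are derived defaults of the package, not measured
#' distances.
#'
#' @param wavelength Imaging wavelength in nm.
#' @param theta_min,theta_max Condenser annulus polar-angle limits (degrees).
#' @param theta_m Mean illumination polar angle (degrees); defaults to the
#'   arithmetic mean of the annulus limits.
#' @param omega_tilt Tilt of the beam-condenser axis relative to the
#'   zone-plate-camera axis (degrees, >= 0).
#' @param p_phi Azimuthal coherence-patch size (degrees); must divide 360.
#' @param n_zones Number of zone-plate zones.
#' @param dr_n Outermost zone width (nm).
#' @param magnification Magnification M.
#' @param f,r_zp,R_f,z_cam,na Optional explicit geometry overriding the
#'   derived defaults; if supplied they must satisfy the thin-lens equation
#'   and NA = r_zp / R_f to 1e-6 relative.
#' @return Object of class `microscope_config`.
#' @examples
#' cfg <- microscope_config(wavelength = wavelength_from_energy(510))
#' cfg$na       # ~0.0486 for dr_n = 25 nm
#' cfg$theta_m  # 1.005 degrees
#' @export
microscope_config <- function(wavelength,
                              theta_min = 0.83, theta_max = 1.18,
                              theta_m = NULL,
                              omega_tilt = 0, p_phi = 1,
                              n_zones = 900, dr_n = 25,
                              magnification = 3600,
                              f = NULL, r_zp = NULL, R_f = NULL,
                              z_cam = NULL, na = NULL) {
  stopifnot(wavelength > 0)
  if (!(theta_min > 0) || theta_max < theta_min) {
    stop("need 0 < theta_min <= theta_max (degrees)")
  }
  if (is.null(theta_m)) theta_m <- mean_annular_angle(theta_min, theta_max)
  if (theta_m < theta_min - 1e-9 || theta_m > theta_max + 1e-9) {
    stop("theta_m must lie within [theta_min, theta_max]")
  }
  if (omega_tilt < 0) stop("omega_tilt must be >= 0")
  if (p_phi <= 0 || abs(360 / p_phi - round(360 / p_phi)) > 1e-9) {
    stop("p_phi must divide 360 evenly")
  }
  if (is.null(r_zp)) r_zp <- 4 * n_zones * dr_n / 2
  if (is.null(f)) f <- (4 * n_zones * dr_n) * dr_n / wavelength
  if (is.null(R_f)) R_f <- f * (1 + 1 / magnification)
  if (is.null(z_cam)) z_cam <- f * (1 + magnification)
  if (is.null(na)) na <- r_zp / R_f
  rel <- function(a, b) abs(a - b) / abs(b)
  if (rel(1 / R_f + 1 / z_cam, 1 / f) > 1e-6) {
    stop("geometry violates the thin-lens equation 1/R_f + 1/z_cam = 1/f")
  }
  if (rel(na, r_zp / R_f) > 1e-6) {
    stop("NA inconsistent with r_zp / R_f")
  }
  M <- z_cam / R_f
  structure(
    list(wavelength = wavelength,
         theta_min = theta_min, theta_max = theta_max, theta_m = theta_m,
         omega_tilt = omega_tilt, p_phi = p_phi,
         n_zones = n_zones, dr_n = dr_n,
         f = f, r_zp = r_zp, R_f = R_f, z_cam = z_cam,
         magnification = M, na = na),
    class = "microscope_config")
}

#' @export
print.microscope_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<microscope_config> lambda = %.4g nm\n",
    "  condenser: theta in [%.3g, %.3g] deg, theta_m = %.4g deg, tilt = %.3g deg, p_phi = %g deg\n",
    "  zone plate: N = %d, dr_n = %g nm, r_zp = %.4g um, f = %.4g mm, NA = %.4g\n",
    "  distances: R_f = %.4g mm, z_cam = %.4g m, M = %.0f\n"),
    x$wavelength, x$theta_min, x$theta_max, x$theta_m, x$omega_tilt, x$p_phi,
    x$n_zones, x$dr_n, x$r_zp / 1e3, x$f / 1e6, x$na,
    x$R_f / 1e6, x$z_cam / 1e9, x$magnification))
  invisible(x)
}

#' Camera sampling grid
#'
#' Pixel grid in sample-plane coordinates (camera coordinates divided by the
#' magnification) and the list of defocus planes. `z_planes` are sphere
#' displacements relative to the in-focus distance R_f; positive z moves the
#' sphere away from the zone plate (toward the condenser, "above focus").
#'
#' @param nx,ny Pixel counts.
#' @param pixel_size Pixel size in sample coordinates (nm); the acquisition
#'   default is 5.5 nm.
#' @param z_planes Strictly increasing defocus values (nm); the acquisition
#'   default is a 40 nm z-step.
#' @return Object of class `camera_grid`.
#' @export
camera_grid <- function(nx = 512, ny = nx, pixel_size = 5.5,
                        z_planes = seq(-6000, 6000, by = 40)) {
  stopifnot(nx >= 8, ny >= 8, pixel_size > 0, length(z_planes) >= 1)
  if (any(diff(z_planes) <= 0)) stop("z_planes must be strictly increasing")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, z_planes = as.numeric(z_planes)),
            class = "camera_grid")
}

#' @export
print.camera_grid <- function(x, ...) {
  cat(sprintf("<camera_grid> %d x %d px @ %.3g nm, %d z-planes in [%.3g, %.3g] nm\n",
              x$nx, x$ny, x$pixel_size, length(x$z_planes),
              min(x$z_planes), max(x$z_planes)))
  invisible(x)
}

# sample-plane pixel centre coordinates, origin at the optical axis
grid_axes <- function(grid) {
  list(x = (seq_len(grid$nx) - (grid$nx %/% 2 + 1)) * grid$pixel_size,
       y = (seq_len(grid$ny) - (grid$ny %/% 2 + 1)) * grid$pixel_size)
}

#' 3D intensity stack
#'
#' Container for a simulated or measured focal series: a (z, y, x) array of
#' non-negative intensities with voxel sizes, and a normalization tag
#' (`"raw"` or `"background_one"` for stacks scaled so that the background
#' far from the object is 1).
#'
#' @param intensities Numeric array with dim (nz, ny, nx), all >= 0.
#' @param voxel Length-3 numeric c(dz, dy, dx) in nm.
#' @param normalization `"raw"` or `"background_one"`.
#' @param z_planes Optional defocus values (nm), length nz.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel, normalization = c("raw", "background_one"),
                        z_planes = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            length(voxel) == 3L, all(voxel > 0))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (is.null(z_planes)) {
    z_planes <- (seq_len(dim(intensities)[1]) - (dim(intensities)[1] + 1) / 2) * voxel[1]
  }
  stopifnot(length(z_planes) == dim(intensities)[1])
  structure(list(intensities = intensities, voxel = as.numeric(voxel),
                 normalization = normalization, z_planes = as.numeric(z_planes)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g nm, %s\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              x$normalization))
  invisible(x)
}

# logical mask of the border annulus (outer `frac` of the inscribed FOV radius)
border_mask <- function(ny, nx, pixel_size, frac = 0.1) {
  xs <- (seq_len(nx) - (nx %/% 2 + 1)) * pixel_size
  ys <- (seq_len(ny) - (ny %/% 2 + 1)) * pixel_size
  r <- sqrt(outer(ys^2, xs^2, "+"))
  rmax <- min(max(abs(xs)), max(abs(ys)))
  r >= (1 - frac) * rmax & r <= rmax
}

#' Background statistics of a stack
#'
#' Median and standard deviation of the border annulus (outer 10% of the
#' inscribed field-of-view radius) across all planes.
#'
#' @param stack An [image_stack].
#' @param frac Annulus width as a fraction of the FOV radius.
#' @return List with `median` and `sd`.
#' @export
stack_background <- function(stack, frac = 0.1) {
  d <- dim(stack$intensities)
  m <- border_mask(d[2], d[3], stack$voxel[2], frac)
  vals <- apply(stack$intensities, 1, function(pl) pl[m])
  list(median = stats::median(vals), sd = stats::sd(vals))
}

#' Normalize a stack so the background is 1
#'
#' Divides the whole stack by the median intensity of the border annulus
#' (a single global factor, preserving relative axial structure).
#'
#' @param stack An [image_stack].
#' @param frac Annulus width fraction.
#' @return A background-normalized [image_stack].
#' @export
normalize_stack <- function(stack, frac = 0.1) {
  bg <- stack_background(stack, frac)$median
  if (!is.finite(bg) || bg <= 0) stop("cannot normalize: non-positive background")
  image_stack(stack$intensities / bg, stack$voxel, "background_one",
              z_planes = stack$z_planes)
}
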