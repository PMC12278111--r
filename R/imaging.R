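# Image formation: fields at the camera and partially coherent stacks.
#
# The chain follows the thin-lens model of the zone plate. Dropping the
# constant factor C e^{ik r_cam^2/(2 z_cam)} e^{ik R_f} common to both paths
# (it cancels in the intensity), the two camera fields for illumination at
# polar angle theta, azimuth phi, and sphere defocus z (z > 0 away from the
# zone plate) are, in sample-plane coordinates x_s = x_cam / M:
#
#   U_pw(x_s) = e^{ik R_f (cos th - 1)} * 2 pi r_zp^2 * Conj(A)(u, v(x_s)),
#       u = k r_zp^2 / R_f,
#       v = k r_zp |sin th (cos ph, sin ph) - x_s / R_f|
#
#   U_sw(x_s) = e^{ikz(1 - cos th)} * (i / (k (R_f + z))) *
#               int_aperture S_th(x',y') e^{-ikz r'^2/(2R_f^2)}
#                            e^{-ik x_s . r' / R_f} dx' dy'
#
# The plane-wave path keeps the full residual quadratic phase -k r'^2/(2R_f)
# across the aperture exactly (Lommel-type integral); the scattered-wave
# path is the Fourier transform of the pupil S_th * defocus factor, the
# standard paraxial form, evaluated by FFT.

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

#' Camera-plane field
#'
#' Complex field over the camera grid (in sample-plane coordinates) for one
#' illumination direction and defocus.
#'
#' @param field Complex matrix (ny x nx).
#' @param x,y Pixel-centre axes (nm, sample coordinates).
#' @param theta,phi Illumination angles (rad).
#' @param z Defocus (nm).
#' @param provenance `"plane_wave"`, `"scattered_wave"` or `"total"`.
#' @return Object of class `camera_field`.
#' @export
camera_field <- function(field, x, y, theta, phi, z,
                         provenance = c("plane_wave", "scattered_wave", "total")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(field), nrow(field) == length(y), ncol(field) == length(x))
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field)))) {
    stop("camera field contains non-finite values")
  }
  structure(list(field = field, x = x, y = y,
                 theta = theta, phi = phi, z = z, provenance = provenance),
            class = "camera_field")
}

#' @export
print.camera_field <- function(x, ...) {
  cat(sprintf("<camera_field:%s> %d x %d px, theta = %.4g deg, phi = %.4g deg, z = %.4g nm\n",
              x$provenance, length(x$x), length(x$y),
              rad2deg(x$theta), rad2deg(x$phi), x$z))
  invisible(x)
}

# table-driven evaluation of 2 pi r_zp^2 Conj(A(u, v)) over a v matrix
pw_eval <- function(vmat, u, r_zp, backend = "lommel", n_table = 4096,
                    quad_n = NULL) {
  vr <- range(vmat)
  vg <- seq(max(vr[1] - 1e-9, 0), vr[2] + 1e-9, length.out = n_table)
  Ag <- if (backend == "lommel") {
    aperture_integral(u, vg)
  } else {
    aperture_integral_quad(u, vg, n = quad_n)
  }
  Fg <- 2 * pi * r_zp^2 * Conj(Ag)
  fre <- stats::splinefun(vg, Re(Fg))
  fim <- stats::splinefun(vg, Im(Fg))
  matrix(complex(real = fre(vmat), imaginary = fim(vmat)),
         nrow(vmat), ncol(vmat))
}

#' Plane-wave field at the camera
#'
#' Field of the oblique illuminating plane wave propagated through the
#' zone-plate lens to the camera. Independent of the sphere defocus `z`
#' (the plane wave exists everywhere); `z` is carried for bookkeeping.
#' Two numerically independent backends are provided: the Lommel-type
#' series (`"lommel"`, default) and direct radial quadrature (`"quad"`).
#'
#' @param theta,phi Illumination polar/azimuthal angles (rad).
#' @param z Defocus (nm), bookkeeping only.
#' @param config A [microscope_config].
#' @param grid A [camera_grid].
#' @param backend `"lommel"` or `"quad"`.
#' @return A [camera_field] with provenance `"plane_wave"`.
#' @export
pw_field <- function(theta, phi, z, config, grid, backend = c("lommel", "quad")) {
  backend <- match.arg(backend)
  ax <- grid_axes(grid)
  k <- 2 * pi / config$wavelength
  u <- k * config$r_zp^2 / config$R_f
  sx <- sin(theta) * cos(phi); sy <- sin(theta) * sin(phi)
  vmat <- k * config$r_zp *
    sqrt(outer((sy - ax$y / config$R_f)^2, (sx - ax$x / config$R_f)^2, "+"))
  fld <- exp(1i * k * config$R_f * (cos(theta) - 1)) *
    pw_eval(vmat, u, config$r_zp, backend = backend,
            n_table = if (backend == "lommel") 4096 else 768)
  camera_field(fld, ax$x, ax$y, theta, phi, z, "plane_wave")
}

# pupil-plane sampling geometry for the FFT backend
pupil_geometry <- function(config, grid, n_fft) {
  k <- 2 * pi / config$wavelength
  dprime <- 2 * pi * config$R_f / (k * n_fft * grid$pixel_size)
  idx <- seq(-n_fft / 2, n_fft / 2 - 1)
  xp <- idx * dprime
  n_ap <- config$r_zp / dprime
  if (n_ap + 2 > n_fft / 2) {
    stop("zone-plate aperture does not fit the pupil grid; increase n_fft or pixel_size")
  }
  list(k = k, dprime = dprime, xp = xp, n_fft = n_fft)
}

#' Scattered-wave field at the camera
#'
#' Fourier transform of the zone-plate pupil function (scattering amplitude
#' evaluated at the oblique-geometry scattering angle, times the paraxial
#' defocus phase), with the spherical-wave prefactor of the scattered wave
#' folded in. Evaluated on an `n_fft` x `n_fft` pupil grid by FFT and cropped
#' to the camera grid; the aperture edge is anti-aliased by area weighting.
#'
#' @param theta,phi Illumination angles (rad).
#' @param z Defocus (nm); positive away from the zone plate.
#' @param S A [scattering_amplitude] covering the needed angle range.
#' @param config A [microscope_config].
#' @param grid A [camera_grid].
#' @param n_fft FFT size (power of two >= grid dimension).
#' @return A [camera_field] with provenance `"scattered_wave"`.
#' @export
sw_field <- function(theta, phi, z, S, config, grid, n_fft = 1024) {
  stopifnot(inherits(S, "scattering_amplitude"))
  pg <- pupil_geometry(config, grid, n_fft)
  k <- pg$k
  # defocus-phase Nyquist check on the pupil grid
  dphase <- k * abs(z) * config$r_zp / config$R_f^2 * pg$dprime
  if (dphase > pi) {
    stop(sprintf(
      "pupil sampling below the defocus-phase Nyquist bound (%.2f rad/sample at z = %g nm); increase n_fft",
      dphase, z))
  }
  # pupil axes oriented like the camera axes: x' along columns, y' along rows
  XP <- matrix(pg$xp, n_fft, n_fft, byrow = TRUE)
  YP <- matrix(pg$xp, n_fft, n_fft)
  RP2 <- XP^2 + YP^2
  w <- pmin(pmax((config$r_zp - sqrt(RP2)) / pg$dprime + 0.5, 0), 1)
  inap <- which(w > 0)
  # anti-aliased rim pixels may lie up to half a sample outside the disk;
  # clamp them radially onto the rim before the angle mapping
  scl <- pmin(1, config$r_zp / sqrt(pmax(RP2[inap], 1e-12)))
  psi <- oblique_map(theta, phi, XP[inap] * scl, YP[inap] * scl, z, config)
  Sv <- interp_amplitude(S, psi, "S1")
  P <- matrix(0 + 0i, n_fft, n_fft)
  P[inap] <- Sv * exp(-1i * k * z * RP2[inap] / (2 * config$R_f^2)) * w[inap]
  Fm <- fftshift2(stats::fft(fftshift2(P)))
  pref <- exp(1i * k * z * (1 - cos(theta))) * (1i / (k * (config$R_f + z)))
  full <- pref * pg$dprime^2 * Fm
  ax <- grid_axes(grid)
  ic <- n_fft %/% 2 + 1
  rows <- ic + (seq_len(grid$ny) - (grid$ny %/% 2 + 1))
  cols <- ic + (seq_len(grid$nx) - (grid$nx %/% 2 + 1))
  camera_field(full[rows, cols], ax$x, ax$y, theta, phi, z, "scattered_wave")
}

#' Total field at the camera
#'
#' Coherent sum of the plane-wave and scattered-wave fields. The relative
#' prefactors of the two paths are already carried inside [pw_field()] and
#' [sw_field()], so the total is a plain complex sum; this constructor only
#' validates that both fields share the same grid and geometry.
#'
#' @param pw A plane-wave [camera_field].
#' @param sw A scattered-wave [camera_field].
#' @return A [camera_field] with provenance `"total"`.
#' @export
total_field <- function(pw, sw) {
  stopifnot(inherits(pw, "camera_field"), inherits(sw, "camera_field"))
  if (pw$provenance != "plane_wave" || sw$provenance != "scattered_wave") {
    stop("total_field() expects one plane-wave and one scattered-wave field")
  }
  if (!isTRUE(all.equal(pw$x, sw$x)) || !isTRUE(all.equal(pw$y, sw$y)) ||
      pw$theta != sw$theta || pw$phi != sw$phi || pw$z != sw$z) {
    stop("mismatched grids or geometry between plane-wave and scattered-wave fields")
  }
  camera_field(pw$field + sw$field, pw$x, pw$y, pw$theta, pw$phi, pw$z, "total")
}

#' Polar illumination angle of a tilted condenser
#'
#' When the beam-condenser axis is tilted by `omega_tilt` relative to the
#' zone-plate-camera axis, the illumination directions form a cone of
#' half-angle `theta_m` around the tilted axis, so the polar angle seen by
#' the objective varies with the azimuth:
#' theta(phi) = acos(cos theta_m cos omega - sin theta_m sin omega cos phi).
#' Reduces to `theta_m` for `omega_tilt = 0`; to first order
#' theta(0) = theta_m + omega and theta(pi) = theta_m - omega.
#'
#' @param phi Azimuthal angle(s) (rad).
#' @param theta_m Mean condenser polar angle (rad).
#' @param omega_tilt Tilt angle (rad, >= 0).
#' @return Polar angle(s) theta(phi) in rad.
#' @export
tilted_theta <- function(phi, theta_m, omega_tilt) {
  if (omega_tilt < 0) stop("omega_tilt must be >= 0")
  acos(pmin(pmax(cos(theta_m) * cos(omega_tilt) -
                   sin(theta_m) * sin(omega_tilt) * cos(phi), -1), 1))
}

# exact illumination direction on the tilted cone: polar angle and azimuth
tilted_direction <- function(phi, theta_m, omega_tilt) {
  if (omega_tilt == 0) {
    # exact limit, keeping the untilted and tilted engines bit-identical
    return(list(theta = rep(theta_m, length(phi)), azimuth = phi))
  }
  st <- sin(theta_m); ct <- cos(theta_m)
  so <- sin(omega_tilt); co <- cos(omega_tilt)
  dx <- st * cos(phi) * co + ct * so
  dy <- st * sin(phi)
  dz <- -st * cos(phi) * so + ct * co
  list(theta = acos(pmin(pmax(dz, -1), 1)), azimuth = atan2(dy, dx))
}

# bilinear sampling of matrix I (values at axes xs, ys) at query points,
# background fill outside the field of view
bilinear_sample <- function(I, xs, ys, xq, yq, fill = 1) {
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fx <- (xq - xs[1]) / dx
  fy <- (yq - ys[1]) / dy
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  ok <- ix >= 0 & ix <= length(xs) - 2 & iy >= 0 & iy <= length(ys) - 2
  ix1 <- pmin(pmax(ix, 0), length(xs) - 2) + 1L
  iy1 <- pmin(pmax(iy, 0), length(ys) - 2) + 1L
  n1 <- length(ys)
  id <- iy1 + (ix1 - 1L) * n1
  out <- (1 - ty) * ((1 - tx) * I[id] + tx * I[id + n1]) +
    ty * ((1 - tx) * I[id + 1L] + tx * I[id + 1L + n1])
  out[!ok] <- fill
  out
}

# azimuthal mean per radial bin of width bw (pixel units of the axes);
# returns bin mean radius, mean value and count
radial_bin <- function(I, xs, ys, bw) {
  r <- sqrt(outer(ys^2, xs^2, "+"))
  b <- floor(as.vector(r) / bw)
  v <- as.vector(I)
  list(r = as.numeric(tapply(as.vector(r), b, mean)),
       mean = as.numeric(tapply(v, b, mean)),
       n = as.numeric(tapply(v, b, length)))
}

# needed scattering-angle coverage for a configuration
needed_psi_max <- function(config, thetas) {
  (max(thetas) + atan(config$r_zp / config$R_f)) * 1.02 + 1e-3
}

# default amplitude table for a sample/config pair
build_amplitude <- function(sample, config, thetas, method, n_psi = 2048) {
  psi <- seq(0, needed_psi_max(config, thetas), length.out = n_psi)
  switch(method,
         mie = mie_amplitudes(sample, psi),
         ada = ada_amplitude(sample, psi),
         ea  = ea_amplitude(sample, psi))
}

# Partially coherent stack engine.
#
# thetas[j], azimuths[j]: polar angle and image-rotation azimuth of the
# j-th coherence patch. For each z-plane the flat-fielded single-patch
# intensity |U_pw + U_sw|^2 / |U_pw|^2 is computed at azimuth 0 for each
# unique polar angle, then the patch intensities are added after rotation
# to their azimuths (incoherent azimuthal sum). When all patches share one
# polar angle and the azimuths cover the circle evenly, the rotation sum
# equals the azimuthal mean and is computed exactly by radial binning.
pc_engine <- function(sample, config, grid, thetas, azimuths,
                      method = "mie", S = NULL, n_fft = 1024,
                      pw_backend = "lommel") {
  stopifnot(length(thetas) == length(azimuths))
  nphi <- length(thetas)
  if (is.null(S)) S <- build_amplitude(sample, config, thetas, method)
  ax <- grid_axes(grid)
  nz <- length(grid$z_planes)
  thr <- signif(thetas, 12)
  uth <- unique(thr)
  even_circle <- {
    d <- sort(azimuths %% (2 * pi))
    gaps <- diff(c(d, d[1] + 2 * pi))
    max(abs(gaps - 2 * pi / nphi)) < 1e-9
  }
  # for a single polar angle and a dense, even azimuth set the discrete
  # rotation sum is indistinguishable from the exact azimuthal mean, which
  # radial binning computes directly; sparse azimuth sets (large coherence
  # patches) keep the discrete sum so their residual ringing is preserved
  symmetric <- length(uth) == 1L && even_circle && nphi >= 180L
  acc <- array(0, c(nz, grid$ny, grid$nx))
  r_q <- sqrt(outer(ax$y^2, ax$x^2, "+"))
  for (th in uth) {
    pw <- pw_field(th, 0, 0, config, grid, backend = pw_backend)
    Ipw <- Mod(pw$field)^2
    jj <- which(thr == th)
    for (iz in seq_len(nz)) {
      z <- grid$z_planes[iz]
      sw <- sw_field(th, 0, z, S, config, grid, n_fft = n_fft)
      Iflat <- Mod(pw$field + sw$field)^2 / Ipw
      if (symmetric) {
        rb <- radial_bin(Iflat, ax$x, ax$y, grid$pixel_size)
        sp <- stats::splinefun(rb$r, rb$mean)
        acc[iz, , ] <- sp(r_q)
      } else {
        pl <- matrix(0, grid$ny, grid$nx)
        for (j in jj) {
          alpha <- azimuths[j]
          xq <- outer(rep(1, grid$ny), ax$x) * cos(alpha) +
            outer(ax$y, rep(1, grid$nx)) * sin(alpha)
          yq <- -outer(rep(1, grid$ny), ax$x) * sin(alpha) +
            outer(ax$y, rep(1, grid$nx)) * cos(alpha)
          pl <- pl + matrix(bilinear_sample(Iflat, ax$x, ax$y, xq, yq, fill = 1),
                            grid$ny, grid$nx)
        }
        acc[iz, , ] <- acc[iz, , ] + pl / nphi
      }
    }
  }
  st <- image_stack(pmax(acc, 0), c(
    if (nz > 1) grid$z_planes[2] - grid$z_planes[1] else 1,
    grid$pixel_size, grid$pixel_size),
    z_planes = grid$z_planes)
  normalize_stack(st)
}

#' Partially coherent Mie image stack
#'
#' Synthesizes the 3D focal stack of the nanosphere under mean-angle annular
#' illumination: the total camera field (plane wave + scattered wave) is
#' computed at the mean polar angle theta_m for one azimuth, its
#' flat-fielded intensity (normalized by the matching blank plane-wave
#' intensity) is rotated through 360 degrees in steps of the coherence-patch
#' size `p_phi`, and the intensities are added. The background of the
#' returned stack is normalized to 1.
#'
#' @param sample A [sphere_sample].
#' @param config A [microscope_config] (theta_m and p_phi are used).
#' @param grid A [camera_grid].
#' @param method Scattering model for the amplitude table: `"mie"`
#'   (default), `"ada"` or `"ea"`; ignored when `S` is given.
#' @param S Optional precomputed [scattering_amplitude].
#' @param n_fft Pupil FFT size.
#' @param pw_backend Plane-wave backend, `"lommel"` or `"quad"`.
#' @return An [image_stack] (background_one).
#' @export
pc_image <- function(sample, config, grid, method = c("mie", "ada", "ea"),
                     S = NULL, n_fft = 1024, pw_backend = "lommel") {
  method <- match.arg(method)
  phis <- deg2rad(seq(0, 360 - config$p_phi, by = config$p_phi))
  th <- deg2rad(config$theta_m)
  pc_engine(sample, config, grid,
            thetas = rep(th, length(phis)), azimuths = phis,
            method = method, S = S, n_fft = n_fft, pw_backend = pw_backend)
}

#' Partially coherent stack with a tilted condenser
#'
#' As [pc_image()], but the illumination directions lie on a cone of
#' half-angle theta_m around a beam-condenser axis tilted by
#' `config$omega_tilt` relative to the zone-plate-camera axis, so the polar
#' angle theta(phi) (see [tilted_theta()]) and the exact azimuth of each
#' patch vary around the circumference. With `omega_tilt = 0` this reduces
#' exactly (bit-identically) to [pc_image()].
#'
#' @inheritParams pc_image
#' @return An [image_stack] (background_one).
#' @export
pc_image_tilted <- function(sample, config, grid, method = c("mie", "ada", "ea"),
                            S = NULL, n_fft = 1024, pw_backend = "lommel") {
  method <- match.arg(method)
  phis <- deg2rad(seq(0, 360 - config$p_phi, by = config$p_phi))
  td <- tilted_direction(phis, deg2rad(config$theta_m), deg2rad(config$omega_tilt))
  pc_engine(sample, config, grid,
            thetas = td$theta, azimuths = td$azimuth,
            method = method, S = S, n_fft = n_fft, pw_backend = pw_backend)
}

#' 3D point-spread function of the objective lens
#'
#' Normalized intensity PSF of a circular (or annular) pupil with the
#' numerical aperture of the zone plate, in the classical paraxial defocus
#' form: h(r, z) proportional to |int_e1^e2 J0(k NA r rho)
#' e^{i k NA^2 z rho^2 / 2} rho d rho|^2. Each z-slice is normalized to unit
#' lateral integral (energy conservation), so convolving an absorption
#' density with h and integrating reproduces the density's integral.
#'
#' @param r Radii (nm), vectorised.
#' @param z Defocus (nm), scalar.
#' @param config A [microscope_config].
#' @param apodization `"full"` or `"annular"`.
#' @param annulus For `"annular"`: c(inner, outer) pupil radius fractions;
#'   defaults to the condenser annulus footprint
#'   c(sin theta_min, sin theta_max)/NA.
#' @return Intensity values h(r, z) (1/nm^2 per slice).
#' @export
lens_psf3d <- function(r, z, config, apodization = c("full", "annular"),
                       annulus = NULL) {
  apodization <- match.arg(apodization)
  k <- 2 * pi / config$wavelength
  if (apodization == "full") {
    e <- c(0, 1)
  } else {
    if (is.null(annulus)) {
      annulus <- c(sin(deg2rad(config$theta_min)),
                   sin(deg2rad(config$theta_max))) / config$na
    }
    e <- annulus
    if (e[1] < 0 || e[2] > 1 || e[1] >= e[2]) {
      stop("annulus must satisfy 0 <= inner < outer <= 1 (pupil fractions)")
    }
  }
  u <- k * config$na^2 * z
  v <- k * config$na * r
  gl <- pracma::gaussLegendre(512, e[1], e[2])
  rho <- gl$x; w <- gl$w
  ph <- exp(1i * u * rho^2 / 2) * rho * w
  C <- vapply(v, function(vi) {
    zz <- sum(besselJ(vi * rho, 0) * ph)
    c(Re(zz), Im(zz))
  }, numeric(2))
  amp2 <- C[1, ]^2 + C[2, ]^2
  amp2 * (k * config$na)^2 / (pi * (e[2]^2 - e[1]^2) / 2) / 2
}

#' Incoherent Beer's-law image stack
#'
#' The comparison model: the Beer's-law absorption density of the sphere,
#' D(r, z') = mu exp(-mu (z' + sqrt(a^2 - r^2))) inside the sphere with
#' mu = 2 k beta, is convolved laterally with the objective's 3D PSF slice
#' h(., z - z') and integrated over z', giving
#' I(r, z) = 1 - int D(., z') (x) h(., z - z') dz'. The phase delta plays no
#' role. With `psf = "delta"` the PSF is replaced by a delta function and
#' the model reduces exactly to Beer's-law chord transmission (used as an
#' oracle).
#'
#' @param sample A [sphere_sample].
#' @param config A [microscope_config].
#' @param grid A [camera_grid].
#' @param apodization `"full"` or `"annular"` pupil (see [lens_psf3d()]).
#' @param annulus Annulus fractions, see [lens_psf3d()].
#' @param n_slices Number of z' integration slices through the sphere.
#' @param psf `"lens"` (default) or `"delta"`.
#' @param n_psf_groups Number of PSF defocus groups across the sphere depth:
#'   the PSF varies negligibly over the +/- a depth of the sphere (the
#'   defocus parameter changes by k NA^2 a << 1 rad), so slices are grouped
#'   and each group convolved with the PSF at its mean depth.
#' @return An [image_stack] (background_one by construction).
#' @export
incbl_image <- function(sample, config, grid,
                        apodization = c("full", "annular"), annulus = NULL,
                        n_slices = 48, psf = c("lens", "delta"),
                        n_psf_groups = 5) {
  apodization <- match.arg(apodization)
  psf <- match.arg(psf)
  a <- sample$a
  mu <- 2 * sample$optics$k * sample$optics$beta
  ax <- grid_axes(grid)
  nz <- length(grid$z_planes)
  if (grid$pixel_size > a / 4) {
    warning("camera grid coarser than a/4: sphere undersampled in the inc-BL model")
  }
  r2 <- outer(ax$y^2, ax$x^2, "+")
  out <- array(1, c(nz, grid$ny, grid$nx))
  if (mu == 0) {
    return(image_stack(out, c(if (nz > 1) diff(grid$z_planes[1:2]) else 1,
                              grid$pixel_size, grid$pixel_size),
                       normalization = "background_one",
                       z_planes = grid$z_planes))
  }
  zp <- seq(-a, a, length.out = n_slices + 1)
  wts <- rep(zp[2] - zp[1], n_slices + 1)
  wts[c(1, n_slices + 1)] <- wts[1] / 2  # trapezoid
  slabs <- lapply(seq_along(zp), function(i) {
    D <- matrix(0, grid$ny, grid$nx)
    ins <- r2 + zp[i]^2 < a^2
    D[ins] <- mu * exp(-mu * (zp[i] + sqrt(a^2 - r2[ins])))
    D
  })
  if (psf == "delta") {
    absorbed <- Reduce(`+`, Map(function(D, w) D * w, slabs, as.list(wts)))
    for (iz in seq_len(nz)) out[iz, , ] <- 1 - absorbed
  } else {
    npad <- 2^ceiling(log2(max(grid$nx, grid$ny) * 2))
    # group the sphere slices by depth; one PSF per group
    grp <- cut(seq_along(zp), breaks = n_psf_groups, labels = FALSE)
    FDg <- lapply(seq_len(n_psf_groups), function(gi) {
      D <- Reduce(`+`, Map(function(Dl, w) Dl * w,
                           slabs[grp == gi], as.list(wts[grp == gi])))
      P <- matrix(0, npad, npad)
      P[seq_len(grid$ny), seq_len(grid$nx)] <- D
      list(fft = stats::fft(P), z = mean(zp[grp == gi]))
    })
    pr <- sqrt(outer(((seq_len(npad) - npad / 2 - 1) * grid$pixel_size)^2,
                     ((seq_len(npad) - npad / 2 - 1) * grid$pixel_size)^2, "+"))
    rtab <- seq(0, max(pr), length.out = 1024)
    for (iz in seq_len(nz)) {
      conv <- matrix(0, npad, npad)
      for (gi in seq_len(n_psf_groups)) {
        dz <- grid$z_planes[iz] - FDg[[gi]]$z
        htab <- lens_psf3d(rtab, dz, config, apodization, annulus)
        hsp <- stats::splinefun(rtab, htab)
        H <- fftshift2(matrix(pmax(hsp(pr), 0), npad, npad))
        conv <- conv + Re(stats::fft(FDg[[gi]]$fft * stats::fft(H),
                                     inverse = TRUE)) / npad^2
      }
      full <- 1 - conv * grid$pixel_size^2
      out[iz, , ] <- full[seq_len(grid$ny), seq_len(grid$nx)]
    }
  }
  image_stack(pmax(out, 0), c(if (nz > 1) diff(grid$z_planes[1:2]) else 1,
                              grid$pixel_size, grid$pixel_size),
              normalization = "background_one", z_planes = grid$z_planes)
}

#' Zone-plate first-order focus versus the Airy pattern
#'
#' Validation utility for the lens approximation of the zone plate: the
#' zone-plate transmission is expanded as a cosine series over diffraction
#' orders; the radial Fresnel integral of the series (orders in `m_orders`,
#' both convergent and divergent terms, plus the DC term) is evaluated at
#' the first-order focal plane and compared with the Airy pattern of a lens
#' with the equivalent NA over the main lobe and first ring.
#'
#' @param config A [microscope_config] (zone count and dr_n are used).
#' @param m_orders Odd diffraction orders to include.
#' @param n_r Number of radial camera samples.
#' @param n_rho Number of radial aperture samples (trapezoid).
#' @return List with `max_rel_deviation` (of normalized intensities,
#'   relative to the Airy peak, over the main lobe + first ring),
#'   `first_zero_zp` and `first_zero_airy` (nm), `order_ratio_13`
#'   (focal intensity ratio of orders m = 1 and m = 3; 9 for an ideal
#'   cosine-series plate), and the radial profiles.
#' @export
zoneplate_airy_check <- function(config, m_orders = c(1, 3, 5, 7),
                                 n_r = 160, n_rho = 2^15 + 1) {
  k <- 2 * pi / config$wavelength
  f <- config$f
  r_zp <- config$r_zp
  lam <- config$wavelength
  rho <- seq(0, r_zp, length.out = n_rho)
  wtz <- rep(1, n_rho); wtz[c(1, n_rho)] <- 0.5
  drho <- rho[2] - rho[1]
  na_eff <- r_zp / f
  rmax <- 7.1 / (k * na_eff)  # just past the second Airy zero
  r <- seq(0, rmax, length.out = n_r)
  field_at <- function(zdist, m_set) {
    # U(r) at distance zdist behind the plate, Fresnel kernel e^{ik rho^2/2z}
    base <- 1i * k * rho^2 / (2 * zdist)
    Tser <- rep(0.5 + 0i, n_rho)
    for (m in m_set) {
      Tser <- Tser + (1 / (m * pi)) *
        (exp(1i * m * pi * rho^2 / (lam * f)) + exp(-1i * m * pi * rho^2 / (lam * f)))
    }
    g <- Tser * exp(base) * rho * wtz * drho
    vapply(r, function(ri) {
      zz <- sum(g * j0fast(k * ri * rho / zdist))
      abs(zz)^2
    }, numeric(1))
  }
  Izp <- field_at(f, m_orders)
  # Airy reference: constant 1/pi amplitude over the aperture, stigmatic
  v <- k * na_eff * r
  airy_amp <- (r_zp^2 / pi) * ifelse(v < 1e-8, 0.5, besselJ(v, 1) / v)
  Iairy <- airy_amp^2
  Izp_n <- Izp / max(Izp)
  Iairy_n <- Iairy / max(Iairy)
  first_zero <- function(I) {
    i <- which(diff(I) > 0)[1]
    if (is.na(i)) return(NA_real_)
    r[i]
  }
  dev <- max(abs(Izp_n - Iairy_n))
  ratio13 <- if (all(c(1, 3) %in% m_orders)) {
    I3 <- field_at(f / 3, m_orders)
    max(Izp) / max(I3)
  } else NA_real_
  list(max_rel_deviation = dev,
       first_zero_zp = first_zero(Izp_n),
       first_zero_airy = first_zero(Iairy_n),
       order_ratio_13 = ratio13,
       r = r, I_zp = Izp_n, I_airy = Iairy_n)
}
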