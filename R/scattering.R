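# Scattering amplitudes of the nanosphere.
#
# Phase convention: the incident field is exp(+ikz) and the scattered wave at
# distance r is S(psi)/(-ik) * exp(ik r)/r, so that the extinction theorem
# reads Q_ext = (4/x^2) Re S(0). Under this convention the forward amplitude
# of a weakly refracting sphere (n real > 1) has a negative imaginary part.

#' Scattering amplitude table
#'
#' Tabulates the complex scattering amplitudes S1(psi), S2(psi) of a sphere
#' on a strictly increasing angle grid starting at psi = 0, with cubic-spline
#' interpolation (real and imaginary parts separately) between grid points.
#' Scalar models store S1 = S2.
#'
#' @param psi Scattering angles in radians, strictly increasing from 0.
#' @param S1,S2 Complex amplitudes per angle.
#' @param method One of `"mie"`, `"ada"`, `"ea"`.
#' @return Object of class `scattering_amplitude`.
#' @seealso [mie_amplitudes()], [ada_amplitude()], [ea_amplitude()]
#' @export
scattering_amplitude <- function(psi, S1, S2 = S1, method = c("mie", "ada", "ea")) {
  method <- match.arg(method)
  stopifnot(length(psi) >= 4, length(S1) == length(psi), length(S2) == length(psi))
  if (abs(psi[1]) > 1e-15) stop("angle grid must start at psi = 0")
  if (any(diff(psi) <= 0)) stop("angle grid must be strictly increasing")
  structure(list(psi = psi, S1 = S1, S2 = S2, method = method), class = "scattering_amplitude")
}

#' @export
print.scattering_amplitude <- function(x, ...) {
  cat(sprintf("<scattering_amplitude> method = %s, %d angles in [0, %.4g rad], S(0) = %.4g%+.4gi\n",
              x$method, length(x$psi), max(x$psi), Re(x$S1[1]), Im(x$S1[1])))
  invisible(x)
}

#' Interpolate a scattering amplitude
#'
#' Cubic-spline interpolation of the tabulated amplitude at arbitrary angles
#' within the table range (real and imaginary parts splined separately).
#'
#' @param sa A [scattering_amplitude].
#' @param psi Angles (rad) at which to evaluate; must lie inside the table.
#' @param component `"S1"` or `"S2"`.
#' @return Complex vector of amplitudes.
#' @export
interp_amplitude <- function(sa, psi, component = c("S1", "S2")) {
  component <- match.arg(component)
  if (max(psi) > max(sa$psi) + 1e-12 || min(psi) < 0) {
    stop(sprintf("requested angle %.4g rad outside tabulated range [0, %.4g]",
                 max(psi), max(sa$psi)))
  }
  S <- sa[[component]]
  fre <- stats::splinefun(sa$psi, Re(S))
  fim <- stats::splinefun(sa$psi, Im(S))
  complex(real = fre(psi), imaginary = fim(psi))
}

#' Default scattering-angle grid
#'
#' Angle grid spanning \[0, factor * NA\] (default factor 1.5), dense enough
#' that spline interpolation error is far below the quadrature tolerance of
#' the amplitude integrals.
#'
#' @param config A [microscope_config] (only `na` is used) or a numeric NA.
#' @param n Number of grid points (>= 2048 by default).
#' @param factor Multiple of the numerical aperture to span.
#' @return Numeric vector of angles (rad).
#' @export
default_psi_grid <- function(config, n = 2048, factor = 1.5) {
  na <- if (inherits(config, "microscope_config")) config$na else config
  seq(0, factor * na, length.out = n)
}

mie_regime_check <- function(sample) {
  if (sample$x < 10) {
    warning("size parameter x < 10: scalar small-angle approximations are unreliable here")
  }
}

ada_regime_check <- function(sample) {
  lam <- sample$optics$wavelength
  if (2 * sample$a < 5 * lam || Mod(sample$optics$n - 1) > 0.1) {
    warning(paste("outside the anomalous-diffraction regime",
                  "(needs 2a >> lambda and |n - 1| << 1); computing anyway"))
  }
}

#' Mie scattering amplitudes
#'
#' Computes S1(psi), S2(psi) from the Mie series (vector spherical
#' harmonics), truncated at the Wiscombe criterion
#' n_max = ceiling(x + 4 x^(1/3) + 2). The logarithmic derivative is obtained
#' by downward recurrence; Riccati-Bessel functions by upward recurrence.
#'
#' @param sample A [sphere_sample].
#' @param psi Scattering-angle grid (rad), strictly increasing from 0;
#'   default [default_psi_grid()] needs a config, so `psi` is required here.
#' @return A [scattering_amplitude] with method `"mie"`.
#' @examples
#' s <- sphere_sample(diameter = 63.2)
#' sa <- mie_amplitudes(s, seq(0, 0.075, length.out = 512))
#' @export
mie_amplitudes <- function(sample, psi) {
  stopifnot(inherits(sample, "sphere_sample"))
  x <- sample$x
  m <- sample$optics$n
  if (!is.finite(x) || !all(is.finite(c(Re(m), Im(m))))) {
    stop("size parameter and refractive index must be finite")
  }
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  nmx <- max(nmax, ceiling(Mod(m * x))) + 16
  D <- complex(nmx + 1)
  mx <- m * x
  for (n in nmx:1) D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  an <- bn <- complex(nmax)
  ps_nm1 <- sin(x); ps_n <- sin(x) / x - cos(x)
  ch_nm1 <- cos(x); ch_n <- cos(x) / x + sin(x)
  for (n in seq_len(nmax)) {
    xi_n <- complex(real = ps_n, imaginary = -ch_n)
    xi_nm1 <- complex(real = ps_nm1, imaginary = -ch_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    an[n] <- (da * ps_n - ps_nm1) / (da * xi_n - xi_nm1)
    bn[n] <- (db * ps_n - ps_nm1) / (db * xi_n - xi_nm1)
    ps_np1 <- (2 * n + 1) / x * ps_n - ps_nm1
    ch_np1 <- (2 * n + 1) / x * ch_n - ch_nm1
    ps_nm1 <- ps_n; ps_n <- ps_np1
    ch_nm1 <- ch_n; ch_n <- ch_np1
  }
  if (any(!is.finite(c(Re(an), Im(an), Re(bn), Im(bn))))) {
    stop(sprintf("Mie series failed to converge (non-finite coefficients; x = %.3g, n_max = %d)",
                 x, nmax))
  }
  mu <- cos(psi)
  S1 <- S2 <- complex(length(psi))
  pi_nm1 <- rep(0, length(psi)); pi_n <- rep(1, length(psi))
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (an[n] * pi_n + bn[n] * tau_n)
    S2 <- S2 + fac * (an[n] * tau_n + bn[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n; pi_n <- pi_np1
  }
  out <- scattering_amplitude(psi, S1, S2, method = "mie")
  attr(out, "an") <- an
  attr(out, "bn") <- bn
  out
}

#' Mie extinction efficiency
#'
#' Extinction efficiency of the sphere, either from the coefficient sum
#' Q_ext = (2/x^2) sum (2n+1) Re(a_n + b_n), or from the forward amplitude
#' via the optical theorem Q_ext = (4/x^2) Re S(0). The two routes share the
#' Mie coefficients but sum them independently; their agreement is a
#' consistency check of the series summation.
#'
#' @param sample A [sphere_sample].
#' @param route `"series"` or `"forward"` (optical theorem).
#' @return Dimensionless extinction efficiency.
#' @export
mie_qext <- function(sample, route = c("series", "forward")) {
  route <- match.arg(route)
  sa <- mie_amplitudes(sample, c(0, 1e-4, 2e-4, 3e-4))
  x <- sample$x
  if (route == "forward") {
    4 / x^2 * Re(sa$S1[1])
  } else {
    an <- attr(sa, "an"); bn <- attr(sa, "bn")
    n <- seq_along(an)
    2 / x^2 * sum((2 * n + 1) * Re(an + bn))
  }
}

# shared integral core of the ADA/EA amplitudes:
#   S(psi) = k^2 int_0^a (1 - exp(i q sqrt(a^2 - xi^2))) J0(k xi psi) xi dxi
# with q = 2k(n-1) for ADA and q = k(n^2-1) for EA. Gauss-Legendre with
# doubling until the requested relative tolerance is met.
soft_sphere_amplitude <- function(sample, psi, q, rel_tol = 1e-8) {
  k <- sample$optics$k
  a <- sample$a
  eval_n <- function(ngl) {
    gl <- pracma::gaussLegendre(ngl, 0, a)
    xi <- gl$x; w <- gl$w
    ph <- 1 - exp(1i * q * sqrt(pmax(a^2 - xi^2, 0)))
    J <- outer(xi, psi, function(xi, p) besselJ(k * xi * p, 0))
    k^2 * colSums((w * xi * ph) * J)
  }
  ngl <- 128
  S <- eval_n(ngl)
  repeat {
    ngl <- ngl * 2
    S2 <- eval_n(ngl)
    sc <- max(Mod(S2))
    err <- if (sc == 0) 0 else max(Mod(S2 - S)) / sc
    S <- S2
    if (err < rel_tol) break
    if (ngl > 16384) stop("soft-sphere amplitude quadrature failed to converge")
  }
  S
}

#' Anomalous-diffraction amplitude
#'
#' Scalar small-angle amplitude of the sphere in the anomalous diffraction
#' approximation (ADA),
#' \deqn{S(\psi) = k^2 \int_0^a (1 - e^{2ik(n-1)\sqrt{a^2-\xi^2}}) J_0(k\xi\psi)\,\xi\,d\xi,}
#' valid when the sphere is much larger than the wavelength and |n - 1| << 1
#' (rays cross the sphere undeviated, accumulating only phase and
#' attenuation). Evaluated by adaptive Gauss-Legendre quadrature to a
#' relative tolerance of 1e-8.
#'
#' @param sample A [sphere_sample].
#' @param psi Angle grid (rad), strictly increasing from 0.
#' @param rel_tol Quadrature relative tolerance.
#' @return A [scattering_amplitude] with method `"ada"` (S1 = S2).
#' @export
ada_amplitude <- function(sample, psi, rel_tol = 1e-8) {
  stopifnot(inherits(sample, "sphere_sample"))
  ada_regime_check(sample)
  q <- 2 * sample$optics$k * (sample$optics$n - 1)
  S <- soft_sphere_amplitude(sample, psi, q, rel_tol)
  scattering_amplitude(psi, S, method = "ada")
}

#' Eikonal amplitude
#'
#' Same integral as [ada_amplitude()] but with the accumulated phase factor
#' (n^2 - 1) in place of 2(n - 1) - the small-angle limit of the parabolic
#' wave equation. For n close to 1 the two coincide to O(|n-1|/2) in the
#' exponent.
#'
#' @inheritParams ada_amplitude
#' @return A [scattering_amplitude] with method `"ea"`.
#' @export
ea_amplitude <- function(sample, psi, rel_tol = 1e-8) {
  stopifnot(inherits(sample, "sphere_sample"))
  ada_regime_check(sample)
  q <- sample$optics$k * (sample$optics$n^2 - 1)
  S <- soft_sphere_amplitude(sample, psi, q, rel_tol)
  scattering_amplitude(psi, S, method = "ea")
}

#' Closed-form forward ADA amplitude
#'
#' Analytic value of the ADA integral at psi = 0 (where J0 = 1), obtained by
#' the substitution u = sqrt(a^2 - xi^2):
#' S(0) = k^2 \[a^2/2 + (i a/rho) e^{i rho a} + (1 - e^{i rho a})/rho^2\]
#' with rho = 2k(n - 1). Used as an independent oracle for the quadrature.
#'
#' @param sample A [sphere_sample].
#' @return Complex forward amplitude.
#' @export
ada_forward_exact <- function(sample) {
  k <- sample$optics$k
  a <- sample$a
  rho <- 2 * k * (sample$optics$n - 1)
  k^2 * (a^2 / 2 + (1i * a / rho) * exp(1i * rho * a) +
           (1 - exp(1i * rho * a)) / rho^2)
}

#' Scattering angle for oblique illumination
#'
#' Geometric transform accounting for oblique plane-wave illumination: the
#' scattering angle psi at a zone-plate point (x', y') is the angle between
#' the incident propagation direction (polar `theta`, azimuth `phi`) and the
#' unit vector from the (axially displaced) sphere to that point. Positive
#' defocus `z` moves the sphere away from the zone plate, so the axial
#' sphere-to-zone-plate distance is R_f + z.
#'
#' @param theta,phi Incident polar and azimuthal angles (rad).
#' @param xp,yp Zone-plate point coordinates (nm), vectorised.
#' @param z Sphere defocus (nm).
#' @param config A [microscope_config].
#' @return Scattering angles psi (rad), same length as `xp`.
#' @export
oblique_map <- function(theta, phi, xp, yp, z, config) {
  stopifnot(inherits(config, "microscope_config"))
  if (abs(theta) >= pi / 2) stop("|theta| must be < pi/2")
  if (any(xp^2 + yp^2 > config$r_zp^2 * (1 + 1e-9))) {
    stop("zone-plate point outside the aperture")
  }
  zd <- config$R_f + z
  RM <- sqrt(xp^2 + yp^2 + zd^2)
  if (any(RM == 0)) stop("zone-plate point coincides with the sphere centre")
  ct <- cos(theta); st <- sin(theta)
  cospsi <- (st * cos(phi) * xp + st * sin(phi) * yp + ct * zd) / RM
  acos(pmin(pmax(cospsi, -1), 1))
}

#' Write a scattering amplitude to CSV
#'
#' Serializes the angle grid and complex amplitudes to a CSV with columns
#' psi_deg, Re_S1, Im_S1, Re_S2, Im_S2, method, for cross-tool comparison.
#'
#' @param sa A [scattering_amplitude].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(sa, path) {
  df <- data.frame(psi_deg = rad2deg(sa$psi),
                   Re_S1 = Re(sa$S1), Im_S1 = Im(sa$S1),
                   Re_S2 = Re(sa$S2), Im_S2 = Im(sa$S2),
                   method = sa$method)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a scattering amplitude from CSV
#'
#' @param path CSV produced by [write_amplitude_csv()].
#' @return A [scattering_amplitude].
#' @export
read_amplitude_csv <- function(path) {
  df <- utils::read.csv(path)
  scattering_amplitude(deg2rad(df$psi_deg),
                       complex(real = df$Re_S1, imaginary = df$Im_S1),
                       complex(real = df$Re_S2, imaginary = df$Im_S2),
                       method = as.character(df$method[1]))
}
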