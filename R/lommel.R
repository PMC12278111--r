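# Defocused circular-aperture integral
#
#   A(u, v) = int_0^1 J0(v p) exp(i u p^2 / 2) p dp
#
# is the kernel of every field propagated through the zone-plate aperture:
# u is the quadratic (defocus/Fresnel) phase across the aperture and v the
# dimensionless transverse frequency. Classically it is expressed through
# Lommel functions; here a rapidly convergent series valid for v < u is used
# (the operating regime of the plane-wave path, where u = k r_zp^2 / R_f),
# obtained by integrating the tail int_1^Inf by parts:
#
#   A = (i/u) exp(-i v^2/(2u)) + (e^{iu/2}/(iu)) sum_{m>=0} (-iv/u)^m J_m(v)
#
# The first ("geometric") term is the stationary-phase contribution, the sum
# the aperture-edge diffraction wave.

j0fast <- function(x) {
  # Bessel J0 with large-argument asymptotics; |error| < 1e-7 for x > 25
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- besselJ(x[!big], 0)
  if (any(big)) {
    xb <- x[big]
    xi <- xb - pi / 4
    x2 <- 1 / xb^2
    p0 <- 1 + x2 * (-9 / 128 + x2 * 3675 / 32768)
    q0 <- (-1 / 8 + x2 * 75 / 1024) / xb
    out[big] <- sqrt(2 / (pi * xb)) * (p0 * cos(xi) - q0 * sin(xi))
  }
  out
}

#' Defocused circular-aperture integral (series form)
#'
#' Evaluates \eqn{A(u,v) = \int_0^1 J_0(v\rho) e^{iu\rho^2/2} \rho\, d\rho}
#' by a convergent Lommel-type series (geometric term plus aperture-edge
#' series), valid for |v| < |u|. Vectorised over `v`.
#'
#' @param u Quadratic-phase parameter (real scalar, != 0).
#' @param v Transverse parameter(s), must satisfy max|v| <= 0.75 |u| (the
#'   edge series converges geometrically in v/u).
#' @param tol Series truncation tolerance.
#' @return Complex vector, one value per `v`.
#' @seealso [aperture_integral_quad()] for the brute-force quadrature oracle.
#' @export
aperture_integral <- function(u, v, tol = 1e-13) {
  stopifnot(length(u) == 1L, u != 0)
  if (max(abs(v)) > 0.75 * abs(u)) {
    stop("series form requires |v| <= 0.75 |u|; use aperture_integral_quad()")
  }
  geo <- (1i / u) * exp(-1i * v^2 / (2 * u))
  s <- complex(length(v))
  term_scale <- rep(1 + 0i, length(v))
  av <- abs(v)
  m <- 0
  repeat {
    # only elements whose geometric factor is still significant need the
    # Bessel term (avoids deep-underflow besselJ calls at high order)
    act <- Mod(term_scale) > tol
    if (m > 5 && !any(act)) break
    s[act] <- s[act] + term_scale[act] * besselJ(av[act], m)
    term_scale <- term_scale * (-1i * v / u)
    m <- m + 1
    if (m > 2000) stop("aperture-integral series did not converge")
  }
  geo + exp(1i * u / 2) / (1i * u) * s
}

#' Defocused circular-aperture integral (quadrature form)
#'
#' Direct Simpson quadrature of the same integral as [aperture_integral()],
#' used as an independent numerical backend. Refuses to run when the radial
#' sampling falls below the local-phase Nyquist bound (8 samples per 2 pi of
#' combined phase).
#'
#' @param u Quadratic-phase parameter.
#' @param v Transverse parameter(s).
#' @param n Number of Simpson panels (even); default chosen from the phase
#'   budget.
#' @return Complex vector, one value per `v`.
#' @export
aperture_integral_quad <- function(u, v, n = NULL) {
  phase_budget <- abs(u) / 2 + max(abs(v))
  n_min <- 2 * ceiling(8 * phase_budget / (2 * pi) / 2) + 2
  if (is.null(n)) n <- max(2 * n_min, 1024)
  if (n < n_min) {
    stop(sprintf(
      "radial sampling below the local-phase Nyquist bound: n = %d < %d needed for |u|/2 + v_max = %.3g rad",
      n, n_min, phase_budget))
  }
  rho <- seq(0, 1, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  e <- exp(1i * u * rho^2 / 2) * rho * w
  out <- vapply(v, function(vi) {
    z <- sum(j0fast(vi * rho) * e)
    c(Re(z), Im(z))
  }, numeric(2))
  complex(real = out[1, ], imaginary = out[2, ]) * (1 / n) / 3
}
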