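# Imaging chain: aperture integrals, camera fields, partially coherent
# stacks, PSF and the inc-BL comparison model.

cfg <- ref_config()
k_ref <- 2 * pi / cfg$wavelength
u_ref <- k_ref * cfg$r_zp^2 / cfg$R_f

test_that("the aperture-integral series matches brute-force quadrature", {
  # operating regime (large u) and a moderate case
  for (u in c(u_ref, 137.5)) {
    v <- seq(0, min(2700, 0.7 * u), length.out = 40)
    a_series <- aperture_integral(u, v)
    a_quad <- aperture_integral_quad(u, v, n = 2^17)
    expect_lt(max(Mod(a_series - a_quad)) / max(Mod(a_quad)), 1e-6)
  }
  # closed form at v = 0: (e^{iu/2} - 1) / (iu)
  for (u in c(3.7, 42, 5655)) {
    expect_equal(aperture_integral(u, 0), (exp(1i * u / 2) - 1) / (1i * u),
                 tolerance = 1e-12)
  }
  expect_error(aperture_integral(10, 9.9), "quad")
  expect_warning(aperture_integral(137.5, seq(0, 96, by = 8)), NA)
  expect_error(aperture_integral_quad(u_ref, 100, n = 64), "Nyquist")
})

test_that("plane-wave backends agree to 1e-3 in relative L2 on fields", {
  g <- small_grid(nx = 64)
  th <- deg2rad(cfg$theta_m)
  f1 <- pw_field(th, 0, 0, cfg, g, backend = "lommel")
  f2 <- pw_field(th, 0, 0, cfg, g, backend = "quad")
  l2 <- sqrt(sum(Mod(f1$field - f2$field)^2) / sum(Mod(f2$field)^2))
  expect_lt(l2, 1e-3)
})

test_that("the blank plane-wave background is flat after the azimuthal sum", {
  # single-field intensity carries percent-level aperture-edge Fresnel
  # ringing; the flat-fielded, azimuthally summed stack background is
  # uniform to much better than 1%
  g <- small_grid(nx = 96)
  th <- deg2rad(cfg$theta_m)
  pw <- pw_field(th, 0, 0, cfg, g)
  Ipw <- Mod(pw$field)^2
  expect_lt((max(Ipw) - min(Ipw)) / mean(Ipw), 0.15)
  s <- gold_sample()
  st <- pc_image(s, cfg, small_grid(nx = 128), n_fft = 512)
  m <- st$intensities[1, , ]
  xs <- (seq_len(128) - 65) * 5.5
  r <- sqrt(outer(xs^2, xs^2, "+"))
  bgvals <- m[r > 250 & r < 340]
  expect_lt(stats::sd(bgvals) / mean(bgvals), 0.01)
})

test_that("a uniform pupil gives the Airy pattern with the textbook zero", {
  g <- small_grid(nx = 64)
  sw <- sw_field(0, 0, 0, unit_amplitude(), cfg, g, n_fft = 2048)
  I <- Mod(sw$field)^2
  ctr <- 33
  prof <- I[ctr, ctr:64]
  i0 <- which(diff(prof) > 0)[1]
  r_zero <- (i0 - 1) * g$pixel_size
  expect_lt(abs(r_zero - 0.61 * cfg$wavelength / cfg$na), g$pixel_size)
  # peak at the centre
  expect_equal(which.max(I) , which(I == I[ctr, ctr]))
})

test_that("the FFT pupil transform matches a radial quadrature oracle", {
  # theta = 0 keeps the pupil radially symmetric, so the camera field is a
  # Hankel-type integral computable independently to high accuracy
  s <- gold_sample()
  g <- small_grid(nx = 64)
  z <- 2000
  sa <- ada_amplitude(s, seq(0, 0.08, length.out = 1024))
  sw <- sw_field(0, 0, z, sa, cfg, g, n_fft = 1024)
  gl <- pracma::gaussLegendre(2000, 0, cfg$r_zp)
  rho <- gl$x; w <- gl$w
  Srho <- interp_amplitude(sa, atan(rho / (cfg$R_f + z)))
  ph <- Srho * exp(-1i * k_ref * z * rho^2 / (2 * cfg$R_f^2)) * rho * w
  pref <- exp(1i * k_ref * z * (1 - cos(0))) * (1i / (k_ref * (cfg$R_f + z)))
  radial_ref <- function(r) {
    pref * 2 * pi * sum(ph * besselJ(k_ref * r * rho / cfg$R_f, 0))
  }
  ctr <- 33
  rads <- c(0, 5, 11, 17, 23, 29) # pixels along +x
  fft_vals <- sw$field[ctr, ctr + rads]
  ref_vals <- vapply(rads, function(p) radial_ref(p * g$pixel_size), complex(1))
  expect_lt(max(Mod(fft_vals - ref_vals)) / max(Mod(ref_vals)), 0.01)
})

test_that("defocus intensity is symmetric for a real scattering amplitude", {
  s0 <- gold_sample(delta = 0)   # pure absorber: S is real
  sa <- ada_amplitude(s0, seq(0, 0.08, length.out = 512))
  expect_lt(max(abs(Im(sa$S1))) / max(abs(Re(sa$S1))), 1e-12)
  g <- small_grid(nx = 48)
  z <- 1500
  Ip <- Mod(sw_field(0, 0, z, sa, cfg, g, n_fft = 512)$field)^2
  Im_ <- Mod(sw_field(0, 0, -z, sa, cfg, g, n_fft = 512)$field)^2
  # exact Hermitian symmetry of the pupil integral is broken only by the
  # spherical-wave prefactor and angle map, both of order z / R_f
  expect_lt(max(abs(Ip - Im_)) / max(Ip), 4 * z / cfg$R_f)
})

test_that("total_field keeps the interference term and checks contracts", {
  s <- gold_sample()
  g <- small_grid(nx = 64)
  th <- deg2rad(cfg$theta_m)
  sa <- ada_amplitude(s, seq(0, 0.08, length.out = 1024))
  pw <- pw_field(th, 0, 0, cfg, g)
  sw <- sw_field(th, 0, 0, sa, cfg, g, n_fft = 512)
  tot <- total_field(pw, sw)
  expect_equal(tot$provenance, "total")
  I_tot <- Mod(tot$field)^2
  I_sum <- Mod(pw$field)^2 + Mod(sw$field)^2
  # the cross-term is comparable to the object contrast itself
  expect_gt(max(abs(I_tot - I_sum)) / max(Mod(pw$field)^2), 0.1)
  # no sphere: total equals the plane wave
  s_none <- scattering_amplitude(seq(0, 0.08, length.out = 8),
                                 rep(0 + 0i, 8), method = "ada")
  sw0 <- sw_field(th, 0, 0, s_none, cfg, g, n_fft = 512)
  tot0 <- total_field(pw, sw0)
  expect_equal(tot0$field, pw$field)
  g2 <- small_grid(nx = 48)
  sw_bad <- sw_field(th, 0, 0, sa, cfg, g2, n_fft = 512)
  expect_error(total_field(pw, sw_bad), "mismatch")
  expect_error(total_field(sw, pw), "expects one plane-wave")
})

test_that("sw_field refuses undersampled defocus phase", {
  s <- gold_sample()
  sa <- ada_amplitude(s, seq(0, 0.08, length.out = 256))
  expect_error(sw_field(0, 0, 8e5, sa, cfg, small_grid(nx = 32), n_fft = 256),
               "Nyquist")
})

test_that("the untilted stack is rotationally symmetric by construction", {
  s <- gold_sample()
  st <- pc_image(s, cfg, small_grid(nx = 96), n_fft = 512)
  pl <- st$intensities[1, , ]
  # a radial function on a square grid is exactly invariant under the
  # dihedral symmetries of the grid
  expect_lt(max(abs(pl - t(pl))), 1e-12)
  # flips about the centre pixel (drop the unpaired first row/column of the
  # even-sized grid)
  core <- pl[2:96, 2:96]
  expect_lt(max(abs(core - core[95:1, ])), 1e-12)
  expect_lt(max(abs(core - core[, 95:1])), 1e-12)
  # azimuthal variation along a circle crossing the contrast-reversal rim
  xs <- (seq_len(96) - 49) * 5.5
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  vals <- vapply(ang, function(a) {
    xq <- 2 * s$a * cos(a); yq <- 2 * s$a * sin(a)
    ix <- findInterval(xq, xs); iy <- findInterval(yq, xs)
    tx <- (xq - xs[ix]) / 5.5; ty <- (yq - xs[iy]) / 5.5
    (1 - ty) * ((1 - tx) * pl[iy, ix] + tx * pl[iy, ix + 1]) +
      ty * ((1 - tx) * pl[iy + 1, ix] + tx * pl[iy + 1, ix + 1])
  }, numeric(1))
  expect_lt(stats::sd(vals) / mean(vals), 0.01)
  # the discrete rotation-sum path agrees with the radial-binning path
  st_rot <- pc_image(s, ref_config(p_phi = 10), small_grid(nx = 96), n_fft = 512)
  expect_lt(max(abs(st_rot$intensities - st$intensities)), 0.01)
})

test_that("larger coherence patches leave more ringing", {
  s <- gold_sample()
  g <- small_grid(nx = 96)
  ring <- vapply(c(1, 30, 90), function(pp) {
    cfgp <- ref_config(p_phi = pp)
    st <- pc_image(s, cfgp, g, n_fft = 512)
    xs <- (seq_len(96) - 49) * 5.5
    r <- sqrt(outer(xs^2, xs^2, "+"))
    stats::sd(st$intensities[1, , ][r > 2 * s$a & r < 5 * s$a])
  }, numeric(1))
  expect_true(all(diff(ring) > 0))
})

test_that("tilted condenser geometry has the right limits", {
  th <- deg2rad(1.005); om <- deg2rad(0.26)
  expect_equal(tilted_theta(seq(0, 2 * pi, length.out = 9), th, 0),
               rep(th, 9))
  expect_equal(tilted_theta(0, th, om), th + om, tolerance = 1e-9)
  expect_equal(tilted_theta(pi, th, om), th - om, tolerance = 1e-9)
  phis <- seq(0, 2 * pi, length.out = 721)[-721]
  expect_lt(abs(mean(tilted_theta(phis, th, om)) - th), om^2 / th)
  expect_error(tilted_theta(0, th, -0.1), "omega_tilt")
})

test_that("zero tilt reproduces the untilted model bit-identically", {
  s <- gold_sample()
  cfg10 <- ref_config(p_phi = 10)
  g <- small_grid(nx = 64, z_planes = c(-400, 0, 400))
  st_u <- pc_image(s, cfg10, g, n_fft = 512)
  st_t <- pc_image_tilted(s, cfg10, g, n_fft = 512)
  expect_identical(st_u$intensities, st_t$intensities)
})

test_that("tilting preserves the in-focus radial average", {
  s <- gold_sample()
  cfgT <- ref_config(omega_tilt = 0.26, p_phi = 4)
  g <- small_grid(nx = 96)
  st_t <- pc_image_tilted(s, cfgT, g, n_fft = 512)
  st_u <- pc_image(s, ref_config(p_phi = 4), g, n_fft = 512)
  pt <- radial_profile(st_t$intensities[1, , ], c(49, 49), 5.5, 5.5)
  pu <- radial_profile(st_u$intensities[1, , ], c(49, 49), 5.5, 5.5)
  ok <- !is.na(pt$intensity) & !is.na(pu$intensity) & pt$r < 220
  expect_lt(max(abs(pt$intensity[ok] - pu$intensity[ok])), 0.01)
})

test_that("the lens PSF has the classical lateral and axial structure", {
  r <- seq(0, 120, by = 1)
  h0 <- lens_psf3d(r, 0, cfg)
  i0 <- which(diff(h0) > 0)[1]
  expect_lt(abs(r[i0] - 0.61 * cfg$wavelength / cfg$na), 1.5)
  # first axial zero at 2 lambda / NA^2
  z0 <- 2 * cfg$wavelength / cfg$na^2
  expect_lt(lens_psf3d(0, z0, cfg) / lens_psf3d(0, 0, cfg), 1e-4)
  # slice energy: lateral integral = 1 (numerically, fine radial grid)
  rr <- seq(0, 3000, by = 0.5)
  for (z in c(0, 1000)) {
    h <- lens_psf3d(rr, z, cfg)
    expect_equal(2 * pi * pracma::trapz(rr, h * rr), 1, tolerance = 0.01)
  }
  # annular apodization elongates the axial profile
  zax <- seq(-2400, 2400, by = 100)
  fwhm <- function(h) {
    h <- h / max(h)
    diff(range(zax[h >= 0.5]))
  }
  hf <- vapply(zax, function(z) lens_psf3d(0, z, cfg, "full"), numeric(1))
  ha <- vapply(zax, function(z) lens_psf3d(0, z, cfg, "annular"), numeric(1))
  expect_gt(fwhm(ha) / fwhm(hf), 1)
  expect_error(lens_psf3d(0, 0, cfg, "annular", annulus = c(0.5, 1.2)), "annulus")
})

test_that("the inc-BL model reduces to Beer's law and to unity", {
  s0 <- gold_sample(delta = 0)
  g <- small_grid(nx = 96)
  # delta-function PSF: exact chord transmission up to the z' slicing
  std <- incbl_image(s0, cfg, g, psf = "delta", n_slices = 96)
  xs <- (seq_len(96) - 49) * 5.5
  r2 <- outer(xs^2, xs^2, "+")
  chord <- 2 * sqrt(pmax(s0$a^2 - r2, 0))
  I_beer <- exp(-2 * s0$optics$k * s0$optics$beta * chord)
  expect_lt(max(abs(std$intensities[1, , ] - I_beer)), 0.01)
  # integrated absorption agrees with the closed form much more tightly
  A_px <- sum(1 - std$intensities[1, , ]) * 5.5^2
  expect_equal(A_px, beer_absorption(s0, "closed"), tolerance = 5e-3)
  # no absorption: image identically one
  s_none <- gold_sample(delta = 0, beta = 0)
  stn <- incbl_image(s_none, cfg, g)
  expect_equal(max(abs(stn$intensities - 1)), 0)
  expect_warning(incbl_image(s0, cfg, camera_grid(nx = 16, pixel_size = 10,
                                                  z_planes = 0)),
                 "coarser")
})

test_that("the inc-BL image never exceeds the background", {
  s0 <- gold_sample(delta = 0)
  g <- camera_grid(nx = 96, pixel_size = 5.5, z_planes = c(-2000, 0, 2000))
  st <- incbl_image(s0, cfg, g)
  expect_lt(max(st$intensities), 1 + 1e-6)
})

test_that("the cosine-series zone plate focuses to an Airy pattern", {
  z1 <- zoneplate_airy_check(cfg, m_orders = 1, n_r = 60, n_rho = 2^14 + 1)
  # m = 1 convergent term alone is exactly the lens quadratic phase
  expect_lt(z1$max_rel_deviation, 1e-4)
  expect_equal(z1$first_zero_zp, z1$first_zero_airy)
})
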