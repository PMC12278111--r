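# The scattering module: Mie series against its small-angle limits.

cfg <- ref_config()
psi <- default_psi_grid(cfg, n = 600)

test_that("Mie, ADA and EA agree in the soft-X-ray gold regime", {
  for (a in c(30, 31.6, 32)) {
    s <- gold_sample(diameter = 2 * a)
    mie <- mie_amplitudes(s, psi)
    ada <- ada_amplitude(s, psi)
    ea <- ea_amplitude(s, psi)
    sc <- max(Mod(ada$S1))
    expect_lt(max(Mod(mie$S1 - ada$S1)) / sc, 0.02)
    expect_lt(max(Mod(mie$S1 - mie$S2)) / max(Mod(mie$S1)), 0.01)
    expect_lt(max(Mod(ada$S1 - ea$S1)) / sc, 0.005)
  }
})

test_that("ADA and EA diverge as the refractive contrast grows", {
  reldev <- function(delta) {
    s <- sphere_sample(diameter = 63.2,
                       optics = optical_constants(energy = 510,
                                                  delta = delta, beta = 0))
    ada <- suppressWarnings(ada_amplitude(s, psi))
    ea <- suppressWarnings(ea_amplitude(s, psi))
    max(Mod(ada$S1 - ea$S1)) / max(Mod(ada$S1))
  }
  expect_gt(reldev(0.1), reldev(0.01))
  expect_gt(reldev(0.01), reldev(0.001))
  # regime violation warns
  s_bad <- sphere_sample(diameter = 63.2,
                         optics = optical_constants(energy = 510,
                                                    delta = -0.1, beta = 0))
  expect_warning(ada_amplitude(s_bad, psi), "regime")
})

test_that("no refractive contrast means no scattering", {
  s1 <- sphere_sample(diameter = 63.2,
                      optics = optical_constants(energy = 510, delta = 0, beta = 0))
  ada <- ada_amplitude(s1, psi)
  expect_equal(max(Mod(ada$S1)), 0)
  mie <- mie_amplitudes(s1, psi)
  expect_lt(max(Mod(mie$S1)), 1e-8)
})

test_that("Mie recovers the Rayleigh small-particle limit", {
  m <- 1.5
  opt <- optical_constants(energy = 510, delta = 1 - m, beta = 0)
  a <- 0.01 / opt$k
  s <- suppressWarnings(sphere_sample(radius = a, optics = opt))
  mie <- mie_amplitudes(s, c(0, 0.01, 0.02, 0.03))
  x <- s$x
  # e^{+ikz} convention: forward amplitude -i x^3 (m^2-1)/(m^2+2)
  S0_ray <- -1i * x^3 * (m^2 - 1) / (m^2 + 2)
  expect_lt(Mod(mie$S1[1] - S0_ray) / Mod(S0_ray), 0.01)
})

test_that("the optical theorem is satisfied by the Mie backend", {
  s <- gold_sample()
  q1 <- mie_qext(s, "series")
  q2 <- mie_qext(s, "forward")
  expect_lt(abs(q1 - q2) / q1, 1e-6)
})

test_that("ADA forward amplitude matches its analytic antiderivative", {
  for (d in c(50, 63.2, 80)) {
    s <- gold_sample(diameter = d)
    ada <- ada_amplitude(s, c(0, 1e-3, 2e-3, 3e-3))
    exact <- ada_forward_exact(s)
    expect_lt(Mod(ada$S1[1] - exact) / Mod(exact), 1e-8)
  }
})

test_that("amplitude interpolation is cubic-accurate between grid points", {
  s <- gold_sample()
  sa <- ada_amplitude(s, psi)
  test_psi <- seq(1e-4, 0.07, length.out = 37)
  direct <- ada_amplitude(s, c(0, test_psi))$S1[-1]
  interp <- interp_amplitude(sa, test_psi)
  expect_lt(max(Mod(interp - direct)) / max(Mod(direct)), 1e-6)
  expect_error(interp_amplitude(sa, max(sa$psi) + 0.01), "outside")
})

test_that("scattering_amplitude validates its grid contract", {
  expect_error(scattering_amplitude(c(0.01, 0.02, 0.03, 0.04), rep(1+0i, 4)),
               "start at psi = 0")
  expect_error(scattering_amplitude(c(0, 0.02, 0.02, 0.04), rep(1+0i, 4)),
               "strictly increasing")
})

test_that("oblique geometry maps illumination directions to scattering angles", {
  cfg <- ref_config()
  # on-axis illumination, on-axis point
  expect_equal(oblique_map(0, 0, 0, 0, 0, cfg), 0)
  # on-axis illumination, aperture edge
  expect_equal(oblique_map(0, 0, cfg$r_zp, 0, 0, cfg),
               atan(cfg$r_zp / cfg$R_f), tolerance = 1e-12)
  # oblique: edge points along and against the illumination azimuth differ
  # by about 2 theta for small angles
  th <- deg2rad(1.005)
  p1 <- oblique_map(th, 0, cfg$r_zp, 0, 0, cfg)
  p2 <- oblique_map(th, 0, -cfg$r_zp, 0, 0, cfg)
  expect_equal(p2 - p1, 2 * th, tolerance = 1e-4)
  # continuity in defocus
  expect_equal(oblique_map(th, 0, 1e4, 2e4, 0, cfg),
               oblique_map(th, 0, 1e4, 2e4, 1e-3, cfg), tolerance = 1e-9)
  expect_error(oblique_map(1.6, 0, 0, 0, 0, cfg), "theta")
  expect_error(oblique_map(0, 0, 2 * cfg$r_zp, 0, 0, cfg), "outside the aperture")
})

test_that("amplitude tables round-trip through CSV", {
  s <- gold_sample()
  sa <- ada_amplitude(s, seq(0, 0.05, length.out = 64))
  f <- withr::local_tempfile(fileext = ".csv")
  write_amplitude_csv(sa, f)
  back <- read_amplitude_csv(f)
  expect_equal(back$psi, sa$psi, tolerance = 1e-12)
  expect_equal(back$S1, sa$S1, tolerance = 1e-12)
  expect_equal(back$method, "ada")
})
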