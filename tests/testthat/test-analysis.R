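# Analysis module: best focus, radial profiles, absorption vs Beer's law.

test_that("find_best_focus returns the argmin voxel with tie-breaking", {
  arr <- array(1, c(12, 20, 24))
  arr[7, 10, 11] <- 0
  st <- image_stack(arr, c(40, 5.5, 5.5), normalization = "background_one")
  f <- find_best_focus(st)
  expect_equal(f$z_index, 7)
  expect_equal(unname(f$center), c(10, 11))
  expect_equal(f$value, 0)
  # ties: earliest z, then y, then x
  arr[3, 15, 2] <- 0
  st2 <- image_stack(arr, c(40, 5.5, 5.5), normalization = "background_one")
  expect_equal(find_best_focus(st2)$z_index, 3)
  # flat stack: no object
  ones <- image_stack(array(1, c(5, 16, 16)), c(40, 5.5, 5.5),
                      normalization = "background_one")
  expect_error(find_best_focus(ones), "no object")
  # raw stacks are refused
  expect_error(find_best_focus(image_stack(arr, c(40, 5.5, 5.5))),
               "background-normalized")
})

test_that("radial_profile reproduces constants and the Airy pattern", {
  cmat <- matrix(3.7, 41, 41)
  p <- radial_profile(cmat, c(21, 21), 5.5, 5.5)
  expect_true(all(abs(p$intensity[!is.na(p$intensity)] - 3.7) < 1e-12))
  # analytic Airy plane sampled on a fine grid
  n <- 257; px <- 1
  xs <- (seq_len(n) - 129) * px
  v <- 0.3 * sqrt(outer(xs^2, xs^2, "+"))
  airy <- ifelse(v < 1e-9, 1, (2 * besselJ(v, 1) / v)^2)
  p2 <- radial_profile(airy, c(129, 129), 2, px)
  ok <- which(!is.na(p2$intensity) & p2$r < 60 & p2$r > 1)
  v_ok <- 0.3 * p2$r[ok]
  expect_lt(max(abs(p2$intensity[ok] - (2 * besselJ(v_ok, 1) / v_ok)^2)), 0.01)
  expect_error(radial_profile(cmat, c(50, 21), 5.5, 5.5), "inside")
  expect_error(radial_profile(cmat, c(21, 21), 0, 5.5), "bin_width")
  # far-off centre leaves inner bins empty -> NA, not zero
  p3 <- radial_profile(cmat, c(1, 1), 2, 5.5)
  expect_true(any(is.na(p3$intensity)))
})

test_that("absorption integrals have their closed-form limits", {
  r <- seq(0.05, 300, by = 0.1)
  # I == 1 -> A == 0
  A0 <- absorption_from_profile(analytic_profile(r, rep(1, length(r))),
                                c(100, 200))
  expect_equal(A0$values, c(0, 0))
  # opaque disk of radius a -> pi a^2
  a <- 31.6
  Ad <- absorption_from_profile(analytic_profile(r, as.numeric(r >= a)),
                                c(50, 150, 250))
  expect_equal(Ad$values, rep(pi * a^2, 3), tolerance = 0.01)
  # Beer chord profile -> closed-form Eq. absorption within 0.5%
  s <- gold_sample(delta = 0)
  chord <- 2 * sqrt(pmax(a^2 - r^2, 0))
  I_beer <- exp(-2 * s$optics$k * s$optics$beta * chord)
  Ab <- absorption_from_profile(analytic_profile(r, I_beer),
                                seq(3 * a, 8 * a, length.out = 8))
  expect_lt(abs(Ab$mean / beer_absorption(s, "closed") - 1), 0.005)
  expect_lt(Ab$sd / Ab$mean, 1e-10)  # profile is exactly 1 beyond the sphere
  # A(r_end) non-decreasing while I <= 1
  expect_true(all(diff(Ab$values) >= 0))
  expect_error(absorption_from_profile(analytic_profile(r, I_beer), 500),
               "beyond the last")
})

test_that("beer_absorption matches its antiderivative and is monotone", {
  s <- sphere_sample(radius = 31.6,
                     optics = optical_constants(energy = 510,
                                                delta = 3.6e-3, beta = 2.6e-3))
  q <- beer_absorption(s, "quadrature")
  cf <- beer_absorption(s, "closed")
  expect_lt(abs(q - cf) / cf, 1e-10)
  # limits
  expect_equal(beer_absorption(gold_sample(beta = 0)), 0)
  dark <- gold_sample(beta = 10)
  expect_equal(beer_absorption(dark, "closed"), pi * dark$a^2, tolerance = 1e-3)
  # strictly increasing in a and in beta, bounded by pi a^2
  Aa <- vapply(c(20, 30, 40), function(a) {
    beer_absorption(sphere_sample(radius = a, optics = s$optics), "closed")
  }, numeric(1))
  expect_true(all(diff(Aa) > 0))
  Ab <- vapply(c(1e-3, 2e-3, 4e-3), function(b) {
    beer_absorption(gold_sample(beta = b), "closed")
  }, numeric(1))
  expect_true(all(diff(Ab) > 0))
  expect_true(all(Ab < pi * gold_sample()$a^2))
})

test_that("axial_asymmetry distinguishes phase objects from pure absorbers", {
  # synthetic stacks with known symmetry
  z <- c(-2, -1, 0, 1, 2)
  base <- array(1, c(5, 9, 9))
  sym <- base; sym[, 5, 5] <- c(0.8, 0.5, 0.2, 0.5, 0.8)
  st_sym <- image_stack(sym, c(1, 1, 1), "background_one", z_planes = z)
  expect_equal(axial_asymmetry(st_sym), 0)
  asym <- base; asym[, 5, 5] <- c(1.2, 1.1, 0.2, 0.5, 0.8)
  st_asym <- image_stack(asym, c(1, 1, 1), "background_one", z_planes = z)
  expect_gt(axial_asymmetry(st_asym), 0.3)
  bad <- image_stack(sym, c(1, 1, 1), "background_one", z_planes = 1:5)
  expect_error(axial_asymmetry(bad), "symmetric")
})

test_that("a pure-phase sphere yields an undefined Beer ratio", {
  s_phase <- gold_sample(beta = 0)   # delta only
  cfg <- ref_config()
  g <- camera_grid(nx = 96, pixel_size = 5.5, z_planes = seq(-600, 600, 300))
  cmp <- compare_model_vs_beer(s_phase, cfg, g, n_fft = 512)
  expect_true(is.na(cmp$ratio))
  expect_match(cmp$note, "pure-phase")
  expect_equal(cmp$A_beer, 0)
  # the measured pseudo-absorption of the phase object is small
  expect_lt(abs(cmp$A_model$mean), 0.25 * pi * s_phase$a^2)
})
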