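test_that("double-slit oracle: central maximum, interference and envelope nulls", {
  lam <- 0.488
  spec <- slit_pair_spec(slit_width = 10 * lam, separation = 80 * lam,
                         screen_distance = 1e4 * lam, screen_extent = 1000)
  expect_equal(double_slit_intensity(0, spec, lam), 1)
  # first interference null: smallest x > 0 with k d x / (2 sqrt(L^2+x^2)) = pi/2,
  # found by an independent root search on the exact argument
  k <- 2 * pi / lam
  d <- spec$separation; L <- spec$screen_distance
  x_null <- stats::uniroot(function(x) k * d * x / (2 * sqrt(L^2 + x^2)) - pi / 2,
                           c(1, 100))$root
  expect_equal(x_null, 30.5, tolerance = 0.01)  # ~ lambda L / (2 d) = 62.5 lambda
  expect_lt(double_slit_intensity(x_null, spec, lam), 1e-6)
  # envelope null where k b x / sqrt(L^2+x^2) = pi
  b <- spec$slit_width / 2
  x_env <- stats::uniroot(function(x) k * b * x / sqrt(L^2 + x^2) - pi,
                          c(100, 2000))$root
  expect_lt(double_slit_intensity(x_env, spec, lam), 1e-6)
})

test_that("Fresnel number classifies diffraction regimes", {
  # F = 1 at l^2 = lambda r0
  expect_equal(fresnel_number(100, 0.5, 100^2 / 0.5)$F, 1)
  fn <- fresnel_number("100 um", "351 nm", "28.49 mm")
  expect_equal(fn$F, 100^2 / (0.351 * 28490))  # barely above unity
  expect_equal(fn$regime, "fresnel")
  # doubling the distance halves F
  expect_equal(fresnel_number(100, 0.351, 2e4)$F,
               fresnel_number(100, 0.351, 4e4)$F * 2)
})

test_that("square-aperture Fresnel solution: symmetry, Fraunhofer limit, quadrature", {
  lam <- 0.351
  # Fraunhofer limit: at F = 0.01 the normalized pattern matches sinc^2 within 1%
  side <- 100
  r0 <- side^2 / (lam * 0.01)
  spec <- square_aperture_spec(side, r0)
  x <- seq(0, 2 * lam * r0 / side, length.out = 40)
  k <- 2 * pi / lam
  fresnel <- square_aperture_intensity(x, 0, spec, lam)
  fraun <- sinc(k * side * x / (2 * r0))^2
  expect_equal(fresnel, fraun, tolerance = 0.01)
  # symmetry in x <-> -x and x <-> y
  spec2 <- square_aperture_spec(side, side^2 / (lam * 2))
  expect_equal(square_aperture_intensity(37, 11, spec2, lam),
               square_aperture_intensity(-37, 11, spec2, lam))
  expect_equal(square_aperture_intensity(37, 11, spec2, lam),
               square_aperture_intensity(11, 37, spec2, lam))
  # on-axis values vs brute-force 2-D quadrature of the Huygens integral
  for (F in c(0.5, 2)) {
    r0 <- side^2 / (lam * F)
    spec3 <- square_aperture_spec(side, r0)
    q <- vapply(c(0, 20, 45), function(xx)
      square_aperture_quadrature(xx, 0, side, lam, r0), numeric(1))
    a <- square_aperture_intensity(c(0, 20, 45), 0, spec3, lam,
                                   normalized = FALSE)
    expect_equal(a / a[1], q / q[1], tolerance = 0.005)
  }
})

test_that("Gaussian beam relations", {
  expect_equal(gaussian_waist(0, 5, 0.488), 5)
  zr <- rayleigh_range(5, 0.488)
  expect_equal(gaussian_waist(zr, 5, 0.488), 5 * sqrt(2))
  expect_equal(focused_waist(0.488, 9933.06, 500),
               2 * 0.488 * 9933.06 / (pi * 500))
})

test_that("Bessel profile and core metrics", {
  expect_equal(bessel_profile(0, 0.5), 1)
  kz <- kappa_for_metric("first_zero")
  expect_lt(abs(besselJ(kz, 0)), 1e-10)
  expect_equal(kz, 2.4048, tolerance = 1e-4)
  ke <- kappa_for_metric("e2")
  # solves J0^2(kappa) = e^-2 to machine-level precision; 1.75 to 3 s.f.
  expect_lt(abs(besselJ(ke, 0)^2 - exp(-2)), 1e-12)
  expect_equal(signif(ke, 3), 1.75)
  # first zero of the profile sits at kappa_first_zero / k_r
  kr <- 0.52
  expect_lt(bessel_profile(kz / kr, kr), 1e-10)
})

test_that("Bessel core radius and matched axicon angle", {
  expect_equal(bessel_core_radius(1e-12, 0.488, 0.04), 0, tolerance = 1e-10)
  # halving sin(beta) doubles r0
  b1 <- 0.02
  b2 <- asin(sin(b1) / 2)
  expect_equal(bessel_core_radius(1.75, 0.488, b2),
               2 * bessel_core_radius(1.75, 0.488, b1))
  # kappa = 1.75, lambda = 488 nm, beta = (1.4631-1) * 5 deg
  beta <- (1.4631 - 1) * 5 * pi / 180
  expect_equal(bessel_core_radius(1.75, 0.488, beta), 3.36, tolerance = 0.01)
  # matched angle: D -> 0 gives alpha -> 0; printed-geometry value ~ 5.45 deg
  expect_lt(matched_axicon_angle(1.4631, 1e-6, 9930), 1e-9)
  a <- matched_axicon_angle(1.4631, 1000, 9930)
  expect_equal(a * 180 / pi, 5.45, tolerance = 0.01)
  expect_error(matched_axicon_angle(1.4631, 4e4, 9930), "no physical axicon")
  # round trip of the matching relation: r0(kappa=1.75) / w0 = 1 +- 0.005
  f <- 9933.06; D <- 500
  alpha <- matched_axicon_angle(1.4631, D, f)
  r0 <- bessel_core_radius(1.75, 0.488, (1.4631 - 1) * alpha)
  w0 <- focused_waist(0.488, f, D)
  expect_equal(r0 / w0, 1, tolerance = 0.005)
})

test_that("axicon deflection: exact Snell within 1% of small-angle form", {
  b_exact <- axicon_deflection("5 deg", 1.4631, "exact")
  b_small <- axicon_deflection("5 deg", 1.4631, "small_angle")
  expect_equal(b_exact, b_small, tolerance = 0.01)
  expect_equal(axicon_deflection(0.05, 1.5, "phase"),
               asin(0.5 * tan(0.05)))
})

test_that("Intralipid dilution reproduces the published table exactly", {
  v <- c(0, 2, 4, 6, 8)
  d <- intralipid_dilution(v, 500, scaling = "table")
  expect_equal(round(d$volume_pct, 5),
                   c(0, 0.39841, 0.79365, 1.18577, 1.5748))
  expect_equal(round(d$mu_s_m, 2), c(0, 557.14, 1114.28, 1671.42, 2228.56))
  expect_equal(round(d$particle_pct, 4), c(0, 0.0908, 0.1816, 0.2724, 0.3632))
  # physical volume-fraction scaling is linear in concentration, not volume
  dv <- intralipid_dilution(8, 500, scaling = "volume_fraction")
  expect_equal(dv$mu_s_m, 557.14 * (8 / 508) / (2 / 502), tolerance = 1e-10)
  expect_lt(dv$mu_s_m, 2228.56)  # the table overstates the 8 uL row slightly
  expect_error(intralipid_dilution(-1, 500), "non-negative")
})
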