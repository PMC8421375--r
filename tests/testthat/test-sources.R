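test_that("packet amplitude normalizes beam power over N packets", {
  beam0 <- beam_spec(0.488, power = 0, profile = "gaussian", e2_width = 100)
  expect_equal(initial_amplitude(beam0, 100), 0)
  # P = 1 mW, A = 1 mm^2, N = 1 -> E0 = sqrt(1e-3 W / 1e6 um^2)
  beam1 <- beam_spec(0.488, power = "1 mW", profile = "gaussian",
                     e2_width = 100, area = 1e6)
  expect_equal(initial_amplitude(beam1, 1), sqrt(1e-3 / 1e6))
  # N in-phase packets in one bin of area A accumulate intensity P / A
  n <- 250
  e0 <- initial_amplitude(beam1, n)
  acc <- make_field_accumulator(c(1L, 1L), bin_size = 1)
  accumulate(acc, x = rep(0, n), y = rep(0, n), opl = rep(0, n),
             amplitude = e0, wavelength = 0.488)
  expect_equal(as.numeric(to_intensity(acc, "raw")$values),
               beam1$power / beam1$area, tolerance = 1e-12)
  expect_error(initial_amplitude(beam_spec(0.5, profile = "plane"), 10),
               "area")
})

test_that("double-slit launches sample the slit areas uniformly", {
  lam <- 0.488
  spec <- slit_pair_spec(10 * lam, 80 * lam, 1e4 * lam, 1000)
  beam <- beam_spec(lam, profile = "plane")
  set.seed(1)
  n <- 1e5
  p <- sample_slit_pair(spec, beam, n)
  b <- spec$slit_width / 2
  left <- abs(p$x + spec$separation / 2) <= b + 1e-9
  right <- abs(p$x - spec$separation / 2) <= b + 1e-9
  # every position inside one slit
  expect_true(all(left | right))
  # slit choice is symmetric: fraction 0.5 within 3 sigma binomial
  expect_lt(abs(mean(left) - 0.5), 3 * sqrt(0.25 / n))
  # within-slit positions uniform (KS test at alpha = 0.01)
  u <- (p$x[left] + spec$separation / 2 + b) / (2 * b)
  expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)
  # all directions forward
  expect_true(all(p$uz > 0))
})

test_that("square-aperture launches are centred and seed-contractual", {
  spec <- square_aperture_spec(100, 28490)
  beam <- beam_spec(0.351, profile = "plane")
  target <- list(z = spec$screen_distance, xlim = c(-500, 500),
                 ylim = c(-500, 500))
  n <- 1e5
  set.seed(2); p1 <- sample_square_aperture(spec, beam, n, target)
  # empirical mean at the aperture centre within 3 sigma
  se <- (spec$side / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(p1$x)), 3 * se)
  expect_lt(abs(mean(p1$y)), 3 * se)
  # different seeds: different streams, same summary statistics within MC error
  set.seed(3); p2 <- sample_square_aperture(spec, beam, n, target)
  expect_false(identical(p1$x, p2$x))
  expect_lt(abs(mean(p1$x) - mean(p2$x)), 6 * se)
  expect_lt(abs(stats::sd(p1$x) - stats::sd(p2$x)), 6 * se)
})

test_that("Huygens directions are unit-norm, forward, and land uniformly", {
  set.seed(4)
  n <- 1e5
  org <- cbind(stats::runif(n, -2, 2), stats::runif(n, -2, 2), 0)
  target <- list(z = 5000, xlim = c(-300, 200), ylim = c(100, 400))
  d <- sample_huygens_direction(org, target, n)
  expect_lt(max(abs(d$ux^2 + d$uy^2 + d$uz^2 - 1)), 1e-12)
  expect_true(all(d$uz > 0))
  # straight-line flights land uniformly over the target rectangle
  lx <- org[, 1] + d$ux / d$uz * (target$z - org[, 3])
  ly <- org[, 2] + d$uy / d$uz * (target$z - org[, 3])
  expect_gt(suppressWarnings(
    stats::ks.test((lx - target$xlim[1]) / diff(target$xlim),
                   "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test((ly - target$ylim[1]) / diff(target$ylim),
                   "punif"))$p.value, 0.01)
  expect_error(sample_huygens_direction(c(0, 0, 5000),
                                        list(z = 5000, xlim = c(-1, 1),
                                             ylim = c(-1, 1))),
               "target plane")
})

test_that("plano-convex trace: axial ray, paraxial focus, aperture misses", {
  lens <- la4249_lens()
  on_axis <- trace_planoconvex(0, 0, lens)
  expect_equal(on_axis$z, 0)
  expect_equal(on_axis$opl, lens$n_lens * lens$thickness)
  expect_equal(c(on_axis$ux, on_axis$uy, on_axis$uz), c(0, 0, 1))
  # paraxial bundle: straight-line continuations cross the axis at
  # f = roc / (n - 1) within 1%
  h <- c(30, 60, 100)
  tr <- trace_planoconvex(h, rep(0, 3), lens)
  z_cross <- tr$z - tr$x / tr$ux * tr$uz
  expect_equal(z_cross, rep(lens$focal_length, 3), tolerance = 0.01)
  # rays beyond the usable aperture are flagged
  miss <- trace_planoconvex(lens$radius + 10, 0, lens)
  expect_false(miss$ok)
})

test_that("axicon trace: Snell deflection, apex convention, azimuthal symmetry", {
  ax <- axicon_spec("5 deg", "12.7 mm", 1.4631)
  tr <- trace_axicon(2000, 0, ax)
  beta <- acos(tr$uz)
  expect_equal(beta, (1.4631 - 1) * ax$alpha, tolerance = 0.01)
  expect_equal(beta, axicon_deflection(ax$alpha, 1.4631, "exact"),
               tolerance = 1e-10)
  # deflection is toward the axis
  expect_lt(tr$ux, 0)
  # apex ray is undeviated
  apex <- trace_axicon(0, 0, ax)
  expect_equal(c(apex$ux, apex$uy, apex$uz), c(0, 0, 1))
  # ring of rays: same exit radius and optical path at every azimuth
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- trace_axicon(800 * cos(th), 800 * sin(th), ax)
  expect_equal(sqrt(ring$x^2 + ring$y^2), rep(800, 8), tolerance = 1e-9)
  expect_lt(diff(range(ring$opl)), 1e-9)
  expect_lt(diff(range(ring$z)), 1e-9)
})

test_that("helical delay adds an azimuthal phase ramp", {
  ax0 <- axicon_spec("5 deg", "12.7 mm", 1.4631, helical_order = 0L)
  ax1 <- axicon_spec("5 deg", "12.7 mm", 1.4631, helical_order = 1L)
  lam <- 0.488
  expect_equal(apply_helical_delay(10, 3, 4, ax0, lam), 10)
  # order 1 at azimuth pi: phase increment pi, i.e. opl increment lambda/2
  d <- apply_helical_delay(0, -5, 0, ax1, lam)
  expect_equal(d, lam / 2)
  # increments stay within one helical period
  set.seed(8)
  xs <- stats::rnorm(100); ys <- stats::rnorm(100)
  inc <- apply_helical_delay(0, xs, ys, ax1, lam)
  expect_true(all(inc >= 0 & inc < lam))
})

test_that("first-order helical axicon produces an on-axis vortex null", {
  cfg <- fig_bessel_axicon(n_packets = 2e6, seed = 6, helical_order = 1L)
  res <- run_experiment(cfg)
  rp <- radial_profile(res$image)
  core <- rp$intensity[rp$r < 2]
  first_ring <- max(rp$intensity[rp$r > 2 & rp$r < 12])
  # the centre is a local minimum (vortex), well below the first bright ring
  expect_lt(mean(core), 0.5 * first_ring)
})

test_that("gaussian launch positions follow the amplitude profile", {
  beam <- la_beam()
  set.seed(9)
  pos <- sample_beam_positions(beam, radius = 5000, n = 2e5)
  w <- beam$e2_width / 2
  # density exp(-r^2/w^2) has per-axis sd w/sqrt(2)
  expect_equal(stats::sd(pos$x), w / sqrt(2), tolerance = 0.01)
  expect_equal(stats::sd(pos$y), w / sqrt(2), tolerance = 0.01)
  # truncation respects the aperture
  pos2 <- sample_beam_positions(beam, radius = 100, n = 1e4)
  expect_true(all(pos2$x^2 + pos2$y^2 <= 100^2))
})
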