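test_that("free path sampling is exponential with mean 1/mu_t", {
  set.seed(10)
  s <- sample_free_path(1, 1e6)      # mu_t = 1 mm^-1
  expect_equal(mean(s), 1000, tolerance = 0.003)
  # the 2 uL dilution row: mu_s = 557.14 m^-1 -> mean free path ~ 1.795 mm
  mu <- intralipid_dilution(2, 500, scaling = "table")$mu_s_mm
  s2 <- sample_free_path(mu, 1e6)
  expect_equal(mean(s2), 1e3 / 0.55714, tolerance = 0.005)
  expect_true(all(s >= 0))
  expect_true(all(is.infinite(sample_free_path(0, 10))))
  expect_error(sample_free_path(-1), "non-negative")
})

test_that("Henyey-Greenstein scattering has mean cosine g and unit outputs", {
  set.seed(11)
  n <- 1e6
  u0 <- list(ux = rep(0, n), uy = rep(0, n), uz = rep(1, n))
  iso <- scatter_direction(u0$ux, u0$uy, u0$uz, g = 0)
  expect_lt(abs(mean(iso$uz)), 3 / sqrt(3 * n))  # sd of cos is 1/sqrt(3)
  hg <- scatter_direction(u0$ux, u0$uy, u0$uz, g = 0.82)
  expect_equal(mean(hg$uz), 0.82, tolerance = 0.002)
  expect_lt(max(abs(hg$ux^2 + hg$uy^2 + hg$uz^2 - 1)), 1e-12)
  # tilted incoming direction: deflection cosine relative to it still = g
  set.seed(12)
  v <- c(1, 2, -0.5) / sqrt(sum(c(1, 2, -0.5)^2))
  hg2 <- scatter_direction(rep(v[1], n), rep(v[2], n), rep(v[3], n), g = 0.6)
  mu <- hg2$ux * v[1] + hg2$uy * v[2] + hg2$uz * v[3]
  expect_equal(mean(mu), 0.6, tolerance = 0.003)
})

test_that("advance moves packets and accrues optical path with the medium index", {
  p <- packets(0, 0, 0, 1, 0, 1, wavelength = 0.488)
  p0 <- advance(p, 0)
  expect_identical(p0$x, p$x)
  expect_identical(p0$opl, p$opl)
  # n = 1.33 over a distance lambda/1.33 adds exactly one wavelength of path
  p1 <- advance(p, 0.488 / 1.33, n_medium = 1.33)
  expect_equal(p1$opl, 0.488, tolerance = 1e-12)
  ph <- 2 * pi * p1$opl / 0.488
  expect_equal(ph %% (2 * pi), 0, tolerance = 1e-9)
  # two successive advances equal one combined advance
  pa <- advance(advance(p, 10, 1.33), 5, 1.33)
  pb <- advance(p, 15, 1.33)
  expect_equal(pa$x, pb$x)
  expect_equal(pa$opl, pb$opl)
})

test_that("ballistic slab traversal exits the far face with exact path", {
  slab <- medium_slab(c(2000, 2000, 2000), c(2000, 2000, 2000),
                      water_props(mu_s = 0))
  # oblique entry: opl = n t / cos(theta)
  ct <- cos(0.2)
  p <- packets(0, 0, 0, sin(0.2), 0, ct, wavelength = 0.488)
  out <- propagate_in_medium(p, slab)
  expect_equal(out$packets$status, PACKET_DETECTED)
  expect_equal(out$packets$z, 2000)
  expect_equal(out$packets$opl, 1.33 * 2000 / ct, tolerance = 1e-9)
  expect_equal(out$packets$x, 2000 * tan(0.2), tolerance = 1e-9)
  expect_equal(out$events, 0L)
})

test_that("ballistic attenuation matches Beer-Lambert over several optical depths", {
  n <- 2e5
  for (od in c(0.5, 1, 2)) {
    mu_s <- od / 2  # slab thickness 2 mm
    slab <- medium_slab(c(4000, 4000, 2000), c(4000, 4000, 2000),
                        water_props(mu_s = mu_s))
    set.seed(100 + round(10 * od))
    p <- packets(rep(0, n), rep(0, n), rep(0, n),
                 rep(0, n), rep(0, n), rep(1, n), wavelength = 0.488)
    out <- propagate_in_medium(p, slab)
    unscattered <- mean(out$events == 0)
    p_ball <- exp(-od)
    expect_lt(abs(unscattered - p_ball),
              3 * sqrt(p_ball * (1 - p_ball) / n))
    # packet conservation: every packet ends in exactly one terminal state
    expect_equal(out$n_detected + out$n_discarded + out$n_absorbed, n)
    expect_true(all(out$packets$status != PACKET_IN_FLIGHT))
  }
})

test_that("steps crossing a lateral face are clipped and discarded", {
  slab <- medium_slab(c(100, 100, 5000), c(100, 100, 5000),
                      water_props(mu_s = 0))
  # aimed at the side wall
  p <- packets(0, 0, 0, 0.9, 0, sqrt(1 - 0.81), wavelength = 0.488)
  out <- propagate_in_medium(p, slab)
  expect_equal(out$packets$status, PACKET_DISCARDED)
  expect_equal(out$packets$x, 50)           # clipped exactly to the face
  expect_lt(out$packets$z, 5000)
})

test_that("absorption terminates packets with probability mu_a/mu_t", {
  slab <- medium_slab(c(1e5, 1e5, 1e4), c(1e5, 1e5, 1e4),
                      optical_properties(mu_s = 1, mu_a = 1, g = 0, n = 1))
  n <- 2e4
  set.seed(14)
  p <- packets(rep(0, n), rep(0, n), rep(0, n),
               rep(0, n), rep(0, n), rep(1, n), wavelength = 0.488)
  out <- propagate_in_medium(p, slab)
  expect_gt(out$n_absorbed, 0)
  expect_equal(out$n_detected + out$n_discarded + out$n_absorbed, n)
})

test_that("ballistic phase equivalence: a non-scattering slab shifts paths by ~(n-1)t", {
  # propagate a diverging paraxial bundle through a mu_s = 0 water slab:
  # exit points continue the straight lines exactly, and every optical path
  # exceeds the geometric one by (n-1) * t up to the O(theta^2) obliquity
  # correction, so the coherent image is the free-space image
  lam <- 0.488
  t_slab <- 1000
  slab <- medium_slab(c(4000, 4000, t_slab), c(4000, 4000, t_slab),
                      water_props(mu_s = 0))
  set.seed(15)
  n <- 3000
  x0 <- stats::runif(n, -10, 10)
  th <- stats::runif(n, -0.005, 0.005)  # paraxial divergence
  p <- packets(x0, rep(0, n), rep(0, n),
               sin(th), rep(0, n), cos(th), wavelength = lam)
  out <- propagate_in_medium(p, slab)
  expect_true(all(out$packets$status == PACKET_DETECTED))
  # straight-line exit points
  expect_equal(out$packets$x, x0 + tan(th) * t_slab, tolerance = 1e-9)
  # optical path = geometric chord * n; excess over (n-1) t is O(theta^2) t
  chord <- t_slab / cos(th)
  expect_equal(out$packets$opl, 1.33 * chord, tolerance = 1e-12)
  excess <- out$packets$opl - chord - (1.33 - 1) * t_slab
  expect_lt(max(abs(excess)), 1.33 * max(th)^2 * t_slab)
  # coherent images with and without the slab match after the global shift
  acc1 <- make_field_accumulator(c(40L, 1L), c(1, 4000))
  acc2 <- make_field_accumulator(c(40L, 1L), c(1, 4000))
  accumulate(acc1, out$packets$x, out$packets$y, opl = out$packets$opl,
             amplitude = 1, wavelength = lam)
  accumulate(acc2, x0 + tan(th) * t_slab, rep(0, n), opl = chord,
             amplitude = 1, wavelength = lam)
  i1 <- as.vector(to_intensity(acc1, "raw")$values)
  i2 <- as.vector(to_intensity(acc2, "raw")$values)
  expect_gt(stats::cor(i1, i2), 0.999)
})

test_that("transport is bit-identical under a fixed seed", {
  cfg <- fig_intralipid_cuvette(volume_ul = 4, n_packets = 2e5, seed = 99)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$image$values, r2$image$values)
  expect_identical(r1$counts, r2$counts)
})
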