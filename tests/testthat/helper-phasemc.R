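# shared fixtures for the test suite

la_beam <- function(D = "0.5 mm") {
  beam_spec(wavelength = 0.488, power = "1 mW", profile = "gaussian",
            e2_width = D)
}

water_props <- function(mu_s = 0, g = 0.82) {
  optical_properties(mu_s = mu_s, mu_a = 0, g = g, n = 1.33)
}

# brute-force 2-D Huygens quadrature over a square aperture: independent
# oracle for the paraxial Fresnel-integral solution (on-axis value)
square_aperture_quadrature <- function(x, y, side, lam, r0, n_grid = 801) {
  g <- seq(-side / 2, side / 2, length.out = n_grid)
  k <- 2 * pi / lam
  # paraxial phase: k ((x-xs)^2 + (y-ys)^2) / (2 r0)
  px <- exp(1i * k * (x - g)^2 / (2 * r0))
  py <- exp(1i * k * (y - g)^2 / (2 * r0))
  h <- g[2] - g[1]
  wts <- rep(1, n_grid); wts[c(1, n_grid)] <- 0.5
  Mod(sum(px * wts) * h * sum(py * wts) * h)^2
}

# azimuthally symmetric Huygens quadrature for the axicon-to-cuvette
# geometry (split air/water optical path, no boundary refraction):
# independent oracle for the coherent exit-face pattern
cuvette_exit_oracle <- function(rho, lam = 0.488, ng = 1.4631, nm = 1.33,
                                alpha = 5 * pi / 180, w = 1000,
                                z_entry = 10000, z_exit = 12000,
                                window = 130) {
  k <- 2 * pi / lam
  tana <- tan(alpha)
  tc <- 12700 * tana + 500
  r <- seq(1e-3, 1000, length.out = 1601)
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  R <- outer(r, rep(1, length(th)))
  TH <- outer(rep(1, length(r)), th)
  X <- R * cos(TH); Y <- R * sin(TH)
  A <- exp(-R^2 / w^2) * R
  ZE <- -R * tana
  vapply(rho, function(p) {
    D <- sqrt((X - p)^2 + Y^2 + (z_exit - ZE)^2)
    f <- (z_entry - ZE) / (z_exit - ZE)
    ex_ <- X + (p - X) * f
    ey_ <- Y * (1 - f)
    inside <- abs(ex_) <= window & abs(ey_) <= window
    L <- ng * (tc + ZE) + D * ((z_entry - ZE) + nm * (z_exit - z_entry)) /
      (z_exit - ZE)
    ig <- A * exp(1i * k * L) * inside
    Mod(sum(ig) * (r[2] - r[1]) * (th[2] - th[1]))^2
  }, numeric(1))
}

# radial average of the coherent excess of a run
excess_radial <- function(img, dr = 1) {
  ex <- img$values - img$incoherent
  xc <- img$origin[1] + (seq_len(dim(ex)[1]) - 0.5) * img$bin_size[1]
  yc <- img$origin[2] + (seq_len(dim(ex)[2]) - 0.5) * img$bin_size[2]
  rr <- sqrt(outer(xc^2, yc^2, "+"))
  pr <- tapply(as.vector(ex), as.vector(floor(rr / dr)), mean)
  data.frame(r = (as.numeric(names(pr)) + 0.5) * dr,
             excess = as.numeric(pr))
}
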