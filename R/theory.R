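#' Analytic theory oracles
#'
#' Closed-form (or quadrature-based) reference solutions used to validate
#' the Monte Carlo engine: Fraunhofer double-slit theory, paraxial Fresnel
#' diffraction by a square aperture, Gaussian beam propagation, Bessel beam
#' relations, and the Intralipid dilution arithmetic. All oracles are pure
#' and deterministic.
#'
#' @name phasemc-theory
NULL

#' Unnormalized sinc, sin(u)/u
#' @param u numeric.
#' @return numeric; 1 at u = 0.
#' @export
sinc <- function(u) ifelse(u == 0, 1, sin(u) / u)

#' Double-slit interference pattern
#'
#' Relative intensity on a screen at distance `L` behind two slits of full
#' width `2b` separated (centre to centre) by `d`:
#' `I(x) = cos^2(k d x / (2 sqrt(L^2+x^2))) * sinc^2(k b x / sqrt(L^2+x^2))`,
#' normalized to 1 at x = 0.
#'
#' @param x screen coordinate(s), um.
#' @param spec a [slit_pair_spec()].
#' @param wavelength vacuum wavelength, um.
#' @return relative intensity in `[0, 1]`.
#' @export
double_slit_intensity <- function(x, spec, wavelength) {
  k <- 2 * pi / parse_length(wavelength)
  d <- spec$separation
  b <- spec$slit_width / 2
  L <- spec$screen_distance
  hyp <- sqrt(L^2 + x^2)
  cos(k * d * x / (2 * hyp))^2 * sinc(k * b * x / hyp)^2
}

#' Fresnel number of a square aperture
#'
#' `F = l^2 / (lambda r0)`; `F > 1` is the near-field (Fresnel) regime,
#' `F < 1` the far-field (Fraunhofer) regime.
#'
#' @param aperture_side side length `l`, um.
#' @param wavelength vacuum wavelength, um.
#' @param distance screen distance `r0`, um.
#' @return list with `F` and `regime` (`"fresnel"` or `"fraunhofer"`).
#' @export
fresnel_number <- function(aperture_side, wavelength, distance) {
  l <- parse_length(aperture_side)
  lam <- parse_length(wavelength)
  r0 <- parse_length(distance)
  stopifnot(l > 0, lam > 0, r0 > 0)
  f <- l^2 / (lam * r0)
  list(F = f, regime = if (f > 1) "fresnel" else "fraunhofer")
}

.fresnel_edge <- function(x, half, lam, r0) {
  # complex edge integral of the separable paraxial solution
  s <- sqrt(2 / (lam * r0))
  u1 <- s * (-half - x)
  u2 <- s * (half - x)
  dc <- pracma::fresnelC(u2) - pracma::fresnelC(u1)
  ds <- pracma::fresnelS(u2) - pracma::fresnelS(u1)
  complex(real = dc, imaginary = ds)
}

#' Paraxial Fresnel diffraction by a square aperture
#'
#' Separable paraxial solution built from Fresnel cosine/sine integrals.
#' In the limit F -> 0 the normalized pattern converges to the Fraunhofer
#' `sinc^2` product.
#'
#' @param x,y screen coordinates, um (recycled against each other).
#' @param spec a [square_aperture_spec()].
#' @param wavelength vacuum wavelength, um.
#' @param normalized if TRUE (default), divide by the on-axis value.
#' @return relative intensity.
#' @export
square_aperture_intensity <- function(x, y = 0, spec, wavelength,
                                      normalized = TRUE) {
  lam <- parse_length(wavelength)
  half <- spec$side / 2
  r0 <- spec$screen_distance
  ix <- Mod(.fresnel_edge(x, half, lam, r0))^2
  iy <- Mod(.fresnel_edge(y, half, lam, r0))^2
  out <- ix * iy / 4
  if (normalized) {
    i0 <- Mod(.fresnel_edge(0, half, lam, r0))^2
    out <- out / (i0^2 / 4)
  }
  out
}

#' Gaussian beam radius as a function of defocus
#'
#' `w(z) = w0 sqrt(1 + (z/zR)^2)` with Rayleigh range `zR = pi w0^2/lambda`.
#'
#' @param z distance from the waist, um.
#' @param w0 waist (1/e^2 intensity radius), um.
#' @param wavelength vacuum wavelength, um.
#' @return beam 1/e^2 radius at `z`, um.
#' @export
gaussian_waist <- function(z, w0, wavelength) {
  stopifnot(w0 > 0)
  zr <- rayleigh_range(w0, wavelength)
  w0 * sqrt(1 + (z / zr)^2)
}

#' Rayleigh range of a Gaussian beam
#' @inheritParams gaussian_waist
#' @return `pi w0^2 / lambda`, um.
#' @export
rayleigh_range <- function(w0, wavelength) pi * w0^2 / parse_length(wavelength)

#' Focused waist of a collimated Gaussian beam
#'
#' `w0 = 2 lambda f / (pi D)` for a beam of 1/e^2 intensity diameter `D`
#' focused by a lens of focal length `f`.
#'
#' @param wavelength vacuum wavelength, um.
#' @param f focal length, um.
#' @param D 1/e^2 intensity diameter at the lens, um.
#' @return waist radius, um.
#' @export
focused_waist <- function(wavelength, f, D) {
  2 * parse_length(wavelength) * parse_length(f) / (pi * parse_length(D))
}

#' Transverse Bessel beam profile
#'
#' `I(r) = J0^2(k_r r)`, normalized to 1 on axis.
#'
#' @param r radial coordinate(s), um.
#' @param k_r radial wavevector, um^-1.
#' @return relative intensity.
#' @export
bessel_profile <- function(r, k_r) {
  stopifnot(k_r > 0)
  besselJ(k_r * r, 0)^2
}

#' Core-width constant kappa for a Bessel beam metric
#'
#' For `metric = "first_zero"` kappa is the smallest positive root of `J0`;
#' for `metric = "e2"` it is the smallest positive root of
#' `J0^2(kappa) = exp(-2)`, i.e. the radius at which the core intensity
#' falls to 1/e^2 of the central maximum.
#'
#' @param metric `"first_zero"` or `"e2"`.
#' @return kappa (dimensionless), found by bracketing root search.
#' @examples
#' round(kappa_for_metric("e2"), 3)        # 1.75 to 3 s.f.
#' round(kappa_for_metric("first_zero"), 4)
#' @export
kappa_for_metric <- function(metric = c("e2", "first_zero")) {
  metric <- match.arg(metric)
  if (metric == "first_zero") {
    stats::uniroot(function(x) besselJ(x, 0), c(2, 3), tol = 1e-12)$root
  } else {
    stats::uniroot(function(x) besselJ(x, 0)^2 - exp(-2), c(1e-9, 2.4),
                   tol = 1e-12)$root
  }
}

#' Bessel beam core radius
#'
#' `r0 = kappa / (k sin beta)` with `k = 2 pi / lambda`.
#'
#' @param kappa core metric constant (see [kappa_for_metric()]).
#' @param wavelength vacuum wavelength, um.
#' @param beta axicon deflection angle, radians, in (0, pi/2).
#' @return core radius, um.
#' @export
bessel_core_radius <- function(kappa, wavelength, beta) {
  stopifnot(beta > 0, beta < pi / 2)
  kappa * parse_length(wavelength) / (2 * pi * sin(beta))
}

#' Axicon deflection angle
#'
#' Exact Snell refraction of an axis-parallel ray at the conical surface
#' gives `beta = asin(n sin alpha) - alpha`; the small-angle form is
#' `(n - 1) alpha`; the thin-element phase-gradient form, which is the
#' deflection encoded in the optical-path profile the Huygens sampler uses,
#' is `asin((n - 1) tan alpha)`.
#'
#' @param alpha axicon opening angle, radians (or string such as "5 deg").
#' @param n refractive index of the axicon.
#' @param method one of `"exact"`, `"small_angle"`, `"phase"`.
#' @return deflection angle beta, radians.
#' @export
axicon_deflection <- function(alpha, n, method = c("exact", "small_angle", "phase")) {
  alpha <- parse_angle(alpha)
  method <- match.arg(method)
  switch(method,
    exact = asin(pmin(1, n * sin(alpha))) - alpha,
    small_angle = (n - 1) * alpha,
    phase = asin(pmin(1, (n - 1) * tan(alpha)))
  )
}

#' Axicon angle matched to a focused Gaussian beam
#'
#' Solves the core-matching relation
#' `1.75 lambda / (2 pi sin beta) = 2 lambda f / (pi D)` for the axicon
#' angle: `alpha = asin(1.75 D / (4 f)) / (n - 1)`, so that the Bessel
#' beam's 1/e^2 core radius equals the Gaussian focal waist.
#'
#' @param n_axicon refractive index of the axicon (> 1).
#' @param D 1/e^2 intensity diameter of the beam on the lens, um.
#' @param f focal length of the Gaussian-arm lens, um.
#' @return alpha, radians.
#' @export
matched_axicon_angle <- function(n_axicon, D, f) {
  D <- parse_length(D); f <- parse_length(f)
  stopifnot(n_axicon > 1, D > 0, f > 0)
  arg <- 1.75 * D / (4 * f)
  if (arg >= 1) stop("1.75 D / (4 f) >= 1: no physical axicon", call. = FALSE)
  asin(arg) / (n_axicon - 1)
}

#' Intralipid dilution arithmetic
#'
#' Converts a stock volume added to water into a volume concentration, a
#' scattering-particle concentration and a scattering coefficient. The
#' anchors reproduce the 2 uL / 500 uL row of the published dilution series
#' (mu_s = 557.14 m^-1, particle concentration 0.0908 percent). Two scalings are
#' supported: `"volume_fraction"` (physically correct linear-in-concentration
#' scaling) and `"table"` (linear in added stock volume, which reproduces the
#' printed dilution table exactly).
#'
#' @param v_stock stock (Intralipid 20 percent) volume, uL.
#' @param v_water water volume, uL.
#' @param scaling `"volume_fraction"` or `"table"`.
#' @param mu_s_anchor_m mu_s (m^-1) of the anchor row, default 557.14.
#' @param anchor_stock_ul,anchor_water_ul anchor row volumes, default 2/500.
#' @param stock_particle_fraction scattering-particle fraction of the stock;
#'   default derived from the anchor row (about 0.228).
#' @return list with `volume_pct`, `particle_pct`, `mu_s_m` (m^-1) and
#'   `mu_s_mm` (mm^-1).
#' @export
intralipid_dilution <- function(v_stock, v_water,
                                scaling = c("volume_fraction", "table"),
                                mu_s_anchor_m = 557.14,
                                anchor_stock_ul = 2, anchor_water_ul = 500,
                                stock_particle_fraction = NULL) {
  scaling <- match.arg(scaling)
  if (any(v_stock < 0) || any(v_water < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  volume_frac <- ifelse(v_stock + v_water > 0, v_stock / (v_stock + v_water), 0)
  anchor_frac <- anchor_stock_ul / (anchor_stock_ul + anchor_water_ul)
  anchor_particle_pct <- 0.0908
  if (is.null(stock_particle_fraction)) {
    stock_particle_fraction <- anchor_particle_pct / (100 * anchor_frac)
  }
  if (scaling == "volume_fraction") {
    mu_s_m <- mu_s_anchor_m * volume_frac / anchor_frac
    particle_pct <- 100 * volume_frac * stock_particle_fraction
  } else {
    ratio <- v_stock / anchor_stock_ul
    mu_s_m <- mu_s_anchor_m * ratio
    particle_pct <- anchor_particle_pct * ratio
  }
  list(volume_pct = 100 * volume_frac,
       particle_pct = particle_pct,
       mu_s_m = mu_s_m,
       mu_s_mm = mu_s_m * 1e-3)
}
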