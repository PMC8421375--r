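#' Built-in validation experiment configurations
#'
#' One configuration per validation study: double slit, square aperture in
#' both diffraction regimes, lens-focused Gaussian beam, axicon Bessel beam
#' (near and far field), and the Intralipid cuvette. Defaults encode the
#' study conditions; packet counts are reduced, desk-scale values and can
#' be overridden.
#'
#' @param n_packets packets to simulate.
#' @param seed run seed.
#' @return an [experiment_config()].
#' @name phasemc-fixtures
NULL

#' @describeIn phasemc-fixtures Young's double slit: 488 nm plane wave,
#'   slit width 10 lambda, separation 80 lambda, screen at 10^4 lambda with
#'   1 mm extent in 2048 bins. The slit length and detector y-range (10 um,
#'   +/-10 um; not part of the printed geometry) keep the y-phase spread
#'   well under a radian so the 1-D slice matches the separable theory.
#' @export
fig_double_slit <- function(n_packets = 1e7, seed = 1) {
  lam <- 0.488
  experiment_config(
    source = beam_spec(wavelength = lam, power = "1 mW", profile = "plane"),
    element = slit_pair_spec(slit_width = 10 * lam, separation = 80 * lam,
                             screen_distance = 1e4 * lam,
                             screen_extent = 1000, slit_length = 10),
    detector = list(distance = 1e4 * lam, extent = c(1000, 20),
                    bins = c(2048L, 1L), ylim = c(-10, 10),
                    normalization = "max_pixel"),
    run = list(n_packets = n_packets, seed = seed))
}

#' @describeIn phasemc-fixtures Square aperture at a chosen Fresnel number
#'   (351 nm, 100 um side; the screen distance is set from F). The detector
#'   is a single coherent y-row, exploiting the separability of the
#'   paraxial solution.
#' @param F Fresnel number of the configuration.
#' @export
fig_square_aperture <- function(F = 2, n_packets = 1e7, seed = 1) {
  lam <- 0.351
  side <- 100
  r0 <- side^2 / (lam * F)
  extent <- if (F >= 1) 4 * side else 8 * lam * r0 / side
  bins <- if (F >= 1) 400L else 160L
  experiment_config(
    source = beam_spec(wavelength = lam, power = "1 mW", profile = "plane"),
    element = square_aperture_spec(side = side, screen_distance = r0),
    detector = list(distance = r0, extent = c(extent, side),
                    bins = c(bins, 1L), ylim = c(-side / 2, side / 2),
                    normalization = "max_pixel"),
    run = list(n_packets = n_packets, seed = seed))
}

#' The LA4249-style UV fused silica plano-convex lens
#'
#' Radius 5 mm, centre thickness 2.2 mm, radius of curvature 4.6 mm,
#' n = 1.4631 at 488 nm; focal length roc/(n-1) = 9.93 mm.
#'
#' @return a [planoconvex_lens_spec()].
#' @export
la4249_lens <- function() {
  planoconvex_lens_spec(radius = "5 mm", thickness = "2.2 mm",
                        roc = "4.6 mm", n_lens = 1.4631)
}

#' @describeIn phasemc-fixtures Gaussian beam focused by the LA4249-style
#'   lens: 488 nm, 0.5 mm 1/e^2 width. The returned config holds the
#'   focal-plane detector; use [fit_waist_scan()] for the waist-vs-z study.
#' @export
fig_gaussian_lens <- function(n_packets = 1e6, seed = 1) {
  lens <- la4249_lens()
  experiment_config(
    source = beam_spec(wavelength = 0.488, power = "1 mW",
                       profile = "gaussian", e2_width = "0.5 mm"),
    element = lens,
    detector = list(distance = lens$focal_length, extent = c(40, 40),
                    bins = c(40L, 1L), ylim = c(-20, 20),
                    normalization = "max_pixel"),
    run = list(n_packets = n_packets, seed = seed))
}

#' @describeIn phasemc-fixtures Bessel beam from a 5 degree axicon
#'   (12.7 mm radius, n = 1.4631) illuminated by a 1 mm 1/e^2 Gaussian at
#'   488 nm; detector 10 mm from the tip, 40 x 40 um at 1 um bins.
#' @param helical_order azimuthal phase order (0 = plain axicon).
#' @export
fig_bessel_axicon <- function(n_packets = 1e7, seed = 1, helical_order = 0L) {
  experiment_config(
    source = beam_spec(wavelength = 0.488, power = "1 mW",
                       profile = "gaussian", e2_width = "1 mm"),
    element = axicon_spec(alpha = "5 deg", radius = "12.7 mm",
                          n_lens = 1.4631, helical_order = helical_order),
    detector = list(distance = "10 mm", extent = c(40, 40),
                    bins = c(40L, 40L), normalization = "max_pixel"),
    run = list(n_packets = n_packets, seed = seed))
}

#' @describeIn phasemc-fixtures Far-field slice of the axicon beam: well
#'   past the ~12 mm axial focal zone the pattern opens into an annulus
#'   (ring radius ~ z tan(beta), ~1.2 mm at the default 35 mm plane). The
#'   detector is a thin slice through the beam axis; the ring wave arrives
#'   at ~2.3 degrees obliquity, so bins must stay below its ~12 um
#'   transverse phase period.
#' @export
fig_bessel_far_field <- function(n_packets = 2e7, seed = 1) {
  cfg <- fig_bessel_axicon(n_packets, seed)
  cfg$detector$distance <- parse_length("35 mm")
  cfg$detector$extent <- c(3280, 12)
  cfg$detector$bins <- c(820L, 1L)
  cfg$detector$ylim <- c(-6, 6)
  cfg
}

#' @describeIn phasemc-fixtures Bessel beam through an Intralipid cuvette:
#'   the 5 degree axicon beam (2 mm 1/e^2 width) enters a 2 mm water
#'   cuvette 10 mm from the tip; the coherent image is recorded on the far
#'   face. `volume_ul` selects the dilution row (0-8 uL in 500 uL).
#' @param volume_ul Intralipid stock volume added to 500 uL of water.
#' @export
fig_intralipid_cuvette <- function(volume_ul = 2, n_packets = 1e7, seed = 1) {
  dil <- intralipid_dilution(volume_ul, 500, scaling = "table")
  experiment_config(
    source = beam_spec(wavelength = 0.488, power = "1 mW",
                       profile = "gaussian", e2_width = "2 mm"),
    element = axicon_spec(alpha = "5 deg", radius = "12.7 mm", n_lens = 1.4631),
    detector = list(distance = "12 mm", extent = c(40, 40),
                    bins = c(20L, 20L), normalization = "max_pixel"),
    medium = list(thickness = "2 mm", width = "2 mm", height = "2 mm",
                  distance = "10 mm", entry_window = 130,
                  properties = optical_properties(mu_s = dil$mu_s_mm,
                                                  mu_a = 0, g = 0.82,
                                                  n = 1.33)),
    run = list(n_packets = n_packets, seed = seed))
}

#' Scan detector planes and fit the Gaussian beam radius
#'
#' Runs one coherent detector plane per z, fits `I(x) = A exp(-2 x^2/w^2)`
#' to the (floor-subtracted) transverse profile by nonlinear least squares,
#' and returns the fitted 1/e^2 radius per plane.
#'
#' @param config a lens configuration such as [fig_gaussian_lens()].
#' @param z_planes plane positions downstream of the lens exit vertex, um.
#' @param n_packets_per_plane packets per plane.
#' @return data frame with `z`, `w_fit` (um) and the theory radius
#'   `w_theory` from [gaussian_waist()] about the fitted focus.
#' @export
fit_waist_scan <- function(config, z_planes, n_packets_per_plane = 5e5) {
  beam <- config$source
  lens <- config$element
  w0 <- focused_waist(beam$wavelength, lens$focal_length, beam$e2_width)
  half <- 20
  w_fit <- vapply(seq_along(z_planes), function(i) {
    acc <- simulate_plane(lens, beam, z_planes[i],
                          xlim = c(-half, half), ylim = c(-half, half),
                          bins = c(80L, 1L),
                          n_packets = n_packets_per_plane,
                          seed = substream_seed(config$run$seed, 5000L + i))
    x <- bin_centers(acc, 1)
    y <- Mod(acc$values[, 1])^2 - acc$power[, 1]
    y <- pmax(y, 0)
    fit_e2_radius(x, y)
  }, numeric(1))
  # w(z)^2 is exactly quadratic in z; a quadratic fit gives the focus
  # position and the minimum waist without grid bias
  qf <- stats::lm(I(w_fit^2) ~ z_planes + I(z_planes^2))
  a <- stats::coef(qf)[[3]]; b <- stats::coef(qf)[[2]]; c0 <- stats::coef(qf)[[1]]
  zf <- -b / (2 * a)
  w0_fit <- sqrt(max(c0 - b^2 / (4 * a), 0))
  out <- data.frame(z = z_planes, w_fit = w_fit,
                    w_theory = gaussian_waist(z_planes - zf, w0,
                                              beam$wavelength))
  attr(out, "z_focus") <- zf
  attr(out, "w0_fit") <- w0_fit
  out
}

#' Fit the 1/e^2 radius of a transverse intensity profile
#'
#' @param x coordinates, um.
#' @param y intensities.
#' @return fitted 1/e^2 radius, um (moment-based start refined by
#'   [stats::nls()]; falls back to the moment estimate).
#' @export
fit_e2_radius <- function(x, y) {
  if (sum(y) <= 0) return(NA_real_)
  mu <- sum(x * y) / sum(y)
  sd0 <- sqrt(sum((x - mu)^2 * y) / sum(y))
  w_start <- 2 * sd0 # for a Gaussian intensity profile, w = 2 sd
  fit <- tryCatch({
    df <- data.frame(x = x, y = y)
    m <- stats::nls(y ~ A * exp(-2 * (x - x0)^2 / w^2), data = df,
                    start = list(A = max(y), x0 = mu, w = w_start),
                    control = stats::nls.control(warnOnly = TRUE))
    abs(stats::coef(m)[["w"]])
  }, error = function(e) w_start)
  fit
}

#' Write the fixture configurations as YAML files
#'
#' @param dir target directory.
#' @return invisibly, the file paths.
#' @export
write_fixture_configs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- list(
    double_slit = list(
      source = list(wavelength = "488 nm", power = "1 mW", profile = "plane"),
      element = list(kind = "slit_pair", slit_width = "4.88 um",
                     separation = "39.04 um", screen_distance = "4.88 mm",
                     screen_extent = "1 mm", slit_length = "10 um"),
      detector = list(distance = "4.88 mm", extent = c("1 mm", "20 um"),
                      bins = c(2048L, 1L), ylim = c("-10 um", "10 um"),
                      normalization = "max_pixel"),
      run = list(n_packets = 1e7, seed = 1)),
    square_aperture_fresnel = list(
      source = list(wavelength = "351 nm", power = "1 mW", profile = "plane"),
      element = list(kind = "square_aperture", side = "100 um",
                     screen_distance = "14.245 mm"),
      detector = list(distance = "14.245 mm", extent = c("400 um", "100 um"),
                      bins = c(400L, 1L), ylim = c("-50 um", "50 um"),
                      normalization = "max_pixel"),
      run = list(n_packets = 1e7, seed = 1)),
    square_aperture_fraunhofer = list(
      source = list(wavelength = "351 nm", power = "1 mW", profile = "plane"),
      element = list(kind = "square_aperture", side = "100 um",
                     screen_distance = "284.9 mm"),
      detector = list(distance = "284.9 mm", extent = c("8 mm", "100 um"),
                      bins = c(160L, 1L), ylim = c("-50 um", "50 um"),
                      normalization = "max_pixel"),
      run = list(n_packets = 1e7, seed = 1)),
    gaussian_lens = list(
      source = list(wavelength = "488 nm", power = "1 mW",
                    profile = "gaussian", e2_width = "0.5 mm"),
      element = list(kind = "planoconvex_lens", radius = "5 mm",
                     thickness = "2.2 mm", roc = "4.6 mm", n_lens = 1.4631),
      detector = list(distance = "9.933 mm", extent = c("40 um", "40 um"),
                      bins = c(40L, 1L), ylim = c("-20 um", "20 um"),
                      normalization = "max_pixel"),
      run = list(n_packets = 1e6, seed = 1)),
    bessel_axicon = list(
      source = list(wavelength = "488 nm", power = "1 mW",
                    profile = "gaussian", e2_width = "1 mm"),
      element = list(kind = "axicon", alpha = "5 deg", radius = "12.7 mm",
                     n_lens = 1.4631, helical_order = 0L),
      detector = list(distance = "10 mm", extent = c("40 um", "40 um"),
                      bins = c(40L, 40L), normalization = "max_pixel"),
      run = list(n_packets = 1e7, seed = 1)),
    intralipid_cuvette = list(
      source = list(wavelength = "488 nm", power = "1 mW",
                    profile = "gaussian", e2_width = "2 mm"),
      element = list(kind = "axicon", alpha = "5 deg", radius = "12.7 mm",
                     n_lens = 1.4631),
      medium = list(thickness = "2 mm", width = "2 mm", height = "2 mm",
                    distance = "10 mm", entry_window = "30 um",
                    intralipid_volume_ul = 2, scaling = "table",
                    g = 0.82, n = 1.33),
      detector = list(distance = "12 mm", extent = c("40 um", "40 um"),
                      bins = c(40L, 40L), normalization = "max_pixel"),
      run = list(n_packets = 1e6, seed = 1))
  )
  paths <- character(0)
  for (nm in names(fixtures)) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(fixtures[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
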