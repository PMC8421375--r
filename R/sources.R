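#' Beam specification
#'
#' Describes the illumination incident on the wavefront-shaping element.
#' For a Gaussian profile, launch positions are sampled with probability
#' density proportional to the transverse field *amplitude*
#' `exp(-r^2/w^2)` (`w` = 1/e^2 intensity radius = `e2_width/2`). The
#' coherent bin estimator is linear in the sampling density, so sampling
#' from the amplitude makes the effective Huygens aperture weight equal to
#' the physical field amplitude; see the methods vignette.
#'
#' @param wavelength vacuum wavelength (um or unit string).
#' @param power beam power (W or unit string). Default 1 mW.
#' @param profile `"plane"` or `"gaussian"`.
#' @param e2_width 1/e^2 intensity diameter `D` (um or unit string);
#'   required for the gaussian profile.
#' @param area illuminated area `A` used in the packet normalization
#'   `E0 = sqrt(P/A)/N`, um^2. Defaults to `pi (D/2)^2` for a gaussian
#'   profile and must be given for a plane profile whose element does not
#'   define one.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(wavelength, power = "1 mW", profile = c("plane", "gaussian"),
                      e2_width = NULL, area = NULL) {
  profile <- match.arg(profile)
  wavelength <- parse_length(wavelength)
  power <- parse_power(power)
  stopifnot(wavelength > 0, power >= 0)
  if (profile == "gaussian") {
    if (is.null(e2_width)) stop("gaussian profile needs e2_width", call. = FALSE)
    e2_width <- parse_length(e2_width)
    stopifnot(e2_width > 0)
    if (is.null(area)) area <- pi * (e2_width / 2)^2
  }
  if (!is.null(area)) area <- parse_length(area)^1 # already um^2 if numeric
  structure(list(wavelength = wavelength, power = power, profile = profile,
                 e2_width = e2_width, area = area),
            class = "beam_spec")
}

#' Initial packet field amplitude
#'
#' `E0 = sqrt(P/A) / N`: the initial electric field amplitude normalizes the
#' beam power over `N` packets, so that `N` in-phase packets accumulated in
#' one bin of area `A` give intensity `N^2 E0^2 = P/A`.
#'
#' @param beam a [beam_spec()].
#' @param n_packets total number of packets in the run.
#' @return scalar amplitude (sqrt(W)/um per packet).
#' @export
initial_amplitude <- function(beam, n_packets) {
  stopifnot(n_packets >= 1)
  if (is.null(beam$area) || beam$area <= 0) {
    stop("beam area must be positive for amplitude normalization", call. = FALSE)
  }
  sqrt(beam$power / beam$area) / n_packets
}

# ---- element specs ---------------------------------------------------------

#' Double-slit element
#'
#' Two parallel slits in an opaque screen, long axis along y. `slit_width`
#' is the full width `2b` of each slit; `separation` is the centre-to-centre
#' distance `d`.
#'
#' @param slit_width full slit width (um or unit string).
#' @param separation centre-to-centre slit separation (um or unit string).
#' @param screen_distance distance to the detector screen `L` (um).
#' @param screen_extent full transverse extent of the detector screen (um).
#' @param slit_length slit extent along y (um); not printed in the classic
#'   geometry, kept small so the 1-D slice stays coherent in y.
#' @return object of class `slit_pair_spec` / `phasemc_element`.
#' @export
slit_pair_spec <- function(slit_width, separation, screen_distance,
                           screen_extent, slit_length = 10) {
  slit_width <- parse_length(slit_width)
  separation <- parse_length(separation)
  screen_distance <- parse_length(screen_distance)
  screen_extent <- parse_length(screen_extent)
  slit_length <- parse_length(slit_length)
  if (!(separation > slit_width && slit_width > 0)) {
    stop("need separation > slit_width > 0", call. = FALSE)
  }
  stopifnot(screen_distance > 0, screen_extent > 0, slit_length > 0)
  structure(list(kind = "slit_pair", slit_width = slit_width,
                 separation = separation, screen_distance = screen_distance,
                 screen_extent = screen_extent, slit_length = slit_length),
            class = c("slit_pair_spec", "phasemc_element"))
}

#' Square aperture element
#'
#' @param side aperture side `l` (um or unit string).
#' @param screen_distance distance `r0` to the detector screen (um).
#' @return object of class `square_aperture_spec` / `phasemc_element`.
#' @export
square_aperture_spec <- function(side, screen_distance) {
  side <- parse_length(side)
  screen_distance <- parse_length(screen_distance)
  stopifnot(side > 0, screen_distance > 0)
  structure(list(kind = "square_aperture", side = side,
                 screen_distance = screen_distance),
            class = c("square_aperture_spec", "phasemc_element"))
}

#' Plano-convex lens element
#'
#' Flat face toward the source; the convex (spherical) face is the Huygens
#' exit surface. In the element frame the exit vertex sits at z = 0 and the
#' flat face at z = -thickness.
#'
#' @param radius aperture semi-diameter (um or unit string).
#' @param thickness centre thickness (um).
#' @param roc radius of curvature of the convex face (um).
#' @param n_lens refractive index of the glass.
#' @return object of class `planoconvex_lens_spec` / `phasemc_element`.
#' @export
planoconvex_lens_spec <- function(radius, thickness, roc, n_lens) {
  radius <- parse_length(radius)
  thickness <- parse_length(thickness)
  roc <- parse_length(roc)
  stopifnot(roc > 0, radius > 0, thickness > 0, n_lens > 1)
  # the spherical surface only exists out to r = roc; rays beyond the
  # sphere's equator hit the cylindrical edge and are discarded
  structure(list(kind = "planoconvex_lens", radius = min(radius, roc),
                 mount_radius = radius,
                 thickness = thickness, roc = roc, n_lens = n_lens,
                 focal_length = roc / (n_lens - 1)),
            class = c("planoconvex_lens_spec", "phasemc_element"))
}

#' Axicon element
#'
#' Flat face toward the source; the conical surface (apex on the optical
#' axis, pointing downstream) is the Huygens exit surface. In the element
#' frame the apex sits at z = 0. A nonzero `helical_order` adds an azimuthal
#' phase delay of `helical_order * phi` for higher-order Bessel beams.
#'
#' @param alpha opening angle (radians or string such as `"5 deg"`).
#' @param radius aperture radius (um or unit string).
#' @param n_lens refractive index.
#' @param helical_order integer >= 0; 0 is a plain axicon.
#' @param thickness centre (apex) thickness, um; defaults to the cone sag
#'   plus 0.5 mm of edge glass.
#' @return object of class `axicon_spec` / `phasemc_element`.
#' @export
axicon_spec <- function(alpha, radius, n_lens, helical_order = 0L,
                        thickness = NULL) {
  alpha <- parse_angle(alpha)
  radius <- parse_length(radius)
  stopifnot(alpha > 0, alpha < pi / 2, radius > 0, n_lens > 1,
            helical_order >= 0)
  if (is.null(thickness)) thickness <- radius * tan(alpha) + 500
  thickness <- parse_length(thickness)
  stopifnot(thickness >= radius * tan(alpha))
  structure(list(kind = "axicon", alpha = alpha, radius = radius,
                 n_lens = n_lens, helical_order = as.integer(helical_order),
                 thickness = thickness),
            class = c("axicon_spec", "phasemc_element"))
}

# ---- Huygens sampling ------------------------------------------------------

#' Sample a Huygens direction toward a rectangle on a detector plane
#'
#' Every point of the emitting surface acts as a source of forward-going
#' secondary wavelets; a direction is drawn by uniformly sampling a point in
#' the target rectangle and normalizing the difference vector. No backward
#' waves: the forward component is strictly positive by construction.
#'
#' @param origin matrix or data frame with columns x, y, z (um), one row per
#'   packet (or a length-3 vector).
#' @param target list with `z` (plane position), `xlim`, `ylim` (length-2
#'   ranges, um).
#' @param n number of directions (defaults to rows of origin).
#' @return list with unit direction components `ux, uy, uz`, the sampled
#'   target points `tx, ty`, and the travel distance `dist` to the plane.
#' @export
sample_huygens_direction <- function(origin, target, n = NULL) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(n)) n <- nrow(origin)
  tx <- stats::runif(n, target$xlim[1], target$xlim[2])
  ty <- stats::runif(n, target$ylim[1], target$ylim[2])
  dx <- tx - origin[, 1]
  dy <- ty - origin[, 2]
  dz <- target$z - origin[, 3]
  if (any(dz == 0)) stop("origin lies on the target plane", call. = FALSE)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  list(ux = dx / d, uy = dy / d, uz = dz / d, tx = tx, ty = ty, dist = d)
}

#' Launch packets from a double slit
#'
#' Positions are uniform over the union of the two slit areas (each slit
#' chosen with probability 1/2); directions are Huygens-sampled toward the
#' screen; optical path starts at zero (plane-wave illumination, equal phase
#' across the slit plane).
#'
#' @param spec a [slit_pair_spec()].
#' @param beam a [beam_spec()].
#' @param n number of packets.
#' @param amplitude packet amplitude E0 (default from [initial_amplitude()]
#'   with `n` packets).
#' @return a [packets()] object positioned at the slit plane (z = 0) with
#'   attribute `target` (the sampled screen points).
#' @export
sample_slit_pair <- function(spec, beam, n, amplitude = NULL) {
  b <- spec$slit_width / 2
  which_slit <- stats::runif(n) < 0.5
  cx <- ifelse(which_slit, -spec$separation / 2, spec$separation / 2)
  x <- cx + stats::runif(n, -b, b)
  y <- stats::runif(n, -spec$slit_length / 2, spec$slit_length / 2)
  half <- spec$screen_extent / 2
  yhalf <- min(half, spec$slit_length)
  dirs <- sample_huygens_direction(cbind(x, y, 0),
    list(z = spec$screen_distance, xlim = c(-half, half),
         ylim = c(-yhalf, yhalf)), n)
  if (is.null(amplitude)) {
    area <- 2 * spec$slit_width * spec$slit_length
    amplitude <- sqrt(beam$power / area) / n
  }
  p <- packets(x, y, 0, dirs$ux, dirs$uy, dirs$uz,
               wavelength = beam$wavelength, amplitude = amplitude)
  attr(p, "target") <- dirs
  p
}

#' Launch packets from a square aperture
#'
#' @inheritParams sample_slit_pair
#' @param spec a [square_aperture_spec()].
#' @param target optional target rectangle (defaults to a screen region of
#'   the same extent as stored in the run configuration); list with `z`,
#'   `xlim`, `ylim`.
#' @return a [packets()] object at the aperture plane.
#' @export
sample_square_aperture <- function(spec, beam, n, target, amplitude = NULL) {
  half <- spec$side / 2
  x <- stats::runif(n, -half, half)
  y <- stats::runif(n, -half, half)
  dirs <- sample_huygens_direction(cbind(x, y, 0), target, n)
  if (is.null(amplitude)) {
    amplitude <- sqrt(beam$power / spec$side^2) / n
  }
  p <- packets(x, y, 0, dirs$ux, dirs$uy, dirs$uz,
               wavelength = beam$wavelength, amplitude = amplitude)
  attr(p, "target") <- dirs
  p
}

#' Sample transverse launch positions for a beam profile
#'
#' Plane profile: uniform over the element aperture disc. Gaussian profile:
#' density proportional to the field amplitude `exp(-r^2/w^2)` (bivariate
#' normal with per-axis sd `w/sqrt(2)`), truncated at the aperture radius by
#' rejection.
#'
#' @param beam a [beam_spec()].
#' @param radius aperture radius, um.
#' @param n number of positions.
#' @return list with `x`, `y` (um).
#' @export
sample_beam_positions <- function(beam, radius, n) {
  if (beam$profile == "plane") {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    return(list(x = r * cos(th), y = r * sin(th)))
  }
  sd <- beam$e2_width / (2 * sqrt(2))
  x <- stats::rnorm(n, 0, sd)
  y <- stats::rnorm(n, 0, sd)
  bad <- which(x^2 + y^2 > radius^2)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    y[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[x[bad]^2 + y[bad]^2 > radius^2]
  }
  list(x = x, y = y)
}

# ---- refractive tracing ----------------------------------------------------

#' Vector Snell refraction
#'
#' @param d matrix (n x 3) of unit incident directions.
#' @param nrm matrix (n x 3) of unit surface normals, oriented against the
#'   incident direction (`sum(d * nrm) < 0`).
#' @param n1,n2 refractive indices on the incident / transmitted side.
#' @return list with `d` (n x 3 transmitted unit directions, NA rows on
#'   total internal reflection) and logical `tir`.
#' @export
refract_snell <- function(d, nrm, n1, n2) {
  eta <- n1 / n2
  ci <- -(d[, 1] * nrm[, 1] + d[, 2] * nrm[, 2] + d[, 3] * nrm[, 3])
  s2 <- eta^2 * (1 - ci^2)
  tir <- s2 > 1
  ct <- sqrt(pmax(0, 1 - s2))
  f <- eta * ci - ct
  out <- eta * d + f * nrm
  out[tir, ] <- NA_real_
  dimnames(out) <- NULL
  list(d = out, tir = unname(tir))
}

#' Trace axis-parallel rays through a plano-convex lens
#'
#' Rays enter the flat face (normal incidence, no bend), travel through the
#' glass to the spherical exit surface, and are refracted there by exact
#' vector Snell. The element frame puts the exit vertex at z = 0.
#'
#' @param x,y entry positions on the flat face, um.
#' @param spec a [planoconvex_lens_spec()].
#' @return list with exit point (`x`, `y`, `z`), `opl` (optical path from
#'   the flat face, um), Snell exit direction (`ux`, `uy`, `uz`; NA on total
#'   internal reflection), and logical `ok` (FALSE where the ray misses the
#'   aperture or is totally internally reflected).
#' @export
trace_planoconvex <- function(x, y, spec) {
  r2 <- x^2 + y^2
  ok <- r2 <= spec$radius^2
  sag <- spec$roc - sqrt(pmax(0, spec$roc^2 - r2))
  zexit <- -sag                       # exit vertex at z = 0
  glass <- spec$thickness - sag       # path from flat face (z = -thickness)
  opl <- spec$n_lens * glass
  # outward normal of the sphere centred at (0, 0, -roc)
  nx <- x / spec$roc
  ny <- y / spec$roc
  nz <- (zexit + spec$roc) / spec$roc
  d <- cbind(0, 0, 1)[rep(1, length(x)), , drop = FALSE]
  # refraction normal must oppose the incident direction: use -outward
  sn <- refract_snell(d, -cbind(nx, ny, nz), spec$n_lens, 1)
  ok <- ok & !sn$tir
  list(x = x, y = y, z = zexit, opl = opl,
       ux = sn$d[, 1], uy = sn$d[, 2], uz = sn$d[, 3], ok = ok)
}

#' Trace axis-parallel rays through an axicon
#'
#' Rays enter the flat face and travel through the glass to the conical exit
#' surface (`z_exit = -r tan(alpha)`, apex at z = 0). The exact Snell
#' refracted direction at the cone is returned for ray-level use; the
#' Huygens wave sampler uses only the exit point and optical path. Rays
#' exactly on the apex axis are left undeviated (degenerate normal,
#' probability-zero event fixed for determinism).
#'
#' @param x,y entry positions on the flat face, um.
#' @param spec an [axicon_spec()].
#' @return list as in [trace_planoconvex()].
#' @export
trace_axicon <- function(x, y, spec) {
  r <- sqrt(x^2 + y^2)
  ok <- r <= spec$radius
  tana <- tan(spec$alpha)
  zexit <- -r * tana
  glass <- spec$thickness - r * tana
  opl <- spec$n_lens * glass
  # cone surface normal (pointing downstream, against which rays refract):
  # gradient of z + r tan(alpha): (tan(a) x/r, tan(a) y/r, 1) normalized
  cosa <- cos(spec$alpha); sina <- sin(spec$alpha)
  safe_r <- ifelse(r > 0, r, 1)
  nx <- sina * x / safe_r
  ny <- sina * y / safe_r
  nz <- rep(cosa, length(x))
  d <- cbind(0, 0, 1)[rep(1, length(x)), , drop = FALSE]
  sn <- refract_snell(d, -cbind(nx, ny, nz), spec$n_lens, 1)
  ux <- sn$d[, 1]; uy <- sn$d[, 2]; uz <- sn$d[, 3]
  on_axis <- r == 0
  ux[on_axis] <- 0; uy[on_axis] <- 0; uz[on_axis] <- 1
  ok <- ok & (!sn$tir | on_axis)
  list(x = x, y = y, z = zexit, opl = opl, ux = ux, uy = uy, uz = uz, ok = ok)
}

#' Apply a helical (azimuthal) phase delay at the axicon exit
#'
#' Adds `helical_order * phi * lambda / (2 pi)` to the optical path, where
#' `phi` is the azimuth of the exit point in `[0, 2 pi)`: the phase increment
#' is `helical_order * phi`, producing an m-th order Bessel (vortex) beam.
#'
#' @param opl optical path lengths, um.
#' @param x,y exit-point coordinates, um.
#' @param spec an [axicon_spec()].
#' @param wavelength vacuum wavelength, um.
#' @return updated optical path lengths.
#' @export
apply_helical_delay <- function(opl, x, y, spec, wavelength) {
  if (spec$helical_order == 0L) return(opl)
  phi <- atan2(y, x)
  phi <- ifelse(phi < 0, phi + 2 * pi, phi)
  opl + spec$helical_order * phi * parse_length(wavelength) / (2 * pi)
}
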