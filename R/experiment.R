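#' Experiment configuration
#'
#' An experiment is source + element + optional medium + detector + run
#' parameters; one configuration per validation figure. Configurations can
#' be built directly or loaded from YAML with [load_experiment_config()].
#'
#' @param source a [beam_spec()].
#' @param element a `phasemc_element` (slit pair, square aperture, lens or
#'   axicon).
#' @param detector list with `distance` (plane position downstream of the
#'   element exit, um), `extent` (length-1 or -2, um), `bins` (length-1 or
#'   -2 integer), and optional `normalization` (`"max_pixel"` default) and
#'   `ylim` (explicit y target range for slit-type 1-D runs).
#' @param medium optional list with `thickness`, `width`, `height` (um),
#'   `distance` (air gap between element exit and entry face, um),
#'   `properties` (an [optical_properties()]), and optional `entry_window`
#'   (half-extent of the Huygens target region on the entry face, um).
#' @param run list with `n_packets` and `seed`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(source, element, detector, medium = NULL,
                              run = list(n_packets = 1e6, seed = 1)) {
  stopifnot(inherits(source, "beam_spec"), inherits(element, "phasemc_element"))
  detector$distance <- parse_length(detector$distance)
  detector$extent <- rep_len(parse_length(detector$extent), 2L)
  detector$bins <- rep_len(as.integer(detector$bins), 2L)
  if (is.null(detector$normalization)) detector$normalization <- "max_pixel"
  if (detector$distance <= 0 || any(detector$extent <= 0) ||
      any(detector$bins <= 0)) {
    stop("invalid detector geometry", call. = FALSE)
  }
  if (!is.null(medium)) {
    medium$thickness <- parse_length(medium$thickness)
    medium$width <- parse_length(medium$width)
    medium$height <- parse_length(medium$height)
    medium$distance <- parse_length(medium$distance)
    stopifnot(inherits(medium$properties, "optical_properties"))
    if (is.null(medium$entry_window)) {
      medium$entry_window <- min(medium$width, medium$height) / 2
    } else {
      medium$entry_window <- parse_length(medium$entry_window)
    }
  }
  run$n_packets <- as.numeric(run$n_packets)
  if (is.null(run$seed)) run$seed <- 1L
  structure(list(source = source, element = element, detector = detector,
                 medium = medium, run = run),
            class = "experiment_config")
}

# illuminated area A for the E0 = sqrt(P/A)/N normalization when the beam
# does not fix one itself: the emitting area of the element
.beam_area <- function(beam, element) {
  if (!is.null(beam$area)) return(beam$area)
  if (inherits(element, "slit_pair_spec")) {
    return(2 * element$slit_width * element$slit_length)
  }
  if (inherits(element, "square_aperture_spec")) return(element$side^2)
  pi * element$radius^2
}

# launch one block of packets from the element exit surface;
# returns exit positions (element frame, exit vertex at z = 0), opl, ok mask
.launch_element <- function(element, beam, m) {
  if (inherits(element, "slit_pair_spec")) {
    b <- element$slit_width / 2
    which_slit <- stats::runif(m) < 0.5
    cx <- ifelse(which_slit, -element$separation / 2, element$separation / 2)
    x <- cx + stats::runif(m, -b, b)
    y <- stats::runif(m, -element$slit_length / 2, element$slit_length / 2)
    return(list(x = x, y = y, z = rep(0, m), opl = rep(0, m),
                ok = rep(TRUE, m)))
  }
  if (inherits(element, "square_aperture_spec")) {
    half <- element$side / 2
    return(list(x = stats::runif(m, -half, half),
                y = stats::runif(m, -half, half),
                z = rep(0, m), opl = rep(0, m), ok = rep(TRUE, m)))
  }
  pos <- sample_beam_positions(beam, element$radius, m)
  if (inherits(element, "planoconvex_lens_spec")) {
    tr <- trace_planoconvex(pos$x, pos$y, element)
  } else if (inherits(element, "axicon_spec")) {
    tr <- trace_axicon(pos$x, pos$y, element)
    tr$opl <- apply_helical_delay(tr$opl, tr$x, tr$y, element, beam$wavelength)
  } else {
    stop("unknown element kind", call. = FALSE)
  }
  list(x = tr$x, y = tr$y, z = tr$z, opl = tr$opl, ok = tr$ok)
}

#' Simulate a free-space detector plane
#'
#' The elementary phased-MC run: packets are launched from the element exit
#' surface, given Huygens directions toward uniformly sampled points of the
#' detector window, flown ballistically to the plane and accumulated
#' coherently at 1 bin per packet. Deterministic given
#' (geometry, seed, n_packets): packets are processed in fixed blocks with
#' per-block substream seeds.
#'
#' @param element a `phasemc_element`.
#' @param beam a [beam_spec()].
#' @param z_plane detector plane position downstream of the element exit
#'   vertex, um.
#' @param xlim,ylim detector window, um.
#' @param bins integer length-2 bin counts.
#' @param n_packets number of packets.
#' @param seed run seed.
#' @param n_ambient refractive index between element and plane (default 1).
#' @return a `field_accumulator`.
#' @export
simulate_plane <- function(element, beam, z_plane, xlim, ylim, bins,
                           n_packets, seed, n_ambient = 1) {
  acc <- make_field_accumulator(bins,
    bin_size = c(diff(xlim) / bins[1], diff(ylim) / bins[2]),
    origin = c(xlim[1], ylim[1]))
  if (n_packets < 1) return(acc)
  bm <- beam
  bm$area <- .beam_area(beam, element)
  e0 <- initial_amplitude(bm, n_packets)
  nblocks <- ceiling(n_packets / .BLOCK)
  for (blk in seq_len(nblocks)) {
    m <- min(.BLOCK, n_packets - (blk - 1) * .BLOCK)
    set.seed(substream_seed(seed, blk))
    L <- .launch_element(element, beam, m)
    tx <- stats::runif(m, xlim[1], xlim[2])
    ty <- stats::runif(m, ylim[1], ylim[2])
    d <- sqrt((tx - L$x)^2 + (ty - L$y)^2 + (z_plane - L$z)^2)
    opl <- L$opl + n_ambient * d
    keep <- L$ok
    accumulate(acc, x = tx[keep], y = ty[keep], opl = opl[keep],
               amplitude = e0, wavelength = beam$wavelength)
  }
  acc
}

#' Run a configured experiment
#'
#' Free-space configurations fly packets from the element exit straight to
#' the detector plane. Medium configurations Huygens-sample the packets onto
#' the medium entry face (so no packet misses the cuvette), propagate them
#' with scattering and phase tracking, record the survivors on the far
#' (exit) face, and discard side/back exits.
#'
#' @param config an [experiment_config()].
#' @param record_planes optional z-planes (distance downstream of the
#'   element, um) at which in-medium transverse fields are recorded (medium
#'   runs only).
#' @return list with `image` (an [to_intensity()] result), `counts`
#'   (launched/detected/discarded/absorbed), `config`, and optionally
#'   `plane_images`.
#' @export
run_experiment <- function(config, record_planes = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  det <- config$detector
  n_packets <- config$run$n_packets
  seed <- config$run$seed
  beam <- config$source
  if (is.null(config$medium)) {
    ylim <- det$ylim
    if (is.null(ylim)) ylim <- c(-det$extent[2] / 2, det$extent[2] / 2)
    acc <- simulate_plane(config$element, beam, det$distance,
                          xlim = c(-det$extent[1] / 2, det$extent[1] / 2),
                          ylim = ylim, bins = det$bins,
                          n_packets = n_packets, seed = seed)
    img <- to_intensity(acc, det$normalization)
    return(list(image = img,
                counts = list(launched = n_packets, detected = acc$n_added,
                              discarded = n_packets - acc$n_added,
                              absorbed = 0),
                config = config))
  }
  md <- config$medium
  z_entry <- md$distance
  slab <- medium_slab(extent = c(md$width, md$height, md$thickness),
                      voxel_size = c(md$width, md$height, md$thickness),
                      properties = md$properties,
                      origin = c(-md$width / 2, -md$height / 2, z_entry))
  acc <- make_field_accumulator(det$bins,
    bin_size = det$extent / det$bins,
    origin = c(-det$extent[1] / 2, -det$extent[2] / 2))
  plane_accs <- NULL
  if (!is.null(record_planes)) {
    plane_accs <- lapply(record_planes, function(z) {
      make_field_accumulator(det$bins, bin_size = det$extent / det$bins,
                             origin = c(-det$extent[1] / 2, -det$extent[2] / 2))
    })
  }
  if (n_packets < 1) {
    return(list(image = to_intensity(acc, det$normalization),
                counts = list(launched = 0, detected = 0, discarded = 0,
                              absorbed = 0),
                config = config))
  }
  bm0 <- beam
  bm0$area <- .beam_area(beam, config$element)
  e0 <- initial_amplitude(bm0, n_packets)
  nblocks <- ceiling(n_packets / .BLOCK)
  tot <- c(detected = 0, discarded = 0, absorbed = 0)
  for (blk in seq_len(nblocks)) {
    m <- min(.BLOCK, n_packets - (blk - 1) * .BLOCK)
    set.seed(substream_seed(seed, blk))
    L <- .launch_element(config$element, beam, m)
    hw <- md$entry_window
    tx <- stats::runif(m, -hw, hw)
    ty <- stats::runif(m, -hw, hw)
    d <- sqrt((tx - L$x)^2 + (ty - L$y)^2 + (z_entry - L$z)^2)
    keep <- which(L$ok)
    p <- packets(x = tx[keep], y = ty[keep], z = rep(z_entry, length(keep)),
                 ux = (tx - L$x)[keep] / d[keep],
                 uy = (ty - L$y)[keep] / d[keep],
                 uz = (z_entry - L$z)[keep] / d[keep],
                 opl = (L$opl + d)[keep],
                 wavelength = beam$wavelength, amplitude = e0)
    out <- propagate_in_medium(p, slab, record_planes = record_planes,
                               accumulators = plane_accs)
    tot["detected"] <- tot["detected"] + out$n_detected
    tot["discarded"] <- tot["discarded"] + out$n_discarded + (m - length(keep))
    tot["absorbed"] <- tot["absorbed"] + out$n_absorbed
    det_idx <- out$packets$status == PACKET_DETECTED
    if (any(det_idx)) {
      accumulate(acc, x = out$packets$x[det_idx], y = out$packets$y[det_idx],
                 opl = out$packets$opl[det_idx], amplitude = e0,
                 wavelength = beam$wavelength)
    }
  }
  res <- list(image = to_intensity(acc, det$normalization),
              counts = as.list(c(launched = n_packets, tot)),
              config = config)
  if (!is.null(plane_accs)) {
    res$plane_images <- lapply(plane_accs, to_intensity, normalization = "raw")
    names(res$plane_images) <- paste0("z=", record_planes)
  }
  res
}

#' Compare a simulated profile or image to an analytic oracle
#'
#' Both inputs are max-normalized before the RMSE; the Pearson correlation
#' is scale-free. A constant (zero-variance) input is flagged as degenerate
#' rather than correlated.
#'
#' @param simulated numeric vector/matrix of simulated intensities.
#' @param oracle numeric vector/matrix of oracle intensities, same shape.
#' @return list with `pearson`, `rmse`, `max_location_offset` (bins),
#'   `degenerate`.
#' @export
compare_to_oracle <- function(simulated, oracle) {
  s <- as.vector(simulated)
  o <- as.vector(oracle)
  if (length(s) != length(o)) stop("incommensurable grids", call. = FALSE)
  if (all(s == 0)) stop("all-zero simulated input", call. = FALSE)
  degenerate <- stats::sd(s) == 0 || stats::sd(o) == 0
  pearson <- if (degenerate) NA_real_ else stats::cor(s, o)
  sn <- s / max(s)
  on <- o / max(o)
  list(pearson = pearson,
       rmse = sqrt(mean((sn - on)^2)),
       max_location_offset = abs(which.max(s) - which.max(o)),
       degenerate = degenerate)
}
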