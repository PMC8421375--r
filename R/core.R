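#' Photon packets
#'
#' Packets are stored in structure-of-arrays form: a list of equal-length
#' numeric vectors, so that every operation in the engine is vectorized over
#' packets. A "single packet" is simply a length-1 set of vectors.
#'
#' Fields: `x`, `y`, `z` (position, um), `ux`, `uy`, `uz` (unit direction),
#' `opl` (accumulated optical path length, sum of n_i * l_i, um),
#' `wavelength` (vacuum wavelength, um), `amplitude` (field amplitude E0,
#' constant after launch), `status` (integer code, see [packet_status]).
#'
#' @param x,y,z numeric, positions in um.
#' @param ux,uy,uz numeric, direction components (will be normalized).
#' @param opl numeric, initial optical path length in um.
#' @param wavelength numeric, vacuum wavelength in um.
#' @param amplitude numeric, field amplitude (non-negative).
#' @return an object of class `phasemc_packets`.
#' @export
packets <- function(x, y, z, ux, uy, uz, opl = 0, wavelength, amplitude = 1) {
  n <- length(x)
  nrm <- sqrt(ux^2 + uy^2 + uz^2)
  if (any(nrm == 0)) stop("zero-length direction vector", call. = FALSE)
  p <- list(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    ux = ux / nrm, uy = uy / nrm, uz = uz / nrm,
    opl = rep_len(as.numeric(opl), n),
    wavelength = rep_len(as.numeric(wavelength), n),
    amplitude = rep_len(as.numeric(amplitude), n),
    status = rep_len(PACKET_IN_FLIGHT, n)
  )
  if (any(p$amplitude < 0)) stop("amplitude must be non-negative", call. = FALSE)
  structure(p, class = "phasemc_packets")
}

#' Packet status codes
#'
#' `PACKET_IN_FLIGHT`, `PACKET_DETECTED`, `PACKET_DISCARDED`,
#' `PACKET_ABSORBED` are integer codes stored in the `status` field of
#' [packets()].
#'
#' @name packet_status
#' @export
PACKET_IN_FLIGHT <- 0L
#' @rdname packet_status
#' @export
PACKET_DETECTED <- 1L
#' @rdname packet_status
#' @export
PACKET_DISCARDED <- 2L
#' @rdname packet_status
#' @export
PACKET_ABSORBED <- 3L

#' @export
length.phasemc_packets <- function(x) length(x$x)

#' Optical properties of a homogeneous medium
#'
#' @param mu_s scattering coefficient, mm^-1 (numeric or unit string).
#' @param mu_a absorption coefficient, mm^-1 (numeric or unit string).
#' @param g Henyey-Greenstein anisotropy factor, strictly inside (-1, 1).
#' @param n refractive index, >= 1.
#' @return an object of class `optical_properties` with fields `mu_s`,
#'   `mu_a`, `mu_t` (all mm^-1), `g`, `n`.
#' @examples
#' optical_properties(mu_s = "557.14 m-1", mu_a = 0, g = 0.82, n = 1.33)
#' @export
optical_properties <- function(mu_s, mu_a = 0, g = 0, n = 1) {
  mu_s <- parse_inverse_length(mu_s)
  mu_a <- parse_inverse_length(mu_a)
  stopifnot(mu_s >= 0, mu_a >= 0, n >= 1)
  if (g <= -1 || g >= 1) stop("g must lie strictly inside (-1, 1)", call. = FALSE)
  structure(list(mu_s = mu_s, mu_a = mu_a, mu_t = mu_s + mu_a, g = g, n = n),
            class = "optical_properties")
}

#' Axis-aligned homogeneous slab (cuvette) medium
#'
#' The slab occupies `[x0, x0+Lx] x [y0, y0+Ly] x [z0, z0+Lz]` in the global
#' frame. Packets enter through the low-z ("back") face; the high-z face is
#' the "far" (detector-facing) face. Voxel indexing is 0-based with half-open
#' intervals `[i*dx, (i+1)*dx)`.
#'
#' @param extent length-3, slab dimensions in um (numbers or unit strings).
#' @param voxel_size length-3, voxel edge lengths in um; extent must be an
#'   integer multiple of the voxel size.
#' @param properties an [optical_properties()] object.
#' @param origin length-3, position of the low corner in um (default centred
#'   on the optical axis with the back face at z = 0).
#' @return an object of class `medium_slab`.
#' @export
medium_slab <- function(extent, voxel_size = NULL, properties,
                        origin = NULL) {
  extent <- parse_length(extent)
  stopifnot(length(extent) == 3, all(extent > 0))
  if (is.null(voxel_size)) voxel_size <- pmin(extent, 1)
  voxel_size <- parse_length(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  nvox <- extent / voxel_size
  if (any(abs(nvox - round(nvox)) > 1e-9)) {
    stop("extent must be an integer number of voxels", call. = FALSE)
  }
  if (is.null(origin)) origin <- c(-extent[1] / 2, -extent[2] / 2, 0)
  origin <- parse_length(origin)
  stopifnot(inherits(properties, "optical_properties"))
  structure(list(extent = extent, voxel_size = voxel_size,
                 n_voxels = as.integer(round(nvox)),
                 properties = properties, origin = origin),
            class = "medium_slab")
}

#' Map points to voxel indices (half-open convention)
#'
#' A point exactly on an internal boundary belongs to the higher-index voxel.
#'
#' @param medium a [medium_slab()].
#' @param x,y,z coordinates in the global frame, um.
#' @return integer matrix with columns `i`, `j`, `k` (0-based); rows are NA
#'   for points outside the slab.
#' @export
voxel_index <- function(medium, x, y, z) {
  i <- floor((x - medium$origin[1]) / medium$voxel_size[1])
  j <- floor((y - medium$origin[2]) / medium$voxel_size[2])
  k <- floor((z - medium$origin[3]) / medium$voxel_size[3])
  out <- cbind(i = i, j = j, k = k)
  bad <- i < 0 | j < 0 | k < 0 |
    i >= medium$n_voxels[1] | j >= medium$n_voxels[2] | k >= medium$n_voxels[3]
  out[bad, ] <- NA_integer_
  out
}

#' Create a complex field accumulator
#'
#' A field accumulator is a 2-D detector plane or a 3-D voxel volume of
#' complex bins. Packet fields (amplitude and phase) are summed per bin and
#' squared to intensity only at read-out, which is how interference is
#' represented: packets never meet at a point, they meet in a bin.
#'
#' Implemented as an environment so accumulation mutates in place.
#'
#' @param bin_counts integer vector, length 2 (plane) or 3 (volume).
#' @param bin_size numeric vector of bin edge lengths, um (recycled).
#' @param origin numeric vector, coordinates of the low corner, um
#'   (default: centred at zero in every axis).
#' @return an object of class `field_accumulator` with fields `values`
#'   (complex array), `power` (accumulated sum of E0^2 per bin, the
#'   incoherent reference), `bin_size`, `origin`, `n_added`, `n_clipped`.
#' @examples
#' acc <- make_field_accumulator(c(40, 40), bin_size = 1)
#' dim(acc$values)
#' @export
make_field_accumulator <- function(bin_counts, bin_size = 1, origin = NULL) {
  bin_counts <- as.integer(bin_counts)
  nd <- length(bin_counts)
  if (!nd %in% c(2L, 3L)) stop("bin_counts must have length 2 or 3", call. = FALSE)
  if (any(bin_counts <= 0L)) stop("bin counts must be positive", call. = FALSE)
  bin_size <- rep_len(parse_length(bin_size), nd)
  if (any(bin_size <= 0)) stop("bin sizes must be positive", call. = FALSE)
  if (is.null(origin)) origin <- -bin_counts * bin_size / 2
  origin <- rep_len(parse_length(origin), nd)
  acc <- new.env(parent = emptyenv())
  acc$values <- array(complex(real = 0, imaginary = 0), dim = bin_counts)
  acc$power <- array(0, dim = bin_counts)
  acc$bin_counts <- bin_counts
  acc$bin_size <- bin_size
  acc$origin <- origin
  acc$n_added <- 0
  acc$n_clipped <- 0
  class(acc) <- "field_accumulator"
  acc
}

#' Bin-centre coordinates of an accumulator axis
#'
#' @param acc a [make_field_accumulator()] object.
#' @param axis axis index (1-based).
#' @return numeric vector of bin centres, um.
#' @export
bin_centers <- function(acc, axis = 1) {
  acc$origin[axis] + (seq_len(acc$bin_counts[axis]) - 0.5) * acc$bin_size[axis]
}

#' Deterministic per-block substream seeds
#'
#' A run is fully determined by (config, seed, packet count). The packet
#' index space is split into fixed-size blocks and each block gets its own
#' seed derived from the run seed, so results do not depend on how blocks
#' are scheduled.
#'
#' @param seed integer run seed.
#' @param stream integer block/stream index (1-based).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m)
  v <- (s * 48271 + as.double(stream) * 22695477 + 12345) %% m
  as.integer(v %% (m - 1) + 1)
}

#' Default packet block size used by the vectorized engine
#' @keywords internal
.BLOCK <- 1000000L
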