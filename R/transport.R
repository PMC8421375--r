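#' Sample exponential free path lengths
#'
#' Standard MCRT step: `s = -ln(U) / mu_t` with `U ~ Uniform(0, 1]`.
#' `mu_t = 0` means free flight (infinite step, clipped at the boundary).
#'
#' @param mu_t total interaction coefficient, mm^-1.
#' @param n number of draws.
#' @return path lengths in um.
#' @export
sample_free_path <- function(mu_t, n = 1) {
  if (mu_t < 0) stop("mu_t must be non-negative", call. = FALSE)
  if (mu_t == 0) return(rep(Inf, n))
  u <- stats::runif(n)
  -log1p(-u) / (mu_t * 1e-3) # mm^-1 -> um^-1; 1-U ~ U avoids log(0)
}

#' Henyey-Greenstein scattering
#'
#' Draws a new unit direction: the deflection cosine comes from the
#' Henyey-Greenstein phase function with anisotropy `g` (mean cosine = g;
#' `g = 0` is isotropic), the azimuth is uniform. The rotation of the
#' deflected direction into the lab frame follows the usual MCML
#' construction, with the numerically degenerate near-vertical branch
#' handled separately.
#'
#' @param ux,uy,uz current unit direction components (vectors).
#' @param g anisotropy factor in (-1, 1).
#' @return list with new `ux`, `uy`, `uz`.
#' @export
scatter_direction <- function(ux, uy, uz, g) {
  n <- length(ux)
  u <- stats::runif(n)
  if (abs(g) < 1e-12) {
    ct <- 2 * u - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u)
    ct <- (1 + g^2 - tmp^2) / (2 * g)
  }
  ct <- pmax(-1, pmin(1, ct))
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(n, 0, 2 * pi)
  cp <- cos(phi); sp <- sin(phi)
  near_vert <- abs(uz) > 0.99999
  denom <- sqrt(pmax(1e-300, 1 - uz^2))
  nx <- st * (ux * uz * cp - uy * sp) / denom + ux * ct
  ny <- st * (uy * uz * cp + ux * sp) / denom + uy * ct
  nz <- -st * cp * denom + uz * ct
  # degenerate: direction along +/- z
  nx[near_vert] <- (st * cp)[near_vert]
  ny[near_vert] <- (st * sp)[near_vert]
  nz[near_vert] <- (sign(uz) * ct)[near_vert]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  list(ux = nx / nrm, uy = ny / nrm, uz = nz / nrm)
}

#' Advance packets along their direction
#'
#' Position moves by `distance * direction`; the optical path grows by
#' `n_medium * distance` (phase is always `2 pi * opl / lambda`).
#'
#' @param p a [packets()] object.
#' @param distance step lengths, um (vector or scalar).
#' @param n_medium refractive index of the medium traversed.
#' @return the updated packets object.
#' @export
advance <- function(p, distance, n_medium = 1) {
  stopifnot(all(distance >= 0))
  p$x <- p$x + distance * p$ux
  p$y <- p$y + distance * p$uy
  p$z <- p$z + distance * p$uz
  p$opl <- p$opl + n_medium * distance
  p
}

# distance to the slab boundary along the current direction, and which face
.slab_exit <- function(p, medium) {
  lo <- medium$origin
  hi <- medium$origin + medium$extent
  big <- 1e300
  tx <- ifelse(p$ux > 0, (hi[1] - p$x) / p$ux,
        ifelse(p$ux < 0, (lo[1] - p$x) / p$ux, big))
  ty <- ifelse(p$uy > 0, (hi[2] - p$y) / p$uy,
        ifelse(p$uy < 0, (lo[2] - p$y) / p$uy, big))
  tz <- ifelse(p$uz > 0, (hi[3] - p$z) / p$uz,
        ifelse(p$uz < 0, (lo[3] - p$z) / p$uz, big))
  t_exit <- pmin(tx, ty, tz)
  face <- ifelse(t_exit == tz & p$uz > 0, "far",
          ifelse(t_exit == tz & p$uz < 0, "back", "side"))
  list(t = pmax(0, t_exit), face = face)
}

#' Propagate packets through a scattering slab
#'
#' The usual MCRT loop with phase tracking: exponential steps against
#' `mu_t`, Henyey-Greenstein direction changes, absorption decided with
#' probability `mu_a/mu_t` per interaction (absorbed packets terminate; no
#' partial weights, so the coherent sum keeps a single well-defined phase
#' per packet). Steps that cross the slab boundary are clipped exactly to
#' the face; packets leaving through the far (detector-facing, high-z) face
#' are `detected`, all other exits are `discarded`. Boundaries are treated
#' as index-matched (no Fresnel reflection or refraction); the medium index
#' enters through the optical path only.
#'
#' @param p a [packets()] object, positioned on or inside the slab and
#'   directed into it.
#' @param medium a [medium_slab()].
#' @param max_events safety cap on interactions per packet.
#' @param record_planes optional numeric vector of z-planes (global frame)
#'   at which the in-medium field should be recorded; requires
#'   `accumulators`, a list of [make_field_accumulator()] (2-D, x/y) of the
#'   same length.
#' @param accumulators list of 2-D accumulators paired with
#'   `record_planes`.
#' @return list with the terminal packets object (`packets`), per-packet
#'   `events` counts, and tallies `n_detected`, `n_discarded`,
#'   `n_absorbed`, `n_maxed`.
#' @export
propagate_in_medium <- function(p, medium, max_events = 10000L,
                                record_planes = NULL, accumulators = NULL) {
  props <- medium$properties
  mu_t <- props$mu_t
  n_med <- props$n
  n <- length(p)
  events <- integer(n)
  alive <- rep(TRUE, n)
  repeat {
    idx <- which(alive)
    if (length(idx) == 0) break
    m <- length(idx)
    s <- sample_free_path(mu_t, m)
    ex <- .slab_exit(list(x = p$x[idx], y = p$y[idx], z = p$z[idx],
                          ux = p$ux[idx], uy = p$uy[idx], uz = p$uz[idx]),
                     medium)
    step <- pmin(s, ex$t)
    if (!is.null(record_planes)) {
      for (j in seq_along(record_planes)) {
        zj <- record_planes[j]
        dz <- p$uz[idx]
        tt <- (zj - p$z[idx]) / dz
        crosses <- is.finite(tt) & tt >= 0 & tt < step & dz != 0
        if (any(crosses)) {
          ii <- idx[crosses]
          tc <- tt[crosses]
          accumulate(accumulators[[j]],
                     x = p$x[ii] + tc * p$ux[ii],
                     y = p$y[ii] + tc * p$uy[ii],
                     opl = p$opl[ii] + n_med * tc,
                     amplitude = p$amplitude[ii],
                     wavelength = p$wavelength[ii])
        }
      }
    }
    p$x[idx] <- p$x[idx] + step * p$ux[idx]
    p$y[idx] <- p$y[idx] + step * p$uy[idx]
    p$z[idx] <- p$z[idx] + step * p$uz[idx]
    p$opl[idx] <- p$opl[idx] + n_med * step
    exits <- s >= ex$t
    if (any(exits)) {
      ie <- idx[exits]
      face <- ex$face[exits]
      p$status[ie] <- ifelse(face == "far", PACKET_DETECTED, PACKET_DISCARDED)
      alive[ie] <- FALSE
    }
    inter <- idx[!exits]
    if (length(inter) > 0) {
      events[inter] <- events[inter] + 1L
      if (props$mu_a > 0) {
        absorbed <- stats::runif(length(inter)) < props$mu_a / mu_t
      } else {
        absorbed <- rep(FALSE, length(inter))
      }
      ia <- inter[absorbed]
      if (length(ia) > 0) {
        p$status[ia] <- PACKET_ABSORBED
        alive[ia] <- FALSE
      }
      is_ <- inter[!absorbed]
      if (length(is_) > 0) {
        nd <- scatter_direction(p$ux[is_], p$uy[is_], p$uz[is_], props$g)
        p$ux[is_] <- nd$ux; p$uy[is_] <- nd$uy; p$uz[is_] <- nd$uz
      }
      over <- inter[events[inter] >= max_events & alive[inter]]
      if (length(over) > 0) {
        warning("packets exceeded max_events; discarded", call. = FALSE)
        p$status[over] <- PACKET_DISCARDED
        alive[over] <- FALSE
      }
    }
  }
  list(packets = p, events = events,
       n_detected = sum(p$status == PACKET_DETECTED),
       n_discarded = sum(p$status == PACKET_DISCARDED),
       n_absorbed = sum(p$status == PACKET_ABSORBED),
       n_maxed = sum(events >= max_events))
}
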