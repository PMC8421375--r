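#' Complex field carried by a packet
#'
#' `E = E0 * exp(2 pi i * opl / lambda)`: unit-modulus phase from the
#' accumulated optical path length times the launch amplitude.
#'
#' @param amplitude packet amplitude E0.
#' @param opl optical path length, um.
#' @param wavelength vacuum wavelength, um.
#' @return complex field value(s), modulus `E0`.
#' @export
packet_field <- function(amplitude, opl, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  ph <- 2 * pi * opl / wavelength
  complex(real = amplitude * cos(ph), imaginary = amplitude * sin(ph))
}

#' Coherently accumulate packet fields into bins
#'
#' Each packet contributes its complex field to exactly the bin containing
#' its hit point; hits outside the accumulator extent are counted in
#' `n_clipped` and ignored. For a 2-D accumulator the hit point is (x, y);
#' a 3-D accumulator also needs `z`.
#'
#' @param acc a [make_field_accumulator()] object (modified in place).
#' @param x,y,z hit coordinates, um.
#' @param opl optical path lengths, um.
#' @param amplitude packet amplitudes.
#' @param wavelength vacuum wavelength(s), um.
#' @return the accumulator, invisibly.
#' @export
accumulate <- function(acc, x, y, z = NULL, opl, amplitude, wavelength) {
  nb <- acc$bin_counts
  i <- floor((x - acc$origin[1]) / acc$bin_size[1])
  j <- floor((y - acc$origin[2]) / acc$bin_size[2])
  inside <- i >= 0 & i < nb[1] & j >= 0 & j < nb[2]
  if (length(nb) == 3L) {
    if (is.null(z)) stop("3-D accumulator needs z", call. = FALSE)
    k <- floor((z - acc$origin[3]) / acc$bin_size[3])
    inside <- inside & k >= 0 & k < nb[3]
  }
  acc$n_clipped <- acc$n_clipped + sum(!inside)
  if (!any(inside)) return(invisible(acc))
  w <- which(inside)
  idx <- i[w] + nb[1] * j[w] + 1
  if (length(nb) == 3L) idx <- idx + nb[1] * nb[2] * k[w]
  amplitude <- rep_len(amplitude, length(x))[w]
  wavelength <- rep_len(wavelength, length(x))[w]
  ph <- 2 * pi * opl[w] / wavelength
  sums <- rowsum(cbind(amplitude * cos(ph), amplitude * sin(ph), amplitude^2),
                 group = idx, reorder = FALSE)
  at <- as.integer(rownames(sums))
  acc$values[at] <- acc$values[at] +
    complex(real = sums[, 1], imaginary = sums[, 2])
  acc$power[at] <- acc$power[at] + sums[, 3]
  acc$n_added <- acc$n_added + length(w)
  invisible(acc)
}

#' Convert an accumulated field to an intensity image
#'
#' Per-bin `|field|^2`, optionally normalized to the brightest bin
#' (`max_pixel`), which is how simulated and experimental images are
#' compared.
#'
#' @param acc a [make_field_accumulator()] object.
#' @param normalization `"raw"` or `"max_pixel"`.
#' @return object of class `intensity_image`: list with `values`
#'   (non-negative array), `incoherent` (sum of E0^2 per bin), `bin_size`,
#'   `origin`, `normalization`, `all_zero` flag.
#' @export
to_intensity <- function(acc, normalization = c("raw", "max_pixel")) {
  normalization <- match.arg(normalization)
  v <- Mod(acc$values)^2
  all_zero <- max(v) == 0
  if (normalization == "max_pixel") {
    if (all_zero) {
      warning("all-zero field; returning raw zeros", call. = FALSE)
    } else {
      v <- v / max(v)
    }
  }
  structure(list(values = v, incoherent = acc$power,
                 bin_size = acc$bin_size, origin = acc$origin,
                 normalization = normalization, all_zero = all_zero,
                 n_added = acc$n_added, n_clipped = acc$n_clipped),
            class = "intensity_image")
}

#' Coherent excess of an accumulated field
#'
#' Per-bin `|sum E|^2 - sum E0^2`: the interference term of the coherent
#' sum. With randomized phases its expectation is zero, so it is the
#' unbiased estimator of the deterministic (phase-structured) intensity on
#' top of the incoherent speckle/noise floor. Used when weak coherent
#' structure must be separated from the Monte Carlo floor at modest packet
#' counts.
#'
#' @param acc a [make_field_accumulator()] object.
#' @return numeric array (can be negative where noise dominates).
#' @export
coherent_excess <- function(acc) {
  Mod(acc$values)^2 - acc$power
}

#' Extract a row/column line profile from an intensity image
#'
#' @param image an [to_intensity()] result (2-D).
#' @param axis `"x"` (profile along x at fixed y-row) or `"y"`.
#' @param index 1-based bin index of the fixed coordinate; defaults to the
#'   central row/column.
#' @return data frame with `coord` (bin centres, um) and `intensity`.
#' @export
line_profile <- function(image, axis = c("x", "y"), index = NULL) {
  axis <- match.arg(axis)
  dims <- dim(image$values)
  if (length(dims) != 2L) stop("line_profile needs a 2-D image", call. = FALSE)
  fixed_dim <- if (axis == "x") 2L else 1L
  if (is.null(index)) index <- (dims[fixed_dim] + 1L) %/% 2L
  if (index < 1L || index > dims[fixed_dim]) {
    stop("profile index out of bounds", call. = FALSE)
  }
  vals <- if (axis == "x") image$values[, index] else image$values[index, ]
  free_dim <- if (axis == "x") 1L else 2L
  coord <- image$origin[free_dim] +
    (seq_len(dims[free_dim]) - 0.5) * image$bin_size[free_dim]
  data.frame(coord = coord, intensity = vals)
}

#' Azimuthally averaged radial profile
#'
#' Averages a 2-D intensity image over annuli about the optical axis
#' (x = y = 0), the standard reduction for Bessel-beam ring systems.
#'
#' @param image an [to_intensity()] result (2-D).
#' @param dr annulus width, um (default: one bin).
#' @return data frame with `r` (annulus centre, um), `intensity` (mean),
#'   `n` (bins per annulus).
#' @export
radial_profile <- function(image, dr = NULL) {
  dims <- dim(image$values)
  if (is.null(dr)) dr <- image$bin_size[1]
  xc <- image$origin[1] + (seq_len(dims[1]) - 0.5) * image$bin_size[1]
  yc <- image$origin[2] + (seq_len(dims[2]) - 0.5) * image$bin_size[2]
  rr <- sqrt(outer(xc^2, yc^2, "+"))
  shell <- floor(rr / dr)
  means <- tapply(as.vector(image$values), as.vector(shell), mean)
  counts <- tapply(as.vector(image$values), as.vector(shell), length)
  ks <- as.numeric(names(means))
  data.frame(r = (ks + 0.5) * dr, intensity = as.numeric(means),
             n = as.integer(counts))
}
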