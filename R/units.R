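#' Unit handling
#'
#' All internal lengths are micrometres (um). Configuration files and spec
#' constructors accept either bare numbers (already in the internal unit) or
#' strings with an explicit unit suffix, e.g. `"488 nm"`, `"2 mm"`,
#' `"557.14 m-1"`, `"5 deg"`. Powers are stored in watts.
#'
#' @name phasemc-units
NULL

.length_factors <- c(
  nm = 1e-3, um = 1, mm = 1e3, cm = 1e4, m = 1e6,
  "µm" = 1, "μm" = 1
)

.split_quantity <- function(x) {
  x <- trimws(x)
  m <- regexec("^([-+0-9.eE]+)[[:space:]]*(.*)$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L || parts[2] == "") {
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(value)) stop("cannot parse quantity: '", x, "'", call. = FALSE)
  list(value = value, unit = trimws(parts[3]))
}

#' Parse a length into micrometres
#'
#' @param x numeric (already in um) or a string with a unit suffix
#'   (`nm`, `um`, `mm`, `cm`, `m`).
#' @return numeric, micrometres.
#' @examples
#' parse_length("488 nm")
#' parse_length("2 mm")
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    q <- .split_quantity(s)
    if (q$unit == "") return(q$value)
    f <- unname(.length_factors[q$unit])
    if (is.na(f)) stop("unknown length unit: '", q$unit, "'", call. = FALSE)
    q$value * f
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse an inverse length (attenuation coefficient) into per-millimetre
#'
#' Scattering/absorption coefficients are stored in mm^-1.
#'
#' @param x numeric (already mm^-1) or string such as `"557.14 m-1"`,
#'   `"2 mm-1"`, `"0.02 um-1"`.
#' @return numeric, mm^-1.
#' @export
parse_inverse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  factors <- c("m-1" = 1e-3, "mm-1" = 1, "um-1" = 1e3, "cm-1" = 1e-1,
               "/m" = 1e-3, "/mm" = 1, "/um" = 1e3, "/cm" = 1e-1)
  vapply(as.character(x), function(s) {
    q <- .split_quantity(s)
    if (q$unit == "") return(q$value)
    f <- unname(factors[q$unit])
    if (is.na(f)) stop("unknown inverse-length unit: '", q$unit, "'", call. = FALSE)
    q$value * f
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse an angle into radians
#'
#' @param x numeric (radians) or string such as `"5 deg"`, `"0.1 rad"`.
#' @return numeric, radians.
#' @export
parse_angle <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    q <- .split_quantity(s)
    if (q$unit == "" || q$unit == "rad") return(q$value)
    if (q$unit == "deg") return(q$value * pi / 180)
    stop("unknown angle unit: '", q$unit, "'", call. = FALSE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse a power into watts
#'
#' @param x numeric (watts) or string such as `"1 mW"`.
#' @return numeric, watts.
#' @export
parse_power <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  factors <- c(W = 1, mW = 1e-3, uW = 1e-6, nW = 1e-9, kW = 1e3)
  vapply(as.character(x), function(s) {
    q <- .split_quantity(s)
    if (q$unit == "") return(q$value)
    f <- unname(factors[q$unit])
    if (is.na(f)) stop("unknown power unit: '", q$unit, "'", call. = FALSE)
    q$value * f
  }, numeric(1), USE.NAMES = FALSE)
}
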