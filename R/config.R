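#' Load an experiment configuration from YAML
#'
#' The file has sections `source`, `element`, `medium` (optional),
#' `detector`, `run`; all lengths carry unit suffixes (`nm`, `um`, `mm`,
#' `m`), angles may use `deg`, attenuation coefficients `m-1`/`mm-1`. The
#' element section is discriminated by `kind`: `slit_pair`,
#' `square_aperture`, `planoconvex_lens` or `axicon`. A medium section may
#' give `mu_s` directly or an `intralipid_volume_ul` (stock volume in 500 uL
#' of water, converted with [intralipid_dilution()]).
#'
#' @param path YAML file path, or a list with the same structure.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (sec in c("source", "element", "detector", "run")) {
    if (is.null(cfg[[sec]])) stop("config missing [", sec, "] section", call. = FALSE)
  }
  src <- cfg$source
  beam <- beam_spec(wavelength = src$wavelength,
                    power = if (is.null(src$power)) "1 mW" else src$power,
                    profile = if (is.null(src$profile)) "plane" else src$profile,
                    e2_width = src$e2_width, area = src$area)
  el <- cfg$element
  element <- switch(el$kind,
    slit_pair = slit_pair_spec(el$slit_width, el$separation,
                               el$screen_distance, el$screen_extent,
                               if (is.null(el$slit_length)) 10 else el$slit_length),
    square_aperture = square_aperture_spec(el$side, el$screen_distance),
    planoconvex_lens = planoconvex_lens_spec(el$radius, el$thickness,
                                             el$roc, el$n_lens),
    axicon = axicon_spec(el$alpha, el$radius, el$n_lens,
                         if (is.null(el$helical_order)) 0L else el$helical_order,
                         el$thickness),
    stop("unknown element kind: ", el$kind, call. = FALSE)
  )
  det <- cfg$detector
  if (is.null(det$distance)) {
    det$distance <- if (!is.null(element$screen_distance))
      element$screen_distance else stop("detector needs a distance", call. = FALSE)
  }
  if (!is.null(det$ylim)) det$ylim <- parse_length(det$ylim)
  medium <- NULL
  if (!is.null(cfg$medium)) {
    md <- cfg$medium
    mu_s <- if (!is.null(md$intralipid_volume_ul)) {
      intralipid_dilution(md$intralipid_volume_ul, 500,
                          scaling = if (is.null(md$scaling)) "table" else md$scaling)$mu_s_mm
    } else {
      md$mu_s
    }
    medium <- list(
      thickness = md$thickness, width = md$width, height = md$height,
      distance = md$distance,
      entry_window = md$entry_window,
      properties = optical_properties(
        mu_s = mu_s,
        mu_a = if (is.null(md$mu_a)) 0 else md$mu_a,
        g = if (is.null(md$g)) 0.82 else md$g,
        n = if (is.null(md$n)) 1.33 else md$n))
  }
  experiment_config(source = beam, element = element, detector = det,
                    medium = medium, run = cfg$run)
}

#' Write run outputs to disk
#'
#' Writes the intensity image as CSV (and TIFF when the `tiff` package is
#' available), the central line profile as CSV, and a JSON metadata sidecar
#' (config digest, seed, packet counts).
#'
#' @param result a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
write_run_outputs <- function(result, dir, name = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- result$image
  paths <- c()
  csv <- file.path(dir, paste0(name, "_image.csv"))
  utils::write.table(img$values, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  paths <- c(paths, csv)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tf <- file.path(dir, paste0(name, "_image.tif"))
    v <- img$values
    tiff::writeTIFF(v / max(v, 1e-300), tf, bits.per.sample = 16L)
    paths <- c(paths, tf)
  }
  prof <- line_profile(img, "x")
  pcsv <- file.path(dir, paste0(name, "_profile.csv"))
  utils::write.csv(prof, pcsv, row.names = FALSE)
  paths <- c(paths, pcsv)
  meta <- list(
    seed = result$config$run$seed,
    n_packets = result$config$run$n_packets,
    counts = result$counts,
    normalization = img$normalization,
    bin_size_um = img$bin_size,
    element_kind = result$config$element$kind
  )
  js <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, js)
  invisible(paths)
}
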