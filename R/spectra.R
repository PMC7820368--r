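#' Construct a spectrum object
#'
#' A spectrum is a sampled function of wavelength: floral or foliage
#' reflectance (unitless fraction in \[0, 1\]), downwelling irradiance
#' (photon flux, arbitrary positive units), or a photoreceptor spectral
#' sensitivity.
#'
#' @param wl numeric vector of wavelengths in nm, strictly increasing.
#' @param value numeric vector, same length as \code{wl}; finite.
#'   Reflectance values must be non-negative.
#' @param kind one of \code{"reflectance"}, \code{"irradiance"},
#'   \code{"sensitivity"}.
#' @return an object of class \code{"spectrum"}: a list with elements
#'   \code{wl}, \code{value} and \code{kind}.
#' @export
spectrum <- function(wl, value, kind = c("reflectance", "irradiance", "sensitivity")) {
  kind <- match.arg(kind)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) != length(value))
    stop("wavelength and value vectors differ in length")
  if (length(wl) < 2L)
    stop("a spectrum needs at least two samples")
  if (any(!is.finite(wl)) || any(!is.finite(value)))
    stop("non-finite wavelengths or values")
  if (any(diff(wl) <= 0))
    stop("non-monotone wavelengths")
  if (kind != "irradiance" && any(value < 0))
    stop(sprintf("negative %s values", kind))
  if (kind == "irradiance" && any(value < 0))
    stop("negative irradiance values")
  structure(list(wl = wl, value = value, kind = kind), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %g-%g nm, range [%g, %g]>\n",
              x$kind, length(x$wl), min(x$wl), max(x$wl),
              min(x$value), max(x$value)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Read a two-column wavelength/value table
#'
#' Reads one measurement file: a delimited text table whose first column is
#' wavelength (nm) and second column is the measured value. The dialect
#' declares whether reflectance is recorded in percent (0-100, the common
#' spectrometer convention) or as a fraction (0-1), and the field delimiter.
#' Rows outside 300-700 nm are retained so they can support interpolation.
#' Small negative readings (instrument noise near zero reflectance) are
#' clipped to zero with a warning.
#'
#' @param path path to the file.
#' @param unit \code{"percent"} (default) or \code{"fraction"}; ignored for
#'   irradiance and sensitivity kinds.
#' @param sep field delimiter (default comma).
#' @param header logical, whether the file has a one-line header.
#' @param kind spectrum kind, see [spectrum()].
#' @return a [spectrum()] in internal units (reflectance as fraction 0-1).
#' @export
read_spectrum <- function(path, unit = c("percent", "fraction"), sep = ",",
                          header = TRUE, kind = "reflectance") {
  unit <- match.arg(unit)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = TRUE, comment.char = "")
  if (ncol(raw) < 2L)
    stop(sprintf("'%s': expected two columns, found %d", path, ncol(raw)))
  wl <- suppressWarnings(as.numeric(raw[[1L]]))
  val <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(wl) | is.na(val))
  if (length(bad)) {
    line <- bad[1L] + if (header) 1L else 0L
    stop(sprintf("'%s': non-numeric row at line %d", path, line))
  }
  if (any(diff(wl) <= 0))
    stop(sprintf("'%s': non-monotone wavelengths", path))
  if (kind == "reflectance") {
    if (unit == "percent") val <- val / 100
    if (any(val < 0)) {
      warning(sprintf("'%s': %d negative reflectance value(s) clipped to 0",
                      path, sum(val < 0)))
      val[val < 0] <- 0
    }
  }
  spectrum(wl, val, kind = kind)
}

#' Resample a spectrum onto the analysis grid
#'
#' Linear interpolation onto a regular wavelength grid, by default
#' 300-700 nm at 1 nm. No extrapolation is performed: the source spectrum
#' must cover the whole grid.
#'
#' @param s a [spectrum()].
#' @param step grid step in nm; must divide the grid span.
#' @param lower,upper grid end points in nm.
#' @return a [spectrum()] sampled exactly at
#'   \code{seq(lower, upper, by = step)}.
#' @export
resample_spectrum <- function(s, step = 1, lower = 300, upper = 700) {
  stopifnot(is_spectrum(s), step > 0)
  if (((upper - lower) / step) %% 1 != 0)
    stop("grid step does not divide the grid span")
  grid <- seq(lower, upper, by = step)
  lo <- min(s$wl); hi <- max(s$wl)
  if (lo > lower || hi < upper) {
    parts <- character(0)
    if (lo > lower) parts <- c(parts, sprintf("%g-%g", lower, min(lo, upper)))
    if (hi < upper) parts <- c(parts, sprintf("%g-%g", max(hi, lower), upper))
    stop(sprintf("source support narrower than the grid: uncovered range %s",
                 paste(parts, collapse = ", ")))
  }
  value <- stats::approx(s$wl, s$value, xout = grid, method = "linear")$y
  spectrum(grid, value, kind = s$kind)
}

#' Weighted pointwise average of spectra
#'
#' Composites several spectra on an identical grid into one by a pointwise
#' weighted mean. Used (a) unweighted, to average replicate measurements or
#' foliage spectra into a background, and (b) weighted by floral display
#' area, to merge the differently colored components of a floral unit into
#' one representative spectrum per species. Weights are renormalised to
#' sum to one.
#'
#' @param parts list of [spectrum()] objects on the identical wavelength
#'   grid and of the same kind.
#' @param weights optional non-negative weights, one per part; equal
#'   weights when omitted.
#' @return a [spectrum()] on the same grid.
#' @export
composite_spectrum <- function(parts, weights = NULL) {
  if (!length(parts) || !all(vapply(parts, is_spectrum, logical(1))))
    stop("'parts' must be a non-empty list of spectrum objects")
  wl <- parts[[1L]]$wl
  kind <- parts[[1L]]$kind
  for (p in parts) {
    if (!identical(p$kind, kind)) stop("mixed spectrum kinds")
    if (length(p$wl) != length(wl) || any(p$wl != wl))
      stop("mismatched wavelength grids")
  }
  if (is.null(weights)) weights <- rep(1, length(parts))
  if (length(weights) != length(parts))
    stop("one weight per part required")
  if (any(weights < 0)) stop("negative weights")
  tot <- sum(weights)
  if (tot <= 0) stop("all-zero weights")
  w <- weights / tot
  vals <- vapply(parts, function(p) p$value, numeric(length(wl)))
  spectrum(wl, drop(vals %*% w), kind = kind)
}

#' Composite per-species spectra from a measurement manifest
#'
#' Applies the two-stage averaging convention: replicate measurements are
#' averaged within each floral-unit component, then components are merged
#' by their display-area weights. Species with a single uniformly colored
#' floral unit have one component with weight 1. Component weights must
#' sum to 1 per species (tolerance 1e-9).
#'
#' @param measurements named list of [spectrum()] objects, all on one grid,
#'   keyed by measurement id.
#' @param manifest data.frame with columns \code{measurement} (key into
#'   \code{measurements}), \code{species}, \code{component},
#'   \code{area_weight}.
#' @return named list of one composite reflectance [spectrum()] per species.
#' @export
species_composites <- function(measurements, manifest) {
  need <- c("measurement", "species", "component", "area_weight")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns measurement, species, component, area_weight")
  missing <- setdiff(manifest$measurement, names(measurements))
  if (length(missing))
    stop(sprintf("measurements absent from the supplied list: %s",
                 paste(missing, collapse = ", ")))
  out <- list()
  for (sp in unique(manifest$species)) {
    rows <- manifest[manifest$species == sp, , drop = FALSE]
    comp_tab <- unique(rows[, c("component", "area_weight")])
    if (anyDuplicated(comp_tab$component))
      stop(sprintf("species '%s': conflicting area weights within a component", sp))
    if (abs(sum(comp_tab$area_weight) - 1) > 1e-9)
      stop(sprintf("species '%s': component area weights sum to %.10f, not 1",
                   sp, sum(comp_tab$area_weight)))
    comps <- lapply(comp_tab$component, function(cc) {
      reps <- rows$measurement[rows$component == cc]
      composite_spectrum(measurements[reps])
    })
    out[[sp]] <- composite_spectrum(comps, weights = comp_tab$area_weight)
  }
  out
}

#' Write / read a wide per-species spectra table
#'
#' The wide CSV has a \code{wl} column followed by one column per species,
#' all on one common grid; it is the on-disk exchange format for composite
#' spectra.
#'
#' @param spectra named list of [spectrum()] objects on an identical grid.
#' @param path output CSV path.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) > 0)
  wl <- spectra[[1L]]$wl
  df <- data.frame(wl = wl)
  for (nm in names(spectra)) {
    if (any(spectra[[nm]]$wl != wl)) stop("mismatched wavelength grids")
    df[[nm]] <- spectra[[nm]]$value
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param kind spectrum kind for the columns being read.
#' @export
read_spectra_csv <- function(path, kind = "reflectance") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "wl") stop("first column must be 'wl'")
  out <- lapply(df[-1L], function(v) spectrum(df$wl, v, kind = kind))
  names(out) <- names(df)[-1L]
  out
}
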