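# 1D slice extraction: emission and excitation spectra pulled out of the
# 2D matrix at a fixed conjugate wavelength, with nearest-existing-
# wavelength semantics and X-axis windowing.

# Nearest grid wavelength to a request.  Ties (a request exactly midway
# between grid points) resolve to the lower wavelength; requests outside
# the axis range clamp to the nearest endpoint with a warning.
.nearest_wavelength <- function(axis, requested, what) {
  if (requested < min(axis) || requested > max(axis))
    warning(sprintf(
      "requested %s %g nm lies outside the axis range %g-%g nm; using the nearest endpoint",
      what, requested, min(axis), max(axis)), call. = FALSE)
  i <- which.min(abs(axis - requested))  # first minimum = lower wavelength
  i
}

#' Extract a 1D emission spectrum at a fixed excitation wavelength
#'
#' Selects the excitation row nearest to `excited_at` (if the requested
#' wavelength does not exist in the spectral array the nearest existing
#' wavelength is used) and returns its acquired emission points within
#' `[x_min, x_max]`, as if a conventional single-excitation emission scan
#' had been run.  Zero-filled, unmeasured cells are never emitted.
#'
#' @param x An [eem()].
#' @param excited_at Requested excitation wavelength (nm).
#' @param x_min,x_max Emission window (nm); defaults span the whole axis.
#' @return A [spectrum1d()] whose `used` field records the row actually
#'   chosen.
#' @examples
#' e <- triangular_to_rectangular(simulate_eem(
#'   hras_plan(), hras_preset()$components, hras_preset()$scatter))
#' emission_slice(e, excited_at = 360)
#' @export
emission_slice <- function(x, excited_at, x_min = -Inf, x_max = Inf) {
  stopifnot(inherits(x, "eem"))
  if (x_min > x_max) stop("x_min must not exceed x_max", call. = FALSE)
  i <- .nearest_wavelength(x$excitation, excited_at, "excitation wavelength")
  keep <- x$acquired[i, ] & x$emission >= x_min & x$emission <= x_max
  if (!any(keep))
    stop("empty slice: no acquired emission points for excitation ",
         x$excitation[i], " nm in [", x_min, ", ", x_max, "] nm",
         call. = FALSE)
  spectrum1d("emission", requested = excited_at, used = x$excitation[i],
             wavelength = x$emission[keep], intensity = x$intensity[i, keep])
}

#' Extract a 1D excitation spectrum at a fixed emission wavelength
#'
#' Column-wise analogue of [emission_slice()]: fixes the emission
#' (detection) wavelength nearest to `detected_at` and returns the acquired
#' cells of that column within `[x_min, x_max]`.  An excitation slice stops
#' where the Rayleigh diagonal truncates the column, since nothing is
#' measured at excitation wavelengths at or above the detection wavelength.
#'
#' @param x An [eem()].
#' @param detected_at Requested emission wavelength (nm).
#' @param x_min,x_max Excitation window (nm).
#' @return A [spectrum1d()].
#' @export
excitation_slice <- function(x, detected_at, x_min = -Inf, x_max = Inf) {
  stopifnot(inherits(x, "eem"))
  if (x_min > x_max) stop("x_min must not exceed x_max", call. = FALSE)
  j <- .nearest_wavelength(x$emission, detected_at, "emission wavelength")
  keep <- x$acquired[, j] & x$excitation >= x_min & x$excitation <= x_max
  if (!any(keep))
    stop("empty slice: no acquired excitation points for emission ",
         x$emission[j], " nm in [", x_min, ", ", x_max, "] nm",
         call. = FALSE)
  spectrum1d("excitation", requested = detected_at, used = x$emission[j],
             wavelength = x$excitation[keep], intensity = x$intensity[keep, j])
}

#' Export a 1D slice as a two-column text file
#'
#' Writes tab-separated (wavelength, intensity) pairs at full precision so
#' the slice can be analysed further in any other software.  The file name
#' embeds the slice kind and the wavelength actually used, e.g.
#' `em_slice_ex_360nm.txt` for an emission spectrum excited at 360 nm.
#'
#' @param s A [spectrum1d()].
#' @param directory Output directory (created if missing).
#' @return The path, invisibly.
#' @export
export_slice <- function(s, directory) {
  stopifnot(inherits(s, "spectrum1d"))
  if (!nzchar(directory))
    stop("filesystem error: empty directory path", call. = FALSE)
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  path <- file.path(directory, slice_filename(s))
  writeLines(paste(.fmt(as.numeric(s$wavelength)), .fmt(s$intensity),
                   sep = "\t"), path)
  invisible(path)
}

slice_filename <- function(s, ext = "txt") {
  stem <- if (s$kind == "emission")
    sprintf("em_slice_ex_%gnm", s$used)
  else
    sprintf("ex_slice_em_%gnm", s$used)
  paste0(stem, ".", ext)
}

#' Read back an exported slice file
#'
#' @param path File written by [export_slice()].
#' @return A data frame with columns `wavelength` and `intensity`.
#' @export
read_slice <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("wavelength", "intensity"),
                          colClasses = c("numeric", "numeric"))
  df
}
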