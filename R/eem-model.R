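# Core data types: wavelength axes, triangular scan sets, rectangular EEMs
# and 1D slices, plus the triangular <-> rectangular conversion everything
# else builds on.

# Tolerance for deciding that a wavelength sits on a uniform grid.  Grids are
# in nanometres, so 1e-9 nm is far below any physical resolution.
.grid_tol <- 1e-9

#' Validate a wavelength axis
#'
#' A wavelength axis is a strictly increasing, uniformly spaced numeric
#' vector of positive wavelengths in nanometres.  Uniformity is checked
#' against the implied (or supplied) step to within 1e-9 nm.
#'
#' @param values Numeric vector of wavelengths (nm).
#' @param step Grid increment in nm.  If `NULL` it is inferred from the
#'   first difference; a single-point axis needs an explicit step only when
#'   a caller depends on it.
#' @param what Label used in error messages.
#' @return The validated numeric vector with the step attached as the
#'   `"step"` attribute (possibly `NA` for a lone point with no step given).
#' @keywords internal
wavelength_axis <- function(values, step = NULL, what = "wavelength axis") {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop(what, " is empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop(what, " must contain finite positive wavelengths", call. = FALSE)
  if (length(values) > 1L) {
    d <- diff(values)
    if (any(d <= 0))
      stop(what, " must be strictly increasing", call. = FALSE)
    if (is.null(step)) step <- d[1L]
    if (any(abs(d - step) > .grid_tol))
      stop(what, " is not uniform: consecutive steps differ from ", step,
           " nm by more than 1e-9 nm", call. = FALSE)
  } else if (is.null(step)) {
    step <- NA_real_
  }
  structure(values, step = as.numeric(step))
}

axis_step <- function(axis) attr(axis, "step")

# Index of `wl` on a uniform grid starting at `origin` with increment `step`;
# errors if `wl` is off-grid.  Used by the triangular -> rectangular placement
# so no interpolation can ever occur.
.grid_index <- function(wl, origin, step, what = "wavelength") {
  idx <- round((wl - origin) / step) + 1L
  if (any(abs(origin + (idx - 1L) * step - wl) > .grid_tol))
    stop("grid mismatch: ", what, " ",
         paste(format(wl[abs(origin + (idx - 1L) * step - wl) > .grid_tol]),
               collapse = ", "),
         " nm not on the grid (origin ", origin, " nm, step ", step, " nm)",
         call. = FALSE)
  as.integer(idx)
}

#' Construct a triangular scan set
#'
#' A triangular scan set is the data object produced by the accelerated
#' acquisition scheme: one emission trace per excitation wavelength, where
#' each trace starts above its excitation wavelength (the region at or below
#' the Rayleigh line is never measured) and all traces end at one common
#' maximum emission wavelength on one common step.
#'
#' @param rows List of rows, each a list with elements `excitation` (nm,
#'   scalar), `emission` (numeric vector, nm) and `intensity` (numeric
#'   vector, counts per second, same length as `emission`).
#' @param channel `"raw"` or `"corrected"` -- which fluorometer channel the
#'   intensities came from.
#' @param step Emission grid step in nm; inferred from the rows when any row
#'   has two or more points, required otherwise.
#' @return An object of class `triangular_scans`.
#' @examples
#' ts <- triangular_scan_set(list(
#'   list(excitation = 200, emission = c(210, 220), intensity = c(1, 2)),
#'   list(excitation = 210, emission = 220, intensity = 3)
#' ), channel = "corrected")
#' ts
#' @export
triangular_scan_set <- function(rows, channel = c("corrected", "raw"),
                                step = NULL) {
  channel <- match.arg(channel)
  if (length(rows) == 0L)
    stop("a triangular scan set needs at least one row", call. = FALSE)
  ex <- vapply(rows, function(r) as.numeric(r$excitation[1L]), numeric(1))
  if (any(diff(ex) <= 0))
    stop("excitation wavelengths must be strictly increasing across rows",
         call. = FALSE)
  if (is.null(step)) {
    for (r in rows) {
      if (length(r$emission) > 1L) { step <- diff(r$emission)[1L]; break }
    }
  }
  em_max <- vapply(rows, function(r) max(r$emission), numeric(1))
  if (max(em_max) - min(em_max) > .grid_tol)
    stop("malformed scan: rows do not share one maximum emission wavelength",
         call. = FALSE)
  rows <- lapply(rows, function(r) {
    em <- wavelength_axis(r$emission, step = step, what = "emission axis")
    y <- as.numeric(r$intensity)
    if (length(y) != length(em))
      stop("malformed scan: intensity and emission lengths differ in row at ",
           r$excitation, " nm excitation", call. = FALSE)
    if (min(em) <= r$excitation + .grid_tol)
      stop("emission must begin above the excitation wavelength (row at ",
           r$excitation, " nm)", call. = FALSE)
    list(excitation = as.numeric(r$excitation[1L]), emission = em,
         intensity = y)
  })
  if (is.null(step)) {
    # every row is a single point; fall back to excitation spacing
    if (length(ex) > 1L) step <- diff(ex)[1L]
    else stop("cannot infer the grid step: supply `step`", call. = FALSE)
  }
  structure(list(rows = rows, channel = channel, step = as.numeric(step)),
            class = "triangular_scans")
}

#' @export
print.triangular_scans <- function(x, ...) {
  ex <- vapply(x$rows, `[[`, numeric(1), "excitation")
  npts <- sum(vapply(x$rows, function(r) length(r$intensity), integer(1)))
  cat(sprintf(
    "Triangular scan set (%s channel): %d excitation rows (%g-%g nm), %d points, %g nm step\n",
    x$channel, length(x$rows), min(ex), max(ex), npts, x$step))
  invisible(x)
}

#' Construct a rectangular excitation-emission matrix
#'
#' @param excitation Excitation axis (rows, Y), nm.
#' @param emission Emission axis (columns, X), nm.
#' @param intensity Numeric matrix, `length(excitation)` x
#'   `length(emission)`, counts per second.
#' @param acquired Logical matrix of the same shape marking measured cells.
#'   Unacquired cells must hold intensity 0, and no cell at or below the
#'   Rayleigh diagonal (emission <= excitation) may be acquired.
#' @param channel Channel label carried along for provenance.
#' @return An object of class `eem` with fields `excitation`, `emission`,
#'   `intensity`, `acquired`, `channel`.
#' @export
eem <- function(excitation, emission, intensity, acquired, channel = "corrected") {
  excitation <- wavelength_axis(excitation, what = "excitation axis")
  emission <- wavelength_axis(emission, what = "emission axis")
  intensity <- as.matrix(intensity)
  acquired <- as.matrix(acquired)
  storage.mode(acquired) <- "logical"
  if (!all(dim(intensity) == c(length(excitation), length(emission))) ||
      !all(dim(acquired) == dim(intensity)))
    stop("intensity/acquired shape must be n_excitation x n_emission",
         call. = FALSE)
  if (any(intensity[!acquired] != 0))
    stop("unacquired cells must hold the zero-fill value 0", call. = FALSE)
  below <- outer(excitation, emission, function(x, m) m <= x + .grid_tol)
  if (any(acquired & below))
    stop("cells at or below the Rayleigh diagonal (emission <= excitation) ",
         "cannot be acquired", call. = FALSE)
  structure(list(excitation = excitation, emission = emission,
                 intensity = intensity, acquired = acquired,
                 channel = channel),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf(
    "EEM (%s): %d excitation x %d emission (%g-%g / %g-%g nm), %d acquired cells\n",
    x$channel, length(x$excitation), length(x$emission),
    min(x$excitation), max(x$excitation), min(x$emission), max(x$emission),
    sum(x$acquired)))
  if (any(x$acquired))
    cat(sprintf("  acquired intensity range: %g to %g counts/s\n",
                min(x$intensity[x$acquired]), max(x$intensity[x$acquired])))
  invisible(x)
}

#' @export
dim.eem <- function(x) dim(x$intensity)

#' Convert a triangular scan set to a rectangular EEM
#'
#' Rebuilds the rectangular matrix commercial plotting software expects by
#' placing every measured trace at its exact emission wavelengths and filling
#' the unmeasured upper spectral triangle with a constant zero.  The emission
#' axis spans from the first excitation wavelength to the common maximum
#' emission wavelength on the common step, so the Rayleigh diagonal
#' (emission = excitation) lies inside the grid.  This is a pure reshaping:
#' no resampling or interpolation ever occurs, and an off-grid emission
#' wavelength is an error.
#'
#' A separate `acquired` mask distinguishes "not measured" (zero-filled) from
#' "measured zero", so downstream statistics such as the contour-scale
#' maximum are never distorted by unmeasured cells.
#'
#' @param scans A [triangular_scan_set()].
#' @return An [eem()].
#' @examples
#' plan <- acquisition_plan("triangular", ex_start = 200, ex_end = 790,
#'                          em_end = 800, step = 10)
#' e <- triangular_to_rectangular(simulate_eem(plan))
#' dim(e)            # 60 x 61
#' sum(e$acquired)   # 1830
#' @export
triangular_to_rectangular <- function(scans) {
  stopifnot(inherits(scans, "triangular_scans"))
  step <- scans$step
  ex <- vapply(scans$rows, `[[`, numeric(1), "excitation")
  em_max <- max(scans$rows[[1L]]$emission)
  em0 <- ex[1L]
  n_em <- .grid_index(em_max, em0, step, "maximum emission wavelength")
  emission <- em0 + (seq_len(n_em) - 1L) * step
  intensity <- matrix(0, nrow = length(ex), ncol = n_em)
  acquired <- matrix(FALSE, nrow = length(ex), ncol = n_em)
  for (i in seq_along(scans$rows)) {
    r <- scans$rows[[i]]
    if (abs(axis_step(r$emission) - step) > .grid_tol &&
        length(r$emission) > 1L)
      stop("malformed scan: row at ", r$excitation,
           " nm uses a different emission step", call. = FALSE)
    j <- .grid_index(r$emission, em0, step, "emission wavelength")
    if (any(j < 1L | j > n_em))
      stop("grid mismatch: emission wavelength outside the global grid",
           call. = FALSE)
    intensity[i, j] <- r$intensity
    acquired[i, j] <- TRUE
  }
  eem(ex, emission, intensity, acquired, channel = scans$channel)
}

#' Convert a rectangular EEM back to a triangular scan set
#'
#' Inverse of [triangular_to_rectangular()]: returns exactly the acquired
#' cells as per-row traces.  Rows with no acquired cells are dropped.  For
#' any valid input, converting back to rectangular reproduces the original
#' matrix bit-exactly (provided every row had at least one acquired cell and
#' the emission axis starts at the first excitation wavelength).
#'
#' @param x An [eem()].
#' @return A [triangular_scan_set()].
#' @export
rectangular_to_triangular <- function(x) {
  stopifnot(inherits(x, "eem"))
  rows <- list()
  for (i in seq_along(x$excitation)) {
    j <- which(x$acquired[i, ])
    if (length(j) == 0L) next
    rows[[length(rows) + 1L]] <- list(
      excitation = x$excitation[i],
      emission = x$emission[j],
      intensity = x$intensity[i, j])
  }
  if (length(rows) == 0L)
    stop("matrix has no acquired cells", call. = FALSE)
  triangular_scan_set(rows, channel = x$channel,
                      step = axis_step(x$emission))
}

#' Construct a 1D spectrum (an emission or excitation slice)
#'
#' @param kind `"emission"` or `"excitation"`.
#' @param requested The wavelength the user asked to fix (nm).
#' @param used The nearest existing wavelength actually used (nm).
#' @param wavelength Numeric vector: the running axis of the slice (nm).
#' @param intensity Counts per second, same length as `wavelength`.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(kind = c("emission", "excitation"), requested, used,
                       wavelength, intensity) {
  kind <- match.arg(kind)
  wavelength <- wavelength_axis(wavelength, what = "slice axis")
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavelength))
    stop("intensity and wavelength lengths differ", call. = FALSE)
  structure(list(kind = kind, requested = as.numeric(requested),
                 used = as.numeric(used), wavelength = wavelength,
                 intensity = intensity),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  fixed <- if (x$kind == "emission") "excited at" else "detected at"
  kind <- paste0(toupper(substring(x$kind, 1, 1)), substring(x$kind, 2))
  cat(sprintf("%s spectrum, %s %g nm (requested %g nm): %d points, %g-%g nm\n",
              kind, fixed, x$used, x$requested,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.spectrum1d <- function(x, ...) {
  data.frame(wavelength = as.numeric(x$wavelength), intensity = x$intensity)
}
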