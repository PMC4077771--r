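# Baseline / difference subtraction, percent-of-scale contour levels,
# scatter-artifact annotation, and peak picking.

#' Subtract a baseline (or reference) EEM
#'
#' Elementwise `sample - baseline` over the cells acquired in both matrices.
#' Used to remove background fluorescence and instrumental artifacts with a
#' buffer-only measurement, or to form a difference spectrum between two
#' related samples or time points -- negative differences are therefore
#' preserved, never clipped.  The two matrices must share exactly equal
#' axes: spectra subtracted against each other are measured on the same
#' programme, so no resampling is offered and an axis mismatch is an error.
#'
#' @param sample,baseline [eem()] objects on identical axes.
#' @return An [eem()] whose acquired mask is the intersection of the two
#'   input masks; all other cells are zero-filled.
#' @export
subtract_baseline <- function(sample, baseline) {
  stopifnot(inherits(sample, "eem"), inherits(baseline, "eem"))
  if (length(sample$excitation) != length(baseline$excitation) ||
      length(sample$emission) != length(baseline$emission) ||
      any(sample$excitation != baseline$excitation) ||
      any(sample$emission != baseline$emission))
    stop("incompatible axes: sample and baseline must share identical ",
         "excitation and emission axes (no interpolation is performed)",
         call. = FALSE)
  acquired <- sample$acquired & baseline$acquired
  intensity <- matrix(0, nrow = nrow(sample$intensity),
                      ncol = ncol(sample$intensity))
  intensity[acquired] <- sample$intensity[acquired] -
    baseline$intensity[acquired]
  eem(sample$excitation, sample$emission, intensity, acquired,
      channel = sample$channel)
}

#' Contour specification in percent of the intensity scale
#'
#' @param lowest_percent,highest_percent Bounds of the displayed interval as
#'   percent of the full intensity scale (0 to 100), ordered.
#' @param n_levels Number of contour levels, at least 1.
#' @return An object of class `contour_spec`.
#' @export
contour_spec <- function(lowest_percent, highest_percent, n_levels) {
  if (lowest_percent < 0 || highest_percent > 100 ||
      lowest_percent > highest_percent)
    stop("need 0 <= lowest_percent <= highest_percent <= 100", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be at least 1", call. = FALSE)
  structure(list(lowest_percent = lowest_percent,
                 highest_percent = highest_percent, n_levels = n_levels),
            class = "contour_spec")
}

#' Compute contour levels as fractions of the acquired-cell maximum
#'
#' "Percent of the full intensity scale" means percent of the maximum
#' intensity over *acquired* cells -- the zero-filled, unmeasured triangle
#' never distorts the scale.  Levels are `n_levels` values evenly spaced
#' from `lowest_percent/100 * M` to `highest_percent/100 * M` where `M` is
#' that (signed) maximum; multiplying all intensities by a positive constant
#' scales every level by the same constant.
#'
#' @param x An [eem()] with at least one acquired cell.
#' @param spec A [contour_spec()].
#' @return Numeric vector of `n_levels` non-decreasing intensity levels.
#' @examples
#' plan <- acquisition_plan("triangular", 200, 790, em_end = 800, step = 10)
#' e <- triangular_to_rectangular(
#'   simulate_eem(plan, fluorophore_component(280, 330, 12, 12, 1000)))
#' contour_levels(e, contour_spec(0, 10, 5))
#' @export
contour_levels <- function(x, spec) {
  stopifnot(inherits(x, "eem"), inherits(spec, "contour_spec"))
  if (!any(x$acquired))
    stop("empty matrix: no acquired cells to scale contours against",
         call. = FALSE)
  m <- max(x$intensity[x$acquired])
  if (spec$n_levels == 1L)
    return(spec$lowest_percent / 100 * m)
  seq(spec$lowest_percent / 100 * m, spec$highest_percent / 100 * m,
      length.out = spec$n_levels)
}

#' Wavelength of the water Raman ridge
#'
#' Raman scatter appears at a fixed wavenumber shift below the excitation
#' line: `1/lambda_raman = 1/lambda_ex - shift` with wavelengths in cm.
#' In nm: `1e7 / (1e7/lambda_ex - shift)`.
#'
#' @param ex_nm Excitation wavelength(s) in nm.
#' @param shift_cm Raman shift in 1/cm (water O-H stretch: about 3400).
#' @return Raman center wavelength(s) in nm; `NA` where the shift exceeds
#'   the excitation wavenumber (no physical solution).
#' @examples
#' raman_wavelength(350, 3400)  # about 397 nm
#' @export
raman_wavelength <- function(ex_nm, shift_cm = 3400) {
  denom <- 1e7 / ex_nm - shift_cm
  out <- ifelse(denom > 0, 1e7 / denom, NA_real_)
  out
}

#' Annotate scatter artifacts in an EEM
#'
#' Marks the cells lying on the three stray-light ridges every grating
#' fluorometer shows: the first-order (Rayleigh) reflection around
#' emission = excitation, the second-order grating reflection around
#' emission = 2 x excitation, and the water Raman ridge running at a small
#' angle to the Rayleigh line.  Masks are pure geometry -- intensities play
#' no role -- and may overlap.
#'
#' @param x An [eem()].
#' @param w1,w2,w3 Half-widths (nm, >= 0) of the first-order, second-order
#'   and Raman bands: a cell is marked when its emission wavelength is
#'   within the half-width of the ridge center.
#' @param raman_shift Raman shift in 1/cm.
#' @return An object of class `scatter_annotation`: logical matrices
#'   `first_order`, `second_order`, `raman` of the EEM's shape, plus the
#'   widths used.
#' @export
annotate_scatter <- function(x, w1 = 10, w2 = 10, w3 = 10,
                             raman_shift = 3400) {
  stopifnot(inherits(x, "eem"))
  if (w1 < 0 || w2 < 0 || w3 < 0)
    stop("widths must be nonnegative", call. = FALSE)
  ex <- x$excitation
  em <- x$emission
  first_order <- outer(ex, em, function(x_, m) abs(m - x_) <= w1)
  second_order <- outer(ex, em, function(x_, m) abs(m - 2 * x_) <= w2)
  rc <- raman_wavelength(ex, raman_shift)
  raman <- matrix(FALSE, nrow = length(ex), ncol = length(em))
  ok <- which(is.finite(rc))
  for (i in ok) raman[i, ] <- abs(em - rc[i]) <= w3
  structure(list(first_order = first_order, second_order = second_order,
                 raman = raman, w1 = w1, w2 = w2, w3 = w3,
                 raman_shift = raman_shift),
            class = "scatter_annotation")
}

#' @export
print.scatter_annotation <- function(x, ...) {
  cat(sprintf(
    "Scatter annotation: %d first-order, %d second-order, %d Raman cells (half-widths %g/%g/%g nm, shift %g 1/cm)\n",
    sum(x$first_order), sum(x$second_order), sum(x$raman),
    x$w1, x$w2, x$w3, x$raman_shift))
  invisible(x)
}

#' Find fluorophore peaks away from scatter ridges
#'
#' Local maxima over the 8-neighborhood among acquired cells not covered by
#' any scatter mask, keeping those at or above `threshold_percent` of the
#' maximum intensity over the candidate (acquired, unmasked) cells.  A cell
#' must strictly exceed all of its in-grid neighbours, so plateaus and flat
#' matrices yield no peaks.
#'
#' @param x An [eem()].
#' @param annotation A [scatter_annotation()] for the same matrix, or `NULL`
#'   to consider every acquired cell.
#' @param threshold_percent Keep peaks with intensity at least this percent
#'   of the candidate-cell maximum (0-100).
#' @return A data frame with columns `excitation`, `emission`, `intensity`,
#'   sorted by decreasing intensity; zero rows when nothing qualifies.
#' @export
find_peaks <- function(x, annotation = NULL, threshold_percent = 10) {
  stopifnot(inherits(x, "eem"))
  if (threshold_percent < 0 || threshold_percent > 100)
    stop("threshold_percent must lie in [0, 100]", call. = FALSE)
  candidate <- x$acquired
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "scatter_annotation"))
    if (any(dim(annotation$first_order) != dim(x$intensity)))
      stop("annotation shape does not match the matrix", call. = FALSE)
    candidate <- candidate & !annotation$first_order &
      !annotation$second_order & !annotation$raman
  }
  empty <- data.frame(excitation = numeric(0), emission = numeric(0),
                      intensity = numeric(0))
  if (!any(candidate)) return(empty)
  m <- max(x$intensity[candidate])
  thr <- threshold_percent / 100 * m
  nr <- nrow(x$intensity); nc <- ncol(x$intensity)
  hits <- list()
  idx <- which(candidate & x$intensity >= thr, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    v <- x$intensity[i, j]
    nb <- expand.grid(ii = i + (-1:1), jj = j + (-1:1))
    nb <- nb[!(nb$ii == i & nb$jj == j) &
               nb$ii >= 1L & nb$ii <= nr & nb$jj >= 1L & nb$jj <= nc, ]
    if (all(x$intensity[cbind(nb$ii, nb$jj)] < v))
      hits[[length(hits) + 1L]] <- data.frame(
        excitation = x$excitation[i], emission = x$emission[j], intensity = v)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out[order(-out$intensity), , drop = FALSE]
}
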