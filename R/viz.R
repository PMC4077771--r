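# Plotting: 2D contour maps and 1D slices, base graphics, blue-to-red
# default colormap, with the Rayleigh diagonal drawn as a separator between
# the measured region and the zero-filled triangle.

#' Blue-to-red sequential colormap
#'
#' @param n Number of colors, at least 1.
#' @return Character vector of `n` colors.
#' @export
blue_red_colormap <- function(n) {
  grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(n)
}

.resolve_colormap <- function(name, n) {
  switch(name,
         blue_red = , default = blue_red_colormap(n),
         grey = , gray = grDevices::gray.colors(n, start = 0.9, end = 0.1),
         heat = grDevices::heat.colors(n),
         terrain = grDevices::terrain.colors(n),
         topo = grDevices::topo.colors(n),
         stop("settings error: unknown colormap '", name, "'",
              call. = FALSE))
}

#' Contour plot of an EEM
#'
#' Draws the intensity matrix as contour lines with emission on X and
#' excitation on Y, the field's standard orientation.  Contour levels come
#' from [contour_levels()], so what is drawn is exactly the percent-of-scale
#' interval requested.  By default a solid diagonal line marks
#' emission = excitation, separating the measured lower-right region from
#' the zero-filled triangle.
#'
#' @param x An [eem()].
#' @param spec A [contour_spec()]; default 0-100% with 20 levels.
#' @param colormap Colormap name (see [blue_red_colormap()]); default the
#'   blue-to-red map.
#' @param diagonal Draw the Rayleigh diagonal separator line.
#' @param main Plot title.
#' @param ... Passed to [graphics::contour()].
#' @return The numeric contour levels used, invisibly.
#' @export
plot.eem <- function(x, spec = contour_spec(0, 100, 20),
                     colormap = "blue_red", diagonal = TRUE,
                     main = "2D fluorescence spectrum", ...) {
  levels <- contour_levels(x, spec)
  cols <- .resolve_colormap(colormap, length(levels))
  graphics::contour(x = as.numeric(x$emission), y = as.numeric(x$excitation),
                    z = t(x$intensity), levels = unique(levels), col = cols,
                    xlab = "Emission wavelength (nm)",
                    ylab = "Excitation wavelength (nm)",
                    main = main, drawlabels = FALSE, ...)
  if (diagonal)
    graphics::abline(a = 0, b = 1, col = "black", lwd = 1.5)
  invisible(levels)
}

#' Line plot of a 1D slice
#'
#' @param x A [spectrum1d()].
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.spectrum1d <- function(x, ...) {
  fixed <- if (x$kind == "emission") "excitation" else "emission"
  graphics::plot(as.numeric(x$wavelength), x$intensity, type = "l",
                 xlab = sprintf("%s wavelength (nm)",
                                if (x$kind == "emission") "Emission"
                                else "Excitation"),
                 ylab = "Intensity (counts/s)",
                 main = sprintf("1D %s spectrum (%s %g nm)",
                                x$kind, fixed, x$used), ...)
  invisible(x)
}

#' Export a figure in the standard file family
#'
#' Renders a plotting closure into four files: a high-resolution PNG for
#' documents, a low-resolution PNG for web pages, an EPS vector file, and a
#' serialized figure-data file (an RDS holding the plotted objects) for
#' later programmatic re-display and adjustment.  Resolutions default to
#' 300 and 72 dpi.
#'
#' @param draw A zero-argument function that draws the figure.
#' @param basename Output file stem (contour percents or slice wavelengths
#'   are embedded by the callers).
#' @param directory Output directory (created if missing).
#' @param figure_data Object to serialize alongside the graphics.
#' @param hi_dpi,lo_dpi PNG resolutions.
#' @return Character vector of the four paths, invisibly.
#' @export
export_graphics <- function(draw, basename, directory, figure_data = NULL,
                            hi_dpi = 300, lo_dpi = 72) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  stem <- file.path(directory, basename)
  paths <- c(hi = paste0(stem, "_hires.png"),
             lo = paste0(stem, "_lores.png"),
             eps = paste0(stem, ".eps"),
             fig = paste0(stem, "_figdata.rds"))
  for (nm in c("hi", "lo")) {
    dpi <- if (nm == "hi") hi_dpi else lo_dpi
    grDevices::png(paths[[nm]], width = 7 * dpi, height = 5.5 * dpi,
                   res = dpi)
    ok <- try(draw(), silent = TRUE)
    grDevices::dev.off()
    if (inherits(ok, "try-error")) stop(attr(ok, "condition"))
  }
  grDevices::postscript(paths[["eps"]], width = 7, height = 5.5,
                        horizontal = FALSE, onefile = FALSE,
                        paper = "special")
  draw()
  grDevices::dev.off()
  saveRDS(figure_data, paths[["fig"]])
  invisible(unname(paths))
}
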