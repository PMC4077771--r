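# The analysis settings ledger and the one-shot driver that ties the
# modules together: read the converted data folder, optionally subtract a
# baseline, then draw/export a 2D contour map or a 1D slice.  The settings
# are a plain key = value text file (deliberately no GUI), so a run is
# adjust-settings / re-launch.

.settings_defaults <- function() {
  list(
    dname = "",
    baseline_name = "",
    baseline_correction = "no",
    lowest_contour_percent = 0,
    highest_contour_percent = 100,
    mode = "2D",
    graphics_export = "off",
    colormap_name = "blue_red",
    n_colors = 20L,
    emission_spectrum_excited_at = NA_real_,
    emission_spectrum_x_min = -Inf,
    emission_spectrum_x_max = Inf,
    excitation_spectrum_detected_at = NA_real_,
    excitation_spectrum_x_min = -Inf,
    excitation_spectrum_x_max = Inf)
}

#' Build an analysis settings object
#'
#' Mirrors the six setting groups of the analysis driver: (1) data source
#' and baseline, with contour percents; (2) operation mode; (3) graphics
#' export switch; (4) 2D colormap and number of contours; (5) 1D emission
#' slice parameters; (6) 1D excitation slice parameters.
#'
#' @param ... Named settings overriding the defaults; see
#'   [read_settings()] for the full key list.
#' @return An object of class `analysis_settings`.
#' @examples
#' s <- analysis_settings(dname = tempdir(), mode = "2D",
#'                        lowest_contour_percent = 3,
#'                        highest_contour_percent = 13)
#' @export
analysis_settings <- function(...) {
  s <- .settings_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(s))
  if (length(unknown) > 0L)
    stop("settings error: unknown setting(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  s[names(over)] <- over
  s$n_colors <- as.integer(s$n_colors)
  if (!s$mode %in% c("2D", "1D emission slice", "1D excitation slice"))
    stop("settings error: mode must be '2D', '1D emission slice' or ",
         "'1D excitation slice'", call. = FALSE)
  if (!s$baseline_correction %in% c("yes", "no"))
    stop("settings error: baseline_correction must be 'yes' or 'no'",
         call. = FALSE)
  if (!s$graphics_export %in% c("on", "off"))
    stop("settings error: graphics_export must be 'on' or 'off'",
         call. = FALSE)
  if (s$lowest_contour_percent < 0 || s$highest_contour_percent > 100 ||
      s$lowest_contour_percent > s$highest_contour_percent)
    stop("settings error: contour percents must satisfy 0 <= lowest <= ",
         "highest <= 100", call. = FALSE)
  if (s$n_colors < 1L)
    stop("settings error: n_colors must be at least 1", call. = FALSE)
  if (s$mode == "1D emission slice" &&
      s$emission_spectrum_x_min > s$emission_spectrum_x_max)
    stop("settings error: emission slice window has x_min > x_max",
         call. = FALSE)
  if (s$mode == "1D excitation slice" &&
      s$excitation_spectrum_x_min > s$excitation_spectrum_x_max)
    stop("settings error: excitation slice window has x_min > x_max",
         call. = FALSE)
  structure(s, class = "analysis_settings")
}

#' Read analysis settings from a plain-text file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment and
#' blank lines are ignored.  Keys are the names of [analysis_settings()]
#' arguments: `dname`, `baseline_name`, `baseline_correction`,
#' `lowest_contour_percent`, `highest_contour_percent`, `mode`,
#' `graphics_export`, `colormap_name`, `n_colors`,
#' `emission_spectrum_excited_at`, `emission_spectrum_x_min`,
#' `emission_spectrum_x_max`, `excitation_spectrum_detected_at`,
#' `excitation_spectrum_x_min`, `excitation_spectrum_x_max`.
#'
#' @param path Settings file path.
#' @param ... Overrides applied on top of the file values (as from CLI
#'   flags).
#' @return An [analysis_settings()] object.
#' @export
read_settings <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  numeric_keys <- c("lowest_contour_percent", "highest_contour_percent",
                    "n_colors", "emission_spectrum_excited_at",
                    "emission_spectrum_x_min", "emission_spectrum_x_max",
                    "excitation_spectrum_detected_at",
                    "excitation_spectrum_x_min", "excitation_spectrum_x_max")
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE))
      stop("settings error: expected 'key = value', got: ", line,
           call. = FALSE)
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    val <- gsub("^['\"]|['\"]$", "", val)
    if (key %in% numeric_keys) val <- as.numeric(val)
    kv[[key]] <- val
  }
  over <- list(...)
  kv[names(over)] <- over
  do.call(analysis_settings, kv)
}

#' @export
print.analysis_settings <- function(x, ...) {
  cat("Analysis settings:\n")
  for (k in names(unclass(x)))
    cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Run one analysis pass over a converted data folder
#'
#' Loads the rectangular matrix from `settings$dname`, optionally subtracts
#' the baseline folder `settings$baseline_name` (writing
#' `spectral_intensity_baseline_corrected.txt` into `dname` whenever the
#' subtraction is on), and dispatches on `settings$mode`:
#'
#' * `"2D"` -- a contour figure at the requested percent interval with
#'   `n_colors` levels; exported file names embed the contour percents, so
#'   re-runs at different levels build up a family of comparable files.
#' * `"1D emission slice"` / `"1D excitation slice"` -- a slice figure plus
#'   a two-column text export; file names embed the wavelength used.
#'
#' With `graphics_export = "off"` (the recommended setting for trial runs
#' while contour levels are being adjusted) no graphics or slice files are
#' written.  Figures are drawn on screen only in interactive sessions;
#' non-interactively the plot is still composed and returned.
#'
#' @param settings An [analysis_settings()] object.
#' @return Invisibly, a list with the loaded `eem`, the `result` (contour
#'   levels or the slice), and `files` written (possibly empty).
#' @export
run_analysis <- function(settings) {
  stopifnot(inherits(settings, "analysis_settings"))
  if (!dir.exists(settings$dname))
    stop("data folder not found: ", settings$dname, call. = FALSE)
  x <- read_matrix_files(settings$dname)
  files <- character(0)
  if (settings$baseline_correction == "yes") {
    if (!dir.exists(settings$baseline_name))
      stop("baseline folder not found: ", settings$baseline_name,
           call. = FALSE)
    b <- read_matrix_files(settings$baseline_name)
    x <- subtract_baseline(x, b)
    p <- write_baseline_corrected(x, settings$dname)
    message("wrote ", p)
    files <- c(files, p)
  }
  export_on <- settings$graphics_export == "on"
  if (settings$mode == "2D") {
    spec <- contour_spec(settings$lowest_contour_percent,
                         settings$highest_contour_percent,
                         settings$n_colors)
    draw <- function() plot(x, spec = spec,
                            colormap = settings$colormap_name)
    levels <- contour_levels(x, spec)
    if (interactive()) draw()
    if (export_on) {
      base <- sprintf("eem2d_contours_%g_to_%g_pct",
                      settings$lowest_contour_percent,
                      settings$highest_contour_percent)
      gp <- export_graphics(draw, base, settings$dname,
                            figure_data = list(eem = x, spec = spec,
                                               levels = levels))
      for (p in gp) message("wrote ", p)
      files <- c(files, gp)
    }
    result <- levels
  } else {
    s <- if (settings$mode == "1D emission slice") {
      emission_slice(x, settings$emission_spectrum_excited_at,
                     settings$emission_spectrum_x_min,
                     settings$emission_spectrum_x_max)
    } else {
      excitation_slice(x, settings$excitation_spectrum_detected_at,
                       settings$excitation_spectrum_x_min,
                       settings$excitation_spectrum_x_max)
    }
    if (s$used != s$requested)
      message(sprintf("requested %g nm not in the array; using nearest %g nm",
                      s$requested, s$used))
    draw <- function() plot(s)
    if (interactive()) draw()
    if (export_on) {
      p_txt <- export_slice(s, settings$dname)
      message("wrote ", p_txt)
      base <- sub("\\.txt$", "", slice_filename(s))
      gp <- export_graphics(draw, base, settings$dname,
                            figure_data = list(slice = s))
      for (p in gp) message("wrote ", p)
      files <- c(files, p_txt, gp)
    }
    result <- s
  }
  invisible(list(eem = x, result = result, files = files))
}
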