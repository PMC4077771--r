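# Reading and writing the plain-text interchange formats: the fluorometer
# group-export dialect (raw + corrected channels) and the four matrix /
# axis files that downstream plotting consumes.
#
# The group-export dialect implemented here is a documented stand-in for
# the vendor layout (which is not publicly specified): a header line per
# trace, "raw:ex=<nm>" or "corr:ex=<nm>", followed by two-column numeric
# lines (emission nm, intensity) separated by a tab or comma.  Raw traces
# precede corrected traces.  CRLF line endings and leading/trailing blank
# lines are tolerated.

.channel_tag <- function(channel) {
  switch(channel, raw = "raw", corrected = "corr",
         stop("unknown channel ", channel, call. = FALSE))
}

# Full-precision serialization so write/read round trips are bit-exact for
# all finite doubles (17 significant digits uniquely identify a double).
.fmt <- function(x) sprintf("%.17g", x)

#' Parse a fluorometer group-export file into a triangular scan set
#'
#' Reads a plain-text group export containing the raw intensities followed
#' by the corrected data and extracts the requested channel, one scan row
#' per trace, sorted by excitation wavelength.  Choosing raw vs corrected
#' changes intensities only, never wavelengths.  Generally the corrected
#' channel is the one to analyse, since the instrument has already applied
#' its time- and wavelength-dependent corrections; the raw channel is for
#' customised corrections.
#'
#' @param path Path to the export file (or a character vector of its lines
#'   via `text`).
#' @param channel `"corrected"` (default) or `"raw"`.
#' @param text Optional character vector of lines, instead of `path`.
#' @return A [triangular_scan_set()].
#' @export
parse_export <- function(path, channel = c("corrected", "raw"), text = NULL) {
  channel <- match.arg(channel)
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("parse error: export file is empty", call. = FALSE)
  tag <- .channel_tag(channel)
  header_re <- "^(raw|corr):ex=([0-9.]+)$"
  rows <- list()
  cur <- NULL   # list(tag, ex, em, y, header_line)
  flush <- function() {
    if (is.null(cur)) return()
    if (cur$tag == tag) {
      if (length(cur$em) == 0L)
        stop("parse error: trace at line ", cur$header_line,
             " has no data points", call. = FALSE)
      rows[[length(rows) + 1L]] <<- list(excitation = cur$ex,
                                         emission = cur$em,
                                         intensity = cur$y)
    }
  }
  seen_channels <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl(header_re, line)) {
      flush()
      m <- regmatches(line, regexec(header_re, line))[[1L]]
      seen_channels <- union(seen_channels, m[2L])
      cur <- list(tag = m[2L], ex = as.numeric(m[3L]),
                  em = numeric(0), y = numeric(0), header_line = ln)
    } else {
      if (is.null(cur))
        stop("parse error at line ", ln, ": data before any trace header",
             call. = FALSE)
      fields <- strsplit(line, "[\t,]")[[1L]]
      fields <- fields[nzchar(trimws(fields))]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 2L || any(is.na(vals)))
        stop("parse error at line ", ln,
             ": expected two numeric columns (emission nm, intensity)",
             call. = FALSE)
      cur$em <- c(cur$em, vals[1L])
      cur$y <- c(cur$y, vals[2L])
    }
  }
  flush()
  if (length(rows) == 0L) {
    if (!tag %in% seen_channels)
      stop("channel not found: no '", tag, "' traces in the export ",
           "(present: ", paste(seen_channels, collapse = ", "), ")",
           call. = FALSE)
    stop("parse error: no usable traces", call. = FALSE)
  }
  rows <- rows[order(vapply(rows, `[[`, numeric(1), "excitation"))]
  triangular_scan_set(rows, channel = channel)
}

#' Write a triangular scan set as a group-export file
#'
#' Emits the documented export dialect with the raw traces first and the
#' corrected traces after them, so [parse_export()] can be exercised end to
#' end against simulated data.  By default the corrected channel simply
#' duplicates the raw one.
#'
#' @param scans A [triangular_scan_set()]: the corrected channel.
#' @param path Output file path.
#' @param raw Optional [triangular_scan_set()] for the raw channel; defaults
#'   to the same traces as `scans`.
#' @return The path, invisibly.
#' @export
write_export <- function(scans, path, raw = NULL) {
  stopifnot(inherits(scans, "triangular_scans"))
  if (is.null(raw)) raw <- scans
  stopifnot(inherits(raw, "triangular_scans"))
  emit <- function(ts, tag) {
    unlist(lapply(ts$rows, function(r) {
      c(sprintf("%s:ex=%s", tag, format(r$excitation)),
        paste(.fmt(as.numeric(r$emission)), .fmt(r$intensity), sep = "\t"))
    }))
  }
  writeLines(c(emit(raw, "raw"), emit(scans, "corr")), path)
  invisible(path)
}

#' Write the rectangular EEM as its three plain-text files
#'
#' Creates `spectral_intensity.txt` (the rectangular intensity matrix, one
#' whitespace-delimited line per excitation row), `emission_wavelengths_Xaxis.txt`
#' and `excitation_wavelengths_Yaxis.txt` (the column and row wavelength
#' arrays).  Values carry full double precision so a re-read reproduces the
#' matrix bit-exactly.  The plain-text contract makes converters for other
#' instruments easy to add.
#'
#' @param x An [eem()].
#' @param directory Output directory (created if missing).
#' @return Character vector of the three paths, invisibly.
#' @export
write_matrix_files <- function(x, directory) {
  stopifnot(inherits(x, "eem"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- file.path(directory, c("spectral_intensity.txt",
                                  "emission_wavelengths_Xaxis.txt",
                                  "excitation_wavelengths_Yaxis.txt"))
  writeLines(apply(x$intensity, 1L, function(r) paste(.fmt(r), collapse = "\t")),
             paths[1L])
  writeLines(.fmt(as.numeric(x$emission)), paths[2L])
  writeLines(.fmt(as.numeric(x$excitation)), paths[3L])
  invisible(paths)
}

#' Read a converted-matrix directory back into an EEM
#'
#' Reads the three files written by [write_matrix_files()].  The acquired
#' mask is not serialized (the interchange files carry none), so it is
#' rebuilt from the zero-fill convention: a cell is acquired exactly when
#' its emission wavelength exceeds its excitation wavelength (the region
#' below the Rayleigh diagonal, where data are measured).  Two corner cases
#' are thereby unrepresentable: a measured value at or above the diagonal,
#' and an unmeasured cell below it (as arises with an emission offset larger
#' than one step) -- the latter re-reads as an acquired zero.
#'
#' @param directory Directory holding the three files.
#' @param intensity_file Name of the matrix file; override to read the
#'   baseline-corrected matrix alongside the shared axis files.
#' @param channel Channel label for the result.
#' @return An [eem()].
#' @export
read_matrix_files <- function(directory,
                              intensity_file = "spectral_intensity.txt",
                              channel = "corrected") {
  paths <- file.path(directory, c(intensity_file,
                                  "emission_wavelengths_Xaxis.txt",
                                  "excitation_wavelengths_Yaxis.txt"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("consistency error: missing file(s) ",
         paste(basename(missing), collapse = ", "), " in ", directory,
         call. = FALSE)
  emission <- scan(paths[2L], quiet = TRUE)
  excitation <- scan(paths[3L], quiet = TRUE)
  lines <- readLines(paths[1L], warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l) scan(text = l, quiet = TRUE))
  if (length(vals) != length(excitation) ||
      any(lengths(vals) != length(emission)))
    stop("consistency error: matrix shape does not match the axis files",
         call. = FALSE)
  intensity <- do.call(rbind, vals)
  acquired <- outer(excitation, emission, function(x_, m) m > x_ + .grid_tol)
  intensity[!acquired] <- 0  # zero-fill convention; see mask note above
  eem(excitation, emission, intensity, acquired, channel = channel)
}

#' Write the baseline-corrected matrix file
#'
#' Saves a single full-precision matrix file named
#' `spectral_intensity_baseline_corrected.txt` into the data directory, so
#' the corrected 2D matrix stays accessible as plain text next to the
#' original conversion files.
#'
#' @param x The baseline-corrected [eem()].
#' @param directory Output directory (created if missing).
#' @return The path, invisibly.
#' @export
write_baseline_corrected <- function(x, directory) {
  stopifnot(inherits(x, "eem"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  path <- file.path(directory, "spectral_intensity_baseline_corrected.txt")
  writeLines(apply(x$intensity, 1L, function(r) paste(.fmt(r), collapse = "\t")),
             path)
  invisible(path)
}
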