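# Synthetic EEM generator: Gaussian-product fluorophore peaks, Rayleigh /
# second-order / water-Raman scatter ridges, and additive Gaussian noise.
# Emulates a protein + mant-GDP measurement so every other module is
# testable without instrument data.

#' Describe a fluorophore as a separable Gaussian peak
#'
#' Intensity contributed at (excitation, emission) is
#' `amplitude * exp(-(ex - ex_center)^2 / (2 ex_width^2))
#'            * exp(-(em - em_center)^2 / (2 em_width^2))`.
#' A separable Gaussian is a modeling convenience, not a physical lineshape;
#' it keeps every test expectation closed-form.
#'
#' @param ex_center,em_center Peak position (nm); `em_center` must exceed
#'   `ex_center` (fluorescence is Stokes-shifted).
#' @param ex_width,em_width Gaussian sigmas (nm), positive.
#' @param amplitude Peak height in counts per second, nonnegative.
#' @return An object of class `fluorophore_component`.
#' @export
fluorophore_component <- function(ex_center, em_center, ex_width, em_width,
                                  amplitude) {
  if (ex_width <= 0 || em_width <= 0)
    stop("widths must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be nonnegative", call. = FALSE)
  if (em_center <= ex_center)
    stop("em_center must exceed ex_center", call. = FALSE)
  structure(list(ex_center = ex_center, em_center = em_center,
                 ex_width = ex_width, em_width = em_width,
                 amplitude = amplitude),
            class = "fluorophore_component")
}

#' Describe the scatter artifacts of a fluorometer
#'
#' Three ridges, each a unit-height Gaussian in the emission direction
#' scaled by its amplitude: the first-order (Rayleigh) reflection centred at
#' emission = excitation, the monochromator-grating second-order reflection
#' centred at emission = 2 x excitation, and the water Raman ridge centred
#' at [raman_wavelength()] for the given wavenumber shift.
#'
#' @param first_order_amp,second_order_amp,raman_amp Ridge heights
#'   (counts/s), nonnegative.
#' @param first_order_width,second_order_width,raman_width Gaussian sigmas
#'   (nm), positive.
#' @param raman_shift Raman shift in 1/cm; 3400 is the water O-H stretch.
#' @return An object of class `scatter_model`.
#' @export
scatter_model <- function(first_order_amp = 0, second_order_amp = 0,
                          raman_amp = 0, first_order_width = 5,
                          second_order_width = 5, raman_width = 5,
                          raman_shift = 3400) {
  amps <- c(first_order_amp, second_order_amp, raman_amp)
  widths <- c(first_order_width, second_order_width, raman_width)
  if (any(amps < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  if (any(widths <= 0)) stop("widths must be positive", call. = FALSE)
  structure(list(first_order_amp = first_order_amp,
                 second_order_amp = second_order_amp,
                 raman_amp = raman_amp,
                 first_order_width = first_order_width,
                 second_order_width = second_order_width,
                 raman_width = raman_width,
                 raman_shift = raman_shift),
            class = "scatter_model")
}

#' Additive Gaussian noise model
#'
#' @param sigma Standard deviation in counts per second, nonnegative.
#' @param seed Integer seed; identical seeds give bit-identical simulations.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, seed = 1L) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# Noise-free intensity at vectors of (ex, em) pairs; shared by the simulator
# and by tests that want an independent expectation.
.synth_signal <- function(ex, em, components, scatter) {
  y <- numeric(length(em))
  for (cm in components) {
    y <- y + cm$amplitude *
      exp(-(ex - cm$ex_center)^2 / (2 * cm$ex_width^2)) *
      exp(-(em - cm$em_center)^2 / (2 * cm$em_width^2))
  }
  if (!is.null(scatter)) {
    y <- y + scatter$first_order_amp *
      exp(-(em - ex)^2 / (2 * scatter$first_order_width^2))
    y <- y + scatter$second_order_amp *
      exp(-(em - 2 * ex)^2 / (2 * scatter$second_order_width^2))
    rc <- raman_wavelength(ex, scatter$raman_shift)
    if (is.finite(rc))
      y <- y + scatter$raman_amp *
        exp(-(em - rc)^2 / (2 * scatter$raman_width^2))
  }
  y
}

#' Simulate a triangular EEM measurement
#'
#' Evaluates every fluorophore component and scatter ridge at each planned
#' (excitation, emission) point of a triangular or trapezoidal acquisition
#' plan and adds Gaussian noise.  Identical seeds give bit-identical output;
#' different seeds change only the noise term.
#'
#' @param plan A triangular or trapezoidal [acquisition_plan()].
#' @param components List of [fluorophore_component()]s (may be empty).
#' @param scatter A [scatter_model()] or `NULL` for no scatter.
#' @param noise A [noise_model()].
#' @param channel Channel label for the resulting scan set.
#' @return A [triangular_scan_set()].
#' @examples
#' plan <- acquisition_plan("triangular", 200, 695, em_end = 700, step = 5)
#' hras <- hras_preset()
#' scans <- simulate_eem(plan, hras$components, hras$scatter,
#'                       noise_model(sigma = 2, seed = 42))
#' @export
simulate_eem <- function(plan, components = list(), scatter = NULL,
                         noise = noise_model(), channel = "corrected") {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (plan$mode == "rectangular")
    stop("simulate_eem needs a triangular or trapezoidal plan (a ",
         "rectangular plan measures at and below the Rayleigh line)",
         call. = FALSE)
  if (inherits(components, "fluorophore_component"))
    components <- list(components)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)
  rows <- vector("list", nrow(plan$rows))
  for (i in seq_len(nrow(plan$rows))) {
    em <- seq(plan$rows$emission_start[i], plan$rows$emission_end[i],
              by = plan$step)
    y <- .synth_signal(plan$rows$excitation[i], em, components, scatter)
    if (noise$sigma > 0) y <- y + stats::rnorm(length(em), 0, noise$sigma)
    rows[[i]] <- list(excitation = plan$rows$excitation[i], emission = em,
                      intensity = y)
  }
  triangular_scan_set(rows, channel = channel, step = plan$step)
}

#' Preset emulating a Ras GTPase / mant-GDP sample
#'
#' Three fluorophore peaks -- protein tyrosine fluorescence at
#' (ex 280, em 330) nm and the two mant-GDP bands at (360, 440) and
#' (260, 440) nm -- with the tyrosine amplitude much larger than either mant
#' band (as when endogenous GDP is only partially exchanged), plus nonzero
#' Rayleigh, second-order and water-Raman scatter.  Widths and absolute
#' amplitudes are invented, documented constants chosen so each peak is well
#' separated from the scatter ridges on a 5 nm grid.
#'
#' @return A list with elements `components` (list of three
#'   [fluorophore_component()]s, tyrosine first) and `scatter` (a
#'   [scatter_model()]).
#' @export
hras_preset <- function() {
  list(
    components = list(
      fluorophore_component(280, 330, ex_width = 12, em_width = 12,
                            amplitude = 1000),
      fluorophore_component(360, 440, ex_width = 18, em_width = 20,
                            amplitude = 260),
      fluorophore_component(260, 440, ex_width = 12, em_width = 20,
                            amplitude = 200)),
    scatter = .shared_scatter())
}

#' Preset emulating the matching buffer-only baseline
#'
#' No fluorophores; exactly the same scatter model as [hras_preset()], so
#' subtracting a simulated buffer from a simulated sample removes the
#' Rayleigh and Raman ridges the way a measured baseline subtraction does.
#'
#' @return A list with elements `components` (empty list) and `scatter`.
#' @export
buffer_preset <- function() {
  list(components = list(), scatter = .shared_scatter())
}

.shared_scatter <- function() {
  scatter_model(first_order_amp = 800, second_order_amp = 300,
                raman_amp = 120, first_order_width = 4,
                second_order_width = 6, raman_width = 6,
                raman_shift = 3400)
}

#' Default acquisition plan for the synthetic sample
#'
#' The measurement grid of the emulated experiment: excitation and emission
#' from 200 to 700 nm with a 5 nm step, triangular, emission starting one
#' step above excitation.
#'
#' @return An [acquisition_plan()].
#' @export
hras_plan <- function() {
  acquisition_plan("triangular", ex_start = 200, ex_end = 695,
                   em_end = 700, step = 5)
}
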