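# Shared generators and comparison helpers for property-style tests.

# A random valid triangular scan set: random grid origin/step/extent with
# emission starting one or more steps above excitation.
random_triangular_scans <- function(n_rows = NULL, step = NULL,
                                    offset_steps = 1L) {
  if (is.null(step)) step <- sample(c(1, 2, 5, 10), 1L)
  if (is.null(n_rows)) n_rows <- sample(2:12, 1L)
  ex_start <- sample(200:400, 1L)
  ex <- ex_start + (seq_len(n_rows) - 1L) * step
  em_max <- max(ex) + (offset_steps + sample(1:20, 1L)) * step
  rows <- lapply(ex, function(x) {
    em <- seq(x + offset_steps * step, em_max, by = step)
    list(excitation = x, emission = em,
         intensity = round(stats::runif(length(em), 0, 1e5), 3))
  })
  triangular_scan_set(rows, channel = sample(c("raw", "corrected"), 1L),
                      step = step)
}

# Matched triangular/rectangular plan pair with a one-step emission offset.
random_matched_plans <- function() {
  step <- sample(c(1, 2, 5, 10), 1L)
  ex_start <- sample(200:400, 1L)
  n_rows <- sample(1:60, 1L)
  ex_end <- ex_start + (n_rows - 1L) * step
  em_end <- ex_end + sample(1:40, 1L) * step
  list(
    tri = acquisition_plan("triangular", ex_start, ex_end, em_end = em_end,
                           step = step),
    rect = acquisition_plan("rectangular", ex_start, ex_end, em_end = em_end,
                            step = step))
}

expect_eem_equal <- function(a, b) {
  expect_equal(as.numeric(a$excitation), as.numeric(b$excitation))
  expect_equal(as.numeric(a$emission), as.numeric(b$emission))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$acquired, b$acquired)
}

expect_scans_equal <- function(a, b) {
  expect_equal(length(a$rows), length(b$rows))
  for (i in seq_along(a$rows)) {
    expect_identical(a$rows[[i]]$excitation, b$rows[[i]]$excitation)
    expect_equal(as.numeric(a$rows[[i]]$emission),
                 as.numeric(b$rows[[i]]$emission))
    expect_identical(a$rows[[i]]$intensity, b$rows[[i]]$intensity)
  }
}

# The 60-row scheme used throughout: excitation 200-790 nm in 10 nm steps,
# each emission scan from one step above excitation to 800 nm.
paper_grid_plan <- function() {
  acquisition_plan("triangular", 200, 790, em_end = 800, step = 10)
}

# Cells within k sigma of any fluorophore component (used to restrict
# ridge-residual checks to regions where no real signal overlaps scatter).
fluorophore_support <- function(x, components, k = 3) {
  sup <- matrix(FALSE, nrow = length(x$excitation), ncol = length(x$emission))
  for (cm in components) {
    sup <- sup | outer(x$excitation, x$emission, function(ex, em)
      abs(ex - cm$ex_center) <= k * cm$ex_width &
        abs(em - cm$em_center) <= k * cm$em_width)
  }
  sup
}
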