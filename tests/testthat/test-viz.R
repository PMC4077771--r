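# Settings model, the analysis driver, and graphics export.

write_demo_folder <- function(dir, seed = 51, baseline = FALSE) {
  pre <- if (baseline) buffer_preset() else hras_preset()
  e <- triangular_to_rectangular(simulate_eem(
    hras_plan(), pre$components, pre$scatter, noise_model(2, seed)))
  write_matrix_files(e, dir)
  e
}

test_that("settings validate and read from key = value text with overrides", {
  f <- tempfile()
  writeLines(c("# demo settings",
               "dname = /data/run1",
               "baseline_correction = 'no'",
               "lowest_contour_percent = 3",
               "highest_contour_percent = 13",
               "mode = '2D'",
               "n_colors = 15",
               "",
               "emission_spectrum_excited_at = 360"), f)
  s <- read_settings(f)
  expect_s3_class(s, "analysis_settings")
  expect_equal(s$dname, "/data/run1")
  expect_equal(s$lowest_contour_percent, 3)
  expect_equal(s$highest_contour_percent, 13)
  expect_equal(s$n_colors, 15L)
  s2 <- read_settings(f, mode = "1D emission slice", dname = "/elsewhere")
  expect_equal(s2$mode, "1D emission slice")
  expect_equal(s2$dname, "/elsewhere")
  expect_error(analysis_settings(mode = "3D"), "settings error")
  expect_error(analysis_settings(lowest_contour_percent = 50,
                                 highest_contour_percent = 10),
               "settings error")
  expect_error(analysis_settings(graphics_export = "maybe"),
               "settings error")
  expect_error(analysis_settings(nonsense = 1), "unknown setting")
})

test_that("2D mode with export off computes levels and leaves the folder unchanged", {
  d <- tempfile()
  e <- write_demo_folder(d)
  before <- list.files(d)
  out <- run_analysis(analysis_settings(
    dname = d, mode = "2D", lowest_contour_percent = 0,
    highest_contour_percent = 10, n_colors = 8))
  expect_identical(list.files(d), before)
  expect_length(out$files, 0L)
  # the figure's level set equals contour_levels exactly
  expect_equal(out$result, contour_levels(out$eem, contour_spec(0, 10, 8)))
})

test_that("2D export writes the four-file family with percents in the names", {
  d <- tempfile()
  write_demo_folder(d)
  out <- suppressMessages(run_analysis(analysis_settings(
    dname = d, mode = "2D", lowest_contour_percent = 3,
    highest_contour_percent = 13, n_colors = 10,
    graphics_export = "on")))
  expect_length(out$files, 4L)
  expect_true(all(file.exists(out$files)))
  expect_true(all(grepl("3", basename(out$files)) &
                    grepl("13", basename(out$files))))
  expect_setequal(tools::file_ext(out$files), c("png", "eps", "rds"))
  # a re-run at different percents coexists as a distinct file family
  out2 <- suppressMessages(run_analysis(analysis_settings(
    dname = d, mode = "2D", lowest_contour_percent = 0,
    highest_contour_percent = 10, n_colors = 10,
    graphics_export = "on")))
  expect_true(all(file.exists(out$files)))
  expect_true(all(file.exists(out2$files)))
  expect_length(intersect(out$files, out2$files), 0L)
  # the serialized figure data reproduces the level set
  fig <- readRDS(grep("figdata", out$files, value = TRUE))
  expect_equal(fig$levels, contour_levels(out$eem, contour_spec(3, 13, 10)))
})

test_that("baseline correction writes the corrected matrix into dname", {
  d <- tempfile(); db <- tempfile()
  e <- write_demo_folder(d, seed = 61)
  b <- write_demo_folder(db, seed = 62, baseline = TRUE)
  out <- suppressMessages(run_analysis(analysis_settings(
    dname = d, baseline_name = db, baseline_correction = "yes",
    mode = "2D")))
  p <- file.path(d, "spectral_intensity_baseline_corrected.txt")
  expect_true(file.exists(p))
  expect_identical(out$eem$intensity,
                   subtract_baseline(e, b)$intensity)
  back <- read_matrix_files(
    d, intensity_file = "spectral_intensity_baseline_corrected.txt")
  expect_identical(back$intensity, out$eem$intensity)
})

test_that("slice modes export the slice text and figures, off mode exports nothing", {
  d <- tempfile()
  write_demo_folder(d, seed = 71)
  out_off <- suppressMessages(run_analysis(analysis_settings(
    dname = d, mode = "1D emission slice",
    emission_spectrum_excited_at = 360)))
  expect_length(out_off$files, 0L)
  expect_s3_class(out_off$result, "spectrum1d")
  out_on <- suppressMessages(run_analysis(analysis_settings(
    dname = d, mode = "1D emission slice",
    emission_spectrum_excited_at = 361,
    graphics_export = "on")))
  expect_equal(out_on$result$used, 360)  # nearest existing wavelength
  expect_length(out_on$files, 5L)       # text + four graphics
  expect_true(any(grepl("em_slice_ex_360nm\\.txt$", out_on$files)))
  expect_true(all(grepl("360", basename(out_on$files))))
  out_ex <- suppressMessages(run_analysis(analysis_settings(
    dname = d, mode = "1D excitation slice",
    excitation_spectrum_detected_at = 440,
    graphics_export = "on")))
  expect_true(any(grepl("ex_slice_em_440nm\\.txt$", out_ex$files)))
})

test_that("re-running identical settings is idempotent apart from timestamps", {
  d <- tempfile()
  write_demo_folder(d, seed = 81)
  s <- analysis_settings(dname = d, mode = "1D emission slice",
                         emission_spectrum_excited_at = 360,
                         graphics_export = "on")
  out1 <- suppressMessages(run_analysis(s))
  txt1 <- readLines(grep("\\.txt$", out1$files, value = TRUE))
  out2 <- suppressMessages(run_analysis(s))
  txt2 <- readLines(grep("\\.txt$", out2$files, value = TRUE))
  expect_identical(sort(out1$files), sort(out2$files))
  expect_identical(txt1, txt2)
})

test_that("the colormap resolves and rejects unknown names", {
  expect_length(blue_red_colormap(7), 7L)
  d <- tempfile()
  write_demo_folder(d, seed = 91)
  expect_error(run_analysis(analysis_settings(
    dname = d, mode = "2D", colormap_name = "nonexistent",
    graphics_export = "on")), "settings error")
})
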