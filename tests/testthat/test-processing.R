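# Baseline subtraction, contour levels, scatter annotation, peak picking.

test_that("self-subtraction yields a zero matrix with the same mask", {
  e <- triangular_to_rectangular(random_triangular_scans())
  z <- subtract_baseline(e, e)
  expect_true(all(z$intensity == 0))
  expect_identical(z$acquired, e$acquired)
})

test_that("subtraction matches a brute-force two-loop oracle and keeps negatives", {
  set.seed(55)
  for (rep in 1:10) {
    step <- 5
    plan <- acquisition_plan("triangular", 300, 340, em_end = 400, step = step)
    a <- triangular_to_rectangular(simulate_eem(
      plan, noise = noise_model(10, rep)))
    b <- triangular_to_rectangular(simulate_eem(
      plan, noise = noise_model(10, rep + 100)))
    d <- subtract_baseline(a, b)
    expected <- matrix(0, nrow(a$intensity), ncol(a$intensity))
    for (i in seq_len(nrow(expected))) {
      for (j in seq_len(ncol(expected))) {
        if (a$acquired[i, j] && b$acquired[i, j])
          expected[i, j] <- a$intensity[i, j] - b$intensity[i, j]
      }
    }
    expect_identical(d$intensity, expected)
  }
  # negative differences survive
  expect_true(any(d$intensity[d$acquired] < 0))
  # (A - B) + B restricted to the joint mask equals A: add B back by
  # subtracting its negation
  neg_b <- eem(b$excitation, b$emission, -b$intensity + 0, b$acquired)
  back <- subtract_baseline(d, neg_b)
  joint <- a$acquired & b$acquired
  expect_equal(back$intensity[joint], a$intensity[joint])
})

test_that("axis mismatches are hard errors, never silent interpolation", {
  a <- triangular_to_rectangular(simulate_eem(
    acquisition_plan("triangular", 300, 340, em_end = 400, step = 5)))
  b <- triangular_to_rectangular(simulate_eem(
    acquisition_plan("triangular", 300, 340, em_end = 400, step = 10)))
  expect_error(subtract_baseline(a, b), "incompatible axes")
})

test_that("contour levels are the stated fractions of the acquired-cell maximum", {
  e <- triangular_to_rectangular(simulate_eem(
    hras_plan(), hras_preset()$components, hras_preset()$scatter))
  m <- max(e$intensity[e$acquired])
  lv1 <- contour_levels(e, contour_spec(0, 10, 11))
  expect_equal(lv1, seq(0, 0.10 * m, length.out = 11))
  lv2 <- contour_levels(e, contour_spec(3, 13, 21))
  expect_equal(lv2[1], 0.03 * m)
  expect_equal(lv2[21], 0.13 * m)
  expect_true(all(diff(lv2) >= 0))
  # degenerate interval: n identical levels
  lv3 <- contour_levels(e, contour_spec(50, 50, 4))
  expect_equal(lv3, rep(0.5 * m, 4))
  # linear scaling in intensity
  e10 <- eem(e$excitation, e$emission, e$intensity * 10, e$acquired)
  expect_equal(contour_levels(e10, contour_spec(3, 13, 21)), lv2 * 10)
})

test_that("the zero-filled triangle never distorts the contour scale", {
  # all acquired values negative: the scale max must be the acquired max,
  # not the zero fill
  e <- eem(c(300, 310), c(305, 315, 325),
           intensity = matrix(c(-5, 0, -2, -4, -1, -3), nrow = 2) *
             matrix(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE), nrow = 2),
           acquired = matrix(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                             nrow = 2))
  expect_equal(contour_levels(e, contour_spec(100, 100, 1)), -1)
  empty <- eem(c(300, 310), c(305, 315),
               intensity = matrix(0, 2, 2),
               acquired = matrix(FALSE, 2, 2))
  expect_error(contour_levels(empty, contour_spec(0, 100, 3)),
               "empty matrix")
})

test_that("zero-width scatter masks mark exactly the ridge grid cells", {
  plan <- acquisition_plan("triangular", 200, 395, em_end = 800, step = 5)
  e <- triangular_to_rectangular(simulate_eem(plan))
  ann <- annotate_scatter(e, w1 = 0, w2 = 0, w3 = 0)
  idx1 <- which(ann$first_order, arr.ind = TRUE)
  expect_true(all(e$emission[idx1[, 2]] == e$excitation[idx1[, 1]]))
  idx2 <- which(ann$second_order, arr.ind = TRUE)
  expect_true(all(e$emission[idx2[, 2]] == 2 * e$excitation[idx2[, 1]]))
  # second-order center for 280 nm excitation sits at 560 nm
  i280 <- which(e$excitation == 280)
  expect_equal(as.numeric(e$emission[which(ann$second_order[i280, ])]), 560)
})

test_that("the water Raman ridge lands at the wavenumber-shifted wavelength", {
  # 1/(1/350e-7 cm - 3400 1/cm) converted to nm
  expect_equal(raman_wavelength(350, 3400),
               1 / (1 / 350e-7 - 3400) * 1e7)
  expect_equal(raman_wavelength(350, 3400), 397.28, tolerance = 1e-4)
  # shift beyond the excitation wavenumber has no physical solution
  expect_true(is.na(raman_wavelength(350, 1e7 / 350 + 1)))
  e <- triangular_to_rectangular(simulate_eem(
    acquisition_plan("triangular", 345, 355, em_end = 500, step = 5)))
  ann <- annotate_scatter(e, w1 = 0, w2 = 0, w3 = 3)
  i350 <- which(e$excitation == 350)
  marked <- as.numeric(e$emission[which(ann$raman[i350, ])])
  expect_equal(marked, c(395, 400))  # the 5 nm grid cells within 3 nm of 397.28
})

test_that("scatter masks are pure geometry, unchanged by intensity", {
  e <- triangular_to_rectangular(simulate_eem(
    hras_plan(), hras_preset()$components, hras_preset()$scatter,
    noise_model(2, 12)))
  a1 <- annotate_scatter(e, 8, 12, 9)
  e2 <- eem(e$excitation, e$emission, e$intensity * 3.7, e$acquired)
  a2 <- annotate_scatter(e2, 8, 12, 9)
  expect_identical(a1$first_order, a2$first_order)
  expect_identical(a1$second_order, a2$second_order)
  expect_identical(a1$raman, a2$raman)
  expect_error(annotate_scatter(e, w1 = -1), "nonnegative")
})

test_that("a single synthetic Gaussian is found at exactly its grid cell", {
  plan <- hras_plan()
  e <- triangular_to_rectangular(simulate_eem(
    plan, list(fluorophore_component(280, 330, 12, 12, 1000))))
  pk <- find_peaks(e, annotation = NULL, threshold_percent = 50)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$excitation, 280)
  expect_equal(pk$emission, 330)
  # exhaustive argmax oracle
  am <- which(e$intensity == max(e$intensity[e$acquired]), arr.ind = TRUE)
  expect_equal(as.numeric(e$excitation[am[1, 1]]), pk$excitation)
  expect_equal(as.numeric(e$emission[am[1, 2]]), pk$emission)
  # flat matrix: no peaks
  flat <- triangular_to_rectangular(simulate_eem(plan))
  expect_equal(nrow(find_peaks(flat, threshold_percent = 0)), 0L)
})

test_that("random isolated Gaussians at SNR >= 10 are recovered within one grid step", {
  set.seed(77)
  plan <- acquisition_plan("triangular", 200, 695, em_end = 700, step = 5)
  for (rep in 1:20) {
    centers <- list(
      c(sample(seq(240, 320, 5), 1), sample(seq(380, 450, 5), 1)),
      c(sample(seq(400, 470, 5), 1), sample(seq(560, 650, 5), 1)))
    amp <- stats::runif(2, 500, 1500)
    sigma_noise <- min(amp) / 20  # SNR >= 20 at the peaks
    comps <- lapply(1:2, function(k)
      fluorophore_component(centers[[k]][1], centers[[k]][2],
                            ex_width = 12, em_width = 12,
                            amplitude = amp[k]))
    e <- triangular_to_rectangular(simulate_eem(
      plan, comps, noise = noise_model(sigma_noise, rep)))
    pk <- find_peaks(e, threshold_percent = 25)
    for (k in 1:2) {
      hit <- pk[abs(pk$excitation - centers[[k]][1]) <= 5 &
                  abs(pk$emission - centers[[k]][2]) <= 5, ]
      expect_gte(nrow(hit), 1L)
    }
  }
})
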