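test_that("window cropping keeps exactly the in-window channels", {
  axis <- seq(400, 1700, by = 1)
  y <- seq_along(axis) * 1.0
  cr <- crop_window(axis, y, 461, 1606)
  expect_true(all(cr$wavenumber >= 461 & cr$wavenumber <= 1606))
  expect_equal(cr$intensity, y[axis >= 461 & axis <= 1606])

  # cropping to the full existing range is the identity
  cr2 <- crop_window(axis, y, min(axis), max(axis))
  expect_equal(cr2$intensity, y)

  # boundary inclusion on both ends
  cr3 <- crop_window(c(1, 2, 3), c(10, 20, 30), 2, 2)
  expect_equal(cr3$wavenumber, 2)
  expect_equal(cr3$intensity, 20)

  expect_error(crop_window(axis, y, 2000, 3000), "no channels")
})

test_that("shape-preserving interpolation reproduces knots and avoids overshoot", {
  x <- 0:10
  y <- x^2
  expect_equal(pchip_interpolate(x, y, x), y, tolerance = 1e-12)

  xx <- seq(0, 10, by = 0.5)
  expect_lt(max(abs(pchip_interpolate(x, y, xx) - xx^2)), 0.1)

  # monotone data stay monotone between knots
  set.seed(1)
  ym <- cumsum(runif(11))
  fine <- seq(0, 10, by = 0.05)
  expect_true(all(diff(pchip_interpolate(x, ym, fine)) >= -1e-12))

  # values never overshoot the local knot interval
  yr <- c(0, 1, 0, 2, 0, 3, 0, 1, 0, 1, 0)
  vals <- pchip_interpolate(x, yr, fine)
  expect_true(all(vals >= min(yr) - 1e-9 & vals <= max(yr) + 1e-9))

  expect_error(pchip_interpolate(x, y, seq(-1, 5)), "extrapolation")
})

test_that("interpolation agrees with an independent monotone-cubic method", {
  x <- seq(0, 20, by = 2)
  set.seed(2)
  y <- abs(rnorm(length(x)))
  xx <- seq(0, 20, by = 0.25)
  ours <- pchip_interpolate(x, y, xx)
  other <- stats::splinefun(x, y, method = "monoH.FC")(xx)
  expect_lt(max(abs(ours - other)), 0.15 * diff(range(y)))
})

test_that("Savitzky-Golay smoothing matches its closed forms", {
  # window 3 / order 1 is a centred 3-point mean on interior channels
  expect_equal(sg_smooth(c(0, 3, 0), 3, 1)[2], 1)

  lin <- 2 * (1:50) + 3
  expect_equal(sg_smooth(lin, 5, 1)[3:48], lin[3:48], tolerance = 1e-10)
  expect_equal(sg_smooth(rep(4, 30), 7, 2), rep(4, 30), tolerance = 1e-10)

  # linearity to machine precision
  set.seed(3)
  s1 <- runif(40); s2 <- runif(40); a <- 2.7
  expect_equal(
    sg_smooth(a * s1 + s2, 5, 2),
    a * sg_smooth(s1, 5, 2) + sg_smooth(s2, 5, 2),
    tolerance = 1e-12
  )

  expect_error(sg_smooth(1:5, 7, 1), "exceeds")
  expect_error(sg_smooth(1:10, 4, 1), "odd")
  expect_error(sg_smooth(1:10, 3, 3), "order")
})

test_that("iterative baseline estimation recovers smooth backgrounds", {
  n <- 400
  x <- seq(0, 1, length.out = n)
  cubic <- 2 + x - 0.5 * x^2 + 0.8 * x^3

  # peakless smooth input: estimate stays within 2% away from the edges
  b <- estimate_baseline(cubic, 0.07, 20)
  interior <- 40:(n - 40)
  expect_lt(max(abs(b[interior] - cubic[interior]) / cubic[interior]), 0.02)

  # baseline + 5 narrow Gaussian peaks: error below 10% of the max peak
  # height on peak-free channels
  centers <- c(60, 130, 200, 270, 340)
  peaks <- rowSums(vapply(centers, function(c0) {
    3 * exp(-((seq_len(n) - c0)^2) / (2 * 4^2))
  }, numeric(n)))
  y <- cubic + peaks
  b2 <- estimate_baseline(y, 0.07, 20)
  peak_free <- which(peaks < 0.01 * max(peaks))
  peak_free <- setdiff(peak_free, c(1:20, (n - 20):n))
  expect_lt(max(abs(b2[peak_free] - cubic[peak_free])), 0.1 * max(peaks))

  # monotone in iteration count, and bounded by a single SG smooth
  b_1 <- estimate_baseline(y, 0.07, 1)
  b_2 <- estimate_baseline(y, 0.07, 2)
  expect_true(all(b_2 <= b_1 + 1e-12))
  expect_true(all(b2 <= sg_smooth(y, ramgrade:::baseline_window(n, 0.07), 1) + 1e-12))
})

test_that("baseline subtraction clamps negative residuals", {
  expect_equal(subtract_baseline(c(1, 2), c(2, 1)), c(0, 1))
  s <- runif(10)
  expect_equal(subtract_baseline(s, s), rep(0, 10))
  expect_equal(subtract_baseline(s, rep(0, 10)), s)
  expect_error(subtract_baseline(1:3, 1:4), "mismatch")
})

test_that("AUC normalization yields unit trapezoidal area", {
  axis <- make_axis(678, 461, 1606)
  y <- auc_normalize(axis, rep(5, 678))
  expect_equal(unique(round(y, 15)), 1 / 1145)

  set.seed(4)
  z <- auc_normalize(axis, runif(678) + 0.1)
  expect_equal(trapz_(axis, z), 1, tolerance = 1e-10)
  # idempotence
  expect_equal(auc_normalize(axis, z), z, tolerance = 1e-12)

  expect_error(auc_normalize(axis, rep(0, 678)), "positive")
})

test_that("the reference-band Gaussian fit locates the Phe band", {
  axis <- make_axis(678, 461, 1606)
  gauss <- function(mu) 0.2 + exp(-(axis - mu)^2 / (2 * 5^2))
  expect_equal(fit_reference_peak(axis, gauss(1005)), 1005, tolerance = 0.01)
  expect_equal(fit_reference_peak(axis, gauss(1007)), 1007, tolerance = 0.1)
  expect_warning(mu <- fit_reference_peak(axis, rep(1, 678)), "falling back")
  expect_true(is.finite(mu))
})

test_that("alignment recovers injected calibration shifts", {
  cfg <- tiny_config(
    grade_levels = 0, points_per_map = c(8, 8), air_pocket_rate = 0,
    shift_jitter_sd = 0, baseline_scale = 0,
    media_mix_fraction_range = c(0, 0), seed = 5
  )  # default noise: Phe-band SNR ~65, well inside the SNR >= 20 regime
  sim <- simulate_dataset(cfg)
  axis <- wavenumbers(sim$data)
  m <- spectra_matrix(sim$data)
  shifts <- c(0, -3, -1.8, -0.5, 0.7, 1.4, 2.6, 3)
  for (i in seq_along(shifts)) {
    m[i, ] <- ramgrade:::shift_spectrum(axis, m[i, ], shifts[i])
  }
  # align after smoothing, as the pipeline does
  shifted <- smooth_spectra(set_spectra(sim$data, m))
  aligned <- align_spectra(shifted)
  # the applied correction must undo the injected shift (reference = row 1)
  err <- abs(aligned$align_shift - (shifts[1] - shifts))
  expect_lt(mean(err), 0.2)

  # identical spectra need no shifting
  same <- set_spectra(sim$data[1:6, ], m[rep(1, 6), ])
  aligned_same <- align_spectra(same)
  expect_equal(aligned_same$align_shift, rep(0, 6))
  expect_equal(spectra_matrix(aligned_same), m[rep(1, 6), ], ignore_attr = TRUE)
})

test_that("a second alignment pass only refines the first", {
  cfg <- tiny_config(
    grade_levels = 0, points_per_map = c(10, 10), air_pocket_rate = 0,
    shift_jitter_sd = 1.5, baseline_scale = 0.2, noise_sd = 0.02, seed = 6
  )
  sim <- simulate_dataset(cfg)
  one <- align_spectra(sim$data, passes = 1)
  two <- align_spectra(sim$data, passes = 2)
  refinement <- abs(two$align_shift - one$align_shift)
  first_pass <- abs(one$align_shift)
  moved <- first_pass > 1e-6
  expect_true(all(refinement[moved] <= first_pass[moved] + 1e-9))

  # after two passes all fitted band centers agree closely
  m <- spectra_matrix(two)
  axis <- wavenumbers(two)
  centers <- apply(m, 1, function(y) {
    suppressWarnings(fit_reference_peak(axis, y))
  })
  expect_lt(max(abs(centers - centers[1])), 0.2)
})

test_that("the full preprocessing pipeline preserves signal shape and area", {
  # well-separated bands: the stripping window can reach the baseline in the
  # gaps, which is what the 2% shape-preservation figure assumes
  cfg <- tiny_config(
    grade_levels = 0, points_per_map = c(10, 10), air_pocket_rate = 0,
    shift_jitter_sd = 0, noise_sd = 0, baseline_scale = 0,
    media_mix_fraction_range = c(0, 0),
    tissue_peaks = dplyr::bind_rows(
      peak_spec(550, 7, 0.5), peak_spec(757, 7, 0.6), peak_spec(1005, 6, 1),
      peak_spec(1260, 8, 0.5), peak_spec(1450, 8, 0.7)
    ),
    seed = 7
  )
  sim <- simulate_dataset(cfg)
  # noiseless spectra on a flat (constant) baseline
  clean <- spectra_matrix(sim$data)
  flat <- clean + 0.3 * max(clean)
  pre <- preprocess_spectra(set_spectra(sim$data, flat))
  axis <- wavenumbers(pre)
  m <- spectra_matrix(pre)

  expect_true(all(m >= 0))
  areas <- apply(m, 1, function(y) trapz_(axis, y))
  expect_true(all(abs(areas - 1) < 0.01))

  # output matches the area-normalized clean signal within 2% RMS
  for (i in seq_len(nrow(m))) {
    target <- auc_normalize(axis, clean[i, ])
    rel_rms <- sqrt(mean((m[i, ] - target)^2)) / sqrt(mean(target^2))
    expect_lt(rel_rms, 0.02)
  }

  # near-idempotence: the baseline left in a preprocessed spectrum is small,
  # also for the realistic curved-baseline configuration
  sim2 <- simulate_dataset(tiny_config(grade_levels = 0, baseline_scale = 0.4,
                                       air_pocket_rate = 0, seed = 8))
  pre2 <- preprocess_spectra(sim2$data)
  m2 <- spectra_matrix(pre2)
  b_again <- estimate_baseline(m2[1, ], 0.07, 20)
  expect_lt(max(b_again), 0.05 * max(m2[1, ]))

  expect_error(preprocess_spectra(sim$data[0, ]), "Empty")
})
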