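#' Preprocessing parameters
#'
#' Defaults reproduce the standard processing chain for dispersive Raman maps
#' of lung tissue: Savitzky-Golay smoothing with a 3-point first-order window,
#' iterative peak-stripping baseline estimation with a first-order SG filter
#' whose window is 7% of the channel count run for 20 iterations, unit-area
#' normalization, and two passes of phenylalanine-band (~1005 cm^-1) peak
#' alignment.
#'
#' @param sg_window Odd SG smoothing window (channels), default 3.
#' @param sg_order SG polynomial order, default 1 (must be < `sg_window`).
#' @param baseline_window_frac Baseline SG window as a fraction of the channel
#'   count, default 0.07.
#' @param baseline_iterations Peak-stripping iterations, default 20.
#' @param align_center Alignment reference band center (cm^-1), default 1005.
#' @param align_halfwidth Half-width of the Gaussian fit window (cm^-1),
#'   default 15.
#' @param align_passes Full alignment passes over the dataset, default 2.
#' @param window_lo,window_hi Spectral window retained (cm^-1), defaults
#'   461 and 1606.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 3, sg_order = 1,
                              baseline_window_frac = 0.07,
                              baseline_iterations = 20,
                              align_center = 1005, align_halfwidth = 15,
                              align_passes = 2,
                              window_lo = 461, window_hi = 1606) {
  cfg <- list(
    sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
    baseline_window_frac = baseline_window_frac,
    baseline_iterations = as.integer(baseline_iterations),
    align_center = align_center, align_halfwidth = align_halfwidth,
    align_passes = as.integer(align_passes),
    window_lo = window_lo, window_hi = window_hi
  )
  if (cfg$sg_window %% 2 != 1) abort("`sg_window` must be odd.")
  if (cfg$sg_order >= cfg$sg_window) abort("`sg_order` must be < `sg_window`.")
  if (cfg$baseline_window_frac <= 0 || cfg$baseline_window_frac >= 1) {
    abort("`baseline_window_frac` must be in (0, 1).")
  }
  if (cfg$baseline_iterations < 1) abort("`baseline_iterations` must be >= 1.")
  if (cfg$align_passes < 1) abort("`align_passes` must be >= 1.")
  if (cfg$window_lo >= cfg$window_hi) abort("`window_lo` must be < `window_hi`.")
  structure(cfg, class = "preprocess_config")
}

#' Crop a spectrum or dataset to a wavenumber window
#'
#' Keeps channels with `lo <= wavenumber <= hi` (both ends inclusive).
#'
#' @param data Spectral dataset tibble.
#' @param lo,hi Window endpoints (cm^-1).
#' @return Dataset restricted to the window.
#' @export
crop_spectra <- function(data, lo = 461, hi = 1606) {
  w <- wavenumbers(data)
  keep <- crop_index(w, lo, hi)
  set_spectra(data, spectra_matrix(data)[, keep, drop = FALSE], w[keep])
}

crop_index <- function(wavenumber, lo, hi) {
  if (lo > hi) abort("`lo` must be <= `hi`.")
  keep <- which(wavenumber >= lo & wavenumber <= hi)
  if (length(keep) == 0) abort("Crop window contains no channels.")
  keep
}

#' Crop a single spectrum vector
#' @param wavenumber,intensity Numeric vectors of equal length.
#' @param lo,hi Window endpoints (cm^-1), inclusive.
#' @return List with cropped `wavenumber` and `intensity`.
#' @export
crop_window <- function(wavenumber, intensity, lo, hi) {
  check_axis(wavenumber)
  keep <- crop_index(wavenumber, lo, hi)
  list(wavenumber = wavenumber[keep], intensity = intensity[keep])
}

#' Shape-preserving piecewise-cubic interpolation onto a target axis
#'
#' Uses the PCHIP monotone cubic Hermite interpolant, which does not overshoot
#' local data extrema; this is the standard choice for merging spectra acquired
#' with different diffraction gratings onto a common axis. Extrapolation is
#' refused.
#'
#' @param x,y Source axis and intensities.
#' @param xout Target axis, which must lie inside `range(x)`.
#' @return Interpolated intensities at `xout`.
#' @export
pchip_interpolate <- function(x, y, xout) {
  check_axis(x)
  eps <- 1e-9 * (max(x) - min(x))
  if (min(xout) < min(x) - eps || max(xout) > max(x) + eps) {
    abort("Target axis lies outside the source range; extrapolation refused.")
  }
  xout <- pmin(pmax(xout, min(x)), max(x))
  signal::pchip(x, y, xout)
}

#' Interpolate a whole dataset onto a target axis
#' @param data Spectral dataset tibble.
#' @param target Target wavenumber axis inside the source range.
#' @return Dataset resampled onto `target`.
#' @export
interpolate_spectra <- function(data, target) {
  check_axis(target)
  w <- wavenumbers(data)
  m <- spectra_matrix(data)
  out <- t(apply(m, 1, function(y) pchip_interpolate(w, y, target)))
  set_spectra(data, out, target)
}

sg_kernel <- function(window, order) {
  signal::sgolay(p = order, n = window)[(window + 1) / 2, ]
}

# SG filtering with reflect padding: the signal is mirrored (excluding the
# endpoint itself) on both sides before convolution, avoiding endpoint collapse
# with short windows.
sg_filter_vec <- function(y, window, order, kernel = NULL) {
  n <- length(y)
  if (window > n) abort("SG window exceeds the spectrum length.")
  if (window %% 2 != 1) abort("SG window must be odd.")
  if (order >= window) abort("SG order must be < window.")
  if (is.null(kernel)) kernel <- sg_kernel(window, order)
  h <- (window - 1) / 2
  pad <- c(y[(h + 1):2], y, y[(n - 1):(n - h)])
  out <- stats::filter(pad, kernel, sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing. With the default `window = 3`,
#' `order = 1` this is a centred 3-point moving average on interior channels,
#' the standard high-frequency noise filter for these spectra.
#'
#' @param y Intensity vector.
#' @param window Odd window length in channels.
#' @param order Polynomial order, < `window`.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(y, window = 3, order = 1) {
  sg_filter_vec(y, window, order)
}

#' Smooth every spectrum of a dataset
#' @param data Spectral dataset tibble.
#' @inheritParams sg_smooth
#' @return Dataset with smoothed spectra.
#' @export
smooth_spectra <- function(data, window = 3, order = 1) {
  m <- spectra_matrix(data)
  if (window > ncol(m)) abort("SG window exceeds the spectrum length.")
  kernel <- sg_kernel(window, order)
  out <- t(apply(m, 1, sg_filter_vec, window = window, order = order, kernel = kernel))
  set_spectra(data, out)
}

baseline_window <- function(n_channels, window_frac) {
  w <- round(window_frac * n_channels)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) {
    warn("Baseline SG window below 3 channels; clamped to 3.")
    w <- 3
  }
  as.integer(w)
}

#' Iterative peak-stripping baseline estimation
#'
#' Schulze-style signal removal: starting from the spectrum itself, each
#' iteration applies a first-order SG filter whose window is `window_frac` of
#' the channel count (rounded to the nearest odd integer) and keeps the
#' pointwise minimum of the current estimate and its smooth. Peaks are eroded
#' while the smooth background survives; the estimate is pointwise
#' non-increasing in the iteration count.
#'
#' @param y Intensity vector.
#' @param window_frac Fraction of the channel count used as SG window
#'   (default 0.07).
#' @param iterations Number of strip iterations (default 20).
#' @return Baseline estimate, same length as `y`.
#' @export
estimate_baseline <- function(y, window_frac = 0.07, iterations = 20) {
  if (window_frac <= 0 || window_frac >= 1) abort("`window_frac` must be in (0, 1).")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  w <- baseline_window(length(y), window_frac)
  kernel <- sg_kernel(w, 1)
  b <- y
  for (k in seq_len(iterations)) {
    b <- pmin(b, sg_filter_vec(b, w, 1, kernel))
  }
  b
}

#' Subtract a baseline, clamping negative residuals to zero
#'
#' Non-negativity of the corrected spectra is required by the downstream
#' basis-restricted NMF, so residuals driven below zero by noise are clamped.
#'
#' @param y Intensity vector.
#' @param baseline Baseline vector of the same length.
#' @return Non-negative corrected vector.
#' @export
subtract_baseline <- function(y, baseline) {
  if (length(y) != length(baseline)) abort("Spectrum/baseline length mismatch.")
  pmax(y - baseline, 0)
}

#' Estimate and subtract baselines for a whole dataset
#' @param data Spectral dataset tibble.
#' @inheritParams estimate_baseline
#' @return Dataset with baseline-corrected, non-negative spectra.
#' @export
correct_baseline <- function(data, window_frac = 0.07, iterations = 20) {
  m <- spectra_matrix(data)
  w <- baseline_window(ncol(m), window_frac)
  kernel <- sg_kernel(w, 1)
  out <- t(apply(m, 1, function(y) {
    b <- y
    for (k in seq_len(iterations)) b <- pmin(b, sg_filter_vec(b, w, 1, kernel))
    pmax(y - b, 0)
  }))
  set_spectra(data, out)
}

#' Normalize a spectrum to unit trapezoidal area
#'
#' @param wavenumber Axis (cm^-1).
#' @param y Intensity vector.
#' @return Vector with trapezoidal area 1 over the axis.
#' @export
auc_normalize <- function(wavenumber, y) {
  check_axis(wavenumber)
  a <- trapz_area(wavenumber, y)
  if (!is.finite(a) || a <= 0) abort("Spectrum area must be positive for AUC normalization.")
  y / a
}

#' Normalize every spectrum of a dataset to unit area
#' @param data Spectral dataset tibble.
#' @return Dataset with unit-area spectra.
#' @export
normalize_auc <- function(data) {
  w <- wavenumbers(data)
  m <- spectra_matrix(data)
  out <- t(apply(m, 1, function(y) auc_normalize(w, y)))
  set_spectra(data, out)
}

#' Fit a Gaussian to the reference band and return its center
#'
#' Nonlinear least-squares fit of `a + h * exp(-(x - mu)^2 / (2 * sigma^2))`
#' restricted to `center +/- halfwidth`, initialized at the windowed argmax.
#' Used to locate the phenylalanine ring-breathing band (~1005 cm^-1) for
#' x-axis drift correction. If the fit fails (e.g. a featureless spectrum) the
#' windowed argmax position is returned with a warning.
#'
#' @param wavenumber Axis (cm^-1).
#' @param y Intensity vector.
#' @param center Nominal band center (cm^-1), default 1005.
#' @param halfwidth Fit window half-width (cm^-1), default 15.
#' @return Fitted band center (cm^-1).
#' @export
fit_reference_peak <- function(wavenumber, y, center = 1005, halfwidth = 15) {
  check_axis(wavenumber)
  win <- which(wavenumber >= center - halfwidth & wavenumber <= center + halfwidth)
  if (length(win) < 5) abort("Reference-peak window must contain at least 5 channels.")
  xw <- wavenumber[win]; yw <- y[win]
  rng <- max(yw) - min(yw)
  fallback <- function() {
    warn("Reference-peak fit failed; falling back to windowed argmax.")
    xw[which.max(yw)]
  }
  if (!is.finite(rng) || rng <= 1e-12 * max(abs(yw), 1)) return(fallback())
  mu0 <- xw[which.max(yw)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yw ~ a + h * exp(-(xw - mu)^2 / (2 * sigma^2)),
      start = list(a = min(yw), h = rng, mu = mu0, sigma = halfwidth / 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fallback())
  mu <- coef(fit)[["mu"]]
  if (!is.finite(mu) || mu < min(xw) || mu > max(xw)) return(fallback())
  mu
}

shift_spectrum <- function(wavenumber, y, delta) {
  # s'(x) = s(x - delta); queries beyond the recorded range take edge values
  q <- pmin(pmax(wavenumber - delta, min(wavenumber)), max(wavenumber))
  signal::pchip(wavenumber, y, q)
}

#' Align all spectra on the reference band of the first spectrum
#'
#' The reference center is the fitted band position of the first spectrum;
#' every other spectrum is shifted along the axis (shape-preserving
#' interpolation, edge-value fill) so its fitted center matches. The full pass
#' is repeated `passes` times to converge residual shifts. Spectra without a
#' fittable band are left unshifted, as are spectra whose apparent shift
#' exceeds `halfwidth / 2` (featureless media/air-pocket spectra fit noise in
#' the reference window; calibration drift is far smaller than the window).
#'
#' @param data Spectral dataset tibble.
#' @param center,halfwidth Reference band window, see [fit_reference_peak()].
#' @param passes Number of full alignment passes (default 2).
#' @return Dataset with aligned spectra and an `align_shift` metadata column
#'   holding the total applied shift (cm^-1) per spectrum.
#' @export
align_spectra <- function(data, center = 1005, halfwidth = 15, passes = 2) {
  if (nrow(data) == 0) abort("Empty dataset.")
  w <- wavenumbers(data)
  m <- spectra_matrix(data)
  total_shift <- numeric(nrow(m))
  max_shift <- halfwidth / 2
  fit_quiet <- function(y) {
    tryCatch(
      withCallingHandlers(
        fit_reference_peak(w, y, center, halfwidth),
        warning = function(cnd) invokeRestart("muffleWarning")
      ),
      error = function(e) NA_real_
    )
  }
  for (pass in seq_len(passes)) {
    mu_ref <- fit_quiet(m[1, ])
    if (!is.finite(mu_ref)) abort("Reference spectrum has no fittable band.")
    for (i in seq_len(nrow(m))[-1]) {
      mu_i <- fit_quiet(m[i, ])
      if (!is.finite(mu_i)) next
      delta <- mu_ref - mu_i
      if (abs(delta) < 1e-6 || abs(delta) > max_shift) next
      m[i, ] <- shift_spectrum(w, m[i, ], delta)
      total_shift[i] <- total_shift[i] + delta
    }
  }
  out <- set_spectra(data, m)
  out$align_shift <- total_shift
  out
}

#' Full preprocessing pipeline
#'
#' Applies, in order: window crop, SG smoothing, iterative baseline estimation
#' and subtraction (negatives clamped), unit-area normalization, and reference
#' band alignment. The stage order follows the conventional processing chain
#' for these maps: normalization precedes alignment, and alignment perturbs
#' the unit area by well under 1%.
#'
#' @param data Spectral dataset tibble.
#' @param config A [preprocess_config()].
#' @return Preprocessed dataset (non-negative, unit-area spectra, aligned).
#' @export
preprocess_spectra <- function(data, config = preprocess_config()) {
  if (!inherits(config, "preprocess_config")) abort("`config` must be a preprocess_config.")
  if (nrow(data) == 0) abort("Empty dataset.")
  data |>
    crop_spectra(config$window_lo, config$window_hi) |>
    smooth_spectra(config$sg_window, config$sg_order) |>
    correct_baseline(config$baseline_window_frac, config$baseline_iterations) |>
    normalize_auc() |>
    align_spectra(config$align_center, config$align_halfwidth, config$align_passes)
}
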