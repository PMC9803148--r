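#' Describe a Gaussian Raman band
#'
#' @param center Band center (cm^-1).
#' @param width Gaussian sigma (cm^-1), > 0.
#' @param amplitude Peak intensity (arbitrary units), >= 0.
#' @return One-row tibble with columns `center`, `width`, `amplitude`.
#' @export
peak_spec <- function(center, width, amplitude) {
  if (any(width <= 0)) abort("Peak `width` must be > 0.")
  if (any(amplitude < 0)) abort("Peak `amplitude` must be >= 0.")
  tibble(center = as.numeric(center), width = as.numeric(width),
         amplitude = as.numeric(amplitude))
}

# Default band libraries. Tissue bands follow commonly reported protein/lipid
# Raman features of lung tissue (Phe ring breathing at 1005 cm^-1 dominant);
# media bands mimic the polymer-rich OCT:PBS embedding compound; collagen bands
# sit at the classic proline/hydroxyproline and amide III positions and carry
# the fibrosis (grade-dependent) signal.
default_tissue_peaks <- function() {
  dplyr::bind_rows(
    peak_spec(508, 8, 0.25), peak_spec(621, 7, 0.20), peak_spec(757, 7, 0.35),
    peak_spec(852, 8, 0.45), peak_spec(935, 8, 0.30), peak_spec(1005, 6, 1.00),
    peak_spec(1095, 9, 0.35), peak_spec(1209, 8, 0.25), peak_spec(1260, 10, 0.40),
    peak_spec(1340, 11, 0.35), peak_spec(1450, 10, 0.55), peak_spec(1585, 9, 0.30)
  )
}

default_media_peaks <- function() {
  dplyr::bind_rows(
    peak_spec(478, 10, 0.50), peak_spec(845, 12, 0.60), peak_spec(917, 9, 0.40),
    peak_spec(1048, 10, 0.80), peak_spec(1140, 11, 0.50), peak_spec(1298, 12, 0.45),
    peak_spec(1468, 12, 0.70)
  )
}

default_collagen_peaks <- function() {
  dplyr::bind_rows(
    peak_spec(855, 7, 0.80), peak_spec(938, 7, 0.70), peak_spec(1245, 9, 0.80)
  )
}

#' Fibrosis and pneumonitis grade sets
#'
#' Regional pathology grades used throughout: fibrosis grades are the fraction
#' of a lung region assessed as fibrotic on Trichrome staining; pneumonitis
#' grades come from semi-quantitative H&E inflammation scoring.
#' @return Numeric vector of grade levels.
#' @export
fibrosis_grade_levels <- function() c(0, 0.05, 0.1, 0.3, 0.5, 0.6, 0.9, 1)

#' @rdname fibrosis_grade_levels
#' @export
pneumonitis_grade_levels <- function() c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.8)

# Strain-specific fibrosis grade support (metadata only; spectral shape is
# strain-independent by default). C3H/HeJ mice present the pneumonitis-prone
# phenotype with low fibrosis grades; C57BL/6J mice span the full fibrotic range.
strain_grade_support <- function() {
  list(
    `C3H/HeJ` = c(0, 0.1, 0.3, 0.5),
    `C57BL/6J` = c(0, 0.05, 0.1, 0.3, 0.6, 0.9, 1)
  )
}

#' Configuration for the synthetic spectral-map generator
#'
#' Defaults emulate the acquisition geometry of cryosectioned murine lung
#' Raman maps: a 678-channel 461--1606 cm^-1 window, 30--80 points per map,
#' three maps per grade level, and per-point contamination by OCT:PBS media
#' (air pockets are media-dominated points).
#'
#' @param n_channels Channels per spectrum (default 678).
#' @param axis_lo,axis_hi Window endpoints in cm^-1 (defaults 461, 1606).
#' @param tissue_peaks,media_peaks,collagen_peaks Tibbles of [peak_spec()] rows.
#' @param grade_levels Fibrosis grade levels simulated (fractions in `[0, 1]`).
#' @param n_maps_per_grade Maps (regions of interest) per grade level.
#' @param points_per_map Integer range (length 2) of points per map.
#' @param media_mix_fraction_range Media weight range for ordinary tissue
#'   points (length-2 vector in `[0, 1]`).
#' @param air_pocket_rate Fraction of points generated as media-dominated
#'   air-pocket spectra (media weight drawn from `[0.7, 1]`).
#' @param baseline_kind `"polynomial"` (random order <= 3 with positive
#'   offset) or `"exponential"`.
#' @param baseline_scale Baseline magnitude as a fraction of the peak intensity
#'   of the unit-area tissue spectrum.
#' @param noise_sd Channel noise standard deviation, same fractional units as
#'   `baseline_scale`.
#' @param shift_jitter_sd Per-spectrum wavenumber calibration jitter (cm^-1).
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 678, axis_lo = 461, axis_hi = 1606,
                             tissue_peaks = default_tissue_peaks(),
                             media_peaks = default_media_peaks(),
                             collagen_peaks = default_collagen_peaks(),
                             grade_levels = fibrosis_grade_levels(),
                             n_maps_per_grade = 3,
                             points_per_map = c(30, 80),
                             media_mix_fraction_range = c(0, 0.25),
                             air_pocket_rate = 0.25,
                             baseline_kind = c("polynomial", "exponential"),
                             baseline_scale = 0.5,
                             noise_sd = 0.015,
                             shift_jitter_sd = 0.3,
                             seed = 1L) {
  baseline_kind <- match.arg(baseline_kind)
  cfg <- list(
    n_channels = as.integer(n_channels), axis_lo = axis_lo, axis_hi = axis_hi,
    tissue_peaks = as_tibble(tissue_peaks), media_peaks = as_tibble(media_peaks),
    collagen_peaks = as_tibble(collagen_peaks),
    grade_levels = as.numeric(grade_levels),
    n_maps_per_grade = as.integer(n_maps_per_grade),
    points_per_map = as.integer(points_per_map),
    media_mix_fraction_range = as.numeric(media_mix_fraction_range),
    air_pocket_rate = as.numeric(air_pocket_rate),
    baseline_kind = baseline_kind, baseline_scale = as.numeric(baseline_scale),
    noise_sd = as.numeric(noise_sd), shift_jitter_sd = as.numeric(shift_jitter_sd),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_channels < 8) abort("`n_channels` must be >= 8.")
  if (cfg$axis_lo >= cfg$axis_hi) abort("`axis_lo` must be < `axis_hi`.")
  for (nm in c("air_pocket_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) abort(sprintf("`%s` must be in [0, 1].", nm))
  }
  rng <- cfg$media_mix_fraction_range
  if (length(rng) != 2 || any(rng < 0) || any(rng > 1) || rng[1] > rng[2]) {
    abort("`media_mix_fraction_range` must be an interval inside [0, 1].")
  }
  if (length(cfg$grade_levels) == 0) abort("`grade_levels` must be non-empty.")
  if (any(cfg$grade_levels < 0 | cfg$grade_levels > 1)) {
    abort("`grade_levels` must lie in [0, 1].")
  }
  if (length(cfg$points_per_map) != 2 || any(cfg$points_per_map < 1) ||
      cfg$points_per_map[1] > cfg$points_per_map[2]) {
    abort("`points_per_map` must be an increasing positive integer range.")
  }
  if (cfg$noise_sd < 0 || cfg$baseline_scale < 0 || cfg$shift_jitter_sd < 0) {
    abort("Noise, baseline and jitter scales must be >= 0.")
  }
  for (nm in c("tissue_peaks", "media_peaks", "collagen_peaks")) {
    pk <- cfg[[nm]]
    if (nrow(pk) == 0) abort(sprintf("`%s` must be non-empty.", nm))
    if (any(pk$center < cfg$axis_lo | pk$center > cfg$axis_hi)) {
      abort(sprintf("A `%s` center lies outside the axis range.", nm))
    }
    if (any(pk$width <= 0) || any(pk$amplitude < 0)) {
      abort(sprintf("`%s` widths must be > 0 and amplitudes >= 0.", nm))
    }
  }
  invisible(cfg)
}

# Sum-of-Gaussians band profile evaluated on an axis (analytic, so spectra can
# be generated directly on a jittered axis).
gaussian_profile <- function(axis, peaks) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$amplitude[i] *
      exp(-(axis - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  out
}

trapz_area <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Build the three fixed basis spectra (tissue, mixed, media)
#'
#' The tissue basis is the sum of the configured tissue Gaussians, the media
#' basis the sum of the media Gaussians, and the mixed (contaminated) basis the
#' 50/50 average of the two; each is normalized to unit trapezoidal area. The
#' tissue library must contain a band near the phenylalanine reference
#' (~1005 cm^-1) because downstream peak alignment anchors on it.
#'
#' @param config A [synthetic_config()].
#' @return A spectral dataset tibble with rows labelled `tissue`, `mixed`,
#'   `media` (column `basis`), usable directly by [fit_gbr_nmf()].
#' @export
make_basis_library <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  if (!any(abs(config$tissue_peaks$center - 1005) <= 15)) {
    abort("`tissue_peaks` must include a band near 1005 cm^-1 (Phe reference).")
  }
  axis <- make_axis(config$n_channels, config$axis_lo, config$axis_hi)
  tissue <- gaussian_profile(axis, config$tissue_peaks)
  media <- gaussian_profile(axis, config$media_peaks)
  tissue <- tissue / trapz_area(axis, tissue)
  media <- media / trapz_area(axis, media)
  mixed <- 0.5 * tissue + 0.5 * media
  mixed <- mixed / trapz_area(axis, mixed)
  raman_dataset(
    tibble(spectrum_id = c("tissue", "mixed", "media"),
           basis = c("tissue", "mixed", "media")),
    rbind(tissue, mixed, media), axis
  )
}

random_baseline <- function(axis, kind, scale, ref_intensity) {
  x <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  shape <- if (kind == "polynomial") {
    deg <- sample(1:3, 1)
    cf <- runif(deg, -0.5, 0.5)
    b <- runif(1, 0.2, 1)
    for (k in seq_len(deg)) b <- b + cf[k] * x^k
    pmax(b, 0.05)
  } else {
    runif(1, 0.5, 1) * exp(-runif(1, 1, 4) * x)
  }
  scale * ref_intensity * shape
}

#' Simulate a grade-structured synthetic spectral-map dataset
#'
#' Each map draws `points_per_map` spectra. A spectrum is a non-negative
#' mixture `w_t * (tissue + grade * collagen) + w_m * media` of unit-area band
#' profiles, on an axis jittered by a per-spectrum calibration shift, plus a
#' smooth positive baseline and Gaussian channel noise. The collagen profile is
#' scaled by the tissue weight and linearly by the fibrosis grade, so the
#' fibrotic signal grows monotonically with grade. A fraction
#' `air_pocket_rate` of points are media-dominated air pockets. All latent
#' quantities are returned as ground truth.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `data` (spectral dataset tibble), `truth`
#'   (tibble of true weights, grade, applied shift, air-pocket flag and a
#'   `baseline` matrix column), and `basis` (the [make_basis_library()] of the
#'   config).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  axis <- make_axis(config$n_channels, config$axis_lo, config$axis_hi)
  basis <- make_basis_library(config)

  raw_t <- gaussian_profile(axis, config$tissue_peaks)
  raw_m <- gaussian_profile(axis, config$media_peaks)
  raw_c <- gaussian_profile(axis, config$collagen_peaks)
  area_t <- trapz_area(axis, raw_t)
  area_m <- trapz_area(axis, raw_m)
  ref_intensity <- max(raw_t / area_t)  # peak of the unit-area tissue spectrum

  support <- strain_grade_support()
  meta <- list(); spec <- list(); truth <- list(); bl <- list()
  idx <- 0L
  for (g in config$grade_levels) {
    strains <- names(support)[map_dbl(support, function(s) min(abs(s - g))) < 1e-9]
    if (length(strains) == 0) strains <- names(support)
    for (m in seq_len(config$n_maps_per_grade)) {
      strain <- if (length(strains) == 1) strains else strains[1 + (m - 1) %% length(strains)]
      map_id <- sprintf("g%s_m%d", format(g), m)
      mouse_id <- sprintf("%s_g%s_%d", sub("/.*", "", strain), format(g), 1 + (m - 1) %/% 2)
      pneu <- sample(pneumonitis_grade_levels(), 1)
      pts_range <- seq(config$points_per_map[1], config$points_per_map[2])
      npts <- if (length(pts_range) == 1) pts_range else sample(pts_range, 1)
      for (pt in seq_len(npts)) {
        idx <- idx + 1L
        is_air <- runif(1) < config$air_pocket_rate
        f <- if (is_air) runif(1, 0.7, 1) else
          runif(1, config$media_mix_fraction_range[1], config$media_mix_fraction_range[2])
        w_t <- 1 - f; w_m <- f
        delta <- if (config$shift_jitter_sd > 0) rnorm(1, 0, config$shift_jitter_sd) else 0
        ax_s <- axis - delta
        tissue_part <- (gaussian_profile(ax_s, config$tissue_peaks) +
                          g * gaussian_profile(ax_s, config$collagen_peaks)) / area_t
        media_part <- gaussian_profile(ax_s, config$media_peaks) / area_m
        clean <- w_t * tissue_part + w_m * media_part
        baseline <- random_baseline(axis, config$baseline_kind,
                                    config$baseline_scale, ref_intensity)
        noise <- if (config$noise_sd > 0) {
          rnorm(length(axis), 0, config$noise_sd * ref_intensity)
        } else 0
        spec[[idx]] <- clean + baseline + noise
        bl[[idx]] <- baseline
        meta[[idx]] <- tibble(
          spectrum_id = sprintf("s%05d", idx), mouse_id = mouse_id, strain = strain,
          map_id = map_id, fibrosis_grade = g, pneumonitis_grade = pneu
        )
        truth[[idx]] <- tibble(
          spectrum_id = sprintf("s%05d", idx), w_tissue = w_t, w_mixed = 0,
          w_media = w_m, grade = g, shift = delta, air_pocket = is_air
        )
      }
    }
  }
  data <- raman_dataset(dplyr::bind_rows(meta), do.call(rbind, spec), axis)
  truth <- dplyr::bind_rows(truth)
  truth$baseline <- do.call(rbind, bl)
  colnames(truth$baseline) <- axis_colnames(axis)
  list(data = data, truth = truth, basis = basis)
}
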