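# Small deterministic fixtures shared across the test files. Everything is
# generated in code; nothing is read from disk except the bundled reference
# confusion tables.

# Compact generator configuration: few grades, one small map per grade.
tiny_config <- function(..., seed = 1L) {
  defaults <- list(
    grade_levels = c(0, 0.5, 1), n_maps_per_grade = 1,
    points_per_map = c(10, 14), seed = seed
  )
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# A linearly independent 3-row basis on the default axis (tissue, media,
# collagen band profiles). Used wherever weight identifiability is needed;
# the default library's mixed basis is an exact tissue/media average and so
# linearly dependent by construction.
independent_basis <- function(n_channels = 678) {
  cfg <- synthetic_config(n_channels = n_channels)
  axis <- make_axis(n_channels, cfg$axis_lo, cfg$axis_hi)
  H <- rbind(
    gaussian_profile_(axis, cfg$tissue_peaks),
    gaussian_profile_(axis, cfg$media_peaks),
    gaussian_profile_(axis, cfg$collagen_peaks)
  )
  H <- H / rowSums(H)
  rownames(H) <- c("tissue", "media", "collagen")
  colnames(H) <- sprintf("%.15g", axis)
  H
}

gaussian_profile_ <- function(axis, peaks) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$amplitude[i] *
      exp(-(axis - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  out
}

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Small classifiable spectral dataset: `k` classes whose mean spectrum differs
# in a handful of signal channels, plus iid noise. Cheap enough for CV loops.
toy_grade_dataset <- function(n_per_class = 40, p = 30, grades = c(0, 0.5, 1),
                              effect = 1, noise = 0.15, seed = 1L) {
  set.seed(seed)
  signal_channels <- c(5, 12, 23)
  n <- n_per_class * length(grades)
  m <- matrix(rnorm(n * p, sd = noise), n, p) + 1
  g <- rep(grades, each = n_per_class)
  for (ch in signal_channels) m[, ch] <- m[, ch] + effect * g
  m <- pmax(m, 0)
  meta <- tibble::tibble(
    spectrum_id = sprintf("t%04d", seq_len(n)),
    mouse_id = "m1", strain = "C57BL/6J", map_id = "map1",
    fibrosis_grade = g, pneumonitis_grade = 0
  )
  raman_dataset(meta, m, seq_len(p) + 1000)
}
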