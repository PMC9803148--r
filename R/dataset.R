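#' Build an equally spaced wavenumber axis
#'
#' The working spectral window for dispersive Raman maps of lung tissue is
#' 461--1606 cm^-1 sampled on 678 channels; this helper builds that (or any
#' other) equally spaced axis.
#'
#' @param n_channels Number of channels (>= 2).
#' @param lo,hi First and last wavenumber (cm^-1), `lo < hi`.
#' @return Numeric vector of length `n_channels`, strictly increasing, with
#'   `lo` and `hi` as its endpoints.
#' @examples
#' axis <- make_axis(678, 461, 1606)
#' diff(axis)[1] * 677  # spans the full window
#' @export
make_axis <- function(n_channels = 678, lo = 461, hi = 1606) {
  if (length(n_channels) != 1 || is.na(n_channels) || n_channels < 2) {
    abort("`n_channels` must be a single integer >= 2.")
  }
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("Need finite `lo` < `hi` for a wavenumber axis.")
  }
  seq(lo, hi, length.out = as.integer(n_channels))
}

axis_colnames <- function(wavenumber) sprintf("%.15g", wavenumber)

#' Assemble a spectral dataset tibble
#'
#' A spectral dataset is a tibble with one row per spectrum: metadata columns
#' (`spectrum_id`, `mouse_id`, `strain`, `map_id`, `fibrosis_grade`,
#' `pneumonitis_grade`) plus a `spectra` matrix column whose column names carry
#' the wavenumber axis, so ordinary dplyr verbs subset spectra and metadata
#' together.
#'
#' @param metadata Data frame of per-spectrum metadata; must contain
#'   `spectrum_id` with unique values.
#' @param spectra Numeric matrix, one row per spectrum.
#' @param wavenumber Numeric strictly increasing axis, one value per column of
#'   `spectra`.
#' @return A tibble with the metadata columns and a `spectra` matrix column.
#' @export
raman_dataset <- function(metadata, spectra, wavenumber) {
  metadata <- as_tibble(metadata)
  spectra <- as.matrix(spectra)
  if (!"spectrum_id" %in% names(metadata)) {
    abort("`metadata` must contain a `spectrum_id` column.")
  }
  if (anyDuplicated(metadata$spectrum_id)) {
    abort("`metadata$spectrum_id` values must be unique.")
  }
  if (nrow(metadata) != nrow(spectra)) {
    abort(sprintf(
      "metadata has %d rows but spectra has %d rows.",
      nrow(metadata), nrow(spectra)
    ))
  }
  check_axis(wavenumber)
  if (length(wavenumber) != ncol(spectra)) {
    abort("`wavenumber` length must equal ncol(spectra).")
  }
  colnames(spectra) <- axis_colnames(wavenumber)
  rownames(spectra) <- NULL
  out <- metadata
  out$spectra <- spectra
  out
}

check_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    abort("Wavenumber axis must be finite numeric.")
  }
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    abort("Wavenumber axis must be strictly increasing.")
  }
  invisible(wavenumber)
}

#' Extract the wavenumber axis of a spectral dataset
#' @param data A spectral dataset tibble (see [raman_dataset()]) or a spectra
#'   matrix with wavenumber column names.
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
wavenumbers <- function(data) {
  m <- spectra_matrix(data)
  as.numeric(colnames(m))
}

#' Extract the n x p intensity matrix of a spectral dataset
#' @inheritParams wavenumbers
#' @return Numeric matrix, one row per spectrum.
#' @export
spectra_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  if (is.data.frame(data)) {
    if (!"spectra" %in% names(data)) {
      abort("Dataset has no `spectra` matrix column.")
    }
    m <- data$spectra
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(data))
    return(m)
  }
  abort("Expected a spectral dataset tibble or a matrix.")
}

#' Replace the spectra of a dataset
#'
#' @param data Spectral dataset tibble.
#' @param spectra New intensity matrix (same number of rows).
#' @param wavenumber Optional new axis; defaults to the axis of `data` when the
#'   channel count is unchanged.
#' @return The dataset with the `spectra` column replaced.
#' @export
set_spectra <- function(data, spectra, wavenumber = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != nrow(data)) abort("Row count mismatch in set_spectra().")
  if (is.null(wavenumber)) {
    if (ncol(spectra) != ncol(spectra_matrix(data))) {
      abort("Channel count changed; supply `wavenumber`.")
    }
    wavenumber <- wavenumbers(data)
  }
  check_axis(wavenumber)
  colnames(spectra) <- axis_colnames(wavenumber)
  rownames(spectra) <- NULL
  data$spectra <- spectra
  data
}

#' Plot spectra coloured by a metadata variable
#'
#' @param data Spectral dataset tibble.
#' @param colour_by Name of a metadata column used for the colour scale
#'   (default `"fibrosis_grade"`).
#' @param n Maximum number of spectra drawn (sampled deterministically by
#'   taking every k-th row); default 50.
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, colour_by = "fibrosis_grade", n = 50) {
  if (nrow(data) == 0) abort("Empty dataset.")
  idx <- unique(round(seq(1, nrow(data), length.out = min(n, nrow(data)))))
  sub <- data[idx, , drop = FALSE]
  long <- tidy_spectra(sub)
  if (!colour_by %in% names(long)) abort(sprintf("No metadata column `%s`.", colour_by))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber, y = .data$intensity,
    group = .data$spectrum_id, colour = factor(.data[[colour_by]])
  )) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(
      x = expression("Raman shift (cm"^-1 * ")"), y = "Intensity (a.u.)",
      colour = colour_by
    ) +
    ggplot2::theme_minimal()
}

#' Pivot a spectral dataset to long (tidy) form
#'
#' @param data Spectral dataset tibble.
#' @return Tibble with one row per (spectrum, channel): metadata columns plus
#'   `wavenumber` and `intensity`.
#' @export
tidy_spectra <- function(data) {
  m <- spectra_matrix(data)
  w <- wavenumbers(data)
  meta <- data[setdiff(names(data), "spectra")]
  long <- tibble(
    row = rep(seq_len(nrow(m)), each = ncol(m)),
    wavenumber = rep(w, times = nrow(m)),
    intensity = as.vector(t(m))
  )
  out <- dplyr::bind_cols(meta[long$row, , drop = FALSE], long[c("wavenumber", "intensity")])
  as_tibble(out)
}
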