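# Lawson-Hanson active-set non-negative least squares for one right-hand side.
# A is p x q (columns = basis spectra), b length p. q is tiny (3 + free rank)
# so the dense normal-equation solves are cheap. Ties in the gradient are
# broken toward the first (lowest-index) candidate, which makes the solver
# deterministic; with the exact-average mixed basis this provably resolves
# weight mass onto the tissue and media columns.
nnls_lawson_hanson <- function(A, b, tol = NULL) {
  q <- ncol(A)
  x <- numeric(q)
  passive <- rep(FALSE, q)
  gradient <- drop(crossprod(A, b))
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(gradient), 1) * q
  AtA <- crossprod(A)
  iter_cap <- 30 * q
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > iter_cap) break
    w <- gradient - drop(AtA %*% x)
    w[passive] <- -Inf
    j <- which.max(w)
    if (!is.finite(w[j]) || w[j] <= tol) break
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(q)
      z[P] <- solve(AtA[P, P, drop = FALSE], gradient[P])
      if (all(z[P] > 1e-14)) {
        x <- z
        break
      }
      neg <- P[z[P] <= 1e-14]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= 1e-12] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
  }
  pmax(x, 0)
}

basis_from <- function(basis) {
  m <- spectra_matrix(basis)
  labels <- if (is.data.frame(basis) && "basis" %in% names(basis)) {
    basis$basis
  } else if (is.data.frame(basis) && "spectrum_id" %in% names(basis)) {
    basis$spectrum_id
  } else if (!is.null(rownames(m))) {
    rownames(m)
  } else {
    paste0("basis", seq_len(nrow(m)))
  }
  list(H = unname(m), labels = as.character(labels))
}

#' Group- and basis-restricted NMF against fixed basis spectra
#'
#' Decomposes the non-negative spectra matrix as `X ~ W H`, where the first
#' rows of `H` are held fixed at the supplied basis spectra (tissue, mixed,
#' media). With `free_rank = 0` (the configuration used for air-pocket
#' removal) each row of `W` is the exact solution of a non-negative least
#' squares problem, solved by a deterministic Lawson-Hanson active-set method:
#' no initialization, no multiplicative updates. With `free_rank > 0`,
#' additional unconstrained basis rows are learned by alternating NNLS updates
#' while the fixed rows are never modified.
#'
#' @param data Spectral dataset tibble (or bare non-negative matrix) to unmix.
#' @param basis Basis spectra as returned by [make_basis_library()] (or any
#'   spectral dataset / matrix on the same axis).
#' @param free_rank Number of additional free basis rows to learn (default 0).
#' @param max_iter,tol Alternating-update controls used when `free_rank > 0`.
#' @return Object of class `gbr_nmf`: list with `scores` (raw n x q weight
#'   matrix W), `normalized` (each column scaled to unit mean, see
#'   [normalize_scores()]), `labels`, `residuals` (per-spectrum residual
#'   L2 norm), `basis` (the H matrix actually used, fixed plus learned rows),
#'   `free_rank` and `spectrum_id`.
#' @export
fit_gbr_nmf <- function(data, basis, free_rank = 0, max_iter = 100, tol = 1e-8) {
  X <- spectra_matrix(data)
  if (min(X) < -1e-8) {
    abort("Spectra must be non-negative (clamp residuals upstream).")
  }
  X <- pmax(X, 0)
  bs <- basis_from(basis)
  H_fixed <- bs$H
  if (ncol(H_fixed) != ncol(X)) {
    abort(sprintf("Basis has %d channels but data has %d.", ncol(H_fixed), ncol(X)))
  }
  if (any(rowSums(H_fixed) <= 0)) abort("Every basis row must have positive area.")
  if (free_rank < 0) abort("`free_rank` must be >= 0.")
  q_fixed <- nrow(H_fixed)

  H <- H_fixed
  labels <- bs$labels
  if (free_rank > 0) {
    # deterministic init: the free components start at the spectra worst
    # explained by the fixed basis alone
    W0 <- t(apply(X, 1, function(b) nnls_lawson_hanson(t(H_fixed), b)))
    res0 <- sqrt(rowSums((X - W0 %*% H_fixed)^2))
    seed_rows <- order(res0, decreasing = TRUE)[seq_len(free_rank)]
    H_free <- X[seed_rows, , drop = FALSE]
    H_free <- H_free / pmax(rowSums(H_free), 1e-12)
    H <- rbind(H_fixed, H_free)
    labels <- c(labels, paste0("free", seq_len(free_rank)))
    prev <- Inf
    for (it in seq_len(max_iter)) {
      W <- t(apply(X, 1, function(b) nnls_lawson_hanson(t(H), b)))
      W_fix <- W[, seq_len(q_fixed), drop = FALSE]
      W_free <- W[, q_fixed + seq_len(free_rank), drop = FALSE]
      R <- X - W_fix %*% H_fixed
      for (j in seq_len(ncol(X))) {
        H[q_fixed + seq_len(free_rank), j] <-
          nnls_lawson_hanson(W_free, R[, j])
      }
      obj <- sum((X - W %*% H)^2)
      if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, 1)) break
      prev <- obj
    }
  }
  W <- t(apply(X, 1, function(b) nnls_lawson_hanson(t(H), b)))
  colnames(W) <- labels
  residuals <- sqrt(rowSums((X - W %*% H)^2))
  ids <- if (is.data.frame(data) && "spectrum_id" %in% names(data)) {
    data$spectrum_id
  } else {
    sprintf("s%05d", seq_len(nrow(X)))
  }
  fit <- structure(
    list(scores = W, normalized = NULL, labels = labels, residuals = residuals,
         basis = H, free_rank = free_rank, spectrum_id = ids),
    class = "gbr_nmf"
  )
  normalize_scores(fit)
}

#' Normalize NMF scores to unit column mean
#'
#' Each score column is divided by its mean, so the threshold value 1 used by
#' the air-pocket filter corresponds to the mean score of that basis.
#' Degenerate all-zero columns are left at zero and flagged (with the default
#' exact-average mixed basis the mixed column is always degenerate, since the
#' active-set solver resolves its weight onto tissue and media).
#'
#' @param fit A `gbr_nmf` object (or a bare non-negative score matrix).
#' @return The object with its `normalized` matrix filled in and a
#'   `degenerate` character vector of flagged column labels (for a bare matrix
#'   input, the normalized matrix with a `degenerate` attribute).
#' @export
normalize_scores <- function(fit) {
  W <- if (inherits(fit, "gbr_nmf")) fit$scores else as.matrix(fit)
  mu <- colMeans(W)
  Wn <- W
  degenerate <- character(0)
  for (j in seq_len(ncol(W))) {
    if (mu[j] > 0) {
      Wn[, j] <- W[, j] / mu[j]
    } else {
      degenerate <- c(degenerate, colnames(W)[j] %||% as.character(j))
    }
  }
  if (inherits(fit, "gbr_nmf")) {
    fit$normalized <- Wn
    fit$degenerate <- degenerate
    fit
  } else {
    attr(Wn, "degenerate") <- degenerate
    Wn
  }
}

#' Threshold filtering of air-pocket / media-contaminated spectra
#'
#' A spectrum is kept when its mean-normalized tissue score is `>= tissue_min`
#' and its mean-normalized media score is `<= media_max` (both boundaries
#' inclusive; the mixed-basis score is not thresholded). With the default
#' thresholds of 1, "score 1" is by construction the mean score of that basis
#' over the dataset.
#'
#' @param fit A fitted `gbr_nmf` object.
#' @param tissue_min Minimum normalized tissue score (default 1).
#' @param media_max Maximum normalized media score (default 1).
#' @param tissue_label,media_label Basis labels used for the two thresholds.
#' @return Object of class `spectra_filter`: list with `keep` (logical mask),
#'   `retention` (mean of the mask), the thresholds, and `spectrum_id`.
#' @export
filter_spectra <- function(fit, tissue_min = 1, media_max = 1,
                           tissue_label = "tissue", media_label = "media") {
  if (!inherits(fit, "gbr_nmf")) abort("`fit` must be a gbr_nmf object.")
  if (tissue_min < 0 || media_max < 0) abort("Thresholds must be >= 0.")
  Wn <- fit$normalized
  for (lab in c(tissue_label, media_label)) {
    if (!lab %in% colnames(Wn)) abort(sprintf("No basis labelled `%s` in the fit.", lab))
  }
  keep <- Wn[, tissue_label] >= tissue_min & Wn[, media_label] <= media_max
  structure(
    list(keep = unname(keep), retention = mean(keep),
         tissue_min = tissue_min, media_max = media_max,
         spectrum_id = fit$spectrum_id),
    class = "spectra_filter"
  )
}

#' Apply a spectra filter to a dataset
#' @param data Spectral dataset tibble the filter was fitted on (same row
#'   order).
#' @param filter A `spectra_filter` from [filter_spectra()].
#' @return The kept subset of `data`.
#' @export
apply_filter <- function(data, filter) {
  if (!inherits(filter, "spectra_filter")) abort("`filter` must be a spectra_filter.")
  if (nrow(data) != length(filter$keep)) {
    abort("Filter mask length does not match the dataset.")
  }
  data[filter$keep, , drop = FALSE]
}

#' @export
print.gbr_nmf <- function(x, ...) {
  cat(sprintf(
    "Basis-restricted NMF: %d spectra x %d bases (%s)%s\n",
    nrow(x$scores), ncol(x$scores), paste(x$labels, collapse = ", "),
    if (x$free_rank > 0) sprintf(", %d free", x$free_rank) else ""
  ))
  cat(sprintf("Mean residual L2 norm: %.4g\n", mean(x$residuals)))
  invisible(x)
}

#' @export
print.spectra_filter <- function(x, ...) {
  cat(sprintf(
    "Spectra filter: tissue >= %g & media <= %g (normalized scores); kept %d/%d (%.1f%%)\n",
    x$tissue_min, x$media_max, sum(x$keep), length(x$keep), 100 * x$retention
  ))
  invisible(x)
}

#' Tidy NMF scores into a long tibble
#' @param x A `gbr_nmf` object.
#' @param ... Unused.
#' @return Tibble with columns `spectrum_id`, `basis`, `score`,
#'   `normalized_score`.
#' @method tidy gbr_nmf
#' @export
tidy.gbr_nmf <- function(x, ...) {
  tibble(
    spectrum_id = rep(x$spectrum_id, times = ncol(x$scores)),
    basis = rep(x$labels, each = nrow(x$scores)),
    score = as.vector(x$scores),
    normalized_score = as.vector(x$normalized)
  )
}

#' One-row summary of an NMF fit
#' @param x A `gbr_nmf` object.
#' @param ... Unused.
#' @return Tibble with `n`, `q`, `free_rank`, `mean_residual`,
#'   `total_residual_ss`.
#' @method glance gbr_nmf
#' @export
glance.gbr_nmf <- function(x, ...) {
  tibble(
    n = nrow(x$scores), q = ncol(x$scores), free_rank = x$free_rank,
    mean_residual = mean(x$residuals),
    total_residual_ss = sum(x$residuals^2)
  )
}

#' Plot normalized score distributions with the filter thresholds
#' @param object A `gbr_nmf` object.
#' @param tissue_min,media_max Thresholds drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gbr_nmf
#' @export
autoplot.gbr_nmf <- function(object, tissue_min = 1, media_max = 1, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$normalized_score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~basis, scales = "free_y") +
    ggplot2::labs(
      x = "Normalized score (column mean = 1)", y = "Spectra",
      title = "Basis-restricted NMF scores"
    ) +
    ggplot2::theme_minimal()
}
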