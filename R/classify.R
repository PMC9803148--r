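#' Grade binning schemes
#'
#' Regional pathology grades (fractions of diseased tissue) can be coarsened
#' into ordered risk levels. Two presets are provided:
#' * `"lmh"`: Low (0--0.1), Medium (0.3--0.6), High (0.9--1).
#' * `"zlmh"`: Zero (0), Low (>0--0.3), Medium (>0.3--0.6), High (>0.6--1).
#'
#' A custom scheme is a tibble with columns `bin`, `lo`, `hi`,
#' `lo_inclusive`; intervals must be disjoint and cover every grade present in
#' the data being binned.
#'
#' @param name `"lmh"` or `"zlmh"`.
#' @return Tibble of class `binning_scheme` describing the ordered bins.
#' @export
binning_scheme <- function(name = c("lmh", "zlmh")) {
  name <- match.arg(name)
  sch <- if (name == "lmh") {
    tibble(
      bin = c("Low", "Medium", "High"),
      lo = c(0, 0.3, 0.9), hi = c(0.1, 0.6, 1),
      lo_inclusive = c(TRUE, TRUE, TRUE)
    )
  } else {
    tibble(
      bin = c("Zero", "Low", "Medium", "High"),
      lo = c(0, 0, 0.3, 0.6), hi = c(0, 0.3, 0.6, 1),
      lo_inclusive = c(TRUE, FALSE, FALSE, FALSE)
    )
  }
  structure(sch, name = name, class = c("binning_scheme", class(sch)))
}

#' Map grades onto the bins of a scheme
#'
#' @param grades Numeric grade values.
#' @param scheme A [binning_scheme()].
#' @return Factor of bin labels, levels in scheme order, same length as
#'   `grades`.
#' @export
bin_grades <- function(grades, scheme) {
  if (!inherits(scheme, "binning_scheme")) abort("`scheme` must be a binning_scheme.")
  out <- rep(NA_character_, length(grades))
  for (i in seq_len(nrow(scheme))) {
    inside <- if (scheme$lo_inclusive[i]) {
      grades >= scheme$lo[i] & grades <= scheme$hi[i]
    } else {
      grades > scheme$lo[i] & grades <= scheme$hi[i]
    }
    hit <- inside & is.na(out)
    out[hit] <- scheme$bin[i]
  }
  if (anyNA(out)) {
    bad <- sort(unique(grades[is.na(out)]))
    abort(sprintf(
      "Grade value(s) not covered by scheme `%s`: %s",
      attr(scheme, "name") %||% "custom", paste(bad, collapse = ", ")
    ))
  }
  factor(out, levels = scheme$bin)
}

#' Random 70/30-style train/test split
#'
#' Uniform split without replacement: `round(train_frac * n)` rows train, the
#' rest test; seeded and reproducible.
#'
#' @param data Spectral dataset tibble (any data frame works).
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test` and the index vector
#'   `train_idx`.
#' @export
split_train_test <- function(data, train_frac = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 rows to split.")
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must be in (0, 1).")
  set.seed(as.integer(seed))
  n_train <- round(train_frac * n)
  if (n_train < 1 || n_train >= n) abort("Split leaves an empty partition.")
  idx <- sort(sample.int(n, n_train))
  list(train = data[idx, , drop = FALSE], test = data[-idx, , drop = FALSE],
       train_idx = idx)
}

label_factor <- function(y) {
  if (is.factor(y)) return(droplevels(y))
  lev <- sort(unique(y))
  factor(y, levels = lev)
}

#' Fit a multinomial LASSO model at a given penalty
#'
#' Minimizes the penalized objective
#' `(1/n) * multinomial negative log-likelihood + lambda * sum |beta|`
#' in the symmetric softmax parameterization (no reference class; the L1
#' penalty resolves the identifiability). Fitting is delegated to the
#' coordinate-descent path solver of \pkg{glmnet}; coefficients at the
#' requested penalty are obtained by exact refitting on the path.
#'
#' @param x Numeric matrix, n spectra x p channels. Column names (the
#'   wavenumber axis) are carried into the model for coefficient maps.
#' @param y Class labels (factor or values coercible to one); at least two
#'   classes must be present.
#' @param lambda Penalty value; `NULL` fits the full path and stores the
#'   smallest-penalty solution.
#' @param standardize Standardize channels before fitting? Default `FALSE`
#'   (spectra are already unit-area).
#' @param nlambda,lambda_min_ratio Path grid controls (100 points, ratio
#'   1e-4).
#' @return Object of class `grading_model`: `classes`, `beta` (p x K sparse
#'   coefficient matrix), `a0` (intercepts), `lambda`, `lambda_max`,
#'   `channels`, plus the underlying path fit.
#' @export
fit_multinomial_lasso <- function(x, y, lambda = NULL, standardize = FALSE,
                                  nlambda = 100, lambda_min_ratio = 1e-4) {
  x <- as.matrix(x)
  y <- label_factor(y)
  if (nlevels(y) < 2) abort("Need at least 2 classes to fit a multinomial model.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  grid <- lambda_grid(x, y, standardize, nlambda, lambda_min_ratio)
  lambda_max <- grid[1]
  lam <- lambda %||% min(grid)
  # fit a path that contains the requested penalty exactly, preserving the
  # warm-start descent from lambda_max
  path_grid <- sort(unique(c(grid[grid > lam], lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(
    x, y, family = "multinomial", lambda = path_grid,
    standardize = standardize, type.multinomial = "ungrouped", thresh = 1e-7, maxit = 1e6
  )
  cf <- coef(fit, s = lam)
  K <- nlevels(y)
  p <- ncol(x)
  beta <- matrix(0, p, K, dimnames = list(colnames(x), levels(y)))
  a0 <- setNames(numeric(K), levels(y))
  for (k in seq_len(K)) {
    v <- as.matrix(cf[[k]])
    a0[k] <- v[1, 1]
    beta[, k] <- v[-1, 1]
  }
  structure(
    list(classes = levels(y), beta = beta, a0 = a0, lambda = lam,
         lambda_max = lambda_max, channels = colnames(x),
         standardize = standardize, path = fit),
    class = "grading_model"
  )
}

lambda_grid <- function(x, y, standardize = FALSE, nlambda = 100,
                        lambda_min_ratio = 1e-4) {
  probe <- glmnet::glmnet(
    x, y, family = "multinomial", nlambda = 5,
    standardize = standardize, type.multinomial = "ungrouped"
  )
  lam_max <- probe$lambda[1]
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
  # keep the head of the grid strictly at-or-above the computed lambda_max so
  # the all-zero boundary solution is reproduced exactly (exp(log(x)) can land
  # one ulp below)
  grid[1] <- lam_max * (1 + 1e-8)
  grid
}

softmax_prob <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$beta)) {
    abort(sprintf("Model expects %d channels, got %d.", nrow(model$beta), ncol(x)))
  }
  eta <- sweep(x %*% model$beta, 2, model$a0, `+`)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Predict class labels (argmax, ties toward the lower grade)
#'
#' Per row, the class with the largest softmax probability; exact ties are
#' broken toward the earlier (lower-grade) class label, i.e. conservatively
#' toward "less diseased".
#'
#' @param model A `grading_model`.
#' @param x Matrix with the model's channels.
#' @return Factor of predicted classes with the model's levels.
#' @export
predict_classes <- function(model, x) {
  p <- softmax_prob(model, x)
  factor(model$classes[apply(p, 1, which.max)], levels = model$classes)
}

#' Multinomial deviance of a model on labelled data
#'
#' `-2 * sum(log p_hat(y_i | x_i))` with probabilities floored at 1e-10
#' before taking logs.
#'
#' @param model A `grading_model`.
#' @param x Matrix of observations.
#' @param y True labels, a subset of the model's classes.
#' @return Non-negative deviance (a sum over observations).
#' @export
multinomial_deviance <- function(model, x, y) {
  y <- as.character(y)
  if (!all(y %in% model$classes)) abort("Labels outside the model's classes.")
  p <- softmax_prob(model, x)
  idx <- cbind(seq_along(y), match(y, model$classes))
  -2 * sum(log(pmax(p[idx], 1e-10)))
}

# penalized objective used by local-optimality probes in the tests
lasso_objective <- function(model, x, y, lambda = model$lambda,
                            beta = model$beta, a0 = model$a0) {
  m <- model
  m$beta <- beta
  m$a0 <- a0
  multinomial_deviance(m, x, y) / (2 * nrow(x)) + lambda * sum(abs(beta))
}

#' Select the LASSO penalty by stratified 10-fold CV and the 1-SE rule
#'
#' Fits the penalty path on a grid of 100 log-spaced values down from the
#' smallest all-zero penalty, with class-stratified folds. For every penalty
#' the held-out multinomial deviance (per observation) is averaged over folds;
#' `lambda_min` minimizes the mean curve and `lambda_1se` is the largest
#' penalty whose mean deviance is within one standard error of the minimum,
#' favouring sparser models.
#'
#' @inheritParams fit_multinomial_lasso
#' @param folds Number of CV folds (default 10). Every class must have at
#'   least `folds` members; bin the grades otherwise.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_lambda`: `lambda` (decreasing grid), `cvm`
#'   (mean per-observation deviance), `cvsd` (standard errors), `lambda_min`,
#'   `lambda_1se`, `folds`, `fold_deviance` (folds x grid matrix).
#' @export
cv_select_lambda <- function(x, y, folds = 10, seed = 1L, standardize = FALSE,
                             nlambda = 100, lambda_min_ratio = 1e-4) {
  x <- as.matrix(x)
  y <- label_factor(y)
  n <- nrow(x)
  if (n < folds) abort("Fewer observations than folds.")
  counts <- table(y)
  if (any(counts < folds)) {
    abort(sprintf(
      "Class(es) rarer than the fold count (%s); consider binning the grades.",
      paste(names(counts)[counts < folds], collapse = ", ")
    ))
  }
  grid <- lambda_grid(x, y, standardize, nlambda, lambda_min_ratio)
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  for (cl in levels(y)) {
    members <- which(y == cl)
    fold_id[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  fold_dev <- matrix(NA_real_, folds, length(grid))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- glmnet::glmnet(
      x[tr, , drop = FALSE], y[tr], family = "multinomial", lambda = grid,
      standardize = standardize, type.multinomial = "ungrouped", thresh = 1e-7, maxit = 1e6
    )
    pr <- predict(fit, x[!tr, , drop = FALSE], type = "response", s = grid)
    yi <- match(as.character(y[!tr]), levels(y))
    for (l in seq_along(grid)) {
      pl <- pr[, , l][cbind(seq_along(yi), yi)]
      fold_dev[k, l] <- -2 * mean(log(pmax(pl, 1e-10)))
    }
  }
  cvm <- colMeans(fold_dev)
  cvsd <- apply(fold_dev, 2, sd) / sqrt(folds)
  i_min <- which.min(cvm)
  ok <- which(cvm <= cvm[i_min] + cvsd[i_min])
  i_1se <- min(ok)  # grid is decreasing, so the first qualifying index is the largest penalty
  structure(
    list(lambda = grid, cvm = cvm, cvsd = cvsd,
         lambda_min = grid[i_min], lambda_1se = grid[i_1se],
         folds = folds, fold_deviance = fold_dev, n = n),
    class = "cv_lambda"
  )
}

#' Confusion matrix over ordered labels
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param labels Ordered label set; defaults to the sorted union of the
#'   factor levels (or values) present.
#' @return Object of class `confusion_matrix`: K x K count matrix, rows =
#'   true, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) abort("Label vectors differ in length.")
  if (is.null(labels)) {
    labels <- if (is.factor(y_true)) {
      union(levels(y_true), levels(factor(y_pred)))
    } else {
      sort(unique(c(as.character(y_true), as.character(y_pred))))
    }
  }
  labels <- as.character(labels)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!all(y_true %in% labels) || !all(y_pred %in% labels)) {
    abort("Labels outside the ordered label set.")
  }
  cm <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(true = labels, predicted = labels))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Classification rate of a confusion matrix
#'
#' The fraction of observations whose predicted class equals the true class:
#' trace divided by total count.
#'
#' @param cm A `confusion_matrix` (or any square count matrix).
#' @return Fraction in `[0, 1]`.
#' @export
classification_rate <- function(cm) {
  n <- sum(cm)
  if (n == 0) abort("Empty confusion matrix.")
  sum(diag(as.matrix(cm))) / n
}

#' Signed per-channel coefficient summary of a fitted model
#'
#' For plotting which wavenumbers drive the grading: channels whose
#' coefficient is positive (intensity increase raises the class likelihood,
#' drawn green), negative (drawn red); zero-coefficient channels are the white
#' background and are omitted from the table.
#'
#' @param model A `grading_model`.
#' @return Tibble with columns `wavenumber` (numeric when channel names parse,
#'   otherwise index), `channel`, `class`, `coefficient`, `direction`
#'   (`"increase"`/`"decrease"`).
#' @export
coefficient_map <- function(model) {
  if (!inherits(model, "grading_model")) abort("`model` must be a grading_model.")
  idx <- which(model$beta != 0, arr.ind = TRUE)
  ch <- model$channels %||% as.character(seq_len(nrow(model$beta)))
  wn <- suppressWarnings(as.numeric(ch))
  if (anyNA(wn)) wn <- seq_len(nrow(model$beta))
  if (nrow(idx) == 0) {
    return(tibble(
      wavenumber = numeric(0), channel = character(0), class = character(0),
      coefficient = numeric(0), direction = character(0)
    ))
  }
  tibble(
    wavenumber = wn[idx[, 1]],
    channel = ch[idx[, 1]],
    class = model$classes[idx[, 2]],
    coefficient = model$beta[idx],
    direction = ifelse(model$beta[idx] > 0, "increase", "decrease")
  ) |>
    arrange(.data$wavenumber, .data$class)
}

#' Run one grading experiment end-to-end
#'
#' Optional strain subsetting, optional grade binning, optional train/test
#' split, penalty selection by stratified CV with the 1-SE rule on the
#' training portion, a final fit at `lambda_1se`, and evaluation (confusion
#' matrix + classification rate) on the held-out set, or by training-data
#' self-prediction when no split is requested (labelled as such).
#'
#' @param data Filtered, preprocessed spectral dataset tibble.
#' @param response `"fibrosis"` or `"pneumonitis"` (uses the matching
#'   `*_grade` metadata column).
#' @param scheme Optional [binning_scheme()].
#' @param strain Optional strain filter (e.g. `"C57BL/6J"`).
#' @param train_frac Optional training fraction; `NULL` fits on the full data.
#' @param seed Integer seed driving the split (seed + 1) and the CV folds
#'   (seed + 2).
#' @param folds CV folds (default 10).
#' @return Object of class `grading_report`: the fitted `model`, `cv` result,
#'   `confusion`, `cr`, `eval_type` (`"test"` or
#'   `"training self-prediction"`), sizes and settings.
#' @export
run_grading_experiment <- function(data, response = c("fibrosis", "pneumonitis"),
                                   scheme = NULL, strain = NULL,
                                   train_frac = NULL, seed = 1L, folds = 10) {
  response <- match.arg(response)
  col <- paste0(response, "_grade")
  if (!col %in% names(data)) abort(sprintf("No `%s` column in the dataset.", col))
  if (!is.null(strain)) {
    data <- data[data$strain %in% strain, , drop = FALSE]
    if (nrow(data) == 0) abort("Strain filter removed every spectrum.")
  }
  y <- data[[col]]
  y <- if (is.null(scheme)) label_factor(y) else bin_grades(y, scheme)
  data$.response <- y
  if (!is.null(train_frac)) {
    sp <- split_train_test(data, train_frac, seed = as.integer(seed) + 1L)
    train <- sp$train; eval_set <- sp$test; eval_type <- "test"
  } else {
    train <- data; eval_set <- data; eval_type <- "training self-prediction"
  }
  x_train <- spectra_matrix(train)
  cv <- cv_select_lambda(x_train, train$.response, folds = folds,
                         seed = as.integer(seed) + 2L)
  model <- fit_multinomial_lasso(x_train, train$.response, lambda = cv$lambda_1se)
  pred <- predict_classes(model, spectra_matrix(eval_set))
  cm <- confusion_matrix(eval_set$.response, pred, labels = model$classes)
  structure(
    list(response = response,
         scheme = if (is.null(scheme)) "none" else attr(scheme, "name") %||% "custom",
         strain = strain %||% "all", train_frac = train_frac,
         eval_type = eval_type, n_train = nrow(train), n_eval = nrow(eval_set),
         seed = as.integer(seed), folds = folds,
         cv = cv, model = model, confusion = cm, cr = classification_rate(cm)),
    class = "grading_report"
  )
}

#' @export
print.grading_report <- function(x, ...) {
  cat(sprintf(
    "Grading experiment: response=%s, binning=%s, strain=%s\n",
    x$response, x$scheme, paste(x$strain, collapse = "+")
  ))
  cat(sprintf(
    "n_train=%d, n_eval=%d (%s), lambda_1se=%.4g\n",
    x$n_train, x$n_eval, x$eval_type, x$model$lambda
  ))
  cat(sprintf("Classification rate: %.1f%%\n", 100 * x$cr))
  invisible(x)
}

#' @export
print.grading_model <- function(x, ...) {
  cat(sprintf(
    "Multinomial LASSO model: %d classes, %d channels, lambda=%.4g (lambda_max=%.4g)\n",
    length(x$classes), nrow(x$beta), x$lambda, x$lambda_max
  ))
  cat(sprintf("Nonzero coefficients: %d\n", sum(x$beta != 0)))
  invisible(x)
}

#' @export
print.cv_lambda <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV over %d penalties: lambda_min=%.4g, lambda_1se=%.4g\n",
    x$folds, length(x$lambda), x$lambda_min, x$lambda_1se
  ))
  invisible(x)
}

#' Tidy methods for grading objects
#'
#' `tidy.cv_lambda()` returns the CV curve; `tidy.grading_model()` the nonzero
#' coefficient table (see [coefficient_map()]); `tidy.confusion_matrix()` the
#' long count table; `tidy.grading_report()` the report's confusion matrix.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cv_lambda
#' @export
tidy.cv_lambda <- function(x, ...) {
  tibble(lambda = x$lambda, mean_deviance = x$cvm, se = x$cvsd)
}

#' @rdname tidy.cv_lambda
#' @method tidy grading_model
#' @export
tidy.grading_model <- function(x, ...) coefficient_map(x)

#' @rdname tidy.cv_lambda
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- as.matrix(unclass(x))
  tibble(
    true = rep(rownames(m), times = ncol(m)),
    predicted = rep(colnames(m), each = nrow(m)),
    count = as.integer(m[cbind(
      rep(seq_len(nrow(m)), times = ncol(m)),
      rep(seq_len(ncol(m)), each = nrow(m))
    )])
  )
}

#' @rdname tidy.cv_lambda
#' @method tidy grading_report
#' @export
tidy.grading_report <- function(x, ...) tidy(x$confusion)

#' Glance methods for grading objects
#' @param x The object.
#' @param ... Unused.
#' @return A one-row tibble of summary figures.
#' @method glance cv_lambda
#' @export
glance.cv_lambda <- function(x, ...) {
  tibble(
    lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
    deviance_min = min(x$cvm), folds = x$folds, n = x$n
  )
}

#' @rdname glance.cv_lambda
#' @method glance grading_model
#' @export
glance.grading_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), n_channels = nrow(x$beta),
    lambda = x$lambda, lambda_max = x$lambda_max,
    n_nonzero = sum(x$beta != 0)
  )
}

#' @rdname glance.cv_lambda
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(n = sum(x), classification_rate = classification_rate(x))
}

#' @rdname glance.cv_lambda
#' @method glance grading_report
#' @export
glance.grading_report <- function(x, ...) {
  tibble(
    response = x$response, scheme = x$scheme,
    strain = paste(x$strain, collapse = "+"), eval_type = x$eval_type,
    n_train = x$n_train, n_eval = x$n_eval,
    lambda_1se = x$model$lambda, classification_rate = x$cr
  )
}

#' Plot a cross-validation curve
#' @param object A `cv_lambda` object.
#' @param ... Unused.
#' @return A ggplot object (deviance vs log lambda with 1-SE band and the two
#'   selected penalties).
#' @method autoplot cv_lambda
#' @export
autoplot.cv_lambda <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$mean_deviance)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_deviance - .data$se,
                   ymax = .data$mean_deviance + .data$se),
      size = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_vline(xintercept = log(object$lambda_min), linetype = 2) +
    ggplot2::geom_vline(xintercept = log(object$lambda_1se), linetype = 3) +
    ggplot2::labs(x = expression(log(lambda)), y = "Multinomial deviance (CV mean)",
                  title = "Cross-validation curve") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "True", fill = "Count") +
    ggplot2::theme_minimal()
}

#' Plot the signed coefficient map of a grading model
#'
#' Vertical bands at the wavenumbers with nonzero coefficients, green where an
#' intensity increase raises the predicted class likelihood and red where it
#' lowers it; the white background marks channels shrunk to zero.
#'
#' @param object A `grading_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grading_model
#' @export
autoplot.grading_model <- function(object, ...) {
  df <- coefficient_map(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "All coefficients are zero") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, xend = .data$wavenumber,
                                   y = 0, yend = .data$coefficient,
                                   colour = .data$direction)) +
    ggplot2::geom_segment() +
    ggplot2::scale_colour_manual(values = c(increase = "forestgreen",
                                            decrease = "firebrick")) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"), y = "Coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
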