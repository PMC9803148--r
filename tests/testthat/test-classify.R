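test_that("binning schemes map grades as printed", {
  lmh <- binning_scheme("lmh")
  zlmh <- binning_scheme("zlmh")
  expect_equal(as.character(bin_grades(0.3, lmh)), "Medium")
  expect_equal(as.character(bin_grades(0.3, zlmh)), "Low")
  expect_equal(as.character(bin_grades(0, zlmh)), "Zero")
  expect_equal(
    as.character(bin_grades(fibrosis_grade_levels(), lmh)),
    c("Low", "Low", "Low", "Medium", "Medium", "Medium", "High", "High")
  )
  expect_equal(
    as.character(bin_grades(fibrosis_grade_levels(), zlmh)),
    c("Zero", "Low", "Low", "Low", "Medium", "Medium", "High", "High")
  )
  # counts preserved
  expect_length(bin_grades(rep(0.5, 7), lmh), 7)
  # uncovered grade named in the error (0.2 is not an lmh fibrosis grade)
  expect_error(bin_grades(c(0, 0.2), lmh), "0.2")
})

test_that("train/test splitting is sized, disjoint, exhaustive and seeded", {
  d <- tibble::tibble(i = seq_len(2412))
  sp <- split_train_test(d, 0.7, seed = 99)
  expect_equal(nrow(sp$test), 724)  # round(0.7 * 2412) = 1688 train
  expect_equal(nrow(sp$train), 1688)
  expect_setequal(c(sp$train$i, sp$test$i), d$i)

  d10 <- tibble::tibble(i = 1:10)
  sp10 <- split_train_test(d10, 0.5, seed = 1)
  expect_equal(nrow(sp10$train), 5)
  expect_equal(nrow(sp10$test), 5)

  again <- split_train_test(d, 0.7, seed = 99)
  expect_identical(sp$train_idx, again$train_idx)
  expect_error(split_train_test(d[1, ], 0.7, 1), "at least 2")
  expect_error(split_train_test(d, 1, 1), "in \\(0, 1\\)")
})

test_that("total shrinkage at large penalties leaves intercept-only models", {
  d <- toy_grade_dataset(seed = 14)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  probe <- fit_multinomial_lasso(x, y, lambda = NULL)
  model <- fit_multinomial_lasso(x, y, lambda = 10 * probe$lambda_max)
  expect_true(all(model$beta == 0))
  # intercepts reproduce class frequencies through the softmax
  p <- exp(model$a0) / sum(exp(model$a0))
  expect_equal(unname(p), as.vector(prop.table(table(y))), tolerance = 1e-4)
})

test_that("a single discriminative channel dominates the fitted coefficients", {
  set.seed(15)
  n <- 120; p <- 15
  x <- matrix(rnorm(n * p, sd = 0.3), n, p)
  y <- rep(c(0, 1), each = n / 2)
  x[, 7] <- x[, 7] + 2 * y   # only channel 7 carries signal
  colnames(x) <- sprintf("%d", seq_len(p) + 1000)
  model <- fit_multinomial_lasso(x, factor(y), lambda = 0.01)
  mag <- rowSums(abs(model$beta))
  expect_equal(unname(which.max(mag)), 7L)
  # increasing channel 7 must favour class "1"
  expect_gt(model$beta[7, "1"], model$beta[7, "0"])

  # sign agrees with an unpenalized univariate logistic fit (oracle)
  uni <- suppressWarnings(glm(y ~ x[, 7], family = binomial()))
  expect_gt(coef(uni)[2] * (model$beta[7, "1"] - model$beta[7, "0"]), 0)
})

test_that("fitted coefficients are locally optimal for the penalized objective", {
  d <- toy_grade_dataset(n_per_class = 30, seed = 16)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  lam <- 0.005
  model <- fit_multinomial_lasso(x, y, lambda = lam)
  obj_hat <- ramgrade:::lasso_objective(model, x, y)
  set.seed(17)
  for (r in 1:100) {
    delta <- matrix(rnorm(length(model$beta)), nrow(model$beta))
    obj_pert <- ramgrade:::lasso_objective(
      model, x, y, beta = model$beta + 1e-3 * delta
    )
    expect_gte(obj_pert, obj_hat - 1e-6)
  }
})

test_that("multinomial deviance matches its closed forms", {
  d <- toy_grade_dataset(n_per_class = 10, seed = 18)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  K <- nlevels(y)
  n <- nrow(x)

  model <- fit_multinomial_lasso(x, y, lambda = 0.002)
  expect_gte(multinomial_deviance(model, x, y), 0)

  # uniform probabilities: deviance = 2 n log K
  uniform <- model
  uniform$beta[] <- 0
  uniform$a0[] <- 0
  expect_equal(multinomial_deviance(uniform, x, y), 2 * n * log(K), tolerance = 1e-10)

  # near-perfect probabilities: deviance ~ 0
  sure <- model
  sure$beta[] <- 0
  onehot <- sure
  dev <- 0
  for (i in seq_len(n)) {
    onehot$a0[] <- -1000
    onehot$a0[as.character(y[i])] <- 1000
    dev <- dev + multinomial_deviance(onehot, x[i, , drop = FALSE], y[i])
  }
  expect_equal(dev, 0, tolerance = 1e-6)

  expect_error(multinomial_deviance(model, x, rep("nope", n)), "classes")
})

test_that("cross-validation selects the penalty by the one-standard-error rule", {
  d <- toy_grade_dataset(n_per_class = 50, seed = 19)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  cv <- cv_select_lambda(x, y, folds = 5, seed = 20)

  expect_gte(cv$lambda_1se, cv$lambda_min)
  i_min <- which.min(cv$cvm)
  i_1se <- which(cv$lambda == cv$lambda_1se)
  expect_lte(cv$cvm[i_1se], cv$cvm[i_min] + cv$cvsd[i_min])
  # largest qualifying penalty: anything larger fails the 1-SE bound
  if (i_1se > 1) {
    expect_true(all(cv$cvm[seq_len(i_1se - 1)] > cv$cvm[i_min] + cv$cvsd[i_min]))
  }
  # deviance decomposition: the mean curve is the fold average, recomputed
  expect_equal(cv$cvm, colMeans(cv$fold_deviance), tolerance = 1e-12)
  expect_equal(cv$cvsd, apply(cv$fold_deviance, 2, sd) / sqrt(5), tolerance = 1e-12)

  # a one-point grid pins both selections to that point
  cv1 <- cv_select_lambda(x, y, folds = 5, seed = 20, nlambda = 1)
  expect_equal(cv1$lambda_1se, cv1$lambda_min)
  expect_length(cv1$lambda, 1)

  # rare classes are refused with advice to bin
  y_rare <- y
  y_rare[seq_len(3)] <- NA
  y_rare <- factor(ifelse(is.na(y_rare), "rare", as.character(y_rare)))
  expect_error(cv_select_lambda(x, y_rare, folds = 5, seed = 1), "binning")
})

test_that("well-separated classes reach high held-out accuracy at lambda_1se", {
  d <- toy_grade_dataset(n_per_class = 200, p = 25, effect = 1.5,
                         noise = 0.25, seed = 21)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  sp <- split_train_test(d, 0.7, seed = 22)
  xtr <- spectra_matrix(sp$train); ytr <- factor(sp$train$fibrosis_grade)
  cv <- cv_select_lambda(xtr, ytr, folds = 10, seed = 23)
  model <- fit_multinomial_lasso(xtr, ytr, lambda = cv$lambda_1se)
  pred <- predict_classes(model, spectra_matrix(sp$test))
  cr <- classification_rate(confusion_matrix(factor(sp$test$fibrosis_grade), pred))
  expect_gte(cr, 0.9)
})

test_that("argmax prediction breaks ties toward the lower grade", {
  d <- toy_grade_dataset(n_per_class = 10, seed = 24)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  model <- fit_multinomial_lasso(x, y, lambda = 0.002)
  zero <- model
  zero$beta[] <- 0
  zero$a0[] <- 0  # balanced intercepts: exact three-way tie everywhere
  pred <- predict_classes(zero, x)
  expect_true(all(pred == model$classes[1]))

  single <- predict_classes(model, x[1, , drop = FALSE])
  expect_length(single, 1)
  expect_error(predict_classes(model, x[, 1:3]), "channels")
})

test_that("confusion matrices match a brute-force tally", {
  set.seed(25)
  labs <- c("a", "b", "c", "d")
  y_true <- sample(labs, 1000, replace = TRUE)
  y_pred <- sample(labs, 1000, replace = TRUE)
  cm <- confusion_matrix(y_true, y_pred, labs)
  expect_equal(sum(cm), 1000)
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    expect_equal(cm[i, j], sum(y_true == labs[i] & y_pred == labs[j]))
  }

  # identity and perturbation behaviour
  cm_id <- confusion_matrix(y_true, y_true, labs)
  expect_equal(sum(diag(cm_id)), 1000)
  y_swap <- y_true
  k <- which(y_true == "a")[1]
  y_swap[k] <- "b"
  cm_sw <- confusion_matrix(y_true, y_swap, labs)
  expect_equal(sum(cm_sw != cm_id), 2)

  expect_error(confusion_matrix(y_true, y_pred, labs[1:2]), "outside")
})

test_that("the classification rate is trace over total", {
  cm3 <- read_confusion_csv(
    system.file("extdata", "confusion_binned_lmh.csv", package = "ramgrade")
  )
  expect_equal(classification_rate(cm3), 2363 / 2415)
  expect_equal(sum(cm3), 2415)
  # conservation: CR * n is exactly the trace
  expect_equal(classification_rate(cm3) * sum(cm3), sum(diag(cm3)))

  ident <- confusion_matrix(c("x", "y"), c("x", "y"))
  expect_equal(classification_rate(ident), 1)
  wrong <- confusion_matrix(c("x", "y"), c("y", "x"))
  expect_equal(classification_rate(wrong), 0)
  expect_error(classification_rate(matrix(0, 2, 2)), "Empty")
})

test_that("coefficient maps partition channels into the display trichotomy", {
  d <- toy_grade_dataset(seed = 26)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  model <- fit_multinomial_lasso(x, y, lambda = 0.01)
  cmap <- coefficient_map(model)
  expect_true(all(cmap$coefficient != 0))
  expect_true(all(cmap$direction %in% c("increase", "decrease")))
  # white channels = everything absent from the table, per class
  n_white <- sum(model$beta == 0)
  expect_equal(nrow(cmap) + n_white, length(model$beta))
  # the loaded signal channels dominate
  top <- cmap |> dplyr::group_by(channel) |>
    dplyr::summarise(m = sum(abs(coefficient))) |> dplyr::arrange(dplyr::desc(m))
  expect_true(top$channel[1] %in% sprintf("%d", c(5, 12, 23) + 1000))

  allzero <- fit_multinomial_lasso(x, y, lambda = 10 * model$lambda_max)
  expect_equal(nrow(coefficient_map(allzero)), 0)
})

test_that("nonzero-coefficient counts grow monotonically down the penalty path", {
  d <- toy_grade_dataset(n_per_class = 60, seed = 27)
  x <- spectra_matrix(d)
  y <- factor(d$fibrosis_grade)
  model <- fit_multinomial_lasso(x, y, nlambda = 40)
  path <- model$path
  nz <- vapply(seq_along(path$lambda), function(l) {
    sum(vapply(path$beta, function(b) sum(b[, l] != 0), numeric(1)))
  }, numeric(1))
  expect_equal(nz[1], 0)  # all-zero at lambda_max
  expect_true(all(diff(nz) >= 0))
})

test_that("grading experiments honour binning, strain filters and splits", {
  d <- toy_grade_dataset(n_per_class = 60, seed = 28)
  d$strain <- rep(c("C57BL/6J", "C3H/HeJ"), length.out = nrow(d))

  rep_b <- run_grading_experiment(
    d, "fibrosis", scheme = binning_scheme("lmh"), seed = 1, folds = 5
  )
  expect_equal(dim(rep_b$confusion), c(3, 3))
  expect_equal(rep_b$eval_type, "training self-prediction")

  expect_error(
    run_grading_experiment(d, "fibrosis", strain = "BALB/c", seed = 1),
    "Strain filter"
  )

  # optimism: self-prediction CR is at least the held-out CR (several seeds)
  for (s in 1:3) {
    full <- run_grading_experiment(d, "fibrosis", seed = s, folds = 5)
    split <- run_grading_experiment(d, "fibrosis", train_frac = 0.7,
                                    seed = s, folds = 5)
    expect_gte(full$cr + 1e-9, split$cr)
  }
})
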