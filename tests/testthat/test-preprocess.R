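make_table <- function(vals, labels = NULL) {
  vals <- as.matrix(vals)
  if (is.null(colnames(vals))) colnames(vals) <- paste0("f",
                                                        seq_len(ncol(vals)))
  if (is.null(labels)) labels <- rep("A", nrow(vals))
  feature_table(vals, labels = labels, label_set = unique(labels))
}

test_that("mean imputation fills masked cells with the non-missing mean", {
  tbl <- make_table(cbind(a = c(1, NA, 3), b = c(4, 5, 6)))
  model <- fit_imputer(tbl)
  expect_equal(unname(model$column_means), c(2, 5))
  imputed <- apply_imputer(model, tbl)
  expect_equal(unname(imputed$values[, "a"]), c(1, 2, 3))
  expect_false(any(imputed$missing_mask))
})

test_that("imputation is the identity when nothing is missing", {
  tbl <- random_missing_table(10, 4, missing_rate = 0, seed = 3)
  model <- fit_imputer(tbl)
  expect_identical(apply_imputer(model, tbl)$values, tbl$values)
})

test_that("imputation preserves each column's non-missing mean", {
  for (seed in 1:5) {
    tbl <- random_missing_table(50, 8, missing_rate = 0.2, seed = seed)
    before <- colMeans(tbl$values, na.rm = TRUE)
    model <- fit_imputer(tbl)
    after <- colMeans(apply_imputer(model, tbl)$values)
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("an all-missing feature fails imputation, naming the feature", {
  vals <- cbind(ok = c(1, 2), dead = c(NA_real_, NA_real_))
  expect_error(fit_imputer(make_table(vals)), "dead")
})

test_that("an all-missing held-out row imputes to the column means", {
  train <- make_table(cbind(a = c(1, 3), b = c(10, 20)))
  model <- fit_imputer(train)
  heldout <- make_table(cbind(a = NA_real_, b = NA_real_))
  expect_equal(unname(apply_imputer(model, heldout)$values[1, ]), c(2, 15))
})

test_that("min-max maps the training range onto [0, 1]", {
  tbl <- make_table(cbind(x = c(0, 5, 10)))
  fit <- fit_transform_scaler(fit_imputer(tbl), tbl, "MINMAX")
  expect_equal(unname(fit$table$values[, 1]), c(0, 0.5, 1))
})

test_that("standardization uses the population deviation", {
  tbl <- make_table(cbind(x = c(2, 4)))
  fit <- fit_transform_scaler(fit_imputer(tbl), tbl, "STANDARDIZE")
  expect_equal(unname(fit$table$values[, 1]), c(-1, 1))  # mean 3, dev 1
})

test_that("a constant feature rescales to all zeros", {
  tbl <- make_table(cbind(x = c(7, 7, 7), y = c(1, 2, 3)))
  for (tr in c("MINMAX", "STANDARDIZE", "LOG_MINMAX")) {
    fit <- fit_transform_scaler(fit_imputer(tbl), tbl, tr)
    expect_equal(unname(fit$table$values[, "x"]), c(0, 0, 0))
  }
})

test_that("log transform demands positive shifted values", {
  tbl <- make_table(cbind(x = c(0, 1, 2)))
  expect_error(
    fit_transform_scaler(fit_imputer(tbl), tbl, "LOG_MINMAX",
                         log_shift = 0),
    "log_shift")
  fit <- fit_transform_scaler(fit_imputer(tbl), tbl, "LOG_MINMAX",
                              log_shift = 1)
  expect_equal(unname(fit$table$values[, 1]),
               (log(c(0, 1, 2) + 1) - log(1)) / (log(3) - log(1)))
})

test_that("applying the fitted scaler to the training table is idempotent", {
  for (tr in c("MINMAX", "STANDARDIZE", "LOG_MINMAX")) {
    tbl <- random_missing_table(25, 6, missing_rate = 0, seed = 5)
    tbl$values <- abs(tbl$values); tbl <- make_table(tbl$values, tbl$labels)
    fit <- fit_transform_scaler(fit_imputer(tbl), tbl, tr)
    expect_equal(apply_scaler(fit$model, tbl)$values, fit$table$values)
  }
})

test_that("held-out values beyond the training range are not clipped", {
  train <- make_table(cbind(x = c(0, 10)))
  fit <- fit_transform_scaler(fit_imputer(train), train, "MINMAX")
  heldout <- make_table(cbind(x = c(-5, 15)))
  out <- apply_scaler(fit$model, heldout)$values[, 1]
  expect_equal(unname(out), c(-0.5, 1.5))
})

test_that("min-max training output always lies in [0, 1]", {
  for (seed in 1:5) {
    tbl <- random_missing_table(30, 7, missing_rate = 0.1, seed = seed)
    pre <- fit_preprocess(tbl, "MINMAX")
    expect_true(all(pre$table$values >= 0 & pre$table$values <= 1))
    expect_equal(unname(apply(pre$table$values, 2, min)), rep(0, 7))
    expect_equal(unname(apply(pre$table$values, 2, max)), rep(1, 7))
  }
})

test_that("standardized training output has mean 0 and population dev 1", {
  tbl <- random_missing_table(40, 5, missing_rate = 0.15, seed = 9)
  pre <- fit_preprocess(tbl, "STANDARDIZE")
  expect_equal(unname(colMeans(pre$table$values)), rep(0, 5),
               tolerance = 1e-12)
  devs <- sqrt(colMeans(sweep(pre$table$values, 2,
                              colMeans(pre$table$values))^2))
  expect_equal(unname(devs), rep(1, 5), tolerance = 1e-12)
})

test_that("scaling an unfitted model or an unimputed table is an error", {
  tbl <- make_table(cbind(x = c(1, NA, 3)))
  model <- fit_imputer(tbl)
  expect_error(apply_scaler(model, tbl), "not been fitted")
  full <- make_table(cbind(x = c(1, 2, 3)))
  fit <- fit_transform_scaler(fit_imputer(full), full, "MINMAX")
  expect_error(apply_scaler(fit$model, make_table(cbind(x = c(1, NA)))),
               "imputed")
  wrong <- make_table(cbind(y = c(1, 2)))
  expect_error(apply_scaler(fit$model, wrong), "feature names")
})

test_that("fitted preprocess models survive JSON serialization", {
  tbl <- random_missing_table(20, 4, missing_rate = 0.2, seed = 13)
  pre <- fit_preprocess(tbl, "LOG_MINMAX")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(pre$model, path)
  back <- read_model(path)
  expect_s3_class(back, "preprocess_model")
  expect_equal(apply_preprocess(back, tbl)$values, pre$table$values)
})
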