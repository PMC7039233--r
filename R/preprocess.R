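#' Fit mean imputation on the non-missing entries of each feature
#'
#' Records, per feature, the arithmetic mean of its non-missing values.
#' Applying the fitted model ([apply_imputer()]) replaces every masked cell
#' by its column mean, so the non-missing mean of each column is preserved
#' exactly.  A feature that is missing in every row cannot be imputed and
#' raises an error naming it.
#'
#' @param table A [feature_table()]; typically a training fold.
#' @return A partial \code{"preprocess_model"} holding \code{column_means};
#'   complete it with [fit_transform_scaler()].
#' @export
fit_imputer <- function(table) {
  validate_feature_table(table)
  means <- colMeans(table$values, na.rm = TRUE)
  all_missing <- table$feature_names[!is.finite(means)]
  if (length(all_missing)) {
    stop("cannot impute feature(s) with no observed values: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  structure(list(feature_names = table$feature_names,
                 column_means = means,
                 transform = NULL,
                 log_shift = NULL,
                 x_min = NULL, x_max = NULL,
                 x_mean = NULL, x_dev = NULL),
            class = "preprocess_model")
}

check_feature_names <- function(model_names, table) {
  if (!identical(model_names, table$feature_names)) {
    stop("feature names of the table do not match the fitted model",
         call. = FALSE)
  }
}

#' Replace missing cells by the fitted column means
#'
#' @param model A \code{"preprocess_model"} from [fit_imputer()].
#' @param table A [feature_table()] with the same feature names.
#' @return The table with every masked cell filled and the mask cleared.
#' @export
apply_imputer <- function(model, table) {
  stopifnot(inherits(model, "preprocess_model"))
  validate_feature_table(table)
  check_feature_names(model$feature_names, table)
  vals <- table$values
  if (any(table$missing_mask)) {
    fill <- matrix(model$column_means, nrow = nrow(vals),
                   ncol = ncol(vals), byrow = TRUE)
    vals[table$missing_mask] <- fill[table$missing_mask]
  }
  feature_table(vals, labels = table$labels,
                feature_names = table$feature_names,
                label_set = table$label_set, blocks = table$blocks)
}

#' Fit and apply the rescaling transform on a training table
#'
#' Completes a \code{"preprocess_model"} with the per-feature statistics of
#' one of three transforms and returns the rescaled training table:
#' \describe{
#'   \item{\code{MINMAX}}{\eqn{(x - x_{min}) / (x_{max} - x_{min})}, mapping
#'     the training minimum to 0 and maximum to 1.}
#'   \item{\code{LOG_MINMAX}}{natural log \eqn{\ln(x + s)} (shift \eqn{s =}
#'     \code{log_shift}) followed by min-max on the log scale; requires
#'     \eqn{x + s > 0} everywhere.}
#'   \item{\code{STANDARDIZE}}{\eqn{(x - x_{mean}) / x_{dev}} with the
#'     population standard deviation (divide by \eqn{n}).}
#' }
#' A constant feature (zero range or zero deviation) maps to 0 for every
#' sample.  Statistics are recorded from this table only, so held-out data
#' rescaled with [apply_scaler()] may legitimately fall outside \[0, 1\];
#' no clipping is applied.
#'
#' @param model A \code{"preprocess_model"} from [fit_imputer()].
#' @param table A fully imputed [feature_table()] (no missing cells).
#' @param transform One of \code{"LOG_MINMAX"}, \code{"MINMAX"},
#'   \code{"STANDARDIZE"}.
#' @param log_shift Non-negative shift used by \code{LOG_MINMAX}
#'   (default 1).
#' @return \code{list(model = completed model, table = rescaled table)}.
#' @export
fit_transform_scaler <- function(model, table,
                                 transform = c("LOG_MINMAX", "MINMAX",
                                               "STANDARDIZE"),
                                 log_shift = 1) {
  stopifnot(inherits(model, "preprocess_model"))
  validate_feature_table(table)
  check_feature_names(model$feature_names, table)
  transform <- match.arg(toupper(transform[1L]),
                         c("LOG_MINMAX", "MINMAX", "STANDARDIZE"))
  if (any(table$missing_mask)) {
    stop("table must be imputed before scaling (missing cells present)",
         call. = FALSE)
  }
  x <- table$values
  model$transform <- transform
  model$log_shift <- as.numeric(log_shift)
  if (transform == "LOG_MINMAX") {
    if (any(x + log_shift <= 0)) {
      stop("nonpositive value under LOG_MINMAX; increase log_shift ",
           "(ln(x + log_shift) requires x + log_shift > 0)", call. = FALSE)
    }
    x <- log(x + log_shift)
  }
  if (transform == "STANDARDIZE") {
    n <- nrow(x)
    model$x_mean <- colMeans(x)
    centered <- sweep(x, 2L, model$x_mean)
    model$x_dev <- sqrt(colSums(centered^2) / n)  # population convention
  } else {
    model$x_min <- apply(x, 2L, min)
    model$x_max <- apply(x, 2L, max)
  }
  list(model = model, table = apply_scaler(model, table))
}

#' Apply a fitted rescaling transform
#'
#' Applies the transform recorded by [fit_transform_scaler()] using the
#' training statistics.  Held-out values outside the training range are NOT
#' clipped: the transforms are linear (or log-linear) maps, not clamps.
#'
#' @param model A completed \code{"preprocess_model"}.
#' @param table An imputed [feature_table()] with matching feature names.
#' @return The rescaled table.
#' @export
apply_scaler <- function(model, table) {
  stopifnot(inherits(model, "preprocess_model"))
  if (is.null(model$transform)) {
    stop("scaler has not been fitted; call fit_transform_scaler() first",
         call. = FALSE)
  }
  validate_feature_table(table)
  check_feature_names(model$feature_names, table)
  if (any(table$missing_mask)) {
    stop("table must be imputed before scaling (missing cells present)",
         call. = FALSE)
  }
  x <- table$values
  if (model$transform == "LOG_MINMAX") {
    if (any(x + model$log_shift <= 0)) {
      stop("nonpositive value under LOG_MINMAX; increase log_shift",
           call. = FALSE)
    }
    x <- log(x + model$log_shift)
  }
  if (model$transform == "STANDARDIZE") {
    dev <- model$x_dev
    safe <- ifelse(dev > 0, dev, 1)
    x <- sweep(sweep(x, 2L, model$x_mean), 2L, safe, "/")
    x[, dev == 0] <- 0
  } else {
    rng <- model$x_max - model$x_min
    safe <- ifelse(rng > 0, rng, 1)
    x <- sweep(sweep(x, 2L, model$x_min), 2L, safe, "/")
    x[, rng == 0] <- 0
  }
  feature_table(x, labels = table$labels,
                feature_names = table$feature_names,
                label_set = table$label_set, blocks = table$blocks)
}

#' One-call training-fold preprocessing: impute then rescale
#'
#' @inheritParams fit_transform_scaler
#' @return \code{list(model, table)} as in [fit_transform_scaler()].
#' @export
fit_preprocess <- function(table,
                           transform = c("LOG_MINMAX", "MINMAX",
                                         "STANDARDIZE"),
                           log_shift = 1) {
  model <- fit_imputer(table)
  fit_transform_scaler(model, apply_imputer(model, table),
                       transform = transform, log_shift = log_shift)
}

#' Apply a fitted preprocessing model (imputation + rescaling)
#'
#' @param model A completed \code{"preprocess_model"}.
#' @param table A [feature_table()] (may contain missing cells).
#' @return The imputed, rescaled table.
#' @export
apply_preprocess <- function(model, table) {
  apply_scaler(model, apply_imputer(model, table))
}
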