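#' Fit principal component analysis on a preprocessed table
#'
#' Classical linear PCA on the training covariance matrix (1/(n-1)
#' normalization) via the singular value decomposition.  Components are the
#' top eigenvectors, ordered by decreasing eigenvalue, under a deterministic
#' sign convention: each component's entry of largest magnitude is positive
#' (ties broken by the lowest feature index), since an eigenvector's sign is
#' otherwise undefined.
#'
#' @param table An imputed, scaled [feature_table()].
#' @param n_components Number of components to keep; must lie in
#'   \code{[1, min(n_samples - 1, n_features)]}.
#' @return An object of class \code{"projection_model"} with fields
#'   \code{center} (training mean vector), \code{components}
#'   (\code{n_components x n_features}, orthonormal rows),
#'   \code{explained_variance} (eigenvalues), and \code{explained_fraction}
#'   (eigenvalue over the total variance of the training table).
#' @export
fit_pca <- function(table, n_components = 25L) {
  validate_feature_table(table)
  if (any(table$missing_mask)) {
    stop("table must be imputed before PCA (missing cells present)",
         call. = FALSE)
  }
  n <- nrow(table$values)
  p <- ncol(table$values)
  kmax <- min(n - 1L, p)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax) {
    stop(sprintf("n_components must lie in [1, %d] for %d x %d data",
                 kmax, n, p), call. = FALSE)
  }
  pr <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  comp <- t(pr$rotation[, seq_len(n_components), drop = FALSE])
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))   # first index on ties
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  ev <- pr$sdev[seq_len(n_components)]^2
  total_var <- sum(apply(table$values, 2L, stats::var))
  structure(list(feature_names = table$feature_names,
                 center = stats::setNames(colMeans(table$values),
                                          table$feature_names),
                 components = comp,
                 explained_variance = ev,
                 explained_fraction = if (total_var > 0) ev / total_var
                                      else rep(0, n_components),
                 n_components = n_components),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %d components over %d features\n",
              x$n_components, length(x$feature_names)))
  cat(sprintf("  cumulative explained fraction: %.4f\n",
              sum(x$explained_fraction)))
  invisible(x)
}

#' Project a table onto fitted principal components
#'
#' Returns \code{(values - center) \%*\% t(components)} as a new table with
#' feature names \code{PC1..PCk}; labels are carried through and block tags
#' reset to \code{OTHER} (a component mixes modalities).
#'
#' @param model A \code{"projection_model"} from [fit_pca()].
#' @param table A [feature_table()] with matching feature names.
#' @return A [feature_table()] of component scores.
#' @export
project <- function(model, table) {
  stopifnot(inherits(model, "projection_model"))
  validate_feature_table(table)
  check_feature_names(model$feature_names, table)
  if (any(table$missing_mask)) {
    stop("table must be imputed before projection", call. = FALSE)
  }
  scores <- sweep(table$values, 2L, model$center) %*% t(model$components)
  feature_table(scores, labels = table$labels,
                feature_names = paste0("PC", seq_len(model$n_components)),
                label_set = table$label_set)
}

#' Smallest number of components reaching a target explained-variance
#' fraction
#'
#' Scans the cumulative explained fractions of a fitted model and returns
#' the smallest k whose cumulative fraction reaches \code{target_fraction}.
#' If the model's stored components never reach the target, returns
#' \code{NA} with a warning (fit more components).
#'
#' @param model A \code{"projection_model"}.
#' @param target_fraction Real in (0, 1].
#' @return Integer count of components, or \code{NA_integer_}.
#' @export
components_for_variance <- function(model, target_fraction) {
  stopifnot(inherits(model, "projection_model"))
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be a single value in (0, 1]", call. = FALSE)
  }
  cum <- cumsum(model$explained_fraction)
  hit <- which(cum >= target_fraction - 1e-9)
  if (!length(hit)) {
    warning("stored components explain only ",
            sprintf("%.4f", cum[length(cum)]),
            " of the variance; target not reached")
    return(NA_integer_)
  }
  as.integer(hit[1L])
}
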