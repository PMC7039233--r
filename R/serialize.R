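#' Serialize fitted models to plain JSON text
#'
#' Fitted preprocessing, projection and classifier models are small named
#' lists of numeric vectors/matrices; writing them as JSON (full double
#' precision) makes a run reproducible and auditable without binary files.
#'
#' @param model A \code{"preprocess_model"}, \code{"projection_model"} or
#'   \code{"classifier_model"}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("preprocess_model", "projection_model",
                   "classifier_model")) {
    stop("not a serializable model: ", kind, call. = FALSE)
  }
  payload <- lapply(unclass(model), function(x) {
    if (is.matrix(x)) list(.matrix = TRUE, nrow = nrow(x),
                           data = as.numeric(t(x)))
    else if (is.numeric(x)) unname(x)   # names are carried by feature_names
    else x
  })
  payload$.class <- kind
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path Path to a JSON model file.
#' @return The model with its original class.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- payload$.class
  payload$.class <- NULL
  out <- lapply(payload, function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      matrix(as.numeric(x$data), nrow = x$nrow, byrow = TRUE)
    } else x
  })
  structure(out, class = kind)
}
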