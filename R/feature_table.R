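#' Labeled samples-by-features table with an explicit missing-value mask
#'
#' The universal currency of the pipeline: a numeric matrix of samples by
#' named features, a class label per sample, an explicit logical mask marking
#' missing cells, and optional modality-block tags per feature (e.g.
#' \code{"PET"}, \code{"CSF"}).  Missing cells hold \code{NA} in
#' \code{values} and \code{TRUE} in \code{missing_mask}, so no downstream
#' arithmetic can silently consume them before imputation.
#'
#' @param values Numeric matrix, \code{n_samples x n_features}.  Cells that
#'   are missing must be \code{NA}.
#' @param labels Character (or factor) vector of per-sample class codes,
#'   length \code{nrow(values)}.
#' @param feature_names Character vector of unique column names; defaults to
#'   \code{colnames(values)}.
#' @param label_set Character vector of admissible class codes; defaults to
#'   the sorted unique labels.  A label outside this set is a schema error.
#' @param blocks Optional named character vector mapping feature name to a
#'   block tag among \code{MRI_VOXEL, MRI_VOLUME, PET, CSF, MMSE,
#'   DEMOGRAPHIC, OTHER}.  Unlisted features default to \code{"OTHER"}.
#'
#' @return An object of class \code{"feature_table"}: a list with elements
#'   \code{values}, \code{feature_names}, \code{labels}, \code{label_set},
#'   \code{missing_mask}, \code{blocks}.
#' @seealso [read_feature_table()], [subset_binary()]
#' @export
feature_table <- function(values, labels, feature_names = colnames(values),
                          label_set = NULL, blocks = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("feature_", seq_len(ncol(values)))
  }
  feature_names <- as.character(feature_names)
  labels <- as.character(labels)
  if (is.null(label_set)) label_set <- sort(unique(labels))
  blocks <- normalize_blocks(blocks, feature_names)
  colnames(values) <- feature_names
  tbl <- structure(
    list(values = values,
         feature_names = feature_names,
         labels = labels,
         label_set = as.character(label_set),
         missing_mask = is.na(values),
         blocks = blocks),
    class = "feature_table")
  validate_feature_table(tbl)
  tbl
}

block_tags <- function() {
  c("MRI_VOXEL", "MRI_VOLUME", "PET", "CSF", "MMSE", "DEMOGRAPHIC", "OTHER")
}

normalize_blocks <- function(blocks, feature_names) {
  out <- stats::setNames(rep("OTHER", length(feature_names)), feature_names)
  if (!is.null(blocks)) {
    blocks <- unlist(blocks)
    unknown <- setdiff(names(blocks), feature_names)
    if (length(unknown)) {
      stop("block map names features not in the table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unique(blocks), block_tags())
    if (length(bad)) {
      stop("unknown block tag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out[names(blocks)] <- blocks
  }
  out
}

validate_feature_table <- function(tbl) {
  stopifnot(inherits(tbl, "feature_table"))
  if (length(tbl$feature_names) != ncol(tbl$values)) {
    stop("feature_names length must equal the number of columns",
         call. = FALSE)
  }
  dup <- tbl$feature_names[duplicated(tbl$feature_names)]
  if (length(dup)) {
    stop("duplicate feature name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (length(tbl$labels) != nrow(tbl$values)) {
    stop("labels length must equal the number of rows", call. = FALSE)
  }
  bad <- setdiff(unique(tbl$labels), tbl$label_set)
  if (length(bad)) {
    stop("label(s) outside the declared label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!identical(dim(tbl$missing_mask), dim(tbl$values))) {
    stop("missing_mask must have the same shape as values", call. = FALSE)
  }
  if (!identical(unname(tbl$missing_mask), unname(is.na(tbl$values)))) {
    stop("missing_mask must be TRUE exactly where values is NA",
         call. = FALSE)
  }
  invisible(tbl)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$labels, levels = x$label_set))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  blk <- table(x$blocks)
  cat("  blocks:", paste(sprintf("%s=%d", names(blk), blk), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

n_samples <- function(tbl) nrow(tbl$values)
n_features <- function(tbl) ncol(tbl$values)

#' Row subset helper keeping all invariants intact
#' @noRd
ft_rows <- function(tbl, idx) {
  feature_table(tbl$values[idx, , drop = FALSE],
                labels = tbl$labels[idx],
                feature_names = tbl$feature_names,
                label_set = tbl$label_set,
                blocks = tbl$blocks)
}

#' Read a delimited feature table
#'
#' Reads a CSV with one header row of feature names plus one label column.
#' Cells equal to \code{missing_token} (or empty) become missing; any other
#' non-numeric cell is a parse error naming the offending column and line.
#'
#' @param path Path to a delimited text file.
#' @param label_column Name of the label column (default \code{"label"}).
#' @param missing_token String encoding a missing cell (default empty).
#' @param label_set Optional admissible class codes; labels outside it are a
#'   schema error.
#' @param block_map Optional block annotation: either a named character
#'   vector (feature -> tag) or the path to a two-column CSV with columns
#'   \code{feature_name, block}.
#' @param sep Field separator (default comma).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               missing_token = "", label_set = NULL,
                               block_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            blank.lines.skip = FALSE)
  if (length(nf) == 0L) stop("empty file: ", path, call. = FALSE)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("parse error in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, sep = sep)
  hdr <- names(raw)
  if (!(label_column %in% hdr)) {
    stop("label column '", label_column, "' not found in header",
         call. = FALSE)
  }
  dup <- hdr[duplicated(hdr)]
  if (length(dup)) {
    stop("duplicate feature name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  feat_cols <- hdr[hdr != label_column]
  n <- nrow(raw)
  values <- matrix(NA_real_, nrow = n, ncol = length(feat_cols),
                   dimnames = list(NULL, feat_cols))
  for (j in feat_cols) {
    cell <- raw[[j]]
    miss <- is.na(cell) | cell == missing_token | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "parse error: non-numeric value '%s' in column '%s', data row %d",
        cell[bad[1L]], j, bad[1L]), call. = FALSE)
    }
    num[miss] <- NA_real_
    values[, j] <- num
  }
  labels <- raw[[label_column]]
  if (!is.null(label_set)) {
    bad <- setdiff(unique(labels), label_set)
    if (length(bad)) {
      stop("label(s) outside the declared label set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  blocks <- read_block_map(block_map)
  if (!is.null(blocks)) blocks <- blocks[intersect(names(blocks), feat_cols)]
  feature_table(values, labels = labels, feature_names = feat_cols,
                label_set = label_set, blocks = blocks)
}

read_block_map <- function(block_map) {
  if (is.null(block_map)) return(NULL)
  if (is.character(block_map) && length(block_map) == 1L &&
      is.null(names(block_map)) && file.exists(block_map)) {
    df <- utils::read.csv(block_map, colClasses = "character",
                          check.names = FALSE)
    if (!all(c("feature_name", "block") %in% names(df))) {
      stop("block map file must have columns feature_name, block",
           call. = FALSE)
    }
    return(stats::setNames(df$block, df$feature_name))
  }
  unlist(block_map)
}

#' Write a feature table as delimited text
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' is bit-identical; missing cells are written as \code{missing_token}.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @param label_column Header name for the label column.
#' @param missing_token String written for missing cells (default empty).
#' @param block_map_path Optional path; when given, the feature -> block map
#'   is written there as a two-column CSV (\code{feature_name, block}).
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(table, path, label_column = "label",
                                missing_token = "", block_map_path = NULL) {
  validate_feature_table(table)
  if (label_column %in% table$feature_names) {
    stop("label column name collides with a feature name: ", label_column,
         call. = FALSE)
  }
  chr <- matrix(sprintf("%.17g", table$values), nrow = nrow(table$values))
  chr[table$missing_mask] <- missing_token
  header <- paste(c(table$feature_names, label_column), collapse = ",")
  rows <- if (nrow(chr) > 0L) {
    paste(apply(cbind(chr, table$labels), 1L, paste, collapse = ","))
  } else character()
  ok <- tryCatch({
    writeLines(c(header, rows), con = path)
    TRUE
  }, error = function(e) {
    stop("cannot write feature table to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(block_map_path)) {
    utils::write.csv(
      data.frame(feature_name = table$feature_names,
                 block = unname(table$blocks[table$feature_names]),
                 stringsAsFactors = FALSE),
      block_map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Restrict a table to a binary classification problem
#'
#' Keeps the rows whose label is one of the two classes of
#' \code{label_pair}, preserving row order.  The first element of the pair
#' is the positive class for all downstream metrics.
#'
#' @param table A [feature_table()].
#' @param label_pair Ordered character vector of two distinct class codes,
#'   \code{c(positive, negative)}.
#' @return A [feature_table()] whose label set is exactly \code{label_pair}.
#' @export
subset_binary <- function(table, label_pair) {
  validate_feature_table(table)
  label_pair <- as.character(label_pair)
  if (length(label_pair) != 2L || label_pair[1L] == label_pair[2L]) {
    stop("label_pair must be two distinct class codes", call. = FALSE)
  }
  for (cl in label_pair) {
    if (!any(table$labels == cl)) {
      stop("class absent from table: ", cl, call. = FALSE)
    }
  }
  keep <- which(table$labels %in% label_pair)
  feature_table(table$values[keep, , drop = FALSE],
                labels = table$labels[keep],
                feature_names = table$feature_names,
                label_set = label_pair,
                blocks = table$blocks)
}
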