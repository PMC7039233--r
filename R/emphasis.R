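#' Replication plan: how many horizontal copies each feature receives
#'
#' The core object of emphasis learning.  A homogeneous plan replicates the
#' whole reduced feature block \code{factor} times; a heterogeneous plan
#' gives feature j \code{counts[j]} copies, emphasizing some features more
#' than others.
#'
#' @param mode \code{"HOMOGENEOUS"} or \code{"HETEROGENEOUS"}.
#' @param factor Positive integer replication factor (homogeneous mode).
#' @param counts Integer vector of per-feature copy counts, all >= 1
#'   (heterogeneous mode).
#' @return An object of class \code{"emphasis_plan"}.
#' @export
emphasis_plan <- function(mode = c("HOMOGENEOUS", "HETEROGENEOUS"),
                          factor = 1L, counts = NULL) {
  mode <- match.arg(toupper(mode[1L]), c("HOMOGENEOUS", "HETEROGENEOUS"))
  if (mode == "HOMOGENEOUS") {
    factor <- as.integer(factor)
    if (length(factor) != 1L || is.na(factor) || factor < 1L) {
      stop("homogeneous plan needs a single replication factor >= 1",
           call. = FALSE)
    }
    counts <- NULL
  } else {
    if (is.null(counts)) stop("heterogeneous plan needs counts",
                              call. = FALSE)
    counts <- as.integer(counts)
    if (any(is.na(counts)) || any(counts < 1L)) {
      stop("every replication count must be a positive integer",
           call. = FALSE)
    }
    factor <- NA_integer_
  }
  structure(list(mode = mode, factor = factor, counts = counts),
            class = "emphasis_plan")
}

#' @export
print.emphasis_plan <- function(x, ...) {
  if (x$mode == "HOMOGENEOUS") {
    cat(sprintf("<emphasis_plan> homogeneous, factor %d\n", x$factor))
  } else {
    cat("<emphasis_plan> heterogeneous, counts:",
        paste(x$counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Replicate features in width according to a plan
#'
#' Homogeneous factor r appends r whole copies of the input block in order
#' (copy 1's columns, then copy 2's, ...), matching the append semantics of
#' the method's outer loop (\code{Data <- [Data, Reduced data]}).
#' Heterogeneous counts place the copies of each source column adjacently,
#' in input column order.  Output names carry a copy suffix
#' (\code{PC3#2} = second copy of PC3).  Every output column is
#' bit-identical to its source column; labels are unchanged.
#'
#' @param table A [feature_table()] with no missing values.
#' @param plan An [emphasis_plan()]; a heterogeneous plan's counts must
#'   match the table's feature count.
#' @return The widened [feature_table()] with \code{factor * k} (or
#'   \code{sum(counts)}) columns.
#' @export
replicate_features <- function(table, plan) {
  validate_feature_table(table)
  stopifnot(inherits(plan, "emphasis_plan"))
  if (any(table$missing_mask)) {
    stop("table must have no missing values before replication",
         call. = FALSE)
  }
  k <- ncol(table$values)
  if (plan$mode == "HOMOGENEOUS") {
    idx <- rep(seq_len(k), times = plan$factor)        # ABAB... layout
    copy <- rep(seq_len(plan$factor), each = k)
  } else {
    if (length(plan$counts) != k) {
      stop(sprintf("plan has %d counts but table has %d features",
                   length(plan$counts), k), call. = FALSE)
    }
    idx <- rep(seq_len(k), times = plan$counts)        # AABB... layout
    copy <- unlist(lapply(plan$counts, seq_len))
  }
  feature_table(table$values[, idx, drop = FALSE],
                labels = table$labels,
                feature_names = paste0(table$feature_names[idx], "#", copy),
                label_set = table$label_set)
}

#' Build the replication plan for a search round
#'
#' Round r of the homogeneous search replicates every feature r times.  In
#' heterogeneous mode the counts grow in proportion to a per-feature weight
#' vector (by default the components' explained variances, so
#' higher-variance components are emphasized more):
#' \code{counts[j] = max(1, round(r * w[j] / max(w)))}.
#'
#' @param round_index Positive integer round number (1 = no emphasis).
#' @param n_features Number of features of the reduced table.
#' @param mode \code{"HOMOGENEOUS"} or \code{"HETEROGENEOUS"}.
#' @param weights Optional positive per-feature weights (heterogeneous
#'   mode); defaults to equal weights when omitted.
#' @return An [emphasis_plan()].
#' @export
plan_for_round <- function(round_index, n_features,
                           mode = c("HOMOGENEOUS", "HETEROGENEOUS"),
                           weights = NULL) {
  round_index <- as.integer(round_index)
  if (is.na(round_index) || round_index < 1L) {
    stop("round_index must be a positive integer", call. = FALSE)
  }
  mode <- match.arg(toupper(mode[1L]), c("HOMOGENEOUS", "HETEROGENEOUS"))
  if (mode == "HOMOGENEOUS") {
    return(emphasis_plan("HOMOGENEOUS", factor = round_index))
  }
  if (is.null(weights)) weights <- rep(1, n_features)
  if (length(weights) != n_features) {
    stop(sprintf("weights has length %d but the reduced table has %d features",
                 length(weights), n_features), call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  counts <- pmax(1L, as.integer(round(round_index * weights / max(weights))))
  emphasis_plan("HETEROGENEOUS", counts = counts)
}
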