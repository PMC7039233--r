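#' Search the replication factor until performance stops improving
#'
#' The method's outer loop: round r evaluates the cross-validated pipeline
#' with the reduced features replicated according to
#' \code{plan_for_round(r, ...)} (homogeneous: r whole copies).  All rounds
#' share the same fold seeds, so round-to-round differences reflect
#' emphasis, not fold noise.  The search stops when the selection metric
#' has failed to exceed the running best by more than
#' \code{config$tolerance} for \code{config$patience} consecutive rounds
#' (\code{stop_reason "NO_IMPROVEMENT"}), or at
#' \code{config$max_repetitions} (\code{"MAX_ROUNDS"}).  The selected round
#' maximizes the selection metric over the evaluated rounds, ties going to
#' the smallest round.
#'
#' @param table A binary [feature_table()] (see [subset_binary()]).
#' @param config A [run_config()].
#' @param weights Optional per-feature weights for heterogeneous plans; by
#'   default the explained variances of a PCA fitted on the preprocessed
#'   full table, so higher-variance components are emphasized more.
#' @return An object of class \code{"search_trace"}: list with
#'   \code{rounds} (list of \code{list(round, plan, result)}),
#'   \code{selected_round}, \code{selection_metric}, \code{stop_reason}.
#' @export
run_emphasis_search <- function(table, config, weights = NULL) {
  validate_feature_table(table)
  stopifnot(inherits(config, "run_config"))
  metric_key <- tolower(config$selection_metric)
  if (config$emphasis_mode == "HETEROGENEOUS" && is.null(weights)) {
    pre <- fit_preprocess(table, transform = config$transform,
                          log_shift = config$log_shift)
    kmax <- min(nrow(table$values) - 1L, ncol(table$values))
    weights <- fit_pca(pre$table,
                       min(config$n_components, kmax))$explained_variance
  }
  rounds <- list()
  best <- -Inf
  stale <- 0L
  stop_reason <- "MAX_ROUNDS"
  for (r in seq_len(config$max_repetitions)) {
    plan <- plan_for_round(r, config$n_components, config$emphasis_mode,
                           weights)
    res <- cross_validate(table, config, plan = plan)
    rounds[[r]] <- list(round = r, plan = plan, result = res)
    m <- res$metrics[[metric_key]]
    if (m > best + config$tolerance) {
      best <- m
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience && r < config$max_repetitions) {
        stop_reason <- "NO_IMPROVEMENT"
        break
      }
    }
  }
  vals <- vapply(rounds, function(x) x$result$metrics[[metric_key]],
                 numeric(1))
  structure(list(rounds = rounds,
                 selected_round = which.max(vals),  # first max on ties
                 selection_metric = config$selection_metric,
                 stop_reason = stop_reason),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf(
    "<search_trace> %d round(s), selected round %d by %s (%s)\n",
    length(x$rounds), x$selected_round, x$selection_metric, x$stop_reason))
  print(summarize_trace(x), row.names = FALSE)
  invisible(x)
}

#' One row of metrics per evaluated search round
#'
#' Mirrors the usual grid report of the method (rounds by six metrics).  An
#' optional baseline evaluation of the unreduced feature set is prepended
#' as round 0.
#'
#' @param trace A \code{"search_trace"} from [run_emphasis_search()].
#' @param baseline Optional \code{"eval_result"} for the unreduced data
#'   (round 0 row), e.g. \code{cross_validate(table, config, reduce =
#'   FALSE)}.
#' @return A data frame with columns \code{round, acc, sen, spec, ppv, npv,
#'   auc, selected}.
#' @export
summarize_trace <- function(trace, baseline = NULL) {
  stopifnot(inherits(trace, "search_trace"))
  if (!length(trace$rounds)) stop("empty trace", call. = FALSE)
  row_of <- function(round, res, selected) {
    data.frame(round = round,
               acc = res$metrics[["acc"]], sen = res$metrics[["sen"]],
               spec = res$metrics[["spec"]], ppv = res$metrics[["ppv"]],
               npv = res$metrics[["npv"]], auc = res$metrics[["auc"]],
               selected = selected)
  }
  out <- do.call(rbind, lapply(trace$rounds, function(x) {
    row_of(x$round, x$result, x$round == trace$selected_round)
  }))
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "eval_result"))
    out <- rbind(row_of(0L, baseline, FALSE), out)
  }
  rownames(out) <- NULL
  out
}
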