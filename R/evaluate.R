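#' Confusion counts of a binary prediction
#'
#' @param truth Character vector of true class codes.
#' @param predicted Character vector of predicted class codes.
#' @param positive_label Class code counted as positive.
#' @return An object of class \code{"confusion_counts"} with integer fields
#'   \code{tp, tn, fp, fn}.
#' @export
confusion_counts <- function(truth, predicted, positive_label) {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == positive_label
  ppos <- predicted == positive_label
  structure(list(tp = sum(pos & ppos), tn = sum(!pos & !ppos),
                 fp = sum(!pos & ppos), fn = sum(pos & !ppos)),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, positive predictive value
#' and negative predictive value.  Any metric with a zero denominator (e.g.
#' sensitivity when no positives were evaluated) is undefined and returned
#' as \code{NA} with a warning; callers exclude such values from averaging.
#'
#' @param counts A [confusion_counts()] (or a list with tp, tn, fp, fn).
#' @return Named numeric vector \code{c(acc, sen, spec, ppv, npv)}.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1) stop("no evaluated samples (all counts zero)",
                      call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0 denominator); excluded from averages",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(acc = (tp + tn) / total,
    sen = ratio(tp, tp + fn, "sensitivity"),
    spec = ratio(tn, tn + fp, "specificity"),
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, tn + fn, "NPV"))
}

#' Area under the ROC curve from decision scores
#'
#' Tie-aware rank (Mann-Whitney) statistic:
#' \eqn{AUC = P(s_{pos} > s_{neg}) + \tfrac{1}{2} P(s_{pos} = s_{neg})},
#' identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric decision values, larger = more positive.
#' @param labels Class codes, same length as \code{scores}.
#' @param positive_label Class code treated as positive.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels, positive_label) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_label
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)                     # average ranks handle ties
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Stratified (or plain) fold assignment
#'
#' Assigns each sample to one of \code{n_folds} folds using the current RNG
#' state.  Stratified assignment permutes each class separately and deals
#' it round-robin, so fold sizes per class differ by at most one.
#' @noRd
make_folds <- function(labels, n_folds, stratified = TRUE) {
  n <- length(labels)
  if (n < n_folds) {
    stop(sprintf("need at least %d samples for %d folds", n_folds, n_folds),
         call. = FALSE)
  }
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        stop(sprintf(
          "stratification infeasible: class '%s' has %d samples, minimum is %d",
          cl, length(idx), n_folds), call. = FALSE)
      }
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Fit the full per-fold pipeline: preprocess -> PCA -> replicate -> SVM
#' @noRd
fit_fold_pipeline <- function(train, config, plan, reduce = TRUE,
                              pre = NULL) {
  if (is.null(pre)) {
    pre <- fit_preprocess(train, transform = config$transform,
                          log_shift = config$log_shift)
    scaled <- pre$table
  } else {
    scaled <- apply_preprocess(pre$model, train)
  }
  if (reduce) {
    if (is.null(pre$pca)) {
      kmax <- min(nrow(scaled$values) - 1L, ncol(scaled$values))
      pca <- fit_pca(scaled, min(config$n_components, kmax))
    } else {
      pca <- pre$pca
    }
    reduced <- project(pca, scaled)
  } else {
    pca <- NULL
    reduced <- scaled
  }
  if (is.null(plan)) plan <- emphasis_plan("HOMOGENEOUS", 1L)
  widened <- replicate_features(reduced, plan)
  svm <- train_linear_svm(widened, positive_label = config$label_pair[1L],
                          cost = config$svm_cost, tol = config$svm_tol)
  list(preprocess = pre$model, pca = pca, plan = plan, svm = svm)
}

#' @noRd
predict_fold_pipeline <- function(fitted, test) {
  scaled <- apply_preprocess(fitted$preprocess, test)
  reduced <- if (!is.null(fitted$pca)) project(fitted$pca, scaled) else scaled
  widened <- replicate_features(reduced, fitted$plan)
  decision_values(fitted$svm, widened)
}

#' Repeated stratified k-fold cross-validation of the emphasis pipeline
#'
#' For each of \code{n_repeats} repeats the data are partitioned into
#' \code{n_folds} stratified folds; each fold serves as test set exactly
#' once while the whole pipeline (imputation, rescaling, PCA, replication,
#' SVM) is fitted on the remaining folds.  With
#' \code{config$global_preprocess = TRUE}, imputation/rescaling/PCA are
#' instead fitted once on the full table (the reference algorithm's order,
#' which leaks test information) and only the SVM is refitted per fold.
#'
#' Aggregation is the "average of averages": each metric is averaged over
#' the folds of a repeat, then over repeats; undefined (0/0) fold metrics
#' are excluded.  With \code{config$pooled_metrics = TRUE} the per-repeat
#' value is computed from the repeat's pooled confusion counts instead.
#' All randomness flows from \code{config$seed} via a per-repeat seed
#' sequence, so any repeat is reproducible in isolation and identical
#' configurations give bit-identical results.
#'
#' @param table A binary [feature_table()] (see [subset_binary()]); labels
#'   must be the two classes of \code{config$label_pair}.
#' @param config A [run_config()].
#' @param plan Optional [emphasis_plan()] applied to the reduced features
#'   (default: no replication).
#' @param reduce Apply the PCA reduction (default \code{TRUE}); set to
#'   \code{FALSE} to evaluate the unreduced feature set.
#' @return An object of class \code{"eval_result"}: list with
#'   \code{per_fold} (data frame of per-repeat, per-fold counts and
#'   metrics), \code{metrics} (named vector acc, sen, spec, ppv, npv, auc),
#'   \code{n_repeats}, \code{n_folds}.
#' @export
cross_validate <- function(table, config, plan = NULL, reduce = TRUE) {
  validate_feature_table(table)
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(unique(table$labels), config$label_pair)
  if (length(bad)) {
    stop("table contains classes outside config$label_pair: ",
         paste(bad, collapse = ", "), " (apply subset_binary first)",
         call. = FALSE)
  }
  n <- nrow(table$values)
  if (n < config$n_folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  repeat_seeds <- with_preserved_seed({
    set.seed(config$seed)
    sample.int(.Machine$integer.max, config$n_repeats)
  })
  global_pre <- NULL
  if (config$global_preprocess) {
    gp <- fit_preprocess(table, transform = config$transform,
                         log_shift = config$log_shift)
    kmax <- min(n - 1L, ncol(table$values))
    gpca <- if (reduce) fit_pca(gp$table, min(config$n_components, kmax))
            else NULL
    global_pre <- list(model = gp$model, pca = gpca)
  }
  rows <- vector("list", config$n_repeats * config$n_folds)
  metric_names <- c("acc", "sen", "spec", "ppv", "npv", "auc")
  ri <- 0L
  for (rep_ix in seq_len(config$n_repeats)) {
    fold <- with_preserved_seed({
      set.seed(repeat_seeds[rep_ix])
      make_folds(table$labels, config$n_folds, config$stratified)
    })
    for (f in seq_len(config$n_folds)) {
      test_ix <- which(fold == f)
      train <- ft_rows(table, which(fold != f))
      test <- ft_rows(table, test_ix)
      fitted <- fit_fold_pipeline(train, config, plan, reduce,
                                  pre = global_pre)
      dv <- predict_fold_pipeline(fitted, test)
      predicted <- ifelse(dv >= 0, config$label_pair[1L],
                          config$label_pair[2L])
      cc <- confusion_counts(test$labels, predicted, config$label_pair[1L])
      met <- suppressWarnings(compute_metrics(cc))
      auc <- if (length(unique(test$labels)) == 2L) {
        auc_from_scores(dv, test$labels, config$label_pair[1L])
      } else NA_real_
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repeat_ix = rep_ix, fold = f,
                               tp = cc$tp, tn = cc$tn, fp = cc$fp,
                               fn = cc$fn,
                               acc = met[["acc"]], sen = met[["sen"]],
                               spec = met[["spec"]], ppv = met[["ppv"]],
                               npv = met[["npv"]], auc = auc)
    }
  }
  per_fold <- do.call(rbind, rows)
  per_repeat <- matrix(NA_real_, config$n_repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  for (rep_ix in seq_len(config$n_repeats)) {
    sub <- per_fold[per_fold$repeat_ix == rep_ix, , drop = FALSE]
    if (config$pooled_metrics) {
      pooled <- structure(list(tp = sum(sub$tp), tn = sum(sub$tn),
                               fp = sum(sub$fp), fn = sum(sub$fn)),
                          class = "confusion_counts")
      met <- suppressWarnings(compute_metrics(pooled))
      per_repeat[rep_ix, ] <- c(met, auc = mean(sub$auc, na.rm = TRUE))
    } else {
      per_repeat[rep_ix, ] <- colMeans(sub[, metric_names], na.rm = TRUE)
    }
  }
  metrics <- colMeans(per_repeat, na.rm = TRUE)
  structure(list(per_fold = per_fold,
                 per_repeat = as.data.frame(per_repeat),
                 metrics = metrics,
                 n_repeats = config$n_repeats,
                 n_folds = config$n_folds),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d-fold CV x %d repeats\n", x$n_folds,
              x$n_repeats))
  cat("  ", paste(sprintf("%s=%.4f", names(x$metrics), x$metrics),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} (which typically calls \code{set.seed} itself) and
#' restores the caller's RNG state afterwards, so library code never
#' perturbs user-level random streams.
#' @noRd
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
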