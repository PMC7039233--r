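recount <- function(cc) {
  # materialize a label/prediction list and recount from scratch
  truth <- rep(c("P", "P", "N", "N"), c(cc$tp, cc$fn, cc$tn, cc$fp))
  pred <- rep(c("P", "N", "N", "P"), c(cc$tp, cc$fn, cc$tn, cc$fp))
  list(acc = mean(truth == pred),
       sen = if (cc$tp + cc$fn > 0) mean(pred[truth == "P"] == "P")
             else NA_real_,
       spec = if (cc$tn + cc$fp > 0) mean(pred[truth == "N"] == "N")
              else NA_real_,
       ppv = if (cc$tp + cc$fp > 0) mean(truth[pred == "P"] == "P")
             else NA_real_,
       npv = if (cc$tn + cc$fn > 0) mean(truth[pred == "N"] == "N")
             else NA_real_)
}

test_that("metrics match direct substitution on worked examples", {
  perfect <- confusion_counts(rep(c("P", "N"), each = 5),
                              rep(c("P", "N"), each = 5), "P")
  expect_equal(unname(compute_metrics(perfect)), rep(1, 5))

  cc <- structure(list(tp = 90L, tn = 80L, fp = 20L, fn = 10L),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(unname(m), c(0.85, 0.90, 0.80, 90 / 110, 80 / 90))
})

test_that("metrics equal a brute-force recount for random counts", {
  set.seed(61)
  for (i in 1:200) {
    cc <- structure(as.list(setNames(rpois(4, 8), c("tp", "tn", "fp",
                                                    "fn"))),
                    class = "confusion_counts")
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0) next
    m <- suppressWarnings(compute_metrics(cc))
    ref <- recount(cc)
    expect_identical(unname(m), unname(unlist(ref)))
  }
})

test_that("0/0 metric denominators yield NA with a warning", {
  cc <- confusion_counts(rep("N", 4), rep("N", 4), "P")   # no positives
  expect_warning(expect_warning(m <- compute_metrics(cc), "sensitivity"),
                 "PPV")
  expect_true(is.na(m[["sen"]]))
  expect_equal(m[["acc"]], 1)
  expect_error(compute_metrics(structure(list(tp = 0L, tn = 0L, fp = 0L,
                                              fn = 0L),
                                         class = "confusion_counts")),
               "no evaluated samples")
})

test_that("accuracy decomposes into prevalence-weighted sen and spec", {
  set.seed(67)
  for (i in 1:50) {
    truth <- sample(c("P", "N"), 40, replace = TRUE)
    pred <- sample(c("P", "N"), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    cc <- confusion_counts(truth, pred, "P")
    m <- suppressWarnings(compute_metrics(cc))
    P <- cc$tp + cc$fn; N <- cc$tn + cc$fp
    expect_equal(m[["acc"]], (m[["sen"]] * P + m[["spec"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("AUC handles perfect ranking and all-tied scores", {
  labels <- rep(c("P", "N"), each = 4)
  expect_equal(auc_from_scores(c(5, 6, 7, 8, 1, 2, 3, 4), labels, "P"), 1)
  expect_equal(auc_from_scores(rep(0, 8), labels, "P"), 0.5)
  expect_error(auc_from_scores(1:4, rep("P", 4), "P"), "both classes")
})

test_that("AUC equals brute-force pairwise concordance, ties at half", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    pos <- scores[labels == "P"]; neg <- scores[labels == "N"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_from_scores(scores, labels, "P"), mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(73)
  scores <- rnorm(50)
  labels <- sample(c("P", "N"), 50, replace = TRUE, prob = c(.4, .6))
  base <- auc_from_scores(scores, labels, "P")
  for (f in list(function(x) 3 * x + 2, exp, function(x) atan(x))) {
    expect_equal(auc_from_scores(f(scores), labels, "P"), base)
  }
})

test_that("every sample is tested exactly once per repeat", {
  tbl <- random_binary_table(n = 40, k = 6, seed = 81)
  cfg <- quick_config(n_repeats = 3L)
  res <- cross_validate(tbl, cfg)
  for (r in 1:3) {
    sub <- res$per_fold[res$per_fold$repeat_ix == r, ]
    expect_equal(nrow(sub), cfg$n_folds)
    expect_equal(sum(sub$tp + sub$tn + sub$fp + sub$fn), 40)
  }
})

test_that("identical seeds give bit-identical evaluation results", {
  tbl <- random_binary_table(n = 30, k = 5, seed = 83)
  cfg <- quick_config()
  r1 <- cross_validate(tbl, cfg)
  r2 <- cross_validate(tbl, cfg)
  expect_identical(r1, r2)
  r3 <- cross_validate(tbl, quick_config(seed = 100L))
  expect_false(identical(r1$per_fold, r3$per_fold))
})

test_that("aggregate metrics are the average over repeats of the average
           over folds", {
  tbl <- random_binary_table(n = 40, k = 6, seed = 85)
  cfg <- quick_config(n_repeats = 4L)
  res <- cross_validate(tbl, cfg)
  for (metric in c("acc", "sen", "spec", "ppv", "npv", "auc")) {
    per_repeat <- tapply(res$per_fold[[metric]], res$per_fold$repeat_ix,
                         mean, na.rm = TRUE)
    expect_equal(res$metrics[[metric]], mean(per_repeat),
                 tolerance = 1e-12)
  }
})

test_that("ten folds on ten samples is leave-one-out", {
  tbl <- random_binary_table(n = 10, k = 3, seed = 87)
  cfg <- quick_config(n_folds = 10L, n_repeats = 1L, n_components = 2L,
                      stratified = FALSE)
  res <- suppressWarnings(cross_validate(tbl, cfg))
  expect_equal(nrow(res$per_fold), 10L)
  expect_true(all(res$per_fold$tp + res$per_fold$tn +
                    res$per_fold$fp + res$per_fold$fn == 1))
})

test_that("stratification failure reports the minimum class size", {
  tbl <- random_binary_table(n = 10, k = 3, seed = 89)
  cfg <- quick_config(n_folds = 8L)
  expect_error(cross_validate(tbl, cfg), "minimum is 8")
})

test_that("shuffled labels drive accuracy to the majority prevalence", {
  tbl <- random_binary_table(n = 60, k = 6, shift = 2, seed = 91)
  set.seed(17)
  null_tbl <- feature_table(tbl$values, labels = sample(tbl$labels),
                            feature_names = tbl$feature_names,
                            label_set = tbl$label_set)
  cfg <- quick_config(n_repeats = 3L)
  res <- cross_validate(null_tbl, cfg)
  prevalence <- max(table(null_tbl$labels)) / 60
  se <- sqrt(prevalence * (1 - prevalence) / 60)
  expect_lt(abs(res$metrics[["acc"]] - prevalence), 3 * se)
})

test_that("global preprocessing mode runs and differs from fold-honest", {
  tbl <- random_missing_table(40, 8, missing_rate = 0.1, seed = 93)
  tbl <- feature_table(abs(tbl$values), labels = rep(c("A", "B"), 20),
                       feature_names = tbl$feature_names,
                       label_set = c("A", "B"))
  cfg_honest <- quick_config(label_pair = c("A", "B"), n_components = 3L)
  cfg_global <- quick_config(label_pair = c("A", "B"), n_components = 3L,
                             global_preprocess = TRUE)
  r1 <- cross_validate(tbl, cfg_honest)
  r2 <- cross_validate(tbl, cfg_global)
  expect_s3_class(r2, "eval_result")
  expect_false(identical(r1$metrics, r2$metrics))
})

test_that("pooled-count aggregation matches hand pooling", {
  tbl <- random_binary_table(n = 40, k = 5, seed = 95)
  cfg <- quick_config(pooled_metrics = TRUE, n_repeats = 2L)
  res <- cross_validate(tbl, cfg)
  sub <- res$per_fold[res$per_fold$repeat_ix == 1, ]
  pooled <- structure(list(tp = sum(sub$tp), tn = sum(sub$tn),
                           fp = sum(sub$fp), fn = sum(sub$fn)),
                      class = "confusion_counts")
  expect_equal(res$per_repeat$acc[1],
               compute_metrics(pooled)[["acc"]], tolerance = 1e-12)
})
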