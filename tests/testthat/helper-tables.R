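# Small programmatic fixtures shared across the suite.

# Gaussian two-class table: k features, the first carrying a class shift.
random_binary_table <- function(n = 60L, k = 10L, shift = 1.5, seed = 1L,
                                classes = c("pos", "neg")) {
  set.seed(seed)
  stopifnot(n %% 2 == 0)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("f", seq_len(k))))
  labels <- rep(classes, each = n / 2)
  X[labels == classes[1L], 1L] <- X[labels == classes[1L], 1L] + shift
  feature_table(X, labels = labels)
}

# Random table with missing cells, for IO/imputation property tests.
random_missing_table <- function(n = 20L, k = 10L, missing_rate = 0.2,
                                 seed = 1L) {
  set.seed(seed)
  X <- matrix(round(rnorm(n * k, 50, 12), 6), n, k,
              dimnames = list(NULL, paste0("v", seq_len(k))))
  if (missing_rate > 0) {
    drop_ix <- which(matrix(runif(n * k) < missing_rate, n, k))
    # keep at least one observed value per column
    for (j in seq_len(k)) {
      col_cells <- ((j - 1L) * n + 1L):(j * n)
      if (all(col_cells %in% drop_ix)) drop_ix <- setdiff(drop_ix,
                                                          col_cells[1L])
    }
    X[drop_ix] <- NA_real_
  }
  feature_table(X, labels = sample(c("A", "B"), n, replace = TRUE),
                label_set = c("A", "B"))
}

# Tiny run_config for fast cross-validation in tests.
quick_config <- function(label_pair = c("pos", "neg"), ...) {
  defaults <- list(label_pair = label_pair, n_components = 5L,
                   n_folds = 5L, n_repeats = 2L, max_repetitions = 3L,
                   transform = "MINMAX", seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(run_config, args)
}
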