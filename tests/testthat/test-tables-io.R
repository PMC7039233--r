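test_that("reading a CSV sets the missing mask from the missing token", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mri,pet,label",
               "1.5,2.5,AD",
               "2.0,,NC",
               "3.5,4.5,AD"), path)
  tbl <- read_feature_table(path, label_set = c("AD", "NC"))
  expect_equal(dim(tbl), c(3L, 2L))
  expect_equal(sum(tbl$missing_mask), 1L)
  expect_true(tbl$missing_mask[2L, "pet"])
  expect_identical(tbl$labels, c("AD", "NC", "AD"))
})

test_that("schema and parse errors name the offending element", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,AD", "3,4,XX"), path)
  expect_error(read_feature_table(path, label_set = c("AD", "NC")), "XX")

  writeLines(c("a,b,label", "1,2,AD", "3,4"), path)
  expect_error(read_feature_table(path), "line 3")

  writeLines(c("a,b,label", "1,oops,AD"), path)
  expect_error(read_feature_table(path), "oops")

  writeLines(c("a,a,label", "1,2,AD"), path)
  expect_error(read_feature_table(path), "duplicate")

  expect_error(read_feature_table(path, label_column = "phenotype"),
               "phenotype")
})

test_that("write/read round trip is lossless for values, mask, labels, names", {
  for (seed in c(1L, 2L, 3L, 4L, 5L)) {
    tbl <- random_missing_table(n = 20L, k = 10L, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_feature_table(tbl, path)
    back <- read_feature_table(path, label_set = tbl$label_set)
    expect_identical(unname(back$values), unname(tbl$values))
    expect_identical(unname(back$missing_mask), unname(tbl$missing_mask))
    expect_identical(back$labels, tbl$labels)
    expect_identical(back$feature_names, tbl$feature_names)
  }
})

test_that("full double precision survives one write/read cycle", {
  set.seed(7)
  vals <- matrix(rnorm(40) * 10^sample(-8:8, 40, TRUE), 10, 4,
                 dimnames = list(NULL, paste0("x", 1:4)))
  tbl <- feature_table(vals, labels = rep(c("A", "B"), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path, label_set = c("A", "B"))
  expect_identical(unname(back$values), unname(vals))
})

test_that("degenerate tables round trip: header-only and all-missing", {
  empty <- feature_table(matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("a", "b", "c"))),
                         labels = character(0), label_set = "AD")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty, path)
  expect_identical(readLines(path), "a,b,c,label")

  allmiss <- feature_table(matrix(NA_real_, 2, 2,
                                  dimnames = list(NULL, c("a", "b"))),
                           labels = c("AD", "NC"))
  write_feature_table(allmiss, path, missing_token = "NA")
  back <- read_feature_table(path, missing_token = "NA",
                             label_set = c("AD", "NC"))
  expect_true(all(back$missing_mask))
})

test_that("block map companion file annotates features", {
  tbl <- random_missing_table(n = 5L, k = 3L, missing_rate = 0, seed = 2L)
  tbl$blocks[c("v1", "v3")] <- c("PET", "CSF")
  path <- withr::local_tempfile(fileext = ".csv")
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path, block_map_path = bpath)
  back <- read_feature_table(path, label_set = tbl$label_set,
                             block_map = bpath)
  expect_identical(back$blocks, tbl$blocks)
})

test_that("subset_binary keeps exactly the two requested classes, in order", {
  set.seed(11)
  vals <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(c("AD", "NC", "MCI"), each = 5)
  tbl <- feature_table(vals, labels = labels)
  sub <- subset_binary(tbl, c("AD", "NC"))
  expect_equal(nrow(sub$values), 10L)
  expect_false("MCI" %in% sub$labels)
  expect_identical(sub$label_set, c("AD", "NC"))
  expect_identical(sub$labels, labels[labels != "MCI"])

  # counts match a brute-force tally for random label mixes
  for (seed in 1:5) {
    set.seed(seed)
    labs <- sample(c("AD", "NC", "MCI"), 30, replace = TRUE,
                   prob = c(.4, .4, .2))
    if (length(unique(labs)) < 3) next
    t2 <- feature_table(matrix(rnorm(60), 30, 2,
                               dimnames = list(NULL, c("x", "y"))),
                        labels = labs)
    s2 <- subset_binary(t2, c("MCI", "NC"))
    expect_equal(nrow(s2$values), sum(labs == "MCI") + sum(labs == "NC"))
  }
})

test_that("subset_binary rejects degenerate or absent classes", {
  tbl <- random_binary_table(n = 10L, k = 2L, classes = c("AD", "NC"))
  expect_error(subset_binary(tbl, c("AD", "AD")), "distinct")
  expect_error(subset_binary(tbl, c("AD", "MCI")), "MCI")
})

test_that("feature_table invariants are enforced", {
  vals <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(feature_table(vals, labels = "one"), "labels length")
  expect_error(feature_table(matrix(1:4, 2, 2,
                                    dimnames = list(NULL, c("a", "a"))),
                             labels = c("x", "y")), "duplicate")
  expect_error(feature_table(vals, labels = c("AD", "NC"),
                             label_set = "AD"), "label")
})
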