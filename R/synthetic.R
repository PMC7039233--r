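#' Specification of a synthetic multimodal cohort table
#'
#' Describes an ADNI-like cohort at the feature-table level: class sizes,
#' modality blocks (MRI voxel/volume summaries, one MMSE score, demographic
#' codes, CSF biomarkers, PET voxel values), a planted low-rank class
#' signal in the biomarker columns, correlated Gaussian noise, and
#' missingness confined to the PET and CSF blocks (the modalities whose
#' examinations are most often skipped).  Defaults mirror the reference
#' cohort: 156 AD / 338 MCI / 211 NC samples and 144 features
#' (132 MRI + 1 MMSE + 4 demographic + 3 CSF + 4 PET).
#'
#' @param n_per_class Named integer vector of samples per class.
#' @param block_sizes Named integer vector of features per block, in column
#'   order; names among \code{MRI_VOXEL, MRI_VOLUME, MMSE, DEMOGRAPHIC,
#'   CSF, PET}.
#' @param signal_rank Dimension of the planted class-mean subspace
#'   (default 2: three class means span at most a plane).  Recoverable by
#'   PCA only when \code{signal_rank <= number of classes - 1}.
#' @param effect_size Pairwise distance between class means along the
#'   planted directions, in units of \code{noise_sd} (default 3; 0 gives
#'   label-free data).
#' @param noise_sd Standard deviation of the Gaussian noise (default 1).
#' @param within_block_cor Exchangeable correlation inside each correlation
#'   block (default 0.3).
#' @param roi_block_size Size of the correlated sub-blocks inside the MRI
#'   blocks (default 4), emulating region-of-interest structure: the 132
#'   MRI summaries come from roughly 16 regions in two kinds (voxel mean
#'   and volume), about 4 features per region and kind; features
#'   summarizing the same region co-vary, features of different regions do
#'   not.
#' @param missing_rate_pet,missing_rate_csf Independent per-cell missing
#'   probabilities in the PET and CSF blocks (defaults 0.25).
#' @param seed Integer seed; generation is a pure function of the spec
#'   including this seed.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_per_class = c(AD = 156L, MCI = 338L,
                                           NC = 211L),
                           block_sizes = c(MRI_VOXEL = 66L,
                                           MRI_VOLUME = 66L,
                                           MMSE = 1L,
                                           DEMOGRAPHIC = 4L,
                                           CSF = 3L,
                                           PET = 4L),
                           signal_rank = 2L,
                           effect_size = 3,
                           noise_sd = 1,
                           within_block_cor = 0.3,
                           roi_block_size = 4L,
                           missing_rate_pet = 0.25,
                           missing_rate_csf = 0.25,
                           seed = 1L) {
  stopifnot(length(n_per_class) >= 2L, !is.null(names(n_per_class)),
            all(n_per_class >= 1L))
  bad <- setdiff(names(block_sizes), block_tags())
  if (length(bad)) stop("unknown block name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(all(block_sizes >= 0L), sum(block_sizes) >= 1L)
  n_features <- sum(block_sizes)
  n_bio <- sum(block_sizes[intersect(names(block_sizes),
                                     c("MRI_VOXEL", "MRI_VOLUME", "CSF",
                                       "PET"))])
  signal_rank <- as.integer(signal_rank)
  if (signal_rank < 1L || signal_rank > n_bio) {
    stop(sprintf("signal_rank must lie in [1, %d] (biomarker columns)",
                 n_bio), call. = FALSE)
  }
  stopifnot(effect_size >= 0, noise_sd > 0,
            within_block_cor >= 0, within_block_cor < 1,
            missing_rate_pet >= 0, missing_rate_pet < 1,
            missing_rate_csf >= 0, missing_rate_csf < 1,
            roi_block_size >= 1L)
  structure(list(n_per_class = n_per_class,
                 n_features = n_features,
                 block_sizes = block_sizes,
                 signal_rank = signal_rank,
                 effect_size = as.numeric(effect_size),
                 noise_sd = as.numeric(noise_sd),
                 within_block_cor = as.numeric(within_block_cor),
                 roi_block_size = as.integer(roi_block_size),
                 missing_rate_pet = as.numeric(missing_rate_pet),
                 missing_rate_csf = as.numeric(missing_rate_csf),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' MMSE score ranges by clinical class (cognitively normal 24-30, mild
#' cognitive impairment 20-24, moderate dementia 13-20)
#' @noRd
mmse_range_for <- function(class_name) {
  switch(class_name,
         NC = c(24L, 30L),
         MCI = c(20L, 24L),
         AD = c(13L, 20L),
         c(13L, 30L))
}

#' Column names and block tags implied by a spec
#' @noRd
synthetic_layout <- function(spec) {
  names_of <- function(block, m) {
    switch(block,
           MRI_VOXEL = sprintf("mri_voxel_%02d", seq_len(m)),
           MRI_VOLUME = sprintf("mri_volume_%02d", seq_len(m)),
           MMSE = rep("mmse", m),
           DEMOGRAPHIC = c("demo_age", "demo_sex", "demo_edu",
                           "demo_marital", sprintf("demo_%02d",
                                                   seq_len(max(0, m - 4L))
                                                   + 4L))[seq_len(m)],
           CSF = c("csf_abeta42", "csf_ttau", "csf_ptau",
                   sprintf("csf_%02d", seq_len(max(0, m - 3L)) +
                             3L))[seq_len(m)],
           PET = sprintf("pet_voxel_%d", seq_len(m)))
  }
  feature_names <- character(0)
  blocks <- character(0)
  for (b in names(spec$block_sizes)) {
    m <- spec$block_sizes[[b]]
    if (m == 0L) next
    feature_names <- c(feature_names, names_of(b, m))
    blocks <- c(blocks, rep(b, m))
  }
  list(feature_names = feature_names,
       blocks = stats::setNames(blocks, feature_names))
}

#' Regular-simplex class-mean coordinates, pairwise distance `dist`
#' @noRd
simplex_coords <- function(n_class, rank, dist) {
  E <- diag(n_class) - 1 / n_class            # centered vertices, dist sqrt(2)
  sv <- svd(E)
  full <- sv$u[, seq_len(n_class - 1L), drop = FALSE] %*%
    diag(sv$d[seq_len(n_class - 1L)], n_class - 1L)
  full <- full * dist / sqrt(2)
  out <- matrix(0, n_class, rank)
  take <- min(rank, n_class - 1L)
  out[, seq_len(take)] <- full[, seq_len(take), drop = FALSE]
  out
}

#' Generate a synthetic multimodal cohort table
#'
#' Draws a random orthonormal signal basis of rank \code{signal_rank} over
#' the biomarker columns (MRI, CSF, PET); class means are the vertices of a
#' regular simplex in that subspace with pairwise distance
#' \code{effect_size * noise_sd}; samples add exchangeable-correlated
#' Gaussian noise (correlation \code{within_block_cor} inside ROI-sized
#' sub-blocks of the MRI blocks and inside the CSF and PET blocks).  The
#' MMSE column is drawn from class-conditional integer ranges (NC 24-30,
#' MCI 20-24, AD 13-20) when \code{effect_size > 0}, and from the pooled
#' range 13-30 for every class when \code{effect_size == 0}, so the null
#' regime is fully label-free.  Demographic columns (age, sex, education,
#' marital code) are label-free by construction.  Biomarker columns are
#' shifted positive so the log transform is applicable; PET and CSF cells
#' are masked missing independently at their spec rates.
#'
#' The planted basis (over the full feature space, zero rows outside the
#' biomarker columns) is attached as attribute \code{"signal_basis"} for
#' [planted_signal_check()].
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_table()] with block tags set and, as attributes,
#'   \code{signal_basis} and \code{spec}.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- synthetic_layout(spec)
  p <- length(layout$feature_names)
  classes <- names(spec$n_per_class)
  labels <- rep(classes, times = spec$n_per_class)
  n <- length(labels)
  bio_cols <- which(layout$blocks %in% c("MRI_VOXEL", "MRI_VOLUME", "CSF",
                                         "PET"))
  with_preserved_seed({
    set.seed(spec$seed)
    # orthonormal basis over biomarker columns
    B <- qr.Q(qr(matrix(stats::rnorm(length(bio_cols) * spec$signal_rank),
                        ncol = spec$signal_rank)))
    coords <- simplex_coords(length(classes), spec$signal_rank,
                             spec$effect_size * spec$noise_sd)
    class_means <- coords %*% t(B)            # n_class x n_bio
    values <- matrix(0, n, p,
                     dimnames = list(NULL, layout$feature_names))
    # correlated noise per correlation block over the biomarker columns
    noise <- matrix(0, n, length(bio_cols))
    start <- 1L
    for (blk in correlation_blocks(spec, layout, bio_cols)) {
      m <- length(blk)
      rho <- spec$within_block_cor
      shared <- stats::rnorm(n)
      Z <- matrix(stats::rnorm(n * m), n, m)
      noise[, start:(start + m - 1L)] <-
        spec$noise_sd * (sqrt(rho) * shared + sqrt(1 - rho) * Z)
      start <- start + m
    }
    class_ix <- match(labels, classes)
    values[, bio_cols] <- class_means[class_ix, , drop = FALSE] + noise
    # shift each biomarker column positive (measurements are positive)
    for (j in bio_cols) {
      values[, j] <- values[, j] - min(values[, j]) + 1
    }
    # MMSE: class-conditional ranges, pooled under the null
    mmse_cols <- which(layout$blocks == "MMSE")
    for (j in mmse_cols) {
      values[, j] <- vapply(labels, function(cl) {
        rng <- if (spec$effect_size > 0) mmse_range_for(cl) else c(13L, 30L)
        as.numeric(sample(seq(rng[1L], rng[2L]), 1L))
      }, numeric(1))
    }
    # demographics: label-free age / sex code / education / marital code
    demo_cols <- which(layout$blocks == "DEMOGRAPHIC")
    demo_gen <- list(function(n) stats::rnorm(n, 75, 7),
                     function(n) stats::rbinom(n, 1L, 0.5),
                     function(n) pmax(stats::rnorm(n, 16, 3), 0),
                     function(n) stats::rbinom(n, 1L, 0.75))
    for (i in seq_along(demo_cols)) {
      gen <- demo_gen[[((i - 1L) %% length(demo_gen)) + 1L]]
      values[, demo_cols[i]] <- gen(n)
    }
    # block-structured missingness in PET and CSF
    for (tag in c("PET", "CSF")) {
      rate <- if (tag == "PET") spec$missing_rate_pet
              else spec$missing_rate_csf
      if (rate > 0) {
        cols <- which(layout$blocks == tag)
        mask <- matrix(stats::runif(n * length(cols)) < rate, n)
        values[, cols][mask] <- NA_real_
      }
    }
    basis_full <- matrix(0, p, spec$signal_rank)
    basis_full[bio_cols, ] <- B
    tbl <- feature_table(values, labels = labels,
                         feature_names = layout$feature_names,
                         label_set = classes, blocks = layout$blocks)
    attr(tbl, "signal_basis") <- basis_full
    attr(tbl, "spec") <- spec
    tbl
  })
}

#' Partition the biomarker columns into correlation blocks
#' @noRd
correlation_blocks <- function(spec, layout, bio_cols) {
  out <- list()
  tags <- layout$blocks[bio_cols]
  for (tag in unique(tags)) {
    cols <- bio_cols[tags == tag]
    if (tag %in% c("MRI_VOXEL", "MRI_VOLUME")) {
      splits <- split(cols, ceiling(seq_along(cols) / spec$roi_block_size))
      out <- c(out, unname(splits))
    } else {
      out <- c(out, list(cols))
    }
  }
  out
}

#' Principal angle between the planted signal subspace and the PCA top
#' subspace
#'
#' Confirms that PCA recovers the emphasis-worthy directions: the table is
#' imputed and standardized, PCA is fitted with \code{signal_rank}
#' components, and the largest principal angle between that subspace and
#' the planted basis (mapped through the same per-feature affine scaling
#' and re-orthonormalized) is returned in degrees.  Small angles mean the
#' reduction step is pointing at the planted class structure.
#'
#' The comparison standardizes (rather than min-max scales) for two
#' reasons: an affine map carries a linear subspace to a linear subspace
#' exactly, which a log transform does not; and min-max scaling gives
#' binary-coded columns (range 1) an order of magnitude more variance than
#' continuous Gaussian columns (range about six standard deviations), so
#' the top components of a min-max-scaled mixed table reflect coding
#' artifacts rather than planted structure.
#'
#' @param table A table from [generate_table()] (carries the
#'   \code{signal_basis} attribute).
#' @param spec The [synthetic_spec()] that produced it.
#' @return Largest principal angle in degrees, in \[0, 90\].
#' @export
planted_signal_check <- function(table, spec) {
  basis <- attr(table, "signal_basis")
  if (is.null(basis)) {
    stop("table carries no signal_basis attribute; was it produced by ",
         "generate_table()?", call. = FALSE)
  }
  pre <- fit_preprocess(table, transform = "STANDARDIZE")
  pca <- fit_pca(pre$table, spec$signal_rank)
  slope <- ifelse(pre$model$x_dev > 0, 1 / pre$model$x_dev, 0)
  mapped <- basis * slope                       # diag(slope) %*% basis
  mapped_orth <- qr.Q(qr(mapped))
  s <- svd(pca$components %*% mapped_orth)$d
  s <- pmin(pmax(s, 0), 1)
  acos(min(s)) * 180 / pi
}
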