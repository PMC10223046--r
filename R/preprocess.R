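#' @name preprocess
#' @title Spectrum standardization, PCA feature extraction and the
#'   systematic 7:3 split
#' @description
#' Standardization transforms every variable (wavelength) to
#' `S = (x - mu) / sigma` using the per-variable mean and *population*
#' standard deviation estimated on the training set. PCA models the
#' (centered) data matrix as `X = T P' + E` with scores `T` (n x k),
#' orthonormal loadings `P` (m x k) ordered by decreasing explained
#' variance, and residual `E`. Both transforms are fitted on training
#' spectra only and then applied unchanged to test spectra.
NULL

dataset_matrix <- function(x) {
  if (inherits(x, "spectra_dataset")) x$reflectance
  else if (is.matrix(x)) x
  else stop("expected a spectra_dataset or a numeric matrix")
}

#' Fit a per-variable standardizer on training spectra
#'
#' @param train A non-empty `spectra_dataset` (or numeric matrix).
#' @return Object of class `standardizer` with fields `mu` and `sigma`
#'   (population standard deviation, i.e. divisor `n`).
#' @examples
#' p <- fit_standardizer(matrix(c(0, 2, 4), ncol = 1))
#' p$mu     # 2
#' p$sigma  # sqrt(8/3) = 1.63299...
#' @export
fit_standardizer <- function(train) {
  X <- dataset_matrix(train)
  if (nrow(X) == 0) stop("cannot fit a standardizer on an empty dataset")
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu, "-")^2))
  structure(list(mu = mu, sigma = sigma), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Variables with zero training standard deviation are mapped to 0 (a
#' constant variable carries no class information).
#'
#' @param ds A `spectra_dataset` or numeric matrix with matching width.
#' @param p A fitted [fit_standardizer()] object.
#' @return Same container type as `ds`, values transformed.
#' @export
apply_standardizer <- function(ds, p) {
  X <- dataset_matrix(ds)
  if (ncol(X) != length(p$mu))
    stop(sprintf("dimension mismatch: data has %d variables, standardizer %d",
                 ncol(X), length(p$mu)))
  sigma <- ifelse(p$sigma == 0, Inf, p$sigma)  # sigma == 0 -> output 0
  S <- sweep(sweep(X, 2, p$mu, "-"), 2, sigma, "/")
  if (inherits(ds, "spectra_dataset")) {
    ds$reflectance <- S
    ds
  } else S
}

#' Fit a PCA feature extractor on training spectra
#'
#' Centers the training matrix and extracts the top `k` principal axes by
#' singular value decomposition; loadings are orthonormal and ordered by
#' decreasing explained variance. The study default retains `k = 100`
#' components from the 2151 spectral variables.
#'
#' @param train A non-empty `spectra_dataset` (or numeric matrix).
#' @param k Number of components, `k <= min(n - 1, m)`.
#' @return Object of class `pca_model` with fields `mean`, `loadings`
#'   (m x k), `explained_variance` and `k`.
#' @export
fit_pca <- function(train, k = 100) {
  X <- dataset_matrix(train)
  n <- nrow(X); m <- ncol(X)
  if (n == 0) stop("cannot fit PCA on an empty dataset")
  kmax <- min(n - 1L, m)
  if (k < 1 || k > kmax)
    stop(sprintf("k = %d out of range: must satisfy 1 <= k <= min(n - 1, m) = %d",
                 k, kmax))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sv <- svd(Xc, nu = 0, nv = k)
  structure(list(
    mean = mu,
    loadings = sv$v,
    explained_variance = sv$d[seq_len(k)]^2 / n,
    k = as.integer(k)
  ), class = "pca_model")
}

#' Project spectra onto fitted principal components
#'
#' Computes scores `T = (X - mean) P`; metadata rows are carried along so
#' downstream models keep their labels.
#'
#' @param ds A `spectra_dataset` or numeric matrix.
#' @param model A fitted [fit_pca()] object.
#' @return For a dataset input, a list of class `spectra_features` with
#'   fields `x` (n x k score matrix) and `meta`; for a matrix input, the
#'   score matrix.
#' @export
apply_pca <- function(ds, model) {
  X <- dataset_matrix(ds)
  if (ncol(X) != length(model$mean))
    stop(sprintf("dimension mismatch: data has %d variables, PCA model %d",
                 ncol(X), length(model$mean)))
  scores <- sweep(X, 2, model$mean, "-") %*% model$loadings
  if (inherits(ds, "spectra_dataset"))
    structure(list(x = scores, meta = ds$meta), class = "spectra_features")
  else scores
}

#' Specification of the systematic train/test split
#'
#' @param train_fraction Proportion of each stratum assigned to training
#'   (default 0.7, the study's 7:3 ratio).
#' @param stratify_by Metadata columns defining strata.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7,
                       stratify_by = c("product_class", "physical_state")) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction, stratify_by = stratify_by,
                 ordering = "interleave_mod10"),
            class = "split_spec")
}

#' Systematic (interleaved) stratified train/test split
#'
#' Deterministic counterpart of random splitting: within each stratum
#' (by default product class x physical state), spectra are numbered
#' `i = 0, 1, ...` in file order and sent to the test set when
#' `i mod 10 >= 10 * train_fraction`, otherwise to training. With the 7:3
#' default every block of ten consecutive replicates contributes seven to
#' training and three to testing, reproducing the study's 420/180 per-state
#' counts exactly.
#'
#' @param ds A non-empty `spectra_dataset`.
#' @param spec A [split_spec()].
#' @return List with `spectra_dataset` elements `train` and `test`.
#' @export
systematic_split <- function(ds, spec = split_spec()) {
  if (n_spectra(ds) == 0) stop("cannot split an empty dataset")
  k_train <- round(10 * spec$train_fraction)
  if (k_train < 1 || k_train > 9)
    stop("train_fraction must allocate between 1 and 9 of every 10 indices to training")
  keys <- ds$meta[, intersect(spec$stratify_by, names(ds$meta)), drop = FALSE]
  strata <- if (ncol(keys)) interaction(keys, drop = TRUE)
            else factor(rep(1L, n_spectra(ds)))
  test_idx <- logical(n_spectra(ds))
  for (s in levels(strata)) {
    rows <- which(strata == s)
    if (length(rows) < 2)
      stop(sprintf("stratum '%s' has %d member(s); need at least 2 to split", s,
                   length(rows)))
    i0 <- seq_along(rows) - 1L
    test_idx[rows] <- (i0 %% 10L) >= k_train
  }
  list(train = subset_spectra(ds, !test_idx),
       test = subset_spectra(ds, test_idx))
}

#' Labels of a feature table
#' @param features A `spectra_features` object.
#' @return Integer vector of product-class labels (0/1).
#' @export
feature_labels <- function(features) {
  stopifnot(inherits(features, "spectra_features"))
  features$meta$product_class
}
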