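#' Preprocessing configuration
#'
#' Bundles the tunable preprocessing parameters: the group-wise valid-value
#' threshold and the downshifted-normal imputation parameters. The defaults
#' (retain a protein when at least 75% of values are observed in at least one
#' tissue group; impute from a normal shrunk to 0.3 sd and shifted down 1.8 sd
#' relative to the observed per-sample distribution) are the standard
#' left-censored proteomics treatment.
#'
#' @param min_valid_fraction Fraction of observed values required in at least
#'   one tissue group for a protein to be retained, in (0, 1].
#' @param impute_width Imputed-distribution sd as a multiple of the observed
#'   per-sample sd (> 0).
#' @param impute_downshift Imputed-distribution mean shift below the observed
#'   per-sample mean, in units of the observed sd (>= 0).
#' @param seed Integer seed making imputation reproducible.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_valid_fraction = 0.75, impute_width = 0.3,
                              impute_downshift = 1.8, seed = 1L) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1,
            impute_width > 0, impute_downshift >= 0)
  structure(list(min_valid_fraction = min_valid_fraction,
                 impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Log2-transform raw intensities
#'
#' Observed cells are replaced by their base-2 logarithm; missing cells stay
#' missing. Matrices already on the log2 scale pass through unchanged when
#' `already_log2 = TRUE`.
#'
#' @param x Expression matrix of raw intensities (all observed values > 0).
#' @param already_log2 If `TRUE` the matrix is returned as is.
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(x, already_log2 = FALSE) {
  validate_expression_matrix(x)
  if (already_log2) return(x)
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("nonpositive intensity at protein ", rownames(x)[bad[1L, 1L]],
         ", sample ", colnames(x)[bad[1L, 2L]])
  }
  log2(x)
}

#' Filter proteins by group-wise valid-value fraction
#'
#' A protein is retained if and only if, in at least one tissue group, the
#' fraction of observed (non-missing) values reaches `min_valid_fraction`
#' (inclusive). Groups are the tissue levels present in the manifest; a tissue
#' with zero samples is skipped. Row order is preserved.
#'
#' @param x Expression matrix with `NA` marking missing values.
#' @param manifest Sample manifest covering every matrix column.
#' @param config A [preprocess_config()], or a number giving the threshold.
#' @return The row-subset matrix.
#' @export
filter_by_valid_fraction <- function(x, manifest, config = preprocess_config()) {
  if (is.numeric(config)) config <- preprocess_config(min_valid_fraction = config)
  mf <- match_manifest(x, manifest)
  keep <- rep(FALSE, nrow(x))
  for (g in levels(mf$tissue)) {
    idx <- which(mf$tissue == g)
    if (length(idx) == 0L) next
    frac <- rowMeans(!is.na(x[, idx, drop = FALSE]))
    keep <- keep | frac >= config$min_valid_fraction
  }
  x[keep, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Each missing cell in sample \eqn{s} is drawn from
#' \eqn{N(\bar{x}_s - d \cdot s_s, (w \cdot s_s)^2)} where \eqn{\bar{x}_s} and
#' \eqn{s_s} are the mean and sd of that sample's observed values, \eqn{d} is
#' the downshift and \eqn{w} the width factor. This models left-censored
#' missingness: values absent because they fell below the detection limit are
#' replaced by draws from the low tail of the sample's intensity distribution.
#' Observed values are untouched; the result is deterministic for a fixed
#' seed.
#'
#' @param x Log2 expression matrix, already filtered; every sample column must
#'   have at least 2 observed values.
#' @param config A [preprocess_config()].
#' @return A complete matrix (no `NA`).
#' @export
impute_downshifted_normal <- function(x, config = preprocess_config()) {
  validate_expression_matrix(x)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2L)) {
    stop("sample with fewer than 2 observed values: ",
         colnames(x)[which(n_obs < 2L)[1L]])
  }
  if (!anyNA(x)) return(x)
  if (!is.null(config$seed)) set.seed(config$seed)
  for (j in seq_len(ncol(x))) {
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0L) next
    obs <- x[!is.na(x[, j]), j]
    m <- mean(obs)
    s <- stats::sd(obs)
    x[miss, j] <- stats::rnorm(length(miss),
                               mean = m - config$impute_downshift * s,
                               sd = config$impute_width * s)
  }
  x
}

#' Run the full preprocessing chain
#'
#' Log2 transform (unless already on that scale), group-wise valid-value
#' filter, then downshifted-normal imputation, in that order: imputation sees
#' only the proteins that survived filtering.
#'
#' @inheritParams filter_by_valid_fraction
#' @param already_log2 Passed to [log2_transform()].
#' @return A complete, filtered log2 matrix, with attributes
#'   `n_proteins_before` and `n_proteins_after`.
#' @export
preprocess_matrix <- function(x, manifest, config = preprocess_config(),
                              already_log2 = TRUE) {
  n_before <- nrow(x)
  x <- log2_transform(x, already_log2 = already_log2)
  x <- filter_by_valid_fraction(x, manifest, config)
  x <- impute_downshifted_normal(x, config)
  attr(x, "n_proteins_before") <- n_before
  attr(x, "n_proteins_after") <- nrow(x)
  x
}
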