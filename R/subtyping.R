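#' Discover tumor subtypes by hierarchical clustering
#'
#' Samples are clustered on correlation distance (1 - Pearson r across the
#' full protein set) with average (UPGMA) linkage and the dendrogram is cut
#' into exactly `k` clusters. Labels T1..Tk are ordered by decreasing cluster
#' size, ties by first appearance in column order, so the labeling is
#' deterministic.
#'
#' @param x Complete expression matrix restricted to the samples to cluster
#'   (typically primary tumors).
#' @param k Number of subtypes.
#' @return An object of class `subtype_assignment`: a named factor (levels
#'   T1..Tk) with the `hclust` tree in attribute `hclust`.
#' @export
hcl_subtypes <- function(x, k = 3L) {
  validate_expression_matrix(x)
  if (anyNA(x)) stop("clustering requires a complete matrix")
  if (k > ncol(x)) stop("k = ", k, " exceeds the ", ncol(x), " samples")
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  first_seen <- vapply(names(sizes), function(cl)
    which(raw == as.integer(cl))[1L], integer(1L))
  ord <- order(-as.integer(sizes), first_seen)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes)[ord])] <- seq_len(k)
  labels <- factor(paste0("T", relabel[raw]),
                   levels = paste0("T", seq_len(k)))
  names(labels) <- colnames(x)
  structure(labels, class = c("subtype_assignment", "factor"), hclust = hc)
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("subtype_assignment over", length(x), "samples:\n")
  print(table(factor(x, levels = levels(x))))
  invisible(x)
}

# multiclass SAM d statistic: between-group contrast over (pooled SE + s0)
.sam_d <- function(x, y, s0) {
  nk <- table(y)
  K <- length(nk)
  n <- sum(nk)
  ind <- outer(y, names(nk), `==`) * 1      # n x K membership
  gm <- x %*% sweep(ind, 2L, as.numeric(nk), `/`)  # group means, p x K
  grand <- rowMeans(x)
  ss_between <- rowSums(sweep(gm - grand, 2L, as.numeric(nk), `*`) * (gm - grand))
  numer <- sqrt(n / prod(as.numeric(nk)) * ss_between)
  ss_within <- rowSums(x^2) - rowSums(sweep(gm^2, 2L, as.numeric(nk), `*`))
  ss_within <- pmax(ss_within, 0)
  s <- sqrt(ss_within / (n - K) * sum(1 / as.numeric(nk)))
  list(d = numer / (s + s0), s = s)
}

#' Multiclass significance analysis with permutation FDR
#'
#' Re-implementation of the SAM procedure for more than two classes. Each
#' protein gets a nonnegative score \eqn{d_i}: the square root of the
#' sample-size-weighted between-group sum of squares (scaled so that for two
#' balanced groups it reduces to the absolute mean difference), divided by the
#' pooled standard error plus an exchangeability constant \eqn{s_0}. The null
#' distribution comes from permuting the class labels; for each threshold
#' \eqn{\Delta} the estimated FDR is
#' \eqn{\hat\pi_0 \cdot \mathrm{median}_b \#\{d^{*b} \ge \Delta\} / \#\{d \ge \Delta\}},
#' with \eqn{\hat\pi_0} estimated from the fraction of observed scores inside
#' the interquartile range of the permuted scores. The selected signature is
#' the largest set (smallest \eqn{\Delta}) whose estimated FDR does not exceed
#' `target_fdr`.
#'
#' @param x Complete expression matrix (proteins x samples).
#' @param labels Factor (or vector) of class labels, one per sample; every
#'   class needs at least 2 samples.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @param target_fdr Target median FDR for signature selection.
#' @param s0 Exchangeability constant; default is the median pooled standard
#'   error across proteins.
#' @return An object of class `sam_fit`: list with `d` (named scores), `s0`,
#'   `pi0`, `n_perm`, `delta_table` (delta, n_selected, fdr), `delta`
#'   (chosen threshold, `Inf` when nothing can be selected at the target),
#'   `selected` (protein ids) and `target_fdr`.
#' @export
sam_multiclass <- function(x, labels, n_perm = 1000L, seed = 1L,
                           target_fdr = 0.05, s0 = NULL) {
  validate_expression_matrix(x)
  if (anyNA(x)) stop("SAM requires a complete matrix")
  labels <- factor(labels)
  if (length(labels) != ncol(x))
    stop("labels must match the number of samples")
  nk <- table(labels)
  if (any(nk < 2L))
    stop("class with fewer than 2 samples: ", names(nk)[which(nk < 2L)[1L]])
  if (n_perm < 100L) stop("n_perm must be at least 100")
  y <- as.character(labels)
  obs <- .sam_d(x, y, s0 = 0)
  if (is.null(s0)) s0 <- stats::median(obs$s)
  d <- .sam_d(x, y, s0 = s0)$d
  names(d) <- rownames(x)
  p <- length(d)

  set.seed(seed)
  deltas <- sort(unique(d))
  null_counts <- matrix(0L, nrow = n_perm, ncol = length(deltas))
  null_pool_lo <- 0L
  null_pool_hi <- 0L
  q_lo <- q_hi <- NULL
  null_all_sample <- numeric(0)
  for (b in seq_len(n_perm)) {
    yb <- sample(y)
    db <- .sam_d(x, yb, s0 = s0)$d
    sorted <- sort(db)
    # count of null scores >= each candidate delta
    null_counts[b, ] <- p - findInterval(deltas, sorted, left.open = TRUE)
    if (b <= 50L) null_all_sample <- c(null_all_sample, db)
  }
  qs <- stats::quantile(null_all_sample, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= qs[1L] & d <= qs[2L]) / (0.5 * p))

  n_sel <- p - findInterval(deltas, sort(d), left.open = TRUE)
  med_null <- apply(null_counts, 2L, stats::median)
  fdr <- ifelse(n_sel == 0L, 0, pmin(1, pi0 * med_null / pmax(n_sel, 1L)))
  delta_table <- data.frame(delta = deltas, n_selected = n_sel, fdr = fdr)

  ok <- which(fdr <= target_fdr & n_sel > 0L)
  if (length(ok) > 0L) {
    chosen <- ok[1L]  # smallest delta meeting the target
    delta <- deltas[chosen]
    selected <- names(d)[d >= delta]
  } else {
    delta <- Inf
    selected <- character(0)
  }
  structure(list(d = d, s0 = s0, pi0 = pi0, n_perm = n_perm,
                 delta_table = delta_table, delta = delta,
                 selected = selected, target_fdr = target_fdr,
                 labels = labels),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("sam_fit:", length(x$d), "proteins,", nlevels(x$labels), "classes,",
      x$n_perm, "permutations\n")
  cat("  s0 =", signif(x$s0, 4), ", pi0 =", signif(x$pi0, 3), "\n")
  if (is.finite(x$delta)) {
    cat("  selected", length(x$selected), "proteins at delta =",
        signif(x$delta, 4), "(estimated FDR <=", x$target_fdr, ")\n")
  } else {
    cat("  no protein selected at target FDR", x$target_fdr, "\n")
  }
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  print(object)
  cat("  d-statistic quantiles:\n")
  print(signif(stats::quantile(object$d), 3))
  invisible(object)
}

#' Plot observed versus expected SAM scores
#'
#' Quantile-quantile style diagnostic: observed ordered scores against the
#' ordered scores expected under label permutation; the selection threshold is
#' drawn when finite.
#'
#' @param x A `sam_fit`.
#' @param ... Passed to `plot`.
#' @export
plot.sam_fit <- function(x, ...) {
  dt <- x$delta_table
  plot(dt$delta, dt$fdr, type = "s", xlab = expression(Delta),
       ylab = "estimated FDR", ...)
  graphics::abline(h = x$target_fdr, lty = 2)
  if (is.finite(x$delta)) graphics::abline(v = x$delta, lty = 3)
  invisible(x)
}

#' Build per-subtype centroids over a protein signature
#'
#' Each subtype's centroid is the per-protein mean over its training samples,
#' restricted to the signature proteins.
#'
#' @param x Complete expression matrix containing the training samples.
#' @param assignment A `subtype_assignment` (or named factor) covering the
#'   training samples.
#' @param signature Character vector of signature protein ids (e.g.
#'   `sam_fit$selected`).
#' @param metric Classification metric, `"pearson"` (default) or
#'   `"euclidean"`.
#' @return An object of class `subtype_model`: list with `signature`,
#'   `centroids` (signature x subtype matrix) and `metric`.
#' @export
build_centroids <- function(x, assignment, signature,
                            metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  signature <- unique(as.character(signature))
  absent <- setdiff(signature, rownames(x))
  if (length(absent) > 0L)
    stop("signature protein absent from matrix: ", absent[1L])
  samples <- names(assignment)
  if (is.null(samples) || !all(samples %in% colnames(x)))
    stop("assignment must be named by samples present in the matrix")
  labs <- factor(assignment)
  cents <- vapply(levels(labs), function(lv) {
    rowMeans(x[signature, samples[labs == lv], drop = FALSE])
  }, numeric(length(signature)))
  cents <- matrix(cents, nrow = length(signature),
                  dimnames = list(signature, levels(labs)))
  structure(list(signature = signature, centroids = cents, metric = metric),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype_model:", length(x$signature), "signature proteins,",
      ncol(x$centroids), "subtypes (", paste(colnames(x$centroids),
      collapse = ", "), "), metric =", x$metric, "\n")
  invisible(x)
}

#' Classify one sample by nearest centroid
#'
#' The sample is assigned to the subtype whose centroid it best matches over
#' the signature proteins present in the sample: highest Pearson correlation
#' (default) or smallest Euclidean distance. At least `min_fraction` of the
#' signature must be present — mirroring classification of external cohorts
#' where only part of the signature maps to measured genes. An exact tie is
#' resolved to the lexicographically first subtype and flagged in the
#' `"tie"` attribute.
#'
#' @param sample_vector Named numeric vector of expression values.
#' @param model A `subtype_model`.
#' @param min_fraction Minimum fraction of signature proteins required.
#' @return The winning subtype label (character) with attributes `score`
#'   (per-subtype scores) and `tie`.
#' @export
classify_by_centroid <- function(sample_vector, model, min_fraction = 0.8) {
  stopifnot(inherits(model, "subtype_model"))
  shared <- intersect(model$signature, names(sample_vector))
  frac <- length(shared) / length(model$signature)
  if (frac < min_fraction) {
    stop(sprintf("only %.0f%% of signature present (need >= %.0f%%)",
                 100 * frac, 100 * min_fraction))
  }
  v <- sample_vector[shared]
  scores <- vapply(colnames(model$centroids), function(lv) {
    cv <- model$centroids[shared, lv]
    if (model$metric == "pearson") stats::cor(v, cv) else -sqrt(sum((v - cv)^2))
  }, numeric(1L))
  best <- max(scores)
  winners <- sort(names(scores)[scores == best])
  structure(winners[1L], score = scores, tie = length(winners) > 1L)
}

#' Classify samples of an expression matrix by nearest centroid
#'
#' @param object A `subtype_model`.
#' @param newdata Expression matrix (features x samples). Feature ids are
#'   matched to the signature, after translation through `idmap` when given.
#' @param idmap Optional two-column data.frame mapping signature feature ids
#'   (column 1, e.g. protein) to the ids used in `newdata` (column 2, e.g.
#'   gene symbol).
#' @param min_fraction Minimum fraction of the signature that must be present.
#' @param ... Unused.
#' @return Factor of subtype labels named by sample.
#' @export
predict.subtype_model <- function(object, newdata, idmap = NULL,
                                  min_fraction = 0.8, ...) {
  if (!is.null(idmap)) {
    hit <- match(rownames(newdata), idmap[[2L]])
    rn <- ifelse(is.na(hit), rownames(newdata), idmap[[1L]][hit])
    keep <- !duplicated(rn)
    newdata <- newdata[keep, , drop = FALSE]
    rownames(newdata) <- rn[keep]
  }
  labs <- vapply(seq_len(ncol(newdata)), function(j) {
    as.character(classify_by_centroid(newdata[, j], object, min_fraction))
  }, character(1L))
  factor(stats::setNames(labs, colnames(newdata)),
         levels = colnames(object$centroids))
}
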