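#' Penalized pairwise edge weights for forest learning
#'
#' For each protein pair the weight is the information-criterion gain of
#' adding the edge to a Gaussian forest model,
#' \deqn{w_{ij} = -n \ln(1 - r_{ij}^2) - \mathrm{penalty},}
#' where \eqn{r_{ij}} is the Pearson correlation over the \eqn{n} samples, the
#' first term is the model-deviance improvement, and the penalty is
#' \eqn{\ln n} (BIC, default) or 2 (AIC) per edge. Only edges with positive
#' weight can enter the minimal-BIC forest. \eqn{r^2} is clipped to
#' \eqn{1 - 10^{-12}} so perfectly correlated pairs get a large finite weight.
#'
#' @param x Complete (imputed) expression matrix, proteins in rows, at least
#'   3 samples.
#' @param penalty `"bic"` or `"aic"`.
#' @return An object of class `edge_weights`: list with the symmetric weight
#'   matrix `w` (diagonal `NA`), sample size `n` and the penalty used.
#' @export
forest_edge_weights <- function(x, penalty = c("bic", "aic")) {
  validate_expression_matrix(x)
  penalty <- match.arg(penalty)
  if (anyNA(x)) stop("weights require a complete matrix; impute first")
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 samples, got ", n)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance protein: ", rownames(x)[which(v == 0)[1L]])
  }
  r2 <- stats::cor(t(x))^2
  r2 <- pmin(r2, 1 - 1e-12)
  pen <- if (penalty == "bic") log(n) else 2
  w <- -n * log1p(-r2) - pen
  diag(w) <- NA_real_
  structure(list(w = w, n = n, penalty = penalty), class = "edge_weights")
}

#' @export
print.edge_weights <- function(x, ...) {
  cat("edge_weights over", nrow(x$w), "proteins, n =", x$n,
      ", penalty =", x$penalty, "\n")
  invisible(x)
}

# incremental connected components by weighted label merging: O(1) lookup,
# relabel-the-smaller-side merges keep total work O(p log p)
.merge_tracker <- function(p) {
  env <- new.env(parent = emptyenv())
  env$comp <- seq_len(p)
  env$members <- as.list(seq_len(p))
  env
}

.merge_components <- function(env, i, j) {
  ci <- env$comp[i]
  cj <- env$comp[j]
  if (ci == cj) return(FALSE)
  if (length(env$members[[ci]]) < length(env$members[[cj]])) {
    tmp <- ci; ci <- cj; cj <- tmp
  }
  env$comp[env$members[[cj]]] <- ci
  env$members[[ci]] <- c(env$members[[ci]], env$members[[cj]])
  env$members[cj] <- list(integer(0))
  TRUE
}

#' Learn the minimal-BIC spanning forest
#'
#' Maximum-weight spanning forest by Kruskal's algorithm over the edges with
#' strictly positive penalized weight. Because every included edge improves
#' the information criterion and the forest constraint forbids cycles, the
#' result is the acyclic Gaussian graphical model minimizing BIC (or AIC).
#' Components need not be connected: proteins with no sufficiently correlated
#' partner stay isolated. Weight ties are broken by the lexicographic row/
#' column index pair, making the result deterministic.
#'
#' @param weights An [forest_edge_weights()] result, or a symmetric numeric
#'   weight matrix with protein dimnames.
#' @return An object of class `forest_model`: list with `vertices`, an edge
#'   data.frame (`from`, `to`, `weight`), and `membership`, the connected
#'   component index of each vertex.
#' @export
learn_minimal_bic_forest <- function(weights) {
  w <- if (inherits(weights, "edge_weights")) weights$w else weights
  if (!isSymmetric(unname(ifelse(is.na(w), 0, w))))
    stop("weight matrix must be symmetric")
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(w)))
  p <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  pos <- !is.na(wt) & wt > 0
  ut <- ut[pos, , drop = FALSE]
  wt <- wt[pos]
  ord <- order(-wt, ut[, 1L], ut[, 2L])
  tracker <- .merge_tracker(p)
  from <- integer(p)
  to <- integer(p)
  ew <- numeric(p)
  n_edges <- 0L
  ei <- ut[, 1L]
  ej <- ut[, 2L]
  for (e in ord) {
    if (.merge_components(tracker, ei[e], ej[e])) {
      n_edges <- n_edges + 1L
      from[n_edges] <- ei[e]
      to[n_edges] <- ej[e]
      ew[n_edges] <- wt[e]
      if (n_edges == p - 1L) break
    }
  }
  from <- from[seq_len(n_edges)]
  to <- to[seq_len(n_edges)]
  ew <- ew[seq_len(n_edges)]
  edges <- data.frame(from = ids[from], to = ids[to], weight = ew,
                      stringsAsFactors = FALSE)
  structure(list(vertices = ids, edges = edges,
                 membership = .components(ids, edges)),
            class = "forest_model")
}

# component labels for a vertex subset: v = global vertex indices, a/b =
# global endpoint indices of the edges inside the subset
.local_components <- function(v, a, b) {
  nv <- length(v)
  la <- match(a, v)
  lb <- match(b, v)
  comp <- seq_len(nv)
  members <- as.list(seq_len(nv))
  for (e in seq_along(la)) {
    ca <- comp[la[e]]
    cb <- comp[lb[e]]
    if (ca == cb) next
    if (length(members[[ca]]) < length(members[[cb]])) {
      tmp <- ca; ca <- cb; cb <- tmp
    }
    comp[members[[cb]]] <- ca
    members[[ca]] <- c(members[[ca]], members[[cb]])
    members[cb] <- list(integer(0))
  }
  comp
}

# connected-component membership of a vertex set under an edge list
.components <- function(ids, edges) {
  tracker <- .merge_tracker(length(ids))
  fi <- match(edges$from, ids)
  ti <- match(edges$to, ids)
  for (e in seq_along(fi)) .merge_components(tracker, fi[e], ti[e])
  comp <- match(tracker$comp, unique(tracker$comp))
  names(comp) <- ids
  comp
}

#' Fit a forest-structured Gaussian graphical model
#'
#' Convenience fitting front end: computes penalized pairwise weights with
#' [forest_edge_weights()] and learns the maximum-weight spanning forest with
#' [learn_minimal_bic_forest()]. The forest organizes proteins by expression
#' profile without any prior biological information.
#'
#' @inheritParams forest_edge_weights
#' @return A `forest_model` (see [learn_minimal_bic_forest()]) with the
#'   call and sample size recorded.
#' @export
forest_pgm <- function(x, penalty = c("bic", "aic")) {
  w <- forest_edge_weights(x, penalty = penalty)
  fit <- learn_minimal_bic_forest(w)
  fit$n <- w$n
  fit$penalty <- w$penalty
  fit$call <- match.call()
  fit
}

#' @export
print.forest_model <- function(x, ...) {
  cat("forest_model:", length(x$vertices), "proteins,", nrow(x$edges),
      "edges,", length(unique(x$membership)), "components\n")
  invisible(x)
}

#' @export
summary.forest_model <- function(object, ...) {
  sizes <- sort(table(object$membership), decreasing = TRUE)
  out <- list(n_vertices = length(object$vertices),
              n_edges = nrow(object$edges),
              n_components = length(sizes),
              component_sizes = as.integer(sizes),
              weight_range = if (nrow(object$edges) > 0)
                range(object$edges$weight) else c(NA_real_, NA_real_))
  class(out) <- "summary.forest_model"
  out
}

#' @export
print.summary.forest_model <- function(x, ...) {
  cat("Forest graphical model\n")
  cat("  vertices:  ", x$n_vertices, "\n")
  cat("  edges:     ", x$n_edges, "\n")
  cat("  components:", x$n_components,
      " (largest ", x$component_sizes[1L], ")\n", sep = "")
  if (!is.na(x$weight_range[1L]))
    cat("  edge weights: [", signif(x$weight_range[1L], 4), ", ",
        signif(x$weight_range[2L], 4), "]\n", sep = "")
  invisible(x)
}

#' Plot a forest model
#'
#' Requires the igraph package; isolated vertices can be hidden to keep large
#' forests readable.
#'
#' @param x A `forest_model`.
#' @param show_isolated Include degree-zero proteins.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.forest_model <- function(x, show_isolated = FALSE, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting a forest_model requires the igraph package")
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = data.frame(name = x$vertices))
  if (!show_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  plot(g, ...)
  invisible(x)
}

#' Export forest edges as a TSV edge list
#'
#' @param forest A `forest_model`.
#' @param path Output path; columns source, target, weight.
#' @return `path`, invisibly.
#' @export
write_forest_edges <- function(forest, path) {
  df <- forest$edges
  colnames(df) <- c("source", "target", "weight")
  write_results(df, path)
}

#' Split a forest into branches of bounded size
#'
#' While any connected component exceeds `max_size`, that component's
#' minimum-weight edge is deleted; the surviving components are the branches
#' later given a biological function. Components smaller than `min_size`
#' (including isolated proteins) are kept but flagged unassigned — too small
#' to annotate. Branches partition the vertex set.
#'
#' @param forest A `forest_model`.
#' @param max_size Largest allowed branch, >= `min_size`.
#' @param min_size Smallest annotatable branch, >= 2.
#' @return A list of class `branch_set`; each element has `proteins` (character
#'   vector) and `assignable` (logical). Branches are ordered by decreasing
#'   size.
#' @export
split_into_branches <- function(forest, max_size = 300L, min_size = 10L) {
  stopifnot(inherits(forest, "forest_model"), max_size >= min_size,
            min_size >= 2L)
  ids <- forest$vertices
  fi <- match(forest$edges$from, ids)
  ti <- match(forest$edges$to, ids)
  w <- forest$edges$weight
  comp <- unname(forest$membership)
  done <- list()
  # stack of (vertex indices, edge indices); oversized entries lose their
  # weakest edge and the two resulting pieces are pushed back
  stack <- lapply(unique(comp), function(cid) {
    list(v = which(comp == cid), e = which(comp[fi] == cid))
  })
  while (length(stack) > 0L) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(item$v) <= max_size) {
      done[[length(done) + 1L]] <- item$v
      next
    }
    cut <- item$e[which.min(w[item$e])]
    keep <- setdiff(item$e, cut)
    local <- .local_components(item$v, fi[keep], ti[keep])
    for (piece in unique(local)) {
      sel <- local == piece
      stack[[length(stack) + 1L]] <-
        list(v = item$v[sel], e = keep[sel[match(fi[keep], item$v)]])
    }
  }
  branches <- lapply(done, function(v) {
    prot <- ids[v]
    list(proteins = prot, assignable = length(prot) >= min_size)
  })
  branches <- branches[order(-vapply(branches, function(b)
    length(b$proteins), integer(1L)))]
  names(branches) <- sprintf("branch%02d", seq_along(branches))
  structure(branches, class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  sizes <- vapply(x, function(b) length(b$proteins), integer(1L))
  assignable <- vapply(x, function(b) b$assignable, logical(1L))
  cat("branch_set:", length(x), "branches (",
      sum(assignable), "assignable,", sum(!assignable), "below min size)\n")
  cat("  sizes:", paste(utils::head(sizes, 15L), collapse = ", "),
      if (length(sizes) > 15L) "..." else "", "\n")
  invisible(x)
}
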