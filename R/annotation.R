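#' Overrepresentation test for a branch against gene sets
#'
#' Exact hypergeometric enrichment of a branch (a connected piece of the
#' forest) against every annotation term, with the background restricted to
#' the proteins actually quantified (the filtered matrix), the conservative
#' convention when a measured background is available. For a term with
#' \eqn{K} background members, branch size \eqn{m}, background size \eqn{N}
#' and overlap \eqn{k}, the p-value is the upper tail
#' \eqn{P(X \ge k)} of the hypergeometric distribution; q-values are
#' Benjamini-Hochberg across the terms tested for this branch, and fold
#' enrichment is \eqn{(k/m)/(K/N)}.
#'
#' @param branch Character vector of branch protein ids (must be a subset of
#'   `background`).
#' @param annot An [annotation_set()]; member sets are intersected with the
#'   background before testing.
#' @param background Character vector of all quantified protein ids.
#' @return A data.frame (one row per term) with columns `term_id`,
#'   `term_name`, `overlap`, `branch_size`, `term_size`, `background_size`,
#'   `fold`, `p`, `q`, ordered by q, then decreasing overlap, then term id.
#' @export
overrepresentation_test <- function(branch, annot, background) {
  stopifnot(inherits(annot, "annotation_set"))
  branch <- unique(as.character(branch))
  background <- unique(as.character(background))
  if (length(branch) == 0L) stop("empty branch")
  stray <- setdiff(branch, background)
  if (length(stray) > 0L)
    stop("branch protein not in background: ", stray[1L])
  N <- length(background)
  m <- length(branch)
  members <- lapply(annot$members, intersect, background)
  K <- lengths(members)
  k <- vapply(members, function(mm) length(intersect(mm, branch)), integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
  fold <- ifelse(k == 0L, 0, (k / m) / (K / N))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = annot$term_id, term_name = annot$term_name,
                    overlap = k, branch_size = m, term_size = K,
                    background_size = N, fold = fold, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, -out$overlap, out$term_id), , drop = FALSE]
}

#' Assign the main biological function of a branch
#'
#' The branch becomes a functional node labeled with the most
#' overrepresented term: minimum q, ties broken by larger overlap and then by
#' term id. A term qualifies only with `q <= q_threshold` and overlap
#' `>= min_overlap`; if none qualifies the node carries no overrepresented
#' function (`term_id` NA) and its main-function set is empty.
#'
#' @param branch Character vector of branch protein ids.
#' @param ora Result of [overrepresentation_test()] for this branch.
#' @param annot The [annotation_set()] used for the test.
#' @param q_threshold Maximum BH q-value for assignment.
#' @param min_overlap Minimum branch/term overlap for assignment.
#' @return An object of class `functional_node`: list with `proteins`,
#'   `term_id`, `term_name`, `main_proteins` (branch members annotated to the
#'   assigned term) and the `ora` table.
#' @export
assign_main_function <- function(branch, ora, annot, q_threshold = 0.05,
                                 min_overlap = 3L) {
  branch <- unique(as.character(branch))
  pass <- ora[ora$q <= q_threshold & ora$overlap >= min_overlap, , drop = FALSE]
  pass <- pass[order(pass$q, -pass$overlap, pass$term_id), , drop = FALSE]
  if (nrow(pass) == 0L) {
    node <- list(proteins = branch, term_id = NA_character_,
                 term_name = NA_character_, main_proteins = character(0),
                 ora = ora)
  } else {
    top <- pass[1L, ]
    node <- list(proteins = branch, term_id = top$term_id,
                 term_name = top$term_name,
                 main_proteins = intersect(branch, annot$members[[top$term_id]]),
                 ora = ora)
  }
  structure(node, class = "functional_node")
}

#' @export
print.functional_node <- function(x, ...) {
  if (is.na(x$term_id)) {
    cat("functional_node (", length(x$proteins),
        " proteins): no overrepresented function\n", sep = "")
  } else {
    cat("functional_node (", length(x$proteins), " proteins): ",
        x$term_name, " [", x$term_id, "], ",
        length(x$main_proteins), " main-function proteins, q = ",
        signif(x$ora$q[x$ora$term_id == x$term_id], 3), "\n", sep = "")
  }
  invisible(x)
}

#' Annotate every assignable branch into functional nodes
#'
#' Runs [overrepresentation_test()] and [assign_main_function()] per branch
#' (multiple testing is corrected within each branch independently). A branch
#' can carry more than one biological function: when tightly co-regulated
#' processes travel together in the forest, a single branch may hold
#' essentially all proteins of a second term. Such secondary functions —
#' terms passing the q and overlap thresholds whose branch overlap covers at
#' least `secondary_coverage` of the term's background members and whose
#' proteins are mostly distinct from the primary function — are emitted as
#' additional functional nodes with their own main-function protein sets, so
#' each node activity tracks one process. Node names are the assigned term
#' names; when two nodes receive the same term the later ones are suffixed
#' " 2", " 3", ... Nodes without an overrepresented function are named
#' "unassigned function".
#'
#' @param branches A `branch_set` from [split_into_branches()].
#' @param annot An [annotation_set()].
#' @param background Character vector of all quantified protein ids.
#' @param secondary_coverage Minimum fraction of a term's background members
#'   that must fall inside the branch for the term to qualify as a secondary
#'   function; set above 1 to disable secondary functions.
#' @inheritParams assign_main_function
#' @return Named list of `functional_node` objects; secondary nodes carry
#'   `secondary = TRUE`.
#' @export
functional_nodes <- function(branches, annot, background, q_threshold = 0.05,
                             min_overlap = 3L, secondary_coverage = 0.8) {
  stopifnot(inherits(branches, "branch_set"))
  keep <- vapply(branches, function(b) b$assignable, logical(1L))
  nodes <- list()
  for (b in branches[keep]) {
    ora <- overrepresentation_test(b$proteins, annot, background)
    primary <- assign_main_function(b$proteins, ora, annot, q_threshold,
                                    min_overlap)
    primary$secondary <- FALSE
    nodes[[length(nodes) + 1L]] <- primary
    if (is.na(primary$term_id)) next
    cand <- ora[ora$term_id != primary$term_id &
                  ora$q <= q_threshold & ora$overlap >= min_overlap &
                  ora$term_size > 0L &
                  ora$overlap / ora$term_size >= secondary_coverage, ,
                drop = FALSE]
    for (ti in cand$term_id) {
      main2 <- intersect(b$proteins, annot$members[[ti]])
      shared <- length(intersect(main2, primary$main_proteins))
      if (shared / length(main2) > 0.5) next  # near-duplicate of the primary
      nodes[[length(nodes) + 1L]] <- structure(
        list(proteins = b$proteins, term_id = ti,
             term_name = annot$term_name[annot$term_id == ti],
             main_proteins = main2,
             ora = ora, secondary = TRUE),
        class = "functional_node")
    }
  }
  raw <- vapply(nodes, function(nd)
    if (is.na(nd$term_name)) "unassigned function" else nd$term_name,
    character(1L))
  labels <- raw
  for (i in seq_along(labels)) {
    prior <- sum(raw[seq_len(i - 1L)] == raw[i])
    if (prior > 0L) labels[i] <- paste(raw[i], prior + 1L)
  }
  names(nodes) <- labels
  nodes
}

#' Per-sample activity of a functional node
#'
#' The activity of a node in a sample is the arithmetic mean of the log2
#' intensities of the node's main-function proteins in that sample.
#'
#' @param x Complete expression matrix containing all main-function proteins.
#' @param node A `functional_node`.
#' @return Named numeric vector over the matrix samples.
#' @export
node_activity <- function(x, node) {
  stopifnot(inherits(node, "functional_node"))
  if (length(node$main_proteins) == 0L)
    stop("node has an empty main-function protein set")
  absent <- setdiff(node$main_proteins, rownames(x))
  if (length(absent) > 0L)
    stop("main-function protein absent from matrix: ", absent[1L])
  colMeans(x[node$main_proteins, , drop = FALSE])
}

#' Activity matrix over a list of functional nodes
#'
#' @param x Complete expression matrix.
#' @param nodes Named list of `functional_node` objects; nodes with an empty
#'   main-function set (no overrepresented function) are skipped.
#' @return Numeric matrix, nodes in rows and samples in columns.
#' @export
node_activity_matrix <- function(x, nodes) {
  keep <- vapply(nodes, function(nd) length(nd$main_proteins) > 0L, logical(1L))
  acts <- vapply(nodes[keep], function(nd) node_activity(x, nd),
                 numeric(ncol(x)))
  acts <- matrix(acts, nrow = ncol(x), ncol = sum(keep),
                 dimnames = list(colnames(x), names(nodes)[keep]))
  t(acts)
}

#' Write a functional-node report
#'
#' @param nodes Named list of `functional_node` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_report <- function(nodes, path) {
  rows <- lapply(seq_along(nodes), function(i) {
    nd <- nodes[[i]]
    data.frame(node = names(nodes)[i],
               term_id = nd$term_id, term_name = nd$term_name,
               q = if (is.na(nd$term_id)) NA_real_
                   else nd$ora$q[nd$ora$term_id == nd$term_id],
               secondary = isTRUE(nd$secondary),
               n_proteins = length(nd$proteins),
               n_main_function = length(nd$main_proteins),
               main_function_proteins = paste(nd$main_proteins, collapse = ","),
               stringsAsFactors = FALSE)
  })
  write_results(do.call(rbind, rows), path)
}
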