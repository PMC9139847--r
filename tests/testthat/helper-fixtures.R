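# shared fixtures and independent oracles for the test suite

tiny_matrix <- function() {
  m <- matrix(c(1.5, 2.0, NA, 3.0,
                2.5, NA, 4.0, 1.0,
                3.5, 3.0, 2.0, 2.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"),
                              c("s1", "s2", "s3", "s4")))
  m
}

tiny_manifest <- function() {
  data.frame(sample_id = c("s1", "s2", "s3", "s4"),
             patient_id = c("a", "a", "b", "b"),
             tissue = factor(c("NT", "T", "NT", "T"),
                             levels = c("NT", "P", "T", "LN")),
             stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small synthetic cohort reused across tests
small_cohort <- function(seed = 7, ...) {
  generate_cohort(simulation_config(
    n_patients = 20, n_proteins = 300, n_blocks = 5,
    block_size_range = c(30, 100), seed = seed, ...))
}

# independent exhaustive maximizer: best acyclic edge subset by total weight,
# enumerating all 2^E subsets of positive-weight edges
brute_force_best_forest <- function(w) {
  p <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[idx]
  keep <- wt > 0
  idx <- idx[keep, , drop = FALSE]
  wt <- wt[keep]
  ne <- length(wt)
  best <- 0
  best_set <- integer(0)
  acyclic <- function(sel) {
    if (length(sel) == 0L) return(TRUE)
    a <- idx[sel, 1L]
    b <- idx[sel, 2L]
    comp <- seq_len(p)
    for (e in seq_along(a)) {
      ca <- comp[a[e]]
      cb <- comp[b[e]]
      if (ca == cb) return(FALSE)
      comp[comp == cb] <- ca
    }
    TRUE
  }
  if (ne > 0L) {
    for (mask in seq_len(2^ne) - 1L) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
      if (!acyclic(sel)) next
      tot <- sum(wt[sel])
      if (tot > best) {
        best <- tot
        best_set <- sel
      }
    }
  }
  list(weight = best,
       edges = if (length(best_set) > 0L)
         cbind(idx[best_set, 1L], idx[best_set, 2L]) else
           matrix(integer(0), ncol = 2))
}

# normalize an edge set (vertex-name pairs) for comparison
edge_key <- function(from, to) {
  if (length(from) == 0L) return(character(0))
  sort(paste(pmin(from, to), pmax(from, to)))
}

# edge key of a brute-force result's index matrix (rows may be empty)
oracle_edge_key <- function(edges, prefix = "V") {
  if (nrow(edges) == 0L) return(character(0))
  edge_key(paste0(prefix, edges[, 1]), paste0(prefix, edges[, 2]))
}

forest_is_acyclic <- function(forest) {
  # leaf pruning: a forest loses all its edges; any remainder is a cycle
  edges <- forest$edges[, c("from", "to")]
  repeat {
    if (nrow(edges) == 0L) return(TRUE)
    deg <- table(c(edges$from, edges$to))
    leaves <- names(deg)[deg == 1]
    if (length(leaves) == 0L) return(FALSE)
    edges <- edges[!(edges$from %in% leaves | edges$to %in% leaves), ,
                   drop = FALSE]
  }
}

# adjusted Rand index, computed from the contingency table definition
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# paired-tissue activity simulation for the mixed-model checks: 40 patients,
# tumor always sampled, other tissues by availability, patient random
# intercept plus iid residual, optional tumor shift relative to NT/P
simulate_paired_activity <- function(effect_T = 0, patient_sd = 1,
                                     resid_sd = 1, n_patients = 40) {
  tissues <- c("NT", "P", "T", "LN")
  avail <- c(NT = 0.9, P = 0.8, T = 1.0, LN = 0.6)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    tt <- tissues[stats::runif(4) < avail]
    if (!"T" %in% tt) tt <- c(tt, "T")
    data.frame(sample_id = paste0("PT", i, "_", tt),
               patient_id = paste0("PT", i), tissue = tt,
               stringsAsFactors = FALSE)
  }))
  rows$tissue <- factor(rows$tissue, levels = tissues)
  u <- stats::rnorm(n_patients, 0, patient_sd)
  names(u) <- paste0("PT", seq_len(n_patients))
  act <- u[rows$patient_id] + stats::rnorm(nrow(rows), 0, resid_sd) +
    ifelse(rows$tissue == "T", effect_T, 0)
  names(act) <- rows$sample_id
  list(activity = act, manifest = rows)
}
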