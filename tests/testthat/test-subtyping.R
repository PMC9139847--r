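make_clustered_matrix <- function(n_per = 6, p = 90, shift = 5, seed = 31) {
  set.seed(seed)
  x <- matrix(rnorm(p * 3 * n_per), p, 3 * n_per,
              dimnames = list(sprintf("P%03d", 1:p),
                              sprintf("s%02d", 1:(3 * n_per))))
  grp <- rep(1:3, each = n_per)
  blocks <- split(1:p, rep(1:3, each = p / 3))
  for (g in 1:3) x[blocks[[g]], grp == g] <- x[blocks[[g]], grp == g] + shift
  list(x = x, truth = factor(paste0("G", grp)))
}

test_that("correlation/average-linkage clustering recovers well-separated groups", {
  mc <- make_clustered_matrix()
  asg <- hcl_subtypes(mc$x, k = 3)
  expect_equal(adjusted_rand(asg, mc$truth), 1.0)
  expect_identical(levels(asg), c("T1", "T2", "T3"))
  expect_identical(names(asg), colnames(mc$x))
})

test_that("duplicated samples merge first and degenerate k works", {
  mc <- make_clustered_matrix(n_per = 3)
  x <- cbind(mc$x, dup = mc$x[, 1])
  asg <- hcl_subtypes(x, k = ncol(x) - 1)  # every singleton except the tied pair
  expect_identical(asg[["dup"]], asg[[colnames(mc$x)[1]]])

  asg1 <- hcl_subtypes(mc$x, k = 1)
  expect_identical(length(unique(asg1)), 1L)
  expect_error(hcl_subtypes(mc$x, k = ncol(mc$x) + 1), "exceeds")
})

test_that("labels are ordered by cluster size", {
  mc <- make_clustered_matrix(n_per = 4)
  # drop samples to make sizes 4, 3, 2
  keep <- c(1:4, 5:7, 9:10)
  asg <- hcl_subtypes(mc$x[, keep], k = 3)
  sizes <- table(asg)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("SAM d-statistic is zero when group means coincide", {
  x <- rbind(P1 = c(1, 2, 3, 1, 2, 3), P2 = c(0, 1, 2, 2, 1, 0))
  colnames(x) <- paste0("s", 1:6)
  y <- factor(rep(c("A", "B"), each = 3))
  fit <- sam_multiclass(x, y, n_perm = 100, seed = 1)
  expect_equal(unname(fit$d), c(0, 0), tolerance = 1e-12)
})

test_that("a strongly shifted protein attains the maximum SAM score", {
  set.seed(5)
  x <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("s%02d", 1:30)))
  y <- factor(rep(c("A", "B", "C"), each = 10))
  x["P007", y == "B"] <- x["P007", y == "B"] + 10
  fit <- sam_multiclass(x, y, n_perm = 100, seed = 2)
  expect_identical(names(which.max(fit$d)), "P007")
  expect_true("P007" %in% fit$selected)
})

test_that("SAM selects nothing (median) on pure-noise data", {
  sizes <- vapply(1:20, function(s) {
    set.seed(4000 + s)
    x <- matrix(rnorm(200 * 30), 200, 30,
                dimnames = list(sprintf("P%03d", 1:200),
                                sprintf("s%02d", 1:30)))
    y <- factor(rep(c("A", "B", "C"), each = 10))
    length(sam_multiclass(x, y, n_perm = 100, seed = s)$selected)
  }, integer(1))
  expect_lte(median(sizes), 1)
})

test_that("SAM is deterministic under a fixed seed and validates inputs", {
  set.seed(77)
  x <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:12)))
  y <- factor(rep(c("A", "B", "C"), each = 4))
  f1 <- sam_multiclass(x, y, n_perm = 100, seed = 9)
  f2 <- sam_multiclass(x, y, n_perm = 100, seed = 9)
  expect_identical(f1$d, f2$d)
  expect_identical(f1$selected, f2$selected)
  expect_error(sam_multiclass(x, factor(c("A", rep(c("B", "C"), c(5, 6)))),
                              n_perm = 100), "fewer than 2 samples")
  expect_error(sam_multiclass(x, y, n_perm = 10), "at least 100")
})

test_that("centroids equal per-subtype means", {
  set.seed(12)
  x <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("s%02d", 1:15)))
  asg <- factor(rep(c("T1", "T2", "T3"), each = 5))
  names(asg) <- colnames(x)
  sig <- rownames(x)[1:12]
  model <- build_centroids(x, asg, sig)
  manual <- sapply(c("T1", "T2", "T3"), function(st)
    rowMeans(x[sig, names(asg)[asg == st]]))
  expect_equal(model$centroids, manual)

  # one sample per subtype: centroid equals the sample
  asg1 <- factor(c("T1", "T2", "T3"))
  names(asg1) <- colnames(x)[1:3]
  m1 <- build_centroids(x[, 1:3], asg1, sig)
  expect_equal(unname(m1$centroids[, "T2"]), unname(x[sig, 2]))

  # duplicated samples in a subtype: centroid equals either
  x2 <- x[, c(1, 1, 2, 3)]
  colnames(x2) <- c("a1", "a2", "b", "c")
  asg2 <- factor(c("T1", "T1", "T2", "T2"))
  names(asg2) <- colnames(x2)
  m2 <- build_centroids(x2, asg2, sig)
  expect_equal(unname(m2$centroids[, "T1"]), unname(x[sig, 1]))
})

test_that("centroid classification is exact on centroids and shift-invariant", {
  set.seed(13)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("s%02d", 1:12)))
  asg <- factor(rep(c("T1", "T2", "T3"), each = 4))
  names(asg) <- colnames(x)
  model <- build_centroids(x, asg, rownames(x))
  for (st in c("T1", "T2", "T3")) {
    v <- model$centroids[, st]
    expect_identical(as.character(classify_by_centroid(v, model)), st)
    expect_identical(as.character(classify_by_centroid(v + 7.5, model)), st)
  }
  # too few shared features errors
  v <- model$centroids[1:10, "T1"]
  expect_error(classify_by_centroid(v, model, min_fraction = 0.8),
               "signature present")
})

test_that("clustering is invariant to per-sample affine rescaling", {
  mc <- make_clustered_matrix(n_per = 4, seed = 55)
  asg1 <- hcl_subtypes(mc$x, k = 3)
  x2 <- sweep(sweep(mc$x, 2, runif(ncol(mc$x), 0.5, 2), `*`),
              2, rnorm(ncol(mc$x)), `+`)
  asg2 <- hcl_subtypes(x2, k = 3)
  expect_equal(adjusted_rand(asg1, asg2), 1.0)
})
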