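test_that("hypergeometric enrichment matches the exact combinatorial sum", {
  bg <- sprintf("P%02d", 1:50)
  annot <- annotation_set(
    term_id = c("T:A", "T:B"),
    term_name = c("in-term", "disjoint"),
    members = list(bg[1:10], bg[41:50]))
  branch <- c(bg[1:3], bg[21:22])  # overlap 3 with T:A, 0 with T:B
  ora <- overrepresentation_test(branch, annot, bg)
  # sum_{x=3..5} C(10,x) C(40,5-x) / C(50,5), frozen from direct enumeration
  expect_equal(ora$p[ora$term_id == "T:A"], 0.048260303196, tolerance = 1e-9)
  expect_equal(ora$fold[ora$term_id == "T:A"], (3 / 5) / (10 / 50))
  # zero overlap: p = 1, fold = 0
  expect_equal(ora$p[ora$term_id == "T:B"], 1)
  expect_equal(ora$fold[ora$term_id == "T:B"], 0)
})

test_that("degenerate certainty gives p = 1 and empty branches error", {
  bg <- paste0("P", 1:10)
  annot <- annotation_set("T:ALL", "everything", list(bg))
  ora <- overrepresentation_test(bg, annot, bg)
  expect_equal(ora$p, 1)
  expect_error(overrepresentation_test(character(0), annot, bg), "empty branch")
})

test_that("BH q-values are monotone in p-rank and bounded by p from below at the top", {
  set.seed(21)
  bg <- sprintf("P%03d", 1:200)
  members <- lapply(1:15, function(i) sample(bg, sample(10:40, 1)))
  annot <- annotation_set(sprintf("T:%02d", 1:15), sprintf("term%02d", 1:15),
                          members)
  branch <- sample(bg, 30)
  ora <- overrepresentation_test(branch, annot, bg)
  ord <- order(ora$p)
  expect_true(all(diff(ora$q[ord]) >= -1e-12))
  expect_gte(ora$q[ord][1], ora$p[ord][1])
})

test_that("main-function assignment applies thresholds and tie-breaks", {
  bg <- sprintf("P%02d", 1:40)
  annot <- annotation_set(c("T:B", "T:A"), c("later", "earlier"),
                          list(bg[1:10], bg[1:10]))
  branch <- bg[1:10]
  # identical terms: equal q and overlap, lexicographic term_id wins
  ora <- overrepresentation_test(branch, annot, bg)
  node <- assign_main_function(branch, ora, annot)
  expect_identical(node$term_id, "T:A")
  expect_setequal(node$main_proteins, branch)

  # equal q, overlaps 5 vs 3: larger overlap wins regardless of table order
  ora2 <- data.frame(term_id = c("T:small", "T:big"),
                     term_name = c("small", "big"),
                     overlap = c(3L, 5L), branch_size = 10L,
                     term_size = c(3L, 5L), background_size = 40L,
                     fold = c(4, 4), p = c(0.001, 0.001), q = c(0.002, 0.002),
                     stringsAsFactors = FALSE)
  annot2 <- annotation_set(c("T:small", "T:big"), c("small", "big"),
                           list(bg[1:3], bg[1:5]))
  node2 <- assign_main_function(bg[1:10], ora2, annot2)
  expect_identical(node2$term_id, "T:big")

  # nothing passes: function-free node
  node3 <- assign_main_function(branch, ora, annot, q_threshold = 1e-30)
  expect_true(is.na(node3$term_id))
  expect_identical(node3$main_proteins, character(0))
  expect_error(node_activity(tiny_matrix(), node3), "empty main-function")
})

test_that("node activity is the column mean of the main-function proteins", {
  x <- matrix(c(2, 4, 1, 3), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  node <- structure(list(proteins = c("P1", "P2"), term_id = "T:1",
                         term_name = "t", main_proteins = c("P1", "P2"),
                         ora = NULL), class = "functional_node")
  act <- node_activity(x, node)
  expect_equal(unname(act), c(3, 2))

  # constant proteins give constant activity
  xc <- matrix(5, 3, 4, dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
  nodec <- structure(list(proteins = paste0("P", 1:3),
                          term_id = "T:1", term_name = "t",
                          main_proteins = paste0("P", 1:3), ora = NULL),
                     class = "functional_node")
  expect_equal(unname(node_activity(xc, nodec)), rep(5, 4))

  # 5-protein node on a 4-sample matrix vs hand-computed subset means
  set.seed(8)
  x5 <- matrix(rnorm(32), 8, 4,
               dimnames = list(paste0("P", 1:8), paste0("s", 1:4)))
  main <- paste0("P", c(1, 3, 4, 6, 8))
  node5 <- structure(list(proteins = rownames(x5), term_id = "T:1",
                          term_name = "t", main_proteins = main, ora = NULL),
                     class = "functional_node")
  manual <- apply(x5[main, ], 2, mean)
  expect_equal(node_activity(x5, node5), manual)
})

test_that("activity is affine-equivariant in the expression matrix", {
  set.seed(9)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  node <- structure(list(proteins = rownames(x), term_id = "T:1",
                         term_name = "t", main_proteins = paste0("P", 1:6),
                         ora = NULL), class = "functional_node")
  a <- 2.5
  b <- -1.25
  expect_equal(node_activity(a * x + b, node), a * node_activity(x, node) + b)
})

test_that("functional_nodes annotates branches and disambiguates repeated names", {
  coh <- small_cohort(seed = 17)
  imp <- preprocess_matrix(coh$matrix, coh$manifest, preprocess_config(seed = 3))
  fit <- forest_pgm(imp)
  br <- split_into_branches(fit, max_size = 120, min_size = 5)
  nodes <- functional_nodes(br, coh$annotation, rownames(imp))
  expect_gt(length(nodes), 0)
  expect_identical(anyDuplicated(names(nodes)), 0L)
  for (nd in nodes) {
    if (!is.na(nd$term_id)) {
      expect_true(all(nd$main_proteins %in% nd$proteins))
      expect_lte(nd$ora$q[1], 0.05)
    }
  }
})
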