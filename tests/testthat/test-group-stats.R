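test_that("constant activity yields zero estimates", {
  mf <- data.frame(sample_id = paste0("s", 1:8),
                   patient_id = rep(paste0("p", 1:4), each = 2),
                   tissue = factor(rep(c("NT", "T"), 4),
                                   levels = c("NT", "P", "T", "LN")))
  act <- setNames(rep(3.2, 8), mf$sample_id)
  res <- suppressWarnings(mixed_model_contrasts(act, mf,
                                                list(`NT->T` = c("NT", "T"))))
  expect_equal(res$estimate, 0)
})

test_that("with no between-patient variance the contrast equals the raw mean difference", {
  # balanced two-tissue design, patient effects exactly zero -> the random
  # intercept is singular and the fixed-effects limit is the group mean gap
  set.seed(14)
  mf <- data.frame(sample_id = paste0("s", 1:20),
                   patient_id = rep(paste0("p", 1:10), each = 2),
                   tissue = factor(rep(c("NT", "T"), 10),
                                   levels = c("NT", "P", "T", "LN")))
  act <- setNames(rnorm(20), mf$sample_id)
  res <- mixed_model_contrasts(act, mf, list(`NT->T` = c("NT", "T")))
  raw_diff <- mean(act[mf$tissue == "T"]) - mean(act[mf$tissue == "NT"])
  expect_equal(res$estimate, raw_diff, tolerance = 1e-6)
  expect_identical(res$direction, if (raw_diff >= 0) "up" else "down")
})

test_that("contrasts with absent tissue levels are skipped with a warning", {
  mf <- data.frame(sample_id = paste0("s", 1:8),
                   patient_id = rep(paste0("p", 1:4), each = 2),
                   tissue = factor(rep(c("NT", "T"), 4),
                                   levels = c("NT", "P", "T", "LN")))
  set.seed(3)
  act <- setNames(rnorm(8), mf$sample_id)
  w <- capture_warnings(res <- mixed_model_contrasts(act, mf))
  expect_true(any(grepl("P->T.*skipped", w)))
  expect_true(any(grepl("T->LN.*skipped", w)))
  expect_identical(res$contrast, "NT->T")
})

test_that("mixed model recovers a planted tissue effect", {
  set.seed(15)
  sim <- simulate_paired_activity(effect_T = 2, patient_sd = 1,
                                  resid_sd = 0.5)
  res <- mixed_model_contrasts(sim$activity, sim$manifest)
  est <- res$estimate[res$contrast == "P->T"]
  expect_lt(abs(est - 2), 0.5)
  expect_lt(res$p[res$contrast == "P->T"], 0.001)
  expect_identical(res$model[1], "mixed")
})

test_that("Mann-Whitney matches exact enumeration and maps significance tiers", {
  acts <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                 dimnames = list("node1", paste0("s", 1:6)))
  asg <- factor(rep(c("T1", "T2"), each = 3))
  names(asg) <- colnames(acts)
  res <- mann_whitney_nodes(acts, asg)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/20, exact two-sided over all C(6,3) splits

  # identical groups: p = 1
  acts2 <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
                  dimnames = list("node1", paste0("s", 1:6)))
  res2 <- mann_whitney_nodes(acts2, asg)
  expect_equal(res2$p, 1)

  # large-sample strong shift lands in the **** tier
  set.seed(16)
  acts3 <- matrix(c(rnorm(40), rnorm(40, 5)), nrow = 1,
                  dimnames = list("node1", paste0("s", 1:80)))
  asg3 <- factor(rep(c("T1", "T2"), each = 40))
  names(asg3) <- colnames(acts3)
  res3 <- mann_whitney_nodes(acts3, asg3)
  expect_lt(res3$p, 1e-4)
  expect_identical(res3$stars, "****")
})

test_that("exact and corrected-normal Mann-Whitney branches agree for n = 8", {
  set.seed(17)
  for (i in 1:5) {
    g1 <- rnorm(8)
    g2 <- rnorm(8)
    p_exact <- wilcox.test(g1, g2, exact = TRUE)$p.value
    p_approx <- wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.011)
  }
})

test_that("chi-squared matches hand computation and handles balance", {
  clin <- data.frame(patient_id = paste0("p", 1:40),
                     var = rep(c("x", "y"), each = 20))
  asg <- factor(rep(c("T1", "T2"), each = 20))
  names(asg) <- clin$patient_id
  # perfect association (20,0;0,20): chi2 = 40, df 1
  res <- suppressWarnings(chi_square_clinical(asg, clin, "var"))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)

  # perfectly balanced table: statistic 0, p = 1
  clin2 <- clin
  clin2$var <- rep(c("x", "y"), 20)
  res2 <- chi_square_clinical(asg, clin2, "var")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  expect_error(chi_square_clinical(asg, clin, "nope"), "unknown clinical")
})

test_that("chi-squared p-values are uniform under independence", {
  set.seed(18)
  n <- 120
  ps <- replicate(400, {
    clin <- data.frame(patient_id = paste0("p", 1:n),
                       var = sample(c("x", "y"), n, replace = TRUE))
    asg <- factor(sample(c("T1", "T2", "T3"), n, replace = TRUE))
    names(asg) <- clin$patient_id
    suppressWarnings(chi_square_clinical(asg, clin, "var"))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the progression summary places significant nodes with direction arrows", {
  res <- data.frame(
    subtype = c("T2", "T2", "T1", "T3"),
    node = c("metabolism", "translation", "adhesion", "ECM"),
    contrast = c("P->T", "NT->T", "T->LN", "T->LN"),
    estimate = c(1.2, 0.8, -0.9, -1.1),
    p = c(0.001, 0.2, 0.01, 0.04),
    stringsAsFactors = FALSE)
  tab <- summarize_differential_nodes(res, alpha = 0.05)
  up_pt <- tab[tab$contrast == "P->T" & tab$direction == "\u2191", ]
  expect_match(up_pt$T2, "metabolism")
  down_tln <- tab[tab$contrast == "T->LN" & tab$direction == "\u2193", ]
  expect_match(down_tln$T1, "adhesion")
  expect_match(down_tln$T3, "ECM")
  # non-significant entries stay out
  expect_false(any(grepl("translation", unlist(tab))))

  # no significant effects: all cells empty
  res$p <- 0.9
  tab2 <- summarize_differential_nodes(res, alpha = 0.05)
  expect_true(all(tab2$T1 == "" & tab2$T2 == "" & tab2$T3 == ""))
})
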