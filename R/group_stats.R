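#' Default tissue progression contrasts
#'
#' NT to T (carcinogenesis against normal background), P to T (carcinogenesis
#' from the preneoplastic lesion) and T to LN (progression to lymph node
#' metastasis).
#'
#' @return List of length-2 character vectors `c(reference, target)`.
#' @export
default_contrasts <- function() {
  list(`NT->T` = c("NT", "T"), `P->T` = c("P", "T"), `T->LN` = c("T", "LN"))
}

#' Mixed-model tissue contrasts for one functional node
#'
#' Fits a linear mixed model of node activity on tissue type with a random
#' intercept per patient (samples are repeated punches/tissues of the same
#' patient), by REML. Each requested contrast (target minus reference tissue)
#' is a linear combination of the fixed effects, tested with a two-sided Wald
#' z-test. If the random-effect fit is singular the model falls back to fixed
#' effects only and the result is flagged; contrasts with an absent tissue are
#' skipped with a warning.
#'
#' @param activity Named numeric vector of node activities (one per sample).
#' @param manifest Sample manifest covering the activity samples.
#' @param contrasts List of `c(reference, target)` tissue pairs; default
#'   [default_contrasts()].
#' @return Data.frame with one row per computed contrast: `contrast`,
#'   `estimate` (target minus reference, activity units), `se`, `p`,
#'   `direction` (`"up"`/`"down"`), `model` (`"mixed"` or `"fixed"`).
#' @export
mixed_model_contrasts <- function(activity, manifest,
                                  contrasts = default_contrasts()) {
  samples <- names(activity)
  if (is.null(samples)) stop("activity must be named by sample")
  idx <- match(samples, manifest$sample_id)
  if (anyNA(idx)) stop("activity sample absent from manifest: ",
                       samples[which(is.na(idx))[1L]])
  df <- data.frame(activity = as.numeric(activity),
                   tissue = droplevels(manifest$tissue[idx]),
                   patient = factor(manifest$patient_id[idx]))
  if (nlevels(df$tissue) < 2L) stop("need at least 2 tissue levels")
  if (nlevels(df$patient) < 2L) stop("need at least 2 patients")
  mixed <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(activity ~ 0 + tissue + (1 | patient), data = df,
                 REML = TRUE)))
    if (lme4::isSingular(fit, tol = 1e-5)) NULL
    else list(beta = lme4::fixef(fit), vc = as.matrix(stats::vcov(fit)))
  }, error = function(e) NULL)
  singular <- is.null(mixed)
  if (singular) {
    # degenerate or singular random-intercept fit: fixed-effects-only model
    fit_fixed <- stats::lm(activity ~ 0 + tissue, data = df)
    beta <- stats::coef(fit_fixed)
    vc <- stats::vcov(fit_fixed)
  } else {
    beta <- mixed$beta
    vc <- mixed$vc
  }
  rows <- list()
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    a <- paste0("tissue", pair[1L])
    b <- paste0("tissue", pair[2L])
    if (!all(c(a, b) %in% names(beta))) {
      warning("contrast ", nm, " skipped: tissue level absent from data")
      next
    }
    cv <- stats::setNames(numeric(length(beta)), names(beta))
    cv[b] <- 1
    cv[a] <- -1
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% vc %*% cv))
    z <- if (se > 0) est / se else 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    rows[[nm]] <- data.frame(
      contrast = nm, estimate = est, se = se, p = p,
      direction = if (est >= 0) "up" else "down",
      model = if (singular) "fixed" else "mixed",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-model contrasts for every functional node
#'
#' @param activities Node activity matrix (nodes x samples), e.g. from
#'   [node_activity_matrix()].
#' @inheritParams mixed_model_contrasts
#' @return Data.frame stacking [mixed_model_contrasts()] results with a
#'   leading `node` column.
#' @export
tissue_contrast_table <- function(activities, manifest,
                                  contrasts = default_contrasts()) {
  rows <- lapply(rownames(activities), function(nd) {
    res <- mixed_model_contrasts(activities[nd, ], manifest, contrasts)
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    cbind(node = nd, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map p-values to significance stars
#'
#' GraphPad-style tiers: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tier labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Mann-Whitney comparison of node activities between subtypes
#'
#' For every node and every pair of subtypes, a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test: exact when both groups have at most 8 samples
#' and the data are tie-free, otherwise the normal approximation with tie
#' correction.
#'
#' @param activities Node activity matrix (nodes x samples).
#' @param assignment Named factor of subtype labels covering the activity
#'   samples.
#' @return Data.frame with columns `node`, `group1`, `group2`, `U`, `p`,
#'   `stars`.
#' @export
mann_whitney_nodes <- function(activities, assignment) {
  samples <- names(assignment)
  if (is.null(samples) || !all(samples %in% colnames(activities)))
    stop("assignment must be named by samples present in the activity matrix")
  labs <- factor(assignment)
  pairs <- utils::combn(levels(labs), 2L, simplify = FALSE)
  rows <- list()
  for (nd in rownames(activities)) {
    for (pr in pairs) {
      g1 <- activities[nd, samples[labs == pr[1L]]]
      g2 <- activities[nd, samples[labs == pr[2L]]]
      exact <- length(g1) <= 8L && length(g2) <= 8L &&
        !anyDuplicated(c(g1, g2))
      wt <- suppressWarnings(
        stats::wilcox.test(g1, g2, exact = exact, correct = !exact)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, group1 = pr[1L], group2 = pr[2L],
        U = unname(wt$statistic), p = wt$p.value, stars = p_stars(wt$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-squared association between subtypes and a clinical variable
#'
#' Pearson chi-squared (no continuity correction) on the subtype x category
#' contingency table, with the expected counts reported and a flag when any
#' expected count drops below 5.
#'
#' @param assignment Named factor of subtype labels, named by patient or
#'   sample matching `clinical`'s `patient_id`.
#' @param clinical Data.frame of per-patient covariates including
#'   `patient_id`.
#' @param variable Column of `clinical` to test.
#' @return List with `statistic`, `df`, `p`, `observed`, `expected` and
#'   `low_expected` (logical).
#' @export
chi_square_clinical <- function(assignment, clinical, variable) {
  if (!variable %in% colnames(clinical))
    stop("unknown clinical variable: ", variable)
  idx <- match(names(assignment), clinical$patient_id)
  if (anyNA(idx))
    stop("patient absent from clinical table: ",
         names(assignment)[which(is.na(idx))[1L]])
  tab <- table(subtype = factor(assignment),
               category = factor(clinical[[variable]][idx]))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 5)
  if (low) warning("expected count below 5; chi-squared approximation is weak")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, observed = tab, expected = ct$expected,
       low_expected = low)
}

#' Summarize significant node contrasts into a progression table
#'
#' Condenses per-subtype contrast results into the compact progression
#' layout: one row per contrast and direction, one column per subtype, each
#' cell listing the nodes whose activity changed significantly in that
#' direction.
#'
#' @param results Data.frame with columns `subtype`, `node`, `contrast`,
#'   `estimate`, `p` (e.g. [tissue_contrast_table()] results stacked over
#'   subtypes with a `subtype` column added).
#' @param alpha Significance level on the unadjusted p-values.
#' @param adjust Optional multiple-testing method (e.g. `"BH"`) applied
#'   within each subtype across nodes and contrasts; `"none"` (default)
#'   mirrors the plain p < 0.05 rule.
#' @return Data.frame with columns `contrast`, `direction` and one column per
#'   subtype; empty cells are `""`.
#' @export
summarize_differential_nodes <- function(results, alpha = 0.05,
                                         adjust = "none") {
  stopifnot(all(c("subtype", "node", "contrast", "estimate", "p") %in%
                  colnames(results)))
  if (adjust != "none") {
    results$p <- stats::ave(results$p, results$subtype,
                            FUN = function(p) stats::p.adjust(p, adjust))
  }
  sig <- results[results$p < alpha, , drop = FALSE]
  contrasts <- unique(results$contrast)
  subtypes <- sort(unique(results$subtype))
  rows <- list()
  for (ct in contrasts) {
    for (dir in c("down", "up")) {
      row <- list(contrast = ct,
                  direction = if (dir == "up") "\u2191" else "\u2193")
      for (st in subtypes) {
        hit <- sig$node[sig$contrast == ct & sig$subtype == st &
                          (sig$estimate >= 0) == (dir == "up")]
        row[[st]] <- paste(hit, collapse = ", ")
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
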