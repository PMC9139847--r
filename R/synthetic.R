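#' Default functional block names for simulated cohorts
#'
#' Ten biological-process blocks spanning the functions typically organizing
#' a tumor proteome: adhesion, complement activation, mitochondria and
#' metabolism, translation, nucleoplasm, splicing, pancreatic secretion,
#' extracellular matrix, cytoskeleton and antigen presentation.
#'
#' @return Character vector of length 10.
#' @export
default_block_names <- function() {
  c("adhesion", "complement_activation", "mitochondria_metabolism",
    "translation", "nucleoplasm", "splicing", "pancreatic_secretion",
    "ECM", "cytoskeleton", "antigen_presentation")
}

#' Default subtype shift map
#'
#' Which blocks are up-shifted in each latent tumor subtype: T1 (adhesion
#' subtype) raises adhesion and complement activation, T2 (metabolic subtype)
#' raises mitochondria/metabolism and translation, T3 (nucleoplasm subtype)
#' raises nucleoplasm and splicing.
#'
#' @return Named list of character vectors of block names.
#' @export
default_subtype_shift_map <- function() {
  list(T1 = c("adhesion", "complement_activation"),
       T2 = c("mitochondria_metabolism", "translation"),
       T3 = c("nucleoplasm", "splicing"))
}

#' Default tissue progression shift map
#'
#' Additive log2 shifts per (block, tissue), relative to non-tumor tissue.
#' The pattern plants clear carcinogenesis effects (NT to T, P to T) and
#' progression effects (T to LN) in both directions: secretory and
#' immune/adhesion blocks rise in the tumor and fall again in the lymph node,
#' nucleoplasm rises monotonically, ECM falls monotonically, and
#' mitochondria/metabolism and translation peak in the preneoplastic lesion.
#'
#' @param shift Magnitude of a single step, log2 units.
#' @return Numeric matrix, blocks x tissues (NT, P, T, LN).
#' @export
default_tissue_shift_map <- function(shift = 0.8) {
  blocks <- default_block_names()
  m <- matrix(0, nrow = length(blocks), ncol = 4L,
              dimnames = list(blocks, c("NT", "P", "T", "LN")))
  m["pancreatic_secretion", ] <- c(0, 0, shift, 0)
  m["nucleoplasm", ] <- c(0, 0, shift, 2 * shift)
  m["ECM", ] <- c(0, 0, -shift, -2 * shift)
  m["mitochondria_metabolism", ] <- c(0, shift, 0, 0)
  m["translation", ] <- c(0, shift, 0, shift)
  m["complement_activation", ] <- c(0, 0, shift, 0)
  m["adhesion", ] <- c(0, 0, shift, 0)
  m
}

#' Simulation configuration
#'
#' Parameters of the synthetic multi-tissue tumor cohort. Defaults mirror the
#' cohort structure the analysis is designed for: 52 patients each
#' contributing a primary tumor plus non-tumor tissue, PanIN and lymph-node
#' samples with availability probabilities 47/52, 43/52 and 31/52; 2311
#' proteins grouped into 10 correlated functional blocks (sizes log-uniform
#' between 50 and 500); a tree-structured Gaussian within each block with
#' adjacent-protein correlation 0.6; three latent tumor subtypes shifting
#' subtype-specific blocks; tissue-progression shifts per block; a patient
#' random intercept; and intensity-dependent (left-censored) missingness.
#'
#' @param n_patients Number of patients.
#' @param n_proteins Number of proteins.
#' @param n_blocks Number of functional blocks.
#' @param rho Correlation between tree-adjacent proteins within a block.
#' @param tissue_prob Availability probability of NT, P and LN samples per
#'   patient (the tumor sample is always present).
#' @param n_subtypes Number of latent tumor subtypes.
#' @param subtype_shift Log2 up-shift applied to a subtype's blocks.
#' @param subtype_shift_map Named list (subtype -> block names) of up-shifted
#'   blocks; see [default_subtype_shift_map()].
#' @param tissue_shift_map Blocks x tissues shift matrix; see
#'   [default_tissue_shift_map()].
#' @param patient_sd Sd of the patient random intercept (log2 units).
#' @param residual_sd Sd of the within-block correlated noise (log2 units).
#' @param baseline_mean,baseline_sd Mean and sd of per-protein baseline
#'   abundance (log2 units).
#' @param missing_rate Target overall fraction of missing cells (MNAR).
#' @param missing_steepness Steepness of the logistic missingness curve per
#'   log2 unit of intensity.
#' @param block_size_range Range for log-uniform block sizes.
#' @param n_decoy_terms Number of random decoy gene sets added to the
#'   annotation so overrepresentation has competition.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 52L, n_proteins = 2311L,
                              n_blocks = 10L, rho = 0.6,
                              tissue_prob = c(NT = 47 / 52, P = 43 / 52,
                                              LN = 31 / 52),
                              n_subtypes = 3L, subtype_shift = 1.0,
                              subtype_shift_map = default_subtype_shift_map(),
                              tissue_shift_map = default_tissue_shift_map(),
                              patient_sd = 0.3, residual_sd = 0.5,
                              baseline_mean = 22, baseline_sd = 1.5,
                              missing_rate = 0.1, missing_steepness = 1.5,
                              block_size_range = c(50L, 500L),
                              n_decoy_terms = 10L, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, all(tissue_prob >= 0), all(tissue_prob <= 1),
            missing_rate >= 0, missing_rate < 1, residual_sd > 0,
            n_blocks >= 1L, n_proteins >= n_blocks)
  cfg <- list(n_patients = as.integer(n_patients),
              n_proteins = as.integer(n_proteins),
              n_blocks = as.integer(n_blocks), rho = rho,
              tissue_prob = tissue_prob, n_subtypes = as.integer(n_subtypes),
              subtype_shift = subtype_shift,
              subtype_shift_map = subtype_shift_map,
              tissue_shift_map = tissue_shift_map,
              patient_sd = patient_sd, residual_sd = residual_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              missing_rate = missing_rate,
              missing_steepness = missing_steepness,
              block_size_range = block_size_range,
              n_decoy_terms = as.integer(n_decoy_terms),
              seed = as.integer(seed))
  blocks <- .block_names(cfg)
  if (missing(subtype_shift_map)) {
    cfg$subtype_shift_map <- lapply(cfg$subtype_shift_map, intersect, blocks)
  }
  if (missing(tissue_shift_map)) {
    keep <- intersect(rownames(cfg$tissue_shift_map), blocks)
    cfg$tissue_shift_map <- cfg$tissue_shift_map[keep, , drop = FALSE]
  }
  bad <- setdiff(unlist(cfg$subtype_shift_map, use.names = FALSE), blocks)
  if (length(bad) > 0L)
    stop("subtype shift map references unknown block: ", bad[1L])
  bad <- setdiff(rownames(cfg$tissue_shift_map), blocks)
  if (length(bad) > 0L)
    stop("tissue shift map references unknown block: ", bad[1L])
  structure(cfg, class = "simulation_config")
}

.block_names <- function(cfg) {
  base <- default_block_names()
  n <- cfg$n_blocks
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("block%02d", seq_len(n - length(base)) + length(base)))
}

# log-uniform block sizes scaled to total n_proteins
.block_sizes <- function(cfg) {
  lo <- log(cfg$block_size_range[1L])
  hi <- log(cfg$block_size_range[2L])
  raw <- exp(stats::runif(cfg$n_blocks, lo, hi))
  sizes <- pmax(2L, as.integer(round(raw / sum(raw) * cfg$n_proteins)))
  # fix rounding drift on the largest block
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] +
    (cfg$n_proteins - sum(sizes))
  sizes
}

# random tree over m vertices: vertex i >= 2 attaches to a uniform earlier one
.random_tree <- function(m) {
  if (m < 2L) return(integer(0))
  vapply(seq_len(m - 1L) + 1L, function(i) sample.int(i - 1L, 1L), integer(1L))
}

# latent tree-Gaussian: unit marginals, correlation rho between tree
# neighbours; rows in tree order, one column per sample
.tree_gaussian <- function(parent, n_samples, rho) {
  m <- length(parent) + 1L
  z <- matrix(0, nrow = m, ncol = n_samples)
  z[1L, ] <- stats::rnorm(n_samples)
  if (m >= 2L) {
    innov <- sqrt(1 - rho^2)
    for (i in 2:m) {
      z[i, ] <- rho * z[parent[i - 1L], ] + innov * stats::rnorm(n_samples)
    }
  }
  z
}

#' Generate a synthetic multi-tissue tumor cohort
#'
#' Draws a complete cohort under the generative model of
#' [simulation_config()]: per-protein baselines, block-wise tree-Gaussian
#' correlated noise, latent patient subtypes shifting subtype-specific blocks
#' in all of the patient's samples, tissue-progression shifts, patient random
#' intercepts, and finally intensity-dependent missingness whose logistic
#' midpoint is calibrated so the expected missing fraction equals
#' `missing_rate`. Deterministic for a fixed seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` (log2 expression, `NA` = missing), `manifest`
#'   (sample_id, patient_id, tissue, subtype), `annotation` (one term per
#'   block plus decoys) and `truth` (block membership, tree edges, per-patient
#'   subtype, shift maps, missingness midpoint).
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  blocks <- .block_names(cfg)
  sizes <- .block_sizes(cfg)
  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  block_of <- rep(blocks, sizes)
  names(block_of) <- protein_ids

  patients <- sprintf("PT%02d", seq_len(cfg$n_patients))
  subtypes <- paste0("T", seq_len(cfg$n_subtypes))
  subtype_of <- sample(rep_len(subtypes, cfg$n_patients))
  names(subtype_of) <- patients

  # per-patient tissue availability (the tumor sample is always present)
  present <- cbind(NT = stats::runif(cfg$n_patients) < cfg$tissue_prob["NT"],
                   P = stats::runif(cfg$n_patients) < cfg$tissue_prob["P"],
                   T = TRUE,
                   LN = stats::runif(cfg$n_patients) < cfg$tissue_prob["LN"])
  manifest <- do.call(rbind, lapply(seq_len(cfg$n_patients), function(i) {
    tt <- colnames(present)[present[i, ]]
    data.frame(sample_id = paste0(patients[i], "_", tt),
               patient_id = patients[i],
               tissue = tt,
               subtype = unname(subtype_of[patients[i]]),
               stringsAsFactors = FALSE)
  }))
  manifest$tissue <- factor(manifest$tissue, levels = .tissue_levels)
  n_samples <- nrow(manifest)

  baseline <- stats::rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
  patient_eff <- stats::rnorm(cfg$n_patients, 0, cfg$patient_sd)
  names(patient_eff) <- patients

  x <- matrix(0, nrow = cfg$n_proteins, ncol = n_samples,
              dimnames = list(protein_ids, manifest$sample_id))
  tree_edges <- list()
  row0 <- 0L
  for (b in seq_along(blocks)) {
    m <- sizes[b]
    parent <- .random_tree(m)
    z <- .tree_gaussian(parent, n_samples, cfg$rho)
    rows <- row0 + seq_len(m)
    x[rows, ] <- cfg$residual_sd * z
    if (m >= 2L) {
      tree_edges[[blocks[b]]] <- data.frame(
        from = protein_ids[rows][parent],
        to = protein_ids[rows][seq_len(m - 1L) + 1L],
        stringsAsFactors = FALSE)
    }
    row0 <- row0 + m
  }
  x <- x + baseline

  # subtype shifts apply to every sample of the patient: the molecular
  # identity of the tumor is detectable from the earliest lesion onwards
  shift_profile <- matrix(0, nrow = cfg$n_proteins, ncol = cfg$n_subtypes,
                          dimnames = list(protein_ids, subtypes))
  for (st in names(cfg$subtype_shift_map)) {
    hit <- block_of %in% cfg$subtype_shift_map[[st]]
    shift_profile[hit, st] <- cfg$subtype_shift
  }
  x <- x + shift_profile[, manifest$subtype, drop = FALSE]

  tshift <- matrix(0, nrow = cfg$n_proteins, ncol = 4L,
                   dimnames = list(protein_ids, c("NT", "P", "T", "LN")))
  for (b in rownames(cfg$tissue_shift_map)) {
    tshift[block_of == b, ] <- rep(cfg$tissue_shift_map[b, ],
                                   each = sum(block_of == b))
  }
  x <- x + tshift[, as.character(manifest$tissue), drop = FALSE]
  x <- sweep(x, 2L, patient_eff[manifest$patient_id], `+`)

  m0 <- NA_real_
  if (cfg$missing_rate > 0) {
    s <- cfg$missing_steepness
    f <- function(m0) mean(stats::plogis((m0 - x) * s)) - cfg$missing_rate
    m0 <- stats::uniroot(f, range(x) + c(-20, 20))$root
    pmiss <- stats::plogis((m0 - x) * s)
    x[stats::runif(length(x)) < pmiss] <- NA_real_
  }

  annot <- .cohort_annotation(cfg, blocks, protein_ids, block_of)
  truth <- list(block = block_of, sizes = stats::setNames(sizes, blocks),
                subtype = subtype_of,
                sample_subtype = stats::setNames(manifest$subtype,
                                                 manifest$sample_id),
                tree_edges = tree_edges,
                subtype_shift_map = cfg$subtype_shift_map,
                subtype_shift = cfg$subtype_shift,
                tissue_shift_map = cfg$tissue_shift_map,
                missing_midpoint = m0)
  list(matrix = x, manifest = manifest, annotation = annot, truth = truth)
}

.cohort_annotation <- function(cfg, blocks, protein_ids, block_of) {
  term_id <- sprintf("SYN:%02d", seq_along(blocks))
  members <- lapply(blocks, function(b) protein_ids[block_of == b])
  term_name <- blocks
  if (cfg$n_decoy_terms > 0L) {
    for (i in seq_len(cfg$n_decoy_terms)) {
      sz <- sample(20:80, 1L)
      term_id <- c(term_id, sprintf("SYN:D%02d", i))
      term_name <- c(term_name, sprintf("decoy_%02d", i))
      members <- c(members, list(sample(protein_ids, sz)))
    }
  }
  annotation_set(term_id, term_name, members)
}

#' Default clinical covariate marginals
#'
#' Categorical marginals typical of a resected PDAC surgical cohort: 60/40
#' male/female, mostly head-of-pancreas primaries, moderate differentiation
#' dominating, R1 resections and pN1 nodal status in the majority.
#'
#' @return Named list of named probability vectors.
#' @export
default_clinical_marginals <- function() {
  list(
    gender = c(Male = 0.60, Female = 0.40),
    diabetes = c(Yes = 0.18, No = 0.80, Unknown = 0.02),
    tobacco = c(Yes = 0.44, No = 0.42, Unknown = 0.14),
    location = c(Head = 0.76, Body = 0.06, Tail = 0.10, Various = 0.08),
    grade = c(Well = 0.12, Moderate = 0.66, Poor = 0.16, Unknown = 0.06),
    resection = c(R0 = 0.32, R1 = 0.68),
    pT = c(pT1 = 0.06, pT2 = 0.22, pT3 = 0.68, pT4 = 0.04),
    pN = c(N0 = 0.22, N1 = 0.78),
    stage = c(Ia = 0.04, Ib = 0.04, IIa = 0.08, IIb = 0.76, III = 0.06,
              IV = 0.02)
  )
}

#' Generate a synthetic clinical table
#'
#' Independent categorical draws per variable from the supplied marginals.
#'
#' @param n Number of patients.
#' @param marginals Named list of named probability vectors; each must sum
#'   to 1.
#' @param seed Integer seed.
#' @param patient_ids Optional patient identifiers (default PT01..).
#' @return Data.frame with `patient_id` and one factor column per variable.
#' @export
generate_clinical_table <- function(n = 50L,
                                    marginals = default_clinical_marginals(),
                                    seed = 1L, patient_ids = NULL) {
  stopifnot(all(abs(vapply(marginals, sum, numeric(1L)) - 1) < 1e-8))
  set.seed(seed)
  if (is.null(patient_ids)) patient_ids <- sprintf("PT%02d", seq_len(n))
  out <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
  for (v in names(marginals)) {
    pr <- marginals[[v]]
    out[[v]] <- factor(sample(names(pr), n, replace = TRUE, prob = pr),
                       levels = names(pr))
  }
  out
}

#' Generate a synthetic external cohort for centroid classification
#'
#' Samples are drawn from the trained subtype centroids plus independent
#' normal noise, a random fraction of signature features is dropped
#' (emulating signatures that only partially map onto an external platform),
#' and feature identifiers are translated through a synthetic protein-to-gene
#' map so classification must go through an id map, as with external
#' transcriptomic cohorts.
#'
#' @param model A `subtype_model` from [build_centroids()].
#' @param n Number of external samples.
#' @param feature_dropout Probability that a signature feature is absent from
#'   the external cohort.
#' @param noise_sd Sd of the independent noise added to the centroid
#'   template.
#' @param seed Integer seed.
#' @return List with `matrix` (gene-id rows x samples), `labels` (true
#'   subtype factor named by sample) and `idmap` (data.frame `protein`,
#'   `gene`).
#' @export
generate_external_cohort <- function(model, n = 300L, feature_dropout = 0.09,
                                     noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(model, "subtype_model"),
            feature_dropout >= 0, feature_dropout < 1)
  set.seed(seed)
  subtypes <- colnames(model$centroids)
  labels <- sample(subtypes, n, replace = TRUE)
  x <- model$centroids[, labels, drop = FALSE] +
    matrix(stats::rnorm(length(model$signature) * n, 0, noise_sd),
           nrow = length(model$signature))
  sample_ids <- sprintf("EXT%03d", seq_len(n))
  colnames(x) <- sample_ids
  keep <- stats::runif(nrow(x)) >= feature_dropout
  x <- x[keep, , drop = FALSE]
  idmap <- data.frame(protein = model$signature,
                      gene = sub("^P", "G", model$signature),
                      stringsAsFactors = FALSE)
  rownames(x) <- idmap$gene[match(rownames(x), idmap$protein)]
  list(matrix = x, labels = factor(stats::setNames(labels, sample_ids),
                                   levels = subtypes),
       idmap = idmap)
}
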