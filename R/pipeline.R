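#' Pipeline configuration
#'
#' Collects every stage's parameters, the input paths and the global seed.
#' Unknown arguments are rejected by the function signature. Either all three
#' input paths (`matrix_path`, `manifest_path`, `gmt_path`) are given, or
#' `simulate` supplies a [simulation_config()] and the cohort is generated.
#'
#' @param out_dir Output directory for the run.
#' @param matrix_path,manifest_path,gmt_path Input files (TSV expression
#'   matrix, CSV/TSV manifest, GMT gene sets), or `NULL` to simulate.
#' @param simulate Optional [simulation_config()] used when no input paths
#'   are given.
#' @param seed Global seed; per-stage seeds are derived from it so stages are
#'   individually reproducible.
#' @param already_log2 Whether the input matrix is already log2-scaled.
#' @param min_valid_fraction,impute_width,impute_downshift Preprocessing
#'   parameters, see [preprocess_config()].
#' @param penalty Forest penalty, `"bic"` or `"aic"`.
#' @param max_size,min_size Branch size bounds, see [split_into_branches()].
#' @param q_threshold,min_overlap Node annotation thresholds, see
#'   [assign_main_function()].
#' @param k Number of tumor subtypes for clustering.
#' @param n_perm,target_fdr SAM parameters, see [sam_multiclass()].
#' @param min_fraction Minimum signature fraction for centroid
#'   classification.
#' @param contrasts Tissue contrasts, see [default_contrasts()].
#' @param per_subtype_networks Re-learn a forest and functional nodes on each
#'   subtype's samples (as opposed to reusing the cohort-wide nodes) before
#'   the per-subtype tissue contrasts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            matrix_path = NULL, manifest_path = NULL,
                            gmt_path = NULL, simulate = NULL, seed = 1L,
                            already_log2 = TRUE,
                            min_valid_fraction = 0.75, impute_width = 0.3,
                            impute_downshift = 1.8,
                            penalty = "bic", max_size = 300L, min_size = 10L,
                            q_threshold = 0.05, min_overlap = 3L,
                            k = 3L, n_perm = 1000L, target_fdr = 0.05,
                            min_fraction = 0.8,
                            contrasts = default_contrasts(),
                            per_subtype_networks = FALSE) {
  have_paths <- !is.null(matrix_path) && !is.null(manifest_path) &&
    !is.null(gmt_path)
  if (!have_paths && is.null(simulate))
    stop("either matrix_path/manifest_path/gmt_path or simulate must be given")
  structure(list(out_dir = out_dir, matrix_path = matrix_path,
                 manifest_path = manifest_path, gmt_path = gmt_path,
                 simulate = simulate, seed = as.integer(seed),
                 already_log2 = already_log2,
                 min_valid_fraction = min_valid_fraction,
                 impute_width = impute_width,
                 impute_downshift = impute_downshift, penalty = penalty,
                 max_size = as.integer(max_size),
                 min_size = as.integer(min_size),
                 q_threshold = q_threshold,
                 min_overlap = as.integer(min_overlap), k = as.integer(k),
                 n_perm = as.integer(n_perm), target_fdr = target_fdr,
                 min_fraction = min_fraction, contrasts = contrasts,
                 per_subtype_networks = per_subtype_networks),
            class = "pipeline_config")
}

.run_stage <- function(name, log, expr) {
  log(paste0("stage ", name, ": start"))
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  log(paste0("stage ", name, ": done"))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order io, preprocess, network, annotation,
#' subtyping, group_stats on the configured inputs (or a simulated cohort),
#' writing every stage product, a log and a config snapshot into `out_dir`.
#' A rerun with the same configuration is bit-identical. A stage failure
#' halts the run with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (they are always written to the
#'   log file).
#' @return Invisibly, a list with the in-memory stage products and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  if (file.exists(log_path)) unlink(log_path)
  log <- function(msg) {
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  set.seed(config$seed)
  stage_seed <- sample.int(2^30, 4L)

  snap <- config
  snap$contrasts <- lapply(snap$contrasts, as.character)
  if (!is.null(snap$simulate)) snap$simulate <- unclass(snap$simulate)
  jsonlite::write_json(unclass(snap),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor", force = TRUE)

  inputs <- .run_stage("io_formats", log, {
    if (!is.null(config$matrix_path)) {
      x <- read_expression_tsv(config$matrix_path)
      manifest <- read_manifest(config$manifest_path)
      annot <- read_gmt(config$gmt_path)
      match_manifest(x, manifest)
      list(matrix = x, manifest = manifest, annotation = annot, truth = NULL)
    } else {
      sim <- unclass(config$simulate)
      sim$seed <- stage_seed[1L]
      generate_cohort(do.call(simulation_config, sim))
    }
  })
  log(paste0("  samples: ", ncol(inputs$matrix), ", tissues: ",
             paste(tissue_counts(inputs$manifest), collapse = "/")))

  pp_cfg <- preprocess_config(config$min_valid_fraction, config$impute_width,
                              config$impute_downshift, seed = stage_seed[2L])
  imputed <- .run_stage("preprocess", log, {
    preprocess_matrix(inputs$matrix, inputs$manifest, pp_cfg,
                      already_log2 = config$already_log2)
  })
  log(paste0("  proteins: ", attr(imputed, "n_proteins_before"), " -> ",
             attr(imputed, "n_proteins_after")))
  write_expression_tsv(imputed, file.path(config$out_dir, "imputed.tsv"))

  forest <- .run_stage("network", log, {
    forest_pgm(imputed, penalty = config$penalty)
  })
  write_forest_edges(forest, file.path(config$out_dir, "edges.tsv"))
  branches <- split_into_branches(forest, config$max_size, config$min_size)
  log(paste0("  forest: ", nrow(forest$edges), " edges, ",
             length(branches), " branches"))

  nodes <- .run_stage("annotation", log, {
    functional_nodes(branches, inputs$annotation, rownames(imputed),
                     config$q_threshold, config$min_overlap)
  })
  activities <- node_activity_matrix(imputed, nodes)
  write_node_report(nodes, file.path(config$out_dir, "nodes.tsv"))
  write_results(data.frame(node = rownames(activities), activities,
                           check.names = FALSE),
                file.path(config$out_dir, "node_activities.tsv"))
  log(paste0("  functional nodes: ", length(nodes), " (",
             sum(vapply(nodes, function(nd) is.na(nd$term_id), logical(1L))),
             " without overrepresented function)"))

  subtyping <- .run_stage("subtyping", log, {
    mf <- match_manifest(imputed, inputs$manifest)
    tumor <- mf$sample_id[mf$tissue == "T"]
    assignment <- hcl_subtypes(imputed[, tumor, drop = FALSE], k = config$k)
    sam <- sam_multiclass(imputed[, tumor, drop = FALSE], assignment,
                          n_perm = config$n_perm, seed = stage_seed[3L],
                          target_fdr = config$target_fdr)
    model <- if (length(sam$selected) >= 2L) {
      build_centroids(imputed[, tumor, drop = FALSE], assignment,
                      sam$selected)
    } else NULL
    list(assignment = assignment, sam = sam, model = model)
  })
  write_results(data.frame(sample_id = names(subtyping$assignment),
                           subtype = as.character(subtyping$assignment)),
                file.path(config$out_dir, "subtypes.tsv"))
  write_results(data.frame(protein = subtyping$sam$selected),
                file.path(config$out_dir, "signature.tsv"))
  log(paste0("  subtype sizes: ",
             paste(table(subtyping$assignment), collapse = "/"),
             "; signature: ", length(subtyping$sam$selected), " proteins"))

  stats_out <- .run_stage("group_stats", log, {
    mf <- match_manifest(imputed, inputs$manifest)
    patient_subtype <- stats::setNames(
      as.character(subtyping$assignment),
      mf$patient_id[match(names(subtyping$assignment), mf$sample_id)])
    rows <- list()
    for (st in levels(subtyping$assignment)) {
      pts <- names(patient_subtype)[patient_subtype == st]
      sel <- mf$sample_id[mf$patient_id %in% pts]
      sub_mat <- imputed[, sel, drop = FALSE]
      sub_nodes <- nodes
      sub_acts <- activities[, sel, drop = FALSE]
      if (config$per_subtype_networks) {
        sub_forest <- forest_pgm(sub_mat, penalty = config$penalty)
        sub_branches <- split_into_branches(sub_forest, config$max_size,
                                            config$min_size)
        sub_nodes <- functional_nodes(sub_branches, inputs$annotation,
                                      rownames(sub_mat), config$q_threshold,
                                      config$min_overlap)
        sub_acts <- node_activity_matrix(sub_mat, sub_nodes)
      }
      res <- withCallingHandlers(
        tissue_contrast_table(sub_acts, inputs$manifest, config$contrasts),
        warning = function(w) {
          log(paste0("  [", st, "] ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!is.null(res) && nrow(res) > 0L)
        rows[[st]] <- cbind(subtype = st, res, stringsAsFactors = FALSE)
    }
    contrast_results <- do.call(rbind, rows)
    rownames(contrast_results) <- NULL
    mw <- mann_whitney_nodes(activities[, names(subtyping$assignment),
                                        drop = FALSE],
                             subtyping$assignment)
    list(contrasts = contrast_results, mann_whitney = mw,
         progression = summarize_differential_nodes(contrast_results))
  })
  write_results(stats_out$contrasts,
                file.path(config$out_dir, "contrasts.tsv"))
  write_results(stats_out$mann_whitney,
                file.path(config$out_dir, "subtype_mann_whitney.tsv"))
  write_results(stats_out$progression,
                file.path(config$out_dir, "progression_table.tsv"))
  log("pipeline complete")

  invisible(list(out_dir = config$out_dir, inputs = inputs,
                 imputed = imputed, forest = forest, branches = branches,
                 nodes = nodes, activities = activities,
                 subtyping = subtyping, stats = stats_out))
}
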