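#' Read a protein expression matrix from tab-separated text
#'
#' Expects proteins in rows and samples in columns: the first column holds
#' protein identifiers and the header row holds sample identifiers. Empty
#' cells and the tokens in `missing_tokens` are read as missing (`NA`).
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file stores samples in rows and the matrix
#'   is transposed after reading so that proteins end up in rows.
#' @param missing_tokens Character tokens treated as missing values.
#' @return A numeric matrix with protein ids as rownames, sample ids as
#'   colnames and `NA` marking missing intensities.
#' @export
read_expression_tsv <- function(path, transpose = FALSE,
                                missing_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "",
                            blank.lines.skip = FALSE)
  if (length(nf) < 2L) stop("expression file needs a header and at least one row: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    stop("ragged row in ", path, ": row ", bad[1L], " has ", nf[bad[1L]],
         " fields, expected ", nf[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, na.strings = missing_tokens,
                          colClasses = "character", comment.char = "")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate protein id: ", dup[1L])
  sample_ids <- colnames(df)[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) stop("duplicate sample id: ", dup[1L])
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)), USE.NAMES = FALSE)
  )
  vals <- matrix(vals, nrow = nrow(df), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  non_numeric <- is.na(vals) & !is.na(as.matrix(df[-1L]))
  if (any(non_numeric)) {
    ij <- which(non_numeric, arr.ind = TRUE)[1L, ]
    stop("non-numeric value at protein ", ids[ij[1L]], ", sample ",
         sample_ids[ij[2L]])
  }
  if (transpose) vals <- t(vals)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' Missing values are written as empty cells, the convention
#' [read_expression_tsv()] reads back.
#'
#' @param x Numeric matrix, proteins in rows.
#' @param path Output path.
#' @param id_column Header for the protein id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "protein") {
  validate_expression_matrix(x)
  # %.17g keeps doubles bit-exact across a write/read round trip
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  chr[is.na(x)] <- ""
  lines <- c(paste(c(id_column, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs protein rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup) > 0L) stop("duplicate protein id: ", dup[1L])
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup) > 0L) stop("duplicate sample id: ", dup[1L])
  invisible(x)
}

#' Construct a gene-set annotation
#'
#' @param term_id Character vector of unique term identifiers.
#' @param term_name Character vector of human-readable term names.
#' @param members Named (by `term_id`) or unnamed list of character vectors of
#'   protein ids; members are deduplicated and must be non-empty.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(term_id = character(), term_name = character(),
                           members = list()) {
  term_id <- as.character(term_id)
  term_name <- as.character(term_name)
  if (length(term_id) != length(term_name) || length(term_id) != length(members))
    stop("term_id, term_name and members must have equal length")
  dup <- term_id[duplicated(term_id)]
  if (length(dup) > 0L) stop("duplicate term id: ", dup[1L])
  members <- lapply(members, function(m) unique(as.character(m)))
  empty <- lengths(members) == 0L
  if (any(empty)) stop("empty member set for term: ", term_id[which(empty)[1L]])
  names(members) <- term_id
  structure(list(term_id = term_id, term_name = term_name, members = members),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set with", length(x$term_id), "terms covering",
      length(unique(unlist(x$members, use.names = FALSE))), "proteins\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$term_id)

#' Read gene sets in GMT format
#'
#' One term per line: `term_id TAB description TAB member TAB member ...`.
#' Members are deduplicated; an empty file yields an empty annotation.
#'
#' @param path Path to a GMT file.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(annotation_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", which(keep)[short[1L]],
         " has fewer than 3 fields in ", path)
  }
  annotation_set(
    term_id = vapply(fields, `[[`, character(1L), 1L),
    term_name = vapply(fields, `[[`, character(1L), 2L),
    members = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write gene sets in GMT format
#'
#' @param annot An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annot, path) {
  stopifnot(inherits(annot, "annotation_set"))
  lines <- vapply(seq_along(annot$term_id), function(i) {
    paste(c(annot$term_id[i], annot$term_name[i], annot$members[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# canonical tissue codes and the tokens accepted for each on read
.tissue_levels <- c("NT", "P", "T", "LN")
.tissue_tokens <- c(
  NT = "NT", "non-tumor" = "NT", "nontumor" = "NT", normal = "NT",
  P = "P", PanIN = "P", panin = "P", preneoplastic = "P",
  T = "T", tumor = "T", Tumor = "T",
  LN = "LN", "lymph-node" = "LN", "lymph_node" = "LN", "lymph node" = "LN",
  lymphnode = "LN"
)

#' Read a sample manifest
#'
#' Comma- or tab-separated text with required columns `sample_id`,
#' `patient_id` and `tissue`, and an optional `subtype` column. Tissue tokens
#' are mapped onto the four canonical codes NT (non-tumor), P (PanIN
#' preneoplastic lesion), T (primary tumor) and LN (lymph node metastasis).
#'
#' @param path Path to the manifest; `.csv` files are read comma-separated,
#'   anything else tab-separated (override with `sep`).
#' @param sep Field separator, or `NULL` to infer from the extension.
#' @return A data.frame with columns `sample_id`, `patient_id`, `tissue`
#'   (factor with levels NT, P, T, LN) and, when present, `subtype`.
#' @export
read_manifest <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  required <- c("sample_id", "patient_id", "tissue")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) stop("duplicate sample id in manifest: ", dup[1L])
  tok <- as.character(df$tissue)
  mapped <- .tissue_tokens[tok]
  unknown <- which(is.na(mapped))
  if (length(unknown) > 0L)
    stop("unknown tissue token in manifest: '", tok[unknown[1L]], "'")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    patient_id = as.character(df$patient_id),
    tissue = factor(unname(mapped), levels = .tissue_levels),
    stringsAsFactors = FALSE
  )
  if ("subtype" %in% colnames(df)) out$subtype <- as.character(df$subtype)
  out
}

#' Write a sample manifest as CSV
#'
#' @param manifest Manifest data.frame as returned by [read_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that every matrix sample is described in the manifest
#'
#' @param x Expression matrix (samples in columns).
#' @param manifest Manifest data.frame.
#' @return The manifest rows for the matrix samples, in matrix column order.
#' @export
match_manifest <- function(x, manifest) {
  validate_expression_matrix(x)
  absent <- setdiff(colnames(x), manifest$sample_id)
  if (length(absent) > 0L)
    stop("sample present in matrix but absent from manifest: ", absent[1L])
  manifest[match(colnames(x), manifest$sample_id), , drop = FALSE]
}

#' Tally samples per tissue type
#'
#' @param manifest Manifest data.frame.
#' @return Named integer vector over the tissue levels NT, P, T, LN.
#' @export
tissue_counts <- function(manifest) {
  table(factor(manifest$tissue, levels = .tissue_levels))
}

#' Write a result table as tab-separated text
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param row_names Whether to keep row names as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, row_names = FALSE) {
  if (row_names) {
    df <- data.frame(id = rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
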