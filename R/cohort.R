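#' Expression cohort container
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' its per-sample annotation. This is the unit the integration, resampling
#' and consensus stages operate on.
#'
#' @param exprs Numeric matrix of log2 expression, genes x samples, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param samples Data frame with columns `sample_id`, `batch`, `group`;
#'   `group` must take values in `"control"` / `"case"`. Row order must
#'   match the columns of `exprs` (it is reordered by `sample_id` match).
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `exprs` (matrix) and `samples` (tibble).
#' @export
expression_cohort <- function(exprs, samples) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    abort("`exprs` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs))) {
    abort("`exprs` must have unique rownames (gene ids).")
  }
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs))) {
    abort("`exprs` must have unique colnames (sample ids).")
  }
  if (anyNA(exprs)) abort("`exprs` must not contain missing values.")
  samples <- as_tibble(samples)
  req <- c("sample_id", "batch", "group")
  if (!all(req %in% names(samples))) {
    abort("`samples` must have columns sample_id, batch, group.")
  }
  if (!setequal(samples$sample_id, colnames(exprs))) {
    abort("`samples$sample_id` must match colnames(exprs).")
  }
  samples <- samples[match(colnames(exprs), samples$sample_id), , drop = FALSE]
  bad <- setdiff(unique(samples$group), c("control", "case"))
  if (length(bad) > 0) {
    abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  samples$batch <- as.character(samples$batch)
  structure(list(exprs = exprs, samples = samples),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", nrow(x$exprs), " genes x ", ncol(x$exprs),
      " samples; ", length(unique(x$samples$batch)), " batch(es)\n", sep = "")
  tab <- table(x$samples$batch, x$samples$group)
  print(tab)
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$exprs)

#' Merge cohorts on their shared genes
#'
#' Intersects the gene sets of two or more cohorts, sorts the shared genes,
#' and concatenates samples. Each sample's batch label is overwritten with
#' the name (or index) of the cohort it came from, so downstream batch
#' correction treats study of origin as the batch.
#'
#' @param cohorts A list of `expression_cohort` objects, optionally named;
#'   names become batch labels (otherwise `"batch1"`, `"batch2"`, ...).
#'
#' @return A merged `expression_cohort` whose gene set is the sorted
#'   intersection of the inputs' gene sets.
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2) {
    abort("`cohorts` must be a list of at least two expression_cohort objects.")
  }
  ok <- vapply(cohorts, inherits, logical(1), "expression_cohort")
  if (!all(ok)) abort("All elements of `cohorts` must be expression_cohort objects.")
  nms <- names(cohorts) %||% paste0("batch", seq_along(cohorts))
  nms[nms == ""] <- paste0("batch", which(nms == ""))

  shared <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$exprs)))
  if (length(shared) == 0) abort("No genes shared across all cohorts; cannot merge.")
  shared <- sort(shared)

  all_ids <- unlist(lapply(cohorts, function(co) co$samples$sample_id))
  if (anyDuplicated(all_ids)) {
    abort("Duplicate sample ids across cohorts; disambiguate before merging.")
  }

  mats <- lapply(cohorts, function(co) co$exprs[shared, , drop = FALSE])
  merged <- do.call(cbind, mats)
  ann <- purrr::map2_dfr(cohorts, nms, function(co, nm) {
    out <- co$samples
    out$batch <- nm
    out
  })
  expression_cohort(merged, ann)
}

#' Read an expression matrix and annotation into a cohort
#'
#' The matrix TSV has genes as rows; its first column holds the gene id and
#' the remaining columns are samples. The annotation TSV has columns
#' `sample_id`, `batch` (or `study_id`) and `group`.
#'
#' @param matrix_path Path to the expression TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return An `expression_cohort`.
#' @export
read_cohort <- function(matrix_path, annotation_path) {
  df <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  if ("study_id" %in% names(ann) && !"batch" %in% names(ann)) {
    ann$batch <- ann$study_id
  }
  ann <- ann[, c("sample_id", "batch", "group")]
  expression_cohort(mat, ann)
}

#' Write a cohort to matrix + annotation TSVs
#'
#' @param cohort An `expression_cohort`.
#' @param matrix_path,annotation_path Output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, matrix_path, annotation_path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  df <- dplyr::bind_cols(tibble(gene = rownames(cohort$exprs)),
                         as_tibble(cohort$exprs))
  readr::write_tsv(df, matrix_path)
  ann <- cohort$samples
  out <- tibble(sample_id = ann$sample_id, study_id = ann$batch,
                group = ann$group)
  readr::write_tsv(out, annotation_path)
  invisible(cohort)
}
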