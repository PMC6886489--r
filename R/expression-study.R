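#' Expression study container
#'
#' An `expression_study` holds one experiment's genes x replicates expression
#' matrix together with its sample and gene annotation. Values are raw counts
#' for sequencing platforms (`platform = "counts"`) or processed intensities
#' for array platforms (`platform = "intensity"`); after FPKM normalization
#' the platform is relabelled `"fpkm"` and treated as intensity-like.
#'
#' @param experiment_id single experiment label.
#' @param platform one of `"counts"`, `"intensity"`, `"fpkm"`.
#' @param matrix numeric genes x replicates matrix, non-negative, with gene
#'   IDs as rownames and sample IDs as colnames.
#' @param samples data.frame with one row per replicate: `sample_id`,
#'   `condition` (`"control"`/`"stress"`), `stress_type` (`"cold"`,
#'   `"water_deficiency"`, `"none"`), `tissue`, `time_point`.
#' @param genes data.frame with one row per gene: `gene_id`, `enzyme_class`,
#'   `clade`, `housekeeping` (logical; exactly one `TRUE`), `length` (bp).
#'
#' @return a validated `expression_study` object.
#' @export
expression_study <- function(experiment_id, platform, matrix, samples, genes) {
  obj <- structure(
    list(experiment_id = as.character(experiment_id),
         platform = platform,
         matrix = matrix,
         samples = samples,
         genes = genes),
    class = "expression_study")
  validate_expression_study(obj)
}

CONDITIONS   <- c("control", "stress")
STRESS_TYPES <- c("cold", "water_deficiency", "none")

#' Validate an expression study
#'
#' Checks the structural invariants: matching IDs between matrix and
#' annotation, >= 2 control replicates, exactly one flagged housekeeping
#' gene, non-negative values, known condition labels, and positive gene
#' lengths when the platform is `"counts"`.
#'
#' @param x an `expression_study`.
#' @return `x`, invisibly unchanged, or an error naming the offending entity.
#' @export
validate_expression_study <- function(x) {
  st <- "expression_study"
  if (!x$platform %in% c("counts", "intensity", "fpkm"))
    stop_ctx(st, "unknown platform '%s' in experiment %s", x$platform, x$experiment_id)
  m <- x$matrix
  if (!is.matrix(m) || !is.numeric(m))
    stop_ctx(st, "expression matrix must be a numeric matrix (experiment %s)", x$experiment_id)
  if (anyNA(m) || any(!is.finite(m)))
    stop_ctx(st, "non-numeric or missing cells in matrix of experiment %s", x$experiment_id)
  if (any(m < 0))
    stop_ctx(st, "negative expression values in experiment %s", x$experiment_id)
  if (anyDuplicated(rownames(m)))
    stop_ctx(st, "duplicated gene IDs in experiment %s: %s", x$experiment_id,
             paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!identical(sort(rownames(m)), sort(as.character(x$genes$gene_id))))
    stop_ctx(st, "gene IDs of matrix and gene sheet differ in experiment %s", x$experiment_id)
  missing_cols <- setdiff(colnames(m), x$samples$sample_id)
  if (length(missing_cols))
    stop_ctx(st, "matrix column(s) absent from sample sheet in experiment %s: %s",
             x$experiment_id, paste(missing_cols, collapse = ", "))
  extra <- setdiff(x$samples$sample_id, colnames(m))
  if (length(extra))
    stop_ctx(st, "sample sheet row(s) without matrix column in experiment %s: %s",
             x$experiment_id, paste(extra, collapse = ", "))
  bad_cond <- setdiff(unique(x$samples$condition), CONDITIONS)
  if (length(bad_cond))
    stop_ctx(st, "unknown condition label(s) in experiment %s: %s",
             x$experiment_id, paste(bad_cond, collapse = ", "))
  bad_st <- setdiff(unique(x$samples$stress_type), STRESS_TYPES)
  if (length(bad_st))
    stop_ctx(st, "unknown stress_type label(s) in experiment %s: %s",
             x$experiment_id, paste(bad_st, collapse = ", "))
  if (sum(x$samples$condition == "control") < 2)
    stop_ctx(st, "experiment %s has fewer than 2 control replicates", x$experiment_id)
  hk <- sum(x$genes$housekeeping)
  if (hk != 1L)
    stop_ctx(st, "experiment %s must flag exactly one housekeeping gene (found %d)",
             x$experiment_id, hk)
  if (x$platform == "counts" && any(!is.finite(x$genes$length) | x$genes$length <= 0))
    stop_ctx(st, "count platform requires positive gene lengths (experiment %s)",
             x$experiment_id)
  # align annotation order with the matrix
  x$genes   <- x$genes[match(rownames(m), x$genes$gene_id), , drop = FALSE]
  x$samples <- x$samples[match(colnames(m), x$samples$sample_id), , drop = FALSE]
  rownames(x$genes) <- rownames(x$samples) <- NULL
  x
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s [%s]: %d genes x %d replicates (%d control, %d stress)\n",
              x$experiment_id, x$platform, nrow(x$matrix), ncol(x$matrix),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "stress")))
  invisible(x)
}

#' Read one expression study from delimited files
#'
#' Reads a genes x replicates TSV matrix (first column = gene ID), the shared
#' sample sheet and the shared gene sheet, subsets both sheets to this
#' experiment, and returns a validated [expression_study()].
#'
#' @param matrix_path TSV matrix; first column gene IDs, remaining columns
#'   one per sample ID.
#' @param samples_path sample sheet TSV with columns `sample_id`,
#'   `experiment_id`, `platform`, `condition`, `stress_type`, `tissue`,
#'   `time_point`.
#' @param genes_path gene sheet TSV with columns `gene_id`, `enzyme_class`,
#'   `clade`, `housekeeping`, `length`.
#' @param experiment_id experiment to extract from the sample sheet; by
#'   default inferred from the sample IDs found in the matrix header.
#' @return an `expression_study`.
#' @export
read_expression_study <- function(matrix_path, samples_path, genes_path,
                                  experiment_id = NULL) {
  st <- "read_expression_study"
  for (p in c(matrix_path, samples_path, genes_path))
    if (!file.exists(p)) stop_ctx(st, "file not found: %s", p)
  tab <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_ctx(st, "matrix %s has no sample columns", matrix_path)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_ctx(st, "non-numeric cells in %s", matrix_path)
  rownames(m) <- ids
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)
  genes$housekeeping <- as.logical(genes$housekeeping)
  keep <- samples$sample_id %in% colnames(m)
  if (!any(keep))
    stop_ctx(st, "no sample sheet rows match the columns of %s", matrix_path)
  samples <- samples[keep, , drop = FALSE]
  if (is.null(experiment_id)) {
    experiment_id <- unique(samples$experiment_id)
    if (length(experiment_id) != 1L)
      stop_ctx(st, "matrix columns map to several experiments: %s",
               paste(experiment_id, collapse = ", "))
  } else {
    samples <- samples[samples$experiment_id == experiment_id, , drop = FALSE]
  }
  platform <- unique(samples$platform)
  if (length(platform) != 1L)
    stop_ctx(st, "experiment %s has inconsistent platform labels", experiment_id)
  genes <- genes[genes$gene_id %in% rownames(m), , drop = FALSE]
  expression_study(experiment_id, platform, m,
                   samples[, c("sample_id", "condition", "stress_type",
                               "tissue", "time_point")],
                   genes)
}

#' Read a directory of expression studies written by [write_study_bundle()]
#'
#' @param dir directory containing `matrix_<experiment>.tsv` files plus
#'   `samples.tsv` and `genes.tsv`.
#' @return list of `expression_study`, named by experiment ID.
#' @export
read_study_bundle <- function(dir) {
  samples_path <- file.path(dir, "samples.tsv")
  genes_path <- file.path(dir, "genes.tsv")
  mats <- sort(list.files(dir, pattern = "^matrix_.*\\.tsv$", full.names = TRUE))
  if (!length(mats)) stop_ctx("read_study_bundle", "no matrix_*.tsv files in %s", dir)
  studies <- lapply(mats, read_expression_study,
                    samples_path = samples_path, genes_path = genes_path)
  names(studies) <- vapply(studies, `[[`, "", "experiment_id")
  studies
}

#' Write a list of expression studies as a TSV bundle
#'
#' One `matrix_<experiment>.tsv` per study plus shared `samples.tsv` and
#' `genes.tsv`; the ground truth of a synthetic bundle (if supplied) is
#' stored as `ground_truth.json`.
#'
#' @param studies list of `expression_study`.
#' @param dir output directory (created if absent).
#' @param truth optional ground-truth list from [generate_meta_experiments()].
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(studies, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samp <- do.call(rbind, lapply(studies, function(s)
    cbind(s$samples, experiment_id = s$experiment_id, platform = s$platform)))
  write_tsv(samp, file.path(dir, "samples.tsv"))
  write_tsv(studies[[1L]]$genes, file.path(dir, "genes.tsv"))
  for (s in studies) {
    tab <- data.frame(gene_id = rownames(s$matrix), s$matrix, check.names = FALSE)
    write_tsv(tab, file.path(dir, sprintf("matrix_%s.tsv", s$experiment_id)))
  }
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
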