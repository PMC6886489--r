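#' FPKM normalization of a count study
#'
#' Converts raw counts to fragments per kilobase of transcript per million
#' mapped reads: `fpkm(g, s) = 1e9 * c(g, s) / (length(g) * total(s))`,
#' where `total(s)` is the library size (column sum) of replicate `s`.
#' Intensity studies are returned unchanged; count studies are relabelled
#' `platform = "fpkm"` so the downstream cascade treats them as
#' intensity-like.
#'
#' @param study an [expression_study()].
#' @return the study with FPKM values, or unchanged if not a count platform.
#' @export
fpkm_normalize <- function(study) {
  if (study$platform != "counts") return(study)
  totals <- colSums(study$matrix)
  if (any(totals == 0))
    stop_ctx("fpkm_normalize", "zero total counts in replicate(s): %s",
             paste(colnames(study$matrix)[totals == 0], collapse = ", "))
  len <- study$genes$length
  study$matrix <- 1e9 * sweep(study$matrix / len, 2L, totals, "/")
  study$platform <- "fpkm"
  study
}

#' Housekeeping-gene normalization
#'
#' Divides every gene's value in each replicate by that replicate's value of
#' the flagged housekeeping gene, removing per-sample multiplicative scale
#' (labelling, loading, depth residuals). The housekeeping row becomes
#' identically 1, so the operation is idempotent.
#'
#' @param study an [expression_study()].
#' @return the study with housekeeping-relative values.
#' @export
housekeeping_normalize <- function(study) {
  hk <- which(study$genes$housekeeping)
  hk_vals <- study$matrix[hk, ]
  if (any(hk_vals == 0))
    stop_ctx("housekeeping_normalize",
             "housekeeping gene '%s' is zero in replicate(s): %s",
             study$genes$gene_id[hk],
             paste(colnames(study$matrix)[hk_vals == 0], collapse = ", "))
  study$matrix <- sweep(study$matrix, 2L, hk_vals, "/")
  study
}

#' Control-relative normalization across experiments
#'
#' For each gene within each experiment, divides all replicate values by the
#' mean of that gene's control replicates, so a value expresses fold change
#' relative to the experiment's own control level and control replicates
#' average exactly 1. This removes per-experiment batch scale and makes
#' replicates comparable across experiments and platforms. Genes whose
#' control mean is zero in an experiment are excluded from that experiment's
#' panel (recorded in `excluded`); the housekeeping gene (identically 1
#' after [housekeeping_normalize()]) is dropped from the panel.
#'
#' @param studies list of [expression_study()], already housekeeping-
#'   normalized (and FPKM-normalized where counts).
#' @return a `normalized_panel`: list with `values` (genes x replicates
#'   fold-change matrix, `NA` where a gene was excluded in an experiment),
#'   `provenance` (per-replicate `sample_id`, `experiment_id`, `condition`,
#'   `stress_type`), `control_means` (per gene x experiment), `excluded`
#'   (gene/experiment pairs with zero control mean), and `genes` metadata.
#' @export
control_relative_normalize <- function(studies) {
  st <- "control_relative_normalize"
  if (!length(studies)) stop_ctx(st, "empty study list")
  gene_ids <- rownames(studies[[1L]]$matrix)
  hk_id <- studies[[1L]]$genes$gene_id[studies[[1L]]$genes$housekeeping]
  panel_genes <- setdiff(gene_ids, hk_id)
  blocks <- list(); prov <- list(); cmeans <- list(); excl <- list()
  for (s in studies) {
    if (!identical(sort(rownames(s$matrix)), sort(gene_ids)))
      stop_ctx(st, "experiment %s does not share the common gene panel", s$experiment_id)
    m <- s$matrix[panel_genes, , drop = FALSE]
    ctrl <- s$samples$condition == "control"
    cm <- rowMeans(m[, ctrl, drop = FALSE])
    zero <- cm == 0
    vals <- sweep(m, 1L, cm, "/")
    vals[zero, ] <- NA_real_
    colnames(vals) <- paste(s$experiment_id, colnames(m), sep = ":")
    blocks[[s$experiment_id]] <- vals
    prov[[s$experiment_id]] <- data.frame(
      replicate = colnames(vals),
      sample_id = s$samples$sample_id,
      experiment_id = s$experiment_id,
      condition = s$samples$condition,
      stress_type = s$samples$stress_type,
      stringsAsFactors = FALSE)
    cmeans[[s$experiment_id]] <- data.frame(
      gene_id = panel_genes, experiment_id = s$experiment_id,
      control_mean = unname(cm), stringsAsFactors = FALSE)
    if (any(zero))
      excl[[s$experiment_id]] <- data.frame(
        gene_id = panel_genes[zero], experiment_id = s$experiment_id,
        stringsAsFactors = FALSE)
  }
  structure(
    list(values = do.call(cbind, blocks),
         provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))),
         control_means = do.call(rbind, c(cmeans, list(make.row.names = FALSE))),
         excluded = if (length(excl))
           do.call(rbind, c(excl, list(make.row.names = FALSE)))
         else data.frame(gene_id = character(), experiment_id = character()),
         genes = studies[[1L]]$genes[match(panel_genes, studies[[1L]]$genes$gene_id), ,
                                     drop = FALSE],
         housekeeping_id = hk_id),
    class = "normalized_panel")
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf("<normalized_panel> %d genes x %d replicates from %d experiment(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$provenance$experiment_id))))
  if (nrow(x$excluded))
    cat(sprintf("  %d gene x experiment cell(s) excluded (zero control mean)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' Run the full normalization cascade on a list of studies
#'
#' FPKM (count platforms only) then housekeeping then control-relative.
#'
#' @param studies list of [expression_study()].
#' @return a `normalized_panel`.
#' @export
normalize_cascade <- function(studies) {
  control_relative_normalize(
    lapply(studies, function(s) housekeeping_normalize(fpkm_normalize(s))))
}

#' Subset a normalized panel to a set of experiments and/or replicates
#'
#' @param panel a `normalized_panel`.
#' @param experiments experiment IDs to keep (default: all).
#' @param replicates replicate IDs to keep (default: all).
#' @return the subsetted `normalized_panel`.
#' @export
subset_panel <- function(panel, experiments = NULL, replicates = NULL) {
  keep <- rep(TRUE, ncol(panel$values))
  if (!is.null(experiments))
    keep <- keep & panel$provenance$experiment_id %in% experiments
  if (!is.null(replicates))
    keep <- keep & panel$provenance$replicate %in% replicates
  panel$values <- panel$values[, keep, drop = FALSE]
  panel$provenance <- panel$provenance[keep, , drop = FALSE]
  rownames(panel$provenance) <- NULL
  panel
}

#' Write a normalized panel as TSV files
#'
#' @param panel a `normalized_panel`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(gene_id = rownames(panel$values), panel$values,
                       check.names = FALSE),
            file.path(dir, "normalized_panel.tsv"))
  write_tsv(panel$provenance, file.path(dir, "provenance.tsv"))
  write_tsv(panel$control_means, file.path(dir, "control_means.tsv"))
  invisible(dir)
}
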