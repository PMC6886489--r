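#' Per-gene stress-vs-control comparison
#'
#' Welch (default) or Student two-sample t-test per gene on log2 fold
#' values. The reported `mean_fold` is the geometric-mean ratio
#' stress/control, matched to the log2 test scale; the arithmetic ratio of
#' group means is reported alongside (`fold_arith`) since control values
#' average 1 by construction of the panel.
#'
#' Degenerate inputs are not imputed: if both groups have zero variance and
#' equal means the gene gets p = 1; zero variance with unequal means gets
#' the machine-minimum p and a `zero_variance` flag. Genes with fewer than
#' two usable replicates in either group get a missing p and an
#' `insufficient_replicates` flag.
#'
#' @param panel a `normalized_panel`.
#' @param stress_replicates,control_replicates replicate IDs (columns of
#'   `panel$values`) for the two groups.
#' @param test `"welch"` or `"student"`.
#' @param eps pseudo-fold added before log2.
#' @return data.frame per gene: `gene`, `n_stress`, `n_control`,
#'   `mean_fold` (geometric), `fold_arith`, `raw_p`, `flag`.
#' @export
compare_groups <- function(panel, stress_replicates, control_replicates,
                           test = c("welch", "student"), eps = 1e-6) {
  test <- match.arg(test)
  st <- "compare_groups"
  bad <- setdiff(c(stress_replicates, control_replicates),
                 colnames(panel$values))
  if (length(bad))
    stop_ctx(st, "unknown replicate(s): %s", paste(bad, collapse = ", "))
  xs_all <- panel$values[, stress_replicates, drop = FALSE]
  xc_all <- panel$values[, control_replicates, drop = FALSE]
  rows <- lapply(seq_len(nrow(panel$values)), function(g) {
    xs <- xs_all[g, ]; xs <- xs[!is.na(xs)]
    xc <- xc_all[g, ]; xc <- xc[!is.na(xc)]
    out <- data.frame(gene = rownames(panel$values)[g],
                      n_stress = length(xs), n_control = length(xc),
                      mean_fold = NA_real_, fold_arith = NA_real_,
                      raw_p = NA_real_, flag = "", stringsAsFactors = FALSE)
    if (length(xs) < 2L || length(xc) < 2L) {
      out$flag <- "insufficient_replicates"
      return(out)
    }
    ls <- log2(xs + eps); lc <- log2(xc + eps)
    out$mean_fold <- 2^(mean(ls) - mean(lc))
    out$fold_arith <- mean(xs) / mean(xc)
    if (var(ls) == 0 && var(lc) == 0) {
      if (mean(ls) == mean(lc)) {
        out$raw_p <- 1
      } else {
        out$raw_p <- .Machine$double.xmin
        out$flag <- "zero_variance"
      }
    } else {
      out$raw_p <- t.test(ls, lc, var.equal = (test == "student"))$p.value
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate correction valid under arbitrary dependence:
#' sorted p-values are scaled by `m * c(m) / i` with the harmonic factor
#' `c(m) = sum(1/j, j = 1..m)`, followed by the cumulative-minimum step and
#' capping at 1. Missing entries are passed through as missing and do not
#' count towards `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values in the input order.
#' @export
by_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_ctx("by_adjust", "p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BY")
  adj
}

#' Direction calls from adjusted p-values
#'
#' `up` when the adjusted p is below `alpha` and the fold exceeds 1, `down`
#' when below 1, `ns` otherwise. A significant gene whose fold is exactly 1
#' is degenerate: called `ns` and flagged.
#'
#' @param stats data.frame from [compare_groups()].
#' @param alpha significance level (applied to BY-adjusted p by default).
#' @param adjust apply [by_adjust()] within this comparison; with `FALSE`
#'   the raw p is thresholded (the summary table's raw-p convention).
#' @param comparison_id,mode identifiers stored in the output rows
#'   (`mode`: `"cluster"` for cluster-vs-control, `"experiment"` for a
#'   within-experiment contrast).
#' @return a `differential_table` data.frame adding `comparison_id`, `mode`,
#'   `adj_p`, `call`.
#' @export
call_regulation <- function(stats, alpha = 0.05, adjust = TRUE,
                            comparison_id = "comparison", mode = "cluster") {
  stats$adj_p <- if (adjust) by_adjust(stats$raw_p) else stats$raw_p
  sig <- !is.na(stats$adj_p) & stats$adj_p < alpha
  stats$call <- ifelse(sig & stats$mean_fold > 1, "up",
                       ifelse(sig & stats$mean_fold < 1, "down", "ns"))
  deg <- sig & stats$mean_fold == 1
  if (any(deg)) {
    stats$call[deg] <- "ns"
    stats$flag[deg] <- paste0(stats$flag[deg], ";degenerate_fold_1")
  }
  stats$comparison_id <- comparison_id
  stats$mode <- mode
  class(stats) <- c("differential_table", "data.frame")
  stats
}

#' Cluster-vs-control differential tables
#'
#' For every non-control cluster of the model, compares the cluster's
#' stress replicates against all control-condition replicates of the panel,
#' with per-comparison BY adjustment.
#'
#' @param panel a `normalized_panel`.
#' @param model a labelled `cluster_model` (see [label_clusters()]).
#' @param alpha,test,adjust see [call_regulation()] and [compare_groups()].
#' @return named list of `differential_table`s, one per stress cluster
#'   (names like `"CR1"`, `"WDR2"`).
#' @export
cluster_differential <- function(panel, model, alpha = 0.05,
                                 test = c("welch", "student"), adjust = TRUE) {
  if (is.null(model$cluster_types)) model <- label_clusters(model, panel)
  prov <- panel$provenance[match(names(model$assignment), panel$provenance$replicate), ]
  controls <- prov$replicate[prov$condition == "control"]
  stress_k <- which(model$cluster_types != "control")
  counters <- c(CR = 0L, WDR = 0L, mixed = 0L)
  tables <- list()
  for (k in stress_k) {
    members <- names(model$assignment)[model$assignment == k]
    stress <- intersect(members, prov$replicate[prov$condition == "stress"])
    if (length(stress) < 2L) next
    type <- model$cluster_types[k]
    counters[type] <- counters[type] + 1L
    id <- sprintf("%s%d", type, counters[type])
    tables[[id]] <- call_regulation(
      compare_groups(panel, stress, controls, test = test),
      alpha = alpha, adjust = adjust, comparison_id = id, mode = "cluster")
    attr(tables[[id]], "cluster_index") <- k
  }
  tables
}

#' Within-experiment stress-vs-control differential tables
#'
#' The small-sample mode used when experiments are too few to filter and
#' cluster: each experiment's stress replicates are compared against its
#' own controls.
#'
#' @inheritParams cluster_differential
#' @return named list of `differential_table`s, one per experiment.
#' @export
experiment_differential <- function(panel, alpha = 0.05,
                                    test = c("welch", "student"),
                                    adjust = TRUE) {
  tables <- list()
  for (e in unique(panel$provenance$experiment_id)) {
    prov <- panel$provenance[panel$provenance$experiment_id == e, ]
    stress <- prov$replicate[prov$condition == "stress"]
    controls <- prov$replicate[prov$condition == "control"]
    if (length(stress) < 2L || length(controls) < 2L) next
    tables[[e]] <- call_regulation(
      compare_groups(panel, stress, controls, test = test),
      alpha = alpha, adjust = adjust, comparison_id = e, mode = "experiment")
  }
  tables
}

#' Fold-change summary matrix across comparisons
#'
#' Genes (annotated by enzyme class and clade) x comparisons matrix of mean
#' fold changes with significance marks; cells for genes absent from a
#' comparison are marked no-data.
#'
#' @param tables named list of `differential_table`s.
#' @param gene_metadata data.frame with `gene_id`, `enzyme_class`, `clade`.
#' @return a `panel_summary`: list with `fold` (genes x comparisons),
#'   `call` (character matrix: `up`/`down`/`ns`/`no_data`), `table`
#'   (annotated wide data.frame, fold values of significant cells suffixed
#'   `*`).
#' @export
summarize_panel <- function(tables, gene_metadata) {
  if (!length(tables)) stop_ctx("summarize_panel", "no differential tables")
  genes <- unique(unlist(lapply(tables, `[[`, "gene")))
  fold <- matrix(NA_real_, length(genes), length(tables),
                 dimnames = list(genes, names(tables)))
  call <- matrix("no_data", length(genes), length(tables),
                 dimnames = list(genes, names(tables)))
  for (j in seq_along(tables)) {
    t_ <- tables[[j]]
    i <- match(t_$gene, genes)
    fold[i, j] <- t_$mean_fold
    call[i, j] <- ifelse(is.na(t_$raw_p), "no_data", t_$call)
  }
  meta <- gene_metadata[match(genes, gene_metadata$gene_id),
                        c("gene_id", "enzyme_class", "clade")]
  ord <- order(meta$enzyme_class, meta$clade, meta$gene_id)
  fold <- fold[ord, , drop = FALSE]
  call <- call[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  marked <- matrix(sprintf("%.3f%s", fold,
                           ifelse(call %in% c("up", "down"), "*", "")),
                   nrow(fold), ncol(fold), dimnames = dimnames(fold))
  marked[call == "no_data"] <- "no_data"
  table <- data.frame(meta, marked, check.names = FALSE, row.names = NULL)
  structure(list(fold = fold, call = call, table = table),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %d genes x %d comparisons (%d significant cells)\n",
              nrow(x$fold), ncol(x$fold), sum(x$call %in% c("up", "down"))))
  invisible(x)
}

#' Write differential results and the summary as TSV/HTML
#'
#' @param tables named list of `differential_table`s.
#' @param summary a `panel_summary`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_differential <- function(tables, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, c(lapply(tables, as.data.frame),
                           list(make.row.names = FALSE)))
  write_tsv(long, file.path(dir, "differential.tsv"))
  write_tsv(summary$table, file.path(dir, "summary.tsv"))
  writeLines(summary_html(summary), file.path(dir, "summary.html"))
  invisible(dir)
}

# minimal heat-styled HTML rendering of a panel_summary
summary_html <- function(s) {
  shade <- function(fold, call) {
    if (call == "no_data" || is.na(fold)) return("background:#f5e96e")
    if (fold > 1) sprintf("background:rgba(220,60,50,%.2f)", min(1, log2(fold) / 3))
    else sprintf("background:rgba(70,170,90,%.2f)", min(1, -log2(fold) / 3))
  }
  hdr <- paste0("<tr><th>gene</th><th>class</th><th>clade</th>",
                paste0("<th>", colnames(s$fold), "</th>", collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(s$fold)), function(i) {
    cells <- vapply(seq_len(ncol(s$fold)), function(j) {
      txt <- if (s$call[i, j] == "no_data") "&mdash;"
             else sprintf("%.2f%s", s$fold[i, j],
                          if (s$call[i, j] %in% c("up", "down")) "<b>*</b>" else "")
      sprintf("<td style='%s'>%s</td>", shade(s$fold[i, j], s$call[i, j]), txt)
    }, character(1))
    meta <- s$table[i, c("gene_id", "enzyme_class", "clade")]
    paste0("<tr><td>", paste(unlist(meta), collapse = "</td><td>"), "</td>",
           paste(cells, collapse = ""), "</tr>")
  }, character(1))
  c("<html><body><table border='1' style='border-collapse:collapse'>",
    hdr, rows, "</table>",
    "<p>* significant; shaded red = up, green = down, yellow = no data</p>",
    "</body></html>")
}
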