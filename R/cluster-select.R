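#' Replicate matrix in the configured distance space
#'
#' Genes with any missing value across the panel's replicates are dropped
#' (recorded in the `"dropped_genes"` attribute).
#'
#' @param panel a `normalized_panel`.
#' @param space `"log2"` (Euclidean distance on `log2(fold + eps)`) or
#'   `"linear"`.
#' @param eps pseudo-fold guarding `log2(0)`.
#' @return replicates x genes numeric matrix.
#' @keywords internal
panel_profile_matrix <- function(panel, space = c("log2", "linear"),
                                 eps = 1e-6) {
  space <- match.arg(space)
  keep <- !apply(panel$values, 1L, anyNA)
  x <- t(panel$values[keep, , drop = FALSE])
  if (space == "log2") x <- log2(x + eps)
  attr(x, "dropped_genes") <- rownames(panel$values)[!keep]
  x
}

#' Ward clustering of replicate fold-change profiles
#'
#' Agglomerative Ward linkage (`stats::hclust`, `"ward.D2"`) on Euclidean
#' distances between replicate profiles, cut into a flat partition. With
#' `n_clusters = "auto"` the cut maximizing the mean silhouette width over
#' `k_range` is chosen.
#'
#' @param panel a `normalized_panel`.
#' @param n_clusters integer number of clusters, or `"auto"`.
#' @param space,eps see [panel_profile_matrix()].
#' @param k_range candidate `k` values for `"auto"`.
#' @return a `cluster_model`: `assignment` (named cluster index per
#'   replicate), `n_clusters`, `linkage` (merge matrix + heights), the
#'   `hclust` object, `distance_space`, `dropped_genes`, and (after
#'   [label_clusters()]) `cluster_types`.
#' @export
cluster_replicates <- function(panel, n_clusters = "auto",
                               space = c("log2", "linear"), eps = 1e-6,
                               k_range = 2:15) {
  st <- "cluster_replicates"
  space <- match.arg(space)
  x <- panel_profile_matrix(panel, space, eps)
  n <- nrow(x)
  d <- dist(x)
  if (max(d) == 0)
    stop_ctx(st, "all replicate profiles are identical; clustering is degenerate")
  hc <- hclust(d, method = "ward.D2")
  if (identical(n_clusters, "auto")) {
    ks <- k_range[k_range >= 2 & k_range <= n - 1L]
    if (!length(ks)) stop_ctx(st, "no feasible k in k_range for %d replicates", n)
    sil <- vapply(ks, function(k) {
      mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"])
    }, numeric(1))
    n_clusters <- ks[which.max(sil)]
  }
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > n)
    stop_ctx(st, "n_clusters (%d) exceeds the number of replicates (%d)",
             n_clusters, n)
  if (n_clusters < 2L) stop_ctx(st, "n_clusters must be >= 2")
  structure(
    list(assignment = cutree(hc, n_clusters),
         n_clusters = n_clusters,
         linkage = list(merge = hc$merge, height = hc$height,
                        labels = hc$labels),
         hclust = hc,
         distance_space = space,
         dropped_genes = attr(x, "dropped_genes"),
         cluster_types = NULL),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d replicates in %d clusters (Ward, %s space)\n",
              length(x$assignment), x$n_clusters, x$distance_space))
  if (!is.null(x$cluster_types))
    cat("  types:", paste(sprintf("%d=%s", seq_along(x$cluster_types),
                                  x$cluster_types), collapse = " "), "\n")
  invisible(x)
}

#' Principal component view of replicate profiles
#'
#' PCA of the replicates x genes fold-change matrix (centered; unscaled by
#' default since all genes share the dimensionless fold-change unit).
#'
#' @param panel a `normalized_panel`.
#' @param space,eps see [panel_profile_matrix()].
#' @param scale. scale genes to unit variance before the decomposition.
#' @return list with `scores` (replicates x components), explained-variance
#'   fractions `explained_variance` (sums to 1), `rotation`, and `center`.
#' @export
pca_profiles <- function(panel, space = c("log2", "linear"), eps = 1e-6,
                         scale. = FALSE) {
  x <- panel_profile_matrix(panel, match.arg(space), eps)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_ctx("pca_profiles", "need >= 2 replicates and >= 2 genes")
  if (all(apply(x, 2L, var) == 0))
    stop_ctx("pca_profiles", "constant profile matrix; PCA undefined")
  p <- prcomp(x, center = TRUE, scale. = scale.)
  list(scores = p$x,
       explained_variance = p$sdev^2 / sum(p$sdev^2),
       rotation = p$rotation,
       center = p$center)
}

#' Label clusters as control / cold-response / water-deficiency-response
#'
#' A cluster is `control` when it contains at least one control replicate
#' and controls form its strict majority; otherwise it takes the majority
#' stress type of its stress replicates (`CR` for cold,
#' `WDR` for water deficiency); an exact stress-type tie gives `mixed`.
#'
#' @param model a `cluster_model`.
#' @param panel the `normalized_panel` the model was fitted on.
#' @return the model with `cluster_types` filled in.
#' @export
label_clusters <- function(model, panel) {
  prov <- panel$provenance[match(names(model$assignment), panel$provenance$replicate), ]
  types <- vapply(seq_len(model$n_clusters), function(k) {
    in_k <- model$assignment == k
    n_ctrl <- sum(prov$condition[in_k] == "control")
    if (n_ctrl >= 1L && n_ctrl > sum(in_k) / 2) return("control")
    stypes <- prov$stress_type[in_k & prov$condition == "stress"]
    n_cold <- sum(stypes == "cold"); n_wd <- sum(stypes == "water_deficiency")
    if (n_cold > n_wd) "CR" else if (n_wd > n_cold) "WDR" else "mixed"
  }, character(1))
  model$cluster_types <- types
  model
}

#' Experiment quality filter from the replicate clustering
#'
#' For every experiment, computes the fraction of its stress replicates that
#' fall into control-containing clusters; the experiment is excluded when
#' that fraction is strictly greater than 0.5 (its stress response is
#' implicit or noisy). Experiments with no stress replicates are retained
#' and flagged (fraction undefined).
#'
#' @param model a `cluster_model` fitted on the full candidate panel
#'   (controls included).
#' @param panel the `normalized_panel` the model was fitted on.
#' @param control_cluster_rule `"any"`: a control-containing cluster is any
#'   cluster with >= 1 control replicate (the literal reading);
#'   `"majority"`: only clusters whose [label_clusters()] type is
#'   `control`.
#' @return list with `retained` (experiment IDs) and `report` (per
#'   experiment: `n_stress`, `n_in_control_clusters`, `fraction`,
#'   `excluded`, `flag`).
#' @export
filter_experiments <- function(model, panel,
                               control_cluster_rule = c("any", "majority")) {
  rule <- match.arg(control_cluster_rule)
  prov <- panel$provenance[match(names(model$assignment), panel$provenance$replicate), ]
  ctrl_clusters <- if (rule == "any") {
    unique(model$assignment[prov$condition == "control"])
  } else {
    m <- if (is.null(model$cluster_types)) label_clusters(model, panel) else model
    which(m$cluster_types == "control")
  }
  exps <- unique(prov$experiment_id)
  rows <- lapply(exps, function(e) {
    in_e <- prov$experiment_id == e & prov$condition == "stress"
    n_s <- sum(in_e)
    n_in <- sum(model$assignment[in_e] %in% ctrl_clusters)
    frac <- if (n_s > 0) n_in / n_s else NA_real_
    data.frame(experiment_id = e, n_stress = n_s, n_in_control_clusters = n_in,
               fraction = frac,
               excluded = isTRUE(frac > 0.5),
               flag = if (n_s == 0) "no_stress_replicates" else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(retained = report$experiment_id[!report$excluded], report = report)
}
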