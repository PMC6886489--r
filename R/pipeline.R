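utils::globalVariables(c("treatment", "ratio", "cultivar", "target", "cq"))

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 15,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, stage, config, seed) {
  jsonlite::write_json(
    list(stage = stage,
         package = "aosmeta",
         version = as.character(utils::packageVersion("aosmeta")),
         seed = seed,
         config_hash = config_hash(config),
         config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}

#' Simulate and write a multi-experiment bundle
#'
#' @param config a [meta_sim_config()].
#' @param out_dir output directory for the TSV bundle and ground truth.
#' @return the simulation result (list of studies + truth), invisibly.
#' @export
run_simulate <- function(config = meta_sim_config(), out_dir) {
  sim <- generate_meta_experiments(config)
  write_study_bundle(sim$studies, out_dir, truth = sim$truth)
  write_manifest(out_dir, "simulate", unclass(config), config$seed)
  invisible(sim)
}

#' Run the meta-analysis workflow end to end
#'
#' Normalization cascade, Ward clustering of the full candidate panel,
#' experiment quality filter, second-pass clustering of the retained panel,
#' cluster-vs-control differential calls with BY correction, and the
#' fold-change summary table. Each stage's tables are written under
#' `out_dir` when given, together with a run manifest (seed + config hash).
#'
#' @param studies list of [expression_study()], or a directory readable by
#'   [read_study_bundle()].
#' @param n_clusters clusters for both passes (integer or `"auto"`).
#' @param alpha significance level for the calls.
#' @param test `"welch"` or `"student"`.
#' @param adjust apply BY adjustment (raw-p mode when `FALSE`).
#' @param filter apply the experiment quality filter.
#' @param control_cluster_rule see [filter_experiments()].
#' @param space,eps distance space options, see [cluster_replicates()].
#' @param seed recorded in the manifest (the workflow itself is
#'   deterministic given its inputs).
#' @param out_dir optional output directory.
#' @return list with `panel`, `model` (first pass), `filter`, `panel2`,
#'   `model2` (second pass, retained experiments), `pca`, `tables`,
#'   `summary`, `retained`.
#' @export
run_meta <- function(studies, n_clusters = "auto", alpha = 0.05,
                     test = "welch", adjust = TRUE, filter = TRUE,
                     control_cluster_rule = "any",
                     space = "log2", eps = 1e-6,
                     seed = NA_integer_, out_dir = NULL) {
  if (is.character(studies) && length(studies) == 1L)
    studies <- read_study_bundle(studies)
  if (!length(studies)) stop_ctx("run_meta", "no input studies")
  config <- list(n_clusters = n_clusters, alpha = alpha, test = test,
                 adjust = adjust, filter = filter,
                 control_cluster_rule = control_cluster_rule,
                 space = space, eps = eps, seed = seed)
  panel <- normalize_cascade(studies)
  model <- label_clusters(
    cluster_replicates(panel, n_clusters, space = space, eps = eps), panel)
  flt <- if (filter) {
    filter_experiments(model, panel, control_cluster_rule)
  } else {
    list(retained = unique(panel$provenance$experiment_id),
         report = data.frame())
  }
  panel2 <- subset_panel(panel, experiments = flt$retained)
  model2 <- label_clusters(
    cluster_replicates(panel2, n_clusters, space = space, eps = eps), panel2)
  pca <- pca_profiles(panel2, space = space, eps = eps)
  tables <- cluster_differential(panel2, model2, alpha = alpha, test = test,
                                 adjust = adjust)
  summary <- if (length(tables)) summarize_panel(tables, panel2$genes) else NULL
  res <- list(panel = panel, model = model, filter = flt, panel2 = panel2,
              model2 = model2, pca = pca, tables = tables, summary = summary,
              retained = flt$retained)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(panel, out_dir)
    assignment <- data.frame(
      replicate = names(model2$assignment),
      cluster = unname(model2$assignment),
      cluster_type = model2$cluster_types[model2$assignment])
    assignment <- cbind(assignment,
      panel2$provenance[match(assignment$replicate, panel2$provenance$replicate),
                        c("experiment_id", "condition", "stress_type")])
    write_tsv(assignment, file.path(out_dir, "assignment.tsv"))
    write_tsv(data.frame(model2$linkage$merge, height = model2$linkage$height),
              file.path(out_dir, "linkage.tsv"))
    write_tsv(data.frame(replicate = rownames(pca$scores), pca$scores,
                         check.names = FALSE),
              file.path(out_dir, "pca_scores.tsv"))
    if (nrow(flt$report))
      write_tsv(flt$report, file.path(out_dir, "filter_report.tsv"))
    if (length(tables)) write_differential(tables, summary, out_dir)
    write_manifest(out_dir, "meta", config, seed)
  }
  invisible(res)
}

#' Run the qPCR quantification workflow end to end
#'
#' Per-well efficiency/Cq estimation (curve plates), efficiency-corrected
#' ratios, the delta-Cq table and, when the design has two crossed factors
#' with replication, the two-way ANOVA; tables are written under `out_dir`
#' when given.
#'
#' @param plate a `qpcr_plate`, or a TSV path readable by
#'   [read_qpcr_plate()].
#' @param efficiencies per-target efficiencies for Cq-only plates (must
#'   include `"REF"`).
#' @param control_treatment label of the control group.
#' @param seed recorded in the manifest.
#' @param out_dir optional output directory.
#' @return list with the fitted `plate`, `ratios`, `dcq`, and `anova`
#'   (`NULL` when the factorial design is incomplete).
#' @export
run_qpcr <- function(plate, efficiencies = NULL,
                     control_treatment = "control",
                     seed = NA_integer_, out_dir = NULL) {
  if (is.character(plate) && length(plate) == 1L)
    plate <- read_qpcr_plate(plate)
  config <- list(control_treatment = control_treatment, seed = seed,
                 efficiencies = as.list(efficiencies))
  plate <- fit_qpcr_plate(plate, efficiencies)
  ratios <- aggregate_ratios(plate, control_treatment = control_treatment)
  dcq <- delta_cq(plate)
  anova <- tryCatch(anova_dcq(dcq), error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(plate$fits, file.path(out_dir, "well_fits.tsv"))
    write_tsv(as.data.frame(ratios), file.path(out_dir, "ratios.tsv"))
    write_tsv(dcq, file.path(out_dir, "dcq.tsv"))
    if (!is.null(anova)) write_tsv(anova, file.path(out_dir, "anova.tsv"))
    grDevices::pdf(file.path(out_dir, "ratio_bars.pdf"), width = 7, height = 5)
    print(plot_ratio_bars(ratios))
    grDevices::dev.off()
    write_manifest(out_dir, "qpcr", config, seed)
  }
  invisible(list(plate = plate, ratios = ratios, dcq = dcq, anova = anova))
}
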