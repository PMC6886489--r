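#' Configuration for the multi-experiment expression simulator
#'
#' The defaults emulate the retained cross-experiment sample the pipeline is
#' designed for: 13 experiments on mixed platforms carrying 70 control and
#' 130 stress replicates of a 35-gene antioxidant panel, with strong planted
#' stress signatures, per-experiment batch scale, per-sample scale, and
#' log-normal replicate noise.
#'
#' @param n_experiments number of experiments.
#' @param n_genes panel size (including the housekeeping gene).
#' @param platform per-experiment platform, `"counts"` (sequencing) or
#'   `"intensity"` (array); recycled. Default alternates.
#' @param n_control_reps,n_stress_reps per-experiment replicate counts;
#'   recycled. Defaults distribute 70 control and 130 stress replicates
#'   across the experiments as evenly as possible.
#' @param stress_type per-experiment stress, `"cold"` or
#'   `"water_deficiency"`; default: first half cold, rest water deficiency.
#' @param baseline_log2_mean,baseline_log2_sd log2 baseline expression
#'   distribution across genes.
#' @param batch_scale_sd log2 sd of the per-experiment batch scale and of
#'   the per-sample scale/library-size factor.
#' @param replicate_noise_sd log2 sd of per-replicate biological noise.
#' @param signature_fold genes x 2 matrix (columns `cold`,
#'   `water_deficiency`) of true stress/control fold changes; 1 = null.
#'   Default plants blocks of strong up (6, 5) and down (0.15, 0.2) folds,
#'   distinct per stress type; the housekeeping gene is always 1.
#' @param signature_jitter_sd log2 sd of per-gene-per-experiment jitter
#'   around the planted fold.
#' @param count_dispersion negative-binomial dispersion for count platforms
#'   (0 = Poisson).
#' @param gene_lengths transcript lengths in bp (recycled).
#' @param library_size_mean expected reads per count-platform sample.
#' @param housekeeping_index index of the housekeeping gene.
#' @param noisy_fraction fraction of experiments whose stress replicates get
#'   NO signature (their true folds are 1), exercising the QC filter.
#' @param seed integer RNG seed; a single stream drives the whole draw.
#' @return a `meta_sim_config` list.
#' @export
meta_sim_config <- function(n_experiments = 13L,
                            n_genes = 35L,
                            platform = NULL,
                            n_control_reps = NULL,
                            n_stress_reps = NULL,
                            stress_type = NULL,
                            baseline_log2_mean = 6,
                            baseline_log2_sd = 1.5,
                            batch_scale_sd = 0.5,
                            replicate_noise_sd = 0.25,
                            signature_fold = NULL,
                            signature_jitter_sd = 0.1,
                            count_dispersion = 0.05,
                            gene_lengths = NULL,
                            library_size_mean = 2e6,
                            housekeeping_index = 1L,
                            noisy_fraction = 0,
                            seed = 1L) {
  n <- as.integer(n_experiments)
  split_even <- function(total, n) {
    base <- rep(total %/% n, n)
    extra <- total %% n
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  cfg <- list(
    n_experiments = n,
    n_genes = as.integer(n_genes),
    platform = rep_len(platform %||% c("intensity", "counts"), n),
    n_control_reps = rep_len(n_control_reps %||% split_even(70L, n), n),
    n_stress_reps = rep_len(n_stress_reps %||% split_even(130L, n), n),
    stress_type = rep_len(stress_type %||%
      c(rep("cold", ceiling(n / 2)), rep("water_deficiency", floor(n / 2))), n),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    batch_scale_sd = batch_scale_sd,
    replicate_noise_sd = replicate_noise_sd,
    signature_fold = signature_fold %||%
      default_signature_fold(as.integer(n_genes), as.integer(housekeeping_index)),
    signature_jitter_sd = signature_jitter_sd,
    count_dispersion = count_dispersion,
    gene_lengths = rep_len(gene_lengths %||%
      round(seq(600, 3600, length.out = as.integer(n_genes))), as.integer(n_genes)),
    library_size_mean = library_size_mean,
    housekeeping_index = as.integer(housekeeping_index),
    noisy_fraction = noisy_fraction,
    seed = as.integer(seed))
  class(cfg) <- "meta_sim_config"
  validate_meta_sim_config(cfg)
}

#' Default planted signature matrix
#'
#' Distinct blocks of strongly regulated genes per stress type (up folds 6
#' and 5, down folds 0.15 and 0.2 for cold and water deficiency); remaining
#' genes and the housekeeping gene are null (fold 1).
#'
#' @param n_genes panel size.
#' @param housekeeping_index housekeeping gene index (always fold 1).
#' @return `n_genes` x 2 matrix with columns `cold`, `water_deficiency`.
#' @export
default_signature_fold <- function(n_genes, housekeeping_index = 1L) {
  sig <- matrix(1, n_genes, 2,
                dimnames = list(NULL, c("cold", "water_deficiency")))
  idx <- setdiff(seq_len(n_genes), housekeeping_index)
  bs <- max(1L, min(6L, length(idx) %/% 4L))
  take <- function(k) idx[seq.int((k - 1L) * bs + 1L, k * bs)]
  if (length(idx) >= 4L) {
    sig[take(1L), "cold"] <- 6
    sig[take(2L), "cold"] <- 0.15
    sig[take(3L), "water_deficiency"] <- 5
    sig[take(4L), "water_deficiency"] <- 0.2
  }
  sig
}

validate_meta_sim_config <- function(cfg) {
  st <- "meta_sim_config"
  if (cfg$n_experiments < 1L || cfg$n_genes < 2L)
    stop_ctx(st, "need at least 1 experiment and 2 genes")
  if (any(cfg$n_control_reps < 2L))
    stop_ctx(st, "every experiment needs >= 2 control replicates")
  if (any(cfg$n_stress_reps < 1L))
    stop_ctx(st, "every experiment needs >= 1 stress replicate")
  if (!all(cfg$platform %in% c("counts", "intensity")))
    stop_ctx(st, "platform must be 'counts' or 'intensity'")
  if (!all(cfg$stress_type %in% c("cold", "water_deficiency")))
    stop_ctx(st, "stress_type must be 'cold' or 'water_deficiency'")
  sf <- cfg$signature_fold
  if (!is.matrix(sf) || nrow(sf) != cfg$n_genes || ncol(sf) != 2L)
    stop_ctx(st, "signature_fold must be an n_genes x 2 matrix")
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_ctx(st, "signature folds must be finite and > 0")
  if (any(sf[cfg$housekeeping_index, ] != 1))
    stop_ctx(st, "housekeeping gene must have true fold 1 in every condition")
  if (cfg$noisy_fraction < 0 || cfg$noisy_fraction > 1)
    stop_ctx(st, "noisy_fraction must be in [0, 1]")
  if (any(cfg$gene_lengths <= 0))
    stop_ctx(st, "gene lengths must be positive")
  cfg
}

default_gene_table <- function(n_genes, housekeeping_index) {
  classes <- c("SOD", "CAT", "APX", "GPX", "GR", "DHAR", "MDHAR")
  gene_id <- sprintf("G%03d", seq_len(n_genes))
  enzyme_class <- rep_len(classes, n_genes)
  clade <- paste0(enzyme_class, "_", LETTERS[((seq_len(n_genes) - 1L) %/%
                                                length(classes)) + 1L])
  enzyme_class[housekeeping_index] <- "other"
  clade[housekeeping_index] <- "HK"
  data.frame(gene_id = gene_id, enzyme_class = enzyme_class, clade = clade,
             housekeeping = seq_len(n_genes) == housekeeping_index,
             length = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate a multi-experiment expression bundle with known ground truth
#'
#' Each gene gets a log2 baseline shared across experiments; each experiment
#' a multiplicative batch scale; each sample a multiplicative scale (arrays)
#' or a library-size factor (sequencing). Stress replicates of non-noisy
#' experiments carry the planted signature fold (jittered per gene x
#' experiment); replicates add log-normal noise. The housekeeping gene
#' co-varies with the batch/sample scale only (no signature, no replicate
#' noise). Count platforms draw negative-binomial (or Poisson) counts from
#' length-weighted expected fractions of the library; intensity platforms
#' emit positive reals.
#'
#' @param config a [meta_sim_config()].
#' @return list with `studies` (list of [expression_study()]) and `truth`
#'   (planted `signature_fold`, per-experiment `realized_fold` after jitter,
#'   `noisy_experiments`, `stress_type`, and the replicate table).
#' @export
generate_meta_experiments <- function(config) {
  cfg <- validate_meta_sim_config(config)
  set.seed(cfg$seed)
  n_noisy <- round(cfg$noisy_fraction * cfg$n_experiments)
  exp_ids <- sprintf("E%02d", seq_len(cfg$n_experiments))
  noisy <- if (n_noisy > 0) sort(sample(cfg$n_experiments, n_noisy)) else integer()
  baseline <- rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  hk <- cfg$housekeeping_index
  genes <- default_gene_table(cfg$n_genes, hk)
  genes$length <- cfg$gene_lengths
  studies <- vector("list", cfg$n_experiments)
  realized <- vector("list", cfg$n_experiments)
  for (e in seq_len(cfg$n_experiments)) {
    stype <- cfg$stress_type[e]
    n_c <- cfg$n_control_reps[e]; n_s <- cfg$n_stress_reps[e]
    n_rep <- n_c + n_s
    condition <- rep(c("control", "stress"), c(n_c, n_s))
    batch <- rnorm(1, 0, cfg$batch_scale_sd)
    # per gene x experiment realized log2 fold (0 for noisy experiments)
    lfc <- if (e %in% noisy) rep(0, cfg$n_genes) else
      log2(cfg$signature_fold[, stype]) +
        rnorm(cfg$n_genes, 0, cfg$signature_jitter_sd) *
        (log2(cfg$signature_fold[, stype]) != 0)
    lfc[hk] <- 0
    realized[[e]] <- 2^lfc
    sample_scale <- rnorm(n_rep, 0, cfg$batch_scale_sd)
    noise <- matrix(rnorm(cfg$n_genes * n_rep, 0, cfg$replicate_noise_sd),
                    cfg$n_genes, n_rep)
    noise[hk, ] <- 0
    sig <- outer(lfc, as.numeric(condition == "stress"))
    log2_expr <- baseline + batch + sig + noise        # biological abundance
    m <- if (cfg$platform[e] == "intensity") {
      2^sweep(log2_expr, 2L, sample_scale, "+")
    } else {
      lib <- cfg$library_size_mean * 2^sample_scale
      mu <- 2^log2_expr * cfg$gene_lengths
      mu <- sweep(mu, 2L, colSums(mu), "/") * rep(lib, each = cfg$n_genes)
      cnt <- if (cfg$count_dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / cfg$count_dispersion)
      else rpois(length(mu), mu)
      matrix(as.numeric(cnt), cfg$n_genes, n_rep)
    }
    sample_id <- sprintf("%s_%s%02d", exp_ids[e],
                         ifelse(condition == "control", "C", "S"),
                         c(seq_len(n_c), seq_len(n_s)))
    dimnames(m) <- list(genes$gene_id, sample_id)
    studies[[e]] <- expression_study(
      exp_ids[e], cfg$platform[e], m,
      data.frame(sample_id = sample_id, condition = condition,
                 stress_type = ifelse(condition == "stress", stype, "none"),
                 tissue = "leaf", time_point = "t0", stringsAsFactors = FALSE),
      genes)
  }
  names(studies) <- exp_ids
  realized <- do.call(cbind, realized)
  colnames(realized) <- exp_ids
  rownames(realized) <- genes$gene_id
  replicates <- do.call(rbind, lapply(studies, function(s)
    data.frame(experiment_id = s$experiment_id, sample_id = s$samples$sample_id,
               condition = s$samples$condition,
               stress_type = s$samples$stress_type, stringsAsFactors = FALSE)))
  rownames(replicates) <- NULL
  list(studies = studies,
       truth = list(signature_fold = cfg$signature_fold,
                    realized_fold = realized,
                    noisy_experiments = exp_ids[noisy],
                    stress_type = setNames(cfg$stress_type, exp_ids),
                    replicates = replicates,
                    seed = cfg$seed))
}
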