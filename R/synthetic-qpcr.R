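#' Configuration for the qPCR plate simulator
#'
#' Defaults follow a typical SYBR relative-quantification design: three
#' target amplicons plus an abundant reference (18S), three treatments
#' (control plus short and prolonged cold), three biological x three
#' technical replicates, 45 cycles, per-well Cq noise of 0.2 cycles.
#'
#' @param targets target amplicon labels.
#' @param treatments treatment labels; the first is the control group.
#' @param cultivars cultivar labels (a full design is simulated per
#'   cultivar).
#' @param true_ratio targets x treatments matrix of true expression ratios
#'   relative to control (control column 1).
#' @param true_efficiency per-target amplification efficiency in (1, 2].
#' @param reference_efficiency reference amplicon efficiency in (1, 2].
#' @param n_bio,n_tech biological / technical replicates per group.
#' @param cq_noise_sd per-well Cq noise, cycles (applied as a template
#'   scale `E^-eps`, shifting the whole curve by `eps` cycles).
#' @param n_cycles cycles per run (>= 30).
#' @param baseline,plateau,target_n0,reference_n0 curve-model parameters:
#'   additive baseline fluorescence, plateau amplitude, and initial template
#'   proxies (dimensionless; fluorescence in the early exponential phase is
#'   `plateau * n0 * E^c`).
#' @param include_ntc add one no-template control well per amplicon.
#' @param seed integer RNG seed.
#' @return a `qpcr_sim_config` list.
#' @export
qpcr_sim_config <- function(targets = c("SOD_A", "CAT_C", "APX_E"),
                            treatments = c("control", "cold_6h", "cold_24h"),
                            cultivars = "S29",
                            true_ratio = NULL,
                            true_efficiency = NULL,
                            reference_efficiency = 1.9,
                            n_bio = 3L, n_tech = 3L,
                            cq_noise_sd = 0.2,
                            n_cycles = 45L,
                            baseline = 0.5, plateau = 10,
                            target_n0 = 1e-6, reference_n0 = 1e-5,
                            include_ntc = TRUE,
                            seed = 1L) {
  if (is.null(true_ratio)) {
    true_ratio <- matrix(1, length(targets), length(treatments),
                         dimnames = list(targets, treatments))
    if (length(treatments) >= 3L && length(targets) >= 3L) {
      # magnitudes typical of cold-stress AOS responses
      true_ratio[1:3, 2:3] <- rbind(c(0.45, 1.52), c(1.86, 0.56), c(1.55, 3.00))
    }
  }
  if (is.null(true_efficiency))
    true_efficiency <- setNames(rep_len(c(1.8, 1.9, 2.0), length(targets)), targets)
  cfg <- list(targets = targets, treatments = treatments, cultivars = cultivars,
              true_ratio = true_ratio,
              true_efficiency = true_efficiency,
              reference_efficiency = reference_efficiency,
              n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
              cq_noise_sd = cq_noise_sd, n_cycles = as.integer(n_cycles),
              baseline = baseline, plateau = plateau,
              target_n0 = target_n0, reference_n0 = reference_n0,
              include_ntc = include_ntc, seed = as.integer(seed))
  class(cfg) <- "qpcr_sim_config"
  validate_qpcr_sim_config(cfg)
}

validate_qpcr_sim_config <- function(cfg) {
  st <- "qpcr_sim_config"
  eff <- c(cfg$true_efficiency, cfg$reference_efficiency)
  if (any(eff <= 1 | eff > 2))
    stop_ctx(st, "efficiencies must lie in (1, 2]")
  if (any(!is.finite(cfg$true_ratio)) || any(cfg$true_ratio <= 0))
    stop_ctx(st, "true ratios must be finite and > 0")
  if (any(cfg$true_ratio[, 1L] != 1))
    stop_ctx(st, "the control column of true_ratio must be 1")
  if (cfg$n_cycles < 30L) stop_ctx(st, "n_cycles must be >= 30")
  if (cfg$n_bio < 1L || cfg$n_tech < 1L)
    stop_ctx(st, "n_bio and n_tech must be >= 1")
  if (cfg$cq_noise_sd < 0) stop_ctx(st, "cq_noise_sd must be >= 0")
  cfg
}

# logistic amplification curve: exponential early phase plateau-limited,
# F(c) = baseline + plateau * u / (1 + u), u = n0 * E^c
amp_curve <- function(n0, efficiency, n_cycles, baseline, plateau) {
  u <- n0 * efficiency^seq_len(n_cycles)
  baseline + plateau * u / (1 + u)
}

#' Simulate a qPCR plate with known ground truth
#'
#' Target template amounts scale with the planted ratio in each treatment;
#' reference template is treatment-independent. Each well's curve follows
#' baseline + exponential-then-plateau growth with the amplicon's true
#' efficiency; per-well noise shifts the curve by `N(0, cq_noise_sd)`
#' cycles.
#'
#' @param config a [qpcr_sim_config()].
#' @return list with `plate` (a `qpcr_plate`: `wells` annotation
#'   data.frame, `curves` wells x cycles matrix, `n_cycles`) and `truth`
#'   (planted ratios, efficiencies, per-well noiseless template).
#' @export
generate_qpcr_plate <- function(config) {
  cfg <- validate_qpcr_sim_config(config)
  set.seed(cfg$seed)
  amplicons <- c(cfg$targets, "REF")
  eff <- c(cfg$true_efficiency, REF = cfg$reference_efficiency)
  rows <- list(); k <- 0L
  for (cv in cfg$cultivars) for (tr in cfg$treatments)
    for (b in seq_len(cfg$n_bio)) for (a in amplicons)
      for (tc in seq_len(cfg$n_tech)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          well_id = sprintf("W%03d", k),
          target = if (a == "REF") "REF" else a,
          role = if (a == "REF") "reference" else "target",
          cultivar = cv, treatment = tr, bio_rep = b, tech_rep = tc,
          stringsAsFactors = FALSE)
      }
  if (cfg$include_ntc)
    for (a in amplicons) {
      k <- k + 1L
      rows[[k]] <- data.frame(well_id = sprintf("W%03d", k), target = a,
                              role = "ntc", cultivar = cfg$cultivars[1L],
                              treatment = "none", bio_rep = 0L, tech_rep = 1L,
                              stringsAsFactors = FALSE)
    }
  wells <- do.call(rbind, rows)
  curves <- matrix(cfg$baseline, nrow(wells), cfg$n_cycles,
                   dimnames = list(wells$well_id, NULL))
  n0 <- numeric(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    if (w$role == "ntc") { n0[i] <- 0; next }
    e <- eff[[w$target]]
    base_n0 <- if (w$role == "reference") cfg$reference_n0 else
      cfg$target_n0 * cfg$true_ratio[w$target, w$treatment]
    shift <- if (cfg$cq_noise_sd > 0) rnorm(1, 0, cfg$cq_noise_sd) else 0
    n0[i] <- base_n0 * e^(-shift)
    curves[i, ] <- amp_curve(n0[i], e, cfg$n_cycles, cfg$baseline, cfg$plateau)
  }
  plate <- structure(list(wells = wells, curves = curves, cq = NULL,
                          n_cycles = cfg$n_cycles),
                     class = "qpcr_plate")
  list(plate = plate,
       truth = list(true_ratio = cfg$true_ratio,
                    true_efficiency = cfg$true_efficiency,
                    reference_efficiency = cfg$reference_efficiency,
                    n0 = setNames(n0, wells$well_id),
                    seed = cfg$seed))
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat(sprintf("<qpcr_plate> %d wells (%d targets), %s\n",
              nrow(x$wells), length(setdiff(unique(x$wells$target), "REF")),
              if (!is.null(x$curves)) sprintf("%d-cycle curves", x$n_cycles)
              else "precomputed Cq"))
  invisible(x)
}

#' Write / read a qPCR plate as long-format TSV
#'
#' Curve plates use one row per well x cycle (`well_id, target, role,
#' cultivar, treatment, bio_rep, tech_rep, cycle, fluorescence`); Cq plates
#' one row per well with a `cq` column.
#'
#' @param plate a `qpcr_plate`.
#' @param path TSV path.
#' @return `path` (write) / a `qpcr_plate` (read).
#' @export
write_qpcr_plate <- function(plate, path) {
  if (!is.null(plate$curves)) {
    long <- merge(cbind(plate$wells, row = seq_len(nrow(plate$wells))),
                  data.frame(cycle = seq_len(plate$n_cycles)))
    long$fluorescence <- plate$curves[cbind(long$row, long$cycle)]
    long <- long[order(long$row, long$cycle),
                 c("well_id", "target", "role", "cultivar", "treatment",
                   "bio_rep", "tech_rep", "cycle", "fluorescence")]
    write_tsv(long, path)
  } else {
    write_tsv(cbind(plate$wells, cq = plate$cq), path)
  }
  invisible(path)
}

#' @rdname write_qpcr_plate
#' @export
read_qpcr_plate <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ann_cols <- c("well_id", "target", "role", "cultivar", "treatment",
                "bio_rep", "tech_rep")
  if ("fluorescence" %in% names(tab)) {
    wells <- unique(tab[, ann_cols])
    rownames(wells) <- NULL
    n_cycles <- max(tab$cycle)
    curves <- matrix(NA_real_, nrow(wells), n_cycles,
                     dimnames = list(wells$well_id, NULL))
    curves[cbind(match(tab$well_id, wells$well_id), tab$cycle)] <- tab$fluorescence
    structure(list(wells = wells, curves = curves, cq = NULL,
                   n_cycles = n_cycles), class = "qpcr_plate")
  } else if ("cq" %in% names(tab)) {
    structure(list(wells = tab[, ann_cols], curves = NULL, cq = tab$cq,
                   n_cycles = NA_integer_), class = "qpcr_plate")
  } else {
    stop_ctx("read_qpcr_plate", "%s has neither 'fluorescence' nor 'cq'", path)
  }
}
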