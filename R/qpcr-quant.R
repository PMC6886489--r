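#' Efficiency-corrected relative expression ratio
#'
#' The multiple-sample efficiency-corrected quantification model:
#' `ratio = e_target^dcq_target / e_reference^dcq_reference`, where each
#' `dcq` is `MEAN_control(Cq) - MEAN_treat(Cq)` for the respective
#' amplicon, so a ratio above 1 means higher expression under treatment.
#' With both efficiencies equal to 2 this reduces to the classical
#' `2^-ddCq`.
#'
#' @param e_target,e_reference amplification efficiencies (> 0; perfect
#'   doubling is 2).
#' @param dcq_target,dcq_reference Cq differences in cycles
#'   (`MEAN_control - MEAN_treat`).
#' @return the expression ratio (vectorized).
#' @export
pfaffl_ratio <- function(e_target, dcq_target, e_reference, dcq_reference) {
  if (any(!is.finite(e_target) | !is.finite(e_reference) |
          e_target <= 0 | e_reference <= 0))
    stop_ctx("pfaffl_ratio", "efficiencies must be finite and > 0")
  if (any(!is.finite(dcq_target) | !is.finite(dcq_reference)))
    stop_ctx("pfaffl_ratio", "Cq differences must be finite")
  e_target^dcq_target / e_reference^dcq_reference
}

# best log-linear window of the given sizes over consecutive-cycle runs;
# closed-form slope/R^2 via window sums (x are consecutive integers)
best_window <- function(cycles, y, sizes = 4:6) {
  best <- list(r2 = -Inf)
  runs <- split(seq_along(cycles), cumsum(c(1L, diff(cycles) != 1L)))
  for (run in runs) {
    L <- length(run)
    xr <- cycles[run]; yr <- y[run]
    cy <- c(0, cumsum(yr)); cyy <- c(0, cumsum(yr^2)); cxy <- c(0, cumsum(xr * yr))
    for (w in sizes[sizes <= L]) {
      st <- seq_len(L - w + 1L)
      Sy <- cy[st + w] - cy[st]
      Syy <- cyy[st + w] - cyy[st]
      Sxy <- cxy[st + w] - cxy[st]
      xs <- xr[st]                      # window start cycle
      Sx <- w * xs + w * (w - 1) / 2
      varx <- w * (w^2 - 1) / 12        # centered x sum of squares
      num <- Sxy - Sx * Sy / w
      vary <- pmax(Syy - Sy^2 / w, 0)
      r2 <- ifelse(vary > 0, num^2 / (varx * vary), 0)
      i <- which.max(r2 - 1e-12 * seq_along(r2))  # prefer earlier (least plateau-curved) start on ties
      cand <- list(r2 = r2[i], slope = num[i] / varx,
                   start = xs[i], size = w,
                   xbar = xs[i] + (w - 1) / 2, ybar = Sy[i] / w)
      if (cand$r2 > best$r2 + 1e-12 ||
          (abs(cand$r2 - best$r2) <= 1e-12 && cand$size > best$size %||% 0L))
        best <- cand
    }
  }
  if (!is.finite(best$r2)) return(NULL)
  best$intercept <- best$ybar - best$slope * best$xbar
  best
}

#' Amplification efficiency and Cq from one fluorescence curve
#'
#' Window-of-linearity estimation: an additive baseline is subtracted
#' (chosen to maximize the log-linearity of the best exponential-phase
#' window, which reduces to the flat early-cycle level for real plateau
#' curves and to zero for a curve that is exponential from cycle 1); among
#' baseline-corrected cycles below `plateau_frac` of the maximum, the
#' window of 4-6 consecutive cycles maximizing the R-squared of
#' `log10(F)` vs cycle is selected; efficiency is `10^slope`; Cq is the
#' fractional cycle at which the fitted line crosses `threshold`
#' (default: geometric mean of the fitted fluorescence at the window
#' bounds).
#'
#' @param curve per-cycle fluorescence.
#' @param n_cycles number of cycles (default `length(curve)`).
#' @param baseline fixed additive baseline; `NULL` to estimate.
#' @param threshold fluorescence threshold for Cq; `NULL` for the
#'   window-based default.
#' @param window_sizes candidate window lengths.
#' @param plateau_frac exponential-phase cap as a fraction of the maximum
#'   corrected fluorescence.
#' @param flat_tol relative range below which a curve is called negative
#'   (no amplification, e.g. an NTC well).
#' @return list: `efficiency`, `cq`, `fit_r2`, `slope`, `intercept` (log10
#'   scale), `baseline`, `window` (first/last cycle), `threshold`, `flag`
#'   (`"ok"`, `"negative"`, or `"no_plateau"`).
#' @export
estimate_efficiency <- function(curve, n_cycles = length(curve),
                                baseline = NULL, threshold = NULL,
                                window_sizes = 4:6, plateau_frac = 0.9,
                                flat_tol = 0.05) {
  st <- "estimate_efficiency"
  curve <- as.numeric(curve)[seq_len(n_cycles)]
  if (n_cycles < 15L) stop_ctx(st, "need >= 15 cycles, got %d", n_cycles)
  neg <- list(efficiency = NA_real_, cq = NA_real_, fit_r2 = NA_real_,
              slope = NA_real_, intercept = NA_real_, baseline = NA_real_,
              window = c(NA_integer_, NA_integer_), threshold = NA_real_,
              flag = "negative")
  rng <- max(curve) - min(curve)
  if (rng <= flat_tol * max(abs(curve), 1e-12)) return(neg)
  cycles <- seq_len(n_cycles)
  score <- function(b) {
    g <- curve - b
    top <- max(g)
    elig <- which(g > top * 1e-4 & g < plateau_frac * top)
    if (length(elig) < min(window_sizes)) return(NULL)
    best_window(cycles[elig], log10(g[elig]), window_sizes)
  }
  if (is.null(baseline)) {
    # alternate window choice and baseline refinement: starting from the
    # curve minimum (an over-subtracting first guess whose residual is
    # negligible against the selected window's signal), pick the best
    # window, then maximize that fixed window's log-linearity over the
    # baseline, and repeat; for a curve exponential from cycle 1 this
    # converges to baseline 0, for plateau curves to the flat ground level
    window_r2 <- function(idx, b) {
      g <- curve[idx] - b
      if (any(g <= 0)) return(-Inf)
      y <- log10(g)
      sy <- sum(y); syy <- sum(y^2); sxy <- sum(idx * y)
      w <- length(idx)
      sx <- sum(idx)
      num <- sxy - sx * sy / w
      varx <- sum(idx^2) - sx^2 / w
      vary <- syy - sy^2 / w
      if (vary <= 0) 0 else num^2 / (varx * vary)
    }
    baseline <- if (min(curve) > 0) min(curve) * (1 - 1e-6) else 0
    for (iter in 1:6) {
      f <- score(baseline)
      if (is.null(f)) return(neg)
      # anchor the baseline fit with every eligible cycle below the window
      # (contiguous with it): the low-signal cycles pin the baseline and
      # prevent it from absorbing plateau curvature inside the window
      g <- curve - baseline
      top <- max(g)
      elig <- which(g > top * 1e-4 & g < plateau_frac * top)
      run_start <- f$start
      while ((run_start - 1L) %in% elig) run_start <- run_start - 1L
      idx <- seq.int(run_start, f$start + f$size - 1L)
      upper <- min(curve[idx]) * (1 - 1e-9)
      if (upper <= 0) { baseline <- 0; break }
      cand <- seq(0, upper, length.out = 33)
      r2s <- vapply(cand, function(b) window_r2(idx, b), numeric(1))
      i <- which.max(r2s)
      lo <- cand[max(1L, i - 1L)]; hi <- cand[min(length(cand), i + 1L)]
      opt <- optimize(function(b) window_r2(idx, b), c(lo, hi),
                      maximum = TRUE, tol = max(1e-14, upper * 1e-12))
      baseline <- if (opt$objective > r2s[i]) opt$maximum else cand[i]
    }
  }
  fit <- score(baseline)
  if (is.null(fit) || !is.finite(fit$slope) || fit$slope <= 0) return(neg)
  if (is.null(threshold)) {
    y_lo <- fit$intercept + fit$slope * fit$start
    y_hi <- fit$intercept + fit$slope * (fit$start + fit$size - 1L)
    threshold <- 10^((y_lo + y_hi) / 2)
  }
  plateau_ok <- (curve[n_cycles] - curve[n_cycles - 2L]) < 0.02 * rng
  list(efficiency = 10^fit$slope,
       cq = (log10(threshold) - fit$intercept) / fit$slope,
       fit_r2 = fit$r2, slope = fit$slope, intercept = fit$intercept,
       baseline = baseline,
       window = c(fit$start, fit$start + fit$size - 1L),
       threshold = threshold,
       flag = if (plateau_ok) "ok" else "no_plateau")
}

#' Fit all wells of a qPCR plate
#'
#' Estimates per-well efficiency and Cq from the curves, pools a
#' per-amplicon efficiency (mean over the amplicon's successful wells) and
#' a common per-amplicon threshold (geometric mean of the per-well window
#' thresholds), and recomputes every well's Cq at that common threshold.
#' For a Cq-only plate the per-target efficiencies must be supplied.
#'
#' @param plate a `qpcr_plate`.
#' @param efficiencies named per-target efficiency vector (must include
#'   `"REF"`); required for Cq-only plates, ignored when curves are
#'   present.
#' @return the plate with `fits` (per-well data.frame) and `amplicons`
#'   (per-target pooled efficiency and threshold) filled in.
#' @export
fit_qpcr_plate <- function(plate, efficiencies = NULL) {
  st <- "fit_qpcr_plate"
  w <- plate$wells
  if (is.null(plate$curves)) {
    if (is.null(efficiencies))
      stop_ctx(st, "Cq-only plate: per-target efficiencies are required")
    missing_t <- setdiff(unique(w$target), names(efficiencies))
    if (length(missing_t))
      stop_ctx(st, "no efficiency supplied for target(s): %s",
               paste(missing_t, collapse = ", "))
    plate$fits <- cbind(w, efficiency = unname(efficiencies[w$target]),
                        cq = plate$cq, fit_r2 = NA_real_,
                        flag = ifelse(is.na(plate$cq), "negative", "ok"))
    plate$amplicons <- data.frame(target = names(efficiencies),
                                  efficiency = unname(efficiencies),
                                  threshold = NA_real_, stringsAsFactors = FALSE)
    return(plate)
  }
  per_well <- lapply(seq_len(nrow(w)),
                     function(i) estimate_efficiency(plate$curves[i, ],
                                                     plate$n_cycles))
  eff <- vapply(per_well, `[[`, numeric(1), "efficiency")
  thr <- vapply(per_well, `[[`, numeric(1), "threshold")
  ok <- vapply(per_well, `[[`, character(1), "flag") != "negative" &
    w$role != "ntc"
  amplicons <- do.call(rbind, lapply(unique(w$target), function(a) {
    sel <- ok & w$target == a
    data.frame(target = a,
               efficiency = if (any(sel)) mean(eff[sel]) else NA_real_,
               threshold = if (any(sel)) exp(mean(log(thr[sel]))) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cq <- rep(NA_real_, nrow(w))
  for (i in seq_len(nrow(w))) {
    if (!ok[i]) next
    f <- per_well[[i]]
    t_amp <- amplicons$threshold[amplicons$target == w$target[i]]
    cq[i] <- (log10(t_amp) - f$intercept) / f$slope
  }
  plate$fits <- cbind(w, efficiency = eff, cq = cq,
                      fit_r2 = vapply(per_well, `[[`, numeric(1), "fit_r2"),
                      flag = vapply(per_well, `[[`, character(1), "flag"))
  plate$amplicons <- amplicons
  plate
}

tech_average <- function(fits) {
  ok <- fits$role != "ntc" & !is.na(fits$cq)
  aggregate(cq ~ target + role + cultivar + treatment + bio_rep,
            data = fits[ok, ], FUN = mean)
}

#' Aggregate a fitted plate into efficiency-corrected expression ratios
#'
#' Technical replicates are averaged into biological-replicate Cq values;
#' `MEAN_control` and `MEAN_treat` are means over biological replicates;
#' per-amplicon pooled efficiencies feed [pfaffl_ratio()]. One estimate is
#' produced per target x cultivar x treatment (the control group's own
#' ratio is 1 by construction, as is the reference amplicon's).
#'
#' @param plate a fitted `qpcr_plate` (see [fit_qpcr_plate()]); an unfitted
#'   curve plate is fitted on the fly.
#' @param efficiencies passed to [fit_qpcr_plate()] for Cq-only plates.
#' @param control_treatment label of the control group.
#' @return a `ratio_estimate` data.frame: `target`, `cultivar`,
#'   `treatment`, `ratio`, `e_target`, `e_reference`, `dcq_target`,
#'   `dcq_reference`, `n_bio`.
#' @export
aggregate_ratios <- function(plate, efficiencies = NULL,
                             control_treatment = "control") {
  st <- "aggregate_ratios"
  if (is.null(plate$fits)) plate <- fit_qpcr_plate(plate, efficiencies)
  fits <- plate$fits
  samples <- unique(fits[fits$role == "target",
                         c("cultivar", "treatment", "bio_rep")])
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    if (!any(fits$role == "reference" & fits$cultivar == s$cultivar &
             fits$treatment == s$treatment & fits$bio_rep == s$bio_rep))
      stop_ctx(st, "reference wells absent for sample (%s, %s, bio %d)",
               s$cultivar, s$treatment, s$bio_rep)
  }
  bio <- tech_average(fits)
  e_of <- function(a) plate$amplicons$efficiency[plate$amplicons$target == a]
  rows <- list(); k <- 0L
  for (cv in unique(bio$cultivar)) {
    ref_cv <- bio[bio$role == "reference" & bio$cultivar == cv, ]
    ref_ctrl <- mean(ref_cv$cq[ref_cv$treatment == control_treatment])
    for (a in unique(bio$target[bio$cultivar == cv])) {
      b_a <- bio[bio$target == a & bio$cultivar == cv, ]
      if (!any(b_a$treatment == control_treatment))
        stop_ctx(st, "missing control biological replicates for %s / %s", a, cv)
      m_ctrl <- mean(b_a$cq[b_a$treatment == control_treatment])
      for (tr in unique(b_a$treatment)) {
        dcq_t <- m_ctrl - mean(b_a$cq[b_a$treatment == tr])
        dcq_r <- ref_ctrl - mean(ref_cv$cq[ref_cv$treatment == tr])
        k <- k + 1L
        rows[[k]] <- data.frame(
          target = a, cultivar = cv, treatment = tr,
          ratio = pfaffl_ratio(e_of(a), dcq_t, e_of("REF"), dcq_r),
          e_target = e_of(a), e_reference = e_of("REF"),
          dcq_target = dcq_t, dcq_reference = dcq_r,
          n_bio = sum(b_a$treatment == tr), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("ratio_estimate", "data.frame")
  res
}

#' Per-sample delta-Cq table
#'
#' `dCq = Cq_target - Cq_reference` per biological replicate (technical
#' replicates averaged first), the response variable of the factorial
#' ANOVA.
#'
#' @param plate a fitted `qpcr_plate`.
#' @return data.frame: `gene`, `cultivar`, `treatment`, `bio_rep`, `dcq`.
#' @export
delta_cq <- function(plate) {
  if (is.null(plate$fits)) plate <- fit_qpcr_plate(plate)
  bio <- tech_average(plate$fits)
  tg <- bio[bio$role == "target", ]
  rf <- bio[bio$role == "reference", ]
  key <- function(d) paste(d$cultivar, d$treatment, d$bio_rep)
  i <- match(key(tg), key(rf))
  if (anyNA(i))
    stop_ctx("delta_cq", "reference Cq missing for some samples")
  data.frame(gene = tg$target, cultivar = tg$cultivar,
             treatment = tg$treatment, bio_rep = tg$bio_rep,
             dcq = tg$cq - rf$cq[i], stringsAsFactors = FALSE)
}

#' Two-way ANOVA on delta-Cq
#'
#' Fixed-effects cultivar x treatment ANOVA per gene on the per-sample
#' `dCq`, with type-II sums of squares (robust to unbalanced layouts
#' without interaction-driven imbalance).
#'
#' @param dcq data.frame from [delta_cq()] (columns `gene`, `cultivar`,
#'   `treatment`, `bio_rep`, `dcq`).
#' @return data.frame: `gene`, `term` (`cultivar`, `treatment`,
#'   `cultivar:treatment`), `df`, `sum_sq`, `F`, `p`.
#' @export
anova_dcq <- function(dcq) {
  st <- "anova_dcq"
  rows <- lapply(unique(dcq$gene), function(g) {
    d <- dcq[dcq$gene == g, ]
    d$cultivar <- factor(d$cultivar); d$treatment <- factor(d$treatment)
    if (nlevels(d$cultivar) < 2L || nlevels(d$treatment) < 2L)
      stop_ctx(st, "gene %s: each factor needs >= 2 levels", g)
    cells <- table(d$cultivar, d$treatment)
    if (any(cells < 2L))
      stop_ctx(st, "gene %s: every cultivar x treatment cell needs >= 2 replicates", g)
    a <- car::Anova(lm(dcq ~ cultivar * treatment, data = d), type = 2)
    terms <- c("cultivar", "treatment", "cultivar:treatment")
    data.frame(gene = g, term = terms,
               df = a[terms, "Df"], sum_sq = a[terms, "Sum Sq"],
               F = a[terms, "F value"], p = a[terms, "Pr(>F)"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Bar plot of expression ratios (control line at y = 1)
#'
#' @param ratios a `ratio_estimate` data.frame.
#' @return a ggplot object: one panel per target, bars per treatment,
#'   dashed control line at `y = 1`.
#' @export
plot_ratio_bars <- function(ratios) {
  r <- ratios[ratios$target != "REF" & ratios$treatment != "control", ]
  ggplot2::ggplot(r, ggplot2::aes(x = treatment, y = ratio,
                                  fill = cultivar)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = "expression ratio (treatment / control)") +
    ggplot2::theme_minimal()
}
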