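logistic_curve <- function(n0, E, n = 45, b = 0.5, P = 10) {
  u <- n0 * E^seq_len(n)
  b + P * u / (1 + u)
}

test_that("the efficiency-corrected ratio implements the quantification model", {
  expect_equal(pfaffl_ratio(2, 1, 2, 0), 2)
  expect_equal(pfaffl_ratio(2, 5, 2, 5), 1)
  expect_equal(pfaffl_ratio(1.9, 3, 2.0, 1), 1.9^3 / 2)
  expect_equal(round(pfaffl_ratio(1.9, 3, 2.0, 1), 4), 3.4295)
  # with both efficiencies 2 the model reduces to 2^(dcq_t - dcq_r)
  set.seed(1)
  x <- runif(1000, -5, 5); y <- runif(1000, -5, 5)
  expect_true(max(abs(pfaffl_ratio(2, x, 2, y) - 2^(x - y))) < 1e-12)
  # monotone in both Cq differences
  expect_true(all(diff(pfaffl_ratio(1.8, seq(-2, 2, 0.5), 1.9, 0)) > 0))
  expect_true(all(diff(pfaffl_ratio(1.8, 0, 1.9, seq(-2, 2, 0.5))) < 0))
  expect_error(pfaffl_ratio(-1, 1, 2, 1), "> 0")
  expect_error(pfaffl_ratio(2, Inf, 2, 0), "finite")
})

test_that("a pure doubling curve yields E = 2 and the analytic Cq", {
  f <- estimate_efficiency(0.001 * 2^(1:20), threshold = 1.024)
  expect_equal(f$efficiency, 2, tolerance = 1e-3)
  expect_equal(f$cq, 10, tolerance = 1e-6)
})

test_that("noiseless plateau curves recover the true efficiency within 0.01", {
  for (E in c(1.8, 1.9, 2.0))
    for (n0 in c(1e-5, 1e-6, 4.5e-7)) {
      f <- estimate_efficiency(logistic_curve(n0, E))
      expect_equal(f$efficiency, E, tolerance = 0.01 / E)
      expect_equal(f$flag, "ok")
    }
})

test_that("flat and no-template curves are flagged negative", {
  f <- estimate_efficiency(rep(0.5, 45))
  expect_equal(f$flag, "negative")
  expect_true(is.na(f$efficiency) && is.na(f$cq))
  expect_error(estimate_efficiency(rep(1, 10)), ">= 15")
})

test_that("zero-noise plates recover planted ratios essentially exactly", {
  sim <- generate_qpcr_plate(qpcr_sim_config(cq_noise_sd = 0, seed = 3))
  r <- aggregate_ratios(fit_qpcr_plate(sim$plate))
  sel <- r$target != "REF" & r$treatment != "control"
  truth <- sim$truth$true_ratio[cbind(r$target[sel], r$treatment[sel])]
  expect_equal(r$ratio[sel], unname(truth), tolerance = 0.02)
  # control group's own ratio is 1 by construction
  expect_true(all(r$ratio[r$treatment == "control"] == 1))
  # reference amplicon's own ratio is exactly 1
  expect_true(all(r$ratio[r$target == "REF"] == 1))
})

test_that("a planted 4-fold difference at E = 2 comes back as ratio 4", {
  tr <- matrix(c(1, 4), 1, 2, dimnames = list("T1", c("control", "treat")))
  cfg <- qpcr_sim_config(targets = "T1", treatments = c("control", "treat"),
                         true_ratio = tr, true_efficiency = c(T1 = 2),
                         reference_efficiency = 2, cq_noise_sd = 0, seed = 2)
  r <- aggregate_ratios(fit_qpcr_plate(generate_qpcr_plate(cfg)$plate))
  expect_equal(r$ratio[r$target == "T1" & r$treatment == "treat"], 4,
               tolerance = 0.01)
})

test_that("missing reference wells are an error", {
  sim <- generate_qpcr_plate(qpcr_sim_config(cq_noise_sd = 0, seed = 4))
  plate <- sim$plate
  keep <- plate$wells$role != "reference"
  plate$wells <- plate$wells[keep, ]
  plate$curves <- plate$curves[keep, ]
  expect_error(aggregate_ratios(fit_qpcr_plate(plate)), "reference wells")
})

test_that("Cq-only plates require per-target efficiencies", {
  sim <- generate_qpcr_plate(qpcr_sim_config(cq_noise_sd = 0, seed = 5))
  fit <- fit_qpcr_plate(sim$plate)
  cq_plate <- structure(list(wells = fit$wells, curves = NULL,
                             cq = fit$fits$cq, n_cycles = 45),
                        class = "qpcr_plate")
  expect_error(fit_qpcr_plate(cq_plate), "efficienc")
  eff <- c(setNames(fit$amplicons$efficiency, fit$amplicons$target))
  r <- aggregate_ratios(cq_plate, efficiencies = eff)
  sel <- r$target != "REF" & r$treatment != "control"
  truth <- sim$truth$true_ratio[cbind(r$target[sel], r$treatment[sel])]
  expect_equal(r$ratio[sel], unname(truth), tolerance = 0.02)
})

test_that("plates round-trip through long-format TSV", {
  sim <- generate_qpcr_plate(qpcr_sim_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_plate(sim$plate, path)
  back <- read_qpcr_plate(path)
  expect_equal(back$wells$well_id, sim$plate$wells$well_id)
  expect_equal(unname(back$curves), unname(sim$plate$curves), tolerance = 1e-9)
})

test_that("the two-way ANOVA matches a brute-force balanced decomposition", {
  set.seed(31)
  d <- expand.grid(cultivar = c("A", "B"), treatment = c("t1", "t2", "t3"),
                   bio_rep = 1:4, stringsAsFactors = FALSE)
  d$gene <- "G"
  d$dcq <- rnorm(nrow(d)) + ifelse(d$treatment == "t2", 1.5, 0)
  a <- anova_dcq(d)
  # naive sums of squares for a balanced layout
  gm <- mean(d$dcq)
  ssa <- sum(tapply(d$dcq, d$cultivar, function(x) length(x) * (mean(x) - gm)^2))
  ssb <- sum(tapply(d$dcq, d$treatment, function(x) length(x) * (mean(x) - gm)^2))
  cell <- aggregate(dcq ~ cultivar + treatment, d, mean)
  ssc <- 4 * sum((cell$dcq - gm)^2) - ssa - ssb
  sse <- sum((d$dcq - ave(d$dcq, d$cultivar, d$treatment))^2)
  dfe <- nrow(d) - 6
  f_oracle <- c(ssa / 1, ssb / 2, ssc / 2) / (sse / dfe)
  expect_equal(a$sum_sq, c(ssa, ssb, ssc), tolerance = 1e-10)
  expect_equal(a$F, f_oracle, tolerance = 1e-10)
  expect_equal(a$p, pf(f_oracle, c(1, 2, 2), dfe, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("the ANOVA detects a planted treatment effect and only that", {
  hit_t <- 0; hit_i <- 0
  for (seed in 1:10) {
    set.seed(seed)
    d <- expand.grid(cultivar = c("S29", "YP"),
                     treatment = c("control", "cold_6h", "cold_24h"),
                     bio_rep = 1:3, stringsAsFactors = FALSE)
    d$gene <- "G"
    d$dcq <- rnorm(nrow(d), 0, 0.3) + ifelse(d$treatment == "control", 0, 2)
    a <- anova_dcq(d)
    if (a$p[a$term == "treatment"] < 0.01) hit_t <- hit_t + 1
    if (a$p[a$term == "cultivar:treatment"] < 0.05) hit_i <- hit_i + 1
  }
  expect_gte(hit_t, 9)
  expect_lte(hit_i, 3)
  # degenerate designs are rejected
  d1 <- data.frame(gene = "G", cultivar = "A",
                   treatment = rep(c("t1", "t2"), each = 3),
                   bio_rep = 1:3, dcq = rnorm(6))
  expect_error(anova_dcq(d1), "levels")
})

test_that("noisy end-to-end plates recover ratios within 15% most of the time", {
  hits <- 0; tot <- 0
  for (s in 1:12) {
    sim <- generate_qpcr_plate(qpcr_sim_config(seed = 400 + s))
    r <- aggregate_ratios(fit_qpcr_plate(sim$plate))
    sel <- r$target != "REF" & r$treatment != "control"
    truth <- sim$truth$true_ratio[cbind(r$target[sel], r$treatment[sel])]
    hits <- hits + sum(abs(r$ratio[sel] - truth) / truth <= 0.15)
    tot <- tot + sum(sel)
  }
  expect_gte(hits / tot, 0.8)
})
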