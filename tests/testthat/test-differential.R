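random_panel <- function(n_genes = 5, n_ctrl = 4, n_stress = 4, seed = 1) {
  set.seed(seed)
  v <- matrix(2^rnorm(n_genes * (n_ctrl + n_stress), 0, 0.5),
              n_genes, n_ctrl + n_stress,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("R", seq_len(n_ctrl + n_stress))))
  structure(list(
    values = v,
    provenance = data.frame(
      replicate = colnames(v), sample_id = colnames(v), experiment_id = "E1",
      condition = rep(c("control", "stress"), c(n_ctrl, n_stress)),
      stress_type = rep(c("none", "cold"), c(n_ctrl, n_stress)))),
    class = "normalized_panel")
}

test_that("identical groups give p = 1 and label swap inverts the fold", {
  p <- random_panel()
  p$values[, 5:8] <- p$values[, 1:4]
  r <- compare_groups(p, paste0("R", 5:8), paste0("R", 1:4))
  expect_true(all(r$raw_p == 1))
  expect_true(all(abs(r$mean_fold - 1) < 1e-12))
  q <- random_panel(seed = 3)
  fwd <- compare_groups(q, paste0("R", 5:8), paste0("R", 1:4))
  rev <- compare_groups(q, paste0("R", 1:4), paste0("R", 5:8))
  expect_equal(fwd$raw_p, rev$raw_p, tolerance = 1e-12)
  expect_equal(fwd$mean_fold, 1 / rev$mean_fold, tolerance = 1e-12)
})

test_that("Welch p-values match the textbook computation", {
  # fixed example: control log2 (0, 0, 0.1), stress (3, 3.1, 2.9)
  v <- rbind(G1 = 2^c(0, 0, 0.1, 3, 3.1, 2.9))
  colnames(v) <- paste0("R", 1:6)
  p <- random_panel(1, 3, 3)
  p$values <- v
  r <- compare_groups(p, paste0("R", 4:6), paste0("R", 1:3), eps = 0)
  expect_equal(r$raw_p, welch_oracle(c(3, 3.1, 2.9), c(0, 0, 0.1)),
               tolerance = 1e-10)
  # random small layouts
  set.seed(11)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    q <- random_panel(3, ny, nx, seed = 100 + i)
    r <- compare_groups(q, paste0("R", (ny + 1):(ny + nx)), paste0("R", 1:ny),
                        eps = 0)
    for (g in 1:3) {
      lx <- log2(q$values[g, (ny + 1):(ny + nx)])
      ly <- log2(q$values[g, 1:ny])
      expect_equal(r$raw_p[g], welch_oracle(lx, ly), tolerance = 1e-10)
    }
  }
})

test_that("zero-variance guards report honestly instead of fabricating p", {
  v <- rbind(G1 = c(2, 2, 4, 4), G2 = c(2, 2, 2, 2))
  colnames(v) <- paste0("R", 1:4)
  p <- random_panel(2, 2, 2); p$values <- v
  r <- compare_groups(p, c("R3", "R4"), c("R1", "R2"))
  expect_equal(r$raw_p[2], 1)                       # identical groups
  expect_equal(r$raw_p[1], .Machine$double.xmin)    # separated, no variance
  expect_equal(r$flag[1], "zero_variance")
})

test_that("BY adjustment reproduces the step-up definition", {
  expect_equal(by_adjust(0.04), 0.04)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3), tolerance = 1e-12)
  expect_equal(by_adjust(c(0.02, 1.0)), c(0.06, 1.0), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:300) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(by_adjust(p), by_bruteforce(p), tolerance = 1e-12)
  }
  # missing entries pass through and are excluded from m
  p <- c(0.01, NA, 0.02, 0.03)
  expect_equal(by_adjust(p), c(0.055, NA, 0.055, 0.055), tolerance = 1e-12)
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BY-adjusted p is monotone in the raw p within a vector", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    a <- by_adjust(p)
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-15))
    expect_true(all(a >= p - 1e-15))
  }
})

test_that("regulation calls follow the alpha/fold rules", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   n_stress = 3, n_control = 3,
                   mean_fold = c(2.3, 0.4, 3.0, 1.0),
                   fold_arith = c(2.3, 0.4, 3.0, 1.0),
                   raw_p = c(0.001, 0.001, 0.2, 0.001),
                   flag = "", stringsAsFactors = FALSE)
  tab <- call_regulation(st, alpha = 0.05, adjust = FALSE)
  expect_equal(tab$call, c("up", "down", "ns", "ns"))
  expect_match(tab$flag[4], "degenerate")
  expect_true(all(tab$adj_p >= tab$raw_p - 1e-15 | !is.na(tab$adj_p)))
})

test_that("the summary matrix reproduces folds and marks missing genes as no-data", {
  meta <- data.frame(gene_id = c("a", "b", "c"),
                     enzyme_class = c("SOD", "SOD", "CAT"),
                     clade = c("A", "B", "A"))
  t1 <- call_regulation(
    data.frame(gene = c("a", "b", "c"), n_stress = 3, n_control = 3,
               mean_fold = c(2, 0.5, 1.1), fold_arith = c(2, 0.5, 1.1),
               raw_p = c(0.001, 0.002, 0.9), flag = ""),
    adjust = FALSE, comparison_id = "CR1")
  t2 <- call_regulation(
    data.frame(gene = c("a", "b"), n_stress = 3, n_control = 3,
               mean_fold = c(1.5, 0.8), fold_arith = c(1.5, 0.8),
               raw_p = c(0.5, 0.6), flag = ""),
    adjust = FALSE, comparison_id = "WDR1")
  s <- summarize_panel(list(CR1 = t1, WDR1 = t2), meta)
  expect_equal(dim(s$fold), c(3, 2))
  expect_equal(s$fold["a", "CR1"], 2)
  expect_equal(s$call["a", "CR1"], "up")
  expect_equal(s$call["c", "WDR1"], "no_data")
  expect_true(is.na(s$fold["c", "WDR1"]))
  # single comparison, pass-through of folds
  s1 <- summarize_panel(list(CR1 = t1), meta)
  expect_equal(unname(s1$fold[t1$gene, 1]), t1$mean_fold)
})

test_that("the global-null labelled comparison keeps false calls controlled", {
  # all-null small panels: fraction of panels with >= 1 BY call at 0.05
  hits <- 0; n_panels <- 120
  sig <- matrix(1, 8, 2, dimnames = list(NULL, c("cold", "water_deficiency")))
  for (seed in seq_len(n_panels)) {
    sim <- generate_meta_experiments(
      meta_sim_config(n_experiments = 2, n_genes = 8, platform = "intensity",
                      n_control_reps = 3, n_stress_reps = 3,
                      signature_fold = sig, signature_jitter_sd = 0,
                      seed = 5000 + seed))
    panel <- normalize_cascade(sim$studies)
    tabs <- experiment_differential(panel, alpha = 0.05)
    any_call <- any(vapply(tabs, function(t) any(t$call != "ns"), logical(1)))
    if (any_call) hits <- hits + 1
  }
  # BY controls FDR (= P(any rejection) under the global null) at 0.05;
  # binomial slack for 120 panels
  expect_lte(hits / n_panels, 0.09)
})
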