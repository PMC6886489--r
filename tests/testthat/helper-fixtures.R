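# small hand-built study: 3 genes (G1 = housekeeping) x 4 samples
tiny_study <- function(platform = "intensity",
                       m = rbind(G1 = c(5, 5, 5, 5),
                                 G2 = c(10, 20, 30, 40),
                                 G3 = c(2, 4, 6, 8)),
                       condition = c("control", "control", "stress", "stress")) {
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  expression_study(
    "EX1", platform, m,
    samples = data.frame(sample_id = colnames(m), condition = condition,
                         stress_type = ifelse(condition == "stress", "cold", "none"),
                         tissue = "leaf", time_point = "t0"),
    genes = data.frame(gene_id = rownames(m),
                       enzyme_class = c("other", "SOD", "CAT"),
                       clade = c("HK", "SOD_A", "CAT_A"),
                       housekeeping = c(TRUE, FALSE, FALSE),
                       length = c(1000, 1500, 2000)))
}

# small noiseless simulation config: two experiments, strong folds
quiet_sim_config <- function(...) {
  meta_sim_config(n_experiments = 2, n_genes = 8,
                  platform = "intensity",
                  n_control_reps = 3, n_stress_reps = 3,
                  replicate_noise_sd = 0, batch_scale_sd = 0,
                  signature_jitter_sd = 0, noisy_fraction = 0, ...)
}

# brute-force BY step-up from the definition (independent of stats::p.adjust)
by_bruteforce <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  a <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(a)))
  pmin(adj, 1)[order(o)]
}

# textbook Welch t-test p-value on two samples
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# adjusted Rand index between two labelings (oracle: mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
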