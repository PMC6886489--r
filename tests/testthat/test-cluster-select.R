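# panel with two planted groups: controls at fold ~1, stress at strong folds
two_group_panel <- function(noise_sd = 0, seed = 1) {
  sig <- matrix(1, 8, 2, dimnames = list(NULL, c("cold", "water_deficiency")))
  sig[2:4, "cold"] <- 8
  cfg <- meta_sim_config(n_experiments = 2, n_genes = 8,
                         platform = "intensity", n_control_reps = 4,
                         n_stress_reps = 4, stress_type = "cold",
                         signature_fold = sig, signature_jitter_sd = 0,
                         replicate_noise_sd = noise_sd, batch_scale_sd = 0.3,
                         seed = seed)
  sim <- generate_meta_experiments(cfg)
  list(panel = normalize_cascade(sim$studies), truth = sim$truth)
}

test_that("zero-noise two-group data is recovered exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  x <- two_group_panel(noise_sd = 0)
  model <- cluster_replicates(x$panel, n_clusters = 2)
  planted <- x$panel$provenance$condition[
    match(names(model$assignment), x$panel$provenance$replicate)]
  expect_equal(ari(model$assignment, planted), 1)
})

test_that("the partition is invariant to replicate column order", {
  x <- two_group_panel(noise_sd = 0.3, seed = 7)
  m1 <- cluster_replicates(x$panel, n_clusters = 3)
  perm <- sample(ncol(x$panel$values))
  shuffled <- x$panel
  shuffled$values <- shuffled$values[, perm]
  shuffled$provenance <- shuffled$provenance[perm, ]
  m2 <- cluster_replicates(shuffled, n_clusters = 3)
  a1 <- m1$assignment[names(m2$assignment)]
  expect_equal(ari(a1, m2$assignment), 1)
})

test_that("identical replicate profiles are rejected as degenerate", {
  x <- two_group_panel(noise_sd = 0)
  flat <- x$panel
  flat$values[] <- 1
  expect_error(cluster_replicates(flat, 2), "degenerate|identical")
})

test_that("merge heights are non-decreasing and k is validated", {
  x <- two_group_panel(noise_sd = 0.2, seed = 3)
  model <- cluster_replicates(x$panel, n_clusters = 4)
  expect_true(all(diff(model$linkage$height) >= -1e-12))
  expect_error(cluster_replicates(x$panel, n_clusters = 999), "exceeds")
})

test_that("PCA explained variance sums to 1 and a rank-1 matrix loads on PC1", {
  x <- two_group_panel(noise_sd = 0.2, seed = 5)
  p <- pca_profiles(x$panel)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  # rank-1 panel (after centering): replicate profiles on a single line
  r1 <- x$panel
  v <- seq_len(nrow(r1$values))
  load <- seq_len(ncol(r1$values))
  r1$values <- exp(outer(v, load) / 20)  # log2-space rank-1
  p1 <- pca_profiles(r1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-9)
  # full-dimension scores reproduce pairwise distances
  d0 <- dist(aosmeta:::panel_profile_matrix(x$panel))
  d1 <- dist(p$scores)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("cluster labels follow the majority rules", {
  x <- two_group_panel(noise_sd = 0)
  model <- cluster_replicates(x$panel, n_clusters = 2)
  prov <- x$panel$provenance
  # craft assignments to exercise each labeling rule
  fake <- model
  n <- length(fake$assignment)
  ctrl_idx <- which(prov$condition == "control")
  stress_idx <- which(prov$condition == "stress")
  # cluster 1: 5 controls + 1 stress -> control; cluster 2: stress only -> CR
  a <- rep(2L, n)
  a[ctrl_idx[1:5]] <- 1L
  a[stress_idx[1]] <- 1L
  names(a) <- prov$replicate
  fake$assignment <- a; fake$n_clusters <- 2L
  lab <- label_clusters(fake, x$panel)
  expect_equal(lab$cluster_types, c("control", "CR"))
  # tie between stress types with no controls -> mixed
  mixed_prov <- prov
  mixed_prov$stress_type[stress_idx[1:2]] <- "water_deficiency"
  fake2 <- fake
  a2 <- rep(1L, n); a2[stress_idx[1:4]] <- 2L
  names(a2) <- prov$replicate
  fake2$assignment <- a2
  panel2 <- x$panel; panel2$provenance <- mixed_prov
  lab2 <- label_clusters(fake2, panel2)
  expect_equal(lab2$cluster_types[2], "mixed")
})

test_that("the exclusion rule is strict: > 50% excludes, exactly 50% retains", {
  x <- two_group_panel(noise_sd = 0)
  prov <- x$panel$provenance
  model <- cluster_replicates(x$panel, n_clusters = 2)
  # construct an assignment: cluster 1 holds all controls, cluster 2 the rest
  build <- function(n_in_control) {
    a <- ifelse(prov$condition == "control", 1L, 2L)
    stress_e1 <- which(prov$condition == "stress")
    a[stress_e1[seq_len(n_in_control)]] <- 1L
    names(a) <- prov$replicate
    m <- model; m$assignment <- a; m$n_clusters <- 2L; m$cluster_types <- NULL
    m
  }
  # 8 stress replicates total (both experiments have 4 each); move replicates
  # of experiment E01 only
  prov_e1 <- prov$experiment_id[prov$condition == "stress"]
  # 2 of 4 in a control cluster -> 0.5, retained
  f_half <- filter_experiments(build(2), x$panel)
  expect_false(f_half$report$excluded[f_half$report$experiment_id == "E01"])
  expect_equal(f_half$report$fraction[f_half$report$experiment_id == "E01"], 0.5)
  # 3 of 4 -> 0.75, excluded
  f_over <- filter_experiments(build(3), x$panel)
  expect_true(f_over$report$excluded[f_over$report$experiment_id == "E01"])
})

test_that("moving a stress replicate into a control cluster never rescues an experiment", {
  x <- two_group_panel(noise_sd = 0)
  prov <- x$panel$provenance
  model <- cluster_replicates(x$panel, n_clusters = 2)
  stress_e1 <- which(prov$condition == "stress" & prov$experiment_id == "E01")
  excluded_before <- FALSE
  for (k in 0:4) {
    a <- ifelse(prov$condition == "control", 1L, 2L)
    a[stress_e1[seq_len(k)]] <- 1L
    names(a) <- prov$replicate
    m <- model; m$assignment <- a
    f <- filter_experiments(m, x$panel)
    excluded_now <- f$report$excluded[f$report$experiment_id == "E01"]
    expect_false(excluded_before && !excluded_now)
    excluded_before <- excluded_now
  }
})

test_that("planted no-response experiments are exactly the excluded set", {
  skip_if_not_installed("mclust")
  ok <- 0
  for (seed in 1:4) {
    sim <- generate_meta_experiments(meta_sim_config(noisy_fraction = 0.3,
                                                     seed = 100 + seed))
    panel <- normalize_cascade(sim$studies)
    model <- cluster_replicates(panel, n_clusters = "auto")
    f <- filter_experiments(model, panel)
    excluded <- f$report$experiment_id[f$report$excluded]
    if (setequal(excluded, sim$truth$noisy_experiments)) ok <- ok + 1
  }
  expect_gte(ok, 3)
})
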