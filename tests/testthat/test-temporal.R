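make_profiles <- function(values) {
  structure(list(values = values, timepoints = seq_len(ncol(values)),
                 row_info = data.frame(gene_id = rownames(values),
                                       genotype = "WT",
                                       stringsAsFactors = FALSE),
                 scaling = "none"),
            class = "temporal_profiles")
}

test_that("stage means average the group's samples per timepoint", {
  counts <- rbind(g1 = c(2, 4, 10, 1), g2 = c(6, 6, 8, 3))
  colnames(counts) <- paste0("s", 1:4)
  samples <- data.frame(sample_id = paste0("s", 1:4), genotype = "WT",
                        condition = c("tumor", "tumor", "tumor", "tumor_free"),
                        timepoint_weeks = c(6, 6, 8, 6), replicate = c(1, 2, 1, 1))
  p <- stage_means(counts, samples, c("g1", "g2"), "WT", "tumor")
  expect_equal(unname(p$values["g1", ]), c(3, 10))  # mean(2,4) then identity
  expect_equal(unname(p$values["g2", ]), c(6, 8))
  expect_error(stage_means(counts, samples, "missing", "WT"),
               class = "cistraj_data_error")
  # brute-force oracle on the fixture
  fx <- default_fixture()
  norm <- normalize_counts(fx$counts)
  genes <- rownames(norm)[1:20]
  got <- stage_means(norm, fx$counts$samples, genes, "KO", "tumor")
  s <- fx$counts$samples
  for (tp_i in seq_along(got$timepoints)) {
    tp <- got$timepoints[tp_i]
    j <- which(s$genotype == "KO" & s$condition == "tumor" &
                 s$timepoint_weeks == tp)
    for (g in genes)
      expect_equal(got$values[g, tp_i], mean(norm[g, j]))
  }
})

test_that("k-means recovers the exact optimum on a 1-D instance", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(paste0("p", 1:4), "t1"))
  fit <- kmeans_cluster(make_profiles(x), K = 2, seed = 1, scaling = "none",
                        relabel_archetypes = FALSE)
  expect_equal(fit$total_within_ss, 0.01, tolerance = 1e-12)
  expect_equal(unname(fit$assignments["p1"]), unname(fit$assignments["p2"]))
  expect_equal(unname(fit$assignments["p3"]), unname(fit$assignments["p4"]))
  expect_false(fit$assignments["p1"] == fit$assignments["p3"])

  fit_n <- kmeans_cluster(make_profiles(x), K = 4, seed = 1, scaling = "none",
                          relabel_archetypes = FALSE)
  expect_equal(fit_n$total_within_ss, 0)
  expect_error(kmeans_cluster(make_profiles(x), K = 5, scaling = "none"),
               class = "cistraj_config_error")
  expect_error(kmeans_cluster(make_profiles(x), K = 0, scaling = "none"),
               class = "cistraj_config_error")
})

test_that("duplicating every point keeps centroids and doubles the SS", {
  set.seed(8)
  x <- matrix(rnorm(18), 6, 3)
  rownames(x) <- paste0("g", 1:6)
  colnames(x) <- paste0("t", 1:3)
  fit1 <- kmeans_cluster(make_profiles(x), K = 2, seed = 4, scaling = "none",
                         relabel_archetypes = FALSE)
  x2 <- rbind(x, x)
  rownames(x2) <- paste0("g", 1:12)
  fit2 <- kmeans_cluster(make_profiles(x2), K = 2, seed = 4, scaling = "none",
                         relabel_archetypes = FALSE)
  expect_equal(fit2$total_within_ss, 2 * fit1$total_within_ss,
               tolerance = 1e-9)
  expect_equal(sort(fit2$centroids[, 1]), sort(fit1$centroids[, 1]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("restarted Lloyd matches stats::kmeans at its best and is deterministic", {
  set.seed(21)
  x <- matrix(rnorm(60 * 3), 60, 3,
              dimnames = list(sprintf("g%02d", 1:60), paste0("t", 1:3)))
  p <- make_profiles(x)
  fit1 <- kmeans_cluster(p, K = 3, seed = 5, scaling = "none",
                         relabel_archetypes = FALSE)
  fit2 <- kmeans_cluster(p, K = 3, seed = 5, scaling = "none",
                         relabel_archetypes = FALSE)
  expect_identical(fit1$assignments, fit2$assignments)
  ref <- stats::kmeans(x, centers = 3, nstart = 50, iter.max = 100)
  expect_lte(fit1$total_within_ss, ref$tot.withinss + 1e-8)
  expect_equal(fit1$total_within_ss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("the stored within-SS is recomputable from assignments and centroids", {
  fx <- default_fixture()
  norm <- normalize_counts(prefilter(fx$counts))
  genes <- rownames(norm)[1:80]
  prof <- stage_means(norm, fx$counts$samples, genes, "WT", "tumor")
  fit <- kmeans_cluster(prof, K = 3, seed = 2)
  expect_equal(recompute_within_ss(fit, prof), fit$total_within_ss,
               tolerance = 1e-9 * max(1, fit$total_within_ss))
})

test_that("elbow curve matches exhaustive optima and never increases on tiny instances", {
  set.seed(12)
  x <- matrix(rnorm(8 * 2), 8, 2,
              dimnames = list(paste0("g", 1:8), c("t1", "t2")))
  p <- make_profiles(x)
  curve <- elbow_curve(p, K_range = 1:4, seed = 3, n_init = 60,
                       scaling = "none")
  expect_true(all(diff(curve) <= 1e-9))
  for (K in 1:4)
    expect_equal(unname(curve[as.character(K)]), exhaustive_kmeans_ss(x, K),
                 tolerance = 1e-8, label = paste("K =", K))
  curve2 <- elbow_curve(p, K_range = 1:4, seed = 3, n_init = 60,
                        scaling = "none")
  expect_identical(curve, curve2)
  # K = n drives the SS to zero
  full <- elbow_curve(make_profiles(x[1:4, ]), K_range = 4, seed = 3,
                      scaling = "none")
  expect_equal(unname(full), 0)
})

test_that("archetype relabeling is stable under row shuffling", {
  fx <- default_fixture()
  norm <- normalize_counts(prefilter(fx$counts))
  tr <- fx$truth$de_genes
  genes <- tr$gene_id[tr$scope != "ko_only"]
  genes <- genes[genes %in% rownames(norm)]
  prof <- build_joint_profiles(norm, fx$counts$samples, genes, character(0))
  fit <- kmeans_cluster(prof, K = 3, seed = 6)
  set.seed(10)
  perm <- sample(nrow(prof$values))
  prof2 <- prof
  prof2$values <- prof$values[perm, ]
  prof2$row_info <- prof$row_info[perm, ]
  fit2 <- kmeans_cluster(prof2, K = 3, seed = 6)
  common <- names(fit$assignments)
  agree <- mean(fit$assignments[common] == fit2$assignments[common])
  expect_gte(agree, 0.98)  # archetype names, not arbitrary k-means labels
})

test_that("exclusivity partition enumerates WT-only, KO-only and shared genes", {
  fit <- structure(list(
    K = 1,
    assignments = stats::setNames(rep(1L, 4), c("WT:a", "WT:b", "WT:c", "KO:c")),
    row_info = data.frame(gene_id = c("a", "b", "c", "c"),
                          genotype = c("WT", "WT", "WT", "KO"))),
    class = "cluster_fit")
  got <- exclusivity_partition(fit, 1, wt_input = c("a", "b", "c"),
                               ko_input = "c")
  expect_equal(got$wt_only, c("a", "b"))
  expect_equal(got$shared, "c")
  expect_length(got$ko_only, 0)

  same <- exclusivity_partition(fit, 1, wt_input = c("a", "b", "c"),
                                ko_input = c("a", "b", "c"))
  expect_length(same$wt_only, 0)
})

test_that("planted WT-exclusive rising genes are recovered as WT-only", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  wt <- call_degs(nb_wald_test(cm, "WT", 6, size_factors_all = sf), 2, 0.1)$gene_ids
  ko <- call_degs(nb_wald_test(cm, "KO", 8, size_factors_all = sf), 2, 0.1)$gene_ids
  prof <- build_joint_profiles(norm, cm$samples, wt, ko)
  fit <- kmeans_cluster(prof, K = 3, seed = 7)
  part <- exclusivity_partition(fit, 2, wt, ko)
  tr <- fx$truth$de_genes
  planted_wt_only_c2 <- tr$gene_id[tr$cluster == 2 & tr$scope == "wt_only"]
  candidates <- intersect(planted_wt_only_c2, wt)  # those that entered
  in_cluster2 <- names(fit$assignments)[fit$assignments == 2]
  recovered <- intersect(candidates, part$wt_only)
  expect_gte(length(recovered) / length(candidates), 0.85)
  # cis-pair genes specifically land in the WT-only rising cluster
  cis <- intersect(c(fx$truth$cis_pairs$lncRNA_id, fx$truth$cis_pairs$pcg_id),
                   candidates)
  expect_gte(mean(cis %in% part$wt_only), 0.8)
})
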