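test_that("prefilter keeps genes at the inclusive boundary", {
  counts <- matrix(c(4, 5, 5, 5, 5, 6), 3, 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- toy_counts(counts)  # totals 9, 10, 11
  expect_equal(rownames(prefilter(cm, 10)$counts), c("b", "c"))
  expect_equal(prefilter(cm, 0)$counts, cm$counts)
  expect_warning(prefilter(cm, 1000), "every gene")
})

test_that("prefilter equals the brute-force row-sum filter on random counts", {
  set.seed(5)
  counts <- matrix(rpois(200 * 6, 3), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  cm <- toy_counts(counts)
  kept <- rownames(prefilter(cm, 10)$counts)
  manual <- rownames(counts)[apply(counts, 1, sum) >= 10]
  expect_identical(kept, manual)
})

test_that("size factors follow the median-of-ratios definition", {
  c1 <- c(10, 20, 40, 80)
  counts <- cbind(s1 = c1, s2 = 2 * c1)
  rownames(counts) <- paste0("g", 1:4)
  sf <- size_factors(toy_counts(counts))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(s1 = c1, s2 = c1, s3 = c1)
  rownames(same) <- paste0("g", 1:4)
  expect_equal(unname(size_factors(toy_counts(same))), rep(1, 3))

  single <- matrix(c1, dimnames = list(paste0("g", 1:4), "s1"))
  expect_equal(unname(size_factors(single)), 1)
})

test_that("scaling one sample scales its factor and leaves normalized values fixed", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  scaled <- cm$counts
  scaled[, 3] <- scaled[, 3] * 4
  sf2 <- size_factors(scaled)
  # scaling one library by c scales its factor by c relative to the others
  # (the geometric-mean reference shifts all factors by the common c^(1/n))
  rel <- sf2 / sf
  expect_equal(unname(rel[3] / rel[1]), 4, tolerance = 1e-10)
  expect_equal(unname(rel[-3] / rel[1]), rep(1, length(rel) - 1),
               tolerance = 1e-10)
  n1 <- normalize_counts(scaled, sf2)
  n0 <- normalize_counts(cm$counts, sf)
  expect_equal(n1 * rel[1], n0, tolerance = 1e-10)
})

test_that("size factors agree with DESeq2's median-of-ratios estimates", {
  skip_if_not_installed("DESeq2")
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = round(cm$counts),
      colData = data.frame(row.names = cm$samples$sample_id,
                           condition = factor(cm$samples$condition)),
      design = ~condition)
    dds <- DESeq2::estimateSizeFactors(dds)
  })
  expect_equal(unname(sf), unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))  # monotone in sorted order
})

test_that("a gene identical across conditions gives log2fc 0 and p 1", {
  counts <- matrix(7, 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  counts[2, ] <- c(50, 50, 50, 50, 50)
  cm <- toy_counts(counts, condition = c("tumor", "tumor", "tumor",
                                         "tumor_free", "tumor_free"))
  de <- nb_wald_test(cm, "WT", 6)
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$pvalue, rep(1, 4))
})

test_that("all-zero genes are reported untested", {
  counts <- rbind(g1 = c(0, 0, 0, 0, 0), g2 = c(9, 7, 8, 3, 2))
  colnames(counts) <- paste0("s", 1:5)
  cm <- toy_counts(counts, condition = c(rep("tumor", 3), rep("tumor_free", 2)))
  de <- nb_wald_test(cm, "WT", 6)
  g1 <- de[de$gene_id == "g1", ]
  expect_equal(g1$log2fc, 0)
  expect_equal(g1$pvalue, 1)
  expect_true(is.na(g1$padj))
})

test_that("contrasts with too few replicates are rejected", {
  counts <- matrix(5, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  cm <- toy_counts(counts, condition = c("tumor", "tumor", "tumor_free"))
  expect_error(nb_wald_test(cm, "WT", 6), "2 replicates",
               class = "cistraj_config_error")
  expect_error(nb_wald_test(cm, "KO", 6), class = "cistraj_config_error")
})

test_that("DEG calls are invariant to sample column order", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  de1 <- nb_wald_test(cm, "WT", 6)
  set.seed(9)
  perm <- sample(ncol(cm$counts))
  cmp <- count_matrix(cm$counts[, perm], cm$samples[perm, ])
  de2 <- nb_wald_test(cmp, "WT", 6)
  s1 <- call_degs(de1, 1.5, 0.1)
  s2 <- call_degs(de2, 1.5, 0.1)
  expect_setequal(s1$gene_ids, s2$gene_ids)
  expect_equal(de1$log2fc, de2$log2fc[match(de1$gene_id, de2$gene_id)])
})

test_that("DEG thresholds use strict inequalities on the stated scales", {
  de <- structure(data.frame(gene_id = c("a", "b", "c"),
                             base_mean = 10, log2fc = c(0.60, 2, -2),
                             se = 0.1, wald_stat = 1,
                             pvalue = c(0.001, 0.001, 0.001),
                             padj = c(0.05, 0.1, 0.02)),
                  class = c("de_result", "data.frame"))
  got <- call_degs(de, 1.5, 0.1)
  expect_true("a" %in% got$gene_ids)          # 0.60 > log2(1.5) = 0.585
  expect_false("b" %in% got$gene_ids)         # padj == fdr_max excluded
  expect_true("c" %in% got$gene_ids)
  expect_equal(call_degs(de, 1.5, 0.1, direction = "up")$gene_ids, "a")
  expect_equal(call_degs(de, 1.5, 0.1, direction = "down")$gene_ids, "c")
  # caption-style log2 threshold: |log2fc| > 1.5 drops gene a
  expect_setequal(call_degs(de, 1.5, 0.1, lfc_scale = "log2")$gene_ids, "c")
  empty <- de[0, ]
  expect_length(call_degs(empty, 1.5, 0.1)$gene_ids, 0)
})

test_that("Venn partition matches enumeration and brute force", {
  got <- deg_set_algebra(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"),
                              C = "g3"))
  expect_equal(got$regions[["A&B&C"]], "g3")
  expect_length(got$union, 3)
  expect_equal(got$regions[["A"]], "g1")
  expect_equal(got$regions[["A&B"]], "g2")

  disjoint <- deg_set_algebra(list(A = c("x", "y"), B = c("z")))
  expect_length(disjoint$regions[["A&B"]], 0)

  set.seed(3)
  sets <- lapply(1:3, function(i) sample(sprintf("g%02d", 1:50), 20))
  names(sets) <- c("t6", "t8", "t10")
  got <- deg_set_algebra(sets)
  for (g in got$union) {
    member <- vapply(sets, function(s) g %in% s, TRUE)
    key <- paste(names(sets)[member], collapse = "&")
    expect_true(g %in% got$regions[[key]])
  }
  expect_equal(sum(got$counts), length(got$union))
})

test_that("PCA separates planted groups and handles degenerate requests", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  norm <- normalize_counts(cm)
  # the strongly planted groups (WT tumor vs WT tumor-free) are linearly
  # separable on PC1; KO tumors are intentionally delayed and weaker
  wt <- cm$samples$genotype == "WT"
  pc <- pca_samples(norm[, wt], n_top_genes = 500, n_components = 2)
  lab <- cm$samples$condition[wt]
  m1 <- mean(pc$coords[lab == "tumor", 1])
  m2 <- mean(pc$coords[lab == "tumor_free", 1])
  thr <- (m1 + m2) / 2
  side <- sign(pc$coords[, 1] - thr) == sign(m1 - thr)
  expect_true(all(side[lab == "tumor"]))
  expect_true(all(!side[lab == "tumor_free"]))

  dup <- norm[, c(1, 1, 2, 3)]
  colnames(dup) <- paste0("d", 1:4)
  pc2 <- pca_samples(dup, 100, 2)
  expect_equal(pc2$coords[1, ], pc2$coords[2, ], tolerance = 1e-8)

  expect_warning(pca_samples(norm[, 1:4], 50, 10), "clamped")
})
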