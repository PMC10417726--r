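test_that("biotype classification partitions a DEG set", {
  ann <- gene_annotation(data.frame(
    gene_id = c("p1", "l1", "p2", "o1"), symbol = c("p1", "l1", "p2", "o1"),
    chrom = "chr1", start = c(0, 1000, 2000, 3000),
    end = c(500, 1500, 2500, 3500), strand = "+",
    biotype = c("protein_coding", "lncRNA", "protein_coding", "other")))
  got <- classify_biotypes(c("p1", "l1", "p2", "o1"), ann)
  expect_equal(got$lncRNA, "l1")
  expect_setequal(got$protein_coding, c("p1", "p2"))
  expect_equal(got$other, "o1")
  empty <- classify_biotypes(character(0), ann)
  expect_length(unlist(empty), 0)
  expect_warning(miss <- classify_biotypes(c("p1", "ghost"), ann), "ghost")
  expect_equal(miss$other, "ghost")
})

test_that("window candidacy follows inclusive span-gap interval arithmetic", {
  ann <- gene_annotation(data.frame(
    gene_id = c("lnc", "near", "far", "edge", "othchr"),
    symbol = c("lnc", "near", "far", "edge", "othchr"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1000000, 1400000, 1600000, 1501000, 1400000),
    end = c(1001000, 1402000, 1602000, 1503000, 1402000),
    strand = "+",
    biotype = c("lncRNA", rep("protein_coding", 4))))
  got <- window_candidates("lnc", ann, window_bp = 500000)
  expect_true("near" %in% got$pcg_id)               # gap 399000
  expect_false("far" %in% got$pcg_id)               # gap 599000
  expect_true("edge" %in% got$pcg_id)               # gap exactly 500000
  expect_equal(got$distance_bp[got$pcg_id == "edge"], 500000)
  expect_false("othchr" %in% got$pcg_id)
  # overlapping spans have distance zero
  ann2 <- gene_annotation(data.frame(
    gene_id = c("lnc", "ov"), symbol = c("lnc", "ov"), chrom = "chr1",
    start = c(1000, 1500), end = c(2000, 2500), strand = "+",
    biotype = c("lncRNA", "protein_coding")))
  expect_equal(window_candidates("lnc", ann2)$distance_bp, 0)
})

test_that("windowed search equals brute-force all-pairs filtering on 500 genes", {
  fx <- generate_fixture(sim_config(n_genes = 500, n_chromosomes = 2,
                                    chrom_length_bp = 4e6,
                                    n_planted_per_cluster = c(5, 10, 5),
                                    n_cis_pairs = 3, seed = 77))
  ann <- fx$annotation
  lncs <- ann$gene_id[ann$biotype == "lncRNA"]
  pcgs <- ann$gene_id[ann$biotype == "protein_coding"]
  want <- brute_window_pairs(ann, lncs, pcgs, 500000)
  got <- do.call(rbind, lapply(lncs, function(l) {
    cand <- window_candidates(l, ann, 500000)
    if (nrow(cand)) data.frame(lncRNA_id = l, pcg_id = cand$pcg_id,
                               distance_bp = cand$distance_bp)
  }))
  key <- function(d) sort(paste(d$lncRNA_id, d$pcg_id, d$distance_bp))
  expect_identical(key(got), key(want))
  expect_gt(nrow(got), 0)
})

test_that("window distances agree with GenomicRanges gaps", {
  skip_if_not_installed("GenomicRanges")
  fx <- default_fixture()
  ann <- fx$annotation
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1, ann$end))
  names(gr) <- ann$gene_id
  lncs <- head(ann$gene_id[ann$biotype == "lncRNA"], 30)
  for (l in lncs) {
    cand <- window_candidates(l, ann, 500000)
    for (i in seq_len(nrow(cand)))
      expect_equal(cand$distance_bp[i],
                   GenomicRanges::distance(gr[l], gr[cand$pcg_id[i]]))
  }
})

test_that("Pearson correlation and its t-based p match the closed form", {
  perfect <- pearson_with_p(1:5, 2 * (1:5))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$pvalue, 0)
  anti <- pearson_with_p(1:5, -(1:5))
  expect_equal(anti$r, -1)
  expect_equal(anti$pvalue, 0)

  worked <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(worked$r, 0.8, tolerance = 1e-12)
  t_stat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(worked$pvalue, 2 * stats::pt(-t_stat, 2), tolerance = 1e-12)
  expect_equal(worked$pvalue, 0.2, tolerance = 1e-6)
  expect_false(worked$pvalue < 0.01)  # meets r >= 0.8 yet fails the p gate

  expect_error(pearson_with_p(1:2, 1:2), class = "cistraj_data_error")
  expect_error(pearson_with_p(rep(1, 5), 1:5),
               class = "cistraj_constant_error")
})

test_that("the screen recovers planted pairs and sorts the report by r", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  degs <- call_degs(nb_wald_test(cm, "WT", 6, size_factors_all = sf), 2, 0.1)
  bio <- classify_biotypes(degs$gene_ids, fx$annotation)
  scr <- screen_pairs(norm, cm$samples, bio$lncRNA, bio$protein_coding,
                      fx$annotation, screen_config())
  planted <- paste(fx$truth$cis_pairs$lncRNA_id, fx$truth$cis_pairs$pcg_id)
  reported <- paste(scr$lncRNA_id, scr$pcg_id)[scr$reported]
  expect_true(all(planted %in% reported))
  rep_r <- scr$pearson_r[scr$reported]
  expect_true(all(diff(rep_r) <= 1e-12))
  expect_true(all(scr$passes_window))
  expect_true(all(scr$pearson_r[scr$reported] >= 0.8))
  expect_true(all(scr$pvalue[scr$reported] < 0.01))
})

test_that("screen flags respect threshold monotonicity and degenerate r_min", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  degs <- call_degs(nb_wald_test(cm, "WT", 6, size_factors_all = sf), 2, 0.1)
  bio <- classify_biotypes(degs$gene_ids, fx$annotation)
  base <- screen_pairs(norm, cm$samples, bio$lncRNA, bio$protein_coding,
                       fx$annotation, screen_config())
  wide <- screen_pairs(norm, cm$samples, bio$lncRNA, bio$protein_coding,
                       fx$annotation, screen_config(window_bp = 1e6,
                                                    r_min = 0.5))
  key <- function(s) paste(s$lncRNA_id, s$pcg_id)
  expect_true(all(key(base)[base$reported] %in% key(wide)[wide$reported]))

  none <- screen_pairs(norm, cm$samples, bio$lncRNA, bio$protein_coding,
                       fx$annotation, screen_config(r_min = 1.01))
  expect_equal(sum(none$reported), 0)
  expect_gt(nrow(none), 0)

  # shuffling samples consistently leaves the screen unchanged
  set.seed(3)
  perm <- sample(ncol(norm))
  shuf <- screen_pairs(norm[, perm], cm$samples[perm, ], bio$lncRNA,
                       bio$protein_coding, fx$annotation, screen_config())
  expect_equal(as.data.frame(base), as.data.frame(shuf))
})

test_that("under a global null the p < 0.01 rate stays near nominal", {
  # independent genes placed densely so many window pairs are evaluated
  set.seed(19)
  n_lnc <- 40; n_pcg <- 160
  ids <- c(sprintf("L%03d", 1:n_lnc), sprintf("P%03d", 1:n_pcg))
  pos <- sort(sample(0:3e6, n_lnc + n_pcg)) * 1L
  ann <- gene_annotation(data.frame(
    gene_id = ids[order(ids)], symbol = ids[order(ids)], chrom = "chr1",
    start = pos, end = pos + 100L, strand = "+",
    biotype = c(rep("lncRNA", n_lnc), rep("protein_coding", n_pcg))))
  n_samp <- 20
  samples <- data.frame(sample_id = paste0("s", 1:n_samp), genotype = "WT",
                        condition = "tumor",
                        timepoint_weeks = rep(c(6, 8, 10, 12), 5),
                        replicate = rep(1:5, each = 4))
  expr <- matrix(rpois(length(ids) * n_samp, 60), length(ids), n_samp,
                 dimnames = list(sort(ids), samples$sample_id))
  scr <- screen_pairs(expr, samples, sprintf("L%03d", 1:n_lnc),
                      sprintf("P%03d", 1:n_pcg), ann,
                      screen_config(window_bp = 500000))
  expect_gt(nrow(scr), 200)
  expect_lte(mean(scr$pvalue < 0.01), 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(scr)))
})

test_that("pair tables round-trip with the documented columns", {
  fx <- default_fixture()
  cm <- prefilter(fx$counts)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  degs <- call_degs(nb_wald_test(cm, "WT", 6, size_factors_all = sf), 2, 0.1)
  bio <- classify_biotypes(degs$gene_ids, fx$annotation)
  scr <- screen_pairs(norm, cm$samples, bio$lncRNA, bio$protein_coding,
                      fx$annotation, screen_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(scr, path)
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(names(back), c("lncRNA", "protein_coding_gene", "PCC",
                              "p_value", "distance_bp", "n_samples"))
  expect_equal(nrow(back), sum(scr$reported))
  expect_equal(back$PCC, signif(scr$pearson_r[scr$reported], 6))

  empty <- scr[scr$pearson_r > 2, ]
  attr(empty, "config") <- attr(scr, "config")
  class(empty) <- class(scr)
  write_pair_table(empty, path)
  expect_equal(nrow(utils::read.delim(path, comment.char = "#")), 0)
})
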