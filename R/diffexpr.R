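#' Prefilter low-count genes
#'
#' Keeps genes whose total count across all samples is at least
#' `min_total` (boundary inclusive: a gene with exactly `min_total` reads is
#' retained). Gene order is preserved.
#'
#' @param cm a [count_matrix()].
#' @param min_total minimum total reads (default 10).
#' @return the filtered [count_matrix()].
#' @export
prefilter <- function(cm, min_total = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) warning("prefilter removed every gene")
  ex <- attr(cm, "exon_counts")
  out <- count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
  attr(out, "exon_counts") <- ex
  out
}

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median over genes of
#' `count / geometric_mean(gene across samples)`, taken over genes with a
#' positive geometric mean (i.e. genes with no zero count). A single sample
#' gets factor 1 by convention.
#'
#' @param cm a [count_matrix()] or plain count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  gm <- geometric_mean_rows(m)
  ok <- gm > 0
  if (!any(ok))
    ct_data_error("no gene with positive counts in every sample; cannot compute size factors")
  sf <- apply(m[ok, , drop = FALSE] / gm[ok], 2, stats::median)
  if (any(sf <= 0))
    ct_data_error("non-positive size factor; too many zero counts")
  sf
}

#' Normalized counts
#'
#' @param cm a [count_matrix()] or matrix.
#' @param sf size factors; computed with [size_factors()] when omitted.
#' @return matrix of counts divided column-wise by the size factors.
#' @export
normalize_counts <- function(cm, sf = NULL) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  sf <- sf %||% size_factors(m)
  sweep(m, 2, sf, "/")
}

# Mean-binned dispersion trend. Per-gene method-of-moments estimates at
# n = 3 vs 2 are far too noisy to plug into a Wald statistic (the test
# would be badly anti-conservative), so genes are binned by base mean
# (~50+ genes per bin) and each gene receives its bin's average
# method-of-moments alpha. With a mean-dispersion trend this is accurate
# and nearly noise-free; gene-specific departures from the trend are not
# modeled (see the methods vignette).
dispersion_trend <- function(base_mean, a_raw, dispersion_min = 1e-8,
                             dispersion_max = 10) {
  ok <- is.finite(a_raw) & base_mean > 0
  fallback <- if (any(ok)) mean(a_raw[ok]) else dispersion_min
  if (sum(ok) < 50)
    return(rep(min(max(fallback, dispersion_min), dispersion_max),
               length(a_raw)))
  nb <- min(25L, max(1L, floor(sum(ok) / 50)))
  breaks <- unique(stats::quantile(base_mean[ok],
                                   probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(base_mean, breaks, include.lowest = TRUE)
  bin_mean <- tapply(a_raw[ok], bin[ok], mean)
  out <- as.numeric(bin_mean[as.character(bin)])
  out[is.na(out)] <- fallback
  pmin(pmax(out, dispersion_min), dispersion_max)
}

#' Negative-binomial Wald test for one stage-matched contrast
#'
#' Tests tumor vs age-matched tumor-free samples within one genotype and
#' timepoint. Per gene: condition means are estimated with size-factor
#' offsets (`sum(counts) / sum(size_factors)`); the NB dispersion
#' (`var = mu + alpha mu^2`) is estimated by method of moments on normalized
#' counts within each condition, pooled by degrees of freedom and then
#' stabilized across genes by a mean-binned dispersion trend (at two or
#' three replicates a per-gene plug-in estimate is hopeless; the trend makes
#' the Wald reference honest) and clamped to `[1e-8, 10]`;
#' `log2fc = log2((mu_tumor + eps)/(mu_free + eps))` with `eps = 0.5`
#' normalized counts; the Wald statistic is `log2fc / se` with the
#' delta-method standard error and a two-sided standard-normal p-value.
#' Benjamini-Hochberg adjusted p-values are computed over all tested genes;
#' all-zero genes get `log2fc = 0`, `p = 1` and no adjusted p.
#'
#' @param cm a [count_matrix()].
#' @param genotype `"WT"` or `"KO"`.
#' @param timepoint timepoint in weeks.
#' @param size_factors_all optional size factors for all samples of `cm`
#'   (e.g. computed once on the full matrix); computed on `cm` when omitted.
#' @param eps pseudo-normalized-count added in the fold change (default 0.5).
#' @param dispersion_min,dispersion_max clamp for the dispersion estimate.
#' @return A `de_result` data.frame: gene_id, base_mean, log2fc, se,
#'   wald_stat, pvalue, padj; attribute `contrast = c(genotype, timepoint)`.
#' @export
nb_wald_test <- function(cm, genotype, timepoint, size_factors_all = NULL,
                         eps = 0.5, dispersion_min = 1e-8,
                         dispersion_max = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  sf_all <- size_factors_all %||% size_factors(cm)
  sel <- cm$samples$genotype == genotype &
    cm$samples$timepoint_weeks == as.integer(timepoint)
  if (!any(sel))
    ct_config_error(sprintf("no samples for contrast (%s, week %s)", genotype, timepoint))
  idx_t <- which(sel & cm$samples$condition == "tumor")
  idx_f <- which(sel & cm$samples$condition == "tumor_free")
  if (length(idx_t) < 2 || length(idx_f) < 2)
    ct_config_error(sprintf(
      "contrast (%s, week %s) needs >= 2 replicates per condition (found %d tumor, %d tumor-free)",
      genotype, timepoint, length(idx_t), length(idx_f)))

  counts <- cm$counts
  sf <- sf_all[colnames(counts)]
  q <- sweep(counts, 2, sf, "/")
  qT <- q[, idx_t, drop = FALSE]; qF <- q[, idx_f, drop = FALSE]
  nT <- length(idx_t); nF <- length(idx_f)
  mT <- rowMeans(qT); mF <- rowMeans(qF)
  vT <- rowSums((qT - mT)^2) / (nT - 1)
  vF <- rowSums((qF - mF)^2) / (nF - 1)
  # per-condition MoM dispersion (normalized scale), pooled by df,
  # then stabilized by the mean-binned trend
  cT <- mean(1 / sf[idx_t]); cF <- mean(1 / sf[idx_f])
  aT <- (vT - mT * cT) / mT^2
  aF <- (vF - mF * cF) / mF^2
  aT[!is.finite(aT)] <- NA; aF[!is.finite(aF)] <- NA
  wT <- (nT - 1) * (!is.na(aT)); wF <- (nF - 1) * (!is.na(aF))
  a_raw <- (ifelse(is.na(aT), 0, aT) * (nT - 1) +
              ifelse(is.na(aF), 0, aF) * (nF - 1)) / (wT + wF)
  base_mean_used <- rowMeans(q[, c(idx_t, idx_f), drop = FALSE])
  alpha <- dispersion_trend(base_mean_used, a_raw, dispersion_min,
                            dispersion_max)

  muT <- rowSums(counts[, idx_t, drop = FALSE]) / sum(sf[idx_t])
  muF <- rowSums(counts[, idx_f, drop = FALSE]) / sum(sf[idx_f])
  log2fc <- log2((muT + eps) / (muF + eps))

  var_mu <- function(mu, idx) {
    s <- sf[idx]
    (mu * sum(s) + alpha * mu^2 * sum(s^2)) / sum(s)^2
  }
  se <- log2(exp(1)) * sqrt(var_mu(muT, idx_t) / (muT + eps)^2 +
                              var_mu(muF, idx_f) / (muF + eps)^2)
  wald <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(wald))

  allzero <- rowSums(counts[, c(idx_t, idx_f), drop = FALSE]) == 0
  log2fc[allzero] <- 0; wald[allzero] <- 0; pvalue[allzero] <- 1
  se[allzero] <- NA_real_

  padj <- rep(NA_real_, nrow(counts))
  tested <- !allzero
  padj[tested] <- bh_adjust(pvalue[tested])
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = unname(rowMeans(q[, c(idx_t, idx_f), drop = FALSE])),
                    log2fc = unname(log2fc), se = unname(se),
                    wald_stat = unname(wald), pvalue = unname(pvalue),
                    padj = unname(padj), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            contrast = list(genotype = genotype,
                            timepoint_weeks = as.integer(timepoint)),
            n_samples = c(tumor = nT, tumor_free = nF),
            dispersion = stats::setNames(alpha, rownames(counts)))
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_result: %s week %d, %d genes, %d with padj < 0.1\n",
              ct$genotype, ct$timepoint_weeks, nrow(x),
              sum(x$padj < 0.1, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), returned in
#' input order; `NA` p-values stay `NA`.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is included iff `padj < fdr_max` (strict) and its fold change
#' exceeds the threshold (strict). With `lfc_scale = "linear"` (default) a
#' fold-change threshold f means `|log2fc| > log2(f)`; with
#' `lfc_scale = "log2"` the threshold is applied to `log2fc` directly.
#' Direction `"up"`/`"down"` applies the signed inequality.
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param fold_change_min fold-change threshold (> 1).
#' @param fdr_max adjusted-p threshold.
#' @param direction one of `"both"`, `"up"`, `"down"`.
#' @param lfc_scale `"linear"` or `"log2"` (see above).
#' @return A `deg_set`: list with `label`, `direction`, `gene_ids`,
#'   `thresholds`.
#' @export
call_degs <- function(de, fold_change_min = 1.5, fdr_max = 0.1,
                      direction = c("both", "up", "down"),
                      lfc_scale = c("linear", "log2")) {
  direction <- match.arg(direction)
  lfc_scale <- match.arg(lfc_scale)
  thr <- if (lfc_scale == "linear") log2(fold_change_min) else fold_change_min
  if (thr <= 0) ct_config_error("fold_change_min must exceed 1 (linear scale)")
  ok_p <- !is.na(de$padj) & de$padj < fdr_max
  ok_fc <- switch(direction,
                  both = abs(de$log2fc) > thr,
                  up = de$log2fc > thr,
                  down = de$log2fc < -thr)
  ct <- attr(de, "contrast")
  label <- if (!is.null(ct)) sprintf("%s_wk%d", ct$genotype, ct$timepoint_weeks)
  else "contrast"
  structure(list(label = label, direction = direction,
                 gene_ids = de$gene_id[ok_p & ok_fc],
                 thresholds = c(fold_change_min = fold_change_min,
                                fdr_max = fdr_max)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set %s (%s): %d genes (FC > %g, FDR < %g)\n", x$label,
              x$direction, length(x$gene_ids), x$thresholds["fold_change_min"],
              x$thresholds["fdr_max"]))
  invisible(x)
}

#' Venn partition of up to three DEG sets
#'
#' @param sets named list of `deg_set` objects (or plain character vectors),
#'   typically keyed by timepoint.
#' @return list with `union` (all members), `counts` (named region sizes)
#'   and `regions` (named membership lists). Region names join set names
#'   with `&`; exclusive regions carry the single set name.
#' @export
deg_set_algebra <- function(sets) {
  if (length(sets) < 1 || length(sets) > 3)
    ct_config_error("deg_set_algebra supports 1 to 3 sets")
  members <- lapply(sets, function(s)
    if (inherits(s, "deg_set")) s$gene_ids else as.character(s))
  nm <- names(members) %||% paste0("set", seq_along(members))
  universe <- sort(unique(unlist(members)))
  inset <- vapply(members, function(m) universe %in% m,
                  logical(length(universe)))
  if (length(universe) == 1) inset <- matrix(inset, nrow = 1)
  regions <- list()
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(members)))
  for (i in seq_len(nrow(patterns))) {
    pat <- unlist(patterns[i, ])
    if (!any(pat)) next
    key <- paste(nm[pat], collapse = "&")
    hit <- apply(inset, 1, function(row) identical(unname(row), unname(pat)))
    regions[[key]] <- universe[hit]
  }
  list(union = universe,
       counts = vapply(regions, length, 1L),
       regions = regions)
}

#' Principal component analysis of samples
#'
#' Transforms normalized counts as `log2(x + 1)`, restricts to the
#' `n_top_genes` most variable genes, centers genes and projects samples
#' onto the leading principal components.
#'
#' @param normalized gene x sample matrix of normalized counts.
#' @param n_top_genes number of most-variable genes retained (default 500).
#' @param n_components number of components (clamped to n_samples - 1 with a
#'   warning).
#' @return list with `coords` (samples x components) and
#'   `explained_variance` (fractions).
#' @export
pca_samples <- function(normalized, n_top_genes = 500, n_components = 2) {
  lm2 <- log2(normalized + 1)
  max_comp <- min(ncol(lm2) - 1, nrow(lm2))
  if (n_components > max_comp) {
    warning(sprintf("n_components clamped from %d to %d", n_components, max_comp))
    n_components <- max_comp
  }
  v <- apply(lm2, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(lm2)))]
  x <- t(lm2[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = expl[seq_len(n_components)])
}
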