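#' Screen configuration for the cis-regulation screen
#'
#' Operational definition of a candidate cis-regulating pair: a lncRNA and a
#' protein-coding gene on the same chromosome within `window_bp` (span gap,
#' boundary inclusive), whose expression correlates at `r >= r_min` with
#' correlation `p < p_max`.
#'
#' @param window_bp genomic window (default 500000).
#' @param r_min minimum Pearson correlation (default 0.80).
#' @param p_max maximum correlation p-value (default 0.01).
#' @param r_mode `"signed"` (default; Table-style positive co-expression) or
#'   `"absolute"` (`|r| >= r_min`).
#' @param distance_anchor `"span_gap"` (default; 0 when spans overlap),
#'   `"start_to_start"`, or `"tss_to_tss"` (strand-aware).
#' @param genotype,condition,timepoints sample scope entering the
#'   correlation; `NULL` means no restriction. The default correlates over
#'   every sample of the experiment, the scope implied by the degrees of
#'   freedom behind published pair p-values of this analysis design.
#' @return A `screen_config` list.
#' @export
screen_config <- function(window_bp = 500000, r_min = 0.80, p_max = 0.01,
                          r_mode = c("signed", "absolute"),
                          distance_anchor = c("span_gap", "start_to_start",
                                              "tss_to_tss"),
                          genotype = NULL, condition = NULL,
                          timepoints = NULL) {
  r_mode <- match.arg(r_mode)
  distance_anchor <- match.arg(distance_anchor)
  if (window_bp <= 0) ct_config_error("window_bp must be positive")
  # r_min > 1 is allowed and simply yields an empty report
  if (r_min <= 0) ct_config_error("r_min must be positive")
  if (p_max <= 0 || p_max >= 1) ct_config_error("p_max must be in (0, 1)")
  structure(list(window_bp = window_bp, r_min = r_min, p_max = p_max,
                 r_mode = r_mode, distance_anchor = distance_anchor,
                 genotype = genotype, condition = condition,
                 timepoints = timepoints),
            class = "screen_config")
}

#' Split a DEG set by annotation biotype
#'
#' @param gene_ids character vector (or a `deg_set`).
#' @param annotation a [gene_annotation()].
#' @return list of character vectors `lncRNA`, `protein_coding`, `other`;
#'   genes missing from the annotation are reported in `other` with a
#'   warning.
#' @export
classify_biotypes <- function(gene_ids, annotation) {
  if (inherits(gene_ids, "deg_set")) gene_ids <- gene_ids$gene_ids
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx))
    warning(paste0("genes absent from annotation treated as 'other': ",
                   paste(gene_ids[is.na(idx)], collapse = ", ")))
  bt <- ifelse(is.na(idx), "other", annotation$biotype[idx])
  list(lncRNA = gene_ids[bt == "lncRNA"],
       protein_coding = gene_ids[bt == "protein_coding"],
       other = gene_ids[!bt %in% c("lncRNA", "protein_coding")])
}

# Pairwise genomic distance between one gene and a pool, by anchor.
genomic_distance <- function(g, pool, anchor = "span_gap") {
  switch(anchor,
         span_gap = pmax(0, pmax(g$start, pool$start) - pmin(g$end, pool$end)),
         start_to_start = abs(g$start - pool$start),
         tss_to_tss = {
           tss1 <- if (g$strand == "+") g$start else g$end - 1L
           tss2 <- ifelse(pool$strand == "+", pool$start, pool$end - 1L)
           abs(tss1 - tss2)
         })
}

#' Protein-coding genes within a window of a lncRNA
#'
#' Same-chromosome candidates whose distance to the lncRNA (by the
#' configured anchor; span gap by default, 0 for overlapping spans) is at
#' most `window_bp`, boundary inclusive. Strand is ignored for the default
#' anchor.
#'
#' @param lnc_id lncRNA gene id.
#' @param annotation a [gene_annotation()]; the candidate pool is its
#'   protein-coding genes (restrict beforehand to apply DE filters).
#' @param window_bp window size (default 500000).
#' @param distance_anchor see [screen_config()].
#' @return data.frame: pcg_id, chrom, distance_bp.
#' @export
window_candidates <- function(lnc_id, annotation, window_bp = 500000,
                              distance_anchor = "span_gap") {
  gi <- match(lnc_id, annotation$gene_id)
  if (is.na(gi)) ct_data_error(paste0("lncRNA not in annotation: ", lnc_id))
  g <- annotation[gi, ]
  pool <- annotation[annotation$biotype == "protein_coding" &
                       annotation$chrom == g$chrom &
                       annotation$gene_id != lnc_id, , drop = FALSE]
  if (!nrow(pool))
    return(data.frame(pcg_id = character(0), chrom = character(0),
                      distance_bp = numeric(0)))
  d <- genomic_distance(g, pool, distance_anchor)
  keep <- d <= window_bp
  data.frame(pcg_id = pool$gene_id[keep], chrom = pool$chrom[keep],
             distance_bp = as.numeric(d[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pearson correlation with t-based p-value
#'
#' `r` is the sample Pearson correlation; the two-sided p-value comes from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (`stats::cor.test`); `r = +/-1` gives `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `pvalue`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) ct_data_error("x and y must have equal length")
  if (length(x) < 3) ct_data_error("correlation needs n >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ct_stop("correlation undefined for a constant vector",
            "cistraj_constant_error")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, pvalue = p, n = length(x))
}

#' Cis lncRNA / protein-coding pair screen
#'
#' For every DE lncRNA, finds DE protein-coding genes within the genomic
#' window and tests the Pearson correlation of their `log2(normalized + 1)`
#' expression over the configured sample scope (all WT tumor samples pooled
#' over timepoints by default). Every evaluated pair is returned with its
#' window/correlation/p flags; the report subset (`attr(, "report")` or
#' rows with `reported = TRUE`) passes all three, sorted by descending r.
#' Pairs with a constant expression vector are skipped with a warning.
#'
#' @param normalized gene x sample matrix of normalized counts.
#' @param samples sample sheet aligned with its columns.
#' @param lnc_degs,pcg_degs DE lncRNA and protein-coding gene ids.
#' @param annotation a [gene_annotation()].
#' @param config a [screen_config()].
#' @return A `cis_screen` data.frame of evaluated pairs: lncRNA_id, pcg_id,
#'   chrom, distance_bp, pearson_r, pvalue, n_samples, passes_window,
#'   passes_r, passes_p, reported.
#' @export
screen_pairs <- function(normalized, samples, lnc_degs, pcg_degs, annotation,
                         config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  samples <- validate_samplesheet(samples)
  if (!identical(colnames(normalized), samples$sample_id))
    ct_data_error("normalized matrix columns must match the sample sheet")
  missing <- setdiff(c(lnc_degs, pcg_degs), rownames(normalized))
  if (length(missing))
    ct_data_error(paste0("DEG ids absent from expression matrix: ",
                         paste(missing, collapse = ", ")))
  scope <- rep(TRUE, nrow(samples))
  if (!is.null(config$genotype))
    scope <- scope & samples$genotype == config$genotype
  if (!is.null(config$condition))
    scope <- scope & samples$condition == config$condition
  if (!is.null(config$timepoints))
    scope <- scope & samples$timepoint_weeks %in% config$timepoints
  if (sum(scope) < 3)
    ct_config_error(sprintf("sample scope selects %d samples; need >= 3", sum(scope)))
  expr <- log2(normalized[, scope, drop = FALSE] + 1)

  lnc_degs <- intersect(lnc_degs, annotation$gene_id)
  sub_ann <- annotation[annotation$gene_id %in% c(lnc_degs, pcg_degs), ,
                        drop = FALSE]
  rows <- list()
  for (lnc in lnc_degs) {
    cand <- window_candidates(lnc, sub_ann, window_bp = config$window_bp,
                              distance_anchor = config$distance_anchor)
    cand <- cand[cand$pcg_id %in% pcg_degs, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      pcg <- cand$pcg_id[i]
      res <- tryCatch(pearson_with_p(expr[lnc, ], expr[pcg, ]),
                      cistraj_constant_error = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf("skipping pair %s-%s: constant expression", lnc, pcg))
        next
      }
      pass_r <- if (config$r_mode == "signed") res$r >= config$r_min
      else abs(res$r) >= config$r_min
      rows[[length(rows) + 1]] <- data.frame(
        lncRNA_id = lnc, pcg_id = pcg, chrom = cand$chrom[i],
        distance_bp = cand$distance_bp[i], pearson_r = res$r,
        pvalue = res$pvalue, n_samples = res$n,
        passes_window = cand$distance_bp[i] <= config$window_bp,
        passes_r = pass_r, passes_p = res$pvalue < config$p_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(lncRNA_id = character(0), pcg_id = character(0),
                  chrom = character(0), distance_bp = numeric(0),
                  pearson_r = numeric(0), pvalue = numeric(0),
                  n_samples = integer(0), passes_window = logical(0),
                  passes_r = logical(0), passes_p = logical(0))
  out$reported <- out$passes_window & out$passes_r & out$passes_p
  out <- out[order(-out$reported, -out$pearson_r, out$lncRNA_id, out$pcg_id), ]
  rownames(out) <- NULL
  structure(out, class = c("cis_screen", "data.frame"), config = config)
}

#' @export
print.cis_screen <- function(x, ...) {
  cat(sprintf("cis_screen: %d evaluated pair(s), %d reported\n",
              nrow(x), sum(x$reported)))
  if (sum(x$reported))
    print(as.data.frame(x[x$reported,
                          c("lncRNA_id", "pcg_id", "pearson_r", "pvalue",
                            "distance_bp")]))
  invisible(x)
}

#' Write the reported pair table
#'
#' One row per reported pair, columns exactly: lncRNA,
#' protein_coding_gene, PCC, p_value, distance_bp, n_samples.
#'
#' @param screen a `cis_screen` from [screen_pairs()].
#' @param path output TSV path.
#' @export
write_pair_table <- function(screen, path) {
  stopifnot(inherits(screen, "cis_screen"))
  cfg <- attr(screen, "config")
  rep <- screen[screen$reported, , drop = FALSE]
  df <- data.frame(lncRNA = rep$lncRNA_id,
                   protein_coding_gene = rep$pcg_id,
                   PCC = signif(rep$pearson_r, 6),
                   p_value = signif(rep$pvalue, 6),
                   distance_bp = rep$distance_bp,
                   n_samples = rep$n_samples, stringsAsFactors = FALSE)
  write_tsv_commented(df, path,
                      params = list(window_bp = cfg$window_bp, r_min = cfg$r_min,
                                    p_max = cfg$p_max, r_mode = cfg$r_mode,
                                    distance_anchor = cfg$distance_anchor))
  invisible(path)
}
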