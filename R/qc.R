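#' Cre-lox reporter recombination check
#'
#' Sorted GFP+ epithelial cells should show high GFP and near-zero mTd
#' reporter counts. A sample passes when
#' `(gfp + 1) / (mtd + 1) >= min_ratio` (pseudocount 1 guards against
#' division by zero). Samples with neither reporter detected additionally
#' get `no_signal = TRUE`.
#'
#' @param cm a [count_matrix()] containing both reporter rows.
#' @param gfp_id,mtd_id reporter feature ids.
#' @param min_ratio minimum GFP/mTd ratio to pass (default 10).
#' @return data.frame: sample_id, gfp_count, mtd_count, ratio, pass,
#'   no_signal.
#' @export
recombination_check <- function(cm, gfp_id = "GFP", mtd_id = "mTd",
                                min_ratio = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  for (id in c(gfp_id, mtd_id))
    if (!id %in% rownames(cm$counts))
      ct_config_error(paste0("spike-in row absent from count matrix: ", id))
  gfp <- cm$counts[gfp_id, ]
  mtd <- cm$counts[mtd_id, ]
  ratio <- (gfp + 1) / (mtd + 1)
  data.frame(sample_id = cm$samples$sample_id,
             gfp_count = as.integer(gfp), mtd_count = as.integer(mtd),
             ratio = unname(ratio), pass = unname(ratio >= min_ratio),
             no_signal = unname(gfp == 0 & mtd == 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Floxed-exon knockout concordance check
#'
#' In a clean knockout the loxP-flanked exon carries no reads. A KO sample
#' is concordant when `exon_count / (gene_count + 1) <= max_exon_fraction`;
#' a flagged KO sample is a recombination escapee. WT samples are reported
#' as not applicable (`NA`).
#'
#' @param exon_counts per-sample counts for the targeted exon feature.
#' @param gene_counts per-sample counts for the parent gene.
#' @param samples sample sheet aligned with the count vectors.
#' @param max_exon_fraction maximum tolerated exon/gene ratio (default 0.01).
#' @return data.frame: sample_id, exon_count, gene_count, exon_fraction,
#'   ko_concordant (logical, NA for WT).
#' @export
floxed_exon_check <- function(exon_counts, gene_counts, samples,
                              max_exon_fraction = 0.01) {
  samples <- validate_samplesheet(samples)
  if (length(exon_counts) != nrow(samples) ||
      length(gene_counts) != nrow(samples))
    ct_data_error("exon/gene count vectors must align with the sample sheet")
  frac <- exon_counts / (gene_counts + 1)
  conc <- ifelse(samples$genotype == "KO", frac <= max_exon_fraction, NA)
  data.frame(sample_id = samples$sample_id,
             exon_count = as.integer(exon_counts),
             gene_count = as.integer(gene_counts),
             exon_fraction = unname(frac), ko_concordant = unname(conc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes detected per sample
#'
#' @param cm a [count_matrix()].
#' @param min_count minimum count for a gene to count as detected.
#' @return named integer vector, one entry per sample.
#' @export
genes_detected <- function(cm, min_count = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  colSums(cm$counts >= min_count)
}

#' Full per-sample QC report
#'
#' Combines the recombination check, the floxed-exon concordance check and
#' the genes-detected summary into one table.
#'
#' @param cm a [count_matrix()]; its `"exon_counts"` attribute (or
#'   `exon_counts` argument) supplies the floxed-exon feature.
#' @param gfp_id,mtd_id,min_ratio see [recombination_check()].
#' @param floxed_gene parent gene of the floxed exon.
#' @param exon_counts optional 1-row matrix of floxed-exon counts; defaults
#'   to the attribute carried by simulated matrices.
#' @param max_exon_fraction see [floxed_exon_check()].
#' @param min_count see [genes_detected()].
#' @return A `qc_report` data.frame.
#' @export
qc_report <- function(cm, gfp_id = "GFP", mtd_id = "mTd", min_ratio = 10,
                      floxed_gene = "Pthlh_like", exon_counts = NULL,
                      max_exon_fraction = 0.01, min_count = 1) {
  rec <- recombination_check(cm, gfp_id, mtd_id, min_ratio)
  ex <- exon_counts %||% attr(cm, "exon_counts")
  out <- data.frame(rec,
                    genes_detected = as.integer(genes_detected(cm, min_count)),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "pass"] <- "recombination_ok"
  if (!is.null(ex) && floxed_gene %in% rownames(cm$counts)) {
    fx <- floxed_exon_check(as.numeric(ex[1, cm$samples$sample_id]),
                            cm$counts[floxed_gene, ], cm$samples,
                            max_exon_fraction)
    out$exon4_count <- fx$exon_count
    out$floxed_gene_count <- fx$gene_count
    out$ko_concordant <- fx$ko_concordant
  }
  structure(out, class = c("qc_report", "data.frame"),
            params = list(min_ratio = min_ratio,
                          max_exon_fraction = max_exon_fraction,
                          min_count = min_count))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples; recombination pass %d/%d",
              nrow(x), sum(x$recombination_ok), nrow(x)))
  if ("ko_concordant" %in% names(x)) {
    ko <- x$ko_concordant[!is.na(x$ko_concordant)]
    cat(sprintf("; KO floxed-exon concordant %d/%d", sum(ko), length(ko)))
    esc <- x$sample_id[!is.na(x$ko_concordant) & !x$ko_concordant]
    if (length(esc)) cat("\n  escapee sample(s): ", paste(esc, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
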