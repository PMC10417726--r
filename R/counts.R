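#' Count matrices with sample metadata
#'
#' A `count_matrix` bundles a gene-by-sample matrix of non-negative integer
#' counts with its sample sheet. The sample sheet has exactly the columns
#' `sample_id`, `genotype` (WT/KO), `condition` (tumor/tumor_free),
#' `timepoint_weeks` and `replicate`; the matrix columns are kept in sample
#' sheet order.
#'
#' @param counts numeric matrix, genes x samples, with dimnames.
#' @param samples data.frame sample sheet (see above).
#' @return A validated `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- validate_samplesheet(samples)
  # a zero-gene matrix is valid (R drops the row dimnames on empty subsets)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    ct_data_error("count matrix must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    ct_data_error("duplicate gene ids in count matrix")
  if (!identical(colnames(counts), samples$sample_id))
    ct_data_error("count matrix columns must match sample sheet order; use read_counts() to reconcile")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    ct_data_error(sprintf(
      "counts must be non-negative integers; offending entry gene=%s sample=%s value=%s",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "double"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_samplesheet <- function(samples) {
  required <- c("sample_id", "genotype", "condition", "timepoint_weeks", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    ct_data_error(paste0("sample sheet missing columns: ", paste(missing, collapse = ", ")))
  samples <- as.data.frame(samples)[required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$timepoint_weeks <- as.integer(samples$timepoint_weeks)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    ct_data_error("duplicate sample_id in sample sheet")
  if (!all(samples$genotype %in% c("WT", "KO")))
    ct_data_error("genotype must be WT or KO")
  if (!all(samples$condition %in% c("tumor", "tumor_free")))
    ct_data_error("condition must be tumor or tumor_free")
  if (!all(samples$timepoint_weeks %in% c(6L, 8L, 10L, 12L)))
    ct_data_error("timepoint_weeks must be one of 6, 8, 10, 12")
  if (any(samples$replicate < 1L)) ct_data_error("replicate must be >= 1")
  key <- paste(samples$genotype, samples$condition, samples$timepoint_weeks,
               samples$replicate)
  if (anyDuplicated(key))
    ct_data_error("duplicate (genotype, condition, timepoint, replicate) in sample sheet")
  rownames(samples) <- NULL
  samples
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(genotype = x$samples$genotype, condition = x$samples$condition))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' Row (gene) and column (sample) subsetting; the sample sheet follows the
#' column subset.
#'
#' @param x a [count_matrix()].
#' @param i,j gene and sample indices.
#' @param ... ignored.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE], x$samples[j, , drop = FALSE])
}

#' Read a sample sheet TSV
#'
#' @param path tab-separated file with columns `sample_id`, `genotype`,
#'   `condition`, `timepoint_weeks`, `replicate`.
#' @return validated sample sheet data.frame.
#' @export
read_samplesheet <- function(path) {
  if (!file.exists(path)) ct_parse_error(paste0("sample sheet not found: ", path))
  validate_samplesheet(read_tsv_commented(path))
}

#' Read a count table plus sample sheet
#'
#' Accepts either a TSV (header row of sample ids, first column of gene ids)
#' or a MatrixMarket triplet file (`.mtx`) with `.rownames`/`.colnames`
#' sidecar files. Columns are reconciled against the sample sheet and
#' reordered to sheet order; integrality and non-negativity are enforced.
#'
#' @param counts_path path to the counts TSV or MTX file.
#' @param samplesheet_path path to the sample sheet TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samplesheet_path) {
  samples <- read_samplesheet(samplesheet_path)
  if (!file.exists(counts_path))
    ct_parse_error(paste0("counts file not found: ", counts_path))
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    rn <- readLines(paste0(counts_path, ".rownames"))
    cn <- readLines(paste0(counts_path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      ct_parse_error("MTX sidecar row/column name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    tab <- read_tsv_commented(counts_path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
  }
  extra <- setdiff(colnames(m), samples$sample_id)
  absent <- setdiff(samples$sample_id, colnames(m))
  if (length(extra) || length(absent))
    ct_data_error(paste0(
      "counts and sample sheet disagree;",
      if (length(extra)) paste0(" in counts only: ", paste(extra, collapse = ", ")),
      if (length(absent)) paste0(" in sheet only: ", paste(absent, collapse = ", "))))
  m <- m[, samples$sample_id, drop = FALSE]
  count_matrix(m, samples)
}

#' Write a count matrix and its sample sheet
#'
#' @param cm a [count_matrix()].
#' @param counts_path output TSV path for the counts.
#' @param samplesheet_path optional output TSV path for the sample sheet.
#' @export
write_counts <- function(cm, counts_path, samplesheet_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samplesheet_path))
    utils::write.table(cm$samples, samplesheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}
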