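#' Gene annotation tables
#'
#' A `gene_annotation` is a data.frame with one row per gene and columns
#' `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`, `biotype`.
#' Coordinates are 0-based half-open (`start` inclusive, `end` exclusive),
#' converted from the 1-based inclusive GTF convention at the I/O boundary so
#' that interval arithmetic (the 500 kb cis window in particular) is
#' unambiguous. Exon intervals, when present, are stored in the `"exons"`
#' attribute as a data.frame (`gene_id`, `start`, `end`) on the same
#' convention.
#'
#' @param genes data.frame with the columns listed above.
#' @param exons optional data.frame with columns `gene_id`, `start`, `end`.
#' @return A validated `gene_annotation` object.
#' @export
gene_annotation <- function(genes, exons = NULL) {
  required <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    ct_data_error(paste0("annotation is missing columns: ",
                         paste(missing, collapse = ", ")))
  genes <- as.data.frame(genes)[required]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    ct_data_error(paste0("duplicate gene_id in annotation: ",
                         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                               collapse = ", ")))
  if (any(genes$start < 0)) ct_data_error("gene start coordinates must be >= 0")
  if (any(genes$start >= genes$end))
    ct_data_error(paste0("start must be < end; offending gene(s): ",
                         paste(genes$gene_id[genes$start >= genes$end], collapse = ", ")))
  if (!all(genes$strand %in% c("+", "-")))
    ct_data_error("strand must be '+' or '-'")
  bad_bt <- !genes$biotype %in% c("protein_coding", "lncRNA", "spike_in", "other")
  if (any(bad_bt))
    ct_data_error(paste0("unknown biotype(s): ",
                         paste(unique(genes$biotype[bad_bt]), collapse = ", ")))
  if (!is.null(exons) && nrow(exons)) {
    exons <- as.data.frame(exons)[c("gene_id", "start", "end")]
    exons$start <- as.integer(exons$start)
    exons$end <- as.integer(exons$end)
    unknown <- setdiff(exons$gene_id, genes$gene_id)
    if (length(unknown))
      ct_data_error(paste0("exons reference unknown gene(s): ",
                           paste(unknown, collapse = ", ")))
    idx <- match(exons$gene_id, genes$gene_id)
    if (any(exons$start < genes$start[idx]) || any(exons$end > genes$end[idx]))
      ct_data_error("exon intervals must lie within their gene span")
    by_gene <- split(exons[c("start", "end")], exons$gene_id)
    for (gid in names(by_gene)) {
      e <- by_gene[[gid]][order(by_gene[[gid]]$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        ct_data_error(paste0("overlapping exons in gene ", gid))
    }
  }
  structure(genes, exons = exons, class = c("gene_annotation", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(table(biotype = x$biotype))
  invisible(x)
}

# Pull one attribute value out of a GTF attribute column. Returns NA where
# the key is absent.
gtf_attribute <- function(attrs, key) {
  pattern <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regmatches(attrs, regexec(pattern, attrs))
  vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
}

map_biotype <- function(raw) {
  out <- rep("other", length(raw))
  out[raw %in% c("protein_coding")] <- "protein_coding"
  out[raw %in% c("lncRNA", "lincRNA")] <- "lncRNA"
  out[raw %in% c("spike_in")] <- "spike_in"
  out
}

#' Read a GTF file into a gene annotation
#'
#' Parses GTF v2.2 `gene` features (with `exon` features attached to their
#' gene) and converts 1-based inclusive coordinates to the package's 0-based
#' half-open convention. The biotype is taken from the `gene_biotype`
#' attribute, falling back to `gene_type`; values other than
#' `protein_coding`/`lncRNA`/`spike_in` map to `"other"`.
#'
#' @param path path to a tab-separated GTF file.
#' @return A [gene_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) ct_parse_error(paste0("GTF file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    ct_parse_error(sprintf("malformed GTF record at line %d: expected 9 tab-separated fields, found %d",
                           line_no[which(nf != 9)[1]], nf[which(nf != 9)[1]]))
  rec <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(rec) <- c("chrom", "source", "feature", "start", "end",
                  "score", "strand", "frame", "attributes")
  rec$line <- line_no

  genes <- rec[rec$feature == "gene", ]
  if (!nrow(genes)) ct_parse_error("no gene features found in GTF")
  gid <- gtf_attribute(genes$attributes, "gene_id")
  if (anyNA(gid))
    ct_parse_error(sprintf("missing gene_id attribute at line %d",
                           genes$line[which(is.na(gid))[1]]))
  if (anyDuplicated(gid))
    ct_data_error(paste0("duplicate gene_id in GTF: ",
                         paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  bt <- gtf_attribute(genes$attributes, "gene_biotype")
  bt2 <- gtf_attribute(genes$attributes, "gene_type")
  bt[is.na(bt)] <- bt2[is.na(bt)]
  sym <- gtf_attribute(genes$attributes, "gene_name")
  sym[is.na(sym)] <- gid[is.na(sym)]

  gene_df <- data.frame(
    gene_id = gid, symbol = sym, chrom = genes$chrom,
    start = as.integer(genes$start) - 1L, end = as.integer(genes$end),
    strand = genes$strand, biotype = map_biotype(bt),
    stringsAsFactors = FALSE
  )

  ex <- rec[rec$feature == "exon", ]
  exons <- NULL
  if (nrow(ex)) {
    egid <- gtf_attribute(ex$attributes, "gene_id")
    if (anyNA(egid))
      ct_parse_error(sprintf("missing gene_id attribute at line %d",
                             ex$line[which(is.na(egid))[1]]))
    exons <- data.frame(gene_id = egid,
                        start = as.integer(ex$start) - 1L,
                        end = as.integer(ex$end),
                        stringsAsFactors = FALSE)
    exons <- exons[exons$gene_id %in% gene_df$gene_id, ]
    if (!nrow(exons)) exons <- NULL
  }
  gene_annotation(gene_df, exons)
}

#' Write a gene annotation to GTF
#'
#' Inverse of [read_gtf()]: converts the internal 0-based half-open
#' coordinates back to 1-based inclusive GTF records.
#'
#' @param annotation a [gene_annotation()].
#' @param path output file path.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  exons <- attr(annotation, "exons")
  lines <- character(0)
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     g$gene_id, g$symbol, g$biotype)
    lines <- c(lines, paste(g$chrom, "cistraj", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", attrs, sep = "\t"))
    if (!is.null(exons)) {
      e <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      if (nrow(e)) {
        e <- e[order(e$start), , drop = FALSE]
        for (j in seq_len(nrow(e))) {
          ea <- sprintf('gene_id "%s"; exon_number "%d";', g$gene_id, j)
          lines <- c(lines, paste(g$chrom, "cistraj", "exon", e$start[j] + 1L,
                                  e$end[j], ".", g$strand, ".", ea, sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
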