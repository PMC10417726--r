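#' Read a GMT gene-set collection
#'
#' GMT lines are tab-separated: set name, description, then member symbols.
#' Duplicate members within a set are dropped (first occurrence kept);
#' identical members may appear in several sets.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of `list(name, description,
#'   genes)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ct_parse_error(paste0("GMT file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      ct_parse_error(sprintf("malformed GMT record at line %d: expected >= 3 tab-separated fields, found %d",
                             i, length(f)))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      ct_parse_error(sprintf("gene set '%s' at line %d has no members", f[1], i))
    sets[[f[1]]] <- list(name = f[1], description = f[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x),
              if (length(x)) paste(range(vapply(x, function(s) length(s$genes), 1L)),
                                   collapse = "-") else "-"))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection` as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(unname(lines), path)
  invisible(path)
}
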