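# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
ct_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cistraj_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ct_config_error <- function(msg) ct_stop(msg, "cistraj_config_error")
ct_parse_error  <- function(msg) ct_stop(msg, "cistraj_parse_error")
ct_data_error   <- function(msg) ct_stop(msg, "cistraj_data_error")

# Derive a per-stage seed from a global one; offsets keep streams disjoint.
# Kept below 2^31 so it is always a valid R integer.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000L + offset) %% 2147483647)
}

# Write a data.frame as TSV with a single comment line recording parameters.
write_tsv_commented <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(params)) {
    kv <- paste(names(params), vapply(params, format_param, ""), sep = "=")
    writeLines(paste0("# cistraj ", paste(kv, collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

format_param <- function(x) {
  if (is.numeric(x)) paste(format(x, digits = 15, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  else paste(as.character(x), collapse = ",")
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

geometric_mean_rows <- function(m) {
  # 0 whenever a row contains a zero (log of 0), matching median-of-ratios use
  out <- exp(rowMeans(log(m)))
  out[!is.finite(out)] <- 0
  out
}
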