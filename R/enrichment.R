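#' Rank genes for preranked enrichment
#'
#' Orders genes by the chosen metric, descending; ties are broken by
#' lexicographic gene id so the ranking is deterministic and invariant to
#' input row order.
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param metric `"wald_stat"` (default; variance-aware) or
#'   `"signed_log2fc"`.
#' @return A `ranked_list` data.frame: `gene_id`, `metric`, ordered.
#' @export
rank_genes <- function(de, metric = c("wald_stat", "signed_log2fc")) {
  metric <- match.arg(metric)
  vals <- switch(metric, wald_stat = de$wald_stat, signed_log2fc = de$log2fc)
  if (anyDuplicated(de$gene_id))
    ct_data_error(paste0("duplicate gene ids in ranking input: ",
                         paste(unique(de$gene_id[duplicated(de$gene_id)]),
                               collapse = ", ")))
  ord <- order(-vals, de$gene_id)
  structure(data.frame(gene_id = de$gene_id[ord], metric = vals[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"), metric_name = metric)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: a set member ("hit") increments the running sum by
#' `|metric|^weight / sum_hits(|metric|^weight)`; a non-member decrements by
#' `1 / (N - N_hits)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed). With `weight_exponent = 0`
#' this is the classic unweighted Kolmogorov-Smirnov statistic.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of member symbols.
#' @param weight_exponent metric weight (default 1).
#' @return list with `es` and the full `running` sum vector.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hits <- ranked$gene_id %in% gene_set
  if (!any(hits)) {
    warning("gene set has no member in the ranked list; skipping")
    return(list(es = NA_real_, running = NULL))
  }
  if (all(hits))
    ct_data_error("gene set covers the entire ranked list; miss decrement undefined")
  w <- abs(ranked$metric)^weight_exponent
  wh <- sum(w[hits])
  inc <- if (wh > 0) w / wh else rep(1 / sum(hits), length(w))
  step <- ifelse(hits, inc, -1 / (length(hits) - sum(hits)))
  running <- cumsum(step)
  es <- signed_extreme(running)
  list(es = es, running = running)
}

# Signed maximal deviation from zero; an exact +/- tie resolves to the
# positive side so the statistic is stable under reorderings of the
# floating-point accumulation.
signed_extreme <- function(values) {
  mx <- max(values); mn <- min(values)
  if (mx >= -mn - 1e-12) mx else mn
}

# Enrichment score from hit positions only (same statistic as
# enrichment_score, O(k) per evaluation) -- used for the permutation null.
es_from_positions <- function(w, pos, N) {
  pos <- sort(pos)
  k <- length(pos)
  wh <- sum(w[pos])
  inc <- if (wh > 0) w[pos] / wh else rep(1 / k, k)
  miss <- 1 / (N - k)
  # running value at each hit, and just before each hit
  at_hit <- cumsum(inc) - (pos - seq_len(k)) * miss
  before_hit <- at_hit - inc
  signed_extreme(c(at_hit, before_hit))
}

#' Preranked GSEA with gene-set permutation
#'
#' Scores each collection set on the ranked list, then builds a null from
#' random member sets of equal size drawn from the ranked universe (the
#' standard preranked fallback when replicate numbers are too small for
#' phenotype permutation). `NES = ES / mean(|null ES| with matching sign)`;
#' the p-value is empirical and two-sided with add-one correction,
#' `p = min(1, 2 (1 + #{sign-matched null >= |ES|}) / (1 + n_permutations))`;
#' FDR across sets is Benjamini-Hochberg.
#'
#' @param ranked a `ranked_list`.
#' @param collection a `gene_set_collection`.
#' @param n_permutations permutations per set size (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param min_size,max_size set-size bounds after restriction to the ranked
#'   universe.
#' @param weight_exponent see [enrichment_score()].
#' @return data.frame: set_name, size, es, nes, pvalue, fdr, leading_edge
#'   (comma-joined); attribute `n_permutations`.
#' @export
gsea_preranked <- function(ranked, collection, n_permutations = 1000,
                           seed = 7, min_size = 5, max_size = 500,
                           weight_exponent = 1) {
  if (n_permutations < 1) ct_config_error("n_permutations must be >= 1")
  N <- nrow(ranked)
  w <- abs(ranked$metric)^weight_exponent
  sizes <- vapply(collection, function(s) sum(ranked$gene_id %in% s$genes), 1L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    warning("no gene set within size bounds")
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), fdr = numeric(0),
                      leading_edge = character(0)))
  }
  collection <- collection[keep]
  sizes <- sizes[keep]

  # one null per distinct set size, shared across sets of that size
  nulls <- list()
  withr::with_seed(stage_seed(seed, 31L), {
    for (k in sort(unique(sizes))) {
      nulls[[as.character(k)]] <- vapply(seq_len(n_permutations), function(i)
        es_from_positions(w, sample.int(N, k), N), numeric(1))
    }
  })

  rows <- lapply(seq_along(collection), function(i) {
    s <- collection[[i]]
    sc <- enrichment_score(ranked, s$genes, weight_exponent)
    es <- sc$es
    null <- nulls[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    exceed <- sum(sign(null) == sign(es) & abs(null) >= abs(es))
    p <- min(1, 2 * (1 + exceed) / (1 + n_permutations))
    hits <- which(ranked$gene_id %in% s$genes)
    peak <- if (es >= 0) which.max(sc$running) else which.min(sc$running)
    le <- if (es >= 0) ranked$gene_id[hits[hits <= peak]]
    else ranked$gene_id[hits[hits >= peak]]
    data.frame(set_name = s$name, size = sizes[i], es = es, nes = nes,
               pvalue = p, leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, -abs(out$nes), out$set_name),
             c("set_name", "size", "es", "nes", "pvalue", "fdr", "leading_edge")]
  rownames(out) <- NULL
  structure(out, n_permutations = n_permutations, seed = seed)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the p-value is the upper-tail hypergeometric probability
#' `P(X >= overlap)` with the universe as population, the set's members in
#' the universe as successes and the query as draws; FDR across sets is
#' Benjamini-Hochberg. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of query genes (e.g. one cluster's DEGs).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of background genes (e.g. all tested
#'   genes).
#' @return data.frame: set_name, overlap, set_size_in_universe, query_size,
#'   universe_size, pvalue, fdr.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(paste0("dropping query genes outside the universe: ",
                   paste(outside, collapse = ", ")))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(collection, function(s) {
    K <- length(intersect(s$genes, universe))
    x <- length(intersect(s$genes, query))
    p <- if (K == 0) 1 else stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = s$name, overlap = x, set_size_in_universe = K,
               query_size = n, universe_size = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- bh_adjust(out$pvalue)
  out[order(out$pvalue, out$set_name), ]
}
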