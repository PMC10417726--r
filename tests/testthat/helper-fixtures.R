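# Shared fixtures and independent oracles for the test suite.
# The default fixture is generated once per session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- generate_fixture(sim_config(seed = 101, n_escapees = 2))
  }
  .fixture_cache$default
}

small_fixture_dir <- function() {
  if (is.null(.fixture_cache$small_dir)) {
    dir <- file.path(tempdir(), "cistraj_small_fixture")
    export_fixture(sim_config(n_genes = 300, n_chromosomes = 3,
                              n_planted_per_cluster = c(12, 12, 12),
                              n_cis_pairs = 3, seed = 202, n_escapees = 1),
                   dir)
    .fixture_cache$small_dir <- dir
  }
  .fixture_cache$small_dir
}

# tiny count_matrix builder
toy_counts <- function(counts, genotype = NULL, condition = NULL,
                       timepoint = NULL) {
  n <- ncol(counts)
  samples <- data.frame(
    sample_id = colnames(counts),
    genotype = genotype %||% rep("WT", n),
    condition = condition %||% rep(c("tumor", "tumor_free"), length.out = n),
    timepoint_weeks = timepoint %||% rep(6L, n),
    replicate = NA_integer_, stringsAsFactors = FALSE)
  key <- paste(samples$genotype, samples$condition, samples$timepoint_weeks)
  samples$replicate <- stats::ave(seq_len(n), key, FUN = seq_along)
  count_matrix(counts, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# naive running-sum enrichment score (literal walk down the list)
naive_enrichment_score <- function(gene_ids, metrics, members, w_exp = 1) {
  hits <- gene_ids %in% members
  nh <- sum(hits); n <- length(gene_ids)
  wh <- sum(abs(metrics[hits])^w_exp)
  running <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hits[i]) {
      if (wh > 0) cur + abs(metrics[i])^w_exp / wh else cur + 1 / nh
    } else cur - 1 / (n - nh)
    running[i] <- cur
  }
  mx <- max(running); mn <- min(running)
  if (mx >= -mn - 1e-12) mx else mn
}

# exhaustive k-means optimum by enumerating all assignments (tiny n only)
exhaustive_kmeans_ss <- function(x, K) {
  n <- nrow(x)
  stopifnot(n <= 9)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < K) next
    ss <- 0
    for (k in seq_len(K)) {
      xs <- x[a == k, , drop = FALSE]
      ss <- ss + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    best <- min(best, ss)
  }
  best
}

# brute-force all-pairs windowed candidate search
brute_window_pairs <- function(annotation, lnc_ids, pcg_ids, window_bp) {
  out <- list()
  for (l in lnc_ids) {
    gl <- annotation[annotation$gene_id == l, ]
    for (p in pcg_ids) {
      gp <- annotation[annotation$gene_id == p, ]
      if (gl$chrom != gp$chrom) next
      gap <- max(0, max(gl$start, gp$start) - min(gl$end, gp$end))
      if (gap <= window_bp)
        out[[length(out) + 1]] <- data.frame(lncRNA_id = l, pcg_id = p,
                                             distance_bp = gap)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(lncRNA_id = character(0), pcg_id = character(0),
                  distance_bp = numeric(0))
}
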