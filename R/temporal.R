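#' Per-timepoint mean expression profiles
#'
#' Builds a gene x timepoint matrix of arithmetic means of normalized counts
#' over the samples of one (genotype, condition) group.
#'
#' @param normalized gene x sample matrix of normalized counts.
#' @param samples sample sheet aligned with the matrix columns.
#' @param gene_ids genes to profile (error if any is absent).
#' @param genotype,condition group selector.
#' @param timepoints ordered weeks to use; defaults to all timepoints
#'   present for the group.
#' @return A `temporal_profiles` object: `values` (genes x timepoints),
#'   `timepoints`, `row_info` (gene_id, genotype), `scaling = "none"`.
#' @export
stage_means <- function(normalized, samples, gene_ids, genotype,
                        condition = "tumor", timepoints = NULL) {
  samples <- validate_samplesheet(samples)
  if (!identical(colnames(normalized), samples$sample_id))
    ct_data_error("normalized matrix columns must match the sample sheet")
  missing <- setdiff(gene_ids, rownames(normalized))
  if (length(missing))
    ct_data_error(paste0("genes absent from expression matrix: ",
                         paste(missing, collapse = ", ")))
  grp <- samples$genotype == genotype & samples$condition == condition
  timepoints <- timepoints %||% sort(unique(samples$timepoint_weeks[grp]))
  vals <- sapply(timepoints, function(tp) {
    j <- which(grp & samples$timepoint_weeks == tp)
    if (!length(j))
      ct_data_error(sprintf("no %s %s samples at week %d", genotype, condition, tp))
    rowMeans(normalized[gene_ids, j, drop = FALSE])
  })
  vals <- matrix(vals, nrow = length(gene_ids),
                 dimnames = list(gene_ids, paste0("wk", timepoints)))
  structure(list(values = vals, timepoints = timepoints,
                 row_info = data.frame(gene_id = gene_ids, genotype = genotype,
                                       stringsAsFactors = FALSE),
                 scaling = "none"),
            class = "temporal_profiles")
}

#' Joint stage-aligned WT/KO profiles
#'
#' Stacks WT and KO trajectories into one matrix whose columns are tumor
#' stages (1st, 2nd, 3rd tumor timepoint) rather than absolute weeks: the WT
#' arm uses weeks 6/8/10 and the KO arm weeks 8/10/12, so a joint clustering
#' of the union of hyperplasia DEGs is well-posed despite the knockout's
#' delayed onset.
#'
#' @param normalized gene x sample normalized counts.
#' @param samples sample sheet.
#' @param wt_genes,ko_genes hyperplasia DEG ids per genotype.
#' @param wt_timepoints,ko_timepoints stage weeks per genotype.
#' @return A `temporal_profiles` with rows named `<genotype>:<gene_id>` and
#'   stage columns.
#' @export
build_joint_profiles <- function(normalized, samples, wt_genes, ko_genes,
                                 wt_timepoints = c(6, 8, 10),
                                 ko_timepoints = c(8, 10, 12)) {
  if (length(wt_timepoints) != length(ko_timepoints))
    ct_config_error("WT and KO stage axes must have the same length")
  parts <- list()
  info <- list()
  if (length(wt_genes)) {
    p <- stage_means(normalized, samples, wt_genes, "WT", "tumor", wt_timepoints)
    parts$WT <- p$values; info$WT <- p$row_info
  }
  if (length(ko_genes)) {
    p <- stage_means(normalized, samples, ko_genes, "KO", "tumor", ko_timepoints)
    parts$KO <- p$values; info$KO <- p$row_info
  }
  if (!length(parts)) ct_data_error("no genes to profile")
  stages <- paste0("stage", seq_along(wt_timepoints))
  vals <- do.call(rbind, lapply(names(parts), function(g) {
    m <- parts[[g]]
    colnames(m) <- stages
    rownames(m) <- paste0(g, ":", rownames(m))
    m
  }))
  structure(list(values = vals, timepoints = seq_along(stages),
                 row_info = do.call(rbind, unname(info)), scaling = "none"),
            class = "temporal_profiles")
}

#' @export
print.temporal_profiles <- function(x, ...) {
  cat(sprintf("temporal_profiles: %d rows x %d timepoints (scaling: %s)\n",
              nrow(x$values), ncol(x$values), x$scaling))
  invisible(x)
}

# Profile transform applied before clustering. "center_log2" (default in the
# pipeline) works on log2(x+1) with per-row mean removed: per-gene baseline
# drops out while shape and amplitude are kept, so a flat low archetype stays
# distinguishable from a decaying one. "zscore" additionally divides by the
# row SD (constant rows are dropped with a warning); "none" clusters raw
# values.
scale_profiles <- function(values, scaling = c("center_log2", "zscore", "none")) {
  scaling <- match.arg(scaling)
  if (scaling == "none") return(values)
  if (scaling == "center_log2") {
    lv <- log2(values + 1)
    return(lv - rowMeans(lv))
  }
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant row(s) before z-scoring", sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (values - rowMeans(values)) / sds
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (K > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[k, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[k, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

# Lloyd's algorithm; an empty cluster is re-seeded at the point farthest
# from its assigned centroid.
lloyd_kmeans <- function(x, centers, max_iter = 300, tol = 1e-6) {
  n <- nrow(x); K <- nrow(centers)
  xx <- rowSums(x^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xx, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    d2own <- d2[cbind(seq_len(n), assign)]
    for (k in seq_len(K)) {
      if (!any(assign == k)) {
        far <- which.max(d2own)
        assign[far] <- k
        d2own[far] <- -Inf
      }
    }
    new_centers <- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(x[assign == k, , drop = FALSE])))
    move <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    if (move < tol^2) break
  }
  d2 <- outer(xx, rowSums(centers^2), "+") - 2 * x %*% t(centers)
  assign <- max.col(-d2, ties.method = "first")
  # exact residual sum (the cross-product form above loses precision)
  wss <- sum((x - centers[assign, , drop = FALSE])^2)
  list(assign = assign, centers = centers, tot_withinss = wss)
}

#' k-means clustering of temporal profiles
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts by
#' total within-cluster sum of squares; deterministic given `seed`. With
#' `K = 3` the cluster labels are renamed to the temporal archetypes by
#' centroid shape: 1 = early peak then decay (most negative stage trend),
#' 2 = sustained rise (most positive trend), 3 = early drop / flat
#' (intermediate trend).
#'
#' @param profiles a `temporal_profiles` object.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param n_init number of restarts (default 25).
#' @param scaling profile transform before clustering; see Details in the
#'   package vignette. One of `"center_log2"` (default), `"zscore"`,
#'   `"none"`.
#' @param max_iter,tol Lloyd iteration cap and centroid-movement tolerance.
#' @param relabel_archetypes rename clusters by archetype shape when K = 3.
#' @return A `cluster_fit`: `K`, `assignments` (named by profile row),
#'   `centroids`, `total_within_ss`, `scaling`, `seed`, `n_init`,
#'   `row_info`.
#' @export
kmeans_cluster <- function(profiles, K = 3, seed = 7, n_init = 25,
                           scaling = c("center_log2", "zscore", "none"),
                           max_iter = 300, tol = 1e-6,
                           relabel_archetypes = TRUE) {
  stopifnot(inherits(profiles, "temporal_profiles"))
  scaling <- match.arg(scaling)
  x <- scale_profiles(profiles$values, scaling)
  if (K < 1 || K > nrow(x))
    ct_config_error(sprintf("K must be in 1..%d (got %s)", nrow(x), K))
  best <- NULL
  withr::with_seed(stage_seed(seed, 21L), {
    for (i in seq_len(n_init)) {
      fit <- lloyd_kmeans(x, kmeanspp_centers(x, K), max_iter, tol)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  assignments <- stats::setNames(best$assign, rownames(x))
  centroids <- best$centers
  rownames(centroids) <- as.character(seq_len(K))
  colnames(centroids) <- colnames(x)
  if (relabel_archetypes && K == 3) {
    relab <- match_archetypes(centroids)
    assignments[] <- relab[assignments]
    centroids <- centroids[order(relab), , drop = FALSE]
    rownames(centroids) <- as.character(1:3)
  }
  row_info <- profiles$row_info
  if (!is.null(row_info)) {
    rownames(row_info) <- rownames(profiles$values)
    row_info <- row_info[names(assignments), , drop = FALSE]
  }
  structure(list(K = K, assignments = assignments, centroids = centroids,
                 total_within_ss = best$tot_withinss, scaling = scaling,
                 seed = seed, n_init = n_init, row_info = row_info),
            class = "cluster_fit")
}

# Map raw k-means labels to archetypes by centroid stage trend
# (last - first): rise -> 2, steepest fall -> 1, remaining -> 3.
match_archetypes <- function(centroids) {
  trend <- centroids[, ncol(centroids)] - centroids[, 1]
  relab <- integer(3)
  relab[which.max(trend)] <- 2L
  relab[which.min(trend)] <- 1L
  relab[relab == 0L] <- 3L
  relab
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("cluster_fit: K = %d, total within-SS = %.4g (scaling %s)\n",
              x$K, x$total_within_ss, x$scaling))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Elbow curve of total within-cluster SS
#'
#' Fits [kmeans_cluster()] for each K and returns the total within-cluster
#' sum of squares, the curve one plots to choose K (the temporal analysis
#' uses K = 3).
#'
#' @inheritParams kmeans_cluster
#' @param K_range candidate cluster numbers.
#' @return named numeric vector, K -> total within-SS.
#' @export
elbow_curve <- function(profiles, K_range = 1:8, seed = 7, n_init = 25,
                        scaling = c("center_log2", "zscore", "none")) {
  scaling <- match.arg(scaling)
  vapply(stats::setNames(K_range, K_range), function(K)
    kmeans_cluster(profiles, K, seed = seed, n_init = n_init,
                   scaling = scaling,
                   relabel_archetypes = FALSE)$total_within_ss,
    numeric(1))
}

#' Recompute total within-cluster SS from a fit
#'
#' @param fit a `cluster_fit`.
#' @param profiles the `temporal_profiles` it was fitted on.
#' @return total within-cluster sum of squares implied by the stored
#'   assignments and centroids.
#' @export
recompute_within_ss <- function(fit, profiles) {
  x <- scale_profiles(profiles$values, fit$scaling)
  x <- x[names(fit$assignments), , drop = FALSE]
  sum((x - fit$centroids[as.character(fit$assignments), , drop = FALSE])^2)
}

#' Genotype exclusivity of a temporal cluster
#'
#' For rows assigned to `cluster_id` in the joint fit: a gene is
#' `wt_only` when its WT profile is in the cluster and the gene is absent
#' from the KO DEG input; `ko_only` symmetrically; `shared` when both
#' genotypes' profiles sit in the cluster.
#'
#' @param fit a `cluster_fit` from [kmeans_cluster()] on
#'   [build_joint_profiles()] output.
#' @param cluster_id cluster (archetype) label.
#' @param wt_input,ko_input the DEG ids that entered the clustering per
#'   genotype.
#' @return list of character vectors `wt_only`, `ko_only`, `shared`.
#' @export
exclusivity_partition <- function(fit, cluster_id, wt_input, ko_input) {
  stopifnot(inherits(fit, "cluster_fit"))
  info <- fit$row_info
  in_cluster <- fit$assignments == cluster_id
  wt_c <- info$gene_id[in_cluster & info$genotype == "WT"]
  ko_c <- info$gene_id[in_cluster & info$genotype == "KO"]
  list(wt_only = sort(setdiff(wt_c, ko_input)),
       ko_only = sort(setdiff(ko_c, wt_input)),
       shared = sort(intersect(wt_c, ko_c)))
}
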