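#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Two distinct DE
#' threshold sets are kept, matching the analysis design: stagewise DEG
#' calling uses fold change > 1.5, FDR < 0.1; the temporal-clustering input
#' (hyperplasia-stage DEGs) uses fold change > 2, FDR < 0.1.
#'
#' @param counts,samples,annotation,gmt input file paths (must exist).
#' @param out_dir output directory (distinct from the input paths).
#' @param exon_counts optional TSV of floxed-exon counts for QC.
#' @param stagewise_fc,timecourse_fc,fdr DE thresholds.
#' @param lfc_scale `"linear"` (default) or `"log2"` threshold convention,
#'   see [call_degs()].
#' @param K number of temporal clusters (default 3).
#' @param wt_timepoints,ko_timepoints stage weeks per genotype (the knockout
#'   arm is sampled one timepoint later).
#' @param n_permutations,gsea_min_size,gsea_max_size GSEA options.
#' @param screen a [screen_config()].
#' @param gfp_id,mtd_id,min_ratio,max_exon_fraction QC options.
#' @param min_total prefilter threshold (total reads per gene).
#' @param seed global seed fanned out to per-stage seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, annotation, gmt, out_dir,
                            exon_counts = NULL,
                            stagewise_fc = 1.5, timecourse_fc = 2, fdr = 0.1,
                            lfc_scale = "linear", K = 3,
                            wt_timepoints = c(6, 8, 10),
                            ko_timepoints = c(8, 10, 12),
                            n_permutations = 1000, gsea_min_size = 5,
                            gsea_max_size = 500,
                            screen = screen_config(),
                            gfp_id = "GFP", mtd_id = "mTd", min_ratio = 10,
                            max_exon_fraction = 0.01, min_total = 10,
                            seed = 7) {
  inputs <- c(counts = counts, samples = samples, annotation = annotation,
              gmt = gmt)
  if (!is.null(exon_counts)) inputs <- c(inputs, exon_counts = exon_counts)
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]))
      ct_config_error(sprintf("input file for '%s' does not exist: %s", nm, inputs[[nm]]))
  if (normalizePath(out_dir, mustWork = FALSE) %in%
      vapply(inputs, normalizePath, "", mustWork = FALSE))
    ct_config_error("out_dir must be distinct from the input paths")
  for (fc in c(stagewise_fc = stagewise_fc, timecourse_fc = timecourse_fc))
    if (lfc_scale == "linear" && fc <= 1)
      ct_config_error("fold-change thresholds must exceed 1")
  if (fdr <= 0 || fdr >= 1) ct_config_error("fdr must be in (0, 1)")
  structure(list(counts = counts, samples = samples, annotation = annotation,
                 gmt = gmt, exon_counts = exon_counts, out_dir = out_dir,
                 stagewise_fc = stagewise_fc, timecourse_fc = timecourse_fc,
                 fdr = fdr, lfc_scale = lfc_scale, K = as.integer(K),
                 wt_timepoints = wt_timepoints, ko_timepoints = ko_timepoints,
                 n_permutations = as.integer(n_permutations),
                 gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
                 screen = screen, gfp_id = gfp_id, mtd_id = mtd_id,
                 min_ratio = min_ratio, max_exon_fraction = max_exon_fraction,
                 min_total = min_total, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Allowed keys per config-file section.
config_schema <- function() {
  list(paths = c("counts", "samples", "annotation", "gmt", "exon_counts",
                 "out_dir"),
       de = c("stagewise_fc", "timecourse_fc", "fdr", "lfc_scale"),
       temporal = c("K", "wt_timepoints", "ko_timepoints"),
       gsea = c("n_permutations", "min_size", "max_size"),
       screen = c("window_bp", "r_min", "p_max", "r_mode", "distance_anchor",
                  "genotype", "condition"),
       qc = c("gfp_id", "mtd_id", "min_ratio", "max_exon_fraction"),
       prefilter = c("min_total"),
       seed = NULL)
}

#' Read and validate a pipeline config file
#'
#' Parses a YAML config with sections `paths`, `de`, `temporal`, `gsea`,
#' `screen`, `qc`, `prefilter` and a top-level `seed`; unknown or duplicate
#' keys are errors (strict mode), missing keys take the package defaults
#' (window 500000, r_min 0.80, K = 3, ...). The resolved configuration is
#' echoed with `message()`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ct_config_error(paste0("config file not found: ", path))
  check_duplicate_keys(readLines(path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) ct_parse_error(paste0("cannot parse config: ",
                                                            conditionMessage(e))))
  schema <- config_schema()
  unknown_top <- setdiff(names(raw), names(schema))
  if (length(unknown_top))
    ct_config_error(paste0("unknown config section(s): ",
                           paste(unknown_top, collapse = ", ")))
  for (sec in setdiff(names(raw), "seed")) {
    bad <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(bad))
      ct_config_error(sprintf("unknown key(s) in section '%s': %s", sec,
                              paste(bad, collapse = ", ")))
  }
  p <- raw$paths
  if (is.null(p$counts) || is.null(p$samples) || is.null(p$annotation) ||
      is.null(p$gmt) || is.null(p$out_dir))
    ct_config_error("paths section must give counts, samples, annotation, gmt, out_dir")
  sc <- raw$screen
  screen <- screen_config(
    window_bp = sc$window_bp %||% 500000, r_min = sc$r_min %||% 0.80,
    p_max = sc$p_max %||% 0.01, r_mode = sc$r_mode %||% "signed",
    distance_anchor = sc$distance_anchor %||% "span_gap",
    genotype = sc$genotype, condition = sc$condition)
  cfg <- pipeline_config(
    counts = p$counts, samples = p$samples, annotation = p$annotation,
    gmt = p$gmt, out_dir = p$out_dir, exon_counts = p$exon_counts,
    stagewise_fc = raw$de$stagewise_fc %||% 1.5,
    timecourse_fc = raw$de$timecourse_fc %||% 2,
    fdr = raw$de$fdr %||% 0.1, lfc_scale = raw$de$lfc_scale %||% "linear",
    K = raw$temporal$K %||% 3,
    wt_timepoints = raw$temporal$wt_timepoints %||% c(6, 8, 10),
    ko_timepoints = raw$temporal$ko_timepoints %||% c(8, 10, 12),
    n_permutations = raw$gsea$n_permutations %||% 1000,
    gsea_min_size = raw$gsea$min_size %||% 5,
    gsea_max_size = raw$gsea$max_size %||% 500,
    screen = screen,
    gfp_id = raw$qc$gfp_id %||% "GFP", mtd_id = raw$qc$mtd_id %||% "mTd",
    min_ratio = raw$qc$min_ratio %||% 10,
    max_exon_fraction = raw$qc$max_exon_fraction %||% 0.01,
    min_total = raw$prefilter$min_total %||% 10,
    seed = raw$seed %||% 7)
  message("resolved config: ", yaml::as.yaml(cfg[!vapply(cfg, is.null, TRUE)]))
  cfg
}

# A light duplicate-key scan: within one indentation block, a repeated key
# is an error (YAML parsers silently keep the last occurrence).
check_duplicate_keys <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  key_lines <- grep("^\\s*[A-Za-z_][A-Za-z0-9_]*\\s*:", lines, value = FALSE)
  indent <- nchar(sub("\\S.*$", "", lines))
  keys <- sub("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:.*$", "\\1", lines)
  path <- character(0)
  seen <- character(0)
  for (i in key_lines) {
    lvl <- indent[i] %/% 2 + 1
    path <- c(path[seq_len(min(lvl - 1, length(path)))], keys[i])
    full <- paste(path, collapse = "/")
    if (full %in% seen)
      ct_parse_error(paste0("duplicate config key: ", full))
    seen <- c(seen, full)
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes qc, prefilter, normalization, per-timepoint stage-matched DE for
#' each genotype, DEG set algebra, hyperplasia-stage timecourse DEG
#' selection, joint temporal k-means clustering, genotype-exclusivity
#' partition, GSEA and ORA, and the cis lncRNA/PCG screen. Every
#' intermediate table is written to `out_dir`; the run is deterministic
#' given the seed (byte-identical outputs across reruns).
#'
#' @param config a [pipeline_config()].
#' @return A `run_report` (list of stage summaries and headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 version = as.character(utils::packageVersion("cistraj")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ct_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "cistraj_stage_error")
    })
  }

  cm <- stage("read_inputs", read_counts(config$counts, config$samples))
  annotation <- stage("read_inputs", read_gtf(config$annotation))
  sets <- stage("read_inputs", read_gmt(config$gmt))
  exon <- NULL
  if (!is.null(config$exon_counts)) {
    tab <- utils::read.delim(config$exon_counts, check.names = FALSE)
    exon <- as.matrix(tab[, -1, drop = FALSE])
    rownames(exon) <- tab[[1]]
    attr(cm, "exon_counts") <- exon
  }
  message(sprintf("[qc] %d genes x %d samples", nrow(cm$counts), ncol(cm$counts)))

  qc <- stage("qc", qc_report(cm, config$gfp_id, config$mtd_id,
                              config$min_ratio,
                              exon_counts = attr(cm, "exon_counts"),
                              max_exon_fraction = config$max_exon_fraction))
  write_tsv_commented(qc, file.path(config$out_dir, "qc.tsv"),
                      params = list(min_ratio = config$min_ratio,
                                    max_exon_fraction = config$max_exon_fraction))
  report$qc <- list(recombination_pass = sum(qc$recombination_ok),
                    n_samples = nrow(qc),
                    escapees = if ("ko_concordant" %in% names(qc))
                      qc$sample_id[!is.na(qc$ko_concordant) & !qc$ko_concordant]
                    else character(0))

  filtered <- stage("prefilter", prefilter(cm, config$min_total))
  message(sprintf("[prefilter] kept %d / %d genes (total reads >= %g)",
                  nrow(filtered$counts), nrow(cm$counts), config$min_total))
  report$prefilter <- list(kept = nrow(filtered$counts),
                           dropped = nrow(cm$counts) - nrow(filtered$counts))

  sf <- stage("normalize", size_factors(filtered))
  normalized <- normalize_counts(filtered, sf)
  write_tsv_commented(data.frame(sample_id = names(sf), size_factor = unname(sf)),
                      file.path(config$out_dir, "size_factors.tsv"))

  contrasts <- rbind(
    data.frame(genotype = "WT", timepoint = config$wt_timepoints),
    data.frame(genotype = "KO", timepoint = config$ko_timepoints))
  de_results <- list()
  stage_sets <- list(WT = list(), KO = list())
  for (i in seq_len(nrow(contrasts))) {
    g <- contrasts$genotype[i]; tp <- contrasts$timepoint[i]
    de <- stage("diffexpr", nb_wald_test(filtered, g, tp, size_factors_all = sf))
    key <- sprintf("%s_wk%d", g, tp)
    de_results[[key]] <- de
    write_tsv_commented(as.data.frame(de),
                        file.path(config$out_dir, paste0("de_", key, ".tsv")),
                        params = list(genotype = g, timepoint_weeks = tp,
                                      test = "nb_wald"))
    degs <- call_degs(de, config$stagewise_fc, config$fdr,
                      lfc_scale = config$lfc_scale)
    stage_sets[[g]][[as.character(tp)]] <- degs
    message(sprintf("[diffexpr] %s week %d: %d DEGs (FC > %g, FDR < %g)",
                    g, tp, length(degs$gene_ids), config$stagewise_fc, config$fdr))
  }
  report$deg_counts <- lapply(stage_sets, function(x)
    vapply(x, function(s) length(s$gene_ids), 1L))
  report$venn <- lapply(stage_sets, function(x) deg_set_algebra(x)$counts)

  # hyperplasia stage = first tumor timepoint per genotype
  hyper <- list(WT = config$wt_timepoints[1], KO = config$ko_timepoints[1])
  tc_degs <- list()
  for (g in c("WT", "KO")) {
    key <- sprintf("%s_wk%d", g, hyper[[g]])
    tc_degs[[g]] <- call_degs(de_results[[key]], config$timecourse_fc,
                              config$fdr, lfc_scale = config$lfc_scale)
    message(sprintf("[temporal] %s hyperplasia (week %d) input: %d DEGs (FC > %g)",
                    g, hyper[[g]], length(tc_degs[[g]]$gene_ids),
                    config$timecourse_fc))
  }
  report$timecourse_input <- vapply(tc_degs, function(s) length(s$gene_ids), 1L)

  profiles <- stage("temporal", build_joint_profiles(
    normalized, filtered$samples, tc_degs$WT$gene_ids, tc_degs$KO$gene_ids,
    config$wt_timepoints, config$ko_timepoints))
  fit <- stage("temporal", kmeans_cluster(profiles, K = config$K,
                                          seed = config$seed))
  cl_df <- data.frame(row = names(fit$assignments),
                      gene_id = fit$row_info$gene_id,
                      genotype = fit$row_info$genotype,
                      cluster = unname(fit$assignments),
                      stringsAsFactors = FALSE)
  write_tsv_commented(cl_df[c("gene_id", "genotype", "cluster")],
                      file.path(config$out_dir, "clusters.tsv"),
                      params = list(K = config$K, seed = config$seed,
                                    scaling = fit$scaling))
  write_tsv_commented(data.frame(cluster = rownames(fit$centroids),
                                 fit$centroids, check.names = FALSE),
                      file.path(config$out_dir, "centroids.tsv"))
  tab <- table(cl_df$cluster)
  report$cluster_sizes <- stats::setNames(as.integer(tab), names(tab))
  message(sprintf("[temporal] K = %d, total within-SS = %.4g", config$K,
                  fit$total_within_ss))

  excl <- lapply(stats::setNames(seq_len(config$K), seq_len(config$K)),
                 function(k) exclusivity_partition(fit, k, tc_degs$WT$gene_ids,
                                                   tc_degs$KO$gene_ids))
  report$exclusive_counts <- lapply(excl, function(e) vapply(e, length, 1L))
  wt_exclusive <- sort(unique(unlist(lapply(excl, `[[`, "wt_only"))))
  bio <- classify_biotypes(wt_exclusive, annotation)
  report$wt_exclusive <- list(total = length(wt_exclusive),
                              lncRNA = length(bio$lncRNA),
                              protein_coding = length(bio$protein_coding))
  message(sprintf("[temporal] WT-exclusive DEGs: %d (%d lncRNA, %d protein-coding)",
                  length(wt_exclusive), length(bio$lncRNA),
                  length(bio$protein_coding)))

  ranked <- stage("enrichment",
                  rank_genes(de_results[[sprintf("WT_wk%d", hyper$WT)]]))
  gsea <- stage("enrichment", gsea_preranked(
    ranked, sets, n_permutations = config$n_permutations, seed = config$seed,
    min_size = config$gsea_min_size, max_size = config$gsea_max_size))
  write_tsv_commented(as.data.frame(gsea),
                      file.path(config$out_dir, "gsea.tsv"),
                      params = list(n_permutations = config$n_permutations,
                                    seed = config$seed))
  report$gsea_top <- utils::head(gsea$set_name, 3)

  cluster1_wt <- excl[["1"]]$wt_only
  ora <- stage("enrichment", ora_hypergeometric(cluster1_wt, sets,
                                                rownames(filtered$counts)))
  write_tsv_commented(ora, file.path(config$out_dir, "ora.tsv"),
                      params = list(query = "cluster1_wt_exclusive"))

  # the screen takes DE gene lists by biotype; the WT hyperplasia DEG lists
  # are used directly (the exclusivity partition above is reported on its
  # own and can be fed to screen_pairs() for an exclusive-only screen)
  bio_de <- classify_biotypes(tc_degs$WT$gene_ids, annotation)
  screen <- stage("cispairs", screen_pairs(
    normalized, filtered$samples, bio_de$lncRNA, bio_de$protein_coding,
    annotation, config$screen))
  write_pair_table(screen, file.path(config$out_dir, "pairs.tsv"))
  report$cis <- list(evaluated = nrow(screen), reported = sum(screen$reported))
  message(sprintf("[cispairs] %d evaluated, %d reported", nrow(screen),
                  sum(screen$reported)))

  report$outputs <- sort(list.files(config$out_dir))
  writeLines(yaml::as.yaml(rapply(report, unclass, how = "replace")),
             file.path(config$out_dir, "run_report.yaml"))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("cistraj run report (seed ", x$seed, ")\n", sep = "")
  cat("  DEGs per contrast:\n")
  for (g in names(x$deg_counts))
    cat(sprintf("    %s: %s\n", g,
                paste(sprintf("wk%s=%d", names(x$deg_counts[[g]]),
                              x$deg_counts[[g]]), collapse = ", ")))
  cat(sprintf("  timecourse input: WT=%d KO=%d\n",
              x$timecourse_input[["WT"]], x$timecourse_input[["KO"]]))
  cat(sprintf("  cluster sizes: %s\n",
              paste(sprintf("%s=%d", names(x$cluster_sizes), x$cluster_sizes),
                    collapse = ", ")))
  cat(sprintf("  WT-exclusive DEGs: %d (%d lncRNA)\n",
              x$wt_exclusive$total, x$wt_exclusive$lncRNA))
  cat(sprintf("  cis pairs: %d evaluated, %d reported\n",
              x$cis$evaluated, x$cis$reported))
  invisible(x)
}
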