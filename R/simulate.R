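#' Simulation configuration
#'
#' Declares the study design emulated by the synthetic-data module: two
#' genotypes (WT, KO) by two conditions (tumor, tumor_free) across four
#' timepoints (6, 8, 10, 12 weeks), with 3 tumor and 2 tumor-free replicates
#' per genotype-timepoint; negative-binomial counts (variance
#' `mu + dispersion * mu^2`); a lncRNA biotype fraction; GFP/mTd reporter
#' spike-in features; a floxed-exon "Pthlh_like" gene whose fourth exon is
#' absent in KO samples; planted temporal archetypes; and cis-linked
#' lncRNA/protein-coding pairs within 500 kb.
#'
#' @param n_genes number of regular genes (three special features --
#'   `Pthlh_like`, `GFP`, `mTd` -- are added on top).
#' @param lncRNA_fraction fraction of regular genes with lncRNA biotype.
#' @param n_chromosomes,chrom_length_bp toy genome geometry.
#' @param design data.frame (genotype, condition, timepoint_weeks,
#'   n_replicates); defaults to the full study design.
#' @param mean_log_expression,sd_log_expression natural-log mean and sd of
#'   per-gene baseline expression.
#' @param dispersion NB dispersion alpha in `var = mu + alpha mu^2`.
#' @param library_size_sdlog sdlog of the log-normal per-sample library-size
#'   multiplier.
#' @param n_planted_per_cluster genes planted per temporal archetype 1..3
#'   (cluster 2 includes the cis-pair genes).
#' @param planted_lfc peak planted log2 fold change.
#' @param wt_exclusive_fraction,ko_exclusive_fraction fractions of planted
#'   non-cis genes whose effect is restricted to one genotype.
#' @param n_cis_pairs number of planted cis lncRNA/PCG pairs (WT-exclusive,
#'   archetype 2 by construction).
#' @param cis_pair_r_target target Pearson correlation (log scale) within a
#'   planted pair.
#' @param n_escapees number of KO tumor samples modeled as recombination
#'   escapees (nonzero floxed-exon counts); 0 by default.
#' @param seed integer seed; every generator draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, lncRNA_fraction = 0.15,
                       n_chromosomes = 5, chrom_length_bp = 1e7,
                       design = default_design(),
                       mean_log_expression = log(100), sd_log_expression = 1,
                       dispersion = 0.1, library_size_sdlog = 0.2,
                       n_planted_per_cluster = c(`1` = 40, `2` = 40, `3` = 40),
                       planted_lfc = 2, wt_exclusive_fraction = 0.5,
                       ko_exclusive_fraction = 0.1,
                       n_cis_pairs = 5, cis_pair_r_target = 0.9,
                       n_escapees = 0, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), lncRNA_fraction = lncRNA_fraction,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              design = design,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              dispersion = dispersion, library_size_sdlog = library_size_sdlog,
              n_planted_per_cluster = n_planted_per_cluster,
              planted_lfc = planted_lfc,
              wt_exclusive_fraction = wt_exclusive_fraction,
              ko_exclusive_fraction = ko_exclusive_fraction,
              n_cis_pairs = as.integer(n_cis_pairs),
              cis_pair_r_target = cis_pair_r_target,
              n_escapees = as.integer(n_escapees), seed = as.integer(seed))
  if (cfg$n_genes < 1) ct_config_error("n_genes must be positive")
  if (cfg$lncRNA_fraction < 0 || cfg$lncRNA_fraction > 1)
    ct_config_error("lncRNA_fraction must be in [0, 1]")
  if (cfg$dispersion <= 0) ct_config_error("dispersion must be > 0")
  if (!nrow(design)) ct_config_error("design must be non-empty")
  if (cfg$cis_pair_r_target <= 0 || cfg$cis_pair_r_target > 1)
    ct_config_error("cis_pair_r_target must be in (0, 1]")
  if (length(cfg$n_planted_per_cluster) != 3)
    ct_config_error("n_planted_per_cluster must give counts for clusters 1..3")
  if (cfg$n_planted_per_cluster[2] < 2 * cfg$n_cis_pairs)
    ct_config_error("cluster 2 must hold at least the 2 * n_cis_pairs cis genes")
  structure(cfg, class = "sim_config")
}

#' Default study design
#'
#' @return data.frame with one row per (genotype, condition, timepoint):
#'   3 tumor and 2 tumor-free replicates per genotype-timepoint.
#' @export
default_design <- function() {
  d <- expand.grid(genotype = c("WT", "KO"),
                   condition = c("tumor", "tumor_free"),
                   timepoint_weeks = c(6L, 8L, 10L, 12L),
                   stringsAsFactors = FALSE)
  d$n_replicates <- ifelse(d$condition == "tumor", 3L, 2L)
  d[order(d$genotype, d$condition, d$timepoint_weeks), ]
}

# Sample sheet implied by a design table; naming is deterministic.
make_samples <- function(config) {
  d <- config$design
  rows <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_wk%02d_r%d", d$genotype[i],
                                   d$condition[i], d$timepoint_weeks[i],
                                   seq_len(d$n_replicates[i])),
               genotype = d$genotype[i], condition = d$condition[i],
               timepoint_weeks = d$timepoint_weeks[i],
               replicate = seq_len(d$n_replicates[i]),
               stringsAsFactors = FALSE)
  }))
  validate_samplesheet(rows)
}

# Temporal archetype shapes over weeks 6/8/10/12 in units of planted_lfc.
# 1: early spike then decay; 2: gradual rise, maintained high; 3: early drop,
# maintained low. KO trajectories are delayed by one timepoint (tumor
# initiation delay), so in stage-aligned coordinates both genotypes share the
# same shapes.
archetype_shapes <- function() {
  rbind(`1` = c(1.2, 0.5, 0.15, 0.05),
        `2` = c(0.65, 1.2, 1.5, 1.55),
        `3` = c(-1, -1.1, -1.15, -1.15))
}

# Cis-pair genes follow a high-amplitude archetype-2 (sustained rise)
# trajectory: most of the pair correlation is carried by the shared tumor
# trajectory itself, so the genes stay strongly differentially expressed;
# simulate_counts rescales the amplitude analytically (and, if still
# insufficient, adds a shared latent factor) to hit cis_pair_r_target.
cis_pair_shape <- function() c(1.3, 1.65, 2.0, 2.1)

#' Generate a toy annotation with planted cis geometry
#'
#' Genes are placed without overlap, uniformly at random, on
#' `n_chromosomes` chromosomes. Special features: one `Pthlh_like`
#' protein-coding gene with 5 exons, and `GFP`/`mTd` spike-in records on
#' their own contig. For each requested cis pair a lncRNA
#' (`LNC_CIS<i>`) is placed so that its span gap to its partner
#' protein-coding gene (`PCG_CIS<i>`) is uniform on [0, 500000] bp.
#'
#' @param config a [sim_config()].
#' @return A [gene_annotation()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_genes
    n_lnc <- round(config$lncRNA_fraction * n)
    n_pcg <- n - n_lnc
    if (n_lnc < config$n_cis_pairs || n_pcg < config$n_cis_pairs)
      ct_config_error("not enough lncRNA/protein-coding genes for the requested cis pairs")
    ids <- character(n); biotype <- character(n)
    lnc_idx <- seq_len(n_lnc); pcg_idx <- n_lnc + seq_len(n_pcg)
    ids[lnc_idx] <- sprintf("LNC%05d", lnc_idx)
    ids[pcg_idx] <- sprintf("PCG%05d", seq_len(n_pcg))
    biotype[lnc_idx] <- "lncRNA"; biotype[pcg_idx] <- "protein_coding"
    if (config$n_cis_pairs > 0) {
      ids[seq_len(config$n_cis_pairs)] <- sprintf("LNC_CIS%d", seq_len(config$n_cis_pairs))
      ids[n_lnc + seq_len(config$n_cis_pairs)] <-
        sprintf("PCG_CIS%d", seq_len(config$n_cis_pairs))
    }
    len <- integer(n)
    len[lnc_idx] <- pmin(pmax(round(exp(stats::rnorm(n_lnc, log(1000), 0.4))), 200L), 50000L)
    len[pcg_idx] <- pmin(pmax(round(exp(stats::rnorm(n_pcg, log(3000), 0.5))), 200L), 50000L)

    # entities: cis pairs are placed as one block (pcg, gap, lnc) so the
    # planted span gap is exact and non-overlap is guaranteed
    ncp <- config$n_cis_pairs
    ent <- vector("list", n - ncp)
    k <- 0L
    pair_gap <- if (ncp > 0) round(stats::runif(ncp, 0, 500000)) else integer(0)
    used_in_pair <- c(seq_len(ncp), n_lnc + seq_len(ncp))
    for (i in seq_len(ncp)) {
      k <- k + 1L
      lnc_first <- stats::runif(1) < 0.5
      members <- if (lnc_first) c(i, n_lnc + i) else c(n_lnc + i, i)
      ent[[k]] <- list(idx = members, gaps = pair_gap[i],
                       len = sum(len[members]) + pair_gap[i])
    }
    for (i in setdiff(seq_len(n), used_in_pair)) {
      k <- k + 1L
      ent[[k]] <- list(idx = i, gaps = integer(0), len = len[i])
    }
    chrom_of <- sample.int(config$n_chromosomes, length(ent), replace = TRUE)
    start <- integer(n)
    chrom <- character(n)
    for (cc in seq_len(config$n_chromosomes)) {
      e_idx <- which(chrom_of == cc)
      if (!length(e_idx)) next
      e_idx <- sample(e_idx)  # random order along the chromosome
      tot <- sum(vapply(ent[e_idx], `[[`, 0, "len"))
      free <- config$chrom_length_bp - tot
      if (free < 0)
        ct_stop(sprintf(
          "cannot place %d features (%d bp) on a %d bp chromosome; increase chrom_length_bp",
          length(e_idx), as.integer(tot), as.integer(config$chrom_length_bp)),
          "cistraj_capacity_error")
      cuts <- sort(stats::runif(length(e_idx), 0, free))
      gaps <- diff(c(0, cuts))
      pos <- 0
      for (j in seq_along(e_idx)) {
        pos <- pos + gaps[j]
        e <- ent[[e_idx[j]]]
        at <- round(pos)
        for (m in seq_along(e$idx)) {
          gi <- e$idx[m]
          start[gi] <- at
          chrom[gi] <- paste0("chr", cc)
          at <- at + len[gi] + if (m <= length(e$gaps)) e$gaps[m] else 0L
        }
        pos <- pos + e$len
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)

    genes <- data.frame(gene_id = ids, symbol = ids, chrom = chrom,
                        start = start, end = start + len, strand = strand,
                        biotype = biotype, stringsAsFactors = FALSE)
    # special features on a dedicated contig: floxed-exon gene + reporters
    pthlh_start <- 100000L
    special <- data.frame(
      gene_id = c("Pthlh_like", "GFP", "mTd"),
      symbol = c("Pthlh_like", "GFP", "mTd"),
      chrom = c("chrS", "chrS", "chrS"),
      start = c(pthlh_start, 1000L, 4000L),
      end = c(pthlh_start + 12000L, 2000L, 5000L),
      strand = c("+", "+", "+"),
      biotype = c("protein_coding", "spike_in", "spike_in"),
      stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = "Pthlh_like",
                        start = pthlh_start + (0:4) * 2400L,
                        end = pthlh_start + (0:4) * 2400L + 800L)
    gene_annotation(rbind(genes, special), exons)
  })
}

#' Build the planted ground truth
#'
#' Assigns planted genes to the three temporal archetypes, marks each as
#' shared, WT-exclusive or KO-exclusive, places the cis-pair genes in
#' archetype 2 with WT-exclusive effects, and (optionally) selects KO tumor
#' samples as recombination escapees.
#'
#' @param config a [sim_config()].
#' @param annotation the matching [generate_annotation()] output.
#' @return A `ground_truth` list: `de_genes` (gene_id, cluster, scope),
#'   `trajectories` (per-genotype gene x timepoint log2FC matrices),
#'   `cis_pairs` (lncRNA_id, pcg_id), `escapee_samples`.
#' @export
make_ground_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 11L), {
    ncp <- config$n_cis_pairs
    cis <- if (ncp > 0)
      data.frame(lncRNA_id = sprintf("LNC_CIS%d", seq_len(ncp)),
                 pcg_id = sprintf("PCG_CIS%d", seq_len(ncp)),
                 stringsAsFactors = FALSE)
    else data.frame(lncRNA_id = character(0), pcg_id = character(0))
    cis_genes <- c(cis$lncRNA_id, cis$pcg_id)
    stopifnot(all(cis_genes %in% annotation$gene_id))

    pool <- setdiff(annotation$gene_id[annotation$biotype != "spike_in"],
                    c(cis_genes, "Pthlh_like"))
    n_extra <- config$n_planted_per_cluster
    n_extra[2] <- n_extra[2] - length(cis_genes)
    if (sum(n_extra) > length(pool))
      ct_config_error("not enough genes to plant the requested clusters")
    picked <- sample(pool, sum(n_extra))
    cluster <- rep.int(1:3, n_extra)
    scope <- character(length(picked))
    for (cl in 1:3) {
      idx <- which(cluster == cl)
      n_wt <- round(config$wt_exclusive_fraction * length(idx))
      n_ko <- round(config$ko_exclusive_fraction * length(idx))
      scope[idx] <- c(rep("wt_only", n_wt), rep("ko_only", n_ko),
                      rep("shared", length(idx) - n_wt - n_ko))
    }
    de <- data.frame(gene_id = c(cis_genes, picked),
                     cluster = c(rep(2L, length(cis_genes)), cluster),
                     scope = c(rep("wt_only", length(cis_genes)), scope),
                     stringsAsFactors = FALSE)

    shapes <- archetype_shapes() * config$planted_lfc
    weeks <- c(6, 8, 10, 12)
    traj <- function(genotype) {
      m <- matrix(0, nrow(de), length(weeks),
                  dimnames = list(de$gene_id, as.character(weeks)))
      for (i in seq_len(nrow(de))) {
        sh <- if (de$gene_id[i] %in% cis_genes)
          cis_pair_shape() * config$planted_lfc
        else shapes[as.character(de$cluster[i]), ]
        if (genotype == "WT" && de$scope[i] != "ko_only") m[i, ] <- sh
        if (genotype == "KO" && de$scope[i] != "wt_only")
          m[i, ] <- c(0, sh[1:3])  # one-timepoint onset delay in KO
      }
      m
    }
    samples <- make_samples(config)
    ko_tumor <- samples$sample_id[samples$genotype == "KO" &
                                    samples$condition == "tumor"]
    escapees <- if (config$n_escapees > 0)
      sort(sample(ko_tumor, config$n_escapees)) else character(0)

    structure(list(de_genes = de,
                   trajectories = list(WT = traj("WT"), KO = traj("KO")),
                   cis_pairs = cis, escapee_samples = escapees),
              class = "ground_truth")
  })
}

#' Simulate a count matrix from annotation and ground truth
#'
#' Tumor samples draw NB counts at `baseline * 2^log2FC(timepoint)`;
#' tumor-free samples at baseline. Per-sample library-size multipliers are
#' log-normal. The GFP reporter is high and mTd near zero in every sample
#' (sorted GFP+ cells); the `Pthlh_like` fourth-exon feature (returned in the
#' `"exon_counts"` attribute) is zero in KO samples except declared escapees.
#' Cis-paired genes share a per-sample log-scale latent factor sized so the
#' expected Pearson correlation of their log counts is about
#' `cis_pair_r_target`.
#'
#' @param config a [sim_config()].
#' @param annotation from [generate_annotation()].
#' @param truth from [make_ground_truth()].
#' @return A [count_matrix()] with attribute `"exon_counts"` (1 x samples
#'   matrix for feature `Pthlh_like:exon4`).
#' @export
simulate_counts <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  unknown <- setdiff(truth$de_genes$gene_id, annotation$gene_id)
  if (length(unknown))
    ct_data_error(paste0("ground truth references unknown gene(s): ",
                         paste(unknown, collapse = ", ")))
  samples <- make_samples(config)
  withr::with_seed(stage_seed(config$seed, 2L), {
    g <- annotation$gene_id
    nG <- length(g); nS <- nrow(samples)
    mu0 <- exp(stats::rnorm(nG, config$mean_log_expression,
                            config$sd_log_expression))
    names(mu0) <- g
    # planted DE genes emulate detectable tumor drivers: their baselines are
    # drawn from the upper expression range so the planted signal is not
    # drowned by shot noise at the study's replicate numbers
    planted <- truth$de_genes$gene_id
    mu0[planted] <- exp(stats::rnorm(length(planted),
                                     config$mean_log_expression + 0.7, 0.4))
    mu0["GFP"] <- 5000; mu0["mTd"] <- 0.2
    mu0["Pthlh_like"] <- exp(stats::rnorm(1, log(500), 0.2))
    # planted pairs sit in the upper expression range so correlation and
    # recovery are measured on well-detected transcripts
    cis_ids <- c(truth$cis_pairs$lncRNA_id, truth$cis_pairs$pcg_id)
    mu0[cis_ids] <- exp(config$mean_log_expression + 0.5)
    lib <- exp(stats::rnorm(nS, 0, config$library_size_sdlog))

    lfc <- matrix(0, nG, nS, dimnames = list(g, samples$sample_id))
    tumor <- samples$condition == "tumor"
    for (j in which(tumor)) {
      tr <- truth$trajectories[[samples$genotype[j]]]
      lfc[rownames(tr), j] <- tr[, as.character(samples$timepoint_weeks[j])]
    }

    # Plant the pair correlation (log2 scale, measured across the whole
    # design). A target r against per-gene measurement variance vbar
    # (delta method, (log2 e)^2 (1/mu + alpha)) requires shared variance
    # needed = r/(1-r) * vbar. The shared tumor trajectory contributes
    # var(traj) for free; if short, the amplitude is scaled up (capped) and
    # a shared latent factor tops it off; if the shared variance overshoots
    # the target, a small independent per-gene jitter brings r back down.
    # Riding the trajectory rather than pure latent noise keeps the pair
    # genes cleanly testable for DE and cleanly clusterable.
    if (nrow(truth$cis_pairs)) {
      v_of <- function(id) log2(exp(1))^2 * (1 / mu0[id] + config$dispersion)
      for (i in seq_len(nrow(truth$cis_pairs))) {
        pair <- c(truth$cis_pairs$lncRNA_id[i], truth$cis_pairs$pcg_id[i])
        r <- config$cis_pair_r_target
        vbar <- mean(vapply(pair, v_of, 0))
        needed <- r / (1 - r + 1e-12) * vbar
        vtraj <- stats::var(lfc[pair[1], ])
        if (vtraj > 0) {
          s <- max(1, min(sqrt(needed / vtraj), 1.5))
          lfc[pair, ] <- lfc[pair, , drop = FALSE] * s
          sdz2 <- max(0, needed - s^2 * vtraj)
        } else {
          sdz2 <- needed
        }
        if (sdz2 > 1e-12) {
          z <- stats::rnorm(nS, 0, sqrt(sdz2)) - sdz2 * log(2) / 2
          lfc[pair, ] <- sweep(lfc[pair, , drop = FALSE], 2, z, "+")
        }
        v_shared <- if (vtraj > 0) s^2 * vtraj + sdz2 else sdz2
        sde2 <- max(0, v_shared * (1 - r) / r - vbar)
        if (sde2 > 1e-12) {
          e <- matrix(stats::rnorm(2 * nS, 0, sqrt(sde2)) - sde2 * log(2) / 2,
                      2, nS)
          lfc[pair, ] <- lfc[pair, , drop = FALSE] + e
        }
      }
    }

    mu <- sweep(mu0 * 2^lfc, 2, lib, "*")
    counts <- matrix(stats::rnbinom(nG * nS, mu = as.vector(mu),
                                    size = 1 / config$dispersion),
                     nG, nS, dimnames = list(g, samples$sample_id))

    exon4 <- integer(nS)
    recombined_ko <- samples$genotype == "KO" &
      !samples$sample_id %in% truth$escapee_samples
    for (j in seq_len(nS)) {
      exon4[j] <- if (recombined_ko[j]) 0L
      else stats::rbinom(1, size = counts["Pthlh_like", j], prob = 0.2)
    }
    exon_counts <- matrix(exon4, 1, nS,
                          dimnames = list("Pthlh_like:exon4", samples$sample_id))
    cm <- count_matrix(counts, samples)
    attr(cm, "exon_counts") <- exon_counts
    cm
  })
}

# Gene sets for the fixture: one set per planted archetype plus random
# decoys drawn from the whole gene universe.
make_gene_sets <- function(config, annotation, truth,
                           n_decoys = 20, decoy_size = 30) {
  withr::with_seed(stage_seed(config$seed, 3L), {
    universe <- annotation$gene_id[annotation$biotype != "spike_in"]
    sets <- list()
    for (cl in 1:3) {
      members <- truth$de_genes$gene_id[truth$de_genes$cluster == cl]
      if (length(members))
        sets[[paste0("PLANTED_CLUSTER", cl)]] <-
          list(name = paste0("PLANTED_CLUSTER", cl),
               description = paste("planted archetype", cl), genes = members)
    }
    for (i in seq_len(n_decoys)) {
      nm <- sprintf("DECOY_SET%02d", i)
      sets[[nm]] <- list(name = nm, description = "random decoy",
                         genes = sort(sample(universe, decoy_size)))
    }
    structure(sets, class = "gene_set_collection")
  })
}

#' Generate the full fixture in memory
#'
#' @param config a [sim_config()].
#' @return list with `config`, `annotation`, `truth`, `counts`
#'   (a [count_matrix()] carrying the `"exon_counts"` attribute) and `sets`.
#' @export
generate_fixture <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  truth <- make_ground_truth(config, annotation)
  counts <- simulate_counts(config, annotation, truth)
  list(config = config, annotation = annotation, truth = truth,
       counts = counts, sets = make_gene_sets(config, annotation, truth))
}

#' Write a fixture directory
#'
#' Writes `annotation.gtf`, `counts.tsv`, `samples.tsv`, `sets.gmt`,
#' `truth.tsv` and `exon_counts.tsv`, all readable by the package's readers.
#' Output is byte-identical across runs at a fixed seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the in-memory fixture list.
#' @export
export_fixture <- function(config, out_dir) {
  fx <- generate_fixture(config)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    ct_stop(paste0("cannot create fixture directory ", out_dir), "cistraj_io_error")
  write_gtf(fx$annotation, file.path(out_dir, "annotation.gtf"))
  write_counts(fx$counts, file.path(out_dir, "counts.tsv"),
               file.path(out_dir, "samples.tsv"))
  write_gmt(fx$sets, file.path(out_dir, "sets.gmt"))
  truth_df <- fx$truth$de_genes
  cis <- fx$truth$cis_pairs
  truth_df$cis_partner <- cis$pcg_id[match(truth_df$gene_id, cis$lncRNA_id)]
  idx <- match(truth_df$gene_id, cis$pcg_id)
  truth_df$cis_partner[!is.na(idx)] <- cis$lncRNA_id[idx[!is.na(idx)]]
  truth_df$cis_partner[is.na(truth_df$cis_partner)] <- "NA"
  write_tsv_commented(truth_df, file.path(out_dir, "truth.tsv"),
                      params = list(seed = fx$config$seed,
                                    planted_lfc = fx$config$planted_lfc,
                                    escapee_samples = if (length(fx$truth$escapee_samples))
                                      fx$truth$escapee_samples else "none"))
  ex <- attr(fx$counts, "exon_counts")
  ex_df <- data.frame(feature_id = rownames(ex), ex, check.names = FALSE)
  utils::write.table(ex_df, file.path(out_dir, "exon_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fx)
}
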