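# deterministic per-stage seed expansion from one master seed
stage_seed <- function(master, k) {
  as.integer((as.double(master) * 97 + 31 * k) %% 2147483647L)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Input is either a
#' [sim_config] (the default demo: simulate, then analyze) or a list of
#' file paths (`counts` and `designs` as named-per-tissue vectors, `gmt` a
#' GMT path).
#'
#' @param sim a [sim_config], or `NULL` when `paths` is given.
#' @param paths list with `counts`, `designs` (named per tissue) and `gmt`.
#' @param n_rank ranked-list size per direction; `NULL` uses the
#'   [rank_top_bottom()] default rule.
#' @param score_threshold absolute standardized-score cutoff for the PCA
#'   route's threshold mode.
#' @param alpha nominal p cutoff used at the cross-tissue step and for
#'   shared enriched pathways.
#' @param gsea_n_perm,weight_p GSEA permutations and weighting exponent.
#' @param overlap_n_perm permutations for overlap tests (0 = hypergeometric
#'   only).
#' @param network_thresholds two absolute-correlation thresholds: the
#'   working threshold and the near-deterministic "core" threshold.
#' @param seed master seed; all stage seeds are expanded from it.
#' @param out_dir if non-NULL, the report bundle is written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL, n_rank = NULL,
                            score_threshold = 3, alpha = 0.05,
                            gsea_n_perm = 1000, weight_p = 1,
                            overlap_n_perm = 1000,
                            network_thresholds = c(0.7, 0.98), seed = 1,
                            out_dir = NULL) {
  if (any(network_thresholds <= 0 | network_thresholds > 1)) {
    abort("Network thresholds must lie in (0, 1].")
  }
  structure(list(sim = sim, paths = paths, n_rank = n_rank,
                 score_threshold = score_threshold, alpha = alpha,
                 gsea_n_perm = gsea_n_perm, weight_p = weight_p,
                 overlap_n_perm = overlap_n_perm,
                 network_thresholds = network_thresholds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, 1L)
    sim <- do.call(sim_config, sim[setdiff(names(sim), character(0))])
    exp <- generate_experiment(sim)
    return(list(tissues = exp$tissues, gene_sets = exp$gene_sets,
                truth = exp$truth))
  }
  p <- config$paths
  tissues <- list()
  for (nm in names(p$counts)) {
    tissues[[nm]] <- list(counts = read_counts(p$counts[[nm]]),
                          design = read_design(p$designs[[nm]]))
  }
  list(tissues = tissues,
       gene_sets = if (!is.null(p$gmt)) read_gmt(p$gmt) else NULL,
       truth = NULL)
}

#' Run the full dual-route analysis
#'
#' Per tissue: log-CPM, correlation PCA with a posteriori discriminant
#' search, component-score gene selection, trend-moderated differential
#' expression, top/bottom logFC ranking, and a PCA-vs-DE consistency
#' overlap. Across tissues: the shared up/down core with overlap statistics,
#' per-category counts, preranked GSEA per tissue and shared enriched
#' pathways. On the planted (or supplied) co-expression module: networks at
#' the working and core thresholds for PKH26+, PKH26- and pooled samples,
#' centralities, giant-component class partition, betweenness rewiring,
#' edge-count comparison and pathway-distribution tables.
#'
#' @param config a [pipeline_config].
#' @return a `quiescr_report` list (see the elements it prints); written to
#'   `config$out_dir` when set.
#' @export
run_quiescence_pipeline <- function(config = pipeline_config()) {
  inputs <- load_pipeline_inputs(config)
  tissues <- inputs$tissues
  report <- list(config = config, tissues = list(), truth = inputs$truth)

  for (nm in names(tissues)) {
    counts <- tissues[[nm]]$counts
    design <- tissues[[nm]]$design
    lcpm <- log_cpm(counts)
    pca <- sample_correlation_pca(lcpm)
    disc <- find_discriminating_component(pca, design, "phenotype")
    de <- fit_two_group_trend(lcpm, design)
    ranks <- rank_top_bottom(de, n = config$n_rank)
    universe <- sort(unique(de$gene))
    ranks_sig <- rank_top_bottom(de, n = config$n_rank,
                                 alpha = config$alpha)
    pca_sel <- NULL
    consistency <- NULL
    if (disc$matched) {
      # the "PCA-derived signature": genes with |standardized score| above
      # the threshold, compared against the nominally significant DE blocks
      pca_sel <- select_genes_by_score(pca, disc$component, "threshold",
                                       threshold = config$score_threshold,
                                       orientation = disc$orientation)
      consistency <- list(
        up = pairwise_overlap(pca_sel$up$gene, ranks_sig$up$gene, universe,
                              config$overlap_n_perm,
                              stage_seed(config$seed, 2L)),
        down = pairwise_overlap(pca_sel$down$gene, ranks_sig$down$gene,
                                universe, config$overlap_n_perm,
                                stage_seed(config$seed, 2L)))
    }
    report$tissues[[nm]] <- list(
      design = design, logcpm = lcpm, pca = pca,
      variance_table = variance_table(pca$eigenvalues),
      discriminant = disc, de = de, ranks = ranks, ranks_sig = ranks_sig,
      pca_selection = pca_sel, consistency = consistency,
      universe = universe)
  }

  # cross-tissue core on the nominally significant top/bottom blocks
  if (length(tissues) >= 2L) {
    a <- report$tissues[[1L]]; b <- report$tissues[[2L]]
    universe <- intersect(a$universe, b$universe)
    report$core <- cross_tissue_core(
      a$ranks_sig$up$gene, b$ranks_sig$up$gene,
      a$ranks_sig$down$gene, b$ranks_sig$down$gene,
      universe, config$overlap_n_perm, stage_seed(config$seed, 3L))
    if (!is.null(inputs$gene_sets)) {
      report$category_counts <- category_counts(
        report$core$shared_up, report$core$shared_down, inputs$gene_sets)
    }
  }

  # preranked GSEA per tissue and shared enriched pathways
  if (!is.null(inputs$gene_sets)) {
    gsea <- list()
    for (nm in names(report$tissues)) {
      de <- report$tissues[[nm]]$de
      dedup <- de |>
        group_by(.data$gene) |>
        slice(which.max(abs(.data$logFC))) |>
        ungroup()
      ranked <- setNames(dedup$logFC, dedup$gene)
      gsea[[nm]] <- gsea_collection(ranked, inputs$gene_sets,
                                    n_perm = config$gsea_n_perm,
                                    weight_p = config$weight_p,
                                    seed = stage_seed(config$seed, 4L))
    }
    report$gsea <- gsea
    if (length(gsea) >= 2L) {
      report$shared_pathways <- shared_enriched(
        gsea[[1L]], gsea[[2L]], alpha = config$alpha,
        n_perm = config$overlap_n_perm, seed = stage_seed(config$seed, 5L))
    }
  }

  # network stage on the module set (and the shared-up core when sizeable)
  module_genes <- if (!is.null(inputs$gene_sets) &&
                      "MODULE_FULL" %in% names(inputs$gene_sets)) {
    inputs$gene_sets[["MODULE_FULL"]]
  } else {
    report$core$shared_up %||% character(0)
  }
  pooled <- pool_tissues(report$tissues)
  report$network <- network_stage(pooled$lcpm, pooled$design, module_genes,
                                  config, inputs$gene_sets)
  if (!is.null(report$core) && length(report$core$shared_up) >= 10L) {
    report$network_core_up <- network_stage(pooled$lcpm, pooled$design,
                                            report$core$shared_up, config,
                                            inputs$gene_sets)
  }

  # hash the analysis configuration only; the output location is not part
  # of the result's identity
  hashable <- config[setdiff(names(config), "out_dir")]
  report$manifest <- list(
    config_hash = rlang::hash(hashable), master_seed = config$seed,
    package_version = as.character(utils::packageVersion("quiescr")),
    n_tissues = length(tissues))
  report <- structure(report, class = "quiescr_report")
  if (!is.null(config$out_dir)) write_report_bundle(report, config$out_dir)
  report
}

# common-gene log-CPM matrix across tissues, columns pooled
pool_tissues <- function(tissues) {
  genes <- Reduce(intersect, lapply(tissues, function(t) rownames(t$logcpm)))
  mats <- lapply(tissues, function(t) unclass(t$logcpm)[genes, , drop = FALSE])
  lcpm <- expr_mat(do.call(cbind, mats), scale = "logcpm")
  design <- bind_rows(lapply(tissues, function(t) t$design))
  list(lcpm = lcpm, design = design)
}

network_stage <- function(lcpm, design, genes, config, collection) {
  genes <- intersect(genes, rownames(lcpm))
  if (length(genes) < 3L) return(NULL)
  thr <- config$network_thresholds
  comparison <- lapply(thr, function(t) {
    edge_count_comparison(lcpm, design, genes, threshold = t)
  })
  names(comparison) <- paste0("t", thr)
  nets_work <- attr(comparison[[1L]], "networks")
  cent_plus <- betweenness_centrality(nets_work$plus)
  cent_minus <- betweenness_centrality(nets_work$minus)
  nets_core <- attr(comparison[[length(thr)]], "networks")
  partition <- class_partition(nets_core$plus, nets_core$minus,
                               universe = genes,
                               n_perm = config$overlap_n_perm,
                               seed = stage_seed(config$seed, 6L))
  classes <- list(plus = giant_component(nets_core$plus)$members,
                  minus = giant_component(nets_core$minus)$members,
                  all = giant_component(nets_core$all)$members)
  out <- list(
    genes = genes, edge_counts = comparison,
    centrality = list(
      plus = left_join(cent_plus, clustering_coefficients(nets_work$plus),
                       by = c("gene", "degree")),
      minus = left_join(cent_minus, clustering_coefficients(nets_work$minus),
                        by = c("gene", "degree"))),
    rewiring = rewiring_report(cent_plus, cent_minus),
    partition = partition, giant_classes = classes)
  if (!is.null(collection)) {
    out$pathway_distribution <- pathway_distribution(classes, collection)
  }
  out
}

#' @export
print.quiescr_report <- function(x, ...) {
  cat("<quiescr_report>\n")
  for (nm in names(x$tissues)) {
    t <- x$tissues[[nm]]
    cat(sprintf("  %s: %d genes x %d samples; discriminating component: %s\n",
                nm, t$pca$n_genes, t$pca$n_samples,
                if (t$discriminant$matched) t$discriminant$component else "none"))
  }
  if (!is.null(x$core)) {
    cat(sprintf("  shared core: %d up, %d down (RR up = %.2f)\n",
                length(x$core$shared_up), length(x$core$shared_down),
                x$core$overlap_up$RR))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  module network: %d genes; shared giant-component class: %d genes\n",
                length(x$network$genes), length(x$network$partition$shared)))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the per-tissue variance tables, loading matrices, gene scores, DE
#' tables, ranked lists, overlap summaries, GSEA tables, network exports and
#' a JSON manifest under `dir`. All files are plain text and bit-stable for
#' a fixed configuration.
#'
#' @param report a `quiescr_report`.
#' @param dir output directory.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  for (nm in names(report$tissues)) {
    t <- report$tissues[[nm]]
    wtsv(variance_table(t$pca$eigenvalues, digits = 3),
         sprintf("%s_variance_table.tsv", nm))
    wtsv(data.frame(sample = rownames(t$pca$eigenvectors),
                    t$pca$eigenvectors, check.names = FALSE),
         sprintf("%s_loadings.tsv", nm))
    wtsv(select(t$de, "gene", "logFC", "aveExpr", "t", "p_value"),
         sprintf("%s_diffexp.tsv", nm))
    if (!is.null(t$consistency)) {
      wtsv(bind_rows(up = t$consistency$up, down = t$consistency$down,
                     .id = "direction"),
           sprintf("%s_consistency_overlap.tsv", nm))
    }
  }
  if (!is.null(report$core)) {
    wtsv(bind_rows(up = report$core$overlap_up,
                   down = report$core$overlap_down, .id = "direction"),
         "cross_tissue_overlap.tsv")
    writeLines(report$core$shared_up, file.path(dir, "shared_up.txt"))
    writeLines(report$core$shared_down, file.path(dir, "shared_down.txt"))
  }
  if (!is.null(report$category_counts)) {
    wtsv(report$category_counts, "category_counts.tsv")
  }
  for (nm in names(report$gsea)) {
    tab <- report$gsea[[nm]]
    tab$leading_edge <- vapply(tab$leading_edge, paste, character(1L),
                               collapse = ",")
    wtsv(tab, sprintf("%s_gsea.tsv", nm))
  }
  if (!is.null(report$network)) {
    nets <- attr(report$network$edge_counts[[1L]], "networks")
    for (sub in names(nets)) {
      write_network(nets[[sub]], file.path(dir, sprintf("net_%s.sif", sub)))
    }
    wtsv(bind_rows(report$network$edge_counts, .id = "threshold"),
         "edge_counts.tsv")
    wtsv(report$network$rewiring, "rewiring.tsv")
    if (!is.null(report$network$pathway_distribution)) {
      wtsv(report$network$pathway_distribution$counts,
           "pathway_distribution.tsv")
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
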