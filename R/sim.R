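#' Simulation configuration
#'
#' Describes a two-tissue label-retention experiment: each tissue has one or
#' more cell lines, each line contributes `replicates` samples per phenotype
#' (quiescent `PKH26_plus` and proliferating `PKH26_minus`). On the log2
#' scale, expected expression is
#'
#' `x = baseline(tissue) + line_offset + signed_effect + w * z + noise`
#'
#' where `baseline` is a per-tissue gene profile shared by all samples (the
#' "tissue attractor" that surfaces as an all-same-sign first component),
#' `line_offset` a per-line gene profile, `signed_effect` is `+effect_size`
#' for planted up-genes and `-effect_size` for planted down-genes in PKH26+
#' samples only, and `w * z` a latent-factor term creating a densely
#' co-expressed module. Module genes are additionally up-shifted by
#' `+effect_size` in PKH26+ samples of every tissue, emulating a
#' morphogenesis-like module: a tightly co-regulated block inside the shared
#' quiescence program. With `wiring = "state_specific"` the module loadings
#' are drawn independently for the two phenotypes, so the module's wiring is
#' rewired between states. Counts are negative-binomial around
#' `libsize * 2^x / normalizer` with gene-constant dispersion; a per-tissue
#' constant normalizer keeps log-scale group differences of planted genes
#' exactly `effect_size` when noise and dispersion are switched off.
#'
#' @param n_genes number of genes.
#' @param tissues list of tissue specs `list(name=, n_lines=, replicates=)`;
#'   the default mirrors a two-line 3+3-replicate tissue (12 samples) and a
#'   one-line 5+5 tissue.
#' @param signature_size planted genes per direction per tissue.
#' @param shared_fraction fraction of each tissue's signature shared across
#'   tissues, in \[0, 1\].
#' @param effect_size quiescence shift in log2 units.
#' @param module_size genes in the correlated module (disjoint from the
#'   signature pool).
#' @param module_strength latent-factor loading magnitude (log2 units).
#' @param baseline_mu,baseline_sigma per-gene log2 baseline distribution.
#' @param line_sigma per-line gene-offset scale (log2 units).
#' @param dispersion negative-binomial dispersion; `0` yields deterministic
#'   expected counts (no sampling noise).
#' @param noise_sigma log2-scale i.i.d. normal noise.
#' @param libsize_mu,libsize_cv library-size mean and coefficient of
#'   variation.
#' @param wiring `"state_specific"` (independent module loadings per
#'   phenotype) or `"shared"` (one loading vector for all samples).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       tissues = list(
                         list(name = "lung", n_lines = 2, replicates = 3),
                         list(name = "colon", n_lines = 1, replicates = 5)),
                       signature_size = 300,
                       shared_fraction = 0.6,
                       effect_size = 2,
                       module_size = 120,
                       module_strength = 1,
                       baseline_mu = 4, baseline_sigma = 2,
                       line_sigma = 1,
                       dispersion = 0.1,
                       noise_sigma = 0.3,
                       libsize_mu = 5e6, libsize_cv = 0.2,
                       wiring = c("state_specific", "shared"),
                       seed = 1) {
  wiring <- match.arg(wiring)
  cfg <- list(n_genes = as.integer(n_genes), tissues = tissues,
              signature_size = as.integer(signature_size),
              shared_fraction = shared_fraction, effect_size = effect_size,
              module_size = as.integer(module_size),
              module_strength = module_strength,
              baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
              line_sigma = line_sigma, dispersion = dispersion,
              noise_sigma = noise_sigma,
              libsize_mu = libsize_mu, libsize_cv = libsize_cv,
              wiring = wiring, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  n_sh <- round(cfg$shared_fraction * cfg$signature_size)
  # disjoint pools: shared + tissue-specific per direction, plus the module
  need <- 2L * (2L * cfg$signature_size - n_sh) + cfg$module_size
  if (need > cfg$n_genes) {
    abort(sprintf(
      "Infeasible sizes: signature + module pools need %d genes, have %d.",
      need, cfg$n_genes))
  }
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    abort("`shared_fraction` must lie in [0, 1].")
  }
  if (cfg$dispersion < 0) abort("`dispersion` must be >= 0.")
  if (length(cfg$tissues) < 1) abort("At least one tissue is required.")
  for (ts in cfg$tissues) {
    if (ts$replicates < 1 || ts$n_lines < 1) {
      abort("Replicates and line counts must be positive.")
    }
  }
  invisible(cfg)
}

sim_gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a synthetic label-retention experiment
#'
#' Draws per-tissue count matrices, sample designs, a ground-truth record and
#' a gene-set collection from a [sim_config]. The gene-set collection
#' contains the full planted module, overlapping pathway-like subsets of it,
#' and size-matched decoy sets of background genes.
#'
#' @param config a [sim_config].
#' @return a `quiescr_sim` list with elements `tissues` (named list of
#'   `list(counts, design)`), `truth`, `gene_sets`, `config`. `truth` holds
#'   `up`/`down` per tissue, `shared_up`/`shared_down`, `module_members`,
#'   per-tissue signed effect vectors and per-sample latent factor values.
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sim_gene_ids(n)
  sig <- config$signature_size
  n_sh <- round(config$shared_fraction * sig)
  n_ts <- length(config$tissues)

  # partition the gene index space into disjoint pools
  pool <- seq_len(n)
  take <- function(k) {
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }
  shared_up <- take(n_sh)
  shared_down <- take(n_sh)
  spec_up <- lapply(seq_len(n_ts), function(i) take(sig - n_sh))
  spec_down <- lapply(seq_len(n_ts), function(i) take(sig - n_sh))
  module <- take(config$module_size)

  truth <- list(tissues = list(), shared_up = genes[shared_up],
                shared_down = genes[shared_down],
                module_members = genes[module])
  tissues_out <- list()

  for (i in seq_len(n_ts)) {
    ts <- config$tissues[[i]]
    up_idx <- c(shared_up, spec_up[[i]])
    down_idx <- c(shared_down, spec_down[[i]])
    effect <- numeric(n)
    effect[up_idx] <- config$effect_size
    effect[down_idx] <- -config$effect_size
    effect[module] <- config$effect_size

    baseline <- rnorm(n, config$baseline_mu, config$baseline_sigma)
    line_off <- matrix(rnorm(n * ts$n_lines, 0, config$line_sigma),
                       n, ts$n_lines)

    design <- tidyr::expand_grid(
      line = sprintf("%s%d", ts$name, seq_len(ts$n_lines)),
      phenotype = c("PKH26_plus", "PKH26_minus"),
      replicate = seq_len(ts$replicates))
    design <- mutate(design,
                     tissue = ts$name,
                     sample = sprintf("%s_%s_r%d", .data$line,
                                      ifelse(.data$phenotype == "PKH26_plus",
                                             "p", "m"),
                                      .data$replicate))
    design <- select(design, "sample", "tissue", "line", "phenotype",
                     "replicate")
    ns <- nrow(design)
    is_plus <- design$phenotype == "PKH26_plus"
    line_num <- as.integer(factor(design$line, levels = unique(design$line)))

    # deterministic part of log2 expression
    x_det <- baseline + matrix(0, n, ns)
    x_det <- x_det + line_off[, line_num, drop = FALSE]
    x_det[, is_plus] <- x_det[, is_plus] + effect

    # latent module factor; loadings per state when wiring is state-specific
    z <- rnorm(ns)
    w_plus <- config$module_strength *
      sample(c(-1, 1), config$module_size, replace = TRUE) *
      runif(config$module_size, 0.8, 1.2)
    w_minus <- if (config$wiring == "state_specific") {
      config$module_strength *
        sample(c(-1, 1), config$module_size, replace = TRUE) *
        runif(config$module_size, 0.8, 1.2)
    } else {
      w_plus
    }
    x <- x_det
    x[module, is_plus] <- x[module, is_plus] + outer(w_plus, z[is_plus])
    x[module, !is_plus] <- x[module, !is_plus] + outer(w_minus, z[!is_plus])
    if (config$noise_sigma > 0) {
      x <- x + matrix(rnorm(n * ns, 0, config$noise_sigma), n, ns)
    }

    libsize <- config$libsize_mu *
      (1 + config$libsize_cv * rnorm(ns))
    libsize <- pmax(libsize, 0.1 * config$libsize_mu)
    # per-tissue constant normalizer: keeps within-tissue log-ratios intact
    normalizer <- mean(colSums(2^x_det))
    mu <- sweep(2^x, 2L, libsize / normalizer, "*")
    counts <- if (config$dispersion == 0) {
      mu
    } else {
      matrix(rnbinom(n * ns, mu = mu, size = 1 / config$dispersion), n, ns)
    }
    dimnames(counts) <- list(genes, design$sample)

    tissues_out[[ts$name]] <- list(counts = expr_mat(counts, scale = "counts"),
                                   design = design)
    truth$tissues[[ts$name]] <- list(
      up = genes[up_idx], down = genes[down_idx],
      effect = setNames(effect, genes),
      latent = setNames(z, design$sample),
      loadings_plus = setNames(w_plus, genes[module]),
      loadings_minus = setNames(w_minus, genes[module]))
  }

  gene_sets <- sim_gene_sets(genes, module,
                             signature = c(shared_up, shared_down,
                                           unlist(spec_up), unlist(spec_down)),
                             n_subsets = 10L)
  structure(list(tissues = tissues_out, truth = truth,
                 gene_sets = gene_sets, config = config),
            class = "quiescr_sim")
}

# pathway-like overlapping subsets of the module + size-matched decoys
sim_gene_sets <- function(genes, module_idx, signature, n_subsets = 10L) {
  msize <- length(module_idx)
  background <- setdiff(seq_along(genes), c(module_idx, signature))
  sets <- list(MODULE_FULL = structure(genes[module_idx],
                                       description = "planted module"))
  for (k in seq_len(n_subsets)) {
    sz <- max(5L, round(runif(1, 0.4, 0.7) * msize))
    members <- genes[sample(module_idx, sz)]
    sets[[sprintf("MODULE_PATHWAY_%02d", k)]] <-
      structure(members, description = "subset of planted module")
    decoy <- genes[sample(background, sz)]
    sets[[sprintf("DECOY_%02d", k)]] <-
      structure(decoy, description = "size-matched background set")
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a simulated experiment to disk
#'
#' Emits one counts TSV and one design TSV per tissue, a truth JSON, and a
#' gene-sets GMT, all plain text and bit-stable for a fixed simulation.
#'
#' @param sim a `quiescr_sim` from [generate_experiment()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$tissues)) {
    write_counts(sim$tissues[[nm]]$counts,
                 file.path(dir, paste0("counts_", nm, ".tsv")))
    write_design(sim$tissues[[nm]]$design,
                 file.path(dir, paste0("design_", nm, ".tsv")))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
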