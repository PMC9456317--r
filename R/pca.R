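#' Samples-as-variables correlation PCA
#'
#' Performs PCA on the samples x samples Pearson correlation matrix computed
#' over genes, i.e. with samples (expression profiles) as variables and genes
#' as statistical units. This is the transposed orientation relative to the
#' usual samples-as-rows PCA: component loadings live in sample space, and
#' genes receive standardized component scores. The dominant component of
#' such a decomposition is typically an all-same-sign "tissue attractor"
#' (size) component; discrimination between cell states, if present, appears
#' as a lower-variance shape component whose loading signs split the two
#' phenotypes.
#'
#' @param m a log-scale [expr_mat] with at least 3 samples.
#' @return an object of class `quiescr_pca` with elements:
#'   * `eigenvalues` — descending, summing to the number of samples;
#'   * `eigenvectors` — samples x components orthonormal loadings (the form
#'     printed in component-pattern tables), oriented so the first sample's
#'     loading is non-negative (first nonzero if zero);
#'   * `correlation_loadings` — `eigenvectors * sqrt(eigenvalue)`, the
#'     sample-component correlations;
#'   * `gene_scores` — genes x components, z-standardized per component;
#'   * `n_samples`, `n_genes`.
#' @export
sample_correlation_pca <- function(m) {
  assert_log_scale(m)
  values <- unclass(m)
  ns <- ncol(values)
  if (ns < 3L) abort("At least 3 samples are required.")
  sds <- apply(values, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Sample(s) with zero variance across genes: %s",
                  paste(colnames(values)[sds == 0], collapse = ", ")))
  }
  R <- cor(values)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  # sign convention: orient each component on its first nonzero sample loading
  for (k in seq_len(ns)) {
    nz <- which(abs(V[, k]) > 1e-12)
    if (length(nz) && V[nz[1L], k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(values), paste0("PC", seq_len(ns)))
  corr_load <- sweep(V, 2L, sqrt(lambda), "*")
  Z <- scale(values)
  scores <- Z %*% V
  score_sd <- apply(scores, 2L, sd)
  score_mu <- colMeans(scores)
  scores <- sweep(scores, 2L, score_mu, "-")
  pos <- score_sd > 0
  scores[, pos] <- sweep(scores[, pos, drop = FALSE], 2L, score_sd[pos], "/")
  scores[, !pos] <- 0
  rownames(scores) <- rownames(values)
  structure(list(eigenvalues = lambda, eigenvectors = V,
                 correlation_loadings = corr_load, gene_scores = scores,
                 n_samples = ns, n_genes = nrow(values)),
            class = "quiescr_pca")
}

#' @export
print.quiescr_pca <- function(x, ...) {
  cat(sprintf("<quiescr_pca> %d genes x %d samples\n", x$n_genes,
              x$n_samples))
  cat("Top of variance table:\n")
  print(head(variance_table(x$eigenvalues), 4L))
  invisible(x)
}

#' Eigenvalue variance table
#'
#' The standard decomposition report: eigenvalue, difference to the next
#' eigenvalue, proportion of total variance, and cumulative proportion. For a
#' correlation-matrix PCA the total equals the number of variables (samples),
#' which can be supplied explicitly when only the leading part of a spectrum
#' is available.
#'
#' @param eigenvalues non-negative, non-increasing numeric vector.
#' @param n_components number of rows to report (default all supplied).
#' @param total total variance used for proportions (default
#'   `sum(eigenvalues)`).
#' @param digits if non-NULL, round the derived columns for report output;
#'   values are otherwise returned unrounded.
#' @return a tibble with columns `component`, `eigenvalue`, `difference`,
#'   `proportion`, `cumulative`.
#' @export
variance_table <- function(eigenvalues, n_components = length(eigenvalues),
                           total = sum(eigenvalues), digits = NULL) {
  if (any(eigenvalues < 0)) abort("Eigenvalues must be non-negative.")
  if (is.unsorted(rev(eigenvalues) + 1e-12)) {
    abort("Eigenvalues must be non-increasing.")
  }
  ev <- eigenvalues[seq_len(n_components)]
  diffs <- c(-diff(eigenvalues), NA_real_)[seq_len(n_components)]
  out <- tibble(component = seq_len(n_components), eigenvalue = ev,
                difference = diffs, proportion = ev / total,
                cumulative = cumsum(ev) / total)
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(c("eigenvalue", "difference",
                                       "proportion", "cumulative"),
                                     ~ round(.x, digits)))
  }
  out
}

#' Find the phenotype-discriminating component
#'
#' Scans components in variance order and declares a component a match iff
#' the signs of its sample loadings perfectly partition the two levels of the
#' chosen design factor, with no exception (a zero loading is neither sign,
#' so it defeats a match). The search is a posteriori: the decomposition is
#' unsupervised and only the loading space is inspected against the design.
#'
#' @param pca a `quiescr_pca`, or a samples x components loading matrix.
#' @param design a design tibble (see [read_design()]); rows are matched to
#'   loading rownames via the `sample` column.
#' @param factor design column to discriminate: `"phenotype"` or `"line"`.
#' @return a `discriminant_report` list: `matched`, `component` (first match
#'   in variance order, NA if none), `candidates` (all matches),
#'   `orientation` (+1 if the first factor level loads positive on the
#'   matched component, -1 otherwise; for phenotype, +1 means positive gene
#'   scores are up in PKH26+), `factor`, `levels`.
#' @export
find_discriminating_component <- function(pca, design,
                                          factor = c("phenotype", "line")) {
  factor <- match.arg(factor)
  L <- if (inherits(pca, "quiescr_pca")) pca$eigenvectors else as.matrix(pca)
  if (is.null(rownames(L))) abort("Loadings must carry sample rownames.")
  idx <- match(rownames(L), design$sample)
  if (anyNA(idx)) abort("Design is missing some samples in the loadings.")
  fac <- design[[factor]][idx]
  levels <- if (factor == "phenotype") {
    c("PKH26_plus", "PKH26_minus")
  } else {
    sort(unique(fac))
  }
  if (length(unique(fac)) != 2L || !all(fac %in% levels)) {
    abort("Exactly two factor levels must be present.")
  }
  in_first <- fac == levels[1L]
  candidates <- integer(0)
  orientations <- integer(0)
  for (k in seq_len(ncol(L))) {
    s <- sign(L[, k])
    if (any(s == 0)) next
    if (all(s[in_first] == 1) && all(s[!in_first] == -1)) {
      candidates <- c(candidates, k); orientations <- c(orientations, 1L)
    } else if (all(s[in_first] == -1) && all(s[!in_first] == 1)) {
      candidates <- c(candidates, k); orientations <- c(orientations, -1L)
    }
  }
  matched <- length(candidates) > 0L
  structure(list(matched = matched,
                 component = if (matched) candidates[1L] else NA_integer_,
                 candidates = candidates,
                 orientation = if (matched) orientations[1L] else NA_integer_,
                 factor = factor, levels = levels),
            class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  if (x$matched) {
    cat(sprintf(
      "<discriminant_report> %s split matched by component %d (orientation %+d)\n",
      x$factor, x$component, x$orientation))
    if (length(x$candidates) > 1L) {
      cat("  all matching components:",
          paste(x$candidates, collapse = ", "), "\n")
    }
  } else {
    cat(sprintf("<discriminant_report> no component matches the %s split\n",
                x$factor))
  }
  invisible(x)
}

#' Select genes by component score
#'
#' Returns orientation-corrected up/down gene lists from the standardized
#' gene scores of one component, either by absolute-score threshold
#' (`|z| > threshold`) or as the top/bottom `n` of the score ranking.
#' Duplicate gene identifiers are resolved by keeping the record with the
#' largest absolute score; ties in the ranking are broken by gene identifier.
#'
#' @param pca a `quiescr_pca`.
#' @param component component index (typically from
#'   [find_discriminating_component()]).
#' @param mode `"threshold"` or `"top_bottom"`.
#' @param threshold absolute standardized-score cutoff (threshold mode).
#' @param n list size per direction (top_bottom mode); must not exceed half
#'   the number of unique genes.
#' @param orientation `+1` or `-1`; scores are multiplied by this so that
#'   positive means up in the first phenotype level.
#' @return list with `up` and `down` ranked tibbles (`gene`, `score`), each
#'   carrying attributes `direction` and `cutoff` (score at the boundary).
#' @export
select_genes_by_score <- function(pca, component,
                                  mode = c("threshold", "top_bottom"),
                                  threshold = 3, n = 6000, orientation = 1) {
  mode <- match.arg(mode)
  sc <- pca$gene_scores[, component] * orientation
  tb <- tibble(gene = rownames(pca$gene_scores), score = sc)
  tb <- tb |>
    group_by(.data$gene) |>
    slice(which.max(abs(.data$score))) |>
    ungroup()
  tb <- arrange(tb, desc(.data$score), .data$gene)
  if (mode == "threshold") {
    up <- filter(tb, .data$score > threshold)
    down <- arrange(filter(tb, .data$score < -threshold), .data$score,
                    .data$gene)
    cut_up <- threshold; cut_down <- -threshold
  } else {
    if (2L * n > nrow(tb)) {
      abort("`n` exceeds half the number of unique genes.")
    }
    up <- head(tb, n)
    down <- arrange(tail(tb, n), .data$score, .data$gene)
    cut_up <- min(up$score); cut_down <- max(down$score)
  }
  list(up = structure(up, direction = "up", cutoff = cut_up),
       down = structure(down, direction = "down", cutoff = cut_down))
}

#' @method tidy quiescr_pca
#' @export
tidy.quiescr_pca <- function(x, ...) variance_table(x$eigenvalues)

#' @method glance quiescr_pca
#' @export
glance.quiescr_pca <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_samples = x$n_samples,
         pc1_proportion = x$eigenvalues[1L] / sum(x$eigenvalues))
}
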