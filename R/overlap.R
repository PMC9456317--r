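#' Overlap of two gene sets with relative risk and significance
#'
#' Measures the intersection of two sets within a stated universe. The
#' effect size is the relative risk `RR = k * N / (a * b)`, the ratio of the
#' observed intersection to its expectation `a * b / N` under independent
#' draws; `RR = 1` means chance-level overlap. Significance is the exact
#' hypergeometric upper tail `P(K >= k)`, optionally accompanied by a
#' permutation p-value obtained by redrawing `set_b` uniformly from the
#' universe (the conditional test matching the hypergeometric conditioning).
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param n_perm number of permutations (0 skips the permutation test).
#' @param seed integer seed for the permutation draw.
#' @return a one-row `overlap_result` tibble: `a`, `b`, `k`, `N`,
#'   `expected_k`, `RR`, `p_hyper`, `p_perm`, `n_perm`, `seed`.
#' @export
pairwise_overlap <- function(set_a, set_b, universe, n_perm = 0,
                             seed = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!length(universe)) abort("Universe must be non-empty.")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("Both sets must be contained in the universe.")
  }
  a <- length(set_a); b <- length(set_b); N <- length(universe)
  k <- length(intersect(set_a, set_b))
  expected_k <- a * b / N
  rr <- if (a > 0 && b > 0) k * N / (a * b) else NA_real_
  p_hyper <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    # drawing b indices out of N and counting those landing in set_a is a
    # uniform redraw of set_b
    hits <- vapply(seq_len(n_perm),
                   function(i) sum(sample.int(N, b) <= a), integer(1L))
    p_perm <- (sum(hits >= k) + 1) / (n_perm + 1)
  }
  out <- tibble(a = a, b = b, k = k, N = N, expected_k = expected_k,
                RR = rr, p_hyper = p_hyper, p_perm = p_perm,
                n_perm = n_perm, seed = seed %||% NA_integer_)
  structure(out, class = c("overlap_result", class(out)))
}

#' Cross-tissue shared signature
#'
#' Intersects the up- and down-regulated gene lists of two tissues over a
#' common universe, yielding the shared "core" signature with overlap
#' statistics, plus the list of discordant genes (up in one tissue, down in
#' the other).
#'
#' @param up_a,down_a,up_b,down_b character vectors of gene ids (e.g. from
#'   [rank_top_bottom()] lists' `gene` columns).
#' @param universe common gene universe (genes measured in both tissues).
#' @param n_perm,seed forwarded to [pairwise_overlap()].
#' @return list with `shared_up`, `shared_down`, `discordant`,
#'   `overlap_up`, `overlap_down` (both `overlap_result`s).
#' @export
cross_tissue_core <- function(up_a, up_b, down_a, down_b, universe,
                              n_perm = 0, seed = NULL) {
  if (!length(universe)) abort("Empty universe intersection.")
  clamp <- function(s) intersect(unique(s), universe)
  up_a <- clamp(up_a); up_b <- clamp(up_b)
  down_a <- clamp(down_a); down_b <- clamp(down_b)
  list(shared_up = sort(intersect(up_a, up_b)),
       shared_down = sort(intersect(down_a, down_b)),
       discordant = sort(union(intersect(up_a, down_b),
                               intersect(down_a, up_b))),
       overlap_up = pairwise_overlap(up_a, up_b, universe, n_perm, seed),
       overlap_down = pairwise_overlap(down_a, down_b, universe, n_perm,
                                       seed))
}

#' Per-category counts of a shared signature
#'
#' Counts shared up- and down-regulated genes per gene set (sets may
#' overlap, so a gene can be counted in several categories); genes annotated
#' to no set are counted in an `"unassigned"` row.
#'
#' @param shared_up,shared_down character vectors of gene ids.
#' @param collection a `gene_set_collection` (see [read_gmt()]).
#' @return a tibble `set`, `up`, `down`, barplot-ready.
#' @export
category_counts <- function(shared_up, shared_down, collection) {
  shared_up <- unique(shared_up); shared_down <- unique(shared_down)
  per_set <- tibble(
    set = names(collection),
    up = vapply(as.list(collection),
                function(s) sum(shared_up %in% s), integer(1L),
                USE.NAMES = FALSE),
    down = vapply(as.list(collection),
                  function(s) sum(shared_down %in% s), integer(1L),
                  USE.NAMES = FALSE))
  annotated <- unique(unlist(collection, use.names = FALSE))
  bind_rows(per_set,
            tibble(set = "unassigned",
                   up = sum(!shared_up %in% annotated),
                   down = sum(!shared_down %in% annotated)))
}
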