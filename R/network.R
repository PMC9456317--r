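#' Thresholded Pearson co-expression network
#'
#' Computes all-pairs Pearson correlations between the listed genes over the
#' chosen sample subset and draws an undirected edge wherever
#' `|r| > r_threshold` (strict inequality). Isolated nodes are retained;
#' zero-variance genes are dropped with a warning.
#'
#' @param m a log-scale [expr_mat].
#' @param genes gene ids to include (default all rows).
#' @param samples sample ids defining the subset (default all columns).
#' @param r_threshold absolute-correlation threshold in (0, 1].
#' @param label free-text label for the sample subset (e.g. `"plus"`).
#' @return a `gene_network` list: `nodes`, `edges`
#'   (tibble `from`, `to`, `r`), `threshold`, `label`.
#' @export
build_coexpression_network <- function(m, genes = NULL, samples = NULL,
                                       r_threshold = 0.7, label = "all") {
  assert_log_scale(m)
  genes <- genes %||% rownames(m)
  samples <- samples %||% colnames(m)
  if (!length(genes)) abort("Empty gene list.")
  if (length(samples) < 3L) abort("At least 3 samples are required.")
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) abort("Genes absent from the matrix.")
  sub <- unclass(m)[genes, samples, drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance gene(s).", sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(sub)
  C <- cor(t(sub))
  C[!upper.tri(C)] <- 0
  hit <- which(abs(C) > r_threshold, arr.ind = TRUE)
  edges <- tibble(from = nodes[hit[, 1L]], to = nodes[hit[, 2L]],
                  r = C[hit])
  edges <- arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, threshold = r_threshold,
                 label = label),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges (|r| > %g, subset '%s')\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$label))
  invisible(x)
}

# adjacency list of integer neighbor vectors
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  adj
}

#' Betweenness centrality
#'
#' Exact betweenness on the undirected, unweighted network via accumulation
#' over breadth-first shortest-path DAGs (Brandes' algorithm). Each
#' unordered node pair is counted once, endpoints are excluded, and tied
#' shortest paths share credit fractionally. Both the raw pair count and the
#' variant normalized by `(n-1)(n-2)/2` are reported.
#'
#' @param net a `gene_network`.
#' @return tibble `gene`, `degree`, `betweenness`, `betweenness_norm`.
#' @export
betweenness_centrality <- function(net) {
  n <- length(net$nodes)
  adj <- adjacency_list(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair visited from both endpoints
  deg <- lengths(adj)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  tibble(gene = net$nodes, degree = deg, betweenness = bc,
         betweenness_norm = bc / norm)
}

#' Local clustering coefficients
#'
#' Fraction of complete triads among each node's neighbor pairs:
#' `triangles / choose(degree, 2)`; nodes with degree < 2 get 0. The
#' network-wide mean is attached as attribute `mean_clustering`.
#'
#' @param net a `gene_network`.
#' @return tibble `gene`, `degree`, `clustering`.
#' @export
clustering_coefficients <- function(net) {
  n <- length(net$nodes)
  adj <- adjacency_list(net)
  cc <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    d <- length(nb)
    if (d < 2L) return(0)
    links <- 0L
    for (a in seq_len(d - 1L)) {
      links <- links + sum(adj[[nb[a]]] %in% nb[(a + 1L):d])
    }
    links / (d * (d - 1L) / 2)
  }, numeric(1L))
  out <- tibble(gene = net$nodes, degree = lengths(adj), clustering = cc)
  structure(out, mean_clustering = mean(cc), class = class(out))
}

#' Connected components and the giant component
#'
#' Components by traversal; the largest is the giant component, ties broken
#' by the lexicographically smallest member gene.
#'
#' @param net a `gene_network`.
#' @return list `members` (sorted giant-component genes), `sizes`
#'   (all component sizes, decreasing), `component` (named membership
#'   vector).
#' @export
giant_component <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) return(list(members = character(0), sizes = integer(0),
                           component = integer(0)))
  adj <- adjacency_list(net)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b) min(net$nodes[comp == b]),
                     character(1L))
    best <- best[order(firsts)][1L]
  }
  list(members = sort(net$nodes[comp == best]),
       sizes = sort(sizes, decreasing = TRUE),
       component = setNames(comp, net$nodes))
}

#' Giant-component class partition between states
#'
#' Splits genes by membership in the giant components of the PKH26+ and
#' PKH26- networks: state-exclusive classes and the shared class, with
#' overlap statistics over a stated universe.
#'
#' @param net_plus,net_minus `gene_network`s built on the same gene universe
#'   and threshold.
#' @param universe gene universe for the overlap test (default: the common
#'   node set).
#' @param n_perm,seed forwarded to [pairwise_overlap()].
#' @return list `plus_only`, `minus_only`, `shared`, `overlap`
#'   (an `overlap_result`).
#' @export
class_partition <- function(net_plus, net_minus, universe = NULL,
                            n_perm = 0, seed = NULL) {
  if (!setequal(net_plus$nodes, net_minus$nodes)) {
    abort("Networks must be built on the same gene universe.")
  }
  universe <- universe %||% net_plus$nodes
  gc_plus <- giant_component(net_plus)$members
  gc_minus <- giant_component(net_minus)$members
  list(plus_only = sort(setdiff(gc_plus, gc_minus)),
       minus_only = sort(setdiff(gc_minus, gc_plus)),
       shared = sort(intersect(gc_plus, gc_minus)),
       overlap = pairwise_overlap(gc_plus, gc_minus, universe, n_perm,
                                  seed))
}

#' Betweenness rewiring report between states
#'
#' Pairs each gene's betweenness in the two state networks, computes a
#' discordance score as the absolute difference of betweenness ranks, and
#' flags "high traffic" genes whose role shifts most between states (above
#' the `flag_quantile` of the rank-shift distribution).
#'
#' @param cent_plus,cent_minus centrality tibbles from
#'   [betweenness_centrality()] over a common gene universe.
#' @param flag_quantile rank-shift quantile above which genes are flagged.
#' @return tibble `gene`, `betweenness_plus`, `betweenness_minus`,
#'   `rank_plus`, `rank_minus`, `discordance`, `flagged`; attributes
#'   `mean_plus`, `mean_minus` carry the two network-wide betweenness means.
#' @export
rewiring_report <- function(cent_plus, cent_minus, flag_quantile = 0.9) {
  if (!setequal(cent_plus$gene, cent_minus$gene)) {
    abort("Centrality tables must cover the same genes.")
  }
  joined <- left_join(
    select(cent_plus, "gene", betweenness_plus = "betweenness"),
    select(cent_minus, "gene", betweenness_minus = "betweenness"),
    by = "gene")
  joined <- mutate(joined,
                   rank_plus = rank(.data$betweenness_plus),
                   rank_minus = rank(.data$betweenness_minus),
                   discordance = abs(.data$rank_plus - .data$rank_minus))
  cut <- quantile(joined$discordance, flag_quantile)
  joined <- mutate(joined,
                   flagged = .data$discordance >= cut &
                     .data$discordance > 0) |>
    arrange(desc(.data$discordance), .data$gene)
  structure(joined, mean_plus = mean(joined$betweenness_plus),
            mean_minus = mean(joined$betweenness_minus),
            class = class(joined))
}

#' Edge-count comparison across sample subsets
#'
#' Builds three networks on an identical gene list — PKH26+ samples only,
#' PKH26- samples only, and all samples pooled — and compares edge counts.
#' Under state-specific co-expression (range restriction), the within-state
#' networks carry more edges than the pooled one.
#'
#' @param m a log-scale [expr_mat].
#' @param design design tibble for the matrix's samples.
#' @param genes gene list common to the three networks.
#' @param threshold absolute-correlation threshold.
#' @return tibble `subset`, `n_samples`, `n_edges`, `density`; attribute
#'   `intra_exceeds_pooled` flags whether both state networks out-edge the
#'   pooled one. The three `gene_network`s are attached as attribute
#'   `networks`.
#' @export
edge_count_comparison <- function(m, design, genes = NULL, threshold = 0.7) {
  idx <- match(colnames(m), design$sample)
  if (anyNA(idx)) abort("Design is missing samples present in the matrix.")
  pheno <- design$phenotype[idx]
  subsets <- list(plus = colnames(m)[pheno == "PKH26_plus"],
                  minus = colnames(m)[pheno == "PKH26_minus"],
                  all = colnames(m))
  nets <- imap(subsets, function(ss, nm) {
    if (length(ss) < 3L) abort(sprintf("Subset '%s' has < 3 samples.", nm))
    build_coexpression_network(m, genes = genes, samples = ss,
                               r_threshold = threshold, label = nm)
  })
  out <- imap(nets, function(net, nm) {
    nn <- length(net$nodes)
    tibble(subset = nm, n_samples = length(subsets[[nm]]),
           n_edges = nrow(net$edges),
           density = if (nn > 1L) nrow(net$edges) / (nn * (nn - 1L) / 2) else 0)
  }) |> bind_rows()
  flag <- out$n_edges[out$subset == "plus"] > out$n_edges[out$subset == "all"] &&
    out$n_edges[out$subset == "minus"] > out$n_edges[out$subset == "all"]
  structure(out, intra_exceeds_pooled = flag, networks = nets,
            class = class(out))
}

#' Pathway distribution across gene classes
#'
#' Counts, for each gene set, how many members fall in each class (e.g.
#' giant-component membership classes of the state networks), and computes
#' the Pearson correlation matrix of the count columns.
#'
#' @param classes named list of gene-id vectors (the class columns).
#' @param collection a `gene_set_collection`.
#' @return list `counts` (tibble, one row per set, one column per class)
#'   and `correlation` (symmetric matrix with unit diagonal; NA where a
#'   column is constant).
#' @export
pathway_distribution <- function(classes, collection) {
  if (!length(collection)) abort("Empty collection.")
  counts <- tibble(set = names(collection))
  for (nm in names(classes)) {
    counts[[nm]] <- unname(vapply(as.list(collection),
                                  function(s) sum(classes[[nm]] %in% s),
                                  integer(1L)))
  }
  M <- as.matrix(counts[, -1L, drop = FALSE])
  cm <- suppressWarnings(cor(M))
  diag(cm) <- 1
  list(counts = counts, correlation = cm)
}

#' Export a network edge list
#'
#' `format = "sif"` writes `geneA pp geneB` lines; `format = "graphml"`
#' writes a minimal GraphML document with the correlation as an edge
#' attribute.
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s pp %s", net$edges$from, net$edges$to)
    isolated <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    node_ids <- setNames(seq_along(net$nodes) - 1L, net$nodes)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="r" for="edge" attr.name="r" attr.type="double"/>',
      '<graph edgedefault="undirected">',
      sprintf('<node id="n%d"><data key="label">%s</data></node>',
              node_ids, names(node_ids)),
      sprintf('<edge source="n%d" target="n%d"><data key="r">%.6f</data></edge>',
              node_ids[net$edges$from], node_ids[net$edges$to], net$edges$r),
      "</graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}
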