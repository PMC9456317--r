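# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

make_net <- function(nodes, edges_df) {
  structure(list(nodes = nodes, edges = edges_df, threshold = 0.7,
                 label = "fixture"),
            class = "gene_network")
}

random_net <- function(n, p = 0.35) {
  nodes <- sprintf("N%02d", seq_len(n))
  comb <- t(combn(n, 2L))
  on <- runif(nrow(comb)) < p
  make_net(nodes, tibble::tibble(from = nodes[comb[on, 1L]],
                                 to = nodes[comb[on, 2L]], r = 0.9))
}

net_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n)
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    A[cbind(fi, ti)] <- TRUE
    A[cbind(ti, fi)] <- TRUE
  }
  A
}

# exhaustive shortest-path enumeration betweenness (feasible for <= 8 nodes)
oracle_betweenness <- function(net) {
  A <- net_adjacency(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0; D[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  paths_between <- function(s, t) {
    res <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (m in which(A[last, ])) {
        if (D[s, m] == length(path) &&
            D[m, t] == D[s, t] - length(path)) {
          walk(c(path, m))
        }
      }
    }
    walk(s)
    res
  }
  bc <- numeric(n)
  if (n >= 2L) {
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      ps <- paths_between(s, t)
      for (p in ps) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(ps)
      }
    }
  }
  bc
}

# triad-count clustering via the adjacency matrix
oracle_clustering <- function(net) {
  A <- net_adjacency(net)
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2))
}

random_logmat <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 6, 2), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(n_samples))))
  expr_mat(m, scale = "log_generic")
}

two_group_design <- function(samples, n_plus, line = "l1", tissue = "t") {
  tibble::tibble(sample = samples, tissue = tissue, line = line,
                 phenotype = rep(c("PKH26_plus", "PKH26_minus"),
                                 c(n_plus, length(samples) - n_plus)),
                 replicate = seq_along(samples))
}

extdata <- function(...) system.file("extdata", ..., package = "quiescr")

null_sim_config <- function(seed) {
  sim_config(n_genes = 500, signature_size = 20, module_size = 20,
             effect_size = 0, module_strength = 0, seed = seed)
}
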