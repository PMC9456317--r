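test_that("edges follow strict absolute-correlation thresholding", {
  x <- seq_len(6)
  vals <- rbind(GA = x, GB = 2 * x + 3, GC = c(5, 1, 4, 2, 6, 3))
  colnames(vals) <- sprintf("s%d", 1:6)
  m <- expr_mat(vals, scale = "log_generic")
  net <- build_coexpression_network(m, r_threshold = 0.7)
  expect_identical(nrow(net$edges), 1L)  # only the exact affine copy
  expect_setequal(c(net$edges$from, net$edges$to), c("GA", "GB"))
  expect_equal(net$edges$r, 1, tolerance = 1e-12)
  # threshold 1.0: strict inequality admits nothing, even r == 1
  expect_identical(nrow(build_coexpression_network(m, r_threshold = 1)$edges),
                   0L)
})

test_that("edge sets equal a brute-force all-pairs correlation scan", {
  set.seed(50)
  m <- random_logmat(15, 8)
  net <- build_coexpression_network(m, r_threshold = 0.5)
  vals <- unclass(m)
  want <- list()
  for (i in 1:14) for (j in (i + 1):15) {
    r <- cor(vals[i, ], vals[j, ])
    if (abs(r) > 0.5) {
      want[[length(want) + 1]] <- c(rownames(vals)[i], rownames(vals)[j])
    }
  }
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, vapply(want, paste, character(1), collapse = " "))
  # monotone thresholding: higher threshold gives a subset
  net2 <- build_coexpression_network(m, r_threshold = 0.8)
  expect_true(all(paste(net2$edges$from, net2$edges$to) %in% got))
})

test_that("betweenness matches hand counts on canonical graphs", {
  path3 <- make_net(c("A", "B", "C"),
                    tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                   r = 0.9))
  bc <- betweenness_centrality(path3)
  expect_equal(bc$betweenness[bc$gene == "B"], 1)
  expect_equal(bc$betweenness[bc$gene != "B"], c(0, 0))
  star <- make_net(c("HUB", "L1", "L2", "L3", "L4"),
                   tibble::tibble(from = "HUB",
                                  to = c("L1", "L2", "L3", "L4"), r = 0.9))
  bs <- betweenness_centrality(star)
  expect_equal(bs$betweenness[bs$gene == "HUB"], choose(4, 2))
  expect_true(all(bs$betweenness[bs$gene != "HUB"] == 0))
  cs <- clustering_coefficients(star)
  expect_true(all(cs$clustering == 0))
  tri <- make_net(c("A", "B", "C"),
                  tibble::tibble(from = c("A", "A", "B"),
                                 to = c("B", "C", "C"), r = 0.9))
  expect_true(all(clustering_coefficients(tri)$clustering == 1))
})

test_that("centralities equal exhaustive oracles on random small graphs", {
  skip_if_not_installed("igraph")
  set.seed(60)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    net <- random_net(n, p = runif(1, 0.2, 0.7))
    bc <- betweenness_centrality(net)
    expect_equal(bc$betweenness, oracle_betweenness(net), tolerance = 1e-9)
    cc <- clustering_coefficients(net)
    expect_equal(cc$clustering, oracle_clustering(net), tolerance = 1e-12)
    # independent library cross-check
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                       vertices = net$nodes)
    expect_equal(bc$betweenness,
                 unname(igraph::betweenness(g)[net$nodes]),
                 tolerance = 1e-9)
    ig_cc <- unname(igraph::transitivity(g, type = "local",
                                         vids = net$nodes))
    expect_equal(cc$clustering, ifelse(is.nan(ig_cc), 0, ig_cc),
                 tolerance = 1e-12)
  }
})

test_that("betweenness totals conserve shortest-path interior incidences", {
  set.seed(61)
  for (i in 1:10) {
    net <- random_net(7, 0.4)
    expect_equal(sum(betweenness_centrality(net)$betweenness),
                 sum(oracle_betweenness(net)), tolerance = 1e-9)
  }
})

test_that("giant component extraction handles ties and isolates", {
  two_tri <- make_net(c("A", "B", "C", "D", "E", "F", "Z"),
                      tibble::tibble(from = c("A", "A", "B", "D", "D", "E"),
                                     to = c("B", "C", "C", "E", "F", "F"),
                                     r = 0.9))
  gc <- giant_component(two_tri)
  expect_identical(gc$sizes, c(3L, 3L, 1L))
  expect_identical(gc$members, c("A", "B", "C"))  # lexicographic tie-break
  full <- random_net(5, 1)
  expect_setequal(giant_component(full)$members, full$nodes)
  empty <- make_net(character(0),
                    tibble::tibble(from = character(0), to = character(0),
                                   r = numeric(0)))
  expect_length(giant_component(empty)$members, 0L)
})

test_that("class partition splits giant-component membership", {
  nodes <- c("A", "B", "C", "D", "E")
  np <- make_net(nodes, tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                       r = 0.9))
  nm <- make_net(nodes, tibble::tibble(from = c("C", "D"), to = c("D", "E"),
                                       r = 0.9))
  cp <- class_partition(np, nm)
  expect_identical(cp$plus_only, c("A", "B"))
  expect_identical(cp$minus_only, c("D", "E"))
  expect_identical(cp$shared, "C")
  same <- class_partition(np, np)
  expect_length(same$plus_only, 0L)
  expect_length(same$minus_only, 0L)
})

test_that("rewiring report flags constructed swaps", {
  genes <- sprintf("g%02d", 1:10)
  cp <- tibble::tibble(gene = genes, degree = 2,
                       betweenness = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                       betweenness_norm = 0)
  ident <- rewiring_report(cp, cp)
  expect_true(all(ident$discordance == 0))
  expect_false(any(ident$flagged))
  swapped <- cp
  swapped$betweenness[c(1, 10)] <- swapped$betweenness[c(10, 1)]
  rw <- rewiring_report(cp, swapped)
  expect_setequal(rw$gene[rw$flagged], c("g01", "g10"))
  expect_identical(rw$gene[1:2], c("g01", "g10"))
})

test_that("state-specific wiring produces the range-restriction signature", {
  # constructed anti-pooling fixture: opposite loadings per state
  set.seed(70)
  z <- rnorm(6)
  w <- c(1, -1, 1, 1, -1)
  u <- c(-1, 1, 1, -1, 1)
  vals <- cbind(outer(w, z), outer(u, z))
  rownames(vals) <- sprintf("M%d", 1:5)
  colnames(vals) <- sprintf("s%d", 1:12)
  vals <- vals + matrix(rnorm(60, 0, 1e-6), 5, 12)
  m <- expr_mat(vals, scale = "log_generic")
  des <- two_group_design(colnames(vals), 6)
  cmp <- edge_count_comparison(m, des, threshold = 0.7)
  n_plus <- cmp$n_edges[cmp$subset == "plus"]
  n_minus <- cmp$n_edges[cmp$subset == "minus"]
  n_all <- cmp$n_edges[cmp$subset == "all"]
  expect_equal(n_plus, choose(5, 2))
  expect_equal(n_minus, choose(5, 2))
  expect_lt(n_all, n_plus)
  expect_true(attr(cmp, "intra_exceeds_pooled"))

  # shared global factor: pooled at least matches the state networks
  vals2 <- outer(w, c(z, z + 3))
  rownames(vals2) <- sprintf("M%d", 1:5)
  colnames(vals2) <- sprintf("s%d", 1:12)
  vals2 <- vals2 + matrix(rnorm(60, 0, 1e-6), 5, 12)
  cmp2 <- edge_count_comparison(expr_mat(vals2, scale = "log_generic"),
                                des, threshold = 0.7)
  expect_gte(cmp2$n_edges[cmp2$subset == "all"],
             max(cmp2$n_edges[cmp2$subset != "all"]))
})

test_that("pathway distribution counts and correlates class columns", {
  coll <- structure(list(P1 = c("g1", "g2", "g3"),
                         P2 = c("g2", "g4", "g5"),
                         P3 = c("g5", "g6")),
                    class = "gene_set_collection")
  classes <- list(plus = c("g1", "g2"), minus = c("g1", "g2"),
                  all = c("g4", "g5"))
  pd <- pathway_distribution(classes, coll)
  expect_identical(pd$counts$plus, c(2L, 1L, 0L))
  expect_equal(pd$correlation["plus", "minus"], 1)
  expect_equal(diag(pd$correlation), c(plus = 1, minus = 1, all = 1))
  expect_equal(pd$correlation, t(pd$correlation))
  # published-style class-count table: rebuild memberships that reproduce
  # the printed per-class counts, then check the output contract
  tab <- utils::read.delim(extdata("pathway_class_counts.tsv"))
  pools <- lapply(seq_len(nrow(tab)),
                  function(i) sprintf("%s_g%02d", tab$pathway[i], 1:30))
  coll2 <- structure(setNames(pools, tab$pathway),
                     class = "gene_set_collection")
  classes2 <- lapply(c(plus = "plus", minus = "minus", all = "all"),
                     function(cl) {
                       unlist(lapply(seq_len(nrow(tab)), function(i) {
                         pools[[i]][seq_len(tab[[cl]][i])]
                       }))
                     })
  pd2 <- pathway_distribution(classes2, coll2)
  expect_identical(pd2$counts$plus, tab$plus)
  expect_identical(pd2$counts$minus, tab$minus)
  expect_identical(pd2$counts$all, tab$all)
  expect_equal(pd2$correlation, t(pd2$correlation))
  expect_equal(unname(diag(pd2$correlation)), rep(1, 3))
})
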