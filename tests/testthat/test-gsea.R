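test_that("running sums reproduce hand-computed curves", {
  ranked <- c(a = 3, b = 2, c = 1, d = 0.5)
  top <- enrichment_score(ranked, "a")
  expect_equal(top$curve$running, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(top$es, 1)
  bottom <- enrichment_score(ranked, "d")
  expect_equal(bottom$curve$running, c(-1 / 3, -2 / 3, -1, 0),
               tolerance = 1e-12)
  expect_equal(bottom$es, -1)
  expect_error(enrichment_score(ranked, "zz"), "intersect")
  expect_error(enrichment_score(ranked, c("a", "b", "c", "d")), "entire")
})

test_that("ES is invariant to metric rescaling and mirrors under reversal", {
  set.seed(3)
  v <- setNames(sort(rnorm(40), decreasing = TRUE), sprintf("g%02d", 1:40))
  set1 <- sample(names(v), 8)
  e1 <- enrichment_score(v, set1)$es
  e2 <- enrichment_score(v * 7, set1)$es
  expect_equal(e1, e2, tolerance = 1e-12)
  # weight 0, reversed ranking: ES negates
  ef <- enrichment_score(setNames(seq(40, 1), names(v)), set1,
                         weight_p = 0)$es
  er <- enrichment_score(setNames(seq(1, 40), names(v)), set1,
                         weight_p = 0)$es
  expect_equal(ef, -er, tolerance = 1e-12)
})

test_that("weight 0 reduces to the two-sample ECDF difference statistic", {
  set.seed(12)
  for (i in 1:10) {
    n <- 30
    v <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
    members <- sample(names(v), 7)
    es <- enrichment_score(v, members, weight_p = 0)$es
    pos <- which(names(v) %in% members)
    # signed sup of ECDF(hit positions) - ECDF(miss positions)
    d <- vapply(seq_len(n), function(t) {
      mean(pos <= t) - mean(setdiff(seq_len(n), pos) <= t)
    }, numeric(1))
    expect_equal(es, d[which.max(abs(d))], tolerance = 1e-12)
  }
})

test_that("collection scan is deterministic and flags planted enrichment", {
  set.seed(77)
  n <- 400
  v <- setNames(rnorm(n), sprintf("g%03d", seq_len(n)))
  v[1:20] <- v[1:20] + 6    # force members to the list top
  coll <- structure(list(PLANTED = names(v)[1:20],
                         RANDOM = sample(names(v), 25)),
                    class = "gene_set_collection")
  r1 <- gsea_collection(v, coll, n_perm = 200, seed = 5)
  r2 <- gsea_collection(v, coll, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  planted <- r1[r1$set == "PLANTED", ]
  expect_gt(planted$es, 0)
  # attains the minimal achievable p given the null sign split
  expect_lte(planted$p_nominal, 1 / (0.25 * 200))
  expect_gte(planted$p_nominal, 1 / (200 + 1))
  expect_true(all(unlist(planted$leading_edge) %in% coll$PLANTED))
  # leading edge sits above the running-sum maximum
  curve <- enrichment_score(v, coll$PLANTED)
  expect_setequal(unlist(planted$leading_edge),
                  curve$curve$gene[curve$curve$hit &
                                     curve$curve$position <=
                                       which.max(curve$curve$running)])
})

test_that("decoy p-values are uniform under the permutation null", {
  # decoy sets within one dataset overlap in genes, so their p-values are
  # dependent; test two independent datasets and require one clean KS
  ksps <- vapply(5:6, function(s) {
    sim <- generate_experiment(sim_config(n_genes = 1000,
                                          signature_size = 50,
                                          module_size = 30, seed = s))
    lc <- log_cpm(sim$tissues$lung$counts)
    de <- fit_two_group_trend(lc, sim$tissues$lung$design)
    ranked <- setNames(de$logFC, de$gene)
    bg <- setdiff(de$gene,
                  c(unlist(lapply(sim$truth$tissues,
                                  function(t) c(t$up, t$down))),
                    sim$truth$module_members))
    set.seed(s)
    decoys <- lapply(1:50, function(i) sample(bg, 30))
    names(decoys) <- sprintf("D%02d", 1:50)
    res <- gsea_collection(ranked,
                           structure(decoys,
                                     class = "gene_set_collection"),
                           n_perm = 200, seed = s + 10)
    suppressWarnings(stats::ks.test(res$p_nominal, "punif"))$p.value
  }, numeric(1))
  expect_gte(sum(ksps > 0.01), 1)
})

test_that("results agree with an independent preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  n <- 500
  v <- setNames(rnorm(n), sprintf("g%03d", seq_len(n)))
  v[1:25] <- v[1:25] + 3
  coll <- list(UP = names(v)[1:25],
               NULL1 = sample(names(v), 40),
               NULL2 = sample(names(v), 15))
  ours <- gsea_collection(v, structure(coll,
                                       class = "gene_set_collection"),
                          n_perm = 500, seed = 2)
  fg <- suppressWarnings(fgsea::fgsea(coll, v, nPermSimple = 2000,
                                      scoreType = "std"))
  for (nm in names(coll)) {
    expect_equal(ours$es[ours$set == nm], fg$ES[fg$pathway == nm],
                 tolerance = 1e-6)
  }
  expect_lt(ours$p_nominal[ours$set == "UP"], 0.01)
  expect_lt(fg$pval[fg$pathway == "UP"], 0.01)
})

test_that("shared enriched pathways intersect by state with sane edges", {
  mk <- function(sets, es, p) {
    tibble::tibble(set = sets, size = 10, es = es, nes = es,
                   p_nominal = p, q_fdr = p)
  }
  a <- mk(c("S1", "S2", "S3", "S4"), c(0.8, 0.7, -0.6, -0.5),
          c(0.01, 0.2, 0.01, 0.03))
  b <- mk(c("S1", "S2", "S3", "S4"), c(0.9, 0.6, -0.7, 0.5),
          c(0.02, 0.01, 0.04, 0.01))
  sh <- shared_enriched(a, b, alpha = 0.05)
  expect_identical(sh$shared_plus, "S1")
  expect_identical(sh$shared_minus, "S3")
  # identical inputs intersect to themselves; alpha = 0 empties everything
  self <- shared_enriched(a, a, alpha = 0.05)
  expect_setequal(self$shared_plus, "S1")
  none <- shared_enriched(a, b, alpha = 0)
  expect_length(none$shared_plus, 0L)
})
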