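test_that("logFC and residual variance match a direct OLS oracle", {
  set.seed(21)
  m <- random_logmat(200, 10)
  attr(m, "scale") <- "logcpm"
  des <- two_group_design(colnames(m), 5)
  fit <- fit_two_group_trend(m, des)
  vals <- unclass(m)
  plus <- des$sample[des$phenotype == "PKH26_plus"]
  minus <- des$sample[des$phenotype == "PKH26_minus"]
  for (i in c(1, 57, 200)) {
    g <- rownames(vals)[i]
    expect_equal(fit$logFC[fit$gene == g],
                 mean(vals[i, plus]) - mean(vals[i, minus]),
                 tolerance = 1e-10)
    resid <- c(vals[i, plus] - mean(vals[i, plus]),
               vals[i, minus] - mean(vals[i, minus]))
    expect_equal(fit$s2[fit$gene == g], sum(resid^2) / 8, tolerance = 1e-10)
  }
  expect_equal(fit$aveExpr, unname(rowMeans(vals)), tolerance = 1e-12)
  # s2_post is a convex combination of s2 and the trend value
  expect_true(all(fit$s2_post >= pmin(fit$s2, fit$trend) - 1e-12))
  expect_true(all(fit$s2_post <= pmax(fit$s2, fit$trend) + 1e-12))
  expect_true(all(fit$p_value > 0 & fit$p_value <= 1))
})

test_that("moderated fit agrees with the established trend pipeline", {
  skip_if_not_installed("limma")
  set.seed(5)
  m <- random_logmat(300, 8)
  attr(m, "scale") <- "logcpm"
  des <- two_group_design(colnames(m), 4)
  ours <- fit_two_group_trend(m, des)
  X <- cbind(1, as.numeric(des$phenotype == "PKH26_plus"))
  lf <- limma::eBayes(limma::lmFit(unclass(m), X), trend = TRUE)
  expect_equal(ours$logFC, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(ours$s2, unname(lf$sigma^2), tolerance = 1e-10)
  # moderation differs in trend/d0 details; demand close agreement, not bits
  expect_gt(cor(ours$t, lf$t[, 2]), 0.99)
  expect_gt(cor(log(ours$p_value), log(lf$p.value[, 2])), 0.98)
})

test_that("null genes and degenerate priors behave as fixed points", {
  vals <- matrix(rnorm(600, 5, 1), 100, 6)
  rownames(vals) <- sprintf("g%03d", 1:100)
  colnames(vals) <- sprintf("s%d", 1:6)
  # gene with identical group means and no within-group spread
  vals[1, ] <- c(4, 4, 4, 4, 4, 4)
  m <- expr_mat(vals, scale = "log_generic")
  attr(m, "scale") <- "logcpm"
  des <- two_group_design(colnames(m), 3)
  fit <- fit_two_group_trend(m, des)
  expect_equal(fit$logFC[1], 0)
  expect_equal(fit$t[1], 0)
  expect_equal(fit$p_value[1], 1)
  expect_true(fit$flagged[1])

  # identical residual variances: shrinkage is a fixed point
  base <- rnorm(6)
  vals2 <- t(vapply(seq_len(50), function(i) 5 + i / 10 + base,
                    numeric(6)))
  rownames(vals2) <- sprintf("g%03d", 1:50)
  colnames(vals2) <- sprintf("s%d", 1:6)
  m2 <- expr_mat(vals2, scale = "log_generic")
  attr(m2, "scale") <- "logcpm"
  fit2 <- fit_two_group_trend(m2, des)
  expect_equal(fit2$s2_post, fit2$s2, tolerance = 1e-6)
})

test_that("phenotype negation negates logFC and swaps the ranked lists", {
  set.seed(13)
  m <- random_logmat(80, 8)
  attr(m, "scale") <- "logcpm"
  des <- two_group_design(colnames(m), 4)
  des_flip <- des
  des_flip$phenotype <- ifelse(des$phenotype == "PKH26_plus",
                               "PKH26_minus", "PKH26_plus")
  f1 <- fit_two_group_trend(m, des)
  f2 <- fit_two_group_trend(m, des_flip)
  expect_equal(f1$logFC, -f2$logFC, tolerance = 1e-10)
  r1 <- rank_top_bottom(f1, n = 20)
  r2 <- rank_top_bottom(f2, n = 20)
  expect_identical(r1$up$gene, r2$down$gene)
  expect_identical(r1$down$gene, r2$up$gene)
})

test_that("ranking partitions, deduplicates, and reports order statistics", {
  recs <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                         logFC = c(3, 2.5, 2, 1, 0.5, -0.2, -1, -2, -2.5, -3),
                         p_value = 0.01)
  r <- rank_top_bottom(recs, n = 5)
  expect_length(intersect(r$up$gene, r$down$gene), 0L)
  expect_setequal(c(r$up$gene, r$down$gene), recs$gene)

  dup <- tibble::tibble(gene = c("gA", "gA", "gB", "gC"),
                        logFC = c(2, 1, 0, -1), p_value = 0.01)
  rd <- rank_top_bottom(dup, n = 1)
  expect_identical(rd$up$gene, "gA")
  expect_identical(rd$up$logFC, 2)

  set.seed(8)
  recs2 <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          logFC = rnorm(100), p_value = runif(100))
  r2 <- rank_top_bottom(recs2, n = 30)
  expect_equal(attr(r2$up, "cutoff"),
               sort(recs2$logFC, decreasing = TRUE)[30])
  expect_equal(attr(r2$down, "cutoff"), sort(recs2$logFC)[30])
  expect_error(rank_top_bottom(recs2, n = 60), "exceeds")
})

test_that("noise-free planted up-genes occupy the top ranks exactly", {
  cfg <- sim_config(n_genes = 300, signature_size = 15, module_size = 10,
                    module_strength = 0, dispersion = 0, noise_sigma = 0,
                    libsize_cv = 0, seed = 17)
  sim <- generate_experiment(cfg)
  lc <- log_cpm(sim$tissues$colon$counts)
  de <- fit_two_group_trend(lc, sim$tissues$colon$design)
  tr <- sim$truth$tissues$colon
  # module genes carry the same up-shift; they share the top block
  top <- rank_top_bottom(de, n = 25)$up$gene
  expect_true(all(tr$up %in% top))
  ranked <- de$gene[order(-de$logFC)]
  expect_setequal(ranked[1:25], c(tr$up, sim$truth$module_members))
})

test_that("moderated p-values are uniform under the synthetic null", {
  rejections <- 0L
  for (s in 1:20) {
    sim <- generate_experiment(null_sim_config(s))
    lc <- log_cpm(sim$tissues$lung$counts)
    de <- fit_two_group_trend(lc, sim$tissues$lung$design)
    ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
    rejections <- rejections + (ks$p.value < 0.01)
  }
  expect_lte(rejections, 3L)
})
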