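# Newton solve of trigamma(y) = x, vectorized enough for scalar use
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Two-group moderated differential expression on log-CPM
#'
#' Per-gene ordinary least squares of log-CPM on phenotype (optionally plus a
#' cell-line covariate), followed by empirical-Bayes moderation of the
#' residual variances toward a mean-variance trend: a locally weighted
#' regression (span 0.5) of `log(s2)` on average expression provides the
#' per-gene prior value, the prior degrees of freedom `d0` are estimated by
#' moment-matching the spread of `log(s2 / trend)` against the scaled-F
#' model, and the posterior variance is the convex combination
#' `s2_post = (d0 * trend + d * s2) / (d0 + d)`. The moderated t statistic
#' `logFC / sqrt(s2_post * v)` is referred to a t distribution on `d + d0`
#' degrees of freedom. When the spread of `log(s2)` is no larger than its
#' sampling noise, `d0` is capped at `10 * d` (near-complete shrinkage).
#'
#' logFC is mean log-CPM in PKH26+ minus mean log-CPM in PKH26-.
#'
#' @param m a `logcpm`-scale [expr_mat].
#' @param design design tibble matching the matrix's samples.
#' @param covariate_line include the cell line as a covariate; default `NULL`
#'   adds it automatically when the design has more than one line.
#' @return a `quiescr_de` tibble with columns `gene`, `logFC`, `aveExpr`,
#'   `s2`, `trend`, `s2_post`, `t`, `p_value`, `flagged` (all-constant rows),
#'   and attributes `d0`, `df_residual`.
#' @export
fit_two_group_trend <- function(m, design, covariate_line = NULL) {
  if (!identical(expr_scale(m), "logcpm")) {
    warn("Expression matrix is not flagged logcpm; fitting on given values.")
  }
  values <- unclass(m)
  idx <- match(colnames(values), design$sample)
  if (anyNA(idx)) abort("Design is missing samples present in the matrix.")
  design <- design[idx, ]
  pheno <- design$phenotype
  if (min(table(pheno)) < 2L) {
    abort("Each phenotype needs at least 2 samples.")
  }
  if (is.null(covariate_line)) {
    covariate_line <- length(unique(design$line)) > 1L
  }
  x_pheno <- as.numeric(pheno == "PKH26_plus")
  X <- cbind(intercept = 1, pheno = x_pheno)
  if (covariate_line && length(unique(design$line)) > 1L) {
    line_f <- factor(design$line)
    X <- cbind(X, stats::model.matrix(~line_f)[, -1L, drop = FALSE])
  }
  ns <- ncol(values)
  df <- ns - ncol(X)
  if (df < 1L) abort("Residual degrees of freedom must be >= 1.")

  fit <- stats::lm.fit(X, t(values))
  coefs <- t(fit$coefficients)
  logfc <- coefs[, "pheno"]
  res <- t(fit$residuals)
  s2 <- rowSums(res^2) / df
  ave <- rowMeans(values)
  flagged <- apply(values, 1L, function(r) diff(range(r)) == 0)

  ok <- s2 > 0 & !flagged
  if (sum(ok) >= 10L) {
    lo <- lowess(ave[ok], log(s2[ok]), f = 0.5)
    trend <- exp(stats::approx(lo$x, lo$y, xout = ave, rule = 2L,
                               ties = mean)$y)
  } else {
    trend <- rep(max(median(s2[s2 > 0]), 1e-8), length(s2))
    if (!any(s2 > 0)) trend <- rep(1e-8, length(s2))
  }

  z <- log(pmax(s2[ok], 1e-300) / trend[ok])
  evar <- if (sum(ok) > 1L) var(z) - trigamma(df / 2) else -1
  d0 <- if (is.finite(evar) && evar > 0) {
    2 * trigamma_inverse(evar)
  } else {
    Inf
  }
  d0 <- min(d0, 10 * df)

  s2_post <- (d0 * trend + df * s2) / (d0 + df)
  v <- chol2inv(chol(crossprod(X)))[2L, 2L]
  t_mod <- logfc / sqrt(s2_post * v)
  p <- 2 * pt(-abs(t_mod), df = df + d0)
  t_mod[flagged] <- 0
  logfc[flagged] <- 0
  p[flagged] <- 1
  p[s2_post == 0 & logfc == 0] <- 1
  t_mod[s2_post == 0 & logfc == 0] <- 0

  out <- tibble(gene = rownames(values), logFC = unname(logfc),
                aveExpr = unname(ave), s2 = unname(s2),
                trend = unname(trend), s2_post = unname(s2_post),
                t = unname(t_mod), p_value = unname(p),
                flagged = unname(flagged))
  structure(out, d0 = d0, df_residual = df,
            class = c("quiescr_de", class(out)))
}

#' @method glance quiescr_de
#' @export
glance.quiescr_de <- function(x, ...) {
  tibble(n_genes = nrow(x), d0 = attr(x, "d0"),
         df_residual = attr(x, "df_residual"),
         n_flagged = sum(x$flagged))
}

#' Top/bottom ranking by log fold change
#'
#' Sorts records by logFC in descending order (ties broken by gene id),
#' after resolving duplicated gene symbols by keeping the record with the
#' largest absolute logFC, and returns the first `n` (up in PKH26+) and last
#' `n` (down in PKH26+) genes. With `alpha` set, genes inside the top/bottom
#' blocks must additionally have nominal `p < alpha`.
#'
#' @param records a `quiescr_de` tibble (or any tibble with `gene`, `logFC`,
#'   `p_value`).
#' @param n list size per direction. Default: 6000 when at least 12000 unique
#'   genes are present, otherwise a quarter of the unique-gene count.
#' @param alpha optional nominal p-value filter applied within the blocks.
#' @return list of `up` and `down` ranked tibbles, each with attributes
#'   `direction` and `cutoff` (the boundary logFC of the unfiltered block).
#' @export
rank_top_bottom <- function(records, n = NULL, alpha = NULL) {
  dedup <- records |>
    group_by(.data$gene) |>
    slice(which.max(abs(.data$logFC))) |>
    ungroup() |>
    arrange(desc(.data$logFC), .data$gene)
  n_unique <- nrow(dedup)
  if (is.null(n)) {
    n <- if (n_unique >= 12000L) 6000L else floor(n_unique / 4)
  }
  if (2L * n > n_unique) {
    abort("`n` exceeds half the number of unique genes.")
  }
  up <- head(dedup, n)
  down <- arrange(tail(dedup, n), .data$logFC, .data$gene)
  cut_up <- min(up$logFC)
  cut_down <- max(down$logFC)
  if (!is.null(alpha)) {
    up <- filter(up, .data$p_value < alpha)
    down <- filter(down, .data$p_value < alpha)
  }
  list(up = structure(up, direction = "up", cutoff = cut_up),
       down = structure(down, direction = "down", cutoff = cut_down))
}
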