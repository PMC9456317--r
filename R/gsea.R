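# normalize ranked input to a named metric vector sorted in descending order
as_ranked_metric <- function(ranked) {
  if (is.data.frame(ranked)) {
    metric_col <- intersect(c("metric", "logFC", "score"), names(ranked))[1L]
    if (is.na(metric_col) || !"gene" %in% names(ranked)) {
      abort("Ranked input needs a `gene` column and a metric column.")
    }
    v <- setNames(ranked[[metric_col]], ranked$gene)
  } else {
    v <- ranked
  }
  if (is.null(names(v))) abort("Ranked metric must carry gene names.")
  if (anyDuplicated(names(v))) abort("Ranked metric has duplicate genes.")
  v[order(-v, names(v))]
}

# ES and extremum positions from sorted hit positions; O(set size)
es_from_positions <- function(idx, w, N) {
  s <- length(idx)
  miss_dec <- 1 / (N - s)
  W <- sum(w)
  if (W == 0) {
    w <- rep(1, s); W <- s
  }
  H <- cumsum(w) / W
  gaps <- (idx - seq_len(s)) * miss_dec
  at_hit <- H - gaps          # running sum right after each hit
  before_hit <- c(0, H[-s]) - gaps  # running sum just before each hit
  j_max <- which.max(at_hit); j_min <- which.min(before_hit)
  pos_dev <- max(at_hit[j_max], 0)
  neg_dev <- min(before_hit[j_min], 0)
  if (pos_dev == 0 && neg_dev == 0) {
    return(list(es = 0, pos_max = NA_integer_, pos_min = NA_integer_))
  }
  if (abs(neg_dev) > pos_dev) {
    es <- neg_dev
  } else if (pos_dev > abs(neg_dev)) {
    es <- pos_dev
  } else {
    # tied magnitudes: take the sign of the earlier extremum
    es <- if (idx[j_max] <= idx[j_min] - 1L) pos_dev else neg_dev
  }
  list(es = es, pos_max = idx[j_max], pos_min = idx[j_min] - 1L,
       hit_j_max = j_max, hit_j_min = j_min)
}

#' Weighted running-sum enrichment score
#'
#' Walks down a ranked gene list; members of the set ("hits") increment the
#' running sum by their normalized weighted metric `|m|^p / sum_hits |m|^p`,
#' non-members decrement it by `1 / (N - N_hits)`. The enrichment score is
#' the running sum's maximum deviation from zero, signed (positive:
#' concentration of the set at the top of the ranking). When the maximum
#' positive and negative deviations tie in magnitude the earlier extremum
#' decides the sign.
#'
#' @param ranked a named metric vector (genes as names) or a tibble with
#'   `gene` and a metric column (`metric`, `logFC` or `score`); sorted in
#'   descending metric order internally.
#' @param geneset character vector of member genes; must intersect the
#'   ranked list and not cover it entirely.
#' @param weight_p metric weighting exponent (1 = classic weighted form,
#'   0 = Kolmogorov-Smirnov form).
#' @return list with `es` and `curve`, a tibble (`position`, `gene`, `hit`,
#'   `running`) of the full running sum.
#' @export
enrichment_score <- function(ranked, geneset, weight_p = 1) {
  v <- as_ranked_metric(ranked)
  N <- length(v)
  hit <- names(v) %in% geneset
  s <- sum(hit)
  if (s == 0) abort("Gene set does not intersect the ranked list.")
  if (s == N) abort("Gene set covers the entire ranked list.")
  w <- abs(v)^weight_p
  w[!hit] <- 0
  W <- sum(w[hit])
  if (W == 0) w[hit] <- 1 / s else w <- w / W
  step <- ifelse(hit, w, -1 / (N - s))
  running <- cumsum(step)
  es <- es_from_positions(which(hit), abs(v[hit])^weight_p, N)$es
  list(es = es,
       curve = tibble(position = seq_len(N), gene = names(v), hit = hit,
                      running = unname(running)))
}

#' Preranked gene-set enrichment over a collection
#'
#' Computes the weighted enrichment score of each set against a ranked gene
#' list, with a permutation null obtained by redrawing the set's positions
#' uniformly in the list (gene-label permutation, the preranked-GSEA null).
#' NES is the ES divided by the mean absolute null ES of matching sign;
#' nominal p is the sign-matched null tail frequency with add-one
#' correction (numerator and denominator both restricted to null scores of
#' the observed sign, keeping the null p-value distribution uniform; the
#' attainable minimum is `1/(n_same_sign + 1) >= 1/(n_perm + 1)`); FDR q
#' follows the positive/negative pooling scheme (pooled
#' normalized null NES tail over observed NES tail, capped at 1).
#'
#' @param ranked named metric vector or tibble (see [enrichment_score()]).
#' @param collection a `gene_set_collection`.
#' @param n_perm permutations per set.
#' @param weight_p metric weighting exponent.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list.
#' @param seed integer seed; identical seeds give identical output.
#' @return a `quiescr_gsea` tibble: `set`, `size`, `es`, `nes`,
#'   `p_nominal`, `q_fdr`, `leading_edge` (list-column), `n_perm`, `seed`.
#' @export
gsea_collection <- function(ranked, collection, n_perm = 1000, weight_p = 1,
                            seed = 1, min_size = 5, max_size = 500) {
  v <- as_ranked_metric(ranked)
  N <- length(v)
  genes <- names(v)
  wp <- abs(v)^weight_p
  keep <- keep(as.list(collection), function(s) {
    k <- sum(genes %in% s)
    k >= min_size && k <= max_size && k < N
  })
  if (!length(keep)) abort("All sets were filtered out.")
  set.seed(seed)
  rows <- vector("list", length(keep))
  null_nes_pos <- list(); null_nes_neg <- list()
  for (i in seq_along(keep)) {
    members <- keep[[i]]
    idx <- which(genes %in% members)
    s <- length(idx)
    obs <- es_from_positions(idx, wp[idx], N)
    null_es <- vapply(seq_len(n_perm), function(b) {
      id <- sort(sample.int(N, s))
      es_from_positions(id, wp[id], N)$es
    }, numeric(1L))
    pos_null <- null_es[null_es >= 0]
    neg_null <- null_es[null_es < 0]
    mean_pos <- if (length(pos_null)) mean(pos_null) else NA_real_
    mean_neg <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
    if (obs$es >= 0) {
      nes <- if (!is.na(mean_pos) && mean_pos > 0) obs$es / mean_pos else NA_real_
      p <- (sum(pos_null >= obs$es) + 1) / (length(pos_null) + 1)
    } else {
      nes <- if (!is.na(mean_neg) && mean_neg > 0) obs$es / mean_neg else NA_real_
      p <- (sum(neg_null <= obs$es) + 1) / (length(neg_null) + 1)
    }
    null_nes_pos[[i]] <- if (!is.na(mean_pos) && mean_pos > 0) {
      pos_null / mean_pos
    } else {
      numeric(0)
    }
    null_nes_neg[[i]] <- if (!is.na(mean_neg) && mean_neg > 0) {
      neg_null / mean_neg
    } else {
      numeric(0)
    }
    le <- if (obs$es > 0) {
      genes[idx[idx <= obs$pos_max]]
    } else if (obs$es < 0) {
      genes[idx[idx > obs$pos_min]]
    } else {
      character(0)
    }
    rows[[i]] <- tibble(set = names(keep)[i], size = s, es = obs$es,
                        nes = nes, p_nominal = p,
                        leading_edge = list(le))
  }
  out <- bind_rows(rows)
  # FDR: pooled normalized null tail over observed tail, by sign
  pool_pos <- unlist(null_nes_pos); pool_neg <- unlist(null_nes_neg)
  obs_nes <- out$nes
  q <- vapply(seq_len(nrow(out)), function(i) {
    x <- obs_nes[i]
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= x) else 0
      den <- mean(obs_nes >= x, na.rm = TRUE)
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= x) else 0
      den <- mean(obs_nes <= x, na.rm = TRUE)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1L))
  out$q_fdr <- q
  out$n_perm <- n_perm
  out$seed <- seed
  out <- select(out, "set", "size", "es", "nes", "p_nominal", "q_fdr",
                "leading_edge", "n_perm", "seed")
  structure(out, class = c("quiescr_gsea", class(out)))
}

#' Shared enriched pathways across two result lists
#'
#' Intersects the significantly enriched sets (nominal `p < alpha`) of two
#' GSEA results, split by enrichment sign (positive: enriched in PKH26+,
#' negative: enriched in PKH26-), with overlap statistics over the universe
#' of commonly tested sets.
#'
#' @param results_a,results_b `quiescr_gsea` tibbles computed against the
#'   same collection.
#' @param alpha nominal significance level.
#' @param n_perm,seed forwarded to [pairwise_overlap()].
#' @return list `shared_plus`, `shared_minus`, `overlap_plus`,
#'   `overlap_minus`.
#' @export
shared_enriched <- function(results_a, results_b, alpha = 0.05,
                            n_perm = 0, seed = NULL) {
  universe <- intersect(results_a$set, results_b$set)
  sig <- function(res, positive) {
    res |>
      filter(.data$p_nominal < alpha,
             if (positive) .data$es > 0 else .data$es < 0) |>
      pull("set") |>
      intersect(universe)
  }
  plus_a <- sig(results_a, TRUE); plus_b <- sig(results_b, TRUE)
  minus_a <- sig(results_a, FALSE); minus_b <- sig(results_b, FALSE)
  list(shared_plus = sort(intersect(plus_a, plus_b)),
       shared_minus = sort(intersect(minus_a, minus_b)),
       overlap_plus = pairwise_overlap(plus_a, plus_b, universe, n_perm,
                                       seed),
       overlap_minus = pairwise_overlap(minus_a, minus_b, universe, n_perm,
                                        seed))
}
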