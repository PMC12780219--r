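# Classic weighted Kolmogorov-Smirnov running-sum enrichment score.
# `stats` must already be sorted in decreasing order with names.
# Returns the signed maximal deviation, the position of the extreme, and
# the leading-edge genes.
gsea_running_es <- function(stats_sorted, gene_set, weight_p = 1) {
  nm <- names(stats_sorted)
  N <- length(nm)
  hit <- nm %in% gene_set
  Nh <- sum(hit)
  if (Nh == N) {
    # degenerate: the set is the whole universe; miss increments undefined,
    # the hit-only running sum tops out at +1
    return(list(es = 1, position = N, leading_edge = nm,
                degenerate = TRUE))
  }
  w <- abs(stats_sorted)^weight_p
  nr <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / Nh
  inc[!hit] <- -1 / (N - Nh)
  run <- cumsum(inc)
  # the running sum always returns to 0, so exactly symmetric positive and
  # negative extremes can tie; the positive extreme wins (within float
  # tolerance) for a deterministic convention
  mx <- max(run); mn <- min(run)
  if (mx + mn >= -1e-12) {
    es <- mx; pos <- which.max(run)
  } else {
    es <- mn; pos <- which.min(run)
  }
  leading <- if (es >= 0) nm[hit & seq_len(N) <= pos]
  else nm[hit & seq_len(N) > pos]
  list(es = es, position = pos, leading_edge = leading, degenerate = FALSE)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes, for each gene set, the classic weighted running-sum
#' enrichment score over a ranked gene list: hits increment the sum by
#' `|stat|^weight_p` (normalized to 1 over the set), misses decrement it
#' by `1/(N - Nh)`, and the enrichment score (ES) is the signed maximal
#' deviation. The null distribution is over random gene sets of the same
#' size: exhaustive enumeration of all subsets when `choose(N, k)` is at
#' most `exhaustive_limit`, otherwise `n_perm` sampled subsets. The
#' normalized score is `NES = ES / mean(|ES_perm|)` over same-sign
#' permutations, and `p_perm = (1 + #{same-sign |ES_perm| >= |ES|}) /
#' (1 + #same-sign)`. P-values are BH-adjusted across sets.
#'
#' @param ranked_stats Named numeric vector (gene-level statistics, e.g.
#'   signed -log10 p); names must be unique. Sorted internally in
#'   decreasing order (ties broken by gene name).
#' @param gene_sets Named list of character vectors; each must intersect
#'   the ranked universe in at least 2 genes.
#' @param weight_p Hit-weight exponent (1 = classic weighted, 0 =
#'   unweighted Kolmogorov-Smirnov).
#' @param n_perm Number of sampled permutations when enumeration is not
#'   exhaustive.
#' @param seed RNG seed for the permutation null.
#' @param exhaustive_limit Enumerate all same-size subsets when
#'   `choose(N, k)` does not exceed this.
#' @return Tibble (one row per set): `gene_set`, `size`, `es`, `nes`,
#'   `p_perm`, `adj_p`, `leading_edge` (list-column), `degenerate`,
#'   `exhaustive`.
#' @export
preranked_gsea <- function(ranked_stats, gene_sets, weight_p = 1,
                           n_perm = 1000, seed = 0,
                           exhaustive_limit = 10000) {
  if (is.null(names(ranked_stats)) || anyDuplicated(names(ranked_stats)))
    abort("`ranked_stats` must be uniquely named.")
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  ord <- order(-ranked_stats, names(ranked_stats))
  stats_sorted <- ranked_stats[ord]
  nm <- names(stats_sorted)
  N <- length(nm)

  rows <- withr::with_seed(as.integer(seed), lapply(names(gene_sets), function(set_name) {
    set <- intersect(gene_sets[[set_name]], nm)
    k <- length(set)
    if (k < 2)
      abort(sprintf("gene set '%s' has fewer than 2 genes in the ranked universe.",
                    set_name), class = "scgain_gsea_error")
    obs <- gsea_running_es(stats_sorted, set, weight_p)
    if (obs$degenerate) {
      return(tibble(gene_set = set_name, size = k, es = obs$es,
                    nes = NA_real_, p_perm = NA_real_,
                    leading_edge = list(obs$leading_edge),
                    degenerate = TRUE, exhaustive = FALSE))
    }
    n_comb <- suppressWarnings(choose(N, k))
    exhaustive <- is.finite(n_comb) && n_comb <= exhaustive_limit
    es_perm <- if (exhaustive) {
      combs <- utils::combn(N, k)
      apply(combs, 2, function(idx)
        gsea_running_es(stats_sorted, nm[idx], weight_p)$es)
    } else {
      vapply(seq_len(n_perm), function(i)
        gsea_running_es(stats_sorted, sample(nm, k), weight_p)$es,
        numeric(1))
    }
    if (obs$es == 0) {
      nes <- 0; p <- 1
    } else {
      same <- sign(es_perm) == sign(obs$es)
      n_same <- sum(same)
      nes <- if (n_same > 0) obs$es / mean(abs(es_perm[same])) else NA_real_
      p <- (1 + sum(same & abs(es_perm) >= abs(obs$es))) / (1 + n_same)
    }
    tibble(gene_set = set_name, size = k, es = obs$es, nes = nes,
           p_perm = p, leading_edge = list(obs$leading_edge),
           degenerate = FALSE, exhaustive = exhaustive)
  }))
  out <- dplyr::bind_rows(rows)
  out$adj_p <- bh_adjust(out$p_perm)
  out[, c("gene_set", "size", "es", "nes", "p_perm", "adj_p",
          "leading_edge", "degenerate", "exhaustive")]
}

#' Signed -log10(p) ranking statistic from a DGE table
#'
#' The default GSEA ranking: `sign(log2_fc) * -log10(p)` with p floored at
#' `1e-300`; `rank_by = "log2_fc"` ranks by fold change instead.
#'
#' @param dge_table Tibble from [differential_expression()].
#' @param rank_by `"signed_logp"` or `"log2_fc"`.
#' @return Named numeric vector keyed by gene id.
#' @export
gsea_ranking <- function(dge_table, rank_by = c("signed_logp", "log2_fc")) {
  rank_by <- match.arg(rank_by)
  s <- if (rank_by == "log2_fc") dge_table$log2_fc
  else sign(dge_table$log2_fc) * -log10(pmax(dge_table$p_value, 1e-300))
  s[is.na(s)] <- 0
  setNames(s, dge_table$gene_id)
}
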