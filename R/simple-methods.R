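#' Vote counting
#'
#' Scores each entity by the number of lists — ranked or unranked — that
#' contain it; higher is better. Ties are broken by the mean normalized rank
#' over the ranked lists (absent = 1.0), then by entity id. Vote counting
#' uses only membership, so it natively accepts unranked input.
#'
#' @param dataset A [gene_dataset()].
#' @return An `aggregation_result` (higher scores are better).
#' @export
vote_counting <- function(dataset) {
  stopifnot(inherits(dataset, "gene_dataset"))
  u <- dataset$universe
  counts <- stats::setNames(numeric(length(u)), u)
  for (gl in dataset$lists) {
    counts[gl$entities] <- counts[gl$entities] + 1
  }
  m_ranked <- build_rank_matrix(dataset, include_unranked = FALSE)
  mean_rank <- if (ncol(m_ranked) > 0L) rowMeans(m_ranked) else
    stats::setNames(rep(1.0, length(u)), u)
  new_aggregation_result(
    ranking = order_by_score(counts, u, decreasing = TRUE,
                             secondary = mean_rank),
    scores = counts,
    method = "VC",
    polarity = "higher",
    tie_note = paste("descending list count; ties by mean normalized rank",
                     "over ranked lists, then entity id"),
    uses_unranked = has_unranked(dataset)
  )
}

#' RepeatChoice aggregation
#'
#' Treats each list as a ranking-with-ties over the universe: a RANKED list
#' orders its members and places all absent entities in one trailing tie
#' block; an UNRANKED list is a single tie block of its members above the
#' absent block. Starting from the first list, each residual tie block is
#' refined by the relative order induced by the next list, and so on;
#' residual ties after the last list are broken by entity id. This successive
#' refinement is exactly lexicographic ordering on the per-list key vectors
#' (effective rank for members, +Inf for absent entities, entity id last),
#' which is how it is computed here. List order is part of the definition:
#' earlier lists dominate.
#'
#' @param dataset A [gene_dataset()].
#' @return An `aggregation_result` (scores are final positions; lower is
#'   better).
#' @export
repeat_choice <- function(dataset) {
  stopifnot(inherits(dataset, "gene_dataset"))
  u <- dataset$universe
  keys <- lapply(dataset$lists, function(gl) {
    k <- stats::setNames(rep(Inf, length(u)), u)
    k[names(effective_ranks(gl))] <- effective_ranks(gl)
    unname(k)
  })
  ord <- do.call(order, c(keys, list(u), list(method = "radix")))
  ranking <- u[ord]
  new_aggregation_result(
    ranking = ranking,
    scores = stats::setNames(seq_along(ranking), ranking),
    method = "RepeatChoice",
    polarity = "lower",
    tie_note = paste("lexicographic refinement in list order;",
                     "residual ties broken by entity id"),
    uses_unranked = has_unranked(dataset)
  )
}
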