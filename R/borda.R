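#' Borda aggregation by a summary statistic of normalized ranks
#'
#' Scores each entity by a summary statistic — arithmetic mean (`MEAN`),
#' median (`MED`) or geometric mean (`GEO`) — of its row in the normalized
#' rank matrix, with absent entities imputed at 1.0. Lower scores are better.
#' With `mix = TRUE` the method accepts UNRANKED lists by the half-list-length
#' rank rule (names `rMixMEAN`/`rMixMED`/`rMixGEO`); with `mix = FALSE`
#' unranked lists are silently dropped (names `rMEAN`/`rMED`/`rGEO`),
#' emulating how ranked-only implementations are used in practice.
#'
#' @param dataset A [gene_dataset()].
#' @param stat One of `"MEAN"`, `"MED"`, `"GEO"`.
#' @param mix Accept unranked lists via the half-length rank rule?
#' @return An `aggregation_result` (lower scores are better).
#' @examples
#' d <- gene_dataset(list(
#'   gene_list("l1", c("a", "b", "c"), "RANKED"),
#'   gene_list("l2", c("b", "a", "c"), "RANKED")
#' ))
#' borda(d, "MEAN")$ranking
#' @export
borda <- function(dataset, stat = c("MEAN", "MED", "GEO"), mix = FALSE) {
  stat <- match.arg(stat)
  m <- build_rank_matrix(dataset, include_unranked = mix)
  if (ncol(m) == 0L) {
    stop("no usable lists: all lists are UNRANKED and mix = FALSE",
         call. = FALSE)
  }
  scores <- switch(stat,
    MEAN = rowMeans(m),
    MED  = row_medians(m),
    GEO  = exp(rowMeans(log(m)))
  )
  ids <- rownames(m)
  new_aggregation_result(
    ranking = order_by_score(scores, ids, decreasing = FALSE),
    scores = scores,
    method = paste0("r", if (mix) "Mix" else "", stat),
    polarity = "lower",
    tie_note = "ascending score; ties broken by entity id (ascending)",
    uses_unranked = mix && has_unranked(dataset)
  )
}

row_medians <- function(m) {
  if (ncol(m) == 1L) return(stats::setNames(m[, 1L], rownames(m)))
  s <- sort_rows(m)
  n <- ncol(m)
  mid <- (n + 1L) / 2
  if (n %% 2L == 1L) {
    stats::setNames(s[, mid], rownames(m))
  } else {
    stats::setNames((s[, n %/% 2L] + s[, n %/% 2L + 1L]) / 2, rownames(m))
  }
}
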