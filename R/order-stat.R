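#' Robust rank aggregation (RRA)
#'
#' For each entity, sort its n normalized ranks (one per usable list, absent
#' = 1.0) as r_(1) <= ... <= r_(n). Under the null that a gene is irrelevant
#' its normalized ranks are i.i.d. uniform, so the k-th order statistic
#' follows Beta(k, n - k + 1). The rho score is the minimum over k of
#' P(Beta(k, n - k + 1) <= r_(k)) — the strongest order-statistic evidence
#' that the gene sits unusually high across lists — and the reported score is
#' the Bonferroni-corrected min(1, n * rho). Lower is better; ordering uses
#' the uncorrected rho so that saturation at 1 does not coarsen the ranking.
#'
#' @param dataset A [gene_dataset()].
#' @param mix Accept unranked lists via the half-length rank rule?
#' @return An `aggregation_result` (lower scores are better).
#' @export
rra <- function(dataset, mix = FALSE) {
  m <- build_rank_matrix(dataset, include_unranked = mix)
  if (ncol(m) == 0L) {
    stop("no usable lists: all lists are UNRANKED and mix = FALSE",
         call. = FALSE)
  }
  n <- ncol(m)
  rs <- sort_rows(m)
  rho <- rep(Inf, nrow(m))
  for (k in seq_len(n)) {
    rho <- pmin(rho, stats::pbeta(rs[, k], k, n - k + 1))
  }
  scores <- stats::setNames(pmin(1, n * rho), rownames(m))
  new_aggregation_result(
    ranking = order_by_score(rho, rownames(m), decreasing = FALSE),
    scores = scores,
    method = if (mix) "MixRRA" else "RRA",
    polarity = "lower",
    tie_note = "ascending rho; ties broken by entity id (ascending)",
    uses_unranked = mix && has_unranked(dataset)
  )
}

#' Stuart aggregation
#'
#' Scores each entity by the exact joint probability that n independent
#' uniforms have order statistics jointly below the entity's sorted
#' normalized ranks: score = P(U_(1) <= r_(1), ..., U_(n) <= r_(n)). Small
#' values indicate that such a consistently high placement is unlikely by
#' chance. Computed by the Stuart-Aerts recursion, here in the rescaled form
#' T_0 = 1, T_k = sum_{j=1..k} (-1)^(j-1) C(k, j) T_{k-j} r_(n-k+1)^j with
#' score = T_n (T_k = k! V_k of the classical recursion, which keeps all
#' intermediates in [0, 1]). `mix = TRUE` gives MixStuart, accepting unranked
#' lists by the half-length rank rule.
#'
#' @inheritParams rra
#' @return An `aggregation_result` (lower scores are better).
#' @export
stuart <- function(dataset, mix = FALSE) {
  m <- build_rank_matrix(dataset, include_unranked = mix)
  if (ncol(m) == 0L) {
    stop("no usable lists: all lists are UNRANKED and mix = FALSE",
         call. = FALSE)
  }
  scores <- stats::setNames(stuart_scores(sort_rows(m)), rownames(m))
  new_aggregation_result(
    ranking = order_by_score(scores, rownames(m), decreasing = FALSE),
    scores = scores,
    method = if (mix) "MixStuart" else "Stuart",
    polarity = "lower",
    tie_note = "ascending score; ties broken by entity id (ascending)",
    uses_unranked = mix && has_unranked(dataset)
  )
}

# Joint order-statistic probability per row of a row-sorted rank matrix.
# Vectorized over rows; O(n^2) in the number of lists.
stuart_scores <- function(rs) {
  n <- ncol(rs)
  tk <- vector("list", n + 1L)
  tk[[1L]] <- rep(1, nrow(rs))
  for (k in seq_len(n)) {
    r <- rs[, n - k + 1L]
    acc <- 0
    rj <- rep(1, nrow(rs))
    for (j in seq_len(k)) {
      rj <- rj * r
      acc <- acc + (-1)^(j - 1) * choose(k, j) * tk[[k - j + 1L]] * rj
    }
    tk[[k + 1L]] <- pmin(pmax(acc, 0), 1)
  }
  tk[[n + 1L]]
}
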