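#' Markov-chain aggregation (MC3)
#'
#' Defines a Markov chain over the entities covered by at least one RANKED
#' list: from state i, pick uniformly one of the ranked lists containing i,
#' then pick an entity j uniformly from that list; move to j if the list
#' ranks j above i, otherwise stay. The chain is mixed with uniform
#' teleportation at rate `teleport` to guarantee ergodicity, and the score is
#' the stationary distribution, found by power iteration. Higher stationary
#' mass means an entity beats others in pairwise comparisons across lists.
#' UNRANKED lists carry no pairwise order information and are not used.
#' Entities absent from every ranked list are appended after the covered
#' ones in entity-id order, with score 0.
#'
#' The sweep is computed list-by-list with suffix sums in O(sum of list
#' lengths) per iteration; the transition matrix is never materialized.
#'
#' @param dataset A [gene_dataset()].
#' @param teleport Teleportation rate in (0, 1); default 0.05.
#' @param tol Convergence tolerance on the max absolute change of the
#'   stationary vector; default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   iteration count.
#' @return An `aggregation_result` (higher scores are better).
#' @export
mc3 <- function(dataset, teleport = 0.05, tol = 1e-10, max_iter = 1e5L) {
  stopifnot(inherits(dataset, "gene_dataset"),
            teleport > 0, teleport < 1, tol > 0)
  ranked <- Filter(is_ranked, dataset$lists)
  if (length(ranked) == 0L) {
    stop("MC3 requires at least one RANKED list", call. = FALSE)
  }
  covered <- sort(unique(unlist(lapply(ranked, `[[`, "entities"),
                                use.names = FALSE)), method = "radix")
  idx_lists <- lapply(ranked, function(gl) match(gl$entities, covered))
  n_cov <- length(covered)
  n_in <- tabulate(unlist(idx_lists, use.names = FALSE), nbins = n_cov)

  v <- rep(1 / n_cov, n_cov)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- numeric(n_cov)
    for (idx in idx_lists) {
      nl <- length(idx)
      u <- v[idx] / (n_in[idx] * nl)
      suffix <- rev(cumsum(rev(u)))              # sum over positions >= p
      inflow <- c(suffix[-1L], 0)                # from strictly worse ranks
      stay <- u * (nl - seq_len(nl) + 1)         # self plus worse picks
      w[idx] <- w[idx] + inflow + stay
    }
    v_new <- teleport / n_cov + (1 - teleport) * w
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop(sprintf("MC3 power iteration did not converge within %d iterations (delta = %.3g)",
                   iter, delta), call. = FALSE)
    }
  }

  scores_cov <- stats::setNames(v, covered)
  head_rank <- order_by_score(scores_cov, covered, decreasing = TRUE)
  rest <- setdiff(dataset$universe, covered)
  rest <- sort(rest, method = "radix")
  scores <- stats::setNames(numeric(length(dataset$universe)),
                            dataset$universe)
  scores[covered] <- v
  new_aggregation_result(
    ranking = c(head_rank, rest),
    scores = scores,
    method = "MC3",
    polarity = "higher",
    tie_note = paste("descending stationary probability; ties by entity id;",
                     "entities outside all ranked lists appended by id"),
    uses_unranked = FALSE,
    converged = TRUE
  )
}

# Dense transition matrix of the same chain; O(n^2) memory, used as an
# independent oracle on small instances.
mc3_transition_matrix <- function(dataset, teleport = 0.05) {
  ranked <- Filter(is_ranked, dataset$lists)
  covered <- sort(unique(unlist(lapply(ranked, `[[`, "entities"),
                                use.names = FALSE)), method = "radix")
  n <- length(covered)
  p <- matrix(0, n, n, dimnames = list(covered, covered))
  n_in <- stats::setNames(numeric(n), covered)
  for (gl in ranked) n_in[gl$entities] <- n_in[gl$entities] + 1
  for (gl in ranked) {
    ents <- gl$entities
    nl <- length(ents)
    for (i in seq_len(nl)) {
      from <- ents[i]
      pick <- 1 / (n_in[from] * nl)
      if (i > 1L) p[from, ents[seq_len(i - 1L)]] <-
          p[from, ents[seq_len(i - 1L)]] + pick
      p[from, from] <- p[from, from] + pick * (nl - i + 1)
    }
  }
  teleport / n + (1 - teleport) * p
}
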