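#' Construct an aggregation result
#'
#' Internal constructor used by every aggregation method. The ranking is a
#' total order over (a subset of) the universe, consistent with the scores
#' under the method's declared polarity; residual ties are always broken by
#' entity id (ascending), recorded in `tie_note`.
#'
#' @param ranking Character vector of entity ids, best first.
#' @param scores Named numeric vector of per-entity scores.
#' @param method Method name as registered in [run_method()].
#' @param polarity `"lower"` if smaller scores are better, `"higher"`
#'   otherwise.
#' @param list_weights Optional named numeric vector of per-list weights.
#' @param tie_note Human-readable record of the tie-breaking keys.
#' @param uses_unranked Whether UNRANKED lists contributed to the result.
#' @param converged Convergence flag for iterative methods (`NA` otherwise).
#' @return Object of class `aggregation_result`.
#' @keywords internal
new_aggregation_result <- function(ranking, scores, method, polarity,
                                   list_weights = NULL,
                                   tie_note = "ties broken by entity id (ascending)",
                                   uses_unranked = FALSE,
                                   converged = NA) {
  stopifnot(!anyDuplicated(ranking), polarity %in% c("lower", "higher"))
  structure(
    list(ranking = ranking, scores = scores, method = method,
         polarity = polarity, list_weights = list_weights,
         tie_note = tie_note, uses_unranked = uses_unranked,
         converged = converged),
    class = "aggregation_result"
  )
}

#' @export
print.aggregation_result <- function(x, n = 10L, ...) {
  cat(sprintf("<aggregation_result> method=%s (%s is better), %d entities ranked%s\n",
              x$method, x$polarity, length(x$ranking),
              if (isTRUE(x$uses_unranked)) ", unranked lists used" else ""))
  top <- utils::head(x$ranking, n)
  df <- data.frame(rank = seq_along(top), entity = top,
                   score = unname(x$scores[top]))
  print(df, row.names = FALSE)
  if (!is.null(x$list_weights)) {
    cat("list weights:\n")
    print(round(x$list_weights, 4))
  }
  invisible(x)
}

#' @export
as.data.frame.aggregation_result <- function(x, ...) {
  data.frame(rank = seq_along(x$ranking), entity = x$ranking,
             score = unname(x$scores[x$ranking]), stringsAsFactors = FALSE)
}

# Order entities by score with entity id as the final key.
order_by_score <- function(scores, ids, decreasing = FALSE, secondary = NULL) {
  keys <- list(if (decreasing) -scores else scores)
  if (!is.null(secondary)) keys <- c(keys, list(secondary))
  keys <- c(keys, list(ids), list(method = "radix"))
  ids[do.call(order, keys)]
}
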