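#' MAIC: meta-analysis by information content
#'
#' Iterative list weighting that infers the quality of each source from how
#' strongly its members are supported by the other sources, and accepts both
#' ranked and unranked lists. Starting from all list weights equal to 1, each
#' iteration computes
#'
#' * a gene score `s(g) = sum over categories c of max { w_l * f_l(rank of g
#'   in l) : l in c, g in l }` — the within-category maximum prevents a gene
#'   from being double-counted by several lists of the same data type;
#' * for each RANKED list, a positional weighting `f_l`: an isotonic
#'   (pool-adjacent-violators) non-increasing fit of its members' current
#'   scores against list position, normalized to mean 1 over the list, so
#'   that top positions of an informative list count more; for UNRANKED
#'   lists `f_l = 1`;
#' * new weights `w_l = sqrt(mean of s(g) over g in l)`, rescaled by their
#'   maximum (the weight scale is a gauge; only ratios matter).
#'
#' Iteration stops when the largest absolute weight change falls below
#' `tol`; if `max_iter` is reached first the last iterate is returned with
#' `converged = FALSE`. When every list is its own category (the default for
#' simulated data) the category maximum reduces to a plain sum over lists.
#'
#' @param dataset A [gene_dataset()]; list categories group sources of the
#'   same data type.
#' @param tol Convergence tolerance on weights (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @return An `aggregation_result` (higher scores are better) whose
#'   `list_weights` hold the final per-list weights.
#' @export
maic <- function(dataset, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(dataset, "gene_dataset"), tol > 0, max_iter >= 1L)
  u <- dataset$universe
  lists <- dataset$lists
  nl <- length(lists)
  list_names <- names(lists)
  categories <- vapply(lists, `[[`, character(1L), "category")
  cat_idx <- match(categories, unique(categories))
  ranked <- vapply(lists, is_ranked, logical(1L))

  # long format: one row per (list, member) pair, in list position order
  lens <- vapply(lists, length, integer(1L))
  gene <- match(unlist(lapply(lists, `[[`, "entities"), use.names = FALSE), u)
  list_of <- rep(seq_len(nl), lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  group_key <- (gene - 1) * max(cat_idx) + cat_idx[list_of]

  f <- rep(1, length(gene))
  w <- rep(1, nl)
  score_genes <- function() {
    val <- w[list_of] * f
    ord <- order(group_key, -val, method = "radix")
    keep <- ord[!duplicated(group_key[ord])]      # category-wise max
    s <- numeric(length(u))
    agg <- rowsum(val[keep], gene[keep])
    s[as.integer(rownames(agg))] <- agg[, 1L]
    s
  }

  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    s <- score_genes()
    member_scores <- s[gene]
    for (l in which(ranked)) {
      sel <- which(list_of == l)
      y <- member_scores[sel]
      fit <- pmax(-stats::isoreg(seq_along(y), -y)$yf, 0)
      f[sel] <- if (mean(fit) > 0) fit / mean(fit) else 1
    }
    w_new <- sqrt(vapply(seq_len(nl),
                         function(l) mean(member_scores[list_of == l]),
                         numeric(1L)))
    if (max(w_new) > 0) w_new <- w_new / max(w_new)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  s <- score_genes()
  scores <- stats::setNames(s, u)
  new_aggregation_result(
    ranking = order_by_score(scores, u, decreasing = TRUE),
    scores = scores,
    method = "MAIC",
    polarity = "higher",
    list_weights = stats::setNames(w, list_names),
    tie_note = "descending information-content score; ties broken by entity id",
    uses_unranked = has_unranked(dataset),
    converged = converged
  )
}
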