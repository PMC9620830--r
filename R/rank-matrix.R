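#' Build the normalized rank matrix of a dataset
#'
#' One row per universe entity, one column per usable list. Entries are
#' normalized effective ranks in (0, 1]: the effective rank (position for
#' RANKED lists, half the list length for every member of an UNRANKED list)
#' divided by the universe size. Normalizing by the universe rather than the
#' list length keeps partial lists over a fixed universe comparable. Entities
#' absent from a list are imputed with 1.0, the worst possible value — the
#' convention shared by the Borda, RRA and Stuart implementations here.
#'
#' @param dataset A [gene_dataset()].
#' @param include_unranked If `FALSE`, UNRANKED lists are dropped (the
#'   behaviour of methods that only accept ranked input).
#' @return Numeric matrix with dimnames `(universe, list names)`. Zero
#'   columns if no list is usable.
#' @export
build_rank_matrix <- function(dataset, include_unranked = TRUE) {
  stopifnot(inherits(dataset, "gene_dataset"))
  lists <- dataset$lists
  if (!include_unranked) lists <- Filter(is_ranked, lists)
  u <- dataset$universe
  m <- matrix(1.0, nrow = length(u), ncol = length(lists),
              dimnames = list(u, unname(vapply(lists, `[[`,
                                               character(1L), "name"))))
  nu <- length(u)
  for (j in seq_along(lists)) {
    r <- effective_ranks(lists[[j]])
    m[names(r), j] <- r / nu
  }
  m
}

# Sort the rows of a matrix in increasing order (single vectorized pass).
sort_rows <- function(m) {
  if (ncol(m) <= 1L) return(m)
  out <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  rownames(out) <- rownames(m)
  out
}
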