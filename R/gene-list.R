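#' Create a gene list
#'
#' A gene list is the unit of input for rank aggregation: one experimental
#' source reporting a set of entities (genes, transcripts, proteins), either
#' with internal order information (`"RANKED"`) or as an unordered set
#' (`"UNRANKED"`). Unranked entities are canonicalized to lexicographic order
#' so that two unranked lists with the same members compare equal regardless
#' of the order they were supplied in.
#'
#' @param name Unique list name (a non-empty string).
#' @param entities Character vector of entity identifiers, no duplicates,
#'   non-empty. For ranked lists the order is the reported ranking, best
#'   first.
#' @param kind Either `"RANKED"` or `"UNRANKED"`.
#' @param category Source category label used by methods (such as MAIC) that
#'   group lists by data type. Defaults to the list name, i.e. every list is
#'   its own category.
#' @return An object of class `gene_list`.
#' @examples
#' gene_list("screen1", c("TP53", "EGFR", "KRAS"), kind = "RANKED")
#' gene_list("pathway", c("KRAS", "EGFR"), kind = "UNRANKED")
#' @export
gene_list <- function(name, entities, kind = c("RANKED", "UNRANKED"),
                      category = name) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(category) || length(category) != 1L || !nzchar(category)) {
    stop("'category' must be a single non-empty string", call. = FALSE)
  }
  entities <- as.character(entities)
  if (length(entities) == 0L) {
    stop(sprintf("gene list '%s' is empty", name), call. = FALSE)
  }
  if (anyDuplicated(entities)) {
    dup <- unique(entities[duplicated(entities)])
    stop(sprintf("gene list '%s' contains duplicated entities: %s",
                 name, paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (kind == "UNRANKED") {
    entities <- sort(entities, method = "radix")
  }
  structure(
    list(name = name, category = category, kind = kind, entities = entities),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s [%s, category=%s], %d entities\n",
              x$name, x$kind, x$category, length(x$entities)))
  head_ids <- paste(utils::head(x$entities, 6L), collapse = ", ")
  cat(sprintf("  %s%s\n", head_ids,
              if (length(x$entities) > 6L) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$entities)

is_ranked <- function(gl) gl$kind == "RANKED"

#' Create a dataset of gene lists
#'
#' A dataset couples a collection of gene lists with the entity universe over
#' which aggregation is performed. Partial lists are the norm in gene-list
#' meta-analysis: each list typically covers only a subset of the universe.
#'
#' @param lists A list of [gene_list()] objects with unique names.
#' @param universe Optional character vector of all entity ids. Defaults to
#'   the union of the list members. Every entity appearing in a list must be
#'   in the universe.
#' @return An object of class `gene_dataset`.
#' @examples
#' d <- gene_dataset(list(
#'   gene_list("a", c("g1", "g2", "g3"), "RANKED"),
#'   gene_list("b", c("g2", "g4"), "UNRANKED")
#' ))
#' d$universe
#' @export
gene_dataset <- function(lists, universe = NULL) {
  if (!is.list(lists) || length(lists) == 0L) {
    stop("'lists' must be a non-empty list of gene_list objects", call. = FALSE)
  }
  ok <- vapply(lists, inherits, logical(1L), what = "gene_list")
  if (!all(ok)) stop("all elements of 'lists' must be gene_list objects",
                     call. = FALSE)
  nms <- vapply(lists, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate list names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  }
  names(lists) <- nms
  members <- unique(unlist(lapply(lists, `[[`, "entities"), use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(members, method = "radix")
  } else {
    universe <- as.character(universe)
    if (anyDuplicated(universe)) {
      stop("'universe' contains duplicated entity ids", call. = FALSE)
    }
    missing <- setdiff(members, universe)
    if (length(missing) > 0L) {
      stop(sprintf("entities appear in lists but not in universe: %s",
                   paste(utils::head(missing, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(lists = lists, universe = universe), class = "gene_dataset")
}

#' @export
print.gene_dataset <- function(x, ...) {
  kinds <- vapply(x$lists, `[[`, character(1L), "kind")
  cat(sprintf("<gene_dataset> %d lists (%d ranked, %d unranked), universe of %d entities\n",
              length(x$lists), sum(kinds == "RANKED"),
              sum(kinds == "UNRANKED"), length(x$universe)))
  invisible(x)
}

#' Number of lists in a dataset
#' @param dataset A [gene_dataset()].
#' @return Integer count of lists.
#' @export
n_lists <- function(dataset) length(dataset$lists)

#' Does the dataset contain unranked lists?
#' @param dataset A [gene_dataset()].
#' @return `TRUE` if at least one list is UNRANKED.
#' @export
has_unranked <- function(dataset) {
  any(vapply(dataset$lists, `[[`, character(1L), "kind") == "UNRANKED")
}

#' Effective ranks of a gene list
#'
#' For a ranked list of length n the effective rank of the i-th entity is i.
#' For an unranked list every member gets the same effective rank n/2 (half
#' the list length, kept as a real number): an unranked source is treated as
#' a single tie block whose members sit, on average, in the middle of the
#' list.
#'
#' @param gl A [gene_list()].
#' @return Named numeric vector of effective ranks, one per member entity.
#' @examples
#' effective_ranks(gene_list("r", c("a", "b", "c"), "RANKED"))
#' effective_ranks(gene_list("u", c("a", "b", "c", "d"), "UNRANKED"))
#' @export
effective_ranks <- function(gl) {
  stopifnot(inherits(gl, "gene_list"))
  n <- length(gl$entities)
  r <- if (is_ranked(gl)) as.numeric(seq_len(n)) else rep(n / 2, n)
  names(r) <- gl$entities
  r
}
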