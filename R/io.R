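#' Read a gene-list dataset from the TSV exchange format
#'
#' The exchange format is line-oriented, one list per line:
#' `name<TAB>category<TAB>RANKED|UNRANKED<TAB>entity1<TAB>entity2...`.
#' Lines starting with `#` are comments. An optional companion universe file
#' carries one entity id per line; without it the universe is the union of
#' the list members.
#'
#' @param path Path to the dataset file.
#' @param universe_path Optional path to a universe file.
#' @param dialect Exchange dialect; only `"tsv"` is defined.
#' @return A [gene_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, universe_path = NULL, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop(sprintf("no gene lists in %s", path), call. = FALSE)
  lists <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 4L) {
      stop(sprintf("malformed record (need name, category, kind, >=1 entity): %s",
                   substr(line, 1L, 60L)), call. = FALSE)
    }
    kind <- fields[3L]
    if (!kind %in% c("RANKED", "UNRANKED")) {
      stop(sprintf("list '%s': kind must be RANKED or UNRANKED, got '%s'",
                   fields[1L], kind), call. = FALSE)
    }
    gene_list(fields[1L], fields[-(1:3)], kind = kind, category = fields[2L])
  })
  universe <- NULL
  if (!is.null(universe_path)) {
    universe <- readLines(universe_path, warn = FALSE)
    universe <- universe[nzchar(universe) & !startsWith(universe, "#")]
  }
  gene_dataset(lists, universe = universe)
}

#' Write a gene-list dataset in the TSV exchange format
#'
#' Records are written in the dataset's list order with a deterministic field
#' layout; unranked lists come out with entities in lexicographic order (their
#' canonical form), so write-then-read is the identity.
#'
#' @param dataset A [gene_dataset()].
#' @param path Output file path.
#' @param universe_path Optional path for a companion universe file. When
#'   omitted, only the list file is written.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, universe_path = NULL) {
  stopifnot(inherits(dataset, "gene_dataset"))
  lines <- vapply(dataset$lists, function(gl) {
    paste(c(gl$name, gl$category, gl$kind, gl$entities), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  if (!is.null(universe_path)) writeLines(dataset$universe, universe_path)
  invisible(path)
}

#' Read a truth reference for evaluation
#'
#' A truth file holds a single record in the exchange format: a RANKED record
#' is a truth ranking (best first), an UNRANKED record a truth set.
#'
#' @param path Path to a one-record exchange-format file.
#' @return A list with elements `kind` (`"RANKED"`/`"UNRANKED"`) and
#'   `entities`.
#' @export
read_truth <- function(path) {
  d <- read_dataset(path)
  if (n_lists(d) != 1L) {
    stop(sprintf("truth file must contain exactly one record, found %d",
                 n_lists(d)), call. = FALSE)
  }
  gl <- d$lists[[1L]]
  list(kind = gl$kind, entities = gl$entities)
}
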