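method_registry <- list(
  rMEAN       = function(dataset, ...) borda(dataset, "MEAN", mix = FALSE),
  rMED        = function(dataset, ...) borda(dataset, "MED",  mix = FALSE),
  rGEO        = function(dataset, ...) borda(dataset, "GEO",  mix = FALSE),
  rMixMEAN    = function(dataset, ...) borda(dataset, "MEAN", mix = TRUE),
  rMixMED     = function(dataset, ...) borda(dataset, "MED",  mix = TRUE),
  rMixGEO     = function(dataset, ...) borda(dataset, "GEO",  mix = TRUE),
  Stuart      = function(dataset, ...) stuart(dataset, mix = FALSE),
  MixStuart   = function(dataset, ...) stuart(dataset, mix = TRUE),
  RRA         = function(dataset, ...) rra(dataset, mix = FALSE),
  VC          = function(dataset, ...) vote_counting(dataset),
  RepeatChoice = function(dataset, ...) repeat_choice(dataset),
  MC3         = function(dataset, ...) mc3(dataset, ...),
  BIRRA       = function(dataset, ...) birra(dataset, ...),
  MAIC        = function(dataset, ...) maic(dataset, ...)
)

# Recognized Bayesian Gibbs-sampling aggregators that this package does not
# implement; the selector may still name them.
unavailable_methods <- c("BiGbottom", "BiGNA", "BARD", "BARC")

#' Names of the implemented aggregation methods
#' @return Character vector of registry names accepted by [run_method()].
#' @export
available_methods <- function() names(method_registry)

#' Run an aggregation method by name
#'
#' Uniform dispatch over the implemented methods: `rMEAN`, `rMED`, `rGEO`,
#' `rMixMEAN`, `rMixMED`, `rMixGEO`, `Stuart`, `MixStuart`, `RRA`, `VC`,
#' `RepeatChoice`, `MC3`, `BIRRA`, `MAIC`. The result records whether
#' UNRANKED lists were actually used. The Bayesian Gibbs-sampling
#' aggregators `BiGbottom`, `BiGNA`, `BARD` and `BARC` are recognized names
#' but not implemented here; requesting one is an error pointing to the
#' original implementations.
#'
#' @param name Registered method name.
#' @param dataset A [gene_dataset()].
#' @param params Named list of method-specific arguments (e.g. `teleport`
#'   for MC3, `prior_pi` for BIRRA, `tol` for MAIC).
#' @return An `aggregation_result`.
#' @examples
#' d <- gene_dataset(list(
#'   gene_list("l1", c("a", "b", "c"), "RANKED"),
#'   gene_list("l2", c("b", "c"), "UNRANKED")
#' ))
#' run_method("rMixGEO", d)$ranking
#' @export
run_method <- function(name, dataset, params = list()) {
  if (name %in% unavailable_methods) {
    stop(sprintf(paste0(
      "method '%s' is recognized but not implemented: it is a Bayesian ",
      "Gibbs-sampling aggregator whose reference implementation lives ",
      "outside this package (BiG / BARD / BARC original code)"), name),
      call. = FALSE)
  }
  fn <- method_registry[[name]]
  if (is.null(fn)) {
    stop(sprintf("unknown method '%s'; implemented methods: %s", name,
                 paste(available_methods(), collapse = ", ")),
         call. = FALSE)
  }
  do.call(fn, c(list(dataset), params))
}
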