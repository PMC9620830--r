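#' Accuracy at a cutoff
#'
#' The coverage measure for simulated experiments, where a truth *ranking*
#' is known: the fraction of the truth's top k that the result's top k
#' recovers, `|top-k(result) intersect top-k(truth)| / k`. When the truth
#' ranking is shorter than k its whole extent is used; when the result is
#' shorter than k the available head is compared but the denominator stays
#' k.
#'
#' @param result An `aggregation_result`.
#' @param truth_ranking Character vector, best first.
#' @param k Positive cutoff.
#' @return A value in `[0, 1]`.
#' @export
accuracy_at_k <- function(result, truth_ranking, k) {
  stopifnot(k >= 1L)
  top_res <- utils::head(result$ranking, k)
  top_tru <- utils::head(truth_ranking, k)
  length(intersect(top_res, top_tru)) / k
}

#' Recall at a cutoff
#'
#' The coverage measure for real-data experiments, where only an unordered
#' truth set is available: the fraction of the truth set found in the
#' result's top k.
#'
#' @param result An `aggregation_result`.
#' @param truth_set Character vector (order ignored), non-empty.
#' @param k Positive cutoff.
#' @return A value in `[0, 1]`, non-decreasing in `k`.
#' @export
recall_at_k <- function(result, truth_set, k) {
  stopifnot(k >= 1L, length(truth_set) > 0L)
  length(intersect(utils::head(result$ranking, k), truth_set)) /
    length(unique(truth_set))
}

#' Replicated simulation experiment
#'
#' Generates `n_reps` datasets from `cfg` (replicate r uses seed
#' `base_seed + r`), runs each method on each, and measures accuracy against
#' the truth ranking at every cutoff. Per method the replicate mean and a
#' 95 % normal-approximation confidence interval (mean +/- 1.96 sd /
#' sqrt(n)) are reported. A method failing on one replicate is recorded as
#' missing for that replicate (with a warning), not silently dropped.
#'
#' @param cfg A [sim_config()].
#' @param methods Character vector of registry names (see
#'   [available_methods()]).
#' @param n_reps Number of replicates (>= 2).
#' @param cutoffs Increasing integer cutoffs; the default grid
#'   `{1, 10, 50, 100, 500, 1000}` spans the top-1-to-top-1000 range used in
#'   benchmark figures.
#' @param base_seed Base seed; defaults to `cfg$seed`.
#' @return Named list (one per method) of `eval_curve` data frames with
#'   columns `cutoff`, `mean`, `ci_half_width`, `n_reps`; the per-replicate
#'   value matrix is attached as attribute `"reps"`.
#' @export
replicate_experiment <- function(cfg, methods, n_reps = 20L,
                                 cutoffs = c(1L, 10L, 50L, 100L, 500L, 1000L),
                                 base_seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 2L,
            all(diff(cutoffs) > 0), all(cutoffs >= 1L))
  vals <- array(NA_real_,
                dim = c(n_reps, length(cutoffs), length(methods)),
                dimnames = list(NULL, cutoffs, methods))
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    sim <- generate_dataset(cfg_r)
    for (mth in methods) {
      res <- tryCatch(run_method(mth, sim$dataset), error = function(e) {
        warning(sprintf("method %s failed on replicate %d: %s",
                        mth, r, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      vals[r, , mth] <- vapply(cutoffs, function(k)
        accuracy_at_k(res, sim$truth_ranking, k), numeric(1L))
    }
  }
  out <- lapply(methods, function(mth) {
    reps <- vals[, , mth, drop = TRUE]
    reps <- matrix(reps, nrow = n_reps,
                   dimnames = list(NULL, cutoffs))
    mu <- colMeans(reps, na.rm = TRUE)
    n_ok <- colSums(!is.na(reps))
    sd_ <- apply(reps, 2L, stats::sd, na.rm = TRUE)
    curve <- data.frame(
      cutoff = cutoffs,
      mean = pmin(pmax(mu, 0), 1),
      ci_half_width = ifelse(n_ok > 1L, 1.96 * sd_ / sqrt(n_ok), NA_real_),
      n_reps = n_ok
    )
    attr(curve, "reps") <- reps
    class(curve) <- c("eval_curve", "data.frame")
    curve
  })
  names(out) <- methods
  out
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("<eval_curve> %d replicates\n", max(x$n_reps)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
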