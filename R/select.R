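#' Infer quality heterogeneity from MAIC list weights
#'
#' Runs [maic()] on the dataset and summarizes the dispersion of the final
#' list weights by their coefficient of variation (sd / mean). MAIC weights
#' track list quality, so widely dispersed weights indicate heterogeneous
#' source quality. The CV is scale-free, hence invariant to the weight gauge.
#'
#' @param dataset A [gene_dataset()] with at least 2 lists.
#' @param het_threshold Dispersion at or above which heterogeneity is called
#'   `"high"` (default 0.5; see [calibrate_het_threshold()]).
#' @param ... Passed to [maic()].
#' @return List with `score` (the CV), `label` (`"low"`/`"high"`),
#'   `weights`, and `converged` (heterogeneity is still reported from the
#'   final iterate when MAIC hit its iteration cap).
#' @export
infer_heterogeneity <- function(dataset, het_threshold = 0.5, ...) {
  stopifnot(inherits(dataset, "gene_dataset"), het_threshold > 0)
  if (n_lists(dataset) < 2L) {
    stop("heterogeneity inference needs at least 2 lists", call. = FALSE)
  }
  res <- maic(dataset, ...)
  w <- res$list_weights
  score <- if (mean(w) > 0) stats::sd(w) / mean(w) else 0
  list(score = score,
       label = if (score >= het_threshold) "high" else "low",
       weights = w,
       converged = res$converged)
}

#' Calibrate the heterogeneity threshold for a dataset's shape
#'
#' Simulates paired low- and high-heterogeneity collections (`D = 0.1` vs
#' `D = 3`) matched to the input's list count and ranked/unranked mix,
#' computes the MAIC weight-dispersion score on each, and returns the
#' midpoint of the two score distributions' means. This anchors the
#' high/low call to datasets of the same shape rather than a universal
#' constant.
#'
#' @param dataset The dataset whose shape (list count and mix) to match.
#' @param M Mean noise scale of the calibration simulations (default 3).
#' @param n_seeds Simulated datasets per heterogeneity level (default 10).
#' @param base_seed Seed for the first calibration dataset.
#' @param n_entities,n_signal Scale of the calibration simulations.
#' @return List with `het_threshold` (the midpoint), `scores_low`,
#'   `scores_high`.
#' @export
calibrate_het_threshold <- function(dataset, M = 3, n_seeds = 10L,
                                    base_seed = 1L, n_entities = 20000L,
                                    n_signal = 1000L) {
  stopifnot(inherits(dataset, "gene_dataset"))
  kinds <- vapply(dataset$lists, `[[`, character(1L), "kind")
  nm <- sprintf("S%02d", seq_along(kinds))
  specs <- data.frame(name = nm, category = nm,
                      kind = unname(sort(kinds, decreasing = TRUE)),
                      stringsAsFactors = FALSE)  # RANKED first
  score_for <- function(D, s) {
    cfg <- sim_config(n_entities = n_entities, n_signal = n_signal, M = M,
                      D = D, list_specs = specs, seed = s)
    infer_heterogeneity(generate_dataset(cfg)$dataset,
                        het_threshold = 0.5)$score
  }
  seeds <- base_seed + seq_len(n_seeds) - 1L
  lo <- vapply(seeds, function(s) score_for(0.1, s), numeric(1L))
  hi <- vapply(seeds, function(s) score_for(3, s), numeric(1L))
  list(het_threshold = (mean(lo) + mean(hi)) / 2,
       scores_low = lo, scores_high = hi)
}

#' Recommend aggregation methods for a dataset's properties
#'
#' The decision table condenses the benchmark evaluation into three
#' questions: does the collection include unranked lists, is it large (many
#' sources), and is the quality heterogeneity high? Each cell lists the
#' method(s) that reached the best top-1000 accuracy for that scenario and
#' stayed robust to noise level, cutoff and absent-gene rate:
#'
#' * unranked present, high heterogeneity: `MAIC` (most robust to quality
#'   spread);
#' * unranked present, low heterogeneity: `MAIC`, `rMixGEO` (the simple
#'   statistic matches MAIC when lists are homogeneous);
#' * ranked only, large, high heterogeneity: `BIRRA`;
#' * ranked only, large, low heterogeneity: `rGEO`, `BiGbottom`, `MAIC`,
#'   `rMEAN`, `MC3` (similar performance);
#' * ranked only, small, high heterogeneity: `BiGbottom` (most robust to
#'   small cutoffs; `MAIC` and `BIRRA` reach the same level at the top-1000
#'   cutoff);
#' * ranked only, small, low heterogeneity: `rGEO`, `MC3`, `BiGbottom`.
#'
#' `BiGbottom` is a recognized but unimplemented Gibbs-sampling method; it is
#' returned with `available = FALSE` so callers can fall back to the next
#' implemented recommendation.
#'
#' @param has_unranked Does the dataset include UNRANKED lists?
#' @param n_lists Number of lists.
#' @param het_label `"low"` or `"high"` quality heterogeneity.
#' @param large_threshold List count at or above which the dataset counts as
#'   large (default 10, separating the benchmark's 11-32-list collections
#'   from its 4-6-list ones).
#' @return Data frame with columns `method` (in preference order),
#'   `available`, `note`.
#' @export
recommend <- function(has_unranked, n_lists, het_label = c("low", "high"),
                      large_threshold = 10L) {
  het_label <- match.arg(het_label)
  stopifnot(is.logical(has_unranked), n_lists >= 1L, large_threshold >= 2L)
  large <- n_lists >= large_threshold
  high <- het_label == "high"
  methods <-
    if (has_unranked) {
      if (high) "MAIC" else c("MAIC", "rMixGEO")
    } else if (large) {
      if (high) "BIRRA" else c("rGEO", "BiGbottom", "MAIC", "rMEAN", "MC3")
    } else {
      if (high) "BiGbottom" else c("rGEO", "MC3", "BiGbottom")
    }
  note <- rep("", length(methods))
  note[methods %in% unavailable_methods] <- "not implemented here"
  if (!has_unranked && !large && high) {
    note <- paste("not implemented here; MAIC and BIRRA reach the same",
                  "performance at the top-1000 cutoff")
  }
  data.frame(method = methods,
             available = !(methods %in% unavailable_methods),
             note = note, stringsAsFactors = FALSE)
}

#' End-to-end method selection for a dataset
#'
#' Inspects the dataset (unranked lists present? number of sources), infers
#' quality heterogeneity from MAIC list weights, and returns the
#' recommendation with the evidence that produced it. Optionally runs the
#' top implemented recommendation.
#'
#' @param dataset A [gene_dataset()].
#' @param large_threshold See [recommend()].
#' @param het_threshold See [infer_heterogeneity()]; use
#'   [calibrate_het_threshold()] for a shape-matched value.
#' @param run_best Run the highest-ranked implemented method and attach its
#'   result?
#' @return A `selection_report`: list with `has_unranked`, `n_lists`,
#'   `heterogeneity` (score, label, weights), `recommendation` (data frame),
#'   and optionally `result`.
#' @export
select_method <- function(dataset, large_threshold = 10L,
                          het_threshold = 0.5, run_best = FALSE) {
  het <- infer_heterogeneity(dataset, het_threshold = het_threshold)
  rec <- recommend(has_unranked(dataset), n_lists(dataset), het$label,
                   large_threshold)
  report <- list(has_unranked = has_unranked(dataset),
                 n_lists = n_lists(dataset),
                 heterogeneity = het,
                 recommendation = rec)
  if (run_best) {
    best <- rec$method[rec$available][1L]
    if (is.na(best)) {
      warning("no implemented method among the recommendations; running MAIC",
              call. = FALSE)
      best <- "MAIC"
    }
    report$result <- run_method(best, dataset)
  }
  class(report) <- "selection_report"
  report
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d lists, unranked %s; heterogeneity %s (score %.3f)\n",
              x$n_lists, if (x$has_unranked) "present" else "absent",
              x$heterogeneity$label, x$heterogeneity$score))
  print(x$recommendation, row.names = FALSE)
  if (!is.null(x$result)) {
    cat("-- result of top recommendation --\n")
    print(x$result)
  }
  invisible(x)
}
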