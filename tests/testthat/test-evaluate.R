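fake_result <- function(ranking) {
  new_aggregation_result(ranking,
                         stats::setNames(seq_along(ranking), ranking),
                         method = "fake", polarity = "lower")
}

test_that("accuracy counts the top-k overlap against the truth ranking", {
  truth <- c("a", "b", "c", "d")
  expect_equal(accuracy_at_k(fake_result(truth), truth, 4), 1.0)
  expect_equal(accuracy_at_k(fake_result(c("x", "y", "z", "w")), truth, 4), 0)
  expect_equal(accuracy_at_k(fake_result(c("a", "x", "b", "y")), truth, 4), 0.5)
  # truth shorter than k: its whole extent is the target
  expect_equal(accuracy_at_k(fake_result(c("a", "b", "x")), c("a", "b"), 3),
               2 / 3)
  # result shorter than k: head compared, denominator stays k
  expect_equal(accuracy_at_k(fake_result(c("a", "b")), truth, 4), 0.5)
})

test_that("recall measures truth-set coverage and is monotone in k", {
  truth_set <- c("a", "b")
  res <- fake_result(c("a", "x", "b", "y"))
  expect_equal(recall_at_k(res, truth_set, 1), 0.5)
  expect_equal(recall_at_k(res, truth_set, 3), 1.0)
  vals <- vapply(1:4, function(k) recall_at_k(res, truth_set, k), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # exhaustion: every truth entity inside the ranking
  expect_equal(recall_at_k(res, truth_set, 10), 1.0)
})

test_that("accuracy and recall coincide when the truth set is the truth top-k", {
  set.seed(12)
  ranking <- sample(sprintf("g%02d", 1:30))
  truth_ranking <- sample(sprintf("g%02d", 1:30), 20)
  res <- fake_result(ranking)
  for (k in c(3, 7, 12)) {
    expect_equal(accuracy_at_k(res, truth_ranking, k),
                 recall_at_k(res, utils::head(truth_ranking, k), k))
  }
})

test_that("noiseless replicated curves are exactly 1 with zero-width intervals", {
  cfg <- small_cfg(M = 1e-9, D = 0, gamma = 0, m_c = 100, D_c = 0)
  curves <- replicate_experiment(cfg, c("rMEAN", "rMixGEO", "VC"), n_reps = 3,
                                 cutoffs = c(1L, 10L, 25L), base_seed = 50)
  for (cv in curves) {
    expect_equal(cv$mean, rep(1, 3))
    expect_equal(cv$ci_half_width, rep(0, 3))
  }
  # methods whose scores plateau (isotonic/binned fits) still recover the
  # full signal set at the signal-sized cutoff
  plateau <- replicate_experiment(cfg, c("MAIC", "BIRRA"), n_reps = 3,
                                  cutoffs = 25L, base_seed = 50)
  expect_equal(plateau$MAIC$mean, 1)
  expect_equal(plateau$BIRRA$mean, 1)
})

test_that("replicated experiments are reproducible and failure-tolerant", {
  cfg <- small_cfg(M = 3, D = 1, scenario = "MixSmall")
  a <- replicate_experiment(cfg, "rMixMEAN", n_reps = 3, cutoffs = c(5L, 25L),
                            base_seed = 60)
  b <- replicate_experiment(cfg, "rMixMEAN", n_reps = 3, cutoffs = c(5L, 25L),
                            base_seed = 60)
  expect_identical(a, b)
  # a ranked-only method on an unranked-only collection: failures become
  # per-replicate NAs with a warning, never silent drops
  cfg_unranked <- sim_config(n_entities = 200L, n_signal = 10L, m_c = 30,
                             L = 10L,
                             list_specs = data.frame(
                               name = c("u1", "u2"), category = c("u1", "u2"),
                               kind = "UNRANKED"))
  curves <- NULL
  msgs <- testthat::capture_warnings(
    curves <- replicate_experiment(cfg_unranked, c("VC", "rGEO"),
                                   n_reps = 2, cutoffs = 5L, base_seed = 1))
  expect_true(any(grepl("rGEO failed", msgs)))
  expect_true(all(is.na(attr(curves$rGEO, "reps"))))
  expect_true(all(!is.na(attr(curves$VC, "reps"))))
})

test_that("confidence width shrinks like one over root replicates", {
  cfg <- sim_config(n_entities = 300L, n_signal = 15L, M = 3, D = 1,
                    m_c = 50, D_c = 0.5, L = 15L,
                    list_specs = preset_list_specs("MixSmall"))
  width_at <- function(n, base) {
    cv <- replicate_experiment(cfg, "rMixMEAN", n_reps = n, cutoffs = 15L,
                               base_seed = base)
    cv$rMixMEAN$ci_half_width
  }
  # single-trial width ratios are noisy (the sd itself is estimated), so
  # the 1/sqrt(4) = 2 scaling is checked on the average over 10 trials
  bases <- 70L + 50L * (0:9)
  ratio <- mean(vapply(bases, function(b) width_at(8L, b), numeric(1L))) /
    mean(vapply(bases, function(b) width_at(32L, b + 25L), numeric(1L)))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})
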