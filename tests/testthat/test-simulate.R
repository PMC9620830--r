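test_that("significance profile is strictly decreasing over exactly n_signal entities", {
  cfg <- sim_config(seed = 1)
  mu <- assign_entity_means(cfg)
  expect_length(mu, 20000L)
  expect_equal(sum(mu > 0), 1000L)
  truth_mu <- sort(mu[mu > 0], decreasing = TRUE)
  expect_true(all(diff(truth_mu) < 0))
  expect_equal(max(mu), 3)
  # degenerate: a single signal entity
  mu1 <- assign_entity_means(sim_config(n_entities = 100L, n_signal = 1L))
  expect_equal(sum(mu1 > 0), 1L)
  # deterministic given the config
  expect_identical(mu, assign_entity_means(sim_config(seed = 1)))
  # signal ids are scrambled, not the lexicographic head of the universe
  expect_false(all(mu[seq_len(1000L)] > 0))
})

test_that("noise scale draw follows the log-normal contract", {
  cfg <- small_cfg(M = 2, D = 0)
  set.seed(1)
  expect_equal(replicate(5, sample_sigma(cfg)), rep(2, 5))
  cfg <- small_cfg(M = 2, D = 0.7)
  set.seed(1)
  draws <- replicate(10000, log(sample_sigma(cfg)))
  se <- 0.7 / sqrt(10000)
  expect_lt(abs(mean(draws) - log(2)), 4 * se)
  expect_lt(abs(sd(draws) - 0.7), 0.05)
  # d_is_variance flips the spread to sqrt(D)
  cfgv <- small_cfg(M = 2, D = 0.49, d_is_variance = TRUE)
  set.seed(1)
  drawsv <- replicate(10000, log(sample_sigma(cfgv)))
  expect_lt(abs(sd(drawsv) - 0.7), 0.05)
  # same seed, same draws
  set.seed(99); a <- replicate(10, sample_sigma(cfg))
  set.seed(99); b <- replicate(10, sample_sigma(cfg))
  expect_identical(a, b)
})

test_that("cut length is min(floor(C) + L, U) and always within [L, U]", {
  cfg <- sim_config(n_entities = 20000L, m_c = 100, D_c = 0, L = 50L)
  set.seed(1)
  expect_equal(replicate(5, sample_cut_length(cfg)), rep(150, 5))
  cfg <- sim_config(n_entities = 20000L, m_c = 1e6, D_c = 0.1, L = 50L,
                    U = 20000L)
  set.seed(1)
  expect_equal(replicate(5, sample_cut_length(cfg)), rep(20000, 5))
  cfg <- small_cfg(m_c = 30, D_c = 3, L = 20L, U = 100L)
  set.seed(1)
  draws <- replicate(500, sample_cut_length(cfg))
  expect_true(all(draws >= 20L & draws <= 100L))
})

test_that("absent-gene removal count follows X = floor(gamma * (n - N_i))", {
  cfg <- small_cfg(gamma = 0.5, M = 3, D = 1, seed = 5)
  sim <- generate_dataset(cfg)
  expect_equal(unname(sim$per_list_removed),
               floor(0.5 * (500 - unname(sim$per_list_cut))))
  cfg0 <- small_cfg(gamma = 0, seed = 5)
  expect_true(all(generate_dataset(cfg0)$per_list_removed == 0))
})

test_that("gamma = 0 noiseless lists are exact prefixes of the truth ranking", {
  cfg <- small_cfg(M = 1e-9, D = 0, gamma = 0, seed = 3)
  sim <- generate_dataset(cfg)
  for (gl in sim$dataset$lists) {
    n_sig_in <- min(length(gl$entities), 25L)
    if (gl$kind == "RANKED") {
      expect_identical(gl$entities[seq_len(n_sig_in)],
                       sim$truth_ranking[seq_len(n_sig_in)])
    } else {
      expect_true(all(sim$truth_ranking[seq_len(n_sig_in)] %in% gl$entities))
    }
  }
})

test_that("datasets are reproducible and respect the configured bounds", {
  cfg <- small_cfg(M = 3, D = 1, seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_length(a$dataset$universe, 500L)
  expect_length(a$truth_set, 25L)
  expect_setequal(a$truth_ranking, a$truth_set)
  for (s in 1:25) {
    sim <- generate_dataset(small_cfg(M = 3, D = 2, seed = s))
    expect_true(all(sim$per_list_cut >= 20L & sim$per_list_cut <= 500L))
    expect_equal(unname(vapply(sim$dataset$lists, length, integer(1L))),
                 unname(sim$per_list_cut))
  }
})

test_that("scenario presets carry the benchmark list counts", {
  counts <- function(s) table(factor(preset_list_specs(s)$kind,
                                     c("RANKED", "UNRANKED")))
  expect_equal(unname(c(counts("MixLarge"))), c(11L, 21L))
  expect_equal(unname(c(counts("MixSmall"))), c(4L, 2L))
  expect_equal(unname(c(counts("RankLarge"))), c(11L, 0L))
  expect_equal(unname(c(counts("RankSmall"))), c(4L, 0L))
  # the Rank spec is exactly the ranked subset of the Mix spec
  ml <- preset_list_specs("MixLarge")
  expect_identical(ml[ml$kind == "RANKED", ], preset_list_specs("RankLarge"))
})

test_that("paired Mix and Rank generations share their ranked lists", {
  mix <- generate_dataset(small_cfg(M = 3, D = 2, seed = 21,
                                    scenario = "MixSmall"))
  rnk <- generate_dataset(small_cfg(M = 3, D = 2, seed = 21,
                                    scenario = "RankSmall"))
  expect_identical(mix$dataset$lists[names(rnk$dataset$lists)],
                   rnk$dataset$lists)
  expect_identical(mix$truth_ranking, rnk$truth_ranking)
})

test_that("removal hits every entity uniformly", {
  # every entity carries distinct significance and sigma -> 0, so the
  # pre-removal ranking is fully deterministic: for original positions
  # <= N_i, absence from the list happens iff the entity was removed,
  # with probability X / n_entities each
  cfg <- sim_config(n_entities = 200L, n_signal = 200L, M = 1e-9, D = 0,
                    m_c = 100, D_c = 0, L = 50L, gamma = 0.5,
                    list_specs = data.frame(name = "l1", category = "l1",
                                            kind = "RANKED"),
                    seed = 1)
  mu <- assign_entity_means(cfg)
  truth_order <- names(mu)[order(-mu, names(mu), method = "radix")]
  set.seed(77)
  n_i <- attr(generate_list(cfg, mu, name = "l0"), "sim_cut")  # deterministic (D_c = 0)
  x <- floor(0.5 * (200 - n_i))
  n_rep <- 400L
  absent <- matrix(0L, nrow = n_i, ncol = 1L)
  set.seed(77)
  for (r in seq_len(n_rep)) {
    gl <- generate_list(cfg, mu, name = "l1")
    expect_equal(attr(gl, "sim_removed"), x)
    absent <- absent + !(truth_order[seq_len(n_i)] %in% gl$entities)
  }
  p <- x / 200
  tol <- 5 * sqrt(p * (1 - p) * n_rep)
  expect_true(all(abs(absent - n_rep * p) < tol))
  # no positional trend: first half vs second half of the kept range
  h <- n_i %/% 2L
  expect_lt(abs(mean(absent[seq_len(h)]) - mean(absent[(n_i - h + 1L):n_i])),
            4 * sqrt(2 * p * (1 - p) * n_rep / h))
})

test_that("accuracy degrades in expectation as mean noise grows", {
  cfg_for <- function(M) sim_config(n_entities = 1000L, n_signal = 50L,
                                    M = M, D = 1, m_c = 120, D_c = 0.5,
                                    L = 30L,
                                    list_specs = preset_list_specs("MixSmall"))
  acc <- vapply(c(1, 3, 10), function(M) {
    mean(vapply(1:20, function(s) {
      sim <- generate_dataset(local({ c <- cfg_for(M); c$seed <- 500L + s; c }))
      accuracy_at_k(run_method("rMixMEAN", sim$dataset), sim$truth_ranking, 50)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(acc) <= 0))
})

test_that("zero heterogeneity concentrates between-list agreement", {
  pair_cors <- function(D, seed) {
    sim <- generate_dataset(sim_config(n_entities = 600L, n_signal = 30L,
                                       M = 3, D = D, m_c = 200, D_c = 0,
                                       L = 50L,
                                       list_specs = preset_list_specs("RankSmall"),
                                       seed = seed))
    m <- build_rank_matrix(sim$dataset)
    cors <- stats::cor(m, method = "spearman")
    cors[upper.tri(cors)]
  }
  v0 <- var(unlist(lapply(1:6, function(s) pair_cors(0, 600L + s))))
  v3 <- var(unlist(lapply(1:6, function(s) pair_cors(3, 600L + s))))
  expect_lt(v0, v3)
})
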