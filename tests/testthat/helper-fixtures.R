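# Fixtures are built in code; nothing is read from disk.

# Generic mixed dataset over a small universe. The first list covers the
# whole universe so that every method produces (almost surely) untied
# scores, which the relabelling-invariance property needs.
generic_dataset <- function(seed = 42, n_universe = 40) {
  set.seed(seed)
  u <- sprintf("g%02d", seq_len(n_universe))
  gene_dataset(list(
    gene_list("full",  sample(u),                    "RANKED"),
    gene_list("part1", sample(u, 30),                "RANKED"),
    gene_list("part2", sample(u, 28),                "RANKED"),
    gene_list("set1",  sample(u, 10),                "UNRANKED"),
    gene_list("set2",  sample(u, 8),                 "UNRANKED")
  ), universe = u)
}

# Small ranked-only dataset.
ranked_dataset <- function(seed = 7, n_universe = 25, n_lists = 4) {
  set.seed(seed)
  u <- sprintf("g%02d", seq_len(n_universe))
  gene_dataset(lapply(seq_len(n_lists), function(i) {
    gene_list(sprintf("l%d", i), sample(u, n_universe - i), "RANKED")
  }), universe = u)
}

# Scaled-down generator config for fast unit/property tests; study-scale
# defaults are exercised in the acceptance suite.
small_cfg <- function(..., scenario = "MixSmall", n_entities = 500L,
                      n_signal = 25L, m_c = 60, D_c = 0.5, L = 20L) {
  sim_config(n_entities = n_entities, n_signal = n_signal, m_c = m_c,
             D_c = D_c, L = L, list_specs = preset_list_specs(scenario), ...)
}

expect_same_ranking <- function(a, b) {
  expect_identical(a$ranking, b$ranking)
}
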