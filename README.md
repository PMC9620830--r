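# rankagg

Rank aggregation of gene lists, with a simulation benchmark to tell you
which method to trust on *your* data.

Biomedical studies answering the same question each report a list of
implicated genes — some ranked, many unranked (pathways, co-expression
clusters, "the hits" of a paper). Combining them into a consensus ranking
is a rank-aggregation problem over a genome-scale universe, and the best
method depends on properties of the collection: whether unranked sources
are present, how many sources there are, and how heterogeneous their
quality is. `rankagg` implements the main unsupervised aggregation
methods, a realistic stochastic generator of gene-list collections with
known truth, an evaluation harness, and an automated method selector.

## The core model

The simulator draws, for list *i* and entity *k* with significance μ_k,

    Z_ki ~ N(μ_k, σ_i²),   ln σ_i ~ N(ln M, D²)

ranks the 20 000-entity universe by decreasing Z, removes
X = ⌊γ·(20000 − N_i)⌋ never-assayed entities uniformly at random, and
truncates to the top N_i = min(⌊C_i⌋ + L, U) with
ln C_i ~ N(ln m_c, D_c²). The top 1000 entities (5 %) with μ_k > 0 form
the ground truth. M sets the mean noise, D the quality heterogeneity
across lists, γ the absent-gene rate; lists are labelled RANKED or
UNRANKED.

Aggregation methods: Borda statistics (`rMEAN`, `rMED`, `rGEO`) and their
unranked-capable Mix variants (members of an unranked list of length n
all get rank n/2), the order-statistic methods `Stuart`/`MixStuart` and
`RRA`, vote counting (`VC`), `RepeatChoice`, Markov-chain aggregation
(`MC3`), iterative Bayesian reweighting (`BIRRA`), and iterative list
weighting by information content (`MAIC`), which also powers the
heterogeneity inference used by the method selector.

## Worked example

Read a collection in the TSV exchange format
(`name<TAB>category<TAB>RANKED|UNRANKED<TAB>gene1<TAB>gene2...`) and
aggregate it with an unranked-capable method:

```r
library(rankagg)
d <- read_dataset(system.file("extdata", "example_collection.tsv",
                              package = "rankagg"))
d
#> <gene_dataset> 3 lists (2 ranked, 1 unranked), universe of 7 entities
run_method("rMixGEO", d)
#> <aggregation_result> method=rMixGEO (lower is better), 7 entities ranked, unranked lists used
#>  rank entity     score
#>     1   TP53 0.2060357
#>     2   EGFR 0.3443060
#>     3   KRAS 0.3743916
#>     4  STK11 0.5984085
#>     5 PIK3CA 0.7539474
#>     6    MYC 0.8298265
#>     7  BRCA1 0.8939035
```

TP53 leads because it sits at or near the top of both screens and is
backed by the pathway set; the geometric mean of normalized ranks (lower
is better) rewards exactly this cross-source consistency.

Simulate a realistic small collection (4 ranked + 2 unranked lists,
high quality heterogeneity), aggregate with MAIC, and ask the selector
what it would have recommended:

```r
sim <- generate_dataset(preset("MixSmall", M = 3, D = 3, seed = 1))
sim
#> <sim_dataset>
#>   <gene_dataset> 6 lists (4 ranked, 2 unranked), universe of 20000 entities
#>   truth: 1000 signal entities; sigma range [0.095, 21.7]
res <- maic(sim$dataset)
accuracy_at_k(res, sim$truth_ranking, 1000)
#> [1] 0.683
round(res$list_weights, 3)
#>   R01   R02   R03   R04   U01   U02
#> 0.787 0.849 0.325 1.000 0.685 0.338
select_method(sim$dataset)
#> <selection_report> 6 lists, unranked present; heterogeneity low (score 0.417)
#>   method available note
#>     MAIC      TRUE
#>  rMixGEO      TRUE
```

MAIC recovers 68 % of the 1000-gene truth in its top 1000 despite
per-list noise scales spanning 0.095–21.7, and its fitted weights
down-rank the noisiest sources. The selector measures weight dispersion
(coefficient of variation 0.417, here just under the default 0.5
threshold — `calibrate_het_threshold()` produces a threshold matched to
the collection's size and mix) and recommends MAIC first either way,
because unranked lists are present.

Replicated benchmarking with confidence intervals:

```r
replicate_experiment(preset("MixLarge", M = 3, D = 3),
                     c("MAIC", "rMixGEO", "VC"),
                     n_reps = 20, cutoffs = c(100L, 1000L))
```

A thin command-line front end over the same functions ships in
`inst/cli/rankagg-cli.R` with `simulate`, `aggregate`, `evaluate` and
`select` subcommands.

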