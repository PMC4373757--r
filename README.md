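# oaconcord

Paired differential expression and cross-study concordance statistics for
post-traumatic osteoarthritis cartilage transcriptomics.

## What this is for

In surgical mouse models of osteoarthritis (destabilisation of the medial
meniscus, DMM), one knee is operated and the contralateral knee serves as
the within-animal control. Expression profiling of micro-dissected
cartilage at successive times after surgery poses two recurring analysis
problems, and this package implements both as a tested, reusable pipeline:

1. **Paired differential expression** per timepoint: per-gene paired
   t-tests (or limma moderated-t) on within-animal ipsilateral −
   contralateral log2 differences, detection filtering,
   Benjamini–Hochberg adjustment, probe→gene collapsing, and
   volcano-style classification. The characteristic result is a DE signal
   that collapses over the post-surgery time course.
2. **Cross-study concordance** of significant-gene lists from independent
   studies (any species or induction method):
   - exact hypergeometric overlap of two lists of sizes $n_1, n_2$ in a
     universe of $U$ genes,
     $P(X=k) = \binom{n_1}{k}\binom{U-n_1}{n_2-k} \big/ \binom{U}{n_2}$,
     computed in log space, with both the point mass and the upper tail
     $P(X \ge k)$ reported;
   - a Venn region algebra for 2–4 lists;
   - a multi-study occurrence histogram (how many genes recur in exactly
     / at least $j$ of $S$ studies) judged against a Monte-Carlo null in
     which each study draws its true list size without replacement from a
     common pool, with a Poisson-binomial closed form as the analytic
     oracle.

Around these sit an interaction-network stage (STRING-style edge tables,
degree-≥10 hub calling, components, GraphML export), hypergeometric
pathway over-representation against GMT catalogues, and a fully seeded
synthetic-data generator that emulates the paired design — 8 animal pairs
per timepoint, planted DE decaying 1224 → 76 → 2 genes, nine study lists
with a planted 22-gene core recurring in five studies — so the entire
pipeline runs and is tested without any external data.

The interfaces are tidyverse-native: data frames in, tibbles out,
`tidy()`/`glance()` on fitted results, `ggplot2` plots via
`plot_volcano()`, `plot_occurrence()` and `autoplot()`.

## A worked example

```r
library(oaconcord)

# paired experiment with planted signal: 500 genes, 60 DE at 2 weeks
exp <- simulate_experiment(sim_config(n_genes = 500, n_probes = 600,
                                      de_counts = c(60, 10, 2), seed = 42))
de <- paired_de(exp, "2w")
glance(de)
#> # A tibble: 1 × 9
#>   timepoint n_pairs n_probes n_probes_tested n_genes n_significant ...
#> 1 2w              8      600             600     500            55
```

55 of 500 genes are called significant (adjusted p < 0.05) — most of the
60 planted genes, with the weakest fold changes (down to 1.5-fold) costing
a few. `plot_volcano(de)` draws the corresponding volcano plot.

```r
# nine synthetic study lists with a 22-gene core planted in 5 studies
sets  <- simulate_study_collection(study_sim_config(seed = 42))
obs   <- occurrence_histogram(sets, universe = 10000)
sizes <- vapply(split(sets$symbol, sets$study_id), length, integer(1))
null  <- occurrence_null(sizes, universe = 10000, n_sims = 2000, seed = 42)

obs$observed_ge[obs$j == 5]
#> [1] 22
null$expected_ge[null$j == 5]
#> [1] 0.104
```

Twenty-two genes recur in five or more of the nine lists, while the null
expects about 0.1 such genes from chance overlap alone — the observed
recurrence is two orders of magnitude above its chance expectation, the
signature of genuine cross-study concordance.
`occurrence_members(obs, 5)` lists the recurring genes;
`plot_occurrence(obs, null)` draws observed squares against expected
circles.

The end-to-end pipeline (`run_pipeline(pipeline_config(...))`) chains
simulation, DE, overlap, occurrence, network and enrichment stages,
writes every table as TSV with a stage/config-hash header plus a
`manifest.json`, and is byte-reproducible under a fixed seed. A thin CLI
wrapper lives at `inst/cli/oaconcord.R`.

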