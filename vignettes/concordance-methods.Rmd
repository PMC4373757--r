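---
title: "Paired differential expression and cross-study concordance: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential expression and cross-study concordance: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaconcord)
library(ggplot2)
```

# The scientific setting

Surgical destabilisation of the medial meniscus (DMM) in the mouse is a
standard model of post-traumatic osteoarthritis. One knee is operated
(ipsilateral) while the other (contralateral) is left intact as a
within-animal control, and micro-dissected medial tibial plateau cartilage
is profiled on expression arrays at several times after surgery. Two
analytical questions follow:

1. **Which genes change in the operated limb, and how does that signal
   evolve?** A paired comparison per timepoint, with the hallmark
   observation that the number of regulated genes collapses over the time
   course (on the order of a thousand genes at 2 weeks, tens at 4 weeks,
   almost none at 8 weeks).
2. **Are the changes concordant with other osteoarthritis transcriptomics
   studies**, across species, platforms and induction methods? This is a
   gene-list overlap problem: pairwise overlaps judged by an exact
   hypergeometric model, and multi-study recurrence judged against a
   Monte-Carlo null.

The package implements both analyses, plus the interaction-network and
pathway over-representation stages that usually accompany them, and a
synthetic-data generator that emulates the design so the whole pipeline is
testable without any external download.

# Paired differential expression

For gene $g$ and animal $a$ the model works on the within-animal paired
difference of log2 intensities, $d_{ga} = y_{ga}^{\mathrm{ipsi}} -
y_{ga}^{\mathrm{contra}}$. The reference test is the two-sided paired
$t$-test on $d_{g\cdot}$ with $n-1$ degrees of freedom; `paired_de()` also
offers a moderated $t$ (empirical-Bayes variance shrinkage via limma,
`method = "moderated"`), which is preferable at small $n$ when the
per-gene variance estimates are unstable. Raw p-values are adjusted with
Benjamini–Hochberg across all tested probes of a timepoint and genes are
called significant at adjusted $p < 0.05$.

Choices that were genuinely open, and how they were resolved:

* **Detection filter.** Array probes carry detection p-values; a probe is
  "confidently detected" when its detection $p <$ 0.05 in at least half
  the samples of *at least one* limb group (`detect_probes()`, defaults
  `alpha_det = 0.05`, `min_fraction = 0.5`). Requiring only one group
  protects genes switched off in control cartilage but induced by surgery.
* **Probe collapsing.** A gene is significant if any of its probes is; its
  reported statistics come from the probe with minimal adjusted $p$, ties
  broken by larger $|\log_2 \mathrm{FC}|$, then lexicographic probe id.
  The rule is deterministic and independent of input row order.
* **Degenerate probes.** Constant paired differences leave the $t$
  statistic undefined. A constant zero difference is reported as $p = 1$
  (no evidence, no variance to judge it by); a constant nonzero difference
  is an infinite $t$ and $p = 0$ — this is exactly the zero-noise limit of
  the generator, where planted fold changes must be recovered to machine
  precision.
* **Volcano highlighting** uses strict fold-change thresholds gated on
  significance: 2.8 / 0.35 for the early timepoint and 1.5 / 0.5 for the
  intermediate one, the conventions used when labelling such plots.

# Overlap statistics

## Pairwise: exact hypergeometric

For two lists of sizes $n_1, n_2$ drawn from a universe of $U$ genes, the
overlap count $X$ is hypergeometric,

$$P(X = k) = \frac{\binom{n_1}{k}\binom{U-n_1}{n_2-k}}{\binom{U}{n_2}}.$$

`hypergeom_overlap()` reports both the point mass (what a concordance
figure plots for an observed overlap) and the upper tail $P(X \ge k)$ (the
conventional enrichment p-value). Coefficients are computed in log space
via log-gamma — universes of $10^4$–$2\times10^4$ genes overflow naive
factorials — and the support masses are renormalised to sum to one, which
removes the $\sim 10^{-12}$ drift that log-gamma rounding accumulates over
supports of thousands of values. The universe $U$ is a required explicit
argument: it is a modelling choice (roughly, the number of genes both
platforms could have called) with no safe universal default; 10,000 is the
package-wide default pool and 15,000 the conventional sensitivity
alternative.

## Multi-study: occurrence histogram and its null

`occurrence_histogram()` counts how many genes appear in exactly $j$ of
$S$ study lists. The null of no concordance is simulated by
`occurrence_null()`: each study draws its true list size uniformly without
replacement from a common pool of $U$ genes, independently of the other
studies, and the histogram is averaged over replicates (10,000 by
default). "Without replacement" applies within a study — that is the only
reading consistent with fixed list sizes — while studies are independent.

The closed-form oracle `occurrence_expectation()` rests on the observation
that a fixed gene belongs to study $i$ with probability $p_i = n_i/U$,
independently across studies (within-study sampling without replacement
does not alter a single gene's marginal). The occurrence count of one gene
is therefore Poisson-binomial, computed by the standard $O(S^2)$
convolution recursion, and the expected histogram is $U$ times its mass
function. The test suite holds the Monte-Carlo mean within three standard
errors of this closed form on a grid of configurations, along with the
bookkeeping identities $\sum_j j\,E[j] = \sum_i n_i$ and
$\sum_j E[j] = U$.

## Symbol harmonization

Cross-species comparison requires one symbol space. `harmonize_symbols()`
upper-cases symbols (making mouse `Fmod` comparable with human `FMOD`)
and optionally translates through a user-supplied two-column ortholog map;
no ortholog *inference* is attempted. Membership, not direction of change,
is what the occurrence machinery counts: direction columns are carried
through for the user but deliberately ignored by the overlap statistics.

# Network and enrichment stages

`build_network()` restricts a STRING-style edge table (scale 0–999 or
0–1, auto-detected; default cutoff 400 / 0.4, the conventional medium
confidence) to edges whose *both* endpoints are significant genes, drops
isolated nodes, collapses duplicate edges keeping the maximum score, and
annotates nodes with fold change, adjusted $p$, degree and connected
component. Hubs are nodes of degree at least 10 (`find_hubs()`), ranked by
degree with lexicographic tie-breaks. Graph containers, components and
GraphML export are igraph's; the degree bookkeeping is cross-checked
against a brute-force adjacency count in the tests.

`enrich()` performs over-representation against a GMT catalogue with the
same exact hypergeometric tail used everywhere else (a single shared
implementation, asserted in the tests). The background is the set of
*detected* genes, not the whole genome — standard ORA practice; pathways
are intersected with the background before testing, and the comparison of
"significantly enriched pathway" sets across studies
(`compare_pathway_sets()`) conventionally uses raw $p < 0.05$, with BH
values also emitted.

# The synthetic-data generator

`simulate_experiment()` emulates the study design, not the chemistry:

* paired limb design, 8 animals per timepoint, three timepoints;
* baseline log2 intensities $\mu_g \sim N(8, 2)$ — a typical microarray
  dynamic range, irrelevant to the paired statistics;
* planted differential expression decaying 1224 → 76 → 2 genes, nested
  across timepoints so late genes persist from early ones;
* signed log2 fold changes uniform on $[0.585, 3]$ (fold change 1.5–8),
  60% up / 40% down;
* per-gene residual noise $N(0, 0.5)$ on the log2 scale; surplus probes
  (1.2 probes per gene) replicate the gene signal plus independent
  probe-level noise at half that SD;
* everything seeded: identical configurations are byte-identical.

It does **not** model bead-level data, background correction, batch
effects, detection failures (all probes carry passing detection p-values)
or inter-gene correlation. Passing tests therefore demonstrate that the
statistics behave correctly under a clean paired design with independent
Gaussian noise — not that any particular biological dataset would
reproduce specific counts.

`simulate_study_collection()` generates $S = 9$ study lists from a
$U = 10{,}000$ pool with a planted core of 22 genes each inserted into
exactly 5 randomly chosen studies. The default list sizes — 1224 followed
by 600, 500, 400, 350, 300, 250, 200, 150 — take the 2-week list at face
value and span the range of published rodent/human osteoarthritis DE-list
sizes; under these sizes the closed form puts the chance expectation of a
gene recurring in five or more lists well below one, so a recovered
22-gene core is unambiguous evidence of planted concordance. Companion
generators provide STRING-style edge tables with planted hubs and toy GMT
catalogues with planted enrichment.

# Problem sizes and numerical choices

The test suite validates the hypergeometric mass against exhaustive
enumeration for all configurations with $U \le 12$ at $10^{-12}$, checks
normalisation for 1000 random configurations up to $U = 20{,}000$,
runs the occurrence null at 10,000 replicates over a grid of
$S \in \{2, 5, 9\}$, $U \in \{100, 10{,}000\}$, measures the DE stage's
false-positive fraction over 200 null simulations (500 genes each) and its
power over 50 simulations of the default regime (about 12% of genes
planted, where mean recovery exceeds 80%), and verifies network degrees
against a brute-force oracle on 100 random graphs. These sizes keep the
whole suite in the low minutes while leaving the Monte-Carlo standard
errors far below the tested tolerances.

Historical figures that depend on external study lists and
database-version-specific interaction data — specific node/edge counts,
cross-study Venn members, published enrichment p-values — are *documented
surfaces*: the functions accept any user-supplied lists of the right
shape, but the package does not claim to reproduce numbers whose inputs it
cannot carry.

# A worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- sim_config(n_genes = 500, n_probes = 600, de_counts = c(60, 10, 2),
                  seed = 42)
exp <- simulate_experiment(cfg)
de <- paired_de(exp, "2w")
glance(de)
plot_volcano(de)

sets <- simulate_study_collection(study_sim_config(seed = 42))
obs <- occurrence_histogram(sets, universe = 10000)
sizes <- vapply(split(sets$symbol, sets$study_id), length, integer(1))
null <- occurrence_null(sizes, universe = 10000, n_sims = 2000, seed = 42)
plot_occurrence(obs, null)
obs$observed_ge[obs$j == 5]    # planted-core recurrence
null$expected_ge[null$j == 5]  # chance expectation
```

# Known limitations

* The DE reference method is a per-gene paired $t$; with 8 pairs the
  moderated variant typically has better calibration and either can be
  selected explicitly.
* The occurrence null ignores direction of change and any between-study
  dependence (shared platforms, shared labs); both make the null
  conservative in opposite directions and neither is modelled.
* The ortholog map must be supplied; symbol upper-casing alone is a crude
  cross-species harmonization and will miss renamed genes.
* Venn region algebra is limited to 2–4 sets by design; higher arities are
  served by the occurrence histogram.
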