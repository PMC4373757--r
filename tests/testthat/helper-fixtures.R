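# Shared fixtures and independent oracles used across the suite.

# Exhaustive hypergeometric pmf: enumerate every size-n2 draw from a
# universe of U labelled genes and count overlaps with a fixed first set.
# Independent of the log-space implementation under test.
enum_overlap_pmf <- function(n1, n2, U) {
  first <- seq_len(n1)
  draws <- utils::combn(U, n2, simplify = FALSE)
  ks <- vapply(draws, function(d) length(intersect(d, first)), integer(1))
  lo <- max(0, n1 + n2 - U)
  hi <- min(n1, n2)
  vapply(lo:hi, function(k) mean(ks == k), numeric(1))
}

# Brute-force degree count from an edge tibble (no igraph).
brute_degrees <- function(edges) {
  syms <- sort(unique(c(edges$protein1, edges$protein2)))
  vapply(setNames(syms, syms), function(s) {
    sum(edges$protein1 == s) + sum(edges$protein2 == s)
  }, integer(1))
}

tiny_experiment <- function(seed = 1, noise_sd = 0.5, n_genes = 120,
                            de_counts = c(12, 4, 1)) {
  simulate_experiment(sim_config(
    n_genes = n_genes, n_probes = round(1.2 * n_genes),
    de_counts = de_counts, noise_sd = noise_sd, seed = seed
  ))
}
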