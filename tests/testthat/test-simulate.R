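test_that("experiment simulation is deterministic in the seed", {
  cfg <- sim_config(n_genes = 80, n_probes = 96, de_counts = c(8, 3, 1), seed = 1)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(sim_config(n_genes = 80, n_probes = 96,
                                      de_counts = c(8, 3, 1), seed = 1))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  d <- simulate_experiment(sim_config(n_genes = 80, n_probes = 96,
                                      de_counts = c(8, 3, 1), seed = 2))
  expect_false(identical(a$matrix, d$matrix))
})

test_that("null configuration plants nothing; zero noise gives exact effects", {
  null <- simulate_experiment(sim_config(n_genes = 50, n_probes = 50,
                                         de_counts = c(0, 0, 0), seed = 1))
  expect_equal(nrow(null$truth), 0L)

  exact <- simulate_experiment(sim_config(n_genes = 40, n_probes = 48,
                                          de_counts = c(5, 2, 1),
                                          noise_sd = 0, seed = 2))
  smp <- exact$samples[exact$samples$timepoint == "2w", ]
  ipsi <- smp$sample_id[smp$limb == "ipsi"]
  contra <- smp$sample_id[smp$limb == "contra"]
  truth2 <- exact$truth[exact$truth$timepoint == "2w", ]
  pm <- exact$probe_map
  for (i in seq_len(nrow(truth2))) {
    probes <- pm$probe_id[pm$gene_symbol == truth2$gene[i]]
    diffs <- rowMeans(exact$matrix[probes, ipsi, drop = FALSE] -
                        exact$matrix[probes, contra, drop = FALSE])
    expect_equal(unname(diffs), rep(truth2$log2fc_true[i], length(probes)),
                 tolerance = 1e-12)
  }
})

test_that("experiment structure honours the paired design", {
  e <- tiny_experiment(seed = 4)
  cfg <- e$config
  expect_equal(nrow(e$matrix), cfg$n_probes)
  expect_equal(ncol(e$matrix), 2 * cfg$n_pairs * length(cfg$timepoints))
  # each animal contributes exactly one ipsi and one contra sample
  tab <- table(e$samples$animal_id, e$samples$limb)
  expect_true(all(tab == 1))
  expect_true(all(rownames(e$matrix) %in% e$probe_map$probe_id))
  # planted sets are nested across the decaying time course
  tp <- cfg$timepoints
  g2 <- e$truth$gene[e$truth$timepoint == tp[1]]
  g4 <- e$truth$gene[e$truth$timepoint == tp[2]]
  g8 <- e$truth$gene[e$truth$timepoint == tp[3]]
  expect_true(all(g8 %in% g4) && all(g4 %in% g2))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 100, n_probes = 50), "n_probes")
  expect_error(sim_config(n_genes = 10, de_counts = c(20, 1, 0)), "de_counts")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(study_sim_config(set_sizes = rep(20, 9), universe_size = 10),
               "universe_size")
  expect_error(study_sim_config(n_studies = 3, set_sizes = c(5, 5, 5),
                                universe_size = 100,
                                planted_core = 10, m_core = 2),
               "planted_core")
})

test_that("study collections honour sizes, uniqueness and the planted core", {
  cfg <- study_sim_config(seed = 3)
  sets <- simulate_study_collection(cfg)
  sl <- split(sets$symbol, sets$study_id)
  expect_equal(unname(lengths(sl)), cfg$set_sizes)
  expect_true(all(vapply(sl, anyDuplicated, integer(1)) == 0))
  prof <- occurrence_histogram(sets)
  expect_gte(prof$observed_ge[prof$j == cfg$m_core], cfg$planted_core)
  core <- attr(sets, "core_genes")
  counts <- table(sets$symbol)
  expect_true(all(counts[core] >= cfg$m_core))
})

test_that("saturated study collections contain every gene everywhere", {
  cfg <- study_sim_config(n_studies = 3, universe_size = 25,
                          set_sizes = c(25, 25, 25), planted_core = 0,
                          m_core = 1, seed = 1)
  sets <- simulate_study_collection(cfg)
  prof <- occurrence_histogram(sets)
  expect_equal(prof$observed[prof$j == 3], 25L)
})

test_that("unplanted collections match the analytic pairwise overlap", {
  # mean pairwise overlap over many seeds within 3 SE of n_i * n_j / U
  U <- 200
  sizes <- c(30, 40)
  n_seeds <- 200
  ks <- vapply(seq_len(n_seeds), function(s) {
    sets <- simulate_study_collection(study_sim_config(
      n_studies = 2, universe_size = U, set_sizes = sizes,
      planted_core = 0, m_core = 1, seed = s))
    sl <- split(sets$symbol, sets$study_id)
    length(intersect(sl[[1]], sl[[2]]))
  }, numeric(1))
  expected <- sizes[1] * sizes[2] / U
  se <- sd(ks) / sqrt(n_seeds)
  expect_lt(abs(mean(ks) - expected), 3 * se)
})

test_that("edge-table and GMT simulators produce valid planted fixtures", {
  syms <- sprintf("G%03d", 1:60)
  ed <- simulate_edge_table(syms, n_hubs = 2, hub_degree = 12,
                            n_background = 40, seed = 2)
  expect_true(all(ed$protein1 != ed$protein2))
  key <- paste(pmin(ed$protein1, ed$protein2), pmax(ed$protein1, ed$protein2))
  expect_equal(anyDuplicated(key), 0L)
  deg <- brute_degrees(ed)
  expect_true(all(deg[attr(ed, "hub_genes")] >= 12))

  gmt <- simulate_gmt(syms, n_pathways = 5, size_range = c(5, 10),
                      enrich_with = syms[1:10], n_enriched = 2, seed = 3)
  expect_length(gmt, 5)
  expect_true(all(lengths(gmt) >= 1))
  expect_gte(length(intersect(gmt[[1]], syms[1:10])), 3)
})
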