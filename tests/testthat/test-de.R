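test_that("detection filter applies the per-group fraction rule", {
  e <- tiny_experiment(seed = 1)
  e$detection[] <- 0.001
  expect_true(all(detect_probes(e)))
  e$detection[] <- 0.99
  expect_false(any(detect_probes(e, alpha_det = 0.05)))

  # one limb group passing suffices
  ipsi <- e$samples$sample_id[e$samples$limb == "ipsi"]
  contra <- e$samples$sample_id[e$samples$limb == "contra"]
  e$detection[1, ipsi] <- 0.01
  e$detection[1, contra] <- 0.9
  expect_true(detect_probes(e, alpha_det = 0.05, min_fraction = 0.5)[[1]])

  expect_error(detect_probes(e, min_fraction = 0), "min_fraction")
  expect_error(detect_probes(e, min_fraction = 1.5), "min_fraction")
  e$detection <- NULL
  expect_warning(flags <- detect_probes(e), "detection")
  expect_true(all(flags))
})

test_that("paired t statistic matches the hand-computed toy", {
  # 3 pairs with differences 1, 2, 3: t = mean / (sd / sqrt(n)) = 2 * sqrt(3)
  contra <- matrix(c(5, 5, 5), nrow = 1)
  ipsi <- contra + c(1, 2, 3)
  e <- list(
    matrix = cbind(ipsi, contra),
    samples = tibble::tibble(
      sample_id = c("a1_i", "a2_i", "a3_i", "a1_c", "a2_c", "a3_c"),
      animal_id = rep(c("a1", "a2", "a3"), 2),
      limb = rep(c("ipsi", "contra"), each = 3),
      timepoint = "2w"
    ),
    probe_map = tibble::tibble(probe_id = "p1", gene_symbol = "G"),
    detection = NULL, truth = NULL, config = NULL
  )
  colnames(e$matrix) <- e$samples$sample_id
  rownames(e$matrix) <- "p1"
  class(e) <- "expr_experiment"
  de <- suppressWarnings(paired_de(e, "2w"))
  t_ref <- 2 * sqrt(3)
  expect_equal(de$genes$p_raw, 2 * pt(-t_ref, df = 2), tolerance = 1e-12)
  expect_equal(de$genes$log2fc, 2)
})

test_that("zero-noise fixtures recover planted fold changes exactly", {
  e <- simulate_experiment(sim_config(n_genes = 60, n_probes = 72,
                                      de_counts = c(6, 2, 1),
                                      noise_sd = 0, seed = 5))
  de <- suppressMessages(paired_de(e, "2w"))
  truth <- e$truth[e$truth$timepoint == "2w", ]
  got <- de$genes[match(truth$gene, de$genes$gene), ]
  expect_equal(got$log2fc, truth$log2fc_true, tolerance = 1e-12)
  expect_true(all(got$significant))
  # unplanted zero-noise genes: constant zero differences, p = 1
  other <- de$genes[!de$genes$gene %in% e$truth$gene, ]
  expect_true(all(other$p_raw == 1))
  expect_false(any(other$significant))
})

test_that("insufficient pairing and unknown timepoints abort", {
  e <- tiny_experiment(seed = 2)
  expect_error(paired_de(e, "16w"), "not present")
  e2 <- e
  keep <- e2$samples$timepoint != "2w" |
    e2$samples$animal_id %in% unique(e2$samples$animal_id[e2$samples$timepoint == "2w"])[1:2]
  e2$samples <- e2$samples[keep, ]
  expect_error(paired_de(e2, "2w"), "Insufficient replication")
})

test_that("BH adjustment is monotone and results ignore probe order", {
  e <- tiny_experiment(seed = 6)
  de <- paired_de(e, "2w")
  tested <- de$probes[de$probes$detected, ]
  ord <- order(tested$p_raw)
  expect_true(all(diff(tested$p_adj[ord]) >= -1e-12))
  expect_true(all(tested$p_adj >= tested$p_raw - 1e-12))
  expect_true(all(tested$p_adj <= 1))

  # permute probe rows: per-probe and per-gene results unchanged
  perm <- sample(nrow(e$matrix))
  e2 <- e
  e2$matrix <- e$matrix[perm, ]
  e2$detection <- e$detection[perm, ]
  de2 <- paired_de(e2, "2w")
  expect_equal(
    dplyr::arrange(de$probes, .data$probe_id),
    dplyr::arrange(de2$probes, .data$probe_id)
  )
  expect_equal(de$genes, de2$genes)
})

test_that("probe collapsing picks the min-adjusted-p representative with tie rules", {
  pm <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                       gene_symbol = c("G1", "G1", "G2", "G3"))
  pr <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    log2fc = c(1.0, 0.14, 0.5, -2),
    p_raw = c(0.001, 0.15, 0.01, 0.2),
    p_adj = c(0.01, 0.20, 0.04, 0.4),
    detected = TRUE,
    significant = c(TRUE, FALSE, TRUE, FALSE)
  )
  g <- collapse_probes(pr, pm)
  expect_equal(g$log2fc[g$gene == "G1"], 1.0)   # min p_adj probe wins
  expect_equal(g$fold_change[g$gene == "G1"], 2.0)
  expect_true(g$significant[g$gene == "G1"])
  expect_equal(g$n_probes[g$gene == "G1"], 2L)
  # single-probe genes pass through unchanged
  expect_equal(g$p_adj[g$gene == "G2"], 0.04)
  expect_false(g$significant[g$gene == "G3"])

  # tie on p_adj: larger |log2fc| wins
  tie <- tibble::tibble(
    probe_id = c("a", "b"), log2fc = c(1, -2),
    p_raw = c(0.01, 0.01), p_adj = c(0.01, 0.01),
    detected = TRUE, significant = TRUE
  )
  gt <- collapse_probes(tie, tibble::tibble(probe_id = c("a", "b"),
                                            gene_symbol = "G"))
  expect_equal(abs(gt$log2fc), 2)

  expect_error(collapse_probes(pr, pm[1:2, ]), "missing from")
})

test_that("volcano classification uses strict thresholds gated on significance", {
  df <- tibble::tibble(
    gene = c("at", "above", "down", "ns"),
    log2fc = log2(c(2.8, 3.0, 0.3, 0.3)),
    fold_change = c(2.8, 3.0, 0.3, 0.3),
    p_raw = 0.001, p_adj = c(0.01, 0.01, 0.01, 0.5),
    detected = TRUE, significant = c(TRUE, TRUE, TRUE, FALSE),
    n_probes = 1L
  )
  lab <- volcano_classify(df, up_fc = 2.8, down_fc = 0.35)
  expect_equal(as.character(lab$label),
               c("other", "highlighted-up", "highlighted-down", "other"))
  expect_error(volcano_classify(df, up_fc = 0.9, down_fc = 0.35), "Thresholds")
})

test_that("moderated-t option runs and broadly agrees with the t-test", {
  skip_if_not_installed("limma")
  e <- tiny_experiment(seed = 8)
  d1 <- paired_de(e, "2w", method = "t")
  d2 <- paired_de(e, "2w", method = "moderated")
  # ranking of strong effects should broadly agree between the two methods
  top1 <- head(d1$genes$gene[order(d1$genes$p_adj)], 10)
  top2 <- head(d2$genes$gene[order(d2$genes$p_adj)], 10)
  expect_gte(length(intersect(top1, top2)), 6)
})

test_that("tidiers expose the gene table and a one-row summary", {
  e <- tiny_experiment(seed = 9)
  de <- paired_de(e, "2w")
  expect_identical(tidy(de), de$genes)
  gl <- glance(de)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_significant, sum(de$genes$significant))
})
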