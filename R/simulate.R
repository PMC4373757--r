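#' Configuration for a synthetic paired expression experiment
#'
#' Describes a paired limb design: at each timepoint a group of animals is
#' operated on one knee (ipsilateral) while the other knee (contralateral)
#' serves as the within-animal control. A planted differential-expression
#' signal decays over the time course, defaulting to the 1224 / 76 / 2
#' regulated genes observed at 2, 4 and 8 weeks in surgically induced
#' murine osteoarthritis cartilage.
#'
#' @param n_genes Number of genes on the simulated platform.
#' @param n_probes Number of probes (>= `n_genes`); every gene gets at least
#'   one probe and the surplus is assigned to random genes, giving the
#'   roughly 1.2 probes-per-gene redundancy typical of bead arrays.
#' @param n_pairs Animals per timepoint (each contributes one ipsilateral
#'   and one contralateral sample).
#' @param timepoints Ordered timepoint labels.
#' @param de_counts Planted differentially expressed gene count per
#'   timepoint. Later timepoints reuse genes from earlier ones where
#'   possible, so persistent genes stay regulated throughout.
#' @param log2fc_range Interval the absolute planted log2 fold changes are
#'   drawn from (default 0.585 to 3, i.e. fold changes 1.5 to 8).
#' @param prop_up Proportion of planted genes that are up-regulated.
#' @param noise_sd Per-gene residual SD on the log2 scale. May be 0 for
#'   noiseless fixtures. Surplus (replicate) probes add independent
#'   probe-level noise at half this value on top of the gene signal.
#' @param baseline_mean,baseline_sd Baseline log2 intensity distribution
#'   (gene means drawn Normal(8, 2), a typical microarray dynamic range).
#' @param seed Integer RNG seed; identical configurations give
#'   bit-identical experiments.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 10000,
                       n_probes = round(1.2 * n_genes),
                       n_pairs = 8,
                       timepoints = c("2w", "4w", "8w"),
                       de_counts = c(1224, 76, 2),
                       log2fc_range = c(0.585, 3),
                       prop_up = 0.6,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1),
    n_probes = check_count(n_probes, "n_probes", min = 1),
    n_pairs = check_count(n_pairs, "n_pairs", min = 1),
    timepoints = as.character(timepoints),
    de_counts = vapply(de_counts, check_count, integer(1), name = "de_counts"),
    log2fc_range = as.numeric(log2fc_range),
    prop_up = prop_up,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    seed = check_count(seed, "seed")
  )
  if (cfg$n_probes < cfg$n_genes) {
    abort("`n_probes` must be at least `n_genes`.")
  }
  if (length(cfg$de_counts) != length(cfg$timepoints)) {
    abort("`de_counts` must have one entry per timepoint.")
  }
  if (any(cfg$de_counts > cfg$n_genes)) {
    abort("`de_counts` entries must not exceed `n_genes`.")
  }
  if (length(cfg$log2fc_range) != 2 || any(cfg$log2fc_range <= 0) ||
      diff(cfg$log2fc_range) < 0) {
    abort("`log2fc_range` must be an increasing positive interval.")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    abort("`noise_sd` must be >= 0.")
  }
  if (cfg$prop_up < 0 || cfg$prop_up > 1) {
    abort("`prop_up` must be in [0, 1].")
  }
  structure(cfg, class = "sim_config")
}

gene_names <- function(n) sprintf("g%06d", seq_len(n))

#' Simulate a paired expression experiment with planted signal
#'
#' Draws a probe-by-sample log2 intensity matrix under the paired design of
#' [sim_config()]. Contralateral samples are gene-wise
#' Normal(\eqn{\mu_g}, `noise_sd`); ipsilateral samples of planted genes are
#' shifted by a signed log2 fold change drawn from `log2fc_range`. Genes
#' carrying several probes replicate the gene signal plus independent
#' probe-level noise, and every probe carries a small detection p-value so
#' the detection-filter stage is exercised.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `expr_experiment`: a list with
#'   \describe{
#'     \item{matrix}{probe x sample log2 intensities}
#'     \item{samples}{tibble `sample_id`, `animal_id`, `limb`, `timepoint`}
#'     \item{probe_map}{tibble `probe_id`, `gene_symbol`}
#'     \item{detection}{probe x sample detection p-values}
#'     \item{truth}{tibble of planted genes: `timepoint`, `gene`,
#'       `log2fc_true`, `direction`}
#'     \item{config}{the generating configuration}
#'   }
#' @examples
#' exp <- simulate_experiment(sim_config(n_genes = 50, de_counts = c(5, 2, 1)))
#' dim(exp$matrix)
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  withr::with_seed(cfg$seed, {
    genes <- gene_names(cfg$n_genes)
    mu <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    names(mu) <- genes

    # Planted DE sets are nested where counts allow, so genes regulated at
    # late timepoints persist from earlier ones (Tnn/Fmod-style persistence).
    planted <- vector("list", length(cfg$timepoints))
    names(planted) <- cfg$timepoints
    prev <- character(0)
    for (t in seq_along(cfg$timepoints)) {
      ct <- cfg$de_counts[t]
      if (ct <= length(prev)) {
        planted[[t]] <- sample(prev, ct)
      } else {
        extra <- sample(setdiff(genes, prev), ct - length(prev))
        planted[[t]] <- c(prev, extra)
      }
      prev <- planted[[t]]
    }

    all_de <- unique(unlist(planted, use.names = FALSE))
    lfc <- runif(length(all_de), cfg$log2fc_range[1], cfg$log2fc_range[2])
    sign_up <- runif(length(all_de)) < cfg$prop_up
    lfc <- ifelse(sign_up, lfc, -lfc)
    names(lfc) <- all_de

    samples <- tidyr::expand_grid(
      timepoint = cfg$timepoints,
      animal = seq_len(cfg$n_pairs),
      limb = c("ipsi", "contra")
    )
    samples <- dplyr::mutate(
      samples,
      animal_id = sprintf("%s_a%02d", .data$timepoint, .data$animal),
      sample_id = sprintf("%s_%s", .data$animal_id, .data$limb)
    )
    samples <- dplyr::select(samples, "sample_id", "animal_id", "limb", "timepoint")

    n_samp <- nrow(samples)
    gmat <- matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$noise_sd),
                   nrow = cfg$n_genes, ncol = n_samp,
                   dimnames = list(genes, samples$sample_id))
    gmat <- gmat + mu
    for (t in cfg$timepoints) {
      ipsi_cols <- samples$sample_id[samples$limb == "ipsi" & samples$timepoint == t]
      pg <- planted[[t]]
      if (length(pg)) gmat[pg, ipsi_cols] <- gmat[pg, ipsi_cols] + lfc[pg]
    }

    # one primary probe per gene carries the gene signal verbatim; surplus
    # probes replicate it with independent probe-level noise
    n_extra <- cfg$n_probes - cfg$n_genes
    probe_gene <- c(genes, if (n_extra > 0) sample(genes, n_extra, replace = TRUE))
    probe_ids <- sprintf("p%07d", seq_len(cfg$n_probes))
    pmat <- gmat[probe_gene, , drop = FALSE]
    if (n_extra > 0) {
      extra_rows <- cfg$n_genes + seq_len(n_extra)
      pmat[extra_rows, ] <- pmat[extra_rows, ] +
        matrix(rnorm(n_extra * n_samp, 0, cfg$noise_sd / 2), nrow = n_extra)
    }
    rownames(pmat) <- probe_ids

    detection <- matrix(runif(cfg$n_probes * n_samp, 0, 0.01),
                        nrow = cfg$n_probes,
                        dimnames = list(probe_ids, samples$sample_id))

    truth <- purrr::map_dfr(cfg$timepoints, function(t) {
      pg <- planted[[t]]
      tibble(timepoint = rep(t, length(pg)), gene = pg,
             log2fc_true = unname(lfc[pg]),
             direction = as.character(ifelse(lfc[pg] > 0, "up", "down")))
    })

    out <- list(
      matrix = pmat,
      samples = samples,
      probe_map = tibble(probe_id = probe_ids, gene_symbol = probe_gene),
      detection = detection,
      truth = truth,
      config = cfg
    )
    class(out) <- "expr_experiment"
    out
  })
}

#' @export
print.expr_experiment <- function(x, ...) {
  cat(sprintf(
    "Paired expression experiment: %d probes x %d samples (%d genes)\n",
    nrow(x$matrix), ncol(x$matrix), x$config$n_genes
  ))
  cat(sprintf("  timepoints: %s; %d pairs each; %d planted DE gene rows\n",
              paste(x$config$timepoints, collapse = ", "),
              x$config$n_pairs, nrow(x$truth)))
  invisible(x)
}

#' Configuration for a synthetic multi-study gene-list collection
#'
#' Fixture generator for cross-study concordance analysis: `n_studies`
#' significant-gene lists drawn from a shared universe, with an optional
#' planted core of genes forced to recur in exactly `m_core` studies each,
#' emulating genuinely concordant disease genes against a background of
#' study-specific hits.
#'
#' Default `set_sizes` are 1224 (the 2-week murine cartilage list) followed
#' by a decreasing range of plausible published DE-list sizes.
#'
#' @param n_studies Number of studies.
#' @param universe_size Shared gene pool size.
#' @param set_sizes Integer vector of per-study list sizes.
#' @param planted_core Number of genes planted to recur.
#' @param m_core Number of studies each planted gene is inserted into.
#' @param seed Integer RNG seed.
#' @return A `study_sim_config` list, validated.
#' @export
study_sim_config <- function(n_studies = 9,
                             universe_size = 10000,
                             set_sizes = c(1224, 600, 500, 400, 350, 300, 250, 200, 150),
                             planted_core = 22,
                             m_core = 5,
                             seed = 1) {
  cfg <- list(
    n_studies = check_count(n_studies, "n_studies", min = 1),
    universe_size = check_count(universe_size, "universe_size", min = 1),
    set_sizes = vapply(set_sizes, check_count, integer(1), name = "set_sizes"),
    planted_core = check_count(planted_core, "planted_core"),
    m_core = check_count(m_core, "m_core", min = 1),
    seed = check_count(seed, "seed")
  )
  if (length(cfg$set_sizes) != cfg$n_studies) {
    abort("`set_sizes` must have one entry per study.")
  }
  if (any(cfg$set_sizes > cfg$universe_size)) {
    abort("`set_sizes` entries must not exceed `universe_size`.")
  }
  if (cfg$m_core > cfg$n_studies) {
    abort("`m_core` must not exceed `n_studies`.")
  }
  if (cfg$planted_core > min(sort(cfg$set_sizes, decreasing = TRUE)[seq_len(cfg$m_core)])) {
    abort("`planted_core` exceeds what the m_core largest studies can hold.")
  }
  structure(cfg, class = "study_sim_config")
}

#' Simulate a collection of study gene lists with a planted shared core
#'
#' Each planted core gene is inserted into exactly `m_core` randomly chosen
#' studies; the remaining slots of every study are filled by sampling
#' without replacement from the universe (excluding that study's existing
#' members), so each list has exactly its configured size and no
#' duplicates.
#'
#' @param cfg A [study_sim_config()].
#' @return A tibble with columns `study_id`, `symbol` and attribute
#'   `"core_genes"` naming the planted genes.
#' @examples
#' sets <- simulate_study_collection(study_sim_config(
#'   n_studies = 3, universe_size = 100, set_sizes = c(20, 15, 10),
#'   planted_core = 2, m_core = 2, seed = 7))
#' occurrence_histogram(sets)
#' @export
simulate_study_collection <- function(cfg = study_sim_config()) {
  if (!inherits(cfg, "study_sim_config")) cfg <- do.call(study_sim_config, cfg)
  withr::with_seed(cfg$seed, {
    genes <- gene_names(cfg$universe_size)
    study_ids <- sprintf("study%02d", seq_len(cfg$n_studies))
    members <- vector("list", cfg$n_studies)
    names(members) <- study_ids

    core <- if (cfg$planted_core > 0) sample(genes, cfg$planted_core) else character(0)
    for (g in core) {
      chosen <- sample.int(cfg$n_studies, cfg$m_core)
      for (i in chosen) members[[i]] <- c(members[[i]], g)
    }
    if (any(lengths(members) > cfg$set_sizes)) {
      abort("Planting infeasible: a study received more core genes than its size.")
    }
    for (i in seq_len(cfg$n_studies)) {
      need <- cfg$set_sizes[i] - length(members[[i]])
      pool <- setdiff(genes, members[[i]])
      members[[i]] <- c(members[[i]], sample(pool, need))
    }
    out <- tibble(
      study_id = rep(study_ids, lengths(members)),
      symbol = unlist(members, use.names = FALSE)
    )
    attr(out, "core_genes") <- core
    out
  })
}

#' Simulate a STRING-style interaction edge table with planted hubs
#'
#' Builds an undirected edge table over the supplied symbols: a few hub
#' genes connected to many random partners plus a background of random
#' edges, with combined scores on the conventional 0-999 scale.
#'
#' @param symbols Character vector of gene symbols to wire.
#' @param n_hubs Number of planted hub genes.
#' @param hub_degree Number of partners per hub.
#' @param n_background Number of additional random edges.
#' @param score_range Combined-score interval on the 0-999 scale.
#' @param seed Integer RNG seed.
#' @return A tibble `protein1`, `protein2`, `combined_score` with no
#'   self-loops or duplicate (unordered) pairs. Planted hubs are attached
#'   as attribute `"hub_genes"`.
#' @export
simulate_edge_table <- function(symbols, n_hubs = 3, hub_degree = 15,
                                n_background = 100,
                                score_range = c(400, 999), seed = 1) {
  if (length(symbols) < 2) {
    out <- tibble(protein1 = character(), protein2 = character(),
                  combined_score = double())
    attr(out, "hub_genes") <- character(0)
    return(out)
  }
  # cap the planted structure at what the symbol set can support
  hub_degree <- min(hub_degree, length(symbols) - 1)
  n_hubs <- min(n_hubs, length(symbols))
  withr::with_seed(check_count(seed, "seed"), {
    hubs <- sample(symbols, n_hubs)
    edges <- purrr::map_dfr(hubs, function(h) {
      partners <- sample(setdiff(symbols, h), hub_degree)
      tibble(protein1 = h, protein2 = partners)
    })
    bg <- tibble(
      protein1 = sample(symbols, n_background, replace = TRUE),
      protein2 = sample(symbols, n_background, replace = TRUE)
    )
    out <- dplyr::bind_rows(edges, bg)
    out <- dplyr::filter(out, .data$protein1 != .data$protein2)
    key <- paste(pmin(out$protein1, out$protein2), pmax(out$protein1, out$protein2))
    out <- out[!duplicated(key), ]
    out$combined_score <- round(runif(nrow(out), score_range[1], score_range[2]))
    attr(out, "hub_genes") <- hubs
    out
  })
}

#' Simulate a toy GMT pathway catalogue
#'
#' Random pathways over a symbol universe, optionally with a few pathways
#' enriched in a supplied gene list (members drawn preferentially from it),
#' so over-representation analysis has planted signal to find.
#'
#' @param symbols Universe of gene symbols.
#' @param n_pathways Number of pathways.
#' @param size_range Pathway size interval.
#' @param enrich_with Optional character vector; the first
#'   `n_enriched` pathways draw ~60% of their members from it.
#' @param n_enriched Number of enriched pathways when `enrich_with` given.
#' @param seed Integer RNG seed.
#' @return A named list of character vectors (pathway id to members), the
#'   in-memory form of a GMT catalogue; see [write_gmt()].
#' @export
simulate_gmt <- function(symbols, n_pathways = 20, size_range = c(10, 60),
                         enrich_with = NULL, n_enriched = 3, seed = 1) {
  withr::with_seed(check_count(seed, "seed"), {
    paths <- lapply(seq_len(n_pathways), function(i) {
      size <- sample(size_range[1]:size_range[2], 1)
      if (!is.null(enrich_with) && i <= n_enriched) {
        n_hit <- min(length(enrich_with), ceiling(0.6 * size))
        c(sample(enrich_with, n_hit),
          sample(setdiff(symbols, enrich_with), size - n_hit))
      } else {
        sample(symbols, size)
      }
    })
    names(paths) <- sprintf("PW%03d", seq_len(n_pathways))
    lapply(paths, unique)
  })
}
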