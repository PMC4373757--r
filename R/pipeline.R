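#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input paths (or the
#' synthetic generator configs that replace them), significance and
#' fold-change thresholds, the hub criterion, the concordance universe and
#' simulation depth, and the master seed all stage seeds derive from.
#'
#' @param out_dir Output directory.
#' @param simulate Logical; when `TRUE` inputs are generated with
#'   [simulate_experiment()] and [simulate_study_collection()].
#' @param sim Arguments for [sim_config()] (list), used when `simulate`.
#' @param study_sim Arguments for [study_sim_config()] (list).
#' @param experiment_dir Directory of a serialised experiment (when not
#'   simulating; see [read_experiment()]).
#' @param gene_list_paths Paths of external study gene-list TSVs.
#' @param edge_table_path Path of the interaction edge table; `NULL` with
#'   `simulate = TRUE` generates one.
#' @param gmt_path Path of a GMT catalogue; `NULL` with `simulate = TRUE`
#'   generates one.
#' @param alpha Adjusted-p significance threshold for DE.
#' @param volcano_fc Named list of `c(up, down)` fold-change highlight
#'   thresholds per timepoint (defaults: 2.8/0.35 at 2w, 1.5/0.5 at 4w).
#' @param min_degree Hub degree criterion.
#' @param universe Concordance universe size (10000; 15000 is the
#'   conventional alternative).
#' @param n_sims Monte-Carlo replicates for the occurrence null.
#' @param m Occurrence level of interest ("shared by at least m studies").
#' @param de_timepoint Timepoint whose gene list feeds the cross-study,
#'   network and enrichment stages.
#' @param stages Character vector of stages to run, in order, among
#'   `"simulate"`, `"de"`, `"overlap"`, `"occurrence"`, `"network"`,
#'   `"enrich"`.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "oaconcord_out",
                            simulate = TRUE,
                            sim = list(),
                            study_sim = list(),
                            experiment_dir = NULL,
                            gene_list_paths = NULL,
                            edge_table_path = NULL,
                            gmt_path = NULL,
                            alpha = 0.05,
                            volcano_fc = list(`2w` = c(2.8, 0.35),
                                              `4w` = c(1.5, 0.5)),
                            min_degree = 10,
                            universe = 10000,
                            n_sims = 10000,
                            m = 5,
                            de_timepoint = "2w",
                            stages = c("simulate", "de", "overlap",
                                       "occurrence", "network", "enrich"),
                            seed = 1) {
  cfg <- list(
    out_dir = out_dir, simulate = isTRUE(simulate),
    sim = sim, study_sim = study_sim,
    experiment_dir = experiment_dir,
    gene_list_paths = gene_list_paths,
    edge_table_path = edge_table_path, gmt_path = gmt_path,
    alpha = alpha, volcano_fc = volcano_fc,
    min_degree = check_count(min_degree, "min_degree"),
    universe = check_count(universe, "universe", min = 1),
    n_sims = check_count(n_sims, "n_sims", min = 1),
    m = check_count(m, "m", min = 1),
    de_timepoint = de_timepoint,
    stages = match.arg(stages, several.ok = TRUE,
                       choices = c("simulate", "de", "overlap", "occurrence",
                                   "network", "enrich")),
    seed = check_count(seed, "seed")
  )
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_seed <- function(cfg, stage) {
  # deterministic per-stage substream, kept within 32-bit integer range
  offsets <- c(simulate = 101L, study = 211L, de = 307L, occurrence = 401L,
               network = 503L, enrich = 601L)
  (cfg$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

pipeline_abort <- function(stage, msg) {
  abort(sprintf("[stage %s] %s", stage, msg),
        class = "oaconcord_pipeline_error", stage = stage)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the paired
#' experiment and study lists, paired DE per timepoint, gene-list export,
#' pairwise overlap and Venn comparison against the study collection,
#' occurrence histogram with its Monte-Carlo null, interaction network and
#' hubs, and pathway over-representation. All outputs are TSV files under
#' `cfg$out_dir`, each tagged with its producing stage and the config
#' hash; a `manifest.json` records the package version, seed, config hash
#' and per-stage row counts. Identical configurations give identical
#' outputs byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each stage plus
#'   the manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analytic configuration: where outputs land does not change them
  hash <- rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  manifest <- list(
    package = "oaconcord",
    version = as.character(utils::packageVersion("oaconcord")),
    seed = cfg$seed,
    config_hash = hash,
    stages = list()
  )
  res <- list(config = cfg)
  note <- function(stage, rows) manifest$stages[[stage]] <<- list(rows = rows)

  # --- inputs -----------------------------------------------------------
  if ("simulate" %in% cfg$stages && cfg$simulate) {
    sim_args <- modifyList(list(seed = stage_seed(cfg, "simulate")), cfg$sim)
    res$experiment <- simulate_experiment(do.call(sim_config, sim_args))
    study_args <- modifyList(list(seed = stage_seed(cfg, "study")), cfg$study_sim)
    res$study_sets <- simulate_study_collection(do.call(study_sim_config, study_args))
    write_experiment(res$experiment, file.path(cfg$out_dir, "experiment"))
    write_stage_tsv(res$study_sets, file.path(cfg$out_dir, "study_gene_lists.tsv"),
                    "simulate", hash)
    note("simulate", nrow(res$study_sets))
  } else {
    if (is.null(cfg$experiment_dir)) {
      pipeline_abort("simulate", "no experiment directory configured and simulation disabled")
    }
    res$experiment <- read_experiment(cfg$experiment_dir)
    if (!is.null(cfg$gene_list_paths)) {
      res$study_sets <- harmonize_symbols(read_gene_lists(cfg$gene_list_paths))
    }
  }

  # --- differential expression -----------------------------------------
  if ("de" %in% cfg$stages) {
    tps <- unique(res$experiment$samples$timepoint)
    res$de <- lapply(setNames(tps, tps), function(tp) {
      de <- paired_de(res$experiment, tp, alpha = cfg$alpha)
      fc <- cfg$volcano_fc[[tp]]
      genes <- if (!is.null(fc)) volcano_classify(de, fc[1], fc[2]) else de$genes
      write_stage_tsv(genes, file.path(cfg$out_dir, sprintf("de_%s.tsv", tp)),
                      "de", hash)
      sig <- genes[genes$significant, , drop = FALSE]
      write_stage_tsv(
        tibble(symbol = sig$gene,
               direction = ifelse(sig$log2fc > 0, "up", "down"),
               species = "synthetic"),
        file.path(cfg$out_dir, sprintf("gene_list_%s.tsv", tp)), "de", hash)
      de
    })
    note("de", sum(vapply(res$de, function(d) nrow(d$genes), integer(1))))
  }

  de_list <- function(stage) {
    if (is.null(res$de)) pipeline_abort(stage, "the de stage has not run")
    de <- res$de[[cfg$de_timepoint]]
    if (is.null(de)) pipeline_abort(stage, sprintf("no DE result at timepoint '%s'",
                                                   cfg$de_timepoint))
    de
  }

  # --- cross-study overlap ---------------------------------------------
  if ("overlap" %in% cfg$stages) {
    if (is.null(res$study_sets)) pipeline_abort("overlap", "no study gene lists available")
    own <- tibble(study_id = "this_study",
                  symbol = significant_genes(de_list("overlap")))
    sets <- harmonize_symbols(dplyr::bind_rows(own, res$study_sets[, c("study_id", "symbol")]))
    res$overlaps <- gene_set_overlaps(sets, universe = cfg$universe)
    write_stage_tsv(res$overlaps, file.path(cfg$out_dir, "pairwise_overlaps.tsv"),
                    "overlap", hash)
    first3 <- unique(sets$study_id)[1:min(3, length(unique(sets$study_id)))]
    if (length(first3) >= 2) {
      vr <- venn_regions(sets[sets$study_id %in% first3, ])
      res$venn <- vr
      write_stage_tsv(dplyr::mutate(vr, members = vapply(.data$members, paste,
                                                         character(1), collapse = ",")),
                      file.path(cfg$out_dir, "venn_regions.tsv"), "overlap", hash)
    }
    note("overlap", nrow(res$overlaps))
  }

  # --- occurrence histogram and null -----------------------------------
  if ("occurrence" %in% cfg$stages) {
    if (is.null(res$study_sets)) pipeline_abort("occurrence", "no study gene lists available")
    sets <- res$study_sets[, c("study_id", "symbol")]
    obs <- occurrence_histogram(sets, universe = cfg$universe)
    sizes <- vapply(gene_set_list(sets), length, integer(1))
    null <- occurrence_null(sizes, universe = cfg$universe,
                            n_sims = cfg$n_sims,
                            seed = stage_seed(cfg, "occurrence"))
    res$occurrence <- list(observed = obs, null = null)
    joined <- dplyr::full_join(as_tibble(obs), as_tibble(null), by = "j")
    write_stage_tsv(joined, file.path(cfg$out_dir, "occurrence.tsv"),
                    "occurrence", hash)
    write_stage_tsv(tibble(symbol = occurrence_members(obs, cfg$m)),
                    file.path(cfg$out_dir,
                              sprintf("genes_in_ge%d_studies.tsv", cfg$m)),
                    "occurrence", hash)
    note("occurrence", nrow(joined))
  }

  # --- interaction network ---------------------------------------------
  if ("network" %in% cfg$stages) {
    de <- de_list("network")
    edges <- if (!is.null(cfg$edge_table_path)) {
      if (!file.exists(cfg$edge_table_path)) {
        pipeline_abort("network", sprintf("edge table '%s' not found", cfg$edge_table_path))
      }
      read_edge_table(cfg$edge_table_path)
    } else if (cfg$simulate) {
      simulate_edge_table(significant_genes(de),
                          seed = stage_seed(cfg, "network"))
    } else {
      pipeline_abort("network", "no edge table path configured")
    }
    res$network <- build_network(de, edges)
    res$hubs <- find_hubs(res$network, min_degree = cfg$min_degree)
    write_stage_tsv(res$network$nodes, file.path(cfg$out_dir, "network_nodes.tsv"),
                    "network", hash)
    write_stage_tsv(res$network$edges, file.path(cfg$out_dir, "network_edges.tsv"),
                    "network", hash)
    write_stage_tsv(res$hubs, file.path(cfg$out_dir, "hubs.tsv"), "network", hash)
    write_graphml(res$network, file.path(cfg$out_dir, "network.graphml"))
    note("network", nrow(res$network$nodes))
  }

  # --- enrichment -------------------------------------------------------
  if ("enrich" %in% cfg$stages) {
    de <- de_list("enrich")
    background <- toupper(de$genes$gene[de$genes$detected])
    sig <- significant_genes(de)
    catalog <- if (!is.null(cfg$gmt_path)) {
      if (!file.exists(cfg$gmt_path)) {
        pipeline_abort("enrich", sprintf("GMT catalogue '%s' not found", cfg$gmt_path))
      }
      read_gmt(cfg$gmt_path)
    } else if (cfg$simulate) {
      simulate_gmt(background, enrich_with = sig,
                   seed = stage_seed(cfg, "enrich"))
    } else {
      pipeline_abort("enrich", "no GMT catalogue path configured")
    }
    res$enrichment <- enrich(sig, catalog, background)
    write_stage_tsv(res$enrichment, file.path(cfg$out_dir, "enrichment.tsv"),
                    "enrich", hash)
    note("enrich", nrow(res$enrichment))
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
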