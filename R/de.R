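#' Detection filter for probes
#'
#' A probe counts as confidently detected when its detection p-value falls
#' below `alpha_det` in at least `min_fraction` of the samples of at least
#' one limb group (operated or control) — a gene switched off in control
#' cartilage but induced by surgery should not be filtered away.
#'
#' @param exp An `expr_experiment` (see [simulate_experiment()] /
#'   [read_experiment()]).
#' @param alpha_det Detection p-value threshold.
#' @param min_fraction Minimum fraction of samples within a limb group that
#'   must pass; must be in (0, 1].
#' @return Named logical vector over probes.
#' @export
detect_probes <- function(exp, alpha_det = 0.05, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1].")
  }
  if (is.null(exp$detection)) {
    warn("No detection p-values present; all probes treated as detected.")
    return(setNames(rep(TRUE, nrow(exp$matrix)), rownames(exp$matrix)))
  }
  det <- exp$detection
  pass_group <- function(limb) {
    cols <- exp$samples$sample_id[exp$samples$limb == limb]
    rowMeans(det[, cols, drop = FALSE] < alpha_det) >= min_fraction
  }
  out <- pass_group("ipsi") | pass_group("contra")
  setNames(out, rownames(det))
}

#' Paired differential expression at one timepoint
#'
#' Tests every detected probe for a difference between operated
#' (ipsilateral) and control (contralateral) limbs using the within-animal
#' paired differences on the log2 scale. The reference method is the
#' two-sided paired t-test; a moderated-t variant (empirical-Bayes shrunk
#' variances via limma) is available with `method = "moderated"`. Raw
#' p-values are Benjamini-Hochberg adjusted across all tested probes of
#' the timepoint, and probe results are collapsed to genes with
#' [collapse_probes()].
#'
#' Probes whose paired differences are constant get p = 1 when the common
#' difference is zero (no evidence of change, no variance to judge it by);
#' a constant nonzero difference is an infinite t and p = 0.
#'
#' @param exp An `expr_experiment`.
#' @param timepoint Timepoint label to analyse.
#' @param alpha Adjusted-p significance threshold.
#' @param alpha_det,min_fraction Passed to [detect_probes()].
#' @param method `"t"` (paired t-test) or `"moderated"` (limma eBayes).
#' @return An object of class `paired_de` with elements `genes` (tibble:
#'   `gene`, `log2fc`, `fold_change`, `p_raw`, `p_adj`, `detected`,
#'   `significant`, `n_probes`), `probes` (per-probe tibble), `timepoint`,
#'   `n_pairs`, `alpha`, `method`. Use [tidy()]/[glance()] or
#'   [significant_genes()].
#' @examples
#' exp <- simulate_experiment(sim_config(n_genes = 100, de_counts = c(10, 2, 1),
#'                                       seed = 3))
#' de <- paired_de(exp, "2w")
#' glance(de)
#' @export
paired_de <- function(exp, timepoint, alpha = 0.05,
                      alpha_det = 0.05, min_fraction = 0.5,
                      method = c("t", "moderated")) {
  method <- match.arg(method)
  smp <- exp$samples[exp$samples$timepoint == timepoint, ]
  if (nrow(smp) == 0) {
    abort(sprintf("Timepoint '%s' not present in the experiment.", timepoint))
  }
  wide <- tidyr::pivot_wider(smp, id_cols = "animal_id",
                             names_from = "limb", values_from = "sample_id")
  if (!all(c("ipsi", "contra") %in% names(wide))) {
    abort("Each animal needs one ipsilateral and one contralateral sample.")
  }
  wide <- wide[!is.na(wide$ipsi) & !is.na(wide$contra), ]
  n_pairs <- nrow(wide)
  if (n_pairs < 3) {
    abort(sprintf("Insufficient replication: %d complete pair(s) at '%s' (need >= 3).",
                  n_pairs, timepoint))
  }

  detected <- detect_probes(exp, alpha_det = alpha_det, min_fraction = min_fraction)
  diffs <- exp$matrix[, wide$ipsi, drop = FALSE] -
    exp$matrix[, wide$contra, drop = FALSE]
  tested <- diffs[detected[rownames(diffs)], , drop = FALSE]

  m <- rowMeans(tested)
  s <- row_sds(tested)
  if (method == "moderated") {
    if (!requireNamespace("limma", quietly = TRUE)) {
      abort("`method = \"moderated\"` requires the limma package.")
    }
    fit <- limma::eBayes(limma::lmFit(tested, design = matrix(1, n_pairs, 1)))
    p_raw <- as.numeric(fit$p.value[, 1])
  } else {
    tval <- m / (s / sqrt(n_pairs))
    p_raw <- 2 * pt(-abs(tval), df = n_pairs - 1)
    zerovar <- s == 0
    if (any(zerovar)) {
      # constant differences: p = 1 if the constant is 0, else t = +/-Inf, p = 0
      p_raw[zerovar] <- ifelse(m[zerovar] == 0, 1, 0)
      if (any(zerovar & m == 0)) {
        inform(sprintf("%d probe(s) with constant zero differences set to p = 1.",
                       sum(zerovar & m == 0)))
      }
    }
  }
  p_adj <- p.adjust(p_raw, method = "BH")

  probes <- tibble(
    probe_id = rownames(tested),
    log2fc = unname(m),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    detected = TRUE,
    significant = unname(p_adj < alpha)
  )
  undet <- rownames(diffs)[!detected[rownames(diffs)]]
  if (length(undet)) {
    probes <- dplyr::bind_rows(probes, tibble(
      probe_id = undet, log2fc = rowMeans(diffs[undet, , drop = FALSE]),
      p_raw = NA_real_, p_adj = NA_real_,
      detected = FALSE, significant = FALSE
    ))
  }
  genes <- collapse_probes(probes, exp$probe_map)

  out <- list(genes = genes, probes = probes, timepoint = timepoint,
              n_pairs = n_pairs, alpha = alpha, method = method)
  class(out) <- "paired_de"
  out
}

#' Collapse probe-level results to gene level
#'
#' A gene is significant if at least one of its probes is. Its reported
#' statistics come from the representative probe with the smallest adjusted
#' p, ties broken by larger absolute log2 fold change, then lexicographic
#' probe id — a deterministic, input-order-independent rule.
#'
#' @param probe_results Tibble with columns `probe_id`, `log2fc`, `p_raw`,
#'   `p_adj`, `detected`, `significant` (as produced inside [paired_de()]).
#' @param probe_map Tibble `probe_id`, `gene_symbol` mapping every probe.
#' @return Gene-level tibble: `gene`, `log2fc`, `fold_change`, `p_raw`,
#'   `p_adj`, `detected`, `significant`, `n_probes`.
#' @export
collapse_probes <- function(probe_results, probe_map) {
  df <- dplyr::inner_join(probe_results, probe_map, by = "probe_id")
  if (nrow(df) < nrow(probe_results)) {
    abort(sprintf("%d probe(s) missing from `probe_map`.",
                  nrow(probe_results) - nrow(df)))
  }
  df <- dplyr::arrange(df, .data$p_adj, dplyr::desc(abs(.data$log2fc)),
                       .data$probe_id)
  rep_probe <- dplyr::slice_head(dplyr::group_by(df, .data$gene_symbol), n = 1)
  counts <- dplyr::summarise(
    dplyr::group_by(df, .data$gene_symbol),
    n_probes = dplyr::n(),
    any_sig = any(.data$significant),
    any_det = any(.data$detected),
    .groups = "drop"
  )
  out <- dplyr::inner_join(
    dplyr::select(dplyr::ungroup(rep_probe), gene = "gene_symbol",
                  "log2fc", "p_raw", "p_adj"),
    counts, by = c(gene = "gene_symbol")
  )
  out <- dplyr::mutate(
    out,
    fold_change = 2^.data$log2fc,
    significant = .data$any_sig,
    detected = .data$any_det
  )
  out <- dplyr::select(out, "gene", "log2fc", "fold_change", "p_raw",
                       "p_adj", "detected", "significant", "n_probes")
  dplyr::arrange(out, .data$gene)
}

#' Significant genes from a paired DE result
#'
#' @param de A `paired_de` object or its gene-level tibble.
#' @return Character vector of significant gene symbols.
#' @export
significant_genes <- function(de) {
  genes <- if (inherits(de, "paired_de")) de$genes else as_tibble(de)
  sort(genes$gene[genes$significant])
}

#' Volcano-style highlighting of fold-change extremes
#'
#' Partitions significant genes into those highlighted for strong
#' up-regulation (fold change strictly greater than `up_fc`), strong
#' down-regulation (fold change strictly less than `down_fc`), and the
#' rest. Non-significant genes are never highlighted. The defaults are the
#' 2-week labelling thresholds (2.8 and 0.35); the 4-week convention is
#' 1.5 / 0.5.
#'
#' @param de A `paired_de` object or gene-level tibble.
#' @param up_fc,down_fc Fold-change thresholds; need `0 < down_fc < 1 < up_fc`.
#' @return The gene-level tibble with an added `label` factor:
#'   `"highlighted-up"`, `"highlighted-down"`, `"other"`.
#' @export
volcano_classify <- function(de, up_fc = 2.8, down_fc = 0.35) {
  if (!(down_fc > 0 && down_fc < 1 && up_fc > 1)) {
    abort("Thresholds must satisfy 0 < down_fc < 1 < up_fc.")
  }
  genes <- if (inherits(de, "paired_de")) de$genes else as_tibble(de)
  dplyr::mutate(genes, label = factor(
    dplyr::case_when(
      .data$significant & .data$fold_change > up_fc ~ "highlighted-up",
      .data$significant & .data$fold_change < down_fc ~ "highlighted-down",
      TRUE ~ "other"
    ),
    levels = c("highlighted-up", "highlighted-down", "other")
  ))
}

#' @export
print.paired_de <- function(x, ...) {
  cat(sprintf(
    "Paired DE at %s (%s, %d pairs): %d/%d detected probes tested, %d significant genes (adj. p < %g)\n",
    x$timepoint, if (x$method == "t") "paired t-test" else "moderated t",
    x$n_pairs, sum(x$probes$detected), nrow(x$probes),
    sum(x$genes$significant), x$alpha
  ))
  invisible(x)
}

#' @rdname paired_de
#' @param x A `paired_de` object.
#' @param ... Unused.
#' @method tidy paired_de
#' @export
tidy.paired_de <- function(x, ...) x$genes

#' @rdname paired_de
#' @method glance paired_de
#' @export
glance.paired_de <- function(x, ...) {
  tibble(
    timepoint = x$timepoint,
    n_pairs = x$n_pairs,
    n_probes = nrow(x$probes),
    n_probes_tested = sum(x$probes$detected),
    n_genes = nrow(x$genes),
    n_significant = sum(x$genes$significant),
    n_significant_probes = sum(x$probes$significant, na.rm = TRUE),
    alpha = x$alpha,
    method = x$method
  )
}
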