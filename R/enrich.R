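#' Pathway over-representation analysis
#'
#' Tests whether a differential-expression gene list is over-represented in
#' each pathway of a catalogue, using the upper-tail hypergeometric
#' probability \eqn{P(X \ge k)} with the same exact implementation as
#' [hypergeom_overlap()]. The background is the set of genes the platform
#' could have called (typically the detected genes), not the whole genome;
#' pathways are intersected with the background before testing, and DE
#' genes outside the background are dropped with a logged count.
#'
#' @param de_genes Character vector of DE gene symbols, or a tibble with a
#'   `symbol` (or `gene`) column.
#' @param catalog Named list of pathway member vectors (see [read_gmt()]).
#' @param background Character vector of background gene symbols.
#' @param min_size Pathways with fewer in-background members are skipped.
#' @return A tibble of class `enrichment_result`, one row per tested
#'   pathway: `pathway_id`, `k` (hits), `K` (pathway size in background),
#'   `n` (DE genes in background), `N` (background size), `p_upper`,
#'   `p_adj` (BH); sorted by `p_upper`, ties by `pathway_id`.
#' @examples
#' bg <- sprintf("G%02d", 1:20)
#' enrich(bg[1:4], list(pw = bg[1:5]), bg)
#' @export
enrich <- function(de_genes, catalog, background, min_size = 1) {
  if (is.data.frame(de_genes)) {
    col <- intersect(c("symbol", "gene"), names(de_genes))[1]
    if (is.na(col)) abort("`de_genes` data frame needs a `symbol` or `gene` column.")
    de_genes <- de_genes[[col]]
  }
  background <- unique(toupper(background))
  if (length(background) == 0) abort("`background` must be nonempty.")
  de_genes <- unique(toupper(de_genes))
  outside <- setdiff(de_genes, background)
  if (length(outside)) {
    inform(sprintf("Dropped %d DE gene(s) not in the background.", length(outside)))
    de_genes <- intersect(de_genes, background)
  }
  N <- length(background)
  n <- length(de_genes)

  rows <- purrr::imap_dfr(catalog, function(members, id) {
    members <- intersect(unique(toupper(members)), background)
    K <- length(members)
    if (K < min_size) return(NULL)
    k <- length(intersect(members, de_genes))
    tibble(pathway_id = id, k = k, K = K, n = n, N = N,
           p_upper = hypergeom_overlap(k, K, n, N)$p_upper)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(pathway_id = character(), k = integer(), K = integer(),
                   n = integer(), N = integer(), p_upper = double(),
                   p_adj = double())
  } else {
    rows$p_adj <- p.adjust(rows$p_upper, method = "BH")
    rows <- dplyr::arrange(rows, .data$p_upper, .data$pathway_id)
  }
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' Compare significantly enriched pathway sets across studies
#'
#' Venn-region comparison of the pathway labels each study calls enriched
#' (conventionally at raw `p_upper` < 0.05). Delegates to [venn_regions()]
#' on the pathway identifiers.
#'
#' @param pathway_sets 2-4 label sets: named list of character vectors, or
#'   a tibble with `study_id` and `pathway_id` (or `symbol`) columns.
#' @return Region tibble as from [venn_regions()].
#' @export
compare_pathway_sets <- function(pathway_sets) {
  if (is.data.frame(pathway_sets) && "pathway_id" %in% names(pathway_sets) &&
      !"symbol" %in% names(pathway_sets)) {
    pathway_sets <- dplyr::rename(pathway_sets, symbol = "pathway_id")
  }
  venn_regions(pathway_sets)
}

#' @rdname enrich
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_sig_raw = sum(x$p_upper < 0.05),
    n_sig_adj = sum(x$p_adj < 0.05),
    top_pathway = if (nrow(x)) x$pathway_id[1] else NA_character_
  )
}
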