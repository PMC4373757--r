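# TSV-based interchange. All tables are tab-separated with a header row;
# pipeline outputs carry a single "# stage=<name> config=<hash>" comment
# line which readers skip.

write_stage_tsv <- function(df, path, stage = NULL, config_hash = NULL) {
  if (!is.null(stage)) {
    writeLines(sprintf("# stage=%s config=%s", stage, config_hash %||% "none"), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read and write study gene lists
#'
#' Gene lists are TSVs with a header and at least a `symbol` column;
#' `direction` and `species` columns are optional and carried through.
#'
#' @param path File path.
#' @param study_id Study label; defaults to the file name without extension.
#' @return `read_gene_list()`: a tibble with `study_id`, `symbol` and any
#'   extra columns. `write_gene_list()`: `path`, invisibly.
#' @export
read_gene_list <- function(path, study_id = NULL) {
  df <- read_tsv_quiet(path)
  if (!"symbol" %in% names(df)) {
    abort(sprintf("'%s' has no `symbol` column.", path))
  }
  df$study_id <- study_id %||% sub("\\.[^.]*$", "", basename(path))
  dplyr::relocate(as_tibble(df), "study_id")
}

#' @rdname read_gene_list
#' @param df Gene-list tibble (needs `symbol`; `study_id` is not written).
#' @export
write_gene_list <- function(df, path) {
  keep <- intersect(c("symbol", "direction", "species"), names(df))
  readr::write_tsv(df[, keep, drop = FALSE], path)
  invisible(path)
}

#' Read several gene-list files into one collection
#'
#' @param paths Character vector of gene-list TSV paths.
#' @return Combined tibble with `study_id` taken from each file name.
#' @export
read_gene_lists <- function(paths) {
  purrr::map_dfr(paths, read_gene_list)
}

#' Read an ortholog map
#'
#' @param path TSV with columns `from`, `to` (or two unnamed columns).
#' @return Tibble with columns `from`, `to`.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_quiet(path)
  if (!all(c("from", "to") %in% names(df))) names(df)[1:2] <- c("from", "to")
  as_tibble(df[, c("from", "to")])
}

#' Read a STRING-style interaction edge table
#'
#' @param path TSV with columns `protein1`, `protein2`, `combined_score`
#'   (first three columns used if names differ).
#' @return Edge tibble.
#' @export
read_edge_table <- function(path) {
  df <- read_tsv_quiet(path)
  if (ncol(df) < 3) abort(sprintf("'%s' needs at least 3 columns.", path))
  if (!all(c("protein1", "protein2", "combined_score") %in% names(df))) {
    names(df)[1:3] <- c("protein1", "protein2", "combined_score")
  }
  as_tibble(df)
}

#' Read and write GMT pathway catalogues
#'
#' Standard GMT: one pathway per line, `id<TAB>description<TAB>gene...`.
#' Reading delegates to the fgsea parser; member symbols are upper-cased
#' on load so they join cleanly with harmonized gene lists.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character member vectors.
#' @export
read_gmt <- function(path) {
  paths <- fgsea::gmtPathways(path)
  lapply(paths, function(m) unique(toupper(m)))
}

#' @rdname read_gmt
#' @param catalog Named list of member vectors.
#' @param descriptions Optional character vector of descriptions (recycled
#'   `"na"` otherwise).
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(catalog))
  lines <- vapply(seq_along(catalog), function(i) {
    paste(c(names(catalog)[i], desc[i], catalog[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read a paired expression experiment as TSV files
#'
#' Serialises the experiment into plain-text TSVs inside `dir`:
#' `expression.tsv` (first column `probe_id`, one column per sample),
#' `samples.tsv` (`sample_id`, `animal_id`, `limb`, `timepoint`),
#' `probe_map.tsv` (`probe_id`, `gene_symbol`), optional `detection.tsv`
#' and `truth.tsv`.
#'
#' @param exp An `expr_experiment`.
#' @param dir Directory (created if needed).
#' @return `write_experiment()`: `dir` invisibly; `read_experiment()`: an
#'   `expr_experiment`.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- as_tibble(exp$matrix, rownames = "probe_id")
  readr::write_tsv(mat, file.path(dir, "expression.tsv"))
  readr::write_tsv(exp$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(exp$probe_map, file.path(dir, "probe_map.tsv"))
  if (!is.null(exp$detection)) {
    det <- as_tibble(exp$detection, rownames = "probe_id")
    readr::write_tsv(det, file.path(dir, "detection.tsv"))
  }
  if (!is.null(exp$truth)) {
    readr::write_tsv(exp$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  as_mat <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  mat <- as_mat(read_tsv_quiet(file.path(dir, "expression.tsv")))
  samples <- read_tsv_quiet(file.path(dir, "samples.tsv"))
  probe_map <- read_tsv_quiet(file.path(dir, "probe_map.tsv"))
  if (!all(rownames(mat) %in% probe_map$probe_id)) {
    abort("Every probe in the matrix must appear in the probe map.")
  }
  det_path <- file.path(dir, "detection.tsv")
  detection <- if (file.exists(det_path)) as_mat(read_tsv_quiet(det_path)) else NULL
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv_quiet(truth_path) else NULL
  out <- list(matrix = mat, samples = samples, probe_map = probe_map,
              detection = detection, truth = truth, config = NULL)
  class(out) <- "expr_experiment"
  out
}
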