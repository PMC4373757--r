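# Internal helpers shared across modules.

# Coerce gene-list input to the canonical long tibble (study_id, symbol).
# Accepts a data frame with at least study_id/symbol columns, or a named
# list of character vectors. Extra columns (direction, species) pass through.
as_gene_sets <- function(x, arg = "sets") {
  if (is.data.frame(x)) {
    if (!all(c("study_id", "symbol") %in% names(x))) {
      abort(sprintf("`%s` must have columns `study_id` and `symbol`.", arg))
    }
    out <- as_tibble(x)
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort(sprintf("`%s` must be a named list of character vectors.", arg))
    }
    out <- tibble(
      study_id = rep(names(x), lengths(x)),
      symbol = as.character(unlist(x, use.names = FALSE))
    )
  } else {
    abort(sprintf("`%s` must be a data frame or a named list.", arg))
  }
  if (anyNA(out$symbol)) abort(sprintf("`%s` contains missing symbols.", arg))
  out
}

# Split canonical tibble into a named list of unique symbol vectors,
# preserving first-appearance order of studies.
gene_set_list <- function(df) {
  ids <- unique(df$study_id)
  lapply(setNames(ids, ids), function(s) unique(df$symbol[df$study_id == s]))
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}


check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
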