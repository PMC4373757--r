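#' Harmonize gene symbols across studies
#'
#' Cross-study comparison needs a single symbol space even though the
#' contributing studies report mouse, rat or human genes. Symbols are
#' upper-cased (the usual human-style convention that makes rodent symbols
#' such as `Fmod` comparable with `FMOD`), optionally translated through a
#' user-supplied ortholog map, and de-duplicated within each study.
#'
#' No ortholog inference is performed: if two symbols should be merged
#' across species, the map must say so.
#'
#' @param sets Gene lists: a data frame with columns `study_id` and `symbol`
#'   (extra columns such as `direction`, `species` are carried along), or a
#'   named list of character vectors.
#' @param ortholog_map Optional two-column data frame (`from`, `to`).
#'   Matching is case-insensitive on `from`; unmapped symbols are kept as
#'   their upper-cased originals.
#' @return A tibble with the same columns as the input, one row per
#'   (study, harmonized symbol). The number of symbols collapsed by
#'   de-duplication is attached as attribute `"n_collapsed"` and reported
#'   with a message when nonzero.
#' @examples
#' harmonize_symbols(list(A = c("Fmod", "Tnn", "FMOD")))
#' @export
harmonize_symbols <- function(sets, ortholog_map = NULL) {
  df <- as_gene_sets(sets)
  df$symbol <- toupper(df$symbol)
  if (!is.null(ortholog_map)) {
    if (!is.data.frame(ortholog_map) || ncol(ortholog_map) < 2L) {
      abort("`ortholog_map` must be a data frame with columns `from` and `to`.")
    }
    map <- as_tibble(ortholog_map)
    if (!all(c("from", "to") %in% names(map))) {
      names(map)[1:2] <- c("from", "to")
    }
    bad <- is.na(map$from) | is.na(map$to) | map$from == "" | map$to == ""
    if (any(bad)) {
      warn(sprintf("Skipping %d malformed ortholog map row(s).", sum(bad)))
      map <- map[!bad, ]
    }
    idx <- match(df$symbol, toupper(map$from))
    n_unmapped <- sum(is.na(idx))
    df$symbol <- ifelse(is.na(idx), df$symbol, toupper(map$to[idx]))
    if (n_unmapped > 0 && n_unmapped < nrow(df)) {
      inform(sprintf("%d symbol(s) had no ortholog mapping; kept as upper-cased originals.", n_unmapped))
    }
  }
  before <- nrow(df)
  df <- dplyr::distinct(df, .data$study_id, .data$symbol, .keep_all = TRUE)
  n_collapsed <- before - nrow(df)
  if (n_collapsed > 0) {
    inform(sprintf("Collapsed %d duplicate symbol(s) within studies.", n_collapsed))
  }
  attr(df, "n_collapsed") <- n_collapsed
  df
}

#' Exact hypergeometric overlap between two gene sets
#'
#' Probability mass and upper-tail probability for the overlap of two sets
#' of sizes `n1` and `n2` drawn without replacement from a universe of `U`
#' genes. The point mass is
#' \deqn{P(X = k) = \binom{n_1}{k}\binom{U - n_1}{n_2 - k} / \binom{U}{n_2},}
#' computed in log space via log-gamma so that universes of tens of
#' thousands of genes do not overflow. The upper tail \eqn{P(X \ge k)} is
#' the conventional enrichment p-value; the point mass is what concordance
#' analyses of observed overlaps typically report.
#'
#' @param k Observed overlap count.
#' @param n1,n2 Sizes of the two sets.
#' @param U Universe (background pool) size. The universe is an explicit
#'   modelling choice; there is no safe default shared across platforms.
#' @return An object of class `overlap_result`: a list with elements `k`,
#'   `n1`, `n2`, `U`, `pmf` (\eqn{P(X=k)}) and `p_upper` (\eqn{P(X\ge k)}).
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' hypergeom_overlap(k = 1, n1 = 3, n2 = 2, U = 6)  # pmf 0.6
#' @export
hypergeom_overlap <- function(k, n1, n2, U) {
  k <- check_count(k, "k"); n1 <- check_count(n1, "n1")
  n2 <- check_count(n2, "n2"); U <- check_count(U, "U", min = 1)
  if (n1 > U || n2 > U) abort("`n1` and `n2` must not exceed `U`.")
  lo <- max(0L, n1 + n2 - U)
  hi <- min(n1, n2)
  if (k < lo || k > hi) {
    abort(sprintf("`k` = %d is outside the overlap support [%d, %d].", k, lo, hi))
  }
  j <- lo:hi
  pmf <- overlap_support_pmf(n1, n2, U)
  res <- list(
    k = k, n1 = n1, n2 = n2, U = U,
    pmf = pmf[j == k],
    p_upper = min(1, sum(pmf[j >= k]))
  )
  class(res) <- "overlap_result"
  res
}

# Normalized pmf over the whole support, log-space binomial coefficients.
# Explicit renormalisation removes the ~1e-12 drift that log-gamma rounding
# accumulates across supports of thousands of terms.
overlap_support_pmf <- function(n1, n2, U) {
  j <- max(0L, n1 + n2 - U):min(n1, n2)
  lp <- lchoose(n1, j) + lchoose(U - n1, n2 - j) - lchoose(U, n2)
  p <- exp(lp - max(lp))
  unname(p / sum(p))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of n1 = %d, n2 = %d in U = %d\n  P(X = k) = %.4g   P(X >= k) = %.4g\n",
    x$k, x$n1, x$n2, x$U, x$pmf, x$p_upper
  ))
  invisible(x)
}

#' Full hypergeometric overlap distribution over its support
#'
#' The probability mass at every attainable overlap count for two sets of
#' sizes `n1` and `n2` in a universe of `U` genes, computed once in log
#' space. Useful for plotting the overlap distribution or verifying
#' normalisation.
#'
#' @inheritParams hypergeom_overlap
#' @return A tibble with columns `k` and `pmf`, covering the support
#'   `max(0, n1 + n2 - U)` to `min(n1, n2)`.
#' @export
overlap_pmf_table <- function(n1, n2, U) {
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  U <- check_count(U, "U", min = 1)
  if (n1 > U || n2 > U) abort("`n1` and `n2` must not exceed `U`.")
  tibble(k = max(0L, n1 + n2 - U):min(n1, n2),
         pmf = overlap_support_pmf(n1, n2, U))
}

#' Pairwise overlap statistics for a collection of gene lists
#'
#' Computes the observed overlap, its hypergeometric point mass and the
#' upper-tail enrichment probability for every pair of studies.
#'
#' @param sets Gene lists (see [harmonize_symbols()] for accepted forms);
#'   symbols are assumed already harmonized.
#' @param universe Universe size `U` for the hypergeometric model.
#' @return A tibble with one row per study pair: `study1`, `study2`, `k`,
#'   `n1`, `n2`, `U`, `pmf`, `p_upper`.
#' @export
gene_set_overlaps <- function(sets, universe) {
  sl <- gene_set_list(as_gene_sets(sets))
  if (length(sl) < 2L) abort("Need at least two studies.")
  pairs <- utils::combn(names(sl), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- sl[[p[1]]]; b <- sl[[p[2]]]
    res <- hypergeom_overlap(length(intersect(a, b)), length(a), length(b), universe)
    tibble(study1 = p[1], study2 = p[2], k = res$k, n1 = res$n1, n2 = res$n2,
           U = res$U, pmf = res$pmf, p_upper = res$p_upper)
  })
}

#' Venn region cardinalities for 2-4 gene sets
#'
#' Partitions the union of the sets into the \eqn{2^S - 1} exclusive
#' membership regions and reports each region's size and members.
#'
#' @inheritParams gene_set_overlaps
#' @return A tibble with one row per region: `region` (member study ids
#'   joined by `"&"`), `n_sets`, `n`, and a `members` list-column. Region
#'   counts always sum to the size of the union.
#' @examples
#' venn_regions(list(A = c("x", "y"), B = c("y", "z")))
#' @export
venn_regions <- function(sets) {
  sl <- gene_set_list(as_gene_sets(sets))
  S <- length(sl)
  if (S < 2L || S > 4L) {
    abort(sprintf("venn_regions supports 2 to 4 sets, got %d.", S))
  }
  universe <- unique(unlist(sl, use.names = FALSE))
  member <- vapply(sl, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sl)))
  pattern <- apply(member, 1, function(r) paste(names(sl)[r], collapse = "&"))
  masks <- unlist(lapply(seq_len(S), function(m) {
    utils::combn(names(sl), m, FUN = paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = masks))
  members <- lapply(masks, function(ms) universe[pattern == ms])
  tibble(
    region = masks,
    n_sets = lengths(strsplit(masks, "&", fixed = TRUE)),
    n = as.integer(counts),
    members = members
  )
}

#' Multi-study occurrence histogram
#'
#' Counts, over the union of all study lists, how many genes occur in
#' exactly `j` of the `S` studies and in at least `m` studies. This is the
#' observed side of the cross-study concordance analysis: genes recurrently
#' regulated across independent experiments regardless of species or model.
#'
#' @inheritParams gene_set_overlaps
#' @param universe Optional pool size `U`; when given, the `j = 0` row
#'   (genes in no study) is included so that the histogram totals `U`.
#' @return A tibble of class `occurrence_profile` with columns `j`,
#'   `observed`, `observed_ge`. Per-gene occurrence counts are attached as
#'   attribute `"gene_counts"`; use [occurrence_members()] to list the
#'   genes at or above a level.
#' @examples
#' occurrence_histogram(list(s1 = c("a", "b"), s2 = c("b", "c"), s3 = "b"))
#' @export
occurrence_histogram <- function(sets, universe = NULL) {
  sl <- gene_set_list(as_gene_sets(sets))
  S <- length(sl)
  counts <- table(unlist(sl, use.names = FALSE))
  observed <- vapply(seq_len(S), function(j) sum(counts == j), integer(1))
  j <- seq_len(S)
  if (!is.null(universe)) {
    universe <- check_count(universe, "universe", min = 1)
    if (universe < length(counts)) {
      abort("`universe` is smaller than the union of the sets.")
    }
    observed <- c(universe - length(counts), observed)
    j <- 0:S
  }
  out <- tibble(
    j = j,
    observed = observed,
    observed_ge = rev(cumsum(rev(observed)))
  )
  attr(out, "gene_counts") <- counts
  attr(out, "n_studies") <- S
  class(out) <- c("occurrence_profile", class(out))
  out
}

#' Genes at or above an occurrence level
#'
#' @param profile An `occurrence_profile` from [occurrence_histogram()].
#' @param min_level Minimum number of studies a gene must appear in.
#' @return Character vector of gene symbols, sorted.
#' @export
occurrence_members <- function(profile, min_level) {
  counts <- attr(profile, "gene_counts")
  if (is.null(counts)) abort("`profile` must come from occurrence_histogram().")
  min_level <- check_count(min_level, "min_level", min = 1)
  sort(names(counts)[counts >= min_level])
}

#' Monte-Carlo occurrence null for multi-study overlap
#'
#' Simulates the null expectation of the occurrence histogram: in each
#' replicate every study draws its true number of genes uniformly without
#' replacement from a common pool of `universe` genes, independently of the
#' other studies, and genes are tabulated by the number of studies that
#' drew them. The mean over replicates estimates the expected number of
#' genes shared by exactly `j` (and at least `m`) studies under the
#' hypothesis of no concordance.
#'
#' @param set_sizes Integer vector of study list sizes.
#' @param universe Pool size genes are drawn from (e.g. 10000 or 15000,
#'   spanning plausible numbers of measurable genes on the platforms).
#' @param n_sims Number of Monte-Carlo replicates.
#' @param seed Integer seed; the simulation is bit-reproducible.
#' @return A tibble of class `occurrence_null` with columns `j` (0 to `S`),
#'   `expected`, `sim_sd` (SD across replicates), `expected_ge`.
#'   Attributes record `n_sims`, `universe`, `seed` and `set_sizes`.
#' @seealso [occurrence_expectation()] for the closed-form mean this
#'   simulation converges to.
#' @examples
#' occurrence_null(c(5, 5), universe = 10, n_sims = 500, seed = 1)
#' @export
occurrence_null <- function(set_sizes, universe, n_sims = 10000, seed = 1) {
  set_sizes <- vapply(set_sizes, check_count, integer(1), name = "set_sizes")
  universe <- check_count(universe, "universe", min = 1)
  n_sims <- check_count(n_sims, "n_sims", min = 1)
  if (any(set_sizes > universe)) {
    abort("All `set_sizes` must be <= `universe`.")
  }
  S <- length(set_sizes)
  tab <- matrix(0L, nrow = n_sims, ncol = S + 1L)
  withr::with_seed(seed, {
    for (r in seq_len(n_sims)) {
      draws <- unlist(lapply(set_sizes, function(n) sample.int(universe, n)),
                      use.names = FALSE)
      occ <- tabulate(tabulate(draws, nbins = universe), nbins = S)
      tab[r, ] <- c(universe - sum(occ), occ)
    }
  })
  expected <- colMeans(tab)
  sim_sd <- apply(tab, 2, sd)
  out <- tibble(
    j = 0:S,
    expected = expected,
    sim_sd = sim_sd,
    expected_ge = rev(cumsum(rev(expected)))
  )
  attr(out, "n_sims") <- n_sims
  attr(out, "universe") <- universe
  attr(out, "seed") <- seed
  attr(out, "set_sizes") <- set_sizes
  class(out) <- c("occurrence_null", class(out))
  out
}

#' Closed-form occurrence expectation (Poisson-binomial oracle)
#'
#' Analytic mean of the occurrence histogram under the null of
#' [occurrence_null()]. A fixed gene belongs to study `i` with probability
#' \eqn{p_i = n_i / U}, independently across studies (within-study sampling
#' without replacement does not change a single gene's marginal), so its
#' occurrence count follows a Poisson-binomial distribution. The expected
#' number of genes at level `j` is `U` times the Poisson-binomial mass at
#' `j`, computed by the standard O(S^2) convolution recursion.
#'
#' @inheritParams occurrence_null
#' @return A tibble with columns `j` (0 to `S`), `expected`, `expected_ge`.
#' @examples
#' occurrence_expectation(c(5, 5), universe = 10)  # 2.5, 5, 2.5
#' @export
occurrence_expectation <- function(set_sizes, universe) {
  set_sizes <- vapply(set_sizes, check_count, integer(1), name = "set_sizes")
  universe <- check_count(universe, "universe", min = 1)
  if (any(set_sizes > universe)) abort("All `set_sizes` must be <= `universe`.")
  p <- set_sizes / universe
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  expected <- universe * f
  tibble(
    j = 0:length(p),
    expected = expected,
    expected_ge = rev(cumsum(rev(expected)))
  )
}
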