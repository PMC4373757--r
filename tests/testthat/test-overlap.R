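test_that("hypergeometric pmf matches exhaustive enumeration on small universes", {
  for (U in c(4, 6, 9)) {
    for (n1 in 0:U) {
      for (n2 in 0:U) {
        lo <- max(0, n1 + n2 - U)
        hi <- min(n1, n2)
        ref <- enum_overlap_pmf(n1, n2, U)
        got <- vapply(lo:hi, function(k) hypergeom_overlap(k, n1, n2, U)$pmf,
                      numeric(1))
        expect_equal(got, ref, tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d U=%d", n1, n2, U))
      }
    }
  }
})

test_that("hypergeometric pmf agrees with dhyper/phyper at large scale", {
  withr::with_seed(42, {
    for (i in 1:50) {
      U <- sample(100:20000, 1)
      n1 <- sample.int(U, 1)
      n2 <- sample.int(U, 1)
      lo <- max(0, n1 + n2 - U)
      hi <- min(n1, n2)
      k <- sample(lo:hi, 1)
      res <- hypergeom_overlap(k, n1, n2, U)
      expect_equal(res$pmf, dhyper(k, n1, U - n1, n2), tolerance = 1e-10)
      expect_equal(res$p_upper, phyper(k - 1, n1, U - n1, n2, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
})

test_that("pmf sums to one over the support and worked examples hold", {
  expect_equal(hypergeom_overlap(1, 3, 2, 6)$pmf, 0.6, tolerance = 1e-12)
  expect_equal(hypergeom_overlap(4, 4, 10, 10)$pmf, 1)   # n2 = U saturation
  expect_equal(hypergeom_overlap(1, 1, 1, 1000)$pmf, 1 / 1000, tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:200) {
      U <- sample.int(20000, 1)
      n1 <- sample.int(U, 1)
      n2 <- sample.int(U, 1)
      tab <- overlap_pmf_table(n1, n2, U)
      expect_equal(sum(tab$pmf), 1, tolerance = 1e-12)
      # the pointwise function agrees with the tabled distribution
      k <- tab$k[sample.int(nrow(tab), 1)]
      expect_equal(hypergeom_overlap(k, n1, n2, U)$pmf,
                   tab$pmf[tab$k == k], tolerance = 1e-12)
    }
  })
})

test_that("k outside the support raises a support error with bounds", {
  expect_error(hypergeom_overlap(3, 2, 5, 100), "support")
  expect_error(hypergeom_overlap(0, 8, 9, 10), "support")  # lo = 7
  expect_error(hypergeom_overlap(1, 3, 2, 1), "exceed")
})

test_that("symbol harmonization upper-cases, maps orthologs and collapses", {
  out <- harmonize_symbols(list(A = c("Fmod", "Tnn")))
  expect_setequal(out$symbol, c("FMOD", "TNN"))

  map <- tibble::tibble(from = "Fn1", to = "FN1")
  out <- harmonize_symbols(list(A = "Fn1"), map)
  expect_equal(out$symbol, "FN1")

  map2 <- tibble::tibble(from = c("A", "B"), to = c("X", "X"))
  expect_message(out2 <- harmonize_symbols(list(s = c("A", "b")), map2),
                 "Collapsed 1")
  expect_equal(out2$symbol, "X")
  expect_equal(attr(out2, "n_collapsed"), 1L)

  bad <- tibble::tibble(from = c("A", NA), to = c("X", "Y"))
  expect_warning(harmonize_symbols(list(s = "A"), bad), "malformed")
})

test_that("venn regions partition the union and permute with input order", {
  r <- venn_regions(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(r$n[r$region == "A"], 1L)
  expect_equal(r$n[r$region == "B"], 1L)
  expect_equal(r$n[r$region == "A&B"], 1L)

  same <- venn_regions(list(A = c("p", "q"), B = c("p", "q")))
  expect_equal(same$n[same$region == "A&B"], 2L)
  expect_equal(sum(same$n[same$region != "A&B"]), 0L)

  withr::with_seed(11, {
    for (i in 1:20) {
      S <- sample(2:4, 1)
      sets <- lapply(seq_len(S), function(j)
        sample(letters, sample(3:15, 1)))
      names(sets) <- LETTERS[seq_len(S)]
      r <- venn_regions(sets)
      expect_equal(sum(r$n), length(unique(unlist(sets))))
      expect_equal(nrow(r), 2^S - 1)
      # permuting set order permutes labels but preserves region contents
      perm <- rev(seq_len(S))
      r2 <- venn_regions(sets[perm])
      key <- function(x) sort(vapply(x$members, function(m)
        paste(sort(m), collapse = ","), character(1)))
      expect_equal(key(r2), key(r))
    }
  })
  expect_error(venn_regions(list(A = "x")), "2 to 4")
  expect_error(venn_regions(list(A = "a", B = "b", C = "c", D = "d", E = "e")),
               "2 to 4")
})

test_that("occurrence histogram counts exact and at-least levels", {
  prof <- occurrence_histogram(list(s1 = c("a", "b"), s2 = c("b", "c"), s3 = "b"))
  expect_equal(prof$observed[prof$j == 1], 2L)
  expect_equal(prof$observed[prof$j == 3], 1L)
  expect_equal(prof$observed_ge[prof$j == 1], 3L)
  expect_setequal(occurrence_members(prof, 3), "b")

  single <- occurrence_histogram(list(only = letters[1:7]))
  expect_equal(single$observed[single$j == 1], 7L)

  with_u <- occurrence_histogram(list(s1 = c("a", "b"), s2 = "b"), universe = 10)
  expect_equal(with_u$observed[with_u$j == 0], 8L)
  expect_equal(sum(with_u$observed), 10L)
})

test_that("closed-form occurrence expectation matches hand-expanded cases", {
  oe <- occurrence_expectation(c(5, 5), universe = 10)
  expect_equal(oe$expected, c(2.5, 5, 2.5), tolerance = 1e-12)

  oe1 <- occurrence_expectation(7, universe = 20)
  expect_equal(oe1$expected, c(13, 7))

  oe0 <- occurrence_expectation(c(0, 0, 0), universe = 50)
  expect_equal(oe0$expected, c(50, 0, 0, 0))

  # bookkeeping identities
  withr::with_seed(3, {
    for (i in 1:20) {
      U <- sample(50:2000, 1)
      sizes <- sample.int(U, sample(2:9, 1), replace = TRUE)
      oe <- occurrence_expectation(sizes, U)
      expect_equal(sum(oe$j * oe$expected), sum(sizes), tolerance = 1e-9)
      expect_equal(sum(oe$expected), U, tolerance = 1e-9)
    }
  })
})

test_that("Monte-Carlo occurrence null agrees with the closed form", {
  sizes <- c(30, 50, 20, 40, 10)
  U <- 200
  n_sims <- 2000
  null <- occurrence_null(sizes, U, n_sims = n_sims, seed = 5)
  oe <- occurrence_expectation(sizes, U)
  for (j in null$j) {
    se <- null$sim_sd[null$j == j] / sqrt(n_sims)
    expect_lt(abs(null$expected[null$j == j] - oe$expected[oe$j == j]),
              3 * se + 1e-9)
  }
  expect_equal(sum(null$j * null$expected), sum(sizes), tolerance = 1e-9)
  expect_equal(sum(null$expected), U, tolerance = 1e-9)
})

test_that("occurrence null saturates and is seed-reproducible", {
  sat <- occurrence_null(c(10, 10, 10), universe = 10, n_sims = 5, seed = 1)
  expect_equal(sat$expected[sat$j == 3], 10)
  expect_equal(sum(sat$expected[sat$j < 3]), 0)

  a <- occurrence_null(c(5, 8), 30, n_sims = 200, seed = 9)
  b <- occurrence_null(c(5, 8), 30, n_sims = 200, seed = 9)
  c <- occurrence_null(c(5, 8), 30, n_sims = 200, seed = 10)
  expect_identical(a$expected, b$expected)
  expect_false(identical(a$expected, c$expected))
  expect_error(occurrence_null(c(50, 5), 30, n_sims = 10), "universe")
})

test_that("pairwise overlap table covers all study pairs", {
  sets <- list(A = letters[1:10], B = letters[5:12], C = letters[8:20])
  ov <- gene_set_overlaps(sets, universe = 100)
  expect_equal(nrow(ov), 3)
  row <- ov[ov$study1 == "A" & ov$study2 == "B", ]
  expect_equal(row$k, length(intersect(sets$A, sets$B)))
  expect_equal(row$p_upper,
               phyper(row$k - 1, 10, 90, 8, lower.tail = FALSE),
               tolerance = 1e-10)
})
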