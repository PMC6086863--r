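test_that("pmf matches closed-form symmetry and enumeration-derived values", {
  expect_equal(cooccur_pmf(2, 1, 1, 1), 0.5)
  # frozen from the exhaustive placement oracle at N = 4, n_a = n_b = 2
  expect_equal(cooccur_pmf(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(cooccur_pmf(4, 2, 2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(cooccur_pmf(4, 2, 2, 0), 1 / 6, tolerance = 1e-12)
  # below the support floor n_a + n_b - N = 2
  expect_identical(cooccur_pmf(5, 3, 4, 1), 0)
  expect_error(cooccur_pmf(5, 6, 2, 1), "n_sites")
})

test_that("pmf equals the exhaustive-enumeration oracle for all N <= 6", {
  for (N in 2:6) for (n_a in 0:N) for (n_b in 0:N) {
    freq <- oracle_pmf(N, n_a, n_b)
    pmf <- cooccur_pmf(N, n_a, n_b, 0:min(n_a, n_b))
    expect_equal(pmf, freq, tolerance = 1e-12,
                 label = sprintf("pmf(N=%d, n_a=%d, n_b=%d)", N, n_a, n_b))
  }
})

test_that("pmf sums to one and agrees with the hypergeometric density", {
  for (N in c(5, 17, 33, 60)) {
    for (n_a in unique(c(1, N %/% 3, N %/% 2, N))) {
      for (n_b in unique(c(1, N %/% 2, N - 1))) {
        s <- cooccur_support(N, n_a, n_b)
        p <- cooccur_pmf(N, n_a, n_b, s)
        expect_lt(abs(sum(p) - 1), 1e-12)
        expect_equal(p, dhyper(s, n_a, N - n_a, n_b), tolerance = 1e-12)
      }
    }
  }
})

test_that("expected co-occurrence is the pmf mean", {
  expect_equal(expected_cooccur(29, 1, 1), 1 / 29)
  s <- cooccur_support(4, 2, 2)
  expect_equal(expected_cooccur(4, 2, 2), sum(s * cooccur_pmf(4, 2, 2, s)))
  expect_equal(expected_cooccur(12, 12, 5), 5)  # ubiquitous species
  expect_error(expected_cooccur(0, 0, 0), "positive")
})

test_that("pair classification follows the threshold rules", {
  # N = 10, n_a = n_b = 5: tail mass at the extremes is 1/252
  pos <- classify_pair(10, 5, 5, 5)
  expect_equal(pos$p_gt, 1 / 252, tolerance = 1e-12)
  expect_identical(pos$classification, "positive")
  neg <- classify_pair(10, 5, 5, 0)
  expect_equal(neg$p_lt, 1 / 252, tolerance = 1e-12)
  expect_identical(neg$classification, "negative")
  # j = 2: p_lt = 126/252, within the 0.1 * N random band
  rnd <- classify_pair(10, 5, 5, 2)
  expect_equal(rnd$p_lt, 126 / 252, tolerance = 1e-12)
  expect_identical(rnd$classification, "random")
  # expected 1/29 < 1 is removed regardless of j
  expect_identical(classify_pair(29, 1, 1, 0)$classification, "removed")
  # outside the attainable range
  expect_error(classify_pair(10, 5, 5, 6), "outside")
})

test_that("inclusive tails overlap by exactly P(j_obs)", {
  set.seed(1)
  for (i in 1:50) {
    N <- sample(3:40, 1)
    n_a <- sample(1:N, 1); n_b <- sample(1:N, 1)
    s <- cooccur_support(N, n_a, n_b)
    j <- sample(rep(s, 2), 1)
    r <- classify_pair(N, n_a, n_b, j, min_expected = 0)
    expect_lt(abs(r$p_lt + r$p_gt - cooccur_pmf(N, n_a, n_b, j) - 1), 1e-9)
    # both tails can never be simultaneously below alpha < 0.5
    expect_false(r$p_lt < 0.05 && r$p_gt < 0.05)
    expect_equal(r$ses, (j - r$expected) / N)
  }
})

test_that("matrix analysis partitions all pairs and bounds the SES", {
  m <- gen_allopatric_matrix(n_groups = 2, species_per_group = 6,
                             islands_per_group = 8, shared_species = 2,
                             occupancy = 0.6, seed = 5)
  res <- cooccur_analyze(m)
  s <- res$summary
  expect_equal(s$n_pairs_total, choose(nrow(m), 2))
  expect_equal(s$n_removed + s$n_positive + s$n_negative + s$n_random +
                 s$n_unclassifiable, s$n_pairs_total)
  expect_true(all(res$pairs$ses >= -1 & res$pairs$ses <= 1))
  expect_true(all(sign(res$pairs$ses) ==
                    sign(res$pairs$j_obs - res$pairs$expected)))
  expect_error(cooccur_analyze(m[1, , drop = FALSE]), "2 species")
})

test_that("classifications are invariant to row/column permutation", {
  m <- gen_common_history_matrix(10, 8, nestedness = 0.6, seed = 7)
  res <- cooccur_analyze(m)
  set.seed(3)
  perm <- unclass(m)[sample(nrow(m)), sample(ncol(m))]
  res2 <- cooccur_analyze(pa_matrix(perm))
  key <- function(p) paste(pmin(p$species_a, p$species_b),
                           pmax(p$species_a, p$species_b))
  expect_identical(res$pairs$classification[order(key(res$pairs))],
                   res2$pairs$classification[order(key(res2$pairs))])
  expect_identical(res$summary, res2$summary)
})

test_that("species with identical widespread ranges classify positive", {
  sites <- 20
  row <- c(rep(1L, 10), rep(0L, 10))
  m <- pa_matrix(rbind(A = row, B = row,
                       C = rep(c(1L, 0L), 10), D = rep(1L, 20)),
                 sites = sprintf("I%02d", 1:sites))
  res <- cooccur_analyze(m)
  ab <- res$pairs[res$pairs$species_a == "A" & res$pairs$species_b == "B", ]
  expect_identical(ab$classification, "positive")
  expect_equal(ab$j_obs, 10)
})
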