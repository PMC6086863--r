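test_that("allopatric matrices have the block structure and shape contract", {
  m <- gen_allopatric_matrix(2, 8, 10, 1, 0.6, seed = 1)
  expect_equal(dim(m), c(17L, 20L))
  spec <- attr(m, "synth_spec")
  expect_equal(spec$scenario, "allopatric")
  expect_equal(spec$seed, 1)
  # endemics never leave their block
  g1 <- grepl("^G1S", rownames(m))
  expect_true(all(m[g1, grepl("^G2I", colnames(m))] == 0))
  # occupancy 1: within-group pairs share every island of the group
  m1 <- gen_allopatric_matrix(2, 4, 6, 0, 1.0, seed = 2)
  expect_true(all(m1[grepl("^G1S", rownames(m1)),
                     grepl("^G1I", colnames(m1))] == 1))
  res <- cooccur_analyze(m1)
  within <- substr(res$pairs$species_a, 1, 2) ==
    substr(res$pairs$species_b, 1, 2)
  expect_true(all(res$pairs$j_obs[within] == 6))
  expect_error(gen_allopatric_matrix(occupancy = 0), "occupancy")
})

test_that("generators are bit-reproducible and pass reader validation", {
  a1 <- gen_allopatric_matrix(seed = 9)
  a2 <- gen_allopatric_matrix(seed = 9)
  expect_identical(unclass(a1)[, ], unclass(a2)[, ])
  expect_false(identical(unclass(a1)[, ],
                         unclass(gen_allopatric_matrix(seed = 10))[, ]))
  expect_identical(as.numeric(gen_pareto_sample(30, 5, 1, seed = 3)),
                   as.numeric(gen_pareto_sample(30, 5, 1, seed = 3)))
  expect_identical(as.numeric(gen_broken_stick_sample(100, 4, seed = 3)),
                   as.numeric(gen_broken_stick_sample(100, 4, seed = 3)))
  # round-trip through the reader keeps every generated matrix valid
  f <- withr::local_tempfile(fileext = ".csv")
  for (s in 1:5) {
    m <- gen_common_history_matrix(10, 8, nestedness = 0.5, seed = s)
    write_presence_absence(m, f)
    expect_identical(unclass(read_presence_absence(f))[, ],
                     unclass(m)[, ])
  }
})

test_that("nestedness endpoints give strict nesting and independence", {
  m <- gen_common_history_matrix(14, 10, nestedness = 1, seed = 6)
  # every pair of islands is subset-comparable
  for (i in 1:(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    expect_true(all(m[, i] >= m[, j]) || all(m[, j] >= m[, i]))
  }
  # nestedness 0: fill close to the requested occupancy
  fills <- vapply(1:30, function(s)
    mean(gen_common_history_matrix(20, 15, nestedness = 0, occupancy = 0.5,
                                   seed = s)), numeric(1))
  expect_lt(abs(mean(fills) - 0.5), 0.03)
  expect_error(gen_common_history_matrix(5, 5, nestedness = 2), "nestedness")
})

test_that("high nestedness yields positives but no negatives", {
  negs <- 0; poss <- 0
  for (s in 1:50) {
    m <- gen_common_history_matrix(12, 10, nestedness = 1, seed = s)
    sm <- summary(cooccur_analyze(m))
    negs <- negs + sm$n_negative
    poss <- poss + sm$n_positive
  }
  expect_equal(negs, 0)
  expect_gt(poss, 0)
})

test_that("significant negatives in allopatric metacommunities span groups", {
  cross_frac <- vapply(1:50, function(s) {
    m <- gen_allopatric_matrix(2, 8, 10, 1, 0.6, seed = s)
    res <- cooccur_analyze(m)
    neg <- res$pairs[res$pairs$classification == "negative", ]
    if (nrow(neg) == 0) return(NA_real_)
    mean(substr(neg$species_a, 1, 2) != substr(neg$species_b, 1, 2))
  }, numeric(1))
  expect_gte(mean(cross_frac, na.rm = TRUE), 0.95)
})

test_that("Pareto samples respect the scale and the high-shape limit", {
  x <- gen_pareto_sample(200, 20, 0.5, seed = 7)
  expect_gte(min(x), 20)
  f <- fit_pareto(x, scale = 20)
  expect_lt(abs(coef(f) - 0.5), 3 * f$estimates$se)
  xb <- gen_pareto_sample(100, 4, 50, seed = 1)
  expect_gte(mean(as.numeric(xb) == 4), 0.95)
})

test_that("broken-stick samples conserve N and have a uniform smaller half at S = 2", {
  for (s in 1:20)
    expect_equal(attr(gen_broken_stick_sample(137, 5, seed = s), "N"), 137)
  smaller <- vapply(1:400, function(s)
    min(as.numeric(gen_broken_stick_sample(1000, 2, seed = s))),
    numeric(1))
  # the smaller segment of a stick broken once is uniform on (0, N/2)
  expect_lt(abs(mean(smaller) - 250), 3 * 500 / sqrt(12) / sqrt(400) + 1)
  ks <- suppressWarnings(ks.test(smaller / 500, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_error(gen_broken_stick_sample(3, 5, seed = 1), "N >= S")
})

test_that("size assemblages cover both sampling modes", {
  pool <- exp(seq(log(0.5), log(84), length.out = 40))
  even <- gen_size_community(pool, 7, "even_log_spaced", seed = 1)
  expect_lt(v_ratio(even), 0.01)
  r1 <- gen_size_community(pool, 7, "random", seed = 4)
  expect_identical(r1, gen_size_community(pool, 7, "random", seed = 4))
  expect_equal(sort(gen_size_community(pool, 40, "random", seed = 1)),
               sort(pool))
  expect_equal(sort(gen_size_community(pool, 40, "even_log_spaced")),
               sort(pool))
  expect_error(gen_size_community(pool, 41, "random"), "pool smaller")
})
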