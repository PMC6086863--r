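test_that("quadrat counts pool into ranked abundance vectors", {
  qc <- quadrat_counts(data.frame(
    community = "C1",
    quadrat = c("Q1", "Q1", "Q2"),
    species = c("A", "B", "A"),
    count = c(3, 1, 2)))
  av <- aggregate_abundances(qc)[["C1"]]
  expect_equal(as.numeric(av), c(5, 1))
  expect_equal(names(av), c("A", "B"))
  expect_equal(attr(av, "N"), 6)
  expect_equal(attr(av, "S"), 2)
  expect_error(aggregate_abundances(qc, "nowhere"), "unknown communit")
  # species observed only as zeros are dropped
  qc2 <- quadrat_counts(data.frame(community = "C1", quadrat = "Q1",
                                   species = c("A", "B"), count = c(4, 0)))
  expect_equal(attr(aggregate_abundances(qc2)[["C1"]], "S"), 1)
  expect_false(is.unsorted(rev(as.numeric(av))))
})

test_that("Pareto closed form agrees with numerical likelihood maximization", {
  x <- abundance_vector(c(200, 51, 33, 22, 30, 97))
  fit <- fit_pareto(x)
  expect_equal(fit$fixed$scale, 22)
  # oracle: direct 1-d maximization of the Pareto log-likelihood
  ll <- function(b) sum(log(b) + b * log(22) - (b + 1) * log(as.numeric(x)))
  b_hat <- optimize(ll, c(1e-3, 50), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(coef(fit)), b_hat, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), attr(x, "S") / sum(log(x / 22)))
  expect_equal(fit$estimates$se, unname(coef(fit)) / sqrt(attr(x, "S")))
  expect_equal(fit$loglik, ll(coef(fit)), tolerance = 1e-9)
  expect_error(fit_pareto(abundance_vector(c(5, 5, 5))), "degenerate")
  expect_error(fit_pareto(x, scale = 40), ">=")
})

test_that("broken stick has no free parameters and a uniform S = 2 density", {
  f <- fit_broken_stick(abundance_vector(c(7, 3)))
  expect_equal(f$df, 0L)
  expect_equal(f$loglik, 2 * log(0.1))
  expect_equal(f$aic, -2 * f$loglik)
  expect_error(fit_broken_stick(abundance_vector(5)), "2 species")
  g <- fit_broken_stick(gen_broken_stick_sample(300, 6, seed = 1))
  expect_equal(g$aic, -2 * g$loglik + 2 * 0)
})

test_that("lognormal fit uses ML moments of log abundance", {
  x <- abundance_vector(c(7, 55))
  f <- fit_lognormal(x)
  expect_equal(unname(coef(f)["meanlog"]), mean(log(c(7, 55))))
  expect_equal(unname(coef(f)["sdlog"]),
               sqrt(mean((log(c(7, 55)) - mean(log(c(7, 55))))^2)))
  expect_equal(f$estimates$se,
               c(coef(f)["sdlog"] / sqrt(2), coef(f)["sdlog"] / 2),
               ignore_attr = TRUE)
  expect_error(fit_lognormal(abundance_vector(c(4, 4, 4))), "degenerate")
})

test_that("generic MLE reproduces the closed forms within 1e-6", {
  x <- gen_pareto_sample(60, 20, 0.8, seed = 11)
  expect_equal(coef(fit_sad(x, "pareto", engine = "numeric")),
               coef(fit_pareto(x)), tolerance = 1e-6)
  expect_equal(coef(fit_sad(x, "lognormal", engine = "numeric")),
               coef(fit_lognormal(x)), tolerance = 1e-6)
  expect_equal(fit_sad(x, "brokenstick", engine = "numeric")$loglik,
               fit_broken_stick(x)$loglik)
})

test_that("geometric parameter recovery is within 3 standard errors", {
  set.seed(202)
  x <- abundance_vector(rgeom(50, 0.5) + 1)
  f <- fit_sad(x, "geometric")
  expect_lt(abs(coef(f) - 0.5), 3 * f$estimates$se)
})

test_that("Zipf on harmonic rank data recovers exponent 1", {
  x <- abundance_vector(c(100, 50, 33, 25))
  f <- fit_sad(x, "zipf")
  # oracle: grid search of the rank-multinomial likelihood
  grid <- seq(0.5, 1.5, by = 1e-4)
  ll <- vapply(grid, function(g) {
    p <- (1:4)^(-g); p <- p / sum(p)
    sum(c(100, 50, 33, 25) * log(p))
  }, numeric(1))
  expect_equal(unname(coef(f)), grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(unname(coef(f)), 1, tolerance = 0.05)
})

test_that("unknown and unimplemented models fail loudly", {
  x <- abundance_vector(c(9, 4, 2))
  expect_error(fit_sad(x, "zeta-prime"), "registered models")
  expect_error(fit_sad(x, "zsm"), "not implemented")
  expect_error(fit_sad(x, "neutral"), "not implemented")
  expect_true(all(c("zsm", "neutral") %in% sad_registry()$model))
})

test_that("every fitted density/mass normalizes to 1 at its estimates", {
  # moderate-tail sample so the discrete sums truncate cleanly
  set.seed(77)
  x <- abundance_vector(round(rlnorm(40, 1.5, 0.8)) + 1)
  tol <- 1e-6
  norm_of <- function(model) {
    f <- suppressWarnings(fit_sad(x, model))
    p <- coef(f)
    switch(model,
      pareto = integrate(function(t) p[1] * f$fixed$scale^p[1] /
                           t^(p[1] + 1), f$fixed$scale, Inf,
                         rel.tol = 1e-9)$value,
      brokenstick = {
        N <- f$fixed$N; S <- f$fixed$S
        integrate(function(t) (S - 1) / N * (1 - t / N)^(S - 2), 0, N,
                  rel.tol = 1e-9)$value
      },
      lognormal = integrate(function(t) dlnorm(t, p[1], p[2]), 0, Inf,
                            rel.tol = 1e-9)$value,
      geometric = sum(p[1] * (1 - p[1])^(0:9999)),
      logseries = sum(p[1]^(1:100000) / (1:100000)) / (-log(1 - p[1])),
      weibull = integrate(function(t) dweibull(t, p[1], p[2]), 0, Inf,
                          rel.tol = 1e-9)$value,
      powerdiscrete = {
        M <- 1e5; s <- p[1]
        (sum((1:M)^(-s)) + M^(1 - s) / (s - 1) + M^(-s) / 2) /
          pracma::zeta(s)
      },
      zipf = sum((1:attr(x, "S"))^(-p[1]) / sum((1:attr(x, "S"))^(-p[1]))),
      zipfmandelbrot = {
        w <- (seq_len(attr(x, "S")) + p[2])^(-p[1]); sum(w / sum(w))
      },
      negbinom = sum(dnbinom(1:5000, size = p[1], mu = p[2])) /
        (1 - dnbinom(0, size = p[1], mu = p[2])),
      poislognormal = {
        kmax <- ceiling(qlnorm(1 - 1e-10, p[1], p[2])) + 200
        mass <- vapply(1:kmax, function(k)
          integrate(function(t) dpois(k, exp(t)) * dnorm(t, p[1], p[2]),
                    p[1] - 12 * p[2], p[1] + 12 * p[2],
                    rel.tol = 1e-10)$value, numeric(1))
        p0 <- integrate(function(t) dpois(0, exp(t)) * dnorm(t, p[1], p[2]),
                        p[1] - 12 * p[2], p[1] + 12 * p[2],
                        rel.tol = 1e-10)$value
        sum(mass) / (1 - p0)
      },
      gamma = integrate(function(t) dgamma(t, p[1], p[2]), 0, Inf,
                        rel.tol = 1e-9)$value)
  }
  for (m in setdiff(sad_registry()$model[sad_registry()$kind != "stub"],
                    character(0))) {
    expect_lt(abs(norm_of(m) - 1), tol, label = paste("normalization of", m))
  }
})

test_that("AIC ranking orders, differences and ties correctly", {
  mk <- function(model, ll, df) structure(
    list(model = model, loglik = ll, df = df, aic = -2 * ll + 2 * df,
         convergence = 0L), class = "sad_fit")
  fits <- list(mk("a", -44.7, 1), mk("b", -45.8, 0), mk("c", -45.65, 2))
  rk <- rank_by_aic(fits)
  expect_equal(rk$aic, c(91.4, 91.6, 95.3))
  expect_equal(rk$delta_aic, c(0, 0.2, 3.9), tolerance = 1e-9)
  # every AIC satisfies the definition
  expect_equal(rk$aic, -2 * rk$loglik + 2 * rk$df)
  # single fit
  expect_equal(rank_by_aic(list(mk("solo", -10, 1)))$delta_aic, 0)
  # a 0-parameter add-on never changes other models' AICs
  rk2 <- rank_by_aic(c(fits, list(mk("flat", -60, 0))))
  expect_equal(sort(rk2$aic[rk2$model %in% c("a", "b", "c")]), rk$aic)
  # ties break by fewer parameters, then name
  rk3 <- rank_by_aic(list(mk("z", -10, 2), mk("y", -11, 1), mk("x", -12, 0)))
  expect_equal(rk3$model, c("x", "y", "z"))
  expect_error(rank_by_aic(list()), "no converged fits")
})

test_that("Pareto tops the ranking on strongly dominance-skewed communities", {
  x <- gen_pareto_sample(100, 22, 0.6, seed = 14)
  rk <- fit_sads(x, models = c("pareto", "brokenstick", "lognormal"))$ranking
  expect_identical(rk$model[1], "pareto")
  expect_equal(rk$delta_aic[1], 0)
})
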