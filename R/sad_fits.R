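# Maximum-likelihood fitting of species abundance distribution (SAD)
# models to a community abundance vector, and AIC ranking. Continuous
# densities (Pareto, lognormal, broken stick, Weibull, gamma) are
# evaluated at the integer abundances as densities, not discretised;
# discrete models use (zero-truncated where needed) mass functions; the
# Zipf family uses the rank-frequency multinomial likelihood with the
# parameter-free multinomial coefficient omitted.

new_sad_fit <- function(model, fixed, estimates, loglik, df, data,
                        convergence = 0L) {
  structure(list(model = model, fixed = fixed, estimates = estimates,
                 loglik = loglik, df = df, aic = -2 * loglik + 2 * df,
                 delta_aic = NA_real_, data = data,
                 convergence = convergence),
            class = "sad_fit")
}

.as_abund <- function(x) {
  if (inherits(x, "abundance_vector")) x else abundance_vector(x)
}

#' Fit a Pareto (continuous power-law) SAD
#'
#' Density `f(x) = b a^b / x^(b+1)` for `x >= a` with fixed scale `a`
#' and free shape `b`. The shape MLE is closed form,
#' `b = S / sum(log(x/a))`, with asymptotic standard error `b/sqrt(S)`.
#'
#' @param x An `abundance_vector` (or positive integer counts).
#' @param scale Fixed scale `a`; default `"min"` uses the smallest
#'   observed abundance.
#' @return A `sad_fit` (df = 1).
#' @export
fit_pareto <- function(x, scale = "min") {
  x <- .as_abund(x)
  a <- if (identical(scale, "min")) min(x) else as.numeric(scale)
  if (a <= 0) stop("scale must be positive")
  if (any(x < a)) stop("all abundances must be >= the scale ", a)
  S <- attr(x, "S")
  denom <- sum(log(x / a))
  if (denom == 0)
    stop("degenerate sample: all abundances equal the scale; shape MLE diverges")
  b <- S / denom
  ll <- sum(log(b) + b * log(a) - (b + 1) * log(x))
  est <- data.frame(parameter = "shape", estimate = b, se = b / sqrt(S))
  new_sad_fit("pareto", list(scale = a), est, ll, 1L, x)
}

#' Evaluate the broken-stick SAD
#'
#' Density `p(x) = (S-1)/N * (1 - x/N)^(S-2)` with N (total abundance)
#' and S (richness) fixed by the data: no free parameters, so
#' AIC = -2 logLik.
#'
#' @param x An `abundance_vector` with S >= 2.
#' @return A `sad_fit` (df = 0).
#' @export
fit_broken_stick <- function(x) {
  x <- .as_abund(x)
  S <- attr(x, "S"); N <- attr(x, "N")
  if (S < 2) stop("broken stick needs at least 2 species")
  if (any(x >= N) && S > 2)
    stop("abundance equal to the total gives zero density (S > 2)")
  ll <- sum(log(S - 1) - log(N) + (S - 2) * log(1 - x / N))
  new_sad_fit("brokenstick", list(N = N, S = S),
              data.frame(parameter = character(), estimate = numeric(),
                         se = numeric()),
              ll, 0L, x)
}

#' Fit a lognormal SAD
#'
#' ML estimates `meanlog = mean(log x)` and the divide-by-S
#' `sdlog = sqrt(mean((log x - meanlog)^2))`, with asymptotic standard
#' errors `sdlog/sqrt(S)` and `sdlog/sqrt(2 S)`.
#'
#' @param x An `abundance_vector` with S >= 2.
#' @return A `sad_fit` (df = 2).
#' @export
fit_lognormal <- function(x) {
  x <- .as_abund(x)
  S <- attr(x, "S")
  if (S < 2) stop("lognormal fit needs at least 2 species")
  ml <- mean(log(x))
  sl <- sqrt(mean((log(x) - ml)^2))
  if (sl == 0) stop("degenerate sample: all abundances equal, sdlog = 0")
  ll <- sum(stats::dlnorm(x, ml, sl, log = TRUE))
  est <- data.frame(parameter = c("meanlog", "sdlog"),
                    estimate = c(ml, sl),
                    se = c(sl / sqrt(S), sl / sqrt(2 * S)))
  new_sad_fit("lognormal", list(), est, ll, 2L, x)
}

#' @export
print.sad_fit <- function(x, ...) {
  fx <- if (length(x$fixed) > 0)
    paste(names(x$fixed), unlist(x$fixed), sep = " = ", collapse = ", ")
  else "none"
  cat("SAD model '", x$model, "' (fixed: ", fx, ")\n", sep = "")
  if (nrow(x$estimates) > 0) {
    with(x$estimates,
         cat(sprintf("  %-10s %.4g +/- %.4g\n", parameter, estimate, se),
             sep = ""))
  }
  cat(sprintf("  logLik %.3f  df %d  AIC %.2f\n", x$loglik, x$df, x$aic))
  if (x$convergence != 0) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
logLik.sad_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
coef.sad_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' Expected ranked abundances under a fitted SAD
#'
#' For plotting and diagnostics: the model's expected abundance at each
#' rank. Broken stick has the classical closed form
#' `E[x_(i)] = (N/S) * sum(1/k, k = i..S)`; continuous models use the
#' quantile at the rank plotting position `(S - i + 0.5)/S`.
#'
#' @param fit A `sad_fit` for model pareto, lognormal or brokenstick.
#' @return Numeric vector of length S, descending.
#' @export
expected_rank_abundance <- function(fit) {
  S <- attr(fit$data, "S"); N <- attr(fit$data, "N")
  i <- seq_len(S)
  switch(fit$model,
    brokenstick = (N / S) * rev(cumsum(1 / rev(i))),
    pareto = {
      b <- fit$estimates$estimate[1]; a <- fit$fixed$scale
      p <- (S - i + 0.5) / S
      a * (1 - p)^(-1 / b)
    },
    lognormal = {
      p <- (S - i + 0.5) / S
      stats::qlnorm(p, fit$estimates$estimate[1], fit$estimates$estimate[2])
    },
    stop("no rank-abundance expectation implemented for model '",
         fit$model, "'"))
}

#' @export
plot.sad_fit <- function(x, ...) {
  ab <- as.numeric(x$data)
  plot(seq_along(ab), ab, log = "y", xlab = "Rank",
       ylab = "Abundance", pch = 19, ...)
  exp_ab <- tryCatch(expected_rank_abundance(x), error = function(e) NULL)
  if (!is.null(exp_ab)) graphics::lines(seq_along(exp_ab), exp_ab, lty = 2)
  invisible(x)
}

#' @export
simulate.sad_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  S <- attr(object$data, "S"); N <- attr(object$data, "N")
  one <- switch(object$model,
    pareto = function()
      gen_pareto_sample(S, object$fixed$scale,
                        object$estimates$estimate[1],
                        seed = sample.int(2^30, 1)),
    brokenstick = function()
      gen_broken_stick_sample(N, S, seed = sample.int(2^30, 1)),
    stop("simulate() supports models pareto and brokenstick"))
  replicate(nsim, one(), simplify = FALSE)
}
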