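# Body-size structure. The V-ratio of a community is the variance of the
# gaps between adjacent log-transformed body masses once species are
# ranked by size (equivalently, the variance of the logs of adjacent
# size ratios). Communities structured by competition are expected to
# space their sizes at near-constant ratios, giving V near 0; a random
# draw from a source pool sets the null expectation.

#' Body-size V-ratio
#'
#' Sorts the masses ascending, takes adjacent log-mass gaps
#' `g_i = log m_(i+1) - log m_(i)`, and returns their variance. A
#' geometric (constant-ratio) size sequence gives exactly 0. Being a
#' function of log-ratios, the statistic is invariant to rescaling all
#' masses by a common factor and to input order.
#'
#' @param masses Body masses (grams), at least 3, all positive.
#' @param denominator `"unbiased"` (default) divides by
#'   `n_ratios - 1`; `"ml"` divides by `n_ratios`. The reference
#'   literature does not pin the convention down, so both are offered.
#' @return The V-ratio (non-negative scalar).
#' @export
v_ratio <- function(masses, denominator = c("unbiased", "ml")) {
  denominator <- match.arg(denominator)
  if (length(masses) < 3)
    stop("V-ratio needs at least 3 species (2 adjacent ratios)")
  if (anyNA(masses) || any(masses <= 0))
    stop("all masses must be positive")
  g <- diff(log(sort(masses)))
  v <- stats::var(g)
  if (denominator == "ml") v <- v * (length(g) - 1) / length(g)
  v
}

#' Build the null-model source pool for a community
#'
#' The pool holds every archipelago species whose mass does not exceed
#' the community's largest species (keeping the null communities'
#' maximum size comparable to the real one), plus `n_hypothetical`
#' hypothetical species whose masses are drawn once, uniformly on the
#' log-mass interval between the pool minimum and the community
#' maximum, so the pool always outnumbers the community.
#'
#' @param all_masses A `body_mass_table` for the whole archipelago (or a
#'   named/plain positive numeric vector of masses).
#' @param community_masses Masses of the community's members (grams).
#' @param n_hypothetical Number of hypothetical species (default 5).
#' @param seed Integer seed for the hypothetical masses.
#' @return Numeric vector of pool masses with attribute `n_hypothetical`.
#' @export
build_source_pool <- function(all_masses, community_masses,
                              n_hypothetical = 5, seed = 1) {
  pool <- if (inherits(all_masses, "body_mass_table")) {
    stats::setNames(all_masses$mass, all_masses$species)
  } else as.numeric(all_masses)
  if (any(pool <= 0) || any(community_masses <= 0))
    stop("masses must be positive")
  cmax <- max(community_masses)
  kept <- pool[pool <= cmax]
  if (length(kept) == 0 || max(kept) < cmax)
    kept <- c(kept, community_max = cmax)  # guarantee the max-size species
  hyp <- if (n_hypothetical > 0) {
    .with_substream(seed, "source-pool", {
      exp(stats::runif(n_hypothetical, log(min(kept)), log(cmax)))
    })
  } else numeric(0)
  if (length(hyp) > 0)
    names(hyp) <- paste0("hypothetical_", seq_along(hyp))
  out <- c(kept, hyp)
  if (length(out) <= length(community_masses))
    stop("source pool (", length(out), ") not larger than community ",
         "richness (", length(community_masses), "); increase ",
         "n_hypothetical or the mass table")
  attr(out, "n_hypothetical") <- n_hypothetical
  out
}

#' Monte-Carlo null distribution of the V-ratio
#'
#' Each iterate draws `S` species from the pool uniformly without
#' replacement and records the V-ratio.
#'
#' @param pool Pool masses (from [build_source_pool()]).
#' @param S Community richness to draw.
#' @param n_iter Iterations (default 1000, minimum 100).
#' @param seed Integer seed; fixed seed gives a bit-identical sample.
#' @param denominator Passed to [v_ratio()].
#' @return List with `values`, `mean`, `var`, `n_iter`, `seed`.
#' @export
vratio_null <- function(pool, S, n_iter = 1000, seed = 1,
                        denominator = "unbiased") {
  if (S < 3) stop("null communities need S >= 3")
  if (length(pool) < S) stop("pool smaller than community richness")
  if (n_iter < 100) stop("use at least 100 null iterations")
  values <- .with_substream(seed, "vratio-null", {
    replicate(n_iter, v_ratio(sample(as.numeric(pool), S),
                              denominator = denominator))
  })
  list(values = values, mean = mean(values), var = stats::var(values),
       n_iter = n_iter, seed = seed)
}

#' Standardized effect size against a null distribution
#'
#' @param observed Observed statistic.
#' @param null_mean,null_var Null-sample mean and variance.
#' @return `(observed - null_mean) / sqrt(null_var)`.
#' @export
standardized_effect_size <- function(observed, null_mean, null_var) {
  if (is.na(null_var) || null_var <= 0)
    stop("null variance must be positive for SES")
  (observed - null_mean) / sqrt(null_var)
}

#' SES and inclusive tail probabilities for an observed V-ratio
#'
#' Tails are inclusive (the observed value counts in both), so
#' `p_lower + p_upper >= 1`.
#'
#' @param observed Observed V-ratio.
#' @param null A null sample (list from [vratio_null()] or a numeric
#'   vector of null values).
#' @return List with `ses`, `p_lower`, `p_upper`, `null_mean`,
#'   `null_var`.
#' @export
ses_tails <- function(observed, null) {
  values <- if (is.list(null)) null$values else as.numeric(null)
  nm <- mean(values); nv <- stats::var(values)
  list(ses = standardized_effect_size(observed, nm, nv),
       p_lower = mean(values <= observed),
       p_upper = mean(values >= observed),
       null_mean = nm, null_var = nv)
}

#' Null-model test of community body-size spacing
#'
#' Full pipeline for one community: observed V-ratio, source-pool
#' construction, Monte-Carlo null, SES and inclusive tails.
#'
#' @param community_masses Masses of the community members (>= 3).
#' @param all_masses Archipelago `body_mass_table` or mass vector.
#' @param community Community identifier for reporting.
#' @inheritParams build_source_pool
#' @inheritParams vratio_null
#' @return An object of class `vratio_result`.
#' @export
vratio_test <- function(community_masses, all_masses,
                        community = "community", n_hypothetical = 5,
                        n_iter = 1000, seed = 1,
                        denominator = "unbiased") {
  obs <- v_ratio(community_masses, denominator = denominator)
  pool <- build_source_pool(all_masses, community_masses,
                            n_hypothetical = n_hypothetical, seed = seed)
  null <- vratio_null(pool, length(community_masses), n_iter = n_iter,
                      seed = seed, denominator = denominator)
  st <- ses_tails(obs, null)
  structure(list(community = community,
                 richness = length(community_masses),
                 observed_v = obs, null_mean = st$null_mean,
                 null_var = st$null_var, p_lower = st$p_lower,
                 p_upper = st$p_upper, ses = st$ses,
                 n_iter = n_iter, seed = seed,
                 pool_size = length(pool)),
            class = "vratio_result")
}

#' @export
print.vratio_result <- function(x, ...) {
  cat("V-ratio null-model test: ", x$community, " (S = ", x$richness,
      ")\n", sep = "")
  cat(sprintf("  observed V %.4g | null mean %.4g, var %.4g (%d iterations, seed %d)\n",
              x$observed_v, x$null_mean, x$null_var, x$n_iter, x$seed))
  cat(sprintf("  SES %.3f | P(lower) %.3f, P(upper) %.3f\n",
              x$ses, x$p_lower, x$p_upper))
  invisible(x)
}

#' Pearson correlation between richness and observed V-ratio
#'
#' @param results A data frame with columns `richness` and `observed_v`
#'   (a list of `vratio_result`s is also accepted), e.g.
#'   [island_vratio_reference()].
#' @param exclude Optional community/island identifiers to drop (the
#'   first column, or `community` field, is matched).
#' @return List of class `cor_report` with `r`, `t`, `df`, `p`, `n`.
#' @export
richness_vratio_correlation <- function(results, exclude = NULL) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "vratio_result"))) {
    results <- data.frame(
      community = vapply(results, `[[`, character(1), "community"),
      richness = vapply(results, `[[`, numeric(1), "richness"),
      observed_v = vapply(results, `[[`, numeric(1), "observed_v"))
  }
  if (!is.null(exclude)) {
    id <- if ("community" %in% names(results)) results$community
          else results[[1]]
    results <- results[!id %in% exclude, , drop = FALSE]
  }
  n <- nrow(results)
  if (n < 3) stop("need at least 3 communities")
  s <- results$richness; v <- results$observed_v
  if (stats::sd(s) == 0 || stats::sd(v) == 0)
    stop("zero variance in richness or V-ratio")
  r <- stats::cor(s, v)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(r = r, t = t, df = df, p = p, n = n,
                 excluded = exclude), class = "cor_report")
}

#' @export
print.cor_report <- function(x, ...) {
  cat(sprintf("Pearson correlation: R = %.3f, t = %.3f, df = %d, P = %.3g (n = %d)\n",
              x$r, x$t, x$df, x$p, x$n))
  if (!is.null(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
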