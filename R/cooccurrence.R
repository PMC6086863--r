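# Exact probabilistic pairwise co-occurrence. Two species occupying n_a
# and n_b of N sites, placed independently and uniformly, share j sites
# with hypergeometric probability
#   P(j) = C(n_a, j) C(N - n_a, n_b - j) / C(N, n_b)
# on the support max(0, n_a + n_b - N) <= j <= min(n_a, n_b). Observed
# co-occurrence is compared with this distribution directly; no matrix
# randomization is involved.

#' Probability mass of shared sites for a species pair
#'
#' @param n_sites Total number of sites N.
#' @param n_a,n_b Number of sites occupied by each species.
#' @param j Number of shared sites (vectorised).
#' @return `P(j)`; zero off-support. Computed with log-factorial
#'   combinatorics, accurate to well below 1e-12 at the matrix sizes in
#'   range here.
#' @export
cooccur_pmf <- function(n_sites, n_a, n_b, j) {
  stopifnot(length(n_sites) == 1, length(n_a) == 1, length(n_b) == 1)
  if (n_sites < 1 || n_a < 0 || n_b < 0 || n_a > n_sites || n_b > n_sites)
    stop("need 0 <= n_a, n_b <= n_sites with n_sites >= 1")
  lo <- max(0, n_a + n_b - n_sites)
  hi <- min(n_a, n_b)
  p <- numeric(length(j))
  ok <- j >= lo & j <= hi & j == round(j)
  p[ok] <- exp(lchoose(n_a, j[ok]) + lchoose(n_sites - n_a, n_b - j[ok]) -
                 lchoose(n_sites, n_b))
  p
}

#' Support of the shared-site distribution
#' @inheritParams cooccur_pmf
#' @return Integer vector of attainable co-occurrence counts.
#' @export
cooccur_support <- function(n_sites, n_a, n_b) {
  seq.int(max(0, n_a + n_b - n_sites), min(n_a, n_b))
}

#' Expected co-occurrence of a species pair
#'
#' The mean of the shared-site distribution, `n_a * n_b / n_sites`.
#'
#' @inheritParams cooccur_pmf
#' @return Expected number of shared sites.
#' @export
expected_cooccur <- function(n_sites, n_a, n_b) {
  if (n_sites == 0) stop("n_sites must be positive")
  if (n_a < 0 || n_b < 0 || n_a > n_sites || n_b > n_sites)
    stop("need 0 <= n_a, n_b <= n_sites")
  n_a * n_b / n_sites
}

#' Classify one species pair
#'
#' Implements the decision rule of the probabilistic co-occurrence
#' analysis: pairs whose expected co-occurrence falls below
#' `min_expected` are removed; otherwise a pair is positive (negative)
#' when the inclusive upper (lower) tail probability of its observed
#' shared-site count is below `alpha`; a non-significant pair is random
#' when the observed count deviates from expectation by at most
#' `random_band * n_sites` sites, else unclassifiable. The standardized
#' effect size is `(j_obs - expected) / n_sites`, bounded in [-1, 1].
#'
#' @inheritParams cooccur_pmf
#' @param j_obs Observed number of shared sites.
#' @param alpha Significance level (default 0.05).
#' @param random_band Fraction of sites within which a deviation counts
#'   as random (default 0.1).
#' @param min_expected Removal threshold on expected co-occurrence
#'   (default 1).
#' @return A one-row data frame with counts, `expected`, inclusive tail
#'   probabilities `p_lt` and `p_gt`, `ses`, and `classification`.
#' @export
classify_pair <- function(n_sites, n_a, n_b, j_obs, alpha = 0.05,
                          random_band = 0.1, min_expected = 1) {
  support <- cooccur_support(n_sites, n_a, n_b)
  if (j_obs < min(support) || j_obs > max(support))
    stop("observed co-occurrence ", j_obs, " outside attainable range [",
         min(support), ", ", max(support), "]")
  pmf <- cooccur_pmf(n_sites, n_a, n_b, support)
  expected <- expected_cooccur(n_sites, n_a, n_b)
  p_lt <- sum(pmf[support <= j_obs])
  p_gt <- sum(pmf[support >= j_obs])
  ses <- (j_obs - expected) / n_sites
  classification <-
    if (expected < min_expected) "removed"
    else if (p_gt < alpha) "positive"
    else if (p_lt < alpha) "negative"
    else if (abs(j_obs - expected) <= random_band * n_sites) "random"
    else "unclassifiable"
  data.frame(n_sites = n_sites, n_a = n_a, n_b = n_b, j_obs = j_obs,
             expected = expected, p_lt = p_lt, p_gt = p_gt, ses = ses,
             classification = classification, stringsAsFactors = FALSE)
}

.cooccur_classes <- c("positive", "negative", "random", "unclassifiable",
                      "removed")

#' Pairwise co-occurrence analysis of a presence-absence matrix
#'
#' Enumerates all unordered species pairs, classifies each with
#' [classify_pair()], and tallies the classes. Removed pairs (expected
#' co-occurrence below `min_expected`) are kept in the output with
#' `classification = "removed"` rather than silently dropped.
#'
#' @param x A `pa_matrix` (or coercible 0/1 matrix), species in rows.
#' @inheritParams classify_pair
#' @return An object of class `cooccur_analysis`: list with `pairs`
#'   (one row per pair) and `summary` (class counts), plus the
#'   thresholds used.
#' @export
cooccur_analyze <- function(x, alpha = 0.05, random_band = 0.1,
                            min_expected = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 species")
  # lighter checks than the pa_matrix reader invariants: an analysis
  # matrix may legitimately carry an unused column (e.g. an empty guild
  # category), which a field presence-absence file may not
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("SP%03d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate species labels")
  if (anyNA(x) || !all(x == 0 | x == 1)) stop("matrix cells must be 0/1")
  sp <- rownames(x)
  n_sites <- ncol(x)
  occ <- rowSums(x)
  idx <- utils::combn(length(sp), 2)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    a <- idx[1, k]; b <- idx[2, k]
    j_obs <- sum(x[a, ] & x[b, ])
    r <- classify_pair(n_sites, occ[[a]], occ[[b]], j_obs, alpha = alpha,
                       random_band = random_band,
                       min_expected = min_expected)
    rows[[k]] <- cbind(data.frame(species_a = sp[a], species_b = sp[b],
                                  stringsAsFactors = FALSE), r)
  }
  pairs <- do.call(rbind, rows)
  counts <- table(factor(pairs$classification, levels = .cooccur_classes))
  summary <- data.frame(
    n_species = nrow(x), n_sites = n_sites,
    n_pairs_total = ncol(idx),
    n_removed = as.integer(counts[["removed"]]),
    n_positive = as.integer(counts[["positive"]]),
    n_negative = as.integer(counts[["negative"]]),
    n_random = as.integer(counts[["random"]]),
    n_unclassifiable = as.integer(counts[["unclassifiable"]]))
  structure(list(pairs = pairs, summary = summary,
                 thresholds = list(alpha = alpha, random_band = random_band,
                                   min_expected = min_expected)),
            class = "cooccur_analysis")
}

#' @export
print.cooccur_analysis <- function(x, ...) {
  s <- x$summary
  cat("Probabilistic co-occurrence analysis\n")
  cat("  ", s$n_species, " species x ", s$n_sites, " sites; ",
      s$n_pairs_total, " pairs (", s$n_removed,
      " removed, expected < ", x$thresholds$min_expected, ")\n", sep = "")
  cat(sprintf("  positive %d | negative %d | random %d | unclassifiable %d  (alpha = %g, random band = %g x sites)\n",
              s$n_positive, s$n_negative, s$n_random, s$n_unclassifiable,
              x$thresholds$alpha, x$thresholds$random_band))
  invisible(x)
}

#' @export
summary.cooccur_analysis <- function(object, ...) object$summary
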