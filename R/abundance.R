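#' Construct a community abundance vector
#'
#' Per-species counts for one community, ranked in descending order of
#' abundance. Carries total abundance N and richness S as attributes.
#'
#' @param x Positive integer counts (optionally named by species).
#' @param community Community identifier.
#' @return A sorted numeric vector of class `abundance_vector` with
#'   attributes `community`, `N` and `S`.
#' @export
abundance_vector <- function(x, community = "community") {
  nm <- names(x)
  x <- stats::setNames(as.numeric(x), nm)
  if (length(x) == 0) stop("empty abundance vector for '", community, "'")
  if (anyNA(x) || any(x < 1) || any(x != round(x)))
    stop("abundances must be positive integers")
  ord <- order(x, decreasing = TRUE)
  structure(x[ord], names = names(x)[ord], community = community,
            N = sum(x), S = length(x), class = "abundance_vector")
}

#' Pool quadrat counts into community abundance vectors
#'
#' Sums each species' counts over all quadrats assigned to a community;
#' species never recorded in the community are dropped.
#'
#' @param qc A `quadrat_counts` table.
#' @param communities Communities to pool; default all present.
#' @return A named list of `abundance_vector`s.
#' @export
aggregate_abundances <- function(qc, communities = NULL) {
  qc <- if (inherits(qc, "quadrat_counts")) qc
        else quadrat_counts(as.data.frame(qc))
  if (is.null(communities)) communities <- unique(qc$community)
  unknown <- setdiff(communities, qc$community)
  if (length(unknown) > 0)
    stop("unknown communit(ies): ", paste(unknown, collapse = ", "))
  out <- lapply(communities, function(cm) {
    sub <- qc[qc$community == cm, ]
    tot <- tapply(sub$count, sub$species, sum)
    tot <- tot[tot > 0]
    if (length(tot) == 0)
      stop("community '", cm, "' has no individuals")
    abundance_vector(tot, community = cm)
  })
  names(out) <- communities
  out
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("Abundance vector '", attr(x, "community"), "': S = ", attr(x, "S"),
      ", N = ", attr(x, "N"), "\n", sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}
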