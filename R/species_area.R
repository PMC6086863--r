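#' Power-law species-area regression
#'
#' Ordinary least squares of log10 species richness on log10 island
#' area, the classical `S = c A^z` relationship on log-log axes. Used as
#' a check for intrinsic differences between island sets: similar slopes
#' `z` across archipelago subsets indicate no gross differences in
#' habitat suitability or colonisation history. The slope, R-squared and
#' F statistic are invariant to the logarithm base.
#'
#' @param attrs An `island_attributes` table (or data frame with
#'   `island`, `area`, `richness`), at least 3 islands.
#' @param base Logarithm base (default 10).
#' @return An object of class `species_area_fit` with fields `slope_z`,
#'   `intercept`, `r_squared`, `f_stat`, `df_resid` and the underlying
#'   `lm` fit.
#' @export
fit_species_area <- function(attrs, base = 10) {
  attrs <- if (inherits(attrs, "island_attributes")) attrs
           else island_attributes(as.data.frame(attrs))
  n <- nrow(attrs)
  if (n < 3) stop("need at least 3 islands (residual df would be <= 0)")
  la <- log(attrs$area, base = base)
  lr <- log(attrs$richness, base = base)
  if (stats::sd(la) == 0) stop("zero variance in log island area")
  fit <- stats::lm(lr ~ la)
  # a perfect power law is a legitimate input; silence summary.lm's
  # "essentially perfect fit" note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope_z = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 f_stat = (n - 2) * r2 / (1 - r2),
                 df_resid = n - 2L, n = n, lm = fit),
            class = "species_area_fit")
}

#' Island attributes from a presence-absence matrix
#'
#' Convenience: richness as column sums of a `pa_matrix`, joined to a
#' table of island areas.
#'
#' @param pa A `pa_matrix`.
#' @param areas Data frame with `island` and `area` columns.
#' @return An `island_attributes` table.
#' @export
island_attributes_from_matrix <- function(pa, areas) {
  rich <- colSums(pa)
  m <- match(colnames(pa), areas$island)
  if (anyNA(m))
    stop("no area for island(s): ",
         paste(colnames(pa)[is.na(m)], collapse = ", "))
  island_attributes(data.frame(island = colnames(pa),
                               area = areas$area[m],
                               richness = as.integer(rich)))
}

#' @export
print.species_area_fit <- function(x, ...) {
  cat(sprintf("Species-area power law: z = %.3f, intercept = %.3f\n",
              x$slope_z, x$intercept))
  cat(sprintf("  R^2 = %.3f, F = %.2f, residual df = %d (n = %d islands)\n",
              x$r_squared, x$f_stat, x$df_resid, x$n))
  invisible(x)
}

#' @export
coef.species_area_fit <- function(object, ...) {
  c(intercept = object$intercept, slope_z = object$slope_z)
}

#' @export
plot.species_area_fit <- function(x, ...) {
  d <- x$lm$model
  plot(d$la, d$lr, xlab = "log10 area", ylab = "log10 richness",
       pch = 19, ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}
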