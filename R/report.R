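#' Write an analysis report to delimited files
#'
#' Assembles the stage outputs of a run into the standard report
#' layout: per-pair classifications plus a class-count summary for each
#' co-occurrence analysis, the AIC-sorted SAD model ranking per
#' community, one row per community of V-ratio results, and a run
#' metadata block recording seeds, iteration counts and thresholds.
#'
#' @param results Named list with any of: `cooccurrence` (a
#'   `cooccur_analysis` or named list of them), `sad` (a `sad_ranking`
#'   or named list of them), `vratio` (a `vratio_result` or list of
#'   them), `species_area` (a `species_area_fit` or list). At least one
#'   stage must be present.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  stages <- intersect(names(results),
                      c("cooccurrence", "sad", "vratio", "species_area"))
  if (length(stages) == 0)
    stop("no stage results to report; expected at least one of ",
         "cooccurrence/sad/vratio/species_area")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  as_named_list <- function(x, cls) {
    if (inherits(x, cls)) list(result = x) else x
  }
  paths <- character(0)
  meta <- c(sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  if ("cooccurrence" %in% stages) {
    co <- as_named_list(results$cooccurrence, "cooccur_analysis")
    pairs <- do.call(rbind, lapply(names(co), function(nm)
      cbind(analysis = nm, co[[nm]]$pairs)))
    summ <- do.call(rbind, lapply(names(co), function(nm)
      cbind(analysis = nm, co[[nm]]$summary)))
    p1 <- file.path(dir, "pair_classifications.csv")
    p2 <- file.path(dir, "cooccurrence_summary.csv")
    utils::write.csv(pairs, p1, row.names = FALSE)
    utils::write.csv(summ, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
    for (nm in names(co)) {
      th <- co[[nm]]$thresholds
      meta <- c(meta, sprintf(
        "cooccurrence[%s]: %d species x %d sites; alpha=%g random_band=%g min_expected=%g",
        nm, co[[nm]]$summary$n_species, co[[nm]]$summary$n_sites,
        th$alpha, th$random_band, th$min_expected))
    }
  }
  if ("sad" %in% stages) {
    sad <- as_named_list(results$sad, "sad_ranking")
    rk <- do.call(rbind, lapply(names(sad), function(nm)
      cbind(community = nm, as.data.frame(sad[[nm]]))))
    p <- file.path(dir, "sad_ranking.csv")
    utils::write.csv(rk, p, row.names = FALSE)
    paths <- c(paths, p)
    meta <- c(meta, sprintf("sad: %d communit(ies), models ranked by AIC",
                            length(sad)))
  }
  if ("vratio" %in% stages) {
    vr <- if (inherits(results$vratio, "vratio_result"))
      list(results$vratio) else results$vratio
    tab <- do.call(rbind, lapply(vr, function(v)
      data.frame(community = v$community, richness = v$richness,
                 observed_v = v$observed_v, null_mean = v$null_mean,
                 null_var = v$null_var, p_lower = v$p_lower,
                 p_upper = v$p_upper, ses = v$ses, n_iter = v$n_iter,
                 seed = v$seed)))
    p <- file.path(dir, "vratio.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    meta <- c(meta, sprintf("vratio: %d communit(ies); n_iter=%s seed=%s",
                            nrow(tab),
                            paste(unique(tab$n_iter), collapse = "/"),
                            paste(unique(tab$seed), collapse = "/")))
  }
  if ("species_area" %in% stages) {
    sa <- as_named_list(results$species_area, "species_area_fit")
    tab <- do.call(rbind, lapply(names(sa), function(nm) {
      f <- sa[[nm]]
      data.frame(island_set = nm, slope_z = f$slope_z,
                 intercept = f$intercept, r_squared = f$r_squared,
                 f_stat = f$f_stat, df_resid = f$df_resid)
    }))
    p <- file.path(dir, "species_area.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    meta <- c(meta, sprintf("species_area: %d island set(s)", nrow(tab)))
  }
  pm <- file.path(dir, "run_metadata.txt")
  writeLines(meta, pm)
  paths <- c(paths, pm)
  invisible(paths)
}
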