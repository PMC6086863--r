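# Guild co-occurrence: the same exact pairwise analysis run on a species
# x guild-category matrix with the four columns Arboreal, Terrestrial,
# Diurnal, Nocturnal. Every species carries exactly one habitat and one
# activity class, so every row sums to 2 and every pair has expected
# co-occurrence 2*2/4 = 1: no pair is removed, and with the lower bound
# of the tail probabilities at 1/6 > 0.05 no pair can ever be
# significant. Pairs sharing exactly one category are random, pairs
# sharing both or neither are unclassifiable.

.guild_categories <- c("Arboreal", "Terrestrial", "Diurnal", "Nocturnal")

#' Build the guild membership matrix
#'
#' @param guilds A `guild_table` (or data frame with `species`,
#'   `habitat`, `activity`).
#' @return A binary species x 4 matrix of class `guild_matrix` over the
#'   columns Arboreal, Terrestrial, Diurnal, Nocturnal; every row sums
#'   to 2.
#' @export
build_guild_matrix <- function(guilds) {
  guilds <- if (inherits(guilds, "guild_table")) guilds
            else guild_table(as.data.frame(guilds))
  m <- matrix(0L, nrow = nrow(guilds), ncol = 4,
              dimnames = list(guilds$species, .guild_categories))
  m[cbind(seq_len(nrow(guilds)), match(guilds$habitat, .guild_categories))] <- 1L
  m[cbind(seq_len(nrow(guilds)), match(guilds$activity, .guild_categories))] <- 1L
  stopifnot(all(rowSums(m) == 2))
  class(m) <- c("guild_matrix", class(unclass(m)))
  m
}

#' Guild co-occurrence analysis
#'
#' Runs [cooccur_analyze()] on the guild membership matrix (4 "sites").
#'
#' @param guilds A `guild_table`, guild data frame, or a prebuilt
#'   `guild_matrix`.
#' @inheritParams classify_pair
#' @return A `cooccur_analysis` over the guild matrix.
#' @export
guild_cooccur <- function(guilds, alpha = 0.05, random_band = 0.1,
                          min_expected = 1) {
  gm <- if (inherits(guilds, "guild_matrix")) guilds
        else build_guild_matrix(guilds)
  cooccur_analyze(unclass(gm), alpha = alpha, random_band = random_band,
                  min_expected = min_expected)
}

.inference_tags <- c("historical_allopatry", "common_history",
                     "competition_consistent", "uninformative")

#' Cross-classify geographic and guild co-occurrence outcomes
#'
#' Confronts each species pair's geographic classification with its
#' guild classification to separate signatures of dispersal history from
#' those of ecological interaction: a geographically negative pair that
#' is not positively associated by guild is tagged historical allopatry
#' (lineages kept apart by barriers, no interaction needed); a
#' geographically positive pair with random/unclassifiable guild outcome
#' is tagged common history (shared colonisation, not habitat
#' filtering); a geographically negative but guild-positive pair is the
#' pattern competition would produce. Everything else is uninformative.
#'
#' @param geo,guild `cooccur_analysis` objects over the same species
#'   universe (geographic sites and guild categories respectively).
#' @return An object of class `interaction_crosstab`: the per-pair tags
#'   and the 5 x 5 contingency table of (geographic, guild)
#'   classifications.
#' @export
cross_classify <- function(geo, guild) {
  stopifnot(inherits(geo, "cooccur_analysis"),
            inherits(guild, "cooccur_analysis"))
  key <- function(p) paste(pmin(p$species_a, p$species_b),
                           pmax(p$species_a, p$species_b), sep = "\r")
  gk <- key(geo$pairs); uk <- key(guild$pairs)
  common <- intersect(gk, uk)
  only <- c(setdiff(gk, uk), setdiff(uk, gk))
  if (length(only) > 0)
    message(length(only),
            " pair(s) present in only one analysis; counted in margins")
  gcl <- geo$pairs$classification[match(common, gk)]
  ucl <- guild$pairs$classification[match(common, uk)]
  tag <- ifelse(gcl == "negative" & ucl == "positive", "competition_consistent",
         ifelse(gcl == "negative" & ucl != "positive", "historical_allopatry",
         ifelse(gcl == "positive" & ucl %in% c("random", "unclassifiable"),
                "common_history", "uninformative")))
  pairs <- data.frame(species_a = geo$pairs$species_a[match(common, gk)],
                      species_b = geo$pairs$species_b[match(common, gk)],
                      geographic = gcl, guild = ucl, inference = tag,
                      stringsAsFactors = FALSE)
  counts <- table(geographic = factor(gcl, levels = .cooccur_classes),
                  guild = factor(ucl, levels = .cooccur_classes))
  structure(list(pairs = pairs, counts = counts,
                 unmatched = length(only)),
            class = "interaction_crosstab")
}

#' @export
print.interaction_crosstab <- function(x, ...) {
  cat("Geographic x guild co-occurrence cross-classification (",
      nrow(x$pairs), " pairs)\n", sep = "")
  print(x$counts)
  cat("Inference tags:\n")
  print(table(factor(x$pairs$inference, levels = .inference_tags)))
  invisible(x)
}
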