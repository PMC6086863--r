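# Readers for the tabular inputs: guild membership, body mass, island
# attributes, quadrat counts, plus run configuration. All are plain
# delimited text with a header row; validation is total and errors name
# the offending rows.

.habitat_levels  <- c("Arboreal", "Terrestrial")
.activity_levels <- c("Diurnal", "Nocturnal")

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
}

#' Read a guild table
#'
#' Each species is assigned one habitat class (Arboreal or Terrestrial)
#' and one diel activity class (Diurnal or Nocturnal); the cross of the
#' two defines its guild.
#'
#' @param path Delimited file with columns `species`, `habitat`,
#'   `activity`.
#' @param sep Field delimiter.
#' @return A validated data frame of class `guild_table`.
#' @export
read_guild_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .require_columns(df, c("species", "habitat", "activity"), path)
  guild_table(df)
}

#' @rdname read_guild_table
#' @param df A data frame with the same columns, built in code.
#' @export
guild_table <- function(df) {
  if (anyDuplicated(df$species))
    stop("duplicated species in guild table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  bad_h <- !df$habitat %in% .habitat_levels
  if (any(bad_h))
    stop("unknown habitat value(s) ",
         paste(unique(df$habitat[bad_h]), collapse = ", "),
         "; allowed: ", paste(.habitat_levels, collapse = ", "))
  bad_a <- !df$activity %in% .activity_levels
  if (any(bad_a))
    stop("unknown activity value(s) ",
         paste(unique(df$activity[bad_a]), collapse = ", "),
         "; allowed: ", paste(.activity_levels, collapse = ", "))
  if (anyNA(df[c("species", "habitat", "activity")]))
    stop("guild table has missing values")
  structure(df[c("species", "habitat", "activity")],
            class = c("guild_table", "data.frame"))
}

#' Read a body-mass table
#'
#' @param path Delimited file with columns `species` and `mass` (grams,
#'   species-level mean, strictly positive).
#' @param sep Field delimiter.
#' @return A validated data frame of class `body_mass_table`.
#' @export
read_body_mass <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .require_columns(df, c("species", "mass"), path)
  body_mass_table(df)
}

#' @rdname read_body_mass
#' @param df A data frame with the same columns, built in code.
#' @export
body_mass_table <- function(df) {
  if (anyDuplicated(df$species))
    stop("duplicated species in body-mass table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  bad <- is.na(df$mass) | df$mass <= 0
  if (any(bad))
    stop("non-positive or missing mass for: ",
         paste(df$species[bad], collapse = ", "))
  structure(df[c("species", "mass")],
            class = c("body_mass_table", "data.frame"))
}

#' Read an island attribute table
#'
#' @param path Delimited file with columns `island`, `area` (km^2,
#'   positive) and `richness` (positive integer).
#' @param sep Field delimiter.
#' @return A validated data frame of class `island_attributes`.
#' @export
read_island_attributes <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .require_columns(df, c("island", "area", "richness"), path)
  island_attributes(df)
}

#' @rdname read_island_attributes
#' @param df A data frame with the same columns, built in code.
#' @export
island_attributes <- function(df) {
  if (anyDuplicated(df$island))
    stop("duplicated island labels: ",
         paste(unique(df$island[duplicated(df$island)]), collapse = ", "))
  bad_a <- is.na(df$area) | df$area <= 0
  if (any(bad_a))
    stop("non-positive area for island(s): ",
         paste(df$island[bad_a], collapse = ", "))
  bad_r <- is.na(df$richness) | df$richness < 1 |
    df$richness != round(df$richness)
  if (any(bad_r))
    stop("richness must be a positive integer; offending island(s): ",
         paste(df$island[bad_r], collapse = ", "))
  structure(df[c("island", "area", "richness")],
            class = c("island_attributes", "data.frame"))
}

#' Read quadrat counts
#'
#' Counts of individuals per species per bounded quadrat (100 m^2), the
#' raw material for community abundance vectors.
#'
#' @param path Delimited file with columns `community`, `quadrat`,
#'   `species`, `count`.
#' @param sep Field delimiter.
#' @return A validated data frame of class `quadrat_counts`.
#' @export
read_quadrat_counts <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .require_columns(df, c("community", "quadrat", "species", "count"), path)
  quadrat_counts(df)
}

#' @rdname read_quadrat_counts
#' @param df A data frame with the same columns, built in code.
#' @export
quadrat_counts <- function(df) {
  bad <- is.na(df$count) | df$count < 0 | df$count != round(df$count)
  if (any(bad))
    stop("counts must be non-negative integers; offending rows: ",
         paste(which(bad), collapse = ", "))
  key <- paste(df$community, df$quadrat, df$species, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (community, quadrat, species) rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  structure(df[c("community", "quadrat", "species", "count")],
            class = c("quadrat_counts", "data.frame"))
}

#' Read a run configuration
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON. Recognised keys: `alpha`,
#' `random_band`, `min_expected`, `n_iter`, `n_hypothetical`, `seed`.
#' Unset keys take the defaults the analyses use.
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @return A named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(alpha = 0.05, random_band = 0.1, min_expected = 1,
                   n_iter = 1000, n_hypothetical = 5, seed = 1L)
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}
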