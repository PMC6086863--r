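# Seeded generators of synthetic communities with the statistical
# structure each analysis stage assumes: two-block allopatric
# metacommunities, nested "common history" archipelagos, abundance
# vectors from known SADs, and size assemblages drawn randomly or
# evenly spaced on the log-mass axis. Every generator records its
# (scenario, parameters, seed) in a `synth_spec` attribute and is
# bit-reproducible under the same seed.

.synth_spec <- function(x, scenario, parameters, seed) {
  attr(x, "synth_spec") <- list(scenario = scenario,
                                parameters = parameters, seed = seed)
  x
}

.redraw_until_valid <- function(draw, max_tries = 100, what = "matrix") {
  for (i in seq_len(max_tries)) {
    m <- draw()
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
  stop("could not generate a ", what, " without empty rows/columns in ",
       max_tries, " tries; the scenario is too sparse")
}

#' Generate a block-allopatric presence-absence matrix
#'
#' Emulates a metacommunity whose groups of islands were colonised
#' independently: each group's endemic species occur (independently with
#' probability `occupancy`) only on that group's islands, while
#' `shared_species` species range across all islands. Any empty
#' row/column triggers a bounded redraw.
#'
#' @param n_groups Number of island groups (default 2).
#' @param species_per_group Endemic species per group.
#' @param islands_per_group Islands per group.
#' @param shared_species Species occurring across all groups.
#' @param occupancy Per-island occupancy probability in (0, 1].
#' @param seed Integer seed.
#' @return A `pa_matrix` of
#'   `n_groups * species_per_group + shared_species` species by
#'   `n_groups * islands_per_group` islands.
#' @export
gen_allopatric_matrix <- function(n_groups = 2, species_per_group = 8,
                                  islands_per_group = 10,
                                  shared_species = 1, occupancy = 0.6,
                                  seed = 1) {
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  n_sp <- n_groups * species_per_group + shared_species
  n_is <- n_groups * islands_per_group
  sp <- c(paste0("G", rep(seq_len(n_groups), each = species_per_group),
                 "S", rep(seq_len(species_per_group), n_groups)),
          if (shared_species > 0) paste0("SH", seq_len(shared_species)))
  isl <- paste0("G", rep(seq_len(n_groups), each = islands_per_group),
                "I", rep(seq_len(islands_per_group), n_groups))
  group_of_island <- rep(seq_len(n_groups), each = islands_per_group)
  group_of_species <- c(rep(seq_len(n_groups), each = species_per_group),
                        rep(0L, shared_species))  # 0 = shared
  m <- .with_substream(seed, "allopatric", {
    .redraw_until_valid(function() {
      cells <- matrix(0L, n_sp, n_is, dimnames = list(sp, isl))
      for (i in seq_len(n_sp)) {
        range <- if (group_of_species[i] == 0L) seq_len(n_is)
                 else which(group_of_island == group_of_species[i])
        cells[i, range] <- as.integer(stats::runif(length(range)) < occupancy)
      }
      cells
    })
  })
  .synth_spec(pa_matrix(m), "allopatric",
              list(n_groups = n_groups,
                   species_per_group = species_per_group,
                   islands_per_group = islands_per_group,
                   shared_species = shared_species, occupancy = occupancy),
              seed)
}

#' Generate a nested "common history" presence-absence matrix
#'
#' Emulates an archipelago assembled by fragmentation of one landmass:
#' poorer islands hold subsets of richer islands' faunas. Each species
#' gets a prevalence `k_i ~ 1 + Binomial(n_islands - 1, occupancy)`; in
#' the perfectly nested template it occupies the `k_i` first islands
#' (islands ordered richest to poorest). Each cell is then occupied with
#' probability `nestedness * template + (1 - nestedness) * occupancy`,
#' so `nestedness = 1` yields a strictly nested matrix and
#' `nestedness = 0` independent occupancy.
#'
#' @param n_species,n_islands Matrix dimensions.
#' @param nestedness Ordering strength in [0, 1].
#' @param occupancy Expected fill in (0, 1).
#' @param seed Integer seed.
#' @return A `pa_matrix`.
#' @export
gen_common_history_matrix <- function(n_species = 15, n_islands = 12,
                                      nestedness = 1, occupancy = 0.5,
                                      seed = 1) {
  if (nestedness < 0 || nestedness > 1) stop("nestedness must be in [0, 1]")
  if (occupancy <= 0 || occupancy >= 1) stop("occupancy must be in (0, 1)")
  sp <- sprintf("SP%02d", seq_len(n_species))
  isl <- sprintf("I%02d", seq_len(n_islands))
  m <- .with_substream(seed, "common-history", {
    .redraw_until_valid(function() {
      k <- 1L + stats::rbinom(n_species, n_islands - 1L, occupancy)
      # the widest-ranging species spans the whole archipelago, so even
      # the poorest island is non-empty in the fully nested template
      k[which.max(k)] <- n_islands
      template <- outer(k, seq_len(n_islands), function(ki, j) (j <= ki) + 0)
      p <- nestedness * template + (1 - nestedness) * occupancy
      matrix(as.integer(stats::runif(n_species * n_islands) < p),
             n_species, n_islands, dimnames = list(sp, isl))
    })
  })
  .synth_spec(pa_matrix(m), "common_history",
              list(n_species = n_species, n_islands = n_islands,
                   nestedness = nestedness, occupancy = occupancy),
              seed)
}

.round_half_up <- function(x) floor(x + 0.5)

.largest_remainder <- function(x, total) {
  f <- floor(x)
  r <- as.integer(round(total - sum(f)))
  if (r > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(r)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Sample an abundance vector from a Pareto SAD
#'
#' Inverse-CDF draws `x_i = round(a * U_i^(-1/b))` (half-up rounding),
#' ranked descending; the minimum is always at least the scale `a`.
#'
#' @param S Number of species.
#' @param scale Scale `a` (>= 1).
#' @param shape Shape `b` (> 0).
#' @param seed Integer seed.
#' @return An `abundance_vector`.
#' @export
gen_pareto_sample <- function(S, scale, shape, seed = 1) {
  if (scale < 1) stop("scale must be >= 1")
  if (shape <= 0) stop("shape must be positive")
  x <- .with_substream(seed, "pareto-sample", {
    .round_half_up(scale * stats::runif(S)^(-1 / shape))
  })
  .synth_spec(abundance_vector(x, community = "pareto_synth"),
              "pareto_sample",
              list(S = S, scale = scale, shape = shape), seed)
}

#' Sample an abundance vector from the broken-stick model
#'
#' S - 1 uniform cuts on (0, N); segment lengths are rounded to
#' integers summing exactly to N by largest-remainder correction and
#' ranked descending. Cut sets whose rounded segments include a zero
#' (possible only for short sticks) are redrawn, so every species keeps
#' a positive count and the sum-to-N conservation stays exact.
#'
#' @param N Total individuals.
#' @param S Number of species (N >= S >= 2).
#' @param seed Integer seed.
#' @return An `abundance_vector` summing exactly to `N`.
#' @export
gen_broken_stick_sample <- function(N, S, seed = 1) {
  if (S < 2 || N < S) stop("need N >= S >= 2")
  x <- .with_substream(seed, "broken-stick-sample", {
    for (i in 1:1000) {
      cuts <- sort(stats::runif(S - 1, 0, N))
      seg <- .largest_remainder(diff(c(0, cuts, N)), N)
      if (all(seg >= 1)) break
      seg <- NULL
    }
    if (is.null(seg))
      stop("could not cut a stick of length ", N, " into ", S,
           " positive integer segments")
    seg
  })
  .synth_spec(abundance_vector(x, community = "broken_stick_synth"),
              "broken_stick_sample", list(N = N, S = S), seed)
}

#' Draw a size assemblage from a mass pool
#'
#' `mode = "random"` draws `S` pool species uniformly without
#' replacement (passive sampling); `mode = "even_log_spaced"` picks, for
#' each point of an even grid on the log-mass axis, the nearest unused
#' pool species — the constant-ratio construction competition theory
#' predicts, yielding small V-ratios.
#'
#' @param pool Pool masses (grams).
#' @param S Community richness (<= pool size).
#' @param mode `"random"` or `"even_log_spaced"`.
#' @param seed Integer seed (used by `"random"` mode).
#' @return Numeric vector of `S` masses with a `synth_spec` attribute.
#' @export
gen_size_community <- function(pool, S, mode = c("random", "even_log_spaced"),
                               seed = 1) {
  mode <- match.arg(mode)
  pool <- as.numeric(pool)
  if (length(pool) < S) stop("pool smaller than requested richness")
  masses <- if (mode == "random") {
    .with_substream(seed, "size-community", sample(pool, S))
  } else {
    lp <- log(pool)
    grid <- seq(min(lp), max(lp), length.out = S)
    chosen <- integer(0)
    for (g in grid) {
      d <- abs(lp - g)
      d[chosen] <- Inf
      chosen <- c(chosen, which.min(d))
    }
    pool[chosen]
  }
  .synth_spec(masses, paste0("size_community_", mode),
              list(S = S, pool_size = length(pool), mode = mode), seed)
}
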