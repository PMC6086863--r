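# Independent oracles used across the suite.

# Exhaustive-enumeration oracle for the shared-site distribution: place
# species A on every possible set of n_a sites and species B on every
# possible set of n_b sites, and count shared sites. Returns frequencies
# over j = 0..min(n_a, n_b).
oracle_pmf <- function(n_sites, n_a, n_b) {
  sets_a <- if (n_a == 0) list(integer(0)) else
    asplit(utils::combn(n_sites, n_a), 2)
  sets_b <- if (n_b == 0) list(integer(0)) else
    asplit(utils::combn(n_sites, n_b), 2)
  counts <- integer(min(n_a, n_b) + 1)
  for (a in sets_a) {
    in_a <- logical(n_sites); in_a[a] <- TRUE
    for (b in sets_b) {
      j <- sum(in_a[b])
      counts[j + 1] <- counts[j + 1] + 1
    }
  }
  counts / (length(sets_a) * length(sets_b))
}

# Random valid guild table over n species.
random_guild_table <- function(n, seed) {
  set.seed(seed)
  guild_table(data.frame(
    species = sprintf("SP%02d", seq_len(n)),
    habitat = sample(c("Arboreal", "Terrestrial"), n, replace = TRUE),
    activity = sample(c("Diurnal", "Nocturnal"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# An archipelago-like body-mass table: 29 species spanning 0.5-84 g,
# log-uniform, endpoints pinned.
archipelago_masses <- function(seed = 42) {
  set.seed(seed)
  m <- exp(stats::runif(27, log(0.5), log(84)))
  body_mass_table(data.frame(
    species = sprintf("SP%02d", 1:29),
    mass = c(0.5, 84, m)))
}
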