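# Seed plumbing. One user-visible integer seed drives a named substream
# per generator/optimizer, so stages can be regenerated independently:
# the substream seed mixes the base seed with a polynomial hash of the
# stream name, reduced mod 2^31 - 1. Evaluation under a substream never
# disturbs the caller's RNG state.

.substream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

.with_substream <- function(seed, name, expr) {
  .with_seed(.substream_seed(seed, name), expr)
}
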