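---
title: "Null models for insular community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for insular community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullassembly)
```

Competitive niche partitioning is expected to leave three fingerprints
on a species assemblage: ecologically similar species should co-occur
less than chance expects, abundance should be divided as if a common
resource axis were being partitioned, and co-existing species should
space their body sizes at roughly constant ratios. **nullassembly**
implements the three corresponding null-model screens for island
assemblages — exact probabilistic co-occurrence, maximum-likelihood
species-abundance-distribution (SAD) model selection, and a body-size
V-ratio randomization — together with seeded synthetic-community
generators that let every stage be validated without field data. This
vignette is the package's account of the statistical machinery: the
models, the tunable parameters, the numerical choices, and the points
where the design was genuinely open.

## Exact probabilistic co-occurrence

For a pair of species occupying `n_a` and `n_b` of `N` islands, with
placements treated as uniform and independent, the number `j` of shared
islands is hypergeometric:

$$P(j) = \frac{\binom{n_a}{j}\binom{N-n_a}{n_b-j}}{\binom{N}{n_b}},
\qquad \max(0, n_a+n_b-N) \le j \le \min(n_a, n_b),$$

with expectation `E = n_a n_b / N`. This is an exact, analytic
alternative to swap-randomization of the matrix: no Monte-Carlo error,
no burn-in diagnostics. The decision rule, applied per unordered pair:

* **removed** if `E < min_expected` (default 1): the pair could not even
  be expected to meet once, so tail probabilities are uninformative;
* **positive** if the inclusive upper tail `P(j >= j_obs) < alpha`
  (default 0.05); **negative** if `P(j <= j_obs) < alpha`;
* **random** if not significant and `|j_obs - E| <= random_band * N`
  (default 0.1): the observed count sits within a tenth of the site
  total of its expectation;
* **unclassifiable** otherwise — too deviant to call random, not
  deviant enough to be significant.

Tails are inclusive, so `p_lt + p_gt = 1 + P(j_obs)`; a consequence
asserted as a test rather than assumed is that both tails can never be
below any `alpha < 0.5` simultaneously, so the positive/negative
precedence in the rule is immaterial. The standardized effect size is
`(j_obs - E)/N`, bounded in `[-1, 1]`.

Numerically, the pmf is evaluated in log space with `lchoose` rather
than with ratios of explicit big integers; at the matrix sizes this
package targets (tens to a few hundred sites) the pmf sums to 1 within
1e-12, which the suite verifies up to `N = 60` alongside exact
agreement with an exhaustive placement-enumeration oracle for all
`N <= 8`.

## Guild co-occurrence and cross-classification

Habitat (Arboreal/Terrestrial) crossed with diel activity
(Diurnal/Nocturnal) defines four guilds. The guild analysis reruns the
same pairwise machinery on a species × 4 *category* matrix in which
every species carries exactly one habitat and one activity mark (row
sum 2). The encoding deserves a flag: with four mutually exclusive
guild columns instead, every pair would have expected co-occurrence
0.25 and be removed by the `E >= 1` rule, so no guild pair could ever
be classified. The category encoding gives every pair `E = 2·2/4 = 1`
exactly, and the support of the pmf at `N = 4, n = 2` makes the
smallest attainable tail probability 1/6 — structurally above any
conventional alpha. Guild analysis therefore *cannot* produce
significant pairs; what it yields is the random/unclassifiable split
(sharing exactly one category vs both-or-neither), which is precisely
the information the cross-classification needs. This encoding is an
interpretation (the alternative is self-contradictory), and the
"theorem-as-test" above is asserted over randomly generated guild
tables in the suite.

Crossing geographic against guild outcomes tags each pair:
geographically negative pairs with no positive guild association are
**historical allopatry** (dispersal barriers, not interactions);
geographically positive pairs with random/unclassifiable guild outcome
are **common history**; the competition-consistent signature
(geographically negative, guild positive) is tagged as such; everything
else is uninformative.

## SAD model selection

Each community is an abundance vector ranked descending (counts pooled
over 100 m² quadrats). Models are fitted by maximum likelihood and
ranked by `AIC = -2 logLik + 2 df`, ties broken by fewer parameters
then name. Three fits have closed forms:

* **Pareto**: `f(x) = b a^b / x^{b+1}` for `x >= a`. The scale `a` is
  fixed at the smallest observed abundance by default (overridable),
  which keeps the single free parameter interpretable as a pure
  dominance-decay shape; `b = S / \sum \ln(x_i/a)`, `SE = b/\sqrt S`.
  A sample entirely at the scale is reported as a degenerate-sample
  error rather than a diverging estimate.
* **Broken stick**: `p(x) = (S-1)/N (1 - x/N)^{S-2}` with `N` and `S`
  fixed by the data; zero free parameters, so `AIC = -2 logLik`.
* **Lognormal**: ML moments of `log x` with the divide-by-S variance;
  asymptotic SEs `sdlog/\sqrt S` and `sdlog/\sqrt{2S}`.

Continuous densities (Pareto, lognormal, broken stick, Weibull, gamma)
are evaluated at the integer abundances *as densities*, not
discretised — the convention that keeps their likelihoods on the scale
on which such communities are conventionally compared. Discrete models
(geometric, log-series, discrete power law, negative binomial,
Poisson-lognormal) use mass functions, zero-truncated where a model
would otherwise put mass on unobservable zero counts. The Zipf and
Zipf–Mandelbrot models are rank-frequency multinomials (`p_i ∝
(i+\beta)^{-g}` over ranks), with the parameter-free multinomial
coefficient omitted; their AICs are therefore comparable within the
rank family but are reported alongside the rest for completeness. The
zero-sum multinomial and neutral sampling models are registered as
stubs that fail loudly: their likelihoods need heavy combinatorial
machinery and they are out of scope, but the registry accepts their
later addition.

The generic optimiser is L-BFGS-B on natural scale with box
constraints, relative log-likelihood tolerance 1e-8, five multi-starts
jittered around moment-based initials (seeded from a fixed substream so
fitting is deterministic), and standard errors from the observed
information via a numerical Hessian. Parameters landing on a domain
boundary are flagged with a warning; failures set a convergence code
and are excluded from rankings with a warning, never silently. The
suite checks that the generic optimiser reproduces the closed forms to
1e-6 and that every fitted density/mass normalizes to 1 within 1e-6.

## Body-size V-ratio

With masses sorted ascending and `g_i = \ln m_{(i+1)} - \ln m_{(i)}`
the adjacent log-mass gaps, the V-ratio is the sample variance of the
`g_i`. Constant size ratios — the classical competitive-spacing
prediction — give exactly 0; irregular spacing inflates it. Two
conventions are defensible for the variance denominator and the
reference literature does not pin one down, so both are offered:
`denominator = "unbiased"` (`n_ratios - 1`, the default) and `"ml"`
(`n_ratios`). The statistic is invariant to rescaling all masses and to
input order (log-ratio properties, both property-tested).

The null model draws communities of the observed richness from a
source pool, uniformly without replacement, and compares the observed
V-ratio with the resulting distribution via inclusive tails and
`SES = (V_obs - mean_null)/sd_null`. The pool holds every archipelago
species no heavier than the community's largest member — pinning the
null's maximum body size to the observed one — plus five hypothetical
species (configurable) drawn once per pool, uniformly on the log-mass
interval between the pool minimum and the community maximum, so the
pool always outnumbers the community. Drawing the hypotheticals once
per pool rather than per iterate keeps the null distribution
conditional on one concrete pool, which is the cleaner reading of an
"arbitrary added species" device; the per-iterate alternative would mix
pool uncertainty into the null. The default 1000 iterations put the
Monte-Carlo SE of the tail probabilities near 0.016, small against the
0.05 decision scale; the iteration count is configurable and recorded,
with a floor of 100.

Calibration and power are property-tested: observed communities drawn
by the null procedure itself give SES centred on 0 with `|SES| > 1.96`
in no more than 7.5% of seeded replicates (the null V-ratio
distribution is right-skewed, so exact 5% coverage is not expected of
a two-sided z-style cut), and communities constructed evenly spaced on
the log-mass axis fall below the null median SES in at least 90% of
replicates.

The richness–V-ratio Pearson correlation uses the textbook
`t = R\sqrt{df/(1-R^2)}`, `df = n - 2`, cross-checked against
`cor.test`. The package bundles the published 23-island V-ratio summary
table (`island_vratio_reference()`), from which it reproduces the
reported correlation (R ≈ −0.43, t ≈ −2.17; R ≈ −0.28 with the
high-V outlier island Chester excluded) and the reported SES values by
direct recomputation.

## Species–area regression

`fit_species_area` regresses `log10` richness on `log10` area by OLS
and reports the power-law slope `z`, `R²`, and `F = (n-2)R²/(1-R²)`.
Slope, `R²` and `F` are invariant to the logarithm base (tested). Since
island areas for the study system are not published, this stage ships
with synthetic fixtures only.

## What the synthetic generators emulate — and what they do not

* `gen_allopatric_matrix`: island groups colonised independently, with
  endemics confined to their block and a configurable number of shared
  species; independent Bernoulli occupancy within range. Defaults (2
  groups × 8 endemics × 10 islands, 1 shared species, occupancy 0.6)
  caricature a two-archipelago system split by a deep channel.
* `gen_common_history_matrix`: a nestedness-controlled archipelago;
  at `nestedness = 1` incidence is strictly nested (every island pair
  subset-comparable), at 0 it degenerates to independent occupancy.
  One species is always given the full island range so the fully
  nested template has no empty island.
* `gen_pareto_sample` / `gen_broken_stick_sample`: inverse-CDF Pareto
  draws rounded half-up, and uniform stick-breaking with
  largest-remainder integerisation (redrawn, with bounded retries, if
  any segment rounds to zero — negligible at the stick lengths used,
  and the sum-to-N conservation stays exact).
* `gen_size_community`: passive random sampling from a mass pool, or
  the even-log-spacing construction that competition theory predicts.

All generators run inside named seed substreams derived from one user
seed (a polynomial hash of the stream name mixed into the seed modulo
2³¹−1), so stages are independently reproducible and bit-identical
under the same seed; every output carries its `(scenario, parameters,
seed)` as metadata and passes the corresponding reader's validation.

These generators reproduce the *statistical structure* each stage
assumes — block allopatry, nestedness, hollow-curve SADs, log-uniform
mass pools — not the biology of real archipelagos: no spatial
geometry, no phylogenetic correlation, no detection error, no
abundance–occupancy coupling. Passing the property battery therefore
demonstrates that the estimators and classifiers behave correctly under
their own assumptions, not that those assumptions hold for any
particular field system.

## Problem sizes and degenerate inputs

The test battery uses sizes chosen to keep Monte-Carlo error well below
the decision thresholds while remaining quick to run: 200 replicates
for type-I control and parameter recovery (binomial SE ≈ 1.5% on a 5%
rate), 200 replicates × 1000 iterations for V-ratio calibration, 2000
draws for the broken-stick rank-expectation check, and exhaustive pmf
enumeration up to `N = 8` (87k placements). Degenerate inputs are
errors with named offenders, not warnings: non-binary or missing
presence-absence cells, duplicate labels, empty rows/columns in field
matrices, non-positive masses/areas, all-equal abundance samples,
zero-variance nulls. A blank matrix cell is an error rather than an
implicit absence, because absence is data in this design.

## Known limitations

* The co-occurrence model conditions on observed row/column totals
  pairwise, not jointly across the whole matrix (it is not a
  fixed-fixed swap null); pairs are not independent of one another, so
  summary counts should be read descriptively.
* SAD standard-error conventions are asymptotic and the rank-family
  likelihood omits the multinomial constant; cross-family ΔAIC
  involving Zipf models should be interpreted cautiously.
* The V-ratio null treats the species pool as known and equal-weight;
  it does not model colonisation probability gradients or abundance
  weighting.
* Arbitrary-precision rational combinatorics would extend exactness
  beyond a few hundred sites; log-space evaluation was chosen as it
  meets the stated accuracy contract over the realistic site range.
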