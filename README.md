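# nullassembly

Null-model inference for insular community assembly.

Does interspecific competition shape which species share an island, how
abundance is divided among them, and how their body sizes are spaced?
**nullassembly** implements the three classical null-model screens used
to answer that question for finite island assemblages (its motivating
system is the insectivorous lizard fauna of a tropical archipelago),
aimed at community ecologists and macroecologists working with
presence–absence matrices, quadrat counts and trait tables:

1. **Exact probabilistic species co-occurrence.** For each pair of
   species occupying *n₁* and *n₂* of *N* islands, the number of shared
   islands *j* under random, independent placement is hypergeometric,
   P(j) = C(n₁, j)·C(N−n₁, n₂−j)/C(N, n₂), with expectation
   E = n₁n₂/N. Pairs are classified positive / negative (inclusive
   tail probability < α), random (|j − E| ≤ 0.1·N), unclassifiable, or
   removed (E < 1), with standardized effect size (j − E)/N ∈ [−1, 1].
   The same machinery runs on a species × guild-category matrix
   (habitat × diel activity), and a geographic-vs-guild
   cross-classification tags pairs as *historical allopatry*, *common
   history*, or *competition-consistent*.
2. **Species abundance distribution (SAD) model selection.** Maximum
   likelihood fits ranked by AIC over a model registry: Pareto
   f(x) = b·aᵇ/x^(b+1) with the scale fixed at the minimum abundance
   (closed-form shape MLE b̂ = S/Σln(xᵢ/a)), the zero-parameter broken
   stick p(x) = (S−1)/N·(1−x/N)^(S−2), lognormal, and a generic
   optimiser for geometric, log-series, Weibull, discrete power law,
   Zipf, Zipf–Mandelbrot, Poisson-lognormal, negative binomial and
   gamma.
3. **Body-size V-ratio null model.** The V-ratio is the variance of
   adjacent log-mass gaps of the size-ranked community (0 for constant
   size ratios). Null communities of equal richness are drawn from a
   source pool capped at the community's maximum mass and padded with
   five hypothetical species; inclusive tail probabilities and
   SES = (V_obs − mean_null)/sd_null quantify departure, and a
   richness–V-ratio Pearson correlation summarises the archipelago.

A species–area power-law regression (`fit_species_area`) and seeded
synthetic-community generators (block-allopatric and nested
archipelagos, Pareto/broken-stick abundance samples, random or
evenly-log-spaced size assemblages) round out the pipeline so every
stage can be exercised and validated without field data. See the
vignette `vignettes/community-null-models.Rmd` for the full methods
account.

## Worked example

```r
library(nullassembly)

# A two-group archipelago: endemics confined to their island group,
# one shared species, occupancy 0.6
m <- gen_allopatric_matrix(n_groups = 2, species_per_group = 8,
                           islands_per_group = 10, shared_species = 1,
                           occupancy = 0.6, seed = 1)
geo <- cooccur_analyze(m)
geo
#> Probabilistic co-occurrence analysis
#>   17 species x 20 sites; 136 pairs (9 removed, expected < 1)
#>   positive 20 | negative 18 | random 88 | unclassifiable 1  (alpha = 0.05, random band = 0.1 x sites)
```

136 pairs are enumerated; 9 are removed because their expected
co-occurrence falls below 1. The 18 negative pairs are species kept
apart by the block structure, the 20 positive pairs co-occur within
their group. Crossing against a guild analysis shows none of the
negatives is competition-consistent:

```r
gt <- guild_table(data.frame(
  species = rownames(m),
  habitat = rep(c("Arboreal", "Terrestrial"), length.out = 17),
  activity = rep(c("Diurnal", "Diurnal", "Nocturnal"), length.out = 17)))
ct <- cross_classify(geo, guild_cooccur(gt))
table(ct$pairs$inference)
#>       common_history historical_allopatry        uninformative
#>                   20                   18                   98
```

SAD selection on a dominance-skewed community ranks Pareto first:

```r
x <- gen_pareto_sample(S = 7, scale = 22, shape = 0.6, seed = 4)
x
#> Abundance vector 'pareto_synth': S = 7, N = 585
#> [1] 302 119  50  38  26  25  25
fit_sads(x, models = c("pareto", "brokenstick", "lognormal"))$ranking
#>         model loglik df   aic delta_aic
#> 1      pareto -32.66  1 67.32     0.000
#> 2 brokenstick -38.27  0 76.55     9.231
#> 3   lognormal -36.78  2 77.56    10.244
```

The V-ratio test for a 5-species island against a 29-species
archipelago mass pool (0.5–84 g):

```r
pool <- exp(seq(log(0.5), log(84), length.out = 29))
vratio_test(c(1.1, 2.4, 9.0, 30.5, 62.0), pool,
            community = "demo-island", n_iter = 1000, seed = 2)
#> V-ratio null-model test: demo-island (S = 5)
#>   observed V 0.09489 | null mean 0.5067, var 0.2098 (1000 iterations, seed 2)
#>   SES -0.899 | P(lower) 0.099, P(upper) 0.901
```

The observed spacing is more regular than 90% of null draws
(SES ≈ −0.9) but not significantly so. Finally, the bundled published
23-island V-ratio summary reproduces the reported negative
richness–V-ratio correlation:

```r
richness_vratio_correlation(island_vratio_reference())
#> Pearson correlation: R = -0.428, t = -2.171, df = 21, P = 0.0415 (n = 23)
```

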