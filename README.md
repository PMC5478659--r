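# sadscale

Scaling and forecasting of species abundance distributions (SADs).

Most SAD work fits a distribution (logseries, lognormal, …) to one sample at
one scale. `sadscale` instead tracks how the SAD *changes* with sample size
and projects it to larger samples. It is aimed at community ecologists with
transect- or plot-based survey data — in the motivating application, island
arthropod surveys of standardized forest transects in which every species
carries an expert classification as a high- or low-dispersal-ability
species.

The method, in the field's standard notation: abundances are binned into
octave classes ($[2^i, 2^{i+1}-1]$), and the distribution of
$x_j = \log_2 n_j$ is summarised by its moments

$$M_n = \tfrac{1}{S}\textstyle\sum_j x_j^n,\qquad
  \mathrm{Skewness} = T_3 = \tfrac{1}{S}\textstyle\sum_j
  \big((x_j-\bar x)/\sigma_x\big)^3 .$$

As transects are accumulated in spatial order (concentrically from each
possible start, giving $T$ orderings for $T$ transects), the raw moments
$M_1..M_{10}$, the richness $S(t)$ and the maximum abundance $N_{\max}(t)$
follow approximate power laws of the number of transects $t$. Fitting those
lines by OLS in log–log space and evaluating them at $2t$ or $4t$ yields
extrapolated moments, from which the SAD itself is rebuilt on
$\lfloor\log_2 N^*_{\max}\rfloor + 1$ octave classes using scaled
(orthonormal) discrete Tchebichef polynomials: $T_n = \sum_k c_{n,k} M_k$,
$\hat p(x) = \sum_{n \le k^*} T_n t_n(x)$, forecast SAD $= S^* \hat p$. The
reconstruction order $k^*$ is chosen by best reconstruction of the observed
largest-size histogram, and forecasts are averaged over all transect
orderings with a ±2 SD band.

A spatially explicit zero-sum neutral simulator (torus lattice, point
speciation, configurable dispersal kernel) generates the two-community test
data behind the package's dispersal predictions: aggregated (low-dispersal)
communities develop a humped SAD at smaller sample sizes, while well-mixed
(high-dispersal) communities stay singleton-rich and more skewed.

## Worked example

Simulate a high- and a low-dispersal community, survey both with the same 32
transect windows, and run the core analyses:

```r
library(sadscale)
land_low  <- run_neutral_sim(L = 256, kernel = "gaussian", sigma = 1,
                             generations = 200, seed = 101)
land_high <- run_neutral_sim(L = 256, kernel = "global",
                             generations = 200, seed = 102)
tab <- landscape_to_transects(land_high, land_low, n_transects = 32, seed = 7)

pooled <- tapply(tab$abundance[tab$dispersal == "low"],
                 tab$species[tab$dispersal == "low"], sum)
bin_abundances(as.vector(pooled))
#> Octave SAD: 11 classes, 49 species
#>         1       2-3       4-7      8-15     16-31     32-63    64-127   128-255
#>         8         6        15         9         7         3         0         0
#>   256-511  512-1023 1024-2047
#>         0         0         1
```

The pooled low-dispersal SAD is already humped (mode at 4–7 individuals,
only 8 singletons out of 49 species). The skewness trajectory separates the
two groups at every sample size:

```r
subset(as.data.frame(skewness_trajectory(tab)), t %in% c(4, 16, 32))
#>  group  t  mean    sd  lower upper  n n_excluded
#>   high  4 4.571 0.344  3.882 5.259 32          0
#>   high 16 3.028 0.110  2.808 3.247 32          0
#>   high 32 2.069 0.000  2.069 2.069 32          0
#>    low  4 0.835 0.634 -0.434 2.103 32          0
#>    low 16 1.289 0.194  0.902 1.676 32          0
#>    low 32 1.340 0.000  1.340 1.340 32          0
```

The high-dispersal SAD is always the more skewed one (singleton-rich, long
right tail); the aggregated community sits near symmetric-on-log2 much
earlier. Each row averages the 32 concentric orderings (one per start
transect), so the SD is 0 at `t = 32` where every ordering has pooled the
whole survey. Moments, richness and their power-law fits:

```r
acc  <- accumulate_sads(tab, order_concentric(tab, "T001"), groups = "high")
ser  <- moment_series(acc, group = "high")
fits <- fit_moment_scaling(ser)
fits$moment_fits$M1
#> Power law: value = 0.352 * size^0.4053  (R^2 = 0.9276, n = 31)
fits$richness_fit
#> Power law: value = 22.04 * size^0.5511  (R^2 = 0.9772, n = 31)
```

and the forecast of the high-dispersal SAD at twice the number of transects,
averaged over all orderings:

```r
forecast_ensemble(tab, factor = 2, group = "high")
#> SAD forecast ensemble (concentric, high group): 2x, 32 orderings, mean S* = 222.0
#>  class  mean    sd
#>      0 21.62 17.18
#>      1 63.17 19.95
#>      2 58.63 19.13
#>      3 37.58  6.63
#>      4 17.27  6.59
#>      ...
```

At double the survey effort the forecast expects ~222 species with the mode
moving into the 2–3 and 4–7 individual classes. `run_sad_pipeline(tab,
"out/")` runs everything above for both groups and writes the tables plus a
JSON run report.

The package also ships the published per-island summary of the Azorean
arthropod survey (`azores_island_summary()`): 99 transects whose island rows
sum exactly to the published archipelago totals (76 664 high- and 25 864
low-dispersal individuals).

## Documentation

The methods vignette (`vignettes/sad-scaling.Rmd`) documents the model and
its assumptions, the tunable parameters and their defaults, the numerical
choices (basis re-orthonormalization, negative-mass clipping, order
selection, degenerate-skewness handling), what the neutral simulator does
and does not emulate, and known limitations.
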