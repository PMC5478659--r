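---
title: "Multi-scale species abundance distributions: moments, scaling, and forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale species abundance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadscale)
```

## The problem

A species abundance distribution (SAD) — the histogram of how many species
occur at each abundance — is usually studied at one fixed sample size, by
fitting a logseries, lognormal or similar distribution.  `sadscale` takes the
complementary view: it asks how the *shape* of the SAD changes as the sample
grows, and whether that change is regular enough to project the SAD to sample
sizes nobody has collected yet.  The motivating system is an island arthropod
survey of standardized 150 m × 5 m forest transects, where species had been
classified by experts as having high or low dispersal ability, but every
component works on any table of (transect, species, abundance) records with
planar or geographic coordinates and a two-level dispersal classification.

Two empirical regularities carry the whole method:

1. at small samples SADs are monotonically decreasing (singleton-dominated),
   and with growing samples they develop a hump at intermediate abundance
   classes — *earlier* for spatially aggregated (low dispersal) species than
   for well-mixed (high dispersal) ones;
2. the raw moments of the log2-abundance distribution, plotted against
   sample size in double-logarithmic axes, fall on approximately straight
   lines.

The first is quantified with the skewness; the second licenses power-law
extrapolation of the moments, from which the SAD itself is rebuilt with
discrete orthogonal polynomials.

## Octave binning and moments

Abundances are binned in doubling (octave) classes: class 0 holds species
with 1 individual, class 1 those with 2–3, class 2 those with 4–7, and so on
(class $i$ covers $[2^i, 2^{i+1}-1]$).  All moment work happens on
$x_j = \log_2 n_j$, the log2 abundance of species $j$.  With $S$ species:

$$M_n = \frac{1}{S}\sum_{j=1}^{S} x_j^n, \qquad
  C_n = \frac{1}{S}\sum_j (x_j-\bar x)^n, \qquad
  T_n = \frac{1}{S}\sum_j \Big(\frac{x_j-\bar x}{\sigma_x}\Big)^n,$$

with $\bar x = M_1$ and $\sigma_x = \sqrt{C_2}$.  Divisors are always $S$
(population convention — these are descriptive moments of a finite
assemblage, not estimators of an infinite-population parameter, so no Bessel
correction is applied).  The skewness $T_3$ is the workhorse: positive for
singleton-rich distributions with a long right tail, shrinking as the hump
develops.  When all abundances are equal, $\sigma_x = 0$ and standardized
moments are reported as `NA` — an undefined value, never a silent zero —
and such steps are excluded (and counted) in trajectory summaries.

An equivalent bin-level formula, $M_n = \sum_i p_i x_i^n$ with $p_i$ the
proportion of species in class $i$, needs a choice for $x_i$; we use the
integer class index $0..NB-1$.  On that support the polynomial
reconstruction below is *exact*, which is the property the forecast relies
on.  The per-species formula with continuous $x_j$ and the bin-index formula
differ by up to about half a bin; the pipeline follows the per-species
moments (they are the ones with clean scaling behaviour) and accepts this
approximation knowingly.

## Accumulating transects

Sample size grows by adding whole transects in spatial order, as a surrogate
for growing area and effort.  Two orderings are available from any start
transect: *concentric* (nearest, second nearest, … from the start) and
*sequential* (greedy nearest-neighbour chain).  With $T$ transects there are
exactly $T$ orderings of each kind, one per start; trajectories report the
across-ordering mean and standard deviation, with mean ± 2 SD as the band.
The two methods give near-identical results in practice; concentric is the
reporting default.  Distance ties are broken by ascending transect id so
runs are reproducible.  Geographic coordinates are projected to metres on
ingest by a small-region equirectangular projection, adequate at the few-km
extents of a transect network.

## Power-law scaling of the moments

For each accumulation the package fits, by ordinary least squares in log-log
space, one line per raw-moment order (default orders 1–10), plus lines for
the species richness $S(t)$ and the abundance of the most abundant species
$N_{\max}(t)$.  The default scaling region starts at $t = 2$ transects,
because very small pools sit below the power-law regime; the region is
user-configurable and deliberately exposed, since its endpoints are a
judgement call on any given dataset.  Accumulated samples are serially
dependent, so residuals oscillate; `residual_diagnostics()` reports the
log-space residuals and their lag-1 autocorrelation so that this can be
inspected rather than ignored.  A generalized least-squares variant with
AR(1) errors is not implemented: on data of this type it is known to leave
the conclusions unchanged while demanding many more points than small
surveys have.

Extrapolation is restricted by design: predictions beyond four times the
largest fitted size draw a warning.  Short-range extrapolation (×2,
optimistically ×4) is the intended envelope; the scaling lines have not been
validated further out, and moment series plausibly change regime at much
larger areas.  A power-mean sanity screen ($M_n^{1/n}$ nondecreasing in $n$,
which true moments of nonnegative values must satisfy) is applied to the
extrapolated moments and a violation is reported as a warning.

## Tchebichef reconstruction and the forecast

The discrete Tchebichef polynomials in their *scaled* (orthonormal) form,
$t_n(x)$ on $x = 0..N-1$, satisfy $\sum_x t_m(x)t_n(x) = \delta_{mn}$ and are
generated by a stable three-term recurrence.  Two numerical details matter:

* the recurrence drifts from orthonormality as the order approaches the
  support size (about $2\times10^{-8}$ already at $N = 32$, full order), so
  the constructor applies one sign-aligned QR re-orthonormalization, which
  restores orthonormality to machine precision while leaving low orders
  unchanged at the $10^{-12}$ level;
* Tchebichef moments can be obtained either from a distribution
  ($T_n = \sum_x p(x)t_n(x)$) or from raw moments through the monomial
  coefficients of $t_n$ ($T_n = \sum_k c_{n,k}M_k$).  The two agree to
  rounding error at moderate orders, but the monomial route is severely
  ill-conditioned at high order and large support (Vandermonde-type
  cancellation), which is one of the two reasons the forecast uses only a
  handful of moments.

The forecast to a target size $t^\ast = 2t_{\max}$ or $4t_{\max}$ proceeds
per ordering: extrapolate $M_1..M_m$, $S$, and $N_{\max}$; size the support
as $NB^\ast = \lfloor\log_2 N_{\max}^\ast\rfloor + 1$ classes; convert the
extrapolated moments (with $M_0 = 1$) to Tchebichef moments; reconstruct
$\hat p$; and scale by $S^\ast$.  The number of moments $k^\ast$ actually
used is chosen by reconstructing the *observed* largest-size histogram from
the fitted moments evaluated at $t_{\max}$ and keeping the order that
minimizes the squared histogram error, with ties going to the smaller order.
In practice $k^\ast$ lands between 3 and 5 — the second reason few moments
are used: higher extrapolated moments are noisy and destabilize the
reconstruction.  Truncated reconstructions can dip below zero; negative
entries are clipped and the result renormalized, with the clipped mass
recorded as an instability indicator.  If a reconstruction clips more than
half of its mass or goes non-finite the order is lowered automatically and
the event logged.  Across orderings, forecasted class counts are averaged
and reported with a ± 2 SD band; order selection happens independently per
ordering, and histograms of different support are zero-padded before
averaging.

## The neutral simulator

`run_neutral_sim()` provides the synthetic communities the pipeline is
validated on: a zero-sum neutral model on an $L \times L$ torus, one
individual per cell, point speciation with probability $\nu$ per birth,
parent drawn from a dispersal kernel centred on the vacated cell.  All
individuals have identical demographic rates; the *only* contrast between
the two simulated communities is the kernel — `global` (well-mixed, the
high-dispersal archetype) versus a discretised Gaussian of width
$\sigma = 1$ cell (strongly aggregated, the low-dispersal archetype).  This
is the minimal model consistent with neutral-theory tenets; the exact update
scheme of the original simulation experiments was not specified, so the
reproduction target is qualitative (the direction and ordering of effects),
not quantitative.

Defaults were fixed once, before any pipeline validation, at desk scale:
`L = 256` (65 536 individuals), 200 generations from a monodominant start,
$\nu = 10^{-3}$ (giving communities of a few hundred species, a realistic
richness for an island arthropod assemblage at this abundance).  A
1024² landscape is supported but unnecessary for the package's tests.
Burn-in adequacy can be monitored via the per-generation richness trace
(`richness_stationary()`, relative change < 1 % over 10 generations).  Square
samples of side $2^k$ tile the lattice exactly (hence the power-of-2
constraint on $L$), and `sample_squares()` averages octave histograms over
all tiles, mirroring the nested-square sampling design of the original
simulation figures.

`landscape_to_transects()` bridges simulator and field pipeline: disjoint
15 × 5-cell windows (elongated like real transects, sized so that dozens fit
disjointly at desk-scale grids) are placed at common random positions in
both landscapes and their contents merged into one two-community transect
table.

What the simulator deliberately does *not* emulate: habitat heterogeneity,
species interactions, continuous dispersal traits, observational error, and
the pitfall-trap/canopy-beating structure within a transect (samples within
a transect are pooled).  Passing tests on simulated data therefore
demonstrate internal consistency of the method and the predicted
dispersal contrast under neutrality — not that any particular real
assemblage satisfies the power-law premise; that must be checked per
dataset through the fit diagnostics.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle: binning
against direct enumeration of $\lfloor\log_2 n\rfloor$; moments against
brute-force summation; orderings against hand-computed distances; truncated
reconstructions against QR-based polynomial projection; tile averages
against per-tile enumeration; and residual autocorrelation against
`stats::acf()`.  The forecast is checked two ways: on a hand-built community
whose moments, richness and $N_{\max}$ follow exact power laws, the ×2
forecast must match the analytic construction to $10^{-6}$; and on simulated
surveys, a forecast fitted on the spatially nearest half of the transects
must place at least 80 % of the octave classes of the full survey's pooled
histogram inside its ± 2 SD band.  The dispersal predictions are asserted
statistically over ten replicate simulations: higher skewness for the
well-mixed community at intermediate square sizes, an interior SAD mode
appearing first in the aggregated community, and the sign of the skewness
contrast surviving a 5 % random flip of dispersal labels.  Test problem
sizes — $L = 128$–256 landscapes, 200 generations, 32-transect surveys, ten
replicate seeds — were chosen as the smallest configurations at which these
contrasts are unambiguous.

## Known limitations

* The per-species moments (Eq. on $x_j$) stand in for bin-index moments in
  the reconstruction; the induced offset is below the bin scale but is not
  corrected.
* OLS on accumulated (autocorrelated) series gives honest point estimates
  but optimistic standard errors; use the residual diagnostics.
* Forecasts inherit every failure of the power-law premise; beyond ×4 the
  package refuses to be quiet about it.
* The dispersal dichotomy is a simplification of a continuous trait; the
  label-flip sensitivity tool quantifies robustness to misclassification
  only, not to the dichotomy itself.
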