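---
title: "Methods: habitat-specific diversity trends from resurvey time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-specific diversity trends from resurvey time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resurveytrends)
```

`resurveytrends` estimates trends in local plant diversity from
vegetation-plot time series and partitions those trends over habitat
types and habitat-change trajectories. This vignette documents the models
and estimators, the parameters that matter, the synthetic-data generator
used for validation, and the numerical and design choices behind them.

## Data model and cleaning rules

The unit of observation is one survey of one plot: a set of
(taxon, layer, percent cover) records with a calendar year, plot area,
and optional EUNIS level-1/level-3 habitat codes. A time series is an
ordered sequence of such observations sharing a series id; semi-permanent
designs (relocated or N-to-N plots) are supported by letting several
observations share a year and, where plot identity is not stable, by
falling back to the series id as the pairing key.

Three cleaning rules are applied by `filter_dataset()`:

1. experimentally manipulated observations are removed (regularly managed
   plots are not "manipulated");
2. series carrying only presence/absence information (no covers) are
   removed, because most indices need abundances;
3. series whose plot area changed by a factor *strictly greater* than two
   are removed — diversity is area-dependent. The boundary ratio of
   exactly 2 is retained; series with partially missing areas are kept
   and flagged, since skipping the ratio rule is safer than guessing an
   area.

`flag_name_mismatches()` searches for systematic taxonomy drift — a taxon
lost while a congener is gained between consecutive observations of the
same plot — and flags a (lost, gained) pair for a site when it recurs in
more than 40% of at least five plots. Flags are advisory only: resolving
them correctly requires consultation with the original surveyors, so the
package never renames automatically.

## Layer combination and cover arithmetic

Species recorded in several vegetation layers are first combined per
taxon with the independence (overlap) formula

$$c = 100\left(1 - \prod_l (1 - c_l/100)\right),$$

which treats layers as independently placed horizontal projections. The
same formula, applied across taxa, gives total vegetation cover, and,
applied within a species group (threatened, non-native, specialist,
generalist), the group cover. This keeps all cover quantities on the same
footing — group cover can never exceed total cover. A consequence worth
remembering: community-level cover saturates. Even if every species'
cover grows at a fixed relative rate, the overlap-combined total grows
more slowly as it approaches 100%.

## Diversity indices and their gates

All indices are computed per observation from the layer-combined covers,
with relative abundances $p_i = c_i / \sum_j c_j$.

**Taxonomic.** Richness $S$; Shannon $H = -\sum_i p_i \ln p_i$; Pielou
evenness $H / \ln S$, undefined (missing) at $S = 1$. Both $H$ and the
evenness are emitted because "diversity" and "evenness in cover" are
distinct summaries; they are scale-invariant in the covers.

**Functional.** Traits are log-transformed and z-scored
(`prepare_traits()`), and collinearity is reduced either by a caller
supplied keep-list or by greedily dropping one member of every pair with
|Pearson r| > 0.6 (the member with the larger mean |r| to all other
retained traits; lexicographic tie-break, so the pruning is
deterministic). A single principal-component projection of the
standardized trait matrix — `trait_projection()`, default `m_axes = 4` —
is shared by *all* observations so that hull volumes are comparable
across plots and years; per-plot projections would make FRic
incommensurable. FRic is the exact convex-hull volume of the present
species in that space (`convhull_volume()`, a facet-enumeration
algorithm exact in any dimension for community-sized point sets); FEve
follows the minimum-spanning-tree formulation with link weights
$EW_l = d_{ij}/(w_i + w_j)$; FDiv measures abundance-weighted spread
around the centroid of the hull vertices. Gates: all three are missing
when species with trait data cover less than 80% of total vegetation
cover (functional indices are badly biased by incomplete traits); FRic
and FDiv additionally need $S > m$ and a non-degenerate hull, FEve needs
$S \ge 3$. Every missing value carries a recorded reason.

**Phylogenetic.** Faith PD (sum of branch lengths of the minimal spanning
subtree; the path to the tree root is included by default,
`include_root = TRUE`, and the choice is recorded), mean pairwise
distance, and mean nearest taxon distance, from the cophenetic matrix of
the pruned tree. The gate is strict: if any present taxon is missing from
the phylogeny, all three are missing — partial prunings would conflate
composition change with coverage change. Abundance weighting
($p_i p_j$ for mpd, $p_i$ for mntd) is available but off by default;
the unweighted forms guarantee mntd ≤ mpd.

**Niche width.** Following the co-occurrence logic that generalists
co-occur with more heterogeneous assemblages, a species' niche width is
the mean multiple-site Simpson dissimilarity

$$\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij}, b_{ji})}
 {\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min(b_{ij}, b_{ji})}$$

over `n_reps = 100` random draws of `n_plots = 20` occupied observations,
at most one per time series (so a densely resurveyed plot cannot dominate
the estimate). Only species with at least `min_occ = 50` occurrences are
scored; species with ≥50 occurrences but fewer than 20 distinct series
are skipped with a recorded reason — sampling the same series twice would
silently break the independence the turnover index assumes. The Simpson
turnover component is used precisely because it ignores richness
differences and nestedness. The lowest and highest deciles
(`floor(0.1 · n_scored)` per tail, ties broken by taxon name) become
specialists and generalists; the community-weighted mean niche width
covers the intermediate species and is gated at 80% niche-data cover.

## Per-series trends

`fit_series_trend()` regresses the (log) index value on calendar year by
ordinary least squares and reports the slope as annual percentage change
$(e^{slope} - 1)\cdot 100$. With two observations this is exactly the
relative change divided by the time span. The four species-count indices
(threatened, non-native, specialist, generalist richness) may be
legitimately zero, so their log fits use value + 0.5; all other indices
exclude non-positive values with a recorded reason rather than silently
offsetting — a zero Shannon index is a structural boundary, not a count.
Raw-scale slopes (original units per year) are fitted without any offset.
Repeated years (N-to-N designs) enter one regression as repeated
x-values. A constant series returns a slope of exactly 0 (the centred
cross-product is skipped), so zero-trend fixtures round-trip exactly.

## Pooling, period splits, and variance partitioning

`weighted_mean_trend()` is an intercept-only weighted least squares with
analytic (importance) weights $w_i = \ln(n_{obs,i})$:
estimate $\sum w_i x_i / \sum w_i$, standard error
$\sqrt{\sum w_i (x_i - \bar x_w)^2 / ((n-1)\sum w_i)}$, and Wald 95% CI
(±1.96 SE). The variance convention matters: analytic weights express
precision, not frequency, and reduce to the classical SE of the mean
under equal weights. Resurvey-design covariates (permanent versus
semi-permanent; relative plot-size change) can be added as centred fixed
effects, leaving the intercept interpretable as the adjusted average.

`balanced_mean_trend()` gives every level-3 habitat equal total weight
(series weight $1/n_h$), after dropping habitats with fewer than ten
series; whether the balanced weight is additionally multiplied by
$\ln n_{obs}$ is a switch (`combine_obs_weight`, default off — the two
weighting rationales are orthogonal and conflating them silently would
change the estimand).

`compare_periods()` splits observations at a year (default 2000; the
split year itself opens the later period), refits trends within each
period, and compares the two trend distributions per index with a
weighted Welch t-test: weights are rescaled to sum to each group's size
(frequency-style), then the usual Welch statistic and
Welch–Satterthwaite degrees of freedom apply. Under equal weights this
is numerically identical to `t.test()`. By default the comparison is
restricted to grassland, shrubland, and forest level-1 habitats, where
both periods are typically well populated.

`dominance_analysis()` decomposes the R² of
`pct_per_year ~ habitat_l3 * trajectory + last_year` into per-block
shares. General dominance is computed by averaging each block's
incremental R² over admissible entry orderings (Shapley value), where
"admissible" enforces marginality: the interaction block may only enter
after both of its main effects. This restriction is a deliberate design
choice — an interaction's R² without its mains is not interpretable —
and the orderings formulation keeps the identity
$\sum_b \text{share}_b = R^2_{full}$ exact (machine precision), which the
test suite asserts at 1e-8. Eligibility follows the 2 × 2 × 10 rule: at
least two level-3 habitats, each with at least two trajectories of at
least ten series; the analysis runs on the qualifying cells only, and the
full-model analysis-of-variance F-test supplies the significance flag.

## Habitat-change trajectories

`classify_trajectory()` looks only at the EUNIS level-3 codes of the
first and last observation. Missing codes at either end make a series
unclassifiable; identical codes are stable; otherwise a pluggable mapping
table of (initial-prefix, final-prefix) rules is consulted
(longest-combined-prefix wins), and unresolved pairs fall back to
level-1 complexity ranks: sparse/man-made < grassland <
shrubland/heathland < forest, with inland waters and mires ranked on
separate scales. A rank increase is succession, a decrease disturbance,
and equal or cross-scale shifts are "other" (e.g. the shipped default
declares wet ↔ dry heath undirected). The fallback is antisymmetric by
construction. The shipped rank table and rules are a documented stand-in
for a full expert mapping, which users can load from CSV via
`read_trajectory_map()`.

## Gamma diversity per decade pair

Pooled richness comparisons are biased by unequal sampling, so
`decadal_gamma_trends()` compares only plots observed in both decades of
a pair (fixed calendar decades), keeping each plot's first observation in
the earlier and last observation in the later decade; the gamma
difference is divided by the pair's distance in decades. The mean trend
is tested against zero with a two-sided t-test, and the sign balance with
an exact binomial test from which zero trends are excluded (a zero
difference carries no sign information). Degenerate cases follow fixed
conventions: all-zero trends skip both tests; identical non-zero trends
report p = 1e-15; a single trend skips the t-test. Decade pairs are not
weighted by temporal distance in the t-test.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_pool()` and
`simulate_dataset()` realize them. The defaults emulate the structure of
large European resurvey compilations: 55% of series hold two
observations, 17.7% three, 8.6% four (the remainder five to ten); spans
mix 1–4 y (10.3%), 5–10 y (43.1%), 11–20 y (18.1%), and 21–103 y
(28.5%); series start anywhere in 1920–2023; trajectories mix as 23.6%
stable, 5.7% succession, 3.4% disturbance, 18.9% other, and 48.5%
unclassifiable; and the injected true trends default to +0.2%/yr
richness and +0.7%/yr per-species cover. The pool holds 120 species with
14 log-normal traits (AR(1) correlation 0.4 on the log scale), a
pure-birth phylogeny, Bernoulli threat (12%) and non-native (8%) flags,
and symmetric-Dirichlet habitat affinities whose concentration tunes
specialists (low) versus generalists (high). Five habitats are used: a
man-made–grassland–shrubland–forest complexity chain plus a mire on its
own rank scale, so every trajectory category is constructible. Initial
richness is 1 + Poisson(13), i.e. about 15 species per plot, a realistic
density for European plots that also keeps exact hull computations cheap.

Mechanics chosen for exact ground truth:

- the richness target at $t$ years is $S_0 e^{rt}$ with *stochastic*
  rounding, so the expected richness is exact and the log-slope bias is
  negligible (deterministic rounding would bias two-point log slopes by
  a tenth of a percentage point at $S \approx 15$);
- turnover is an equal-rate swap (remove one, add one), Poisson in the
  elapsed time, so turnover and the richness trend are orthogonal knobs;
- per-species covers are a lognormal baseline multiplied by $e^{ct}$
  with lognormal noise, capped at 100; with zero trend, turnover, and
  noise every community is bitwise constant, making "all trends exactly
  zero" a testable exact statement;
- habitat switches (succession/disturbance/other) happen at the series
  midpoint and change both the sampling pool and the recorded EUNIS
  codes, so the endpoint classifier recovers the generated trajectory
  exactly; unclassifiable series carry no level-3 code;
- two-layer species split their cover so the overlap combination
  reconstructs the target exactly.

What the generator does *not* emulate: spatial structure and dispersal,
climate or land-use covariates, observer error, real European species
pools, and directional trait selection. Passing the validation suite
therefore demonstrates estimator correctness under a known generative
model — not that real data satisfy that model. Two emergent properties
deserve emphasis. First, the community-level total-cover trend is
smaller than the injected per-species cover trend because the overlap
combination saturates; ground truth is defined on the injected
per-species rate. Second, under stationary turnover the decadal gamma
t-test is approximately calibrated *because* realistic spans scatter
plots across the century, so different decade pairs draw nearly disjoint
plot sets; if every plot spanned every decade, the shared decade gammas
would correlate the trends and inflate the type-I rate well above
nominal.

## Numerical choices

- Convex hulls: facet enumeration over all d-subsets with vectorized
  cofactor normals (tolerance 1e-9 relative to the point scale), Gram
  determinants for simplex facets, recursion for coplanar ones;
  rank-deficient point sets are reported degenerate rather than measured
  as zero.
- OLS slopes use the closed-form centred cross-product; constant
  responses return exactly 0.
- The weighted-mean SE uses the analytic-weight formula above; the
  covariate variant goes through `lm(..., weights = )`, whose intercept
  variance matches it at p = 1.
- Missing values are `NA` in memory and empty fields on disk; every
  gated index records a reason string alongside.
- `write_results()` emits a manifest (config echo, seed, versions)
  without wall-clock fields, so identical inputs produce byte-identical
  outputs.

## Validation problem sizes

The test suite validates each estimator against independent oracles
(shoelace areas, brute-force path lengths, hand-enumerated dissimilarity,
closed-form two-point slopes, the established phylogenetic-diversity
implementations) and runs three stochastic experiments: parameter
recovery on 500 two-observation series over 10 years with a true
+1.0%/yr richness trend (pooled estimate within 3 SE; CI coverage over
100 replicates), the dominance R² identity on simulated
habitat × trajectory designs, and the gamma t-test type-I rate over 200
stationary replicates of an 80-series community. These sizes give
Monte-Carlo standard errors small enough for the stated tolerances while
keeping the default validation run in the minutes range on one CPU.

## Known limitations

- The interaction-after-mains restriction makes the dominance shares a
  constrained Shapley value; packages that average over all orderings
  will attribute slightly more to the interaction block.
- The weighted t-test's frequency-style rescaling is one of several
  conventions; a normalized-weight variant would change degrees of
  freedom for very unequal weights.
- Gamma pairing falls back to series ids where plot ids are absent,
  which under-pairs true N-to-N designs.
- `estimate_niche_widths()` counts occurrences after filtering;
  pre-filter counting would score slightly more species.
- FRic cost grows combinatorially with richness at `m_axes = 4`
  (exact enumeration); for species-rich plots (> ~40 taxa) reduce
  `m_axes` or expect longer runtimes.
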