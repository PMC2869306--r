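# igt — inductive game theory for multiparty conflict time series

`igt` extracts candidate conflict decision-making strategies directly from
event time series of multiparty fights, the way a behavioural ecologist's
dataset actually arrives: one row per fight, a set of participant ids, a few
per-participant annotations, grouped into observation periods. It is written
for researchers studying conflict dynamics in social groups (the motivating
system is a 48-individual pigtailed macaque society) who want to ask *why
fights start and spread* without positing payoffs.

## The method

1. **Membership correlations.** For source tuples (individuals or pairs) and
   target tuples, estimate the conditional membership probability across
   consecutive fights,

   p̂(T | S) = N(fights ⊇ T following a fight ⊇ S within a period) /
   N(fights ⊇ S with a same-period successor),

   and subtract its expectation under a Monte Carlo null that reshuffles
   fight order within periods while keeping compositions intact:
   Δp = p̂ − ⟨p̂⟩_null. Significance is empirical (two-sided 95% from the
   null ensemble, mid-p ties); overall significance re-runs the whole
   detection pipeline on surrogate series.
2. **Strategy fitting (the ansatz).** An (n,k)+combinator strategy matrix
   assigns each (source n-tuple, target k-tuple) a signed probability of a
   join/avoid recommendation; entries are set equal to the measured Δp.
   (1,1) is the pairwise "rogue actor" class, (2,1) triadic discrimination,
   (1,2) triadic coordination; AND is conflict-averse (unanimity), OR
   conflict-prone.
3. **Cascade simulation.** Spontaneous seed pairs trigger chains of fights:
   each fight's members issue recommendations, the combinator resolves them,
   and the cascade ends when fewer than two individuals would join.
4. **Model–data comparison.** Fight-size distributions (the *long fraction*
   F(s) = N(s) / Σ_{s′>2} N(s′)), a Pearson battery over appearance and
   co-appearance observables, shuffle and coarse-graining perturbations of
   the fitted strategy, per-group χ², AIC on the size distribution, and
   population cost of conflict (contact and redirected aggression received,
   by fight-size class, paired one-tailed signed-rank tests).

A synthetic-data module generates ground-truth-known fight tables (planted
strategies, role and aggression annotations, a macaque-scaled fixture), so
the whole pipeline is testable end to end without the undeposited empirical
data.

## A worked example

```r
library(igt)

fx  <- macaque_fixture(seed = 1)     # ~1,100 fights, 48 individuals, 20 periods
fc  <- fight_correlations(fx$series, n = 1, k = 1, n_shuffles = 1000, seed = 2)
head(correlation_edges(fc), 3)      # directed edges with |delta_p| > 6% at 95%
#> # A tibble: 3 × 4
#>   from  to    delta_p sign
#>   <chr> <chr>   <dbl> <chr>
#> 1 m07   m01    0.0841 attraction
#> 2 m18   m01    0.0671 attraction
#> 3 m19   m01    0.0778 attraction

sum(fc$significant_95 & fc$delta_p > 0)   # significant positive (1,1) cells
#> [1] 230

excess_significance(fx$series, n_shuffles = 100, n_surrogates = 40, seed = 5)
#> Excess-significance test: observed 228 significant positive cells;
#>  null mean 63.7 (40 surrogates); p = 0
```

The observed series has far more significant positive membership
correlations than any of its time-shuffled surrogates (~230 against a null
mean of ~64): fights carry memory of who fought whom. Fitting a triadic
conflict-averse model and simulating it:

```r
fit <- fit_strategy(
  fight_correlations(fx$series, n = 2, k = 1, n_shuffles = 60, seed = 4),
  n = 2, k = 1, combinator = "AND", roster = roster_of(fx$series)$id
)
sim <- simulate_series(fit, n_fights = 10000, seed = 6)
head(long_fraction(fx$series), 4)  # share of each size among fights > 2
#> # A tibble: 4 × 3
#>    size count fraction
#>   <int> <int>    <dbl>
#> 1     3    43   0.259
#> 2     4    20   0.120
#> 3     5    14   0.0843
#> 4     6     5   0.0301
plot_long_fraction(list(data = fx$series, `(2,1)+AND` = sim))
```

Cost of large fights (on annotated data):

```r
tab <- cost_table(fx$series, kind = "contact")
glance(tab)              # population mean frequency of receipt by size class
#> # A tibble: 4 × 6
#>   class population_mean  median     q25     q75 n_fights
#>   <fct>           <dbl>   <dbl>   <dbl>   <dbl>    <int>
#> 1 2             0.00178 0.00107 0.00107 0.00214      934
#> 2 3             0.00436 0       0       0             43
#> 3 4             0.0104  0       0       0             20
#> 4 >4            0.0999  0.0971  0.0874  0.117        103

adjacent_class_test(tab, "4", ">4")  # paired one-tailed signed-rank
#> # A tibble: 1 × 7
#>   lower upper n_pairs n_zero_dropped statistic       p_value method
#>   <chr> <chr>   <int>          <int>     <dbl>         <dbl> <chr>
#> 1 4     >4         48              0      1172 0.00000000105 normal

autoplot(tab)                        # box plots by size class
```

Individuals receive contact aggression far more often per fight in the
largest size class — the population cost of cascades.

A thin command-line wrapper (`exec/igt.R`) chains the same steps:
`synth → correlate → fit → simulate → perturb → compare → cost`, each writing
a JSON manifest so every artefact is reproducible from its manifest alone.

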