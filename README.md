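# poprecover

Stochastic recovery analysis for stage-structured populations hit by an
environmental disaster.

When an oil spill or similar event depresses survival or reproduction for
a stretch of years, will the population return to its pre-event size — and
how long will that take? `poprecover` answers these questions for any
stage-structured life cycle by combining:

* an annual **projection matrix** with entries
  $P_i = \sigma_i(1-\gamma_i)$ (survive and stay),
  $G_i = \sigma_i\gamma_i$ (survive and advance) and a fecundity $b$;
* a **time-varying proportional reduction** $\varepsilon(t)$ of the
  targeted rates — held at $\varepsilon_0$ for $T_{Critical}$ years, then
  decaying to zero by $T_{End}$ along either a sigmoid
  ($a/(1+e^{t-T_M})-d$, the *continuous recovery function*) or a step
  (the *step recovery function*), with juvenile survival amplified by
  factors $c_j \ge 1$;
* **demographic stochasticity**: each individual's fate each year is a
  multinomial draw over stay/advance/die, and each potential mother
  produces a calf as an independent Bernoulli event.

Monte-Carlo replicates of the resulting nonautonomous model
$n(t) = A(\varepsilon(t))\,n(t-1)$ yield the recovery probability
$\Phi = S_N/K$ (the fraction of $K$ replicates whose total at year $N$ is
at or above the pre-event total) and the mean first-passage recovery time
among recovered, non-extinct replicates.

The packaged reference case is the Gulf-of-Mexico female sperm whale
population: five stages (calf, juvenile, mature, mother, post-breeding),
asymptotic growth rate $\lambda \approx 1.0096$ per year, and an initial
vector of 832 females derived from a census of 1665 whales at a 1:1 sex
ratio. It is intended for quantitative ecologists and ecotoxicological
risk assessors, but every component accepts arbitrary user-supplied life
cycles.

## Worked example

A disaster reduces adult survival by 6% and juvenile survival by 12%
($c_1 = c_2 = 2$) for ten years, after which the environment recovers
along a sigmoid completed at year 20:

```r
library(poprecover)

m <- recovery_model(scenario = disturbance(0.06, t_critical = 10, t_end = 20))
summary(m)
#> Population recovery model: 5 stages, 832 individuals at year 0
#>   pre-event growth rate lambda = 1.0096
#> Disturbance scenario (CRF, target: survival)
#>   epsilon0 = 0.06, t_critical = 10, t_end = 20
#>   juvenile amplification c1 = 2, c2 = 2
#>   sigmoid inflection policy: midpoint
#>   stable stage distribution: 0.0850 0.2078 0.3617 0.1783 0.1672
#>   initial stage vector: 71 173 301 148 139

recovery_probability(m, years = 100, reps = 5000, seed = 1)
#> Recovery endpoint (final rule, threshold 832, K = 5000, N = 100, seed 1)
#>   Phi = 0.2154  (recovered 1077 / 5000, MC se 0.0058)
#>   extinct replicates: 0
#>   recovery year among 1077 recovered non-extinct replicates: mean 94.7 (sd 4.6)
```

About one replicate in five is back to 832 females within a century; the
ones that make it do so only in the final decade. The same disaster
applied to *reproduction* instead — even total barrenness for ten years
(`disturbance(1, 10, 20, target = "fecundity")`) — leaves recovery
certain, because survival stays high while the population waits out the
barren years: for long-lived species, lethal impacts dominate comparable
sublethal ones.

Other entry points: `predict()` for the deterministic expected
trajectory, `simulate()`/`plot()` for replicate trajectories,
`mean_recovery_time()`, `sweep_grid()` for $\varepsilon_0 \times
T_{Critical}$ grids, `read_config()`/`write_config()` for YAML run
configurations (`sperm_whale_config()` is the packaged one), and a
command-line front end at `inst/cli/poprecover.R` with subcommands
`project`, `simulate`, `phi`, `mrt` and `sweep`.

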