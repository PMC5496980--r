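---
title: "Modeling population recovery after an environmental disaster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling population recovery after an environmental disaster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poprecover)
```

## The model

`poprecover` simulates the recovery of a stage-structured population after
a single environmental disaster — an oil spill is the motivating case — by
combining three ingredients:

1. a **stage-structured projection matrix** built from vital rates,
2. a **time-varying proportional reduction** of those rates that decays as
   the environment recovers, and
3. **demographic stochasticity**: every individual survives, develops and
   reproduces as an independent random event.

### The projection matrix

Each stage $i$ has an annual survivorship $\sigma_i$ and a conditional
transition probability $\gamma_i$: a surviving individual advances along
its life-cycle arc with probability $\gamma_i$ and stays put otherwise.
The matrix entries are therefore $P_i = \sigma_i(1-\gamma_i)$ (survive and
stay) and $G_i = \sigma_i\gamma_i$ (survive and advance), plus a single
annual fecundity $b$ (female offspring per reproducing female, at most one
per year). The packaged default is the five-stage female sperm whale life
cycle of the Gulf of Mexico population: calf → juvenile → mature → mother
→ post-breeding, with post-breeders returning to the mature stage and
births flowing from the mature stage to the calf stage. Any other
stay/advance wiring can be supplied through `vital_rates(advance_to =,
birth_from =, birth_to =)`; only the five-stage cycle ships with reference
numbers.

```{r}
whale <- sperm_whale_rates()
b <- projection_matrices(whale)
round(b$A, 4)
growth_rate(b)
round(stable_stage(b), 4)
```

The reference matrix grows at $\lambda \approx 1.0096$ per year — a slowly
growing population, which is what makes its recovery prospects after a
disaster a live question.

### Environmental recovery functions

A disaster reduces targeted vital rates proportionally by
$\varepsilon(t)$. Two shapes are available:

* the **continuous recovery function** (CRF) holds the reduction at
  $\varepsilon_0$ for `t_critical` years, then relaxes it along a sigmoid
  $a/(1+e^{t-T_M}) - d$ that reaches zero at `t_end`;
* the **step recovery function** (SRF) holds $\varepsilon_0$ until
  `t_critical` and then drops instantly to zero.

The sigmoid coefficients $a$ and $d$ are solved exactly from the two
boundary conditions $\varepsilon_c(T_{Critical}) = \varepsilon_0$ and
$\varepsilon_c(T_{End}) = 0$; tests verify the boundaries to $10^{-12}$.
The SRF is biologically implausible but useful: run with the step at
`t_critical` it bounds the CRF from above (best case), and with the step
at `t_end` from below (worst case), so a population's recovery prospects
can be bracketed without detailed knowledge of the environmental recovery
process. This bounding is asserted pointwise on $\varepsilon(t)$ and
Monte-Carlo-wise on recovery probabilities in the test suite.

**Where the inflection sits (`tm_policy`).** The boundary conditions fix
$a$ and $d$ but not $T_M$. The default, `"midpoint"`, places the
inflection at $T_M = (T_{Critical}+T_{End})/2$, the centre of the recovery
window, giving the symmetric S-shaped relaxation the model intends; this
choice reproduces the reference results for the sperm whale case. The
alternative `"literal"` policy, $T_M = (T_{End}-T_{Critical})/2$, measures
the half-window from the time origin rather than from the window; for
typical scenarios such as $(T_{Critical}, T_{End}) = (10, 20)$ it puts the
inflection at $t = 5$ — before recovery even begins — so the "sigmoid"
collapses into a near-instantaneous drop at `t_critical` and the CRF
becomes indistinguishable from the best-case SRF. Both policies satisfy
the boundary conditions exactly; only the shape between the boundaries
differs. We keep `"literal"` available because the formula appears in the
literature, but we consider it a transcription of the midpoint intent and
do not recommend it.

**Time indexing.** Abundances are censused annually, $n(0)$ being the
pre-event census taken at the moment of the disaster. The projection step
into year $t$ uses the environment of year $t$:
$n(t) = A(\varepsilon(t))\,n(t-1)$ for $t = 1, \dots, N$. Because the
sigmoid still equals $\varepsilon_0$ (to within a percent) at
$t = T_{Critical}$, a scenario with `t_critical = 10` exposes the
population to essentially the full reduction for its first ten years, as
the scenario's name suggests. The alternative convention — using
$\varepsilon(t)$ for the step *out of* year $t$ — would add one extra
fully-reduced year and systematically overstate the impact; with the
reference scenario it roughly triples the shortfall in the 100-year
recovery probability relative to the published characteristics of this
parameterization, which is why we fixed the convention this way.

### Lethal and sublethal targets

Lethal impacts (`target = "survival"`) scale adult survivorships by
$1-\varepsilon(t)$ and the two juvenile stages by $1 - c_j\varepsilon(t)$,
$c_j \ge 1$, because early life stages are typically more sensitive to
toxicants; the constraint $c_j\varepsilon_0 \le 1$ keeps rates in $[0,1]$
and is enforced at construction. Sublethal impacts
(`target = "fecundity"`) scale $b$ by $1-\varepsilon(t)$. Transition
probabilities $\gamma_i$ are never altered: a surviving individual's
development schedule is assumed unaffected. `target = "both"` applies both
reductions simultaneously; it is an extension beyond the two canonical
single-target analyses and is documented as such.

### Demographic stochasticity

One year of the stochastic model moves every individual independently:
the $n_j$ individuals of stage $j$ are distributed multinomially over the
$S+1$ fates of column $j$ of the fate matrix (stay, advance, die — the
appended death row makes each column a complete distribution, and column
sums are kept at exactly 1, a property the tests check with
`identical()`), and each of the $n_j$ potential parents produces one
female offspring with the fertility probability, independently of its own
fate that year. Multinomial draws are implemented as the exact conditional
binomial chain, which vectorizes across Monte-Carlo replicates; the
one-step distribution is verified in the tests against a brute-force
enumeration of all outcomes for tiny populations (chi-square at
$\alpha = 0.001$ on $10^5$ draws) and its mean against $A n$ (within 4
Monte-Carlo standard errors at $2\times10^4$ draws). Extinction (total
reaching zero) is absorbing.

## Endpoints

`recovery_probability()` estimates $\Phi$, the probability that the total
female abundance at the horizon $N$ is at or above its pre-event value
(or any chosen threshold), from $K$ independent replicates; extinct
replicates count as not recovered. The default rule checks the **final**
year only, matching the endpoint's definition; a **first-passage** rule
(any year $t \ge 1$ at or above the threshold) is available as a config
flag and is what `mean_recovery_time()` necessarily uses. Replicates that
never recover within the horizon are excluded from the mean recovery time
and reported, not imputed; so are extinct replicates. `sweep_grid()`
recomputes either endpoint over axes of $\varepsilon_0$ and/or
$T_{Critical}$, seeding each cell as `seed + cell` so cells are
reproducible independently of evaluation order.

Because the model tracks females only, "pre-event size" means the female
total (832 in the reference case, from a census of 1665 at a 1:1 sex
ratio), not the full census.

```{r}
m <- recovery_model(whale, disturbance(0.06, t_critical = 10, t_end = 20))
m
recovery_probability(m, years = 100, reps = 2000, seed = 1)
```

A 6% survival reduction for a decade leaves only about a one-in-five
chance of recovery within a century. Contrast a *complete* loss of
reproduction for the same decade:

```{r}
mf <- recovery_model(whale, disturbance(1, t_critical = 10, t_end = 20,
                                        target = "fecundity"))
recovery_probability(mf, years = 100, reps = 2000, seed = 1)
```

Recovery is certain: with adult survival above 0.97, ten barren years only
dent a long-lived population slightly. For long-lived species, lethal
effects dominate comparable sublethal effects — the classic pattern.

## Numerical and design choices

* **Initial vector rounding.** The female count is `floor(total × ratio)`
  and each stage's share of the stable distribution is rounded half-up
  entry by entry. For the reference census this reproduces
  (71, 173, 301, 148, 139), which sums exactly to 832, so no
  largest-remainder correction is needed.
* **Eigen-analysis** uses base `eigen()`; the dominant eigenpair is taken
  by maximum modulus, checked real, and the eigenvector sign-normalized to
  a probability vector. The eigenpair identity $Aw = \lambda w$ is tested
  to $10^{-10}$.
* **Reproducibility.** Every stochastic entry point takes an integer
  `seed`. Replicates advance in lockstep inside one vectorized stream, so
  a result is reproducible given the same (seed, reps, years) triple;
  grid cells get independent derived seeds.
* **Replicate counts.** Defaults are $K = 5000$ for recovery
  probabilities (binomial standard error $\approx 0.006$ at
  $\Phi = 0.2$) and $K = 1000$ per sweep cell; the Monte-Carlo
  checks in the test suite use $500$–$20000$ draws depending on the
  sharpness of the property tested. Calls with $K < 1000$ warn that the
  Monte-Carlo error may exceed reporting precision.
* **Degenerate inputs.** All-zero rates give the zero matrix with a
  death-row of ones; a CRF with `t_end = t_critical` degenerates to the
  SRF; zero populations propagate as zeros.

## What the simulator does and does not capture

The generator reproduces the study conditions of the reference analysis:
a closed single-sex population, constant pre-event rates, a single
disturbance, and individual-level demographic stochasticity. It does not
model environmental stochasticity in the rates, density dependence,
multi-year toxicant carry-over in individuals, two-sex dynamics,
immigration, or sequential disasters — so a high simulated recovery
probability speaks to demographic risk under the stated scenario, not to
all risks a real population faces. Vital-rate uncertainty (the reference
estimates are approximate and partly borrowed from other populations) is
also outside the scope: rates enter as point values, and interval
estimates on $\lambda$ from resampled rates are deliberately not
reproduced here.
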