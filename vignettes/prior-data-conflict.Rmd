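---
title: "Detecting prior-data conflict in Beta-Binomial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prior-data conflict in Beta-Binomial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbconflict)
library(dplyr)
```

## The problem

An elicited prior is a claim about data not yet seen. When the data arrive,
they may contradict that claim in two ways: the prior can put its mass far
from where the likelihood concentrates (a conflict in location), or it can be
far more precise than the data warrant (a conflict in information
uncertainty). `bbconflict` implements two checks for this situation in the
conjugate Beta-Binomial model, where an expert prior
$\pi^E(\theta) = \mathrm{Beta}(\alpha, \beta)$ meets binomial data $y_n$ with
$n$ trials and $s$ successes. Throughout we parameterize the prior by its
*location* $\alpha/(\alpha+\beta)$ and *concentration* $\alpha+\beta$.

## The two criteria

**Data Agreement Criterion (DAC).** Update a non-informative benchmark prior
$\pi^B = \mathrm{Beta}(1,1)$ with the data to get the benchmark posterior
$\pi^B(\theta \mid y_n) = \mathrm{Beta}(1+s,\, 1+n-s)$, which stands in for
"what the data say". The DAC is the ratio

$$ \mathrm{DAC} \;=\;
   \frac{\Delta\!\left(\pi^B(\theta \mid y_n)\,\|\,\pi^E(\theta)\right)}
        {\Delta\!\left(\pi^B(\theta \mid y_n)\,\|\,\pi^B(\theta)\right)}, $$

for a distance or divergence $\Delta$; a ratio strictly above 1 means the
oblivious benchmark prior agrees with the data better than the expert does,
and conflict is flagged. The flag needs no tuning, but it does need the
benchmark, and it treats the benchmark posterior as a temporary truth: with
little data the ratio can flag an expert who is merely more confident than a
small sample can corroborate.

**Prior-predictive surprise (Nott et al. style).** Measure how far the
expert's own posterior moved from the expert's prior,
$D(y_n) = \Delta(\pi^E(\theta \mid y_n)\,\|\,\pi^E(\theta))$, and calibrate
that movement against what the expert implicitly predicted: with $Y$ drawn
from the prior predictive (here Beta-Binomial$(n, \alpha, \beta)$),

$$ p \;=\; P\!\left(D(Y) \ge D(y_n)\right), $$

flagging conflict when $p \le 0.05$. Because $D$ depends on the data only
through the sufficient statistic $s$, the p-value is computed *exactly* by
enumerating the $n+1$ outcomes (`nott_p(..., method = "exact")`); a seeded
Monte Carlo backend (`method = "mc"`) reproduces the classical
draw-and-compare construction and agrees with enumeration within binomial
sampling error. The inclusive $\ge$ in the tail probability makes the
discrete p-value conservative (super-uniform) and $p = 1$ attainable.

Both criteria are generic over the distance measure. The registry
(`distance_measures()`) carries the twelve measures compared in the
simulation study -- total variation, Hellinger, Kolmogorov, Euclidean,
Manhattan, Sorensen, intersection, harmonic mean, Bhattacharyya, divergence,
Jeffreys, Jensen-Shannon -- plus the Kullback-Leibler divergence and the
Rényi family. Similarity-type entries (intersection, harmonic mean) are
registered as $1-$similarity so that larger always means more conflict, the
only orientation under which a single conflict rule can serve all measures.

```{r example}
expert <- beta_shape(20, 80)        # location 0.2, concentration 100
data <- binomial_sample(100, 50)    # the data sit at 0.5

tidy(dac(expert, data, "kullback_leibler"))
tidy(nott_p(expert, n = 100, s_obs = 50, "kullback_leibler"))
```

## Numerical choices

*Discretization.* All distances are evaluated on a common discretization of
$\theta \in [0,1]$: `bins` equal-width bins (default $B = 2000$) whose
probabilities are exact Beta CDF increments. CDF increments telescope, so
the masses sum to one even when a shape parameter is below 1 and the density
is unbounded at an endpoint -- which happens on the study grid (location
0.05 at concentration 10 gives $\alpha = 0.5$). Densities are never
evaluated at 0 or 1.

*Log-domain computation.* Beta-Binomial masses are computed from log Beta
functions and normalized in log space, so concentration 200 priors with
$n = 200$ do not overflow. Natural logarithms are used throughout; the base
cancels in the DAC ratio but not in ties of the surprise ordering, so it is
fixed for determinism.

*Underflow.* A bin's analytic mass is strictly positive, but the CDF
increment can underflow double precision deep in a tail. Bins whose linear
mass falls below $10^{-250}$ carry a stable log-mass computed by the
midpoint rule on the log density (the log density is nearly linear across a
bin there, so the rule is extremely accurate); log-ratio measures use these
stable logs. Bare numeric vectors without shape information fall back to a
$10^{-300}$ floor under logarithms. Bins where both masses vanish contribute
nothing.

*Accuracy.* Against the closed-form digamma identity for the Beta KL
divergence, the $B = 2000$ numeric path is accurate to about $3\times10^{-5}$
whenever the divergence is at most a couple of nats -- the regime that
contains the DAC $=1$ and $p = 0.05$ decision boundaries (the package's
tests pin this property). For nearly disjoint concentrated pairs the
divergence itself grows to hundreds of nats and the discrete sum undershoots
by an amount that grows with the divergence: a finite binning cannot resolve
the within-bin variation of the log ratio. Decisions are unaffected (those
cells are far beyond any threshold), but single distance *values* in the
deep-conflict region should not be read as high-precision integrals.
`euclidean` and `divergence` have no continuous limit under refinement of
probability-mass vectors and are documented as grid-dependent; an alternate
`mode = "density"` evaluation exists in `prob_distance()` so both
conventions (bin masses vs raw density values) can be compared.

*Degenerate input.* With $n = 0$ the benchmark posterior equals the
benchmark prior, the DAC denominator is 0, and `dac()` refuses; the surprise
discrepancy is identically 0 and `nott_p()` returns $p = 1$. A denominator
below $10^{-12}$ is treated the same way.

## The simulation study

`study_config()` fixes the study conditions: a population with
$\theta = 0.5$; sample sizes 50, 100, 200; expert priors on a grid crossing
locations $0.05, 0.07, \ldots, 0.95$ (46 values) with concentrations
$10, 12, \ldots, 200$ (96 values); the twelve registry measures; a
Beta(1,1) benchmark; conflict thresholds DAC $> 1$ and $p \le 0.05$.

`run_fixed_sample_grid()` evaluates both criteria for one fixed sample at
every grid cell. The sample's success count defaults to $s = n/2$, the modal
outcome at $\theta = 0.5$: the underlying single random sample's count is
not something that can be recovered, so the package uses the reproducible
modal stand-in and asserts the qualitative orderings softly. The orderings
this produces (with $n = 100$): Jeffreys is the most lenient DAC measure and
Kolmogorov the most stringent; under the surprise criterion the divergence
measure is the most lenient; and the area of the prior grid on which the
twelve measures disagree is several times larger for the DAC than for the
surprise criterion. `lenience_ranking()` and `consensus_partition()` compute
these summaries; ranking ties break alphabetically.

`run_replicates()` draws 1000 binomial samples per cell on a reduced grid
(locations 0.2--0.5, concentrations 50/100/200) and reports how often each
measure flags conflict. Both criteria enter a sample only through $s$, so
each cell computes each criterion once per distinct outcome and weights by
the empirical counts -- at most $n+1$ evaluations per cell per measure
regardless of the number of replicates (a property the tests verify against
brute-force per-sample evaluation). Child seeds derive from the master seed
by a fixed affine-mod scheme over cell indices, so any subset of cells
reproduces in isolation.

```{r replicates, eval = FALSE}
cfg <- study_config(n_values = 50, replicate_locations = 0.2,
                    replicate_concentrations = 50, replicates = 1000)
reps <- run_replicates(cfg)
autoplot(reps, criterion = "nott")
```

What the generator emulates -- and does not. The replicate generator draws
i.i.d. binomial samples at a known, fixed $\theta$; it makes no attempt to
model overdispersion, drift, or elicitation error in the expert priors
themselves. Passing tests therefore show that the criteria behave as
designed under a correctly specified sampling model; they say nothing about
robustness to misspecified likelihoods, which both criteria would attribute
to the prior-data relationship.

## Design decisions worth knowing

- **Exact enumeration is the default p-value backend.** The classical
  construction draws $10^5$ predictive replicates; enumeration over the
  $n+1$ outcomes is exact and faster, and the Monte Carlo backend remains
  available (and tested against enumeration) for fidelity to that
  construction.
- **Distances are computed on normalized bin-probability vectors.** This
  makes the dimensionless measures well defined, at the cost of making total
  variation, Manhattan and Sorensen exact multiples of one another -- hence
  rank-equivalent, with identical DAC values (the ratio cancels the scale).
  Distinct published decision contours for these three measures most likely
  reflect mixing continuous-distribution routines with raw density vectors;
  `mode = "density"` lets a user reproduce that convention without the
  package endorsing either.
- **The DAC is U-shaped in concentration at a matching location.** With
  location fixed at the truth and $s = n/2$, the ratio is smallest when the
  expert's concentration matches the benchmark posterior's ($n+2$) and grows
  on both sides; the overconfident branch is the "conflict in information
  uncertainty" regime. Tests assert the U shape rather than global
  monotonicity.
- **Anomalous measures are run, not excluded.** The divergence measure (and
  to a lesser extent Euclidean) behaves erratically at low concentrations;
  the study reports these anomalies rather than filtering them.
- **Problem sizes in the test-suite.** The packaged checks run the full
  46 x 96 grid at $n = 100$ and a 200-replicate sweep of the most
  diagnostic cell; module tests use coarser binnings (200--1000 bins) where
  only determinism or counting is at stake.

## Limitations

One-dimensional conjugate Beta-Binomial only: no hierarchical or
non-conjugate posteriors, no multi-parameter $\theta$, no improper
benchmarks (a distance to an improper prior is not defined, and the
benchmark here is always a proper Beta). The registry is the fixed set of
fourteen measures; it is not a general f-divergence framework. Exact
boundary positions of published decision contours are not bit-reproducible
because the underlying single sample and discretization are not published;
the package reproduces the orderings and rates that do not depend on them.
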