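---
title: "Optimal allocation and sample size for two-arm cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal allocation and sample size for two-arm cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtoptim)
```

## The design problem

In a parallel two-arm cluster randomized trial (CRT) intact groups —
schools, villages, practices — are randomized, and a continuous outcome is
measured on `m` individuals per cluster. When measurement is burdensome or
expensive (accelerometry, anthropometry, household surveys), the number of
individuals *measured* is the quantity to economize, and it need not equal
the number exposed. crtoptim addresses the design question: given a total
number of clusters `K`, how should clusters and measured individuals be
split between the arms, and how large should the cluster sizes be in each
arm, to reach a target power with the fewest measurements?

Unequal allocation pays off when the arms differ in their variance
structure. An intervention that standardizes care can shrink the
intracluster correlation (ICC) or the outcome variance in the intervention
arm; participatory interventions adapted locally can inflate them. The
package therefore keeps four variance parameters: the control-arm total
variance `sigma0_sq`, the variance ratio `gamma` (intervention over
control), and arm-specific ICCs `rho0` and `rho1`.

## Model and power function

Outcomes follow a random-intercept model per arm: for individual $j$ in
cluster $i$ with arm indicator $X_i$,

$$Y_{ij} = \beta_0 + \beta_1 X_i + (1-X_i)u_{0i} + X_i u_{1i}
  + (1-X_i)\varepsilon_{0ij} + X_i \varepsilon_{1ij},$$

with independent mean-zero Normal cluster effects and errors whose
variances are $\rho\sigma^2_{\text{arm}}$ and
$(1-\rho)\sigma^2_{\text{arm}}$. A design is summarized by the total
measured $N$, total clusters $K$, the proportion $p$ of measured
individuals in the intervention arm and the proportion $g$ of clusters
there; these determine the per-arm cluster sizes
$m_1 = pN/(gK)$ and $m_0 = (1-p)N/((1-g)K)$.

Each arm contributes an effective sample size, its count deflated by the
design effect $1+(m-1)\rho$:

$$ESS_0 = \frac{(1-p)N}{1+(m_0-1)\rho_0}, \qquad
  ESS_1 = \frac{pN}{1+(m_1-1)\rho_1},$$

and the large-sample two-sided power to detect a mean difference $d$ is

$$\Phi\!\left(\frac{d/\sigma_0}{\sqrt{1/ESS_0+\gamma/ESS_1}}
  - Z_{1-\alpha/2}\right).$$

`crt_power()` evaluates this in two algebraically identical
parameterizations (`form = "ess"` / `"design-effect"`) so that the
equivalence is a checkable property rather than an assumption. All
quantiles are computed to machine precision; no table-rounded $Z$ values
are used anywhere, because the reference design values are reproduced only
at full precision.

## Optimal allocation

Maximizing power at fixed $(N, K)$ separates in $p$ and $g$: the objective
can be written
$\frac{1-\rho_0}{1-p} + \frac{\gamma(1-\rho_1)}{p}
 + \frac{N\rho_0}{(1-g)K} + \frac{\gamma N \rho_1}{gK}$,
so each proportion has its own closed-form optimum regardless of the
other:

$$\frac{p_{opt}}{1-p_{opt}} = \sqrt{\frac{\gamma(1-\rho_1)}{1-\rho_0}},
\qquad
\frac{g_{opt}}{1-g_{opt}} = \sqrt{\frac{\gamma\rho_1}{\rho_0}}.$$

Individuals go in proportion to the square root of within-cluster
variability, clusters to the square root of between-cluster variability.
With equal variance and realistic ICC differences, $p_{opt}$ stays very
close to 1/2 while $g_{opt}$ can be far from it — the efficiency of
unequal designs comes from where the *clusters* go, not the individuals.

`optimal_allocation_fixed_sizes()` covers the older regime where both
cluster sizes are prespecified; there the optimum follows the
design-effect-inflated variances,
$p/(1-p) = \sqrt{\gamma[1+(m_1-1)\rho_1]/[1+(m_0-1)\rho_0]}$. The two
regimes genuinely disagree except in symmetric cases (for instance equal
ICCs with equal cluster sizes, where both reduce to $\sqrt{\gamma}$): with
sizes frozen, measuring more individuals in the high-ICC arm is the only
way to buy that arm more clusters. The package implements both and the
test suite asserts the coincidence case and the direction of the
disagreement, not a false equivalence.

### Degenerate ICCs

If $\rho_0 = \rho_1 = 0$ clustering is irrelevant; `optimal_allocation()`
returns `g_opt = 0.5` flagged `clusters_immaterial`. If exactly one ICC is
zero the formal optimum is a boundary ($g_{opt}$ of 0 or 1); the boundary
value is returned with a warning and `boundary = TRUE` instead of being
passed off as an interior design, since a realizable trial needs clusters
in both arms. $\rho = 1$ is rejected at construction.

## Sample size and feasibility

`solve_total_n()` inverts the power function for $N$ given $(K, p, g)$:

$$N\left[\frac{d^2}{\sigma_0^2(Z_{1-\alpha/2}+Z_{1-\beta})^2}
 - \frac{\gamma\rho_1}{gK} - \frac{\rho_0}{(1-g)K}\right]
 = \frac{1-\rho_0}{1-p} + \frac{\gamma(1-\rho_1)}{p}.$$

The bracket is positive — a finite solution exists — only when $K$ exceeds
the bound returned by `min_clusters()`; below it the between-cluster
variance cannot be averaged away no matter how many individuals are
measured, and the solver raises an explicit infeasibility error rather
than returning a negative total. `solve_total_n_fixed_arms()` is the same
equation with the per-arm cluster counts fixed.

## From continuous optimum to realizable trial

Continuous optima involve fractional clusters and cluster sizes.
`round_optimal_design()` makes a trial out of them in a fixed order chosen
to preserve the power guarantee:

1. `K1 = round(g_opt * K)` (nearest integer; ties round up), `K0 = K - K1`;
2. a provisional continuous total from the fixed-arms equation at `p_opt`;
3. both cluster sizes rounded **up**, so the achieved power, re-evaluated
   with `crt_power()`, is always at least the target.

This rounding path reproduces the reference design table for the school
physical-activity scenario (control ICC 0.1, intervention ICC 0.01,
standardized effect 0.278, 80% power) at every tabulated `K` except
`K = 38`, where the published row corresponds to a different rounding
variant; the discrepancy is a handful of individuals and our rule is the
one that carries a provable power guarantee, so it is used uniformly. The
same reasoning fixes the equal-allocation comparator (`equal_design()`):
the common cluster size is always rounded up, which reproduces the
published comparator at `K = 40, 46, 50`; the published value at `K = 30`
(1500) implies round-to-nearest and is not matched deliberately.

`round_constrained_design()` clamps the cluster split to a minimum number
of clusters per arm — small arms invalidate common analysis methods, so a
floor of 8–10 clusters per arm is standard practice — and then follows the
same path.

### Fixed cluster size in one arm

When one arm's cluster size is capped (consent rates, facility size),
fixing `m1` ties $p$ and $g$ together through
$m_0 = (N - gKm_1)/((1-g)K)$, and no closed-form optimum exists: the
optimum now depends on $N$ and $K$ jointly. `fixed_m1_design()` searches
the integer cluster splits directly: for each admissible `K1` it solves
the power equation *exactly* for the continuous control-arm cluster size
(a one-line rearrangement — no grid walk), ceilings it, and keeps the
split minimizing the realized total. Ties are broken toward more
intervention clusters, which respects the minimum-clusters motivation. The
companion `power_curve_fixed_m1()` reproduces the graphical version of the
same search — power over a `(g, N)` grid — for inspection; its default
N-grid step of 5 in the CLI is a presentation choice, the optimizer itself
never uses a grid. Infeasible grid cells (intervention arm consuming all
measurements, or an implied control cluster size below one individual) are
flagged, not dropped, so curves plot over the full requested range.

## Suboptimal designs and parameter uncertainty

`suboptimal_curve()` traces the theoretical $N$ as one proportion moves
off-optimum, which is how a trialist prices a logistically preferred
allocation; the curve is convex with its minimum at the closed-form
optimum, and is typically flat nearby — modest deviations cost little.

`uncertainty_sweep()` handles the realistic situation where the ICCs are
only known to ranges. It evaluates required totals at every corner of the
ICC (optionally also variance-ratio) box over a grid of `g`, and
recommends the rounded design sized at the all-high corner: any design
powered there is powered everywhere in the box, by monotonicity of the
required total in the ICCs. The sweep holds $p$ fixed because $p_{opt}$
barely moves across realistic ranges (0.507–0.512 over the box used in
the examples). The recommendation is deliberately conservative; if the
true parameters sit at the low corner the design is overpowered, and more
refined (e.g. prior-weighted) strategies are out of scope.

## Monte Carlo validation

The simulation module is the package's check that the analytic machinery
matches the model it claims to describe. `simulate_trial()` draws full
individual-level datasets from the random-effects model;
`empirical_power()` tests each replicate with the known-variance $z$
contrast — the difference in arm means standardized by
$\sqrt{\sigma_0^2/ESS_0 + \gamma\sigma_0^2/ESS_1}$ — because that statistic
is exactly what the large-sample power function describes. Using estimated
variances instead would entangle formula validation with small-sample
estimation noise; a cluster-level Welch t-test (`test = "cluster_t"`) is
provided for realism but is not the validation oracle, and with few
clusters it sits below the analytic value, as large-sample formulas
should be expected to.

Reproducibility: each replicate derives its own seed as
`(seed + 48271 * replicate) mod (2^31 - 1)`, so replicate `r` is
identical whether generated alone or inside a sweep, serially or in
parallel.

What the simulations do and do not show: they confirm the power and
variance formulas under the generating model — Normal errors, a common
cluster size within arm, no attrition, no baseline covariates. Real trials
violate all of these to some degree; in particular variable cluster sizes
within an arm inflate the design effect beyond $1+(m-1)\rho$, and with
few clusters the intended mixed-model analysis has its own
degrees-of-freedom corrections that the known-variance theory ignores.
Passing tests here validate the mathematics, not those robustness claims.

## Problem sizes and numerical choices

The validation suite uses 2,000 replicates per design for the
five-design panel and 10,000 replicates for the headline empirical-power
and type-I checks, with agreement asserted within three binomial Monte
Carlo standard errors; the ICC-recovery check uses 2,000 clusters of 50
per arm, where the ANOVA moment estimator is accurate to a few
thousandths. Grid oracles for the optima use a step of 0.001–0.002 and
assert agreement to one grid step. Internal identities (the two power
forms, solver round-trips, arm-swap symmetry) are asserted at 1e-10 to
1e-12. Nearest-integer rounding of the cluster split uses
`floor(x + 0.5)` so that halves round up deterministically rather than
to even.

## Limitations

Everything is large-sample normal theory: no t/Satterthwaite small-sample
corrections, no binary or count outcomes, no baseline measurements, no
within-arm cluster-size variation, no cost-weighted optimality. The
minimum-clusters constraint is the blunt, practical guard against the
small-sample regime; the formulas themselves do not know about it.
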