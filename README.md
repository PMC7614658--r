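# crtoptim

Optimal design of two-arm parallel cluster randomized trials (CRTs) with a
continuous outcome, when the intracluster correlation (ICC) and the outcome
variance may differ between arms and **both** the allocation of clusters and
the cluster size (individuals *measured* per cluster) may be chosen freely
per arm.

## Who this is for

Trial statisticians sizing a CRT where measurement is the expensive part —
accelerometer wear, anthropometry, household surveys — and where the
intervention itself may change the variance structure (standardizing care
shrinks the ICC; locally adapted interventions can inflate it). Given a
number of clusters `K`, the package finds the design measuring the fewest
individuals `N` that reaches a target power, with or without practical
constraints (minimum clusters per arm, a cap on cluster size).

## The model and the core results

Outcomes follow a per-arm random-intercept model
`Y_ij = β0 + β1·X_i + u_i + ε_ij`, with arm-specific total variance
(`σ0²` control, `γσ0²` intervention) and arm-specific ICCs `ρ0`, `ρ1`.
A design is `(N, K, p, g)`: `p` the share of measured individuals and `g`
the share of clusters in the intervention arm, which determine the per-arm
cluster sizes `m1 = pN/(gK)`, `m0 = (1−p)N/((1−g)K)`. With the
arm-specific effective sample size `ESS = n_arm / (1+(m−1)ρ)`, the
large-sample two-sided power to detect a mean difference `d` is

    Φ( (d/σ0) / sqrt(1/ESS0 + γ/ESS1) − z_{1−α/2} ).

Power at fixed `(N, K)` is maximized in closed form, separately in each
proportion:

    p_opt/(1−p_opt) = sqrt( γ(1−ρ1) / (1−ρ0) )     (individuals)
    g_opt/(1−g_opt) = sqrt( γρ1 / ρ0 )             (clusters)

— individuals follow the square root of within-cluster variability,
clusters the square root of between-cluster variability. Sample-size
solvers, feasibility bounds (a minimum `K` below which no finite `N`
suffices), integer rounding with a power guarantee, constrained searches,
sensitivity sweeps over ICC ranges, and Monte Carlo validation from the
generating model are built on top.

## Worked example

A school-based physical-activity trial measures 40 students in each of 30
schools (15 per arm); that design detects a standardized effect of 0.278
with 80% power if both ICCs are 0.05. Suppose instead the control arm
(routine practice, highly variable between schools) has ICC 0.1 and the
standardizing intervention has ICC 0.01, equal variance:

```r
library(crtoptim)
mod <- outcome_model(rho0 = 0.1, rho1 = 0.01)
eff <- effect_spec(d = 0.278)           # alpha = 0.05, power = 0.8

optimal_allocation(mod)
#> Optimal allocation: p_opt = 0.512, g_opt = 0.240
#>   ratios: p/(1-p) = 1.049, g/(1-g) = 0.3162
```

Nearly half the *individuals* but under a quarter of the *clusters* go to
the intervention arm: the low-ICC arm gets few, large clusters. Realizable
designs over a range of `K`, next to the conventional balanced design:

```r
design_table(c(30, 40, 50), mod, eff)
#>   K K0 K1 m0 m1   N N_equal power_achieved
#>  30 23  7 20 68 936    1530         0.8013
#>  40 30 10 12 36 720     880         0.8105
#>  50 38 12  8 26 616     700         0.8099
```

At `K = 30` the optimal design measures 936 students where the balanced
design needs ~1500; the advantage shrinks as clusters become plentiful.
If at most 45 students per school can be measured and each arm must keep
at least 10 schools:

```r
fixed_m1_design(30, 45, mod, eff, design_constraints(min_clusters_per_arm = 10))
#> Integer design: K0 = 20, K1 = 10, m0 = 28, m1 = 45, N = 1010
```

with achieved power 0.8016. A command-line interface wraps the same
functions:

```sh
./exec/crtoptim size --k-min 30 --k-max 50 --k-step 2 \
    --d 0.278 --rho0 0.1 --rho1 0.01 --out designs.csv
```

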