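# Shared fixtures and independent oracles.

# Reference scenario: school trial, highly variable routine practice
# (control ICC 0.1), standardizing intervention (ICC 0.01), equal variance.
school_model <- function() outcome_model(sigma0_sq = 1, gamma = 1,
                                         rho0 = 0.1, rho1 = 0.01)
school_effect <- function() effect_spec(d = 0.278, alpha = 0.05, power = 0.8)

# Independent power oracle: variance of the difference in arm means written
# directly from counts (never through effective_sample_sizes / crt_power).
oracle_power <- function(K0, K1, m0, m1, d, rho0, rho1,
                         sigma0_sq = 1, gamma = 1, alpha = 0.05) {
  v <- sigma0_sq * (1 + (m0 - 1) * rho0) / (K0 * m0) +
    gamma * sigma0_sq * (1 + (m1 - 1) * rho1) / (K1 * m1)
  pnorm(abs(d) / sqrt(v) - qnorm(1 - alpha / 2))
}

# Random valid model/design draws for property tests.
random_model <- function() {
  outcome_model(sigma0_sq = runif(1, 0.2, 5), gamma = runif(1, 0.3, 3),
                rho0 = runif(1, 0.005, 0.3), rho1 = runif(1, 0.005, 0.3))
}

random_continuous_design <- function() {
  K <- runif(1, 10, 80)
  continuous_design(N = runif(1, 5, 60) * K, K = K,
                    p = runif(1, 0.15, 0.85), g = runif(1, 0.15, 0.85))
}

# ANOVA-style moment estimator of the ICC from balanced cluster data.
sample_icc <- function(y, m) {
  ymat <- matrix(y, nrow = m)
  k <- ncol(ymat)
  cmeans <- colMeans(ymat)
  msb <- m * sum((cmeans - mean(y))^2) / (k - 1)
  msw <- sum(sweep(ymat, 2, cmeans)^2) / (k * (m - 1))
  (msb - msw) / (msb + (m - 1) * msw)
}
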