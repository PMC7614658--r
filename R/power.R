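# Analytic power and sample-size solvers (large-sample normal theory).

#' Analytic power of a two-arm cluster randomized trial design
#'
#' Large-sample normal-approximation power for the two-sided test of a
#' difference in means. Two algebraically equivalent parameterizations are
#' provided: `"ess"` writes the variance of the estimated difference through
#' the arm-specific effective sample sizes,
#' \deqn{\Phi\!\left(\frac{|d|/\sigma_0}{\sqrt{1/ESS_0 + \gamma/ESS_1}}
#'   - Z_{1-\alpha/2}\right),}
#' while `"design-effect"` writes it through the design effects and the
#' numbers measured per arm directly. They agree to machine precision; the
#' option exists to make that equivalence checkable.
#'
#' @param design A `crt_design` (continuous or integer).
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()]; `d = 0` is allowed and returns
#'   \eqn{\alpha/2}.
#' @param form Which parameterization to evaluate (default `"ess"`).
#' @return The power, a probability in (0, 1).
#' @examples
#' des <- integer_design(K0 = 15, K1 = 15, m0 = 40, m1 = 40)
#' mod <- outcome_model(rho0 = 0.05, rho1 = 0.05)
#' crt_power(des, mod, effect_spec(d = 0.278))
#' @export
crt_power <- function(design, model, effect, form = c("ess", "design-effect")) {
  form <- match.arg(form)
  stopifnot(inherits(model, "crt_model"), inherits(effect, "crt_effect"))
  std <- abs(effect$d) / sqrt(model$sigma0_sq)
  if (form == "ess") {
    ess <- effective_sample_sizes(design, model)
    se_sq <- 1 / ess$ess0 + model$gamma / ess$ess1
  } else {
    deff0 <- 1 + (design$m0 - 1) * model$rho0
    deff1 <- 1 + (design$m1 - 1) * model$rho1
    se_sq <- deff0 / ((1 - design$p) * design$N) +
      model$gamma * deff1 / (design$p * design$N)
  }
  stats::pnorm(std / sqrt(se_sq) - z_alpha(effect$alpha))
}

# Shared right-hand side of the sample-size equation:
# (1-rho0)/(1-p) + gamma*(1-rho1)/p.
.size_numerator <- function(p, model) {
  (1 - model$rho0) / (1 - p) + model$gamma * (1 - model$rho1) / p
}

# d^2 / (sigma0^2 (Z_{1-a/2} + Z_{1-b})^2), the per-individual information
# the design must supply.
.size_target <- function(model, effect) {
  if (effect$d == 0) {
    stop("invalid parameter: a nonzero target difference `d` is required ",
         "to solve for sample size", call. = FALSE)
  }
  effect$d^2 / (model$sigma0_sq * (z_alpha(effect$alpha) + z_beta(effect$power))^2)
}

#' Total individuals required given clusters and allocation proportions
#'
#' Solves the large-sample power equation for the total number of
#' individuals measured `N`, given the total clusters `K` and the allocation
#' proportions `p` (individuals) and `g` (clusters):
#' \deqn{N\left[\frac{d^2}{\sigma_0^2 (Z_{1-\alpha/2}+Z_{1-\beta})^2}
#'   - \frac{\gamma\rho_1}{gK} - \frac{\rho_0}{(1-g)K}\right]
#'   = \frac{1-\rho_0}{1-p} + \frac{\gamma(1-\rho_1)}{p}.}
#' A positive solution exists only when the bracketed term is positive, i.e.
#' when `K` exceeds [min_clusters()]: with too few clusters the
#' between-cluster variance cannot be averaged away however many individuals
#' are measured.
#'
#' @param K Total clusters.
#' @param p,g Allocation proportions for individuals and clusters, in (0, 1).
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @return The real-valued total `N` achieving the target power exactly.
#' @examples
#' mod <- outcome_model(rho0 = 0.1, rho1 = 0.01)
#' eff <- effect_spec(d = 0.278)
#' solve_total_n(K = 40, p = 0.512, g = 0.25, mod, eff)
#' @export
solve_total_n <- function(K, p, g, model, effect) {
  K <- check_scalar(K, "K", 0, open_lower = TRUE)
  p <- check_scalar(p, "p", 0, 1, TRUE, TRUE)
  g <- check_scalar(g, "g", 0, 1, TRUE, TRUE)
  bracket <- .size_target(model, effect) -
    model$gamma * model$rho1 / (g * K) - model$rho0 / ((1 - g) * K)
  if (bracket <= 0) {
    stop("No valid solution (N > 0): K = ", K, " does not exceed the ",
         "feasibility bound K > sigma0^2*(Z[1-alpha/2]+Z[1-beta])^2/d^2 * ",
         "(gamma*rho1/g + rho0/(1-g)) = ",
         signif(min_clusters(g, model, effect), 6), call. = FALSE)
  }
  .size_numerator(p, model) / bracket
}

#' Total individuals required given fixed clusters per arm
#'
#' Variant of [solve_total_n()] for the common situation where the numbers
#' of clusters in each arm, `K0` and `K1`, are fixed (equivalently `g` is
#' fixed at `K1/(K0+K1)`):
#' \deqn{N\left[\frac{d^2}{\sigma_0^2 (Z_{1-\alpha/2}+Z_{1-\beta})^2}
#'   - \frac{\gamma\rho_1}{K_1} - \frac{\rho_0}{K_0}\right]
#'   = \frac{1-\rho_0}{1-p} + \frac{\gamma(1-\rho_1)}{p}.}
#'
#' @param K0,K1 Clusters in the control / intervention arm.
#' @param p Proportion of measured individuals in the intervention arm.
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @return The real-valued total `N`.
#' @export
solve_total_n_fixed_arms <- function(K0, K1, p, model, effect) {
  K0 <- check_scalar(K0, "K0", 1)
  K1 <- check_scalar(K1, "K1", 1)
  p <- check_scalar(p, "p", 0, 1, TRUE, TRUE)
  bracket <- .size_target(model, effect) -
    model$gamma * model$rho1 / K1 - model$rho0 / K0
  if (bracket <= 0) {
    stop("No valid solution (N > 0): with K0 = ", K0, " and K1 = ", K1,
         " the required information exceeds what any number of individuals ",
         "can supply (need gamma*rho1/K1 + rho0/K0 < d^2/(sigma0^2*",
         "(Z[1-alpha/2]+Z[1-beta])^2))", call. = FALSE)
  }
  .size_numerator(p, model) / bracket
}

#' Minimum number of clusters for a feasible trial
#'
#' Below this bound no finite number of individuals achieves the target
#' power, because the between-cluster component of variance is averaged over
#' clusters, not individuals:
#' \deqn{K > \frac{\sigma_0^2 (Z_{1-\alpha/2}+Z_{1-\beta})^2}{d^2}
#'   \left[\frac{\gamma\rho_1}{g} + \frac{\rho_0}{1-g}\right].}
#'
#' @param g Proportion of clusters allocated to the intervention arm.
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @return The strict lower bound on the total number of clusters (real;
#'   0 when both ICCs are 0).
#' @export
min_clusters <- function(g, model, effect) {
  g <- check_scalar(g, "g", 0, 1, TRUE, TRUE)
  (model$gamma * model$rho1 / g + model$rho0 / (1 - g)) / .size_target(model, effect)
}

#' Detectable difference for a fixed design
#'
#' Inverts the power function: the difference in means detectable with the
#' requested power at the requested two-sided level is
#' \deqn{d = \sigma_0 (Z_{1-\alpha/2} + Z_{1-\beta})
#'   \sqrt{1/ESS_0 + \gamma/ESS_1}.}
#'
#' @param design A `crt_design`.
#' @param model An [outcome_model()].
#' @param power Target power, in (0, 1).
#' @param alpha Two-sided significance level.
#' @return The detectable difference `d`, in outcome units (divide by
#'   \eqn{\sigma_0} for the standardized effect).
#' @examples
#' des <- integer_design(K0 = 15, K1 = 15, m0 = 40, m1 = 40)
#' solve_effect_size(des, outcome_model(rho0 = 0.05, rho1 = 0.05))
#' @export
solve_effect_size <- function(design, model, power = 0.8, alpha = 0.05) {
  power <- check_scalar(power, "power", 0, 1, TRUE, TRUE)
  alpha <- check_scalar(alpha, "alpha", 0, 1, TRUE, TRUE)
  ess <- effective_sample_sizes(design, model)
  sqrt(model$sigma0_sq) * (z_alpha(alpha) + stats::qnorm(power)) *
    sqrt(1 / ess$ess0 + model$gamma / ess$ess1)
}
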