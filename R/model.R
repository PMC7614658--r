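# Parameter containers: outcome variance model and target effect.

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("invalid parameter: `", name, "` must be a single finite number",
         call. = FALSE)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop("invalid parameter: `", name, "` = ", x, " is outside ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", call. = FALSE)
  }
  as.numeric(x)
}

#' Outcome variance model for a two-arm cluster randomized trial
#'
#' Describes the arm-specific variance structure of a continuous outcome
#' measured in a parallel-group cluster randomized trial. The outcome in each
#' arm decomposes into a cluster-level random effect and an individual-level
#' error, both Normal; the intracluster correlation (ICC) is the proportion of
#' total variance attributable to between-cluster variability and is allowed
#' to differ between arms, as is the total variance.
#'
#' @param sigma0_sq Total outcome variance in the control arm
#'   (outcome units squared). Must be positive.
#' @param gamma Ratio of the intervention-arm to the control-arm total
#'   variance, \eqn{\gamma = \sigma_1^2 / \sigma_0^2}. Must be positive.
#' @param rho0,rho1 Intracluster correlation in the control and intervention
#'   arm respectively; each must lie in \eqn{[0, 1)}. \eqn{\rho = 1} is
#'   rejected because the effective sample size degenerates as the cluster
#'   size varies.
#'
#' @return An object of class `crt_model`: a list with the four inputs plus
#'   the implied variance components `sigma0u_sq`, `sigma0e_sq` (control-arm
#'   between-cluster and within-cluster variance) and `sigma1u_sq`,
#'   `sigma1e_sq` (intervention arm).
#'
#' @examples
#' outcome_model(sigma0_sq = 1, gamma = 1, rho0 = 0.1, rho1 = 0.01)
#' @export
outcome_model <- function(sigma0_sq = 1, gamma = 1, rho0, rho1) {
  sigma0_sq <- check_scalar(sigma0_sq, "sigma0_sq", lower = 0, open_lower = TRUE)
  gamma <- check_scalar(gamma, "gamma", lower = 0, open_lower = TRUE)
  rho0 <- check_scalar(rho0, "rho0", lower = 0, upper = 1, open_upper = TRUE)
  rho1 <- check_scalar(rho1, "rho1", lower = 0, upper = 1, open_upper = TRUE)
  structure(
    list(
      sigma0_sq = sigma0_sq, gamma = gamma, rho0 = rho0, rho1 = rho1,
      sigma0u_sq = rho0 * sigma0_sq,
      sigma0e_sq = (1 - rho0) * sigma0_sq,
      sigma1u_sq = rho1 * gamma * sigma0_sq,
      sigma1e_sq = (1 - rho1) * gamma * sigma0_sq
    ),
    class = "crt_model"
  )
}

#' @export
print.crt_model <- function(x, ...) {
  cat("Two-arm cluster trial outcome model\n")
  cat(sprintf("  control:      total variance %.4g, ICC %.4g\n",
              x$sigma0_sq, x$rho0))
  cat(sprintf("  intervention: total variance %.4g (gamma = %.4g), ICC %.4g\n",
              x$gamma * x$sigma0_sq, x$gamma, x$rho1))
  invisible(x)
}

#' Target effect, significance level and power
#'
#' @param d Target difference in outcome means, in outcome units. May be
#'   negative (the two-sided test is symmetric; its absolute value is used in
#'   power calculations) and may be zero for null/type-I-error checks.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Desired power \eqn{1 - \beta}, in (0, 1).
#'
#' @return An object of class `crt_effect` with components `d`, `alpha`,
#'   `power`.
#' @examples
#' effect_spec(d = 0.278, alpha = 0.05, power = 0.8)
#' @export
effect_spec <- function(d, alpha = 0.05, power = 0.8) {
  d <- check_scalar(d, "d")
  alpha <- check_scalar(alpha, "alpha", 0, 1, TRUE, TRUE)
  power <- check_scalar(power, "power", 0, 1, TRUE, TRUE)
  structure(list(d = d, alpha = alpha, power = power), class = "crt_effect")
}

#' @export
print.crt_effect <- function(x, ...) {
  cat(sprintf(
    "Target difference %.4g at two-sided alpha = %.3g, power = %.3g\n",
    x$d, x$alpha, x$power))
  invisible(x)
}

# Normal quantiles used throughout; full machine precision, never table values.
z_alpha <- function(alpha) stats::qnorm(1 - alpha / 2)
z_beta <- function(power) stats::qnorm(power)
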