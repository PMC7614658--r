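# Trial design containers and the cluster-size identities.

#' Cluster sizes implied by totals and allocation proportions
#'
#' Given the total number of individuals measured `N`, the total number of
#' clusters `K`, the proportion `p` of measured individuals in the
#' intervention arm and the proportion `g` of clusters in the intervention
#' arm, the common cluster size in each arm is determined:
#' \deqn{m_1 = pN/(gK), \qquad m_0 = (1-p)N/((1-g)K).}
#'
#' @param N Total individuals measured (real, > 0).
#' @param K Total clusters (real, > 0).
#' @param p Proportion of measured individuals in the intervention arm, (0, 1).
#' @param g Proportion of clusters in the intervention arm, (0, 1).
#'
#' @return A list with components `m0` and `m1` (control- and
#'   intervention-arm cluster size; real-valued).
#' @examples
#' cluster_sizes(N = 1200, K = 30, p = 0.5, g = 0.5)
#' @export
cluster_sizes <- function(N, K, p, g) {
  N <- check_scalar(N, "N", 0, open_lower = TRUE)
  K <- check_scalar(K, "K", 0, open_lower = TRUE)
  p <- check_scalar(p, "p", 0, 1, TRUE, TRUE)
  g <- check_scalar(g, "g", 0, 1, TRUE, TRUE)
  list(m0 = (1 - p) * N / ((1 - g) * K), m1 = p * N / (g * K))
}

#' Continuous (real-valued) trial design
#'
#' A design described by totals and allocation proportions, with real-valued
#' cluster sizes derived via [cluster_sizes()]. Integrality is imposed only
#' when a continuous optimum is rounded to a realizable design
#' (see [round_optimal_design()]).
#'
#' @inheritParams cluster_sizes
#' @return An object of classes `crt_design_continuous`, `crt_design`, with
#'   components `N`, `K`, `p`, `g`, `m0`, `m1`.
#' @examples
#' continuous_design(N = 936, K = 30, p = 0.512, g = 7 / 30)
#' @export
continuous_design <- function(N, K, p, g) {
  m <- cluster_sizes(N, K, p, g)
  structure(
    list(N = N, K = K, p = p, g = g, m0 = m$m0, m1 = m$m1),
    class = c("crt_design_continuous", "crt_design")
  )
}

#' Integer (realizable) trial design
#'
#' A design a trialist can actually run: integer numbers of clusters per arm
#' and integer common cluster sizes. The total measured is
#' `N = K0 * m0 + K1 * m1` exactly; the allocation proportions `p` and `g`
#' are derived.
#'
#' @param K0,K1 Clusters in the control / intervention arm (integers >= 1).
#' @param m0,m1 Individuals measured per cluster in the control /
#'   intervention arm (integers >= 1).
#' @return An object of classes `crt_design_integer`, `crt_design` with
#'   components `K0`, `K1`, `m0`, `m1`, `N`, `K`, `p`, `g`.
#' @examples
#' integer_design(K0 = 23, K1 = 7, m0 = 20, m1 = 68)
#' @export
integer_design <- function(K0, K1, m0, m1) {
  for (nm in c("K0", "K1", "m0", "m1")) {
    v <- get(nm)
    check_scalar(v, nm, lower = 1)
    if (v != round(v)) {
      stop("invalid design: `", nm, "` must be an integer", call. = FALSE)
    }
  }
  N <- K0 * m0 + K1 * m1
  structure(
    list(K0 = K0, K1 = K1, m0 = m0, m1 = m1,
         N = N, K = K0 + K1, p = K1 * m1 / N, g = K1 / (K0 + K1)),
    class = c("crt_design_integer", "crt_design")
  )
}

#' @export
print.crt_design <- function(x, ...) {
  if (inherits(x, "crt_design_integer")) {
    cat(sprintf(
      "Integer design: K0 = %d, K1 = %d, m0 = %d, m1 = %d, N = %d\n",
      x$K0, x$K1, x$m0, x$m1, x$N))
  } else {
    cat(sprintf(
      "Continuous design: N = %.4g, K = %.4g, p = %.4g, g = %.4g (m0 = %.4g, m1 = %.4g)\n",
      x$N, x$K, x$p, x$g, x$m0, x$m1))
  }
  invisible(x)
}

#' Arm-specific design effects and effective sample sizes
#'
#' The design effect in each arm is the familiar variance inflation
#' \eqn{1 + (m - 1)\rho} for measuring \eqn{m} correlated individuals per
#' cluster. The effective sample size (ESS) of an arm is the number measured
#' in that arm divided by its design effect — the equivalent number of
#' independent observations:
#' \deqn{ESS_0 = \frac{(1-p)N}{1 + (m_0-1)\rho_0}, \qquad
#'       ESS_1 = \frac{pN}{1 + (m_1-1)\rho_1}.}
#'
#' @param design A `crt_design` (continuous or integer).
#' @param model An [outcome_model()].
#' @return An object of class `crt_ess`: list with `ess0`, `ess1`, `deff0`,
#'   `deff1`.
#' @examples
#' d <- integer_design(K0 = 15, K1 = 15, m0 = 40, m1 = 40)
#' effective_sample_sizes(d, outcome_model(rho0 = 0.05, rho1 = 0.05))
#' @export
effective_sample_sizes <- function(design, model) {
  stopifnot(inherits(design, "crt_design"), inherits(model, "crt_model"))
  if (design$m0 < 1 || design$m1 < 1) {
    stop("invalid design: cluster sizes must be at least 1 (m0 = ",
         signif(design$m0, 4), ", m1 = ", signif(design$m1, 4), ")",
         call. = FALSE)
  }
  deff0 <- 1 + (design$m0 - 1) * model$rho0
  deff1 <- 1 + (design$m1 - 1) * model$rho1
  structure(
    list(ess0 = (1 - design$p) * design$N / deff0,
         ess1 = design$p * design$N / deff1,
         deff0 = deff0, deff1 = deff1),
    class = "crt_ess"
  )
}

#' @export
print.crt_ess <- function(x, ...) {
  cat(sprintf("Effective sample sizes: control %.2f (design effect %.3f), intervention %.2f (design effect %.3f)\n",
              x$ess0, x$deff0, x$ess1, x$deff1))
  invisible(x)
}

#' Control-arm cluster size when the intervention-arm cluster size is fixed
#'
#' With `m1` fixed, choosing `g` determines `m0` through the accounting
#' identity \eqn{m_0 = (N - gKm_1) / ((1-g)K)}. Feasibility requires the
#' intervention arm to measure fewer than all `N` individuals,
#' i.e. \eqn{gKm_1 < N}.
#'
#' @inheritParams cluster_sizes
#' @param m1 Fixed intervention-arm cluster size.
#' @return The real-valued control-arm cluster size `m0`.
#' @examples
#' m0_given_fixed_m1(N = 995, K = 30, g = 1 / 3, m1 = 45)
#' @export
m0_given_fixed_m1 <- function(N, K, g, m1) {
  N <- check_scalar(N, "N", 0, open_lower = TRUE)
  K <- check_scalar(K, "K", 0, open_lower = TRUE)
  g <- check_scalar(g, "g", 0, 1, TRUE, TRUE)
  m1 <- check_scalar(m1, "m1", 1)
  if (g * K * m1 >= N) {
    stop("infeasible: the intervention arm would measure g*K*m1 = ",
         signif(g * K * m1, 6), " individuals, which must be less than N = ",
         N, call. = FALSE)
  }
  (N - g * K * m1) / ((1 - g) * K)
}
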