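# Closed-form optimal allocation of individuals and clusters.

new_allocation <- function(p_opt, g_opt, clusters_immaterial = FALSE,
                           boundary = FALSE) {
  structure(
    list(p_opt = p_opt, g_opt = g_opt,
         p_ratio = p_opt / (1 - p_opt), g_ratio = g_opt / (1 - g_opt),
         clusters_immaterial = clusters_immaterial, boundary = boundary),
    class = "crt_allocation"
  )
}

#' @export
print.crt_allocation <- function(x, ...) {
  cat(sprintf("Optimal allocation: p_opt = %.3f, g_opt = %.3f\n",
              x$p_opt, x$g_opt))
  cat(sprintf("  ratios: p/(1-p) = %.4g, g/(1-g) = %.4g\n",
              x$p_ratio, x$g_ratio))
  if (x$clusters_immaterial)
    cat("  note: no clustering in either arm; allocation of clusters is immaterial\n")
  if (x$boundary)
    cat("  warning: a zero ICC in one arm pushes g_opt to the boundary\n")
  invisible(x)
}

#' Optimal allocation when cluster size can be chosen freely
#'
#' For fixed totals `N` (individuals measured) and `K` (clusters), power is
#' maximized over the allocation proportions at
#' \deqn{\frac{p_{opt}}{1-p_{opt}} = \sqrt{\frac{\gamma(1-\rho_1)}{1-\rho_0}},
#' \qquad
#' \frac{g_{opt}}{1-g_{opt}} = \sqrt{\frac{\gamma\rho_1}{\rho_0}}.}
#' Individuals are allocated in proportion to the square root of each arm's
#' within-cluster variability, clusters in proportion to the square root of
#' its between-cluster variability. Neither optimum depends on `N` or `K`,
#' so each proportion is optimal whatever the other is fixed at.
#'
#' Degenerate ICCs: if both ICCs are zero, clustering is irrelevant and
#' `g_opt` is reported as 0.5 with `clusters_immaterial = TRUE`; if exactly
#' one ICC is zero the cluster optimum sits on the boundary (all clusters in
#' the arm with the nonzero between-cluster variance would be pointless to
#' subdivide) — the boundary value is returned with a warning and
#' `boundary = TRUE` rather than silently pretending it is an interior
#' design.
#'
#' @param model An [outcome_model()].
#' @return A `crt_allocation`: list with `p_opt`, `g_opt`, the odds-style
#'   ratios `p_ratio` and `g_ratio`, and the flags `clusters_immaterial` and
#'   `boundary`.
#' @examples
#' optimal_allocation(outcome_model(rho0 = 0.1, rho1 = 0.01))
#' @export
optimal_allocation <- function(model) {
  stopifnot(inherits(model, "crt_model"))
  sp1 <- sqrt(model$gamma * (1 - model$rho1))
  sp0 <- sqrt(1 - model$rho0)
  p_opt <- sp1 / (sp1 + sp0)
  if (model$rho0 == 0 && model$rho1 == 0) {
    return(new_allocation(p_opt, 0.5, clusters_immaterial = TRUE))
  }
  if (model$rho0 == 0 || model$rho1 == 0) {
    g_opt <- if (model$rho0 == 0) 1 else 0
    warning("one arm has ICC 0: the optimal cluster allocation is the ",
            "boundary g = ", g_opt, ", not an interior design", call. = FALSE)
    out <- new_allocation(p_opt, g_opt, boundary = TRUE)
    return(out)
  }
  sg1 <- sqrt(model$gamma * model$rho1)
  sg0 <- sqrt(model$rho0)
  new_allocation(p_opt, sg1 / (sg1 + sg0))
}

#' Optimal allocation when both cluster sizes are fixed
#'
#' When the common cluster sizes `m0` and `m1` are prespecified, power is
#' maximized at the individual allocation ratio
#' \deqn{\frac{p_{opt}}{1-p_{opt}} =
#'   \sqrt{\frac{\gamma[1 + (m_1-1)\rho_1]}{1 + (m_0-1)\rho_0}},}
#' the classical square-root-of-variance rule applied to the design-effect
#' inflated variances. The equivalent cluster allocation ratio follows from
#' the accounting identity \eqn{g/(1-g) = (m_0/m_1)\, p/(1-p)}.
#'
#' @param m0,m1 Fixed cluster sizes (>= 1).
#' @param model An [outcome_model()].
#' @return A `crt_allocation`.
#' @examples
#' optimal_allocation_fixed_sizes(m0 = 40, m1 = 10,
#'                                outcome_model(rho0 = 0.1, rho1 = 0.01))
#' @export
optimal_allocation_fixed_sizes <- function(m0, m1, model) {
  stopifnot(inherits(model, "crt_model"))
  m0 <- check_scalar(m0, "m0", 1)
  m1 <- check_scalar(m1, "m1", 1)
  deff0 <- 1 + (m0 - 1) * model$rho0
  deff1 <- 1 + (m1 - 1) * model$rho1
  p_ratio <- sqrt(model$gamma * deff1 / deff0)
  p_opt <- p_ratio / (1 + p_ratio)
  g_ratio <- (m0 / m1) * p_ratio
  new_allocation(p_opt, g_ratio / (1 + g_ratio))
}
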