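# Rounding continuous optima to realizable integer designs, constrained
# searches, sensitivity sweeps, and design tables.

#' Practical constraints on a trial design
#'
#' @param min_clusters_per_arm Minimum clusters in each arm (integer >= 1;
#'   default 1, i.e. no binding constraint).
#' @param fixed_m1 Fixed intervention-arm cluster size, or `NULL`.
#' @param max_cluster_size Maximum feasible cluster size in either arm, or
#'   `NULL`.
#' @param fixed_p,fixed_g Fix the allocation proportion of individuals /
#'   clusters, or `NULL` to use the optimum.
#' @return An object of class `crt_constraints`.
#' @export
design_constraints <- function(min_clusters_per_arm = 1, fixed_m1 = NULL,
                               max_cluster_size = NULL, fixed_p = NULL,
                               fixed_g = NULL) {
  min_clusters_per_arm <- check_scalar(min_clusters_per_arm,
                                       "min_clusters_per_arm", 1)
  if (!is.null(fixed_m1)) fixed_m1 <- check_scalar(fixed_m1, "fixed_m1", 1)
  if (!is.null(max_cluster_size))
    max_cluster_size <- check_scalar(max_cluster_size, "max_cluster_size", 1)
  if (!is.null(fixed_p)) fixed_p <- check_scalar(fixed_p, "fixed_p", 0, 1, TRUE, TRUE)
  if (!is.null(fixed_g)) fixed_g <- check_scalar(fixed_g, "fixed_g", 0, 1, TRUE, TRUE)
  if (!is.null(fixed_m1) && !is.null(max_cluster_size) &&
      fixed_m1 > max_cluster_size) {
    stop("conflicting constraints: fixed_m1 = ", fixed_m1,
         " exceeds max_cluster_size = ", max_cluster_size, call. = FALSE)
  }
  structure(
    list(min_clusters_per_arm = min_clusters_per_arm, fixed_m1 = fixed_m1,
         max_cluster_size = max_cluster_size, fixed_p = fixed_p,
         fixed_g = fixed_g),
    class = "crt_constraints"
  )
}

#' Plausible ranges for the ICCs (and optionally the variance ratio)
#'
#' @param rho0,rho1 Length-2 numeric vectors `c(lo, hi)` with
#'   `0 <= lo <= hi < 1`.
#' @param gamma Optional length-2 vector of variance-ratio endpoints; `NULL`
#'   keeps the base model's value.
#' @return An object of class `crt_icc_range`.
#' @export
icc_range <- function(rho0, rho1, gamma = NULL) {
  chk <- function(x, name, hi_open) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        x[1] > x[2]) {
      stop("invalid parameter: `", name, "` must be c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
    if (x[1] < 0 || (hi_open && x[2] >= 1)) {
      stop("invalid parameter: `", name, "` endpoints out of range",
           call. = FALSE)
    }
    as.numeric(x)
  }
  rho0 <- chk(rho0, "rho0", TRUE)
  rho1 <- chk(rho1, "rho1", TRUE)
  if (!is.null(gamma)) {
    gamma <- chk(gamma, "gamma", FALSE)
    if (gamma[1] <= 0) stop("invalid parameter: `gamma` must be positive",
                            call. = FALSE)
  }
  structure(list(rho0 = rho0, rho1 = rho1, gamma = gamma),
            class = "crt_icc_range")
}

# Nearest integer with ties rounded up (round() would round half to even).
round_half_up <- function(x) floor(x + 0.5)

# Shared rounding step: given integer clusters per arm and the individual
# allocation p, size the trial and round cluster sizes up so the achieved
# power can only exceed the target.
.size_and_ceil <- function(K0, K1, p, model, effect) {
  N_star <- solve_total_n_fixed_arms(K0, K1, p, model, effect)
  m1 <- ceiling(p * N_star / K1)
  m0 <- ceiling((1 - p) * N_star / K0)
  out <- integer_design(K0, K1, m0, m1)
  attr(out, "provisional_N") <- N_star
  out
}

#' Round the unconstrained continuous optimum to a realizable design
#'
#' Converts the closed-form optimum into integers in the order that
#' preserves the power guarantee: the intervention-arm cluster count
#' `K1 = round(g_opt * K)` (nearest integer, ties up), then a provisional
#' continuous total from [solve_total_n_fixed_arms()] at `p_opt`, then both
#' cluster sizes rounded up. Because of the ceilings the reported
#' `N = K0*m0 + K1*m1` slightly exceeds the continuous requirement and the
#' achieved power slightly exceeds the target.
#'
#' @param K Total number of clusters (integer >= 2).
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @param allocation Optionally a precomputed `crt_allocation`; defaults to
#'   [optimal_allocation()] of `model`.
#' @return A `crt_design_integer`; the continuous provisional total is
#'   attached as attribute `"provisional_N"`.
#' @examples
#' round_optimal_design(K = 30, outcome_model(rho0 = 0.1, rho1 = 0.01),
#'                      effect_spec(d = 0.278))
#' @export
round_optimal_design <- function(K, model, effect,
                                 allocation = optimal_allocation(model)) {
  K <- check_scalar(K, "K", 2)
  stopifnot(inherits(allocation, "crt_allocation"))
  K1 <- round_half_up(allocation$g_opt * K)
  if (K1 < 1 || K1 > K - 1) {
    stop("invalid design: g_opt = ", signif(allocation$g_opt, 4),
         " rounds to ", K1, " intervention clusters out of K = ", K,
         call. = FALSE)
  }
  .size_and_ceil(K - K1, K1, allocation$p_opt, model, effect)
}

#' Optimal integer design under a minimum-clusters-per-arm constraint
#'
#' As [round_optimal_design()], but the intervention-arm cluster count
#' implied by `g_opt` (or by `fixed_g`) is clamped to
#' `[min_clusters_per_arm, K - min_clusters_per_arm]` before sizing. With an
#' inactive constraint the result is identical to the unconstrained
#' rounding.
#'
#' @inheritParams round_optimal_design
#' @param constraints A [design_constraints()].
#' @return A `crt_design_integer`.
#' @examples
#' round_constrained_design(K = 30, outcome_model(rho0 = 0.1, rho1 = 0.01),
#'                          effect_spec(d = 0.278),
#'                          design_constraints(min_clusters_per_arm = 10))
#' @export
round_constrained_design <- function(K, model, effect,
                                     constraints = design_constraints()) {
  K <- check_scalar(K, "K", 2)
  stopifnot(inherits(constraints, "crt_constraints"))
  min_c <- constraints$min_clusters_per_arm
  if (K < 2 * min_c) {
    stop("infeasible constraint: K = ", K, " cannot hold at least ",
         min_c, " clusters in each arm", call. = FALSE)
  }
  alloc <- optimal_allocation(model)
  g <- if (!is.null(constraints$fixed_g)) constraints$fixed_g else alloc$g_opt
  p <- if (!is.null(constraints$fixed_p)) constraints$fixed_p else alloc$p_opt
  K1 <- min(max(round_half_up(g * K), min_c), K - min_c)
  des <- .size_and_ceil(K - K1, K1, p, model, effect)
  if (!is.null(constraints$max_cluster_size) &&
      max(des$m0, des$m1) > constraints$max_cluster_size) {
    stop("infeasible constraint: required cluster size ",
         max(des$m0, des$m1), " exceeds max_cluster_size = ",
         constraints$max_cluster_size,
         " (consider fixed_m1_design() with m1 at the maximum)",
         call. = FALSE)
  }
  des
}

# Continuous control-arm cluster size achieving the target power with
# K0 control clusters, given the intervention arm contributes ESS1.
# Returns Inf when no finite m0 suffices, NA when even m0 -> Inf overshoots
# is impossible (ESS1 alone already insufficient).
.m0_root <- function(K0, ess1, model, effect) {
  need <- .size_target(model, effect) - model$gamma / ess1
  if (need <= 0) return(NA_real_)     # intervention arm cannot carry enough
  ess0_req <- 1 / need
  denom <- K0 - ess0_req * model$rho0 # ESS0 saturates at K0/rho0 as m0 -> Inf
  if (denom <= 0) return(Inf)
  ess0_req * (1 - model$rho0) / denom
}

#' Optimal integer design with the intervention-arm cluster size fixed
#'
#' With `m1` fixed (typically at a feasibility ceiling), the free choices
#' are the split of `K` clusters between arms and the control-arm cluster
#' size. For each admissible intervention-arm count `K1` the power equation
#' is solved exactly for the continuous control-arm cluster size, which is
#' then rounded up; the design minimizing the total `N = K0*m0 + K1*m1` is
#' returned, with ties broken toward more intervention clusters.
#'
#' @param K Total clusters.
#' @param m1 Fixed intervention-arm cluster size.
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @param constraints A [design_constraints()]; `min_clusters_per_arm`
#'   restricts the admissible `K1`.
#' @return A `crt_design_integer` with the continuous control-arm cluster
#'   size attached as attribute `"m0_continuous"`.
#' @examples
#' fixed_m1_design(K = 30, m1 = 45, outcome_model(rho0 = 0.1, rho1 = 0.01),
#'                 effect_spec(d = 0.278),
#'                 design_constraints(min_clusters_per_arm = 10))
#' @export
fixed_m1_design <- function(K, m1, model, effect,
                            constraints = design_constraints()) {
  K <- check_scalar(K, "K", 2)
  m1 <- check_scalar(m1, "m1", 1)
  stopifnot(inherits(constraints, "crt_constraints"))
  min_c <- constraints$min_clusters_per_arm
  if (K < 2 * min_c) {
    stop("infeasible constraint: K = ", K, " cannot hold at least ",
         min_c, " clusters in each arm", call. = FALSE)
  }
  deff1 <- 1 + (m1 - 1) * model$rho1
  best <- NULL
  for (K1 in seq.int(min_c, K - min_c)) {
    K0 <- K - K1
    m0c <- .m0_root(K0, K1 * m1 / deff1, model, effect)
    if (!is.finite(m0c)) next
    m0 <- max(1, ceiling(m0c))
    N <- K0 * m0 + K1 * m1
    # minimize N; on ties prefer the larger K1
    if (is.null(best) || N < best$N || (N == best$N && K1 > best$K1)) {
      best <- list(K0 = K0, K1 = K1, m0 = m0, m0c = m0c, N = N)
    }
  }
  if (is.null(best)) {
    stop("infeasible: no admissible split of K = ", K, " clusters achieves ",
         "the target power for any finite control-arm cluster size with ",
         "m1 = ", m1, call. = FALSE)
  }
  out <- integer_design(best$K0, best$K1, best$m0, m1)
  attr(out, "m0_continuous") <- best$m0c
  out
}

#' Power surface over (g, N) with one cluster size fixed
#'
#' Evaluates the analytic power on a grid of cluster-allocation proportions
#' and totals, with the intervention-arm cluster size held at `m1` and the
#' control-arm cluster size determined by [m0_given_fixed_m1()]. Grid points
#' where the intervention arm would consume all measurements
#' (`g*K*m1 >= N`) or the implied control cluster size falls below 1 are
#' flagged infeasible rather than dropped, so the full grid can be plotted.
#'
#' @param K Total clusters.
#' @param m1 Fixed intervention-arm cluster size.
#' @param N_grid Numeric vector of totals to evaluate.
#' @param g_grid Numeric vector of cluster-allocation proportions in (0, 1).
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @return A data.frame with columns `g`, `N`, `m0`, `feasible`, `power`
#'   (power is `NA` on infeasible rows).
#' @export
power_curve_fixed_m1 <- function(K, m1, N_grid, g_grid, model, effect) {
  K <- check_scalar(K, "K", 2)
  m1 <- check_scalar(m1, "m1", 1)
  stopifnot(length(N_grid) >= 1, length(g_grid) >= 1)
  grid <- expand.grid(N = as.numeric(N_grid), g = as.numeric(g_grid),
                      KEEP.OUT.ATTRS = FALSE)
  m0 <- (grid$N - grid$g * K * m1) / ((1 - grid$g) * K)
  feasible <- grid$g * K * m1 < grid$N & m0 >= 1
  pow <- rep(NA_real_, nrow(grid))
  for (i in which(feasible)) {
    des <- continuous_design(grid$N[i], K, grid$g[i] * K * m1 / grid$N[i],
                             grid$g[i])
    pow[i] <- crt_power(des, model, effect)
  }
  data.frame(g = grid$g, N = grid$N, m0 = m0, feasible = feasible,
             power = pow)
}

#' Theoretical sample size as one allocation proportion moves off-optimum
#'
#' Quantifies the cost of a deliberately suboptimal allocation: the
#' continuous total `N` required for the target power is evaluated along a
#' grid of one proportion while the other is held fixed (typically at its
#' optimum). The minimum of the resulting curve sits at the analytic
#' optimum; its flatness near the optimum shows how forgiving the design
#' is. Values are theoretical — a realizable trial needs integer rounding
#' on top.
#'
#' @param K Total clusters.
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @param vary Which proportion the grid varies, `"p"` or `"g"`.
#' @param held_value Value at which the other proportion is held.
#' @param grid Numeric vector of grid points in (0, 1).
#' @return A data.frame with columns `p`, `g`, `N`, `feasible`; `N` is `NA`
#'   on rows where `K` is below the feasibility bound for that `g`.
#' @examples
#' mod <- outcome_model(rho0 = 0.1, rho1 = 0.01)
#' suboptimal_curve(K = 40, mod, effect_spec(d = 0.278), vary = "g",
#'                  held_value = 0.512, grid = seq(0.2, 0.5, 0.05))
#' @export
suboptimal_curve <- function(K, model, effect, vary = c("p", "g"),
                             held_value, grid) {
  vary <- match.arg(vary)
  K <- check_scalar(K, "K", 0, open_lower = TRUE)
  held_value <- check_scalar(held_value, "held_value", 0, 1, TRUE, TRUE)
  stopifnot(is.numeric(grid), length(grid) >= 1, all(grid > 0 & grid < 1))
  p <- if (vary == "p") grid else rep(held_value, length(grid))
  g <- if (vary == "g") grid else rep(held_value, length(grid))
  N <- rep(NA_real_, length(grid))
  feasible <- rep(TRUE, length(grid))
  for (i in seq_along(grid)) {
    N[i] <- tryCatch(solve_total_n(K, p[i], g[i], model, effect),
                     error = function(e) NA_real_)
    feasible[i] <- is.finite(N[i])
  }
  data.frame(p = p, g = g, N = N, feasible = feasible)
}

#' Sample-size sensitivity over plausible ICC (and variance-ratio) ranges
#'
#' Evaluates the continuous required total `N` over a grid of cluster
#' allocations at every corner of the plausible parameter box, holding the
#' individual allocation fixed (the optimum moves very little across
#' realistic ICC ranges). Any design powered at the corner with the largest
#' ICCs (and variance ratio) retains at least the target power everywhere in
#' the box, so the conservative recommendation is the rounded optimal
#' design at that corner.
#'
#' @param K Total clusters.
#' @param range A [icc_range()].
#' @param model_base An [outcome_model()] supplying `sigma0_sq` (and `gamma`
#'   when the range does not vary it).
#' @param effect An [effect_spec()].
#' @param p_fixed Individual allocation proportion held fixed across the
#'   sweep.
#' @param g_grid Numeric vector of cluster-allocation proportions.
#' @return An object of class `crt_sweep`: list with `table` (data.frame
#'   `rho0`, `rho1`, `gamma`, `g`, `N`, `feasible`), `corners` (data.frame
#'   of corner parameters with each corner's own `p_opt` and `g_opt`), and
#'   `recommendation` (the rounded integer design at the most demanding
#'   corner).
#' @examples
#' sweep <- uncertainty_sweep(K = 40,
#'   icc_range(rho0 = c(0.075, 0.1), rho1 = c(0.01, 0.025)),
#'   outcome_model(rho0 = 0.1, rho1 = 0.01), effect_spec(d = 0.278),
#'   p_fixed = 0.51, g_grid = seq(0.25, 0.45, 0.05))
#' sweep$recommendation
#' @export
uncertainty_sweep <- function(K, range, model_base, effect, p_fixed,
                              g_grid) {
  K <- check_scalar(K, "K", 2)
  stopifnot(inherits(range, "crt_icc_range"), inherits(model_base, "crt_model"))
  p_fixed <- check_scalar(p_fixed, "p_fixed", 0, 1, TRUE, TRUE)
  gammas <- if (is.null(range$gamma)) model_base$gamma else unique(range$gamma)
  corners <- expand.grid(rho0 = unique(range$rho0),
                         rho1 = unique(range$rho1),
                         gamma = gammas, KEEP.OUT.ATTRS = FALSE)
  corners$p_opt <- NA_real_
  corners$g_opt <- NA_real_
  rows <- vector("list", nrow(corners))
  for (ci in seq_len(nrow(corners))) {
    mod <- outcome_model(model_base$sigma0_sq, corners$gamma[ci],
                         corners$rho0[ci], corners$rho1[ci])
    alloc <- optimal_allocation(mod)
    corners$p_opt[ci] <- alloc$p_opt
    corners$g_opt[ci] <- alloc$g_opt
    N <- vapply(g_grid, function(g) {
      tryCatch(solve_total_n(K, p_fixed, g, mod, effect),
               error = function(e) NA_real_)
    }, numeric(1))
    rows[[ci]] <- data.frame(rho0 = corners$rho0[ci],
                             rho1 = corners$rho1[ci],
                             gamma = corners$gamma[ci],
                             g = as.numeric(g_grid), N = N,
                             feasible = is.finite(N))
  }
  # conservative corner: largest ICCs and variance ratio
  hi <- outcome_model(model_base$sigma0_sq, max(gammas),
                      max(range$rho0), max(range$rho1))
  structure(
    list(table = do.call(rbind, rows), corners = corners,
         recommendation = round_optimal_design(K, hi, effect)),
    class = "crt_sweep"
  )
}

#' @export
print.crt_sweep <- function(x, ...) {
  cat("ICC/variance uncertainty sweep over", nrow(x$corners), "corners\n")
  cat(sprintf("  p_opt across corners: [%.3f, %.3f]\n",
              min(x$corners$p_opt), max(x$corners$p_opt)))
  cat("Conservative recommendation (sized at the most demanding corner):\n  ")
  print(x$recommendation)
  invisible(x)
}

#' Comparator design with equal clusters and cluster size per arm
#'
#' The conventional balanced design: `K/2` clusters per arm, a common
#' cluster size solved from the sample-size equation at `p = g = 0.5` and
#' rounded up.
#'
#' @param K Total clusters (must be even).
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @return A `crt_design_integer` with `K0 = K1 = K/2` and `m0 = m1`.
#' @export
equal_design <- function(K, model, effect) {
  K <- check_scalar(K, "K", 2)
  if (K %% 2 != 0) {
    stop("invalid parameter: the equal-allocation comparator needs an even ",
         "K (got ", K, ")", call. = FALSE)
  }
  N_cont <- solve_total_n_fixed_arms(K / 2, K / 2, 0.5, model, effect)
  m <- ceiling(N_cont / K)
  integer_design(K / 2, K / 2, m, m)
}

#' Design table over a range of total cluster counts
#'
#' For each `K`, rounds the (optionally constrained) optimal design to
#' integers and reports it alongside the equal-allocation comparator,
#' mirroring the layout of a sample-size table: one row per `K` with the
#' clusters and cluster size per arm, the total measured, the comparator
#' total and the achieved power.
#'
#' @param K Integer vector of total cluster counts.
#' @param model An [outcome_model()].
#' @param effect An [effect_spec()].
#' @param constraints Optional [design_constraints()]; the default imposes
#'   nothing.
#' @return A data.frame with columns `K`, `K0`, `K1`, `m0`, `m1`, `N`,
#'   `N_equal` (`NA` for odd `K`), `power_achieved`.
#' @examples
#' design_table(seq(30, 50, 2), outcome_model(rho0 = 0.1, rho1 = 0.01),
#'              effect_spec(d = 0.278))
#' @export
design_table <- function(K, model, effect,
                         constraints = design_constraints()) {
  stopifnot(is.numeric(K), length(K) >= 1)
  rows <- lapply(K, function(k) {
    des <- round_constrained_design(k, model, effect, constraints)
    N_eq <- if (k %% 2 == 0) equal_design(k, model, effect)$N else NA_real_
    data.frame(K = k, K0 = des$K0, K1 = des$K1, m0 = des$m0, m1 = des$m1,
               N = des$N, N_equal = N_eq,
               power_achieved = crt_power(des, model, effect))
  })
  do.call(rbind, rows)
}

#' Write / read a design table as commented CSV
#'
#' Writes a rectangular design table with a commented provenance header
#' (package version, optional seed and configuration echo) so a table can
#' be re-read and every row's power recomputed.
#'
#' @param table A data.frame as produced by [design_table()] or the grid
#'   operations.
#' @param path Output file path.
#' @param seed Optional integer recorded in the header.
#' @param config Optional named list echoed in the header as `key=value`.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(table, path, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(table))
  header <- c(
    paste0("# crtoptim ", as.character(utils::packageVersion("crtoptim"))),
    if (!is.null(seed)) paste0("# seed=", seed),
    if (!is.null(config))
      paste0("# ", names(config), "=", vapply(config, format, character(1)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_table
#' @export
read_design_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
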