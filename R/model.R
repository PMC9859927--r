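#' Right-hand side of the multi-group SIR vaccination model
#'
#' The 6n compartment rates for one group i are
#' \deqn{dS_i/dt = -\sum_j (\beta^1_{ij} I_j + \beta^2_{ij} I^V_j) S_i - v_i}
#' \deqn{dI_i/dt = \sum_j (\beta^1_{ij} I_j + \beta^2_{ij} I^V_j) S_i - \mu^1_i I_i}
#' \deqn{dR_i/dt = \mu^1_i I_i}
#' and similarly for the vaccinated compartments with `beta3`, `beta4`,
#' `mu2` and the transfer `+v_i`, where the vaccination transfer is
#' `v_i = u_i S_i / (N_i - w_i)`: doses are given at random to the
#' not-yet-vaccinated, so only the susceptible share of them moves mass.
#' When a group is fully vaccinated (`N_i - w_i` below `1e-12 * N_i`) the
#' transfer is clamped to 0, removing the 0/0 singularity.
#'
#' @param state named or ordered numeric vector `c(S, I, R, SV, IV, RV)`,
#'   each block length n.
#' @param params an [epidemic_parameters()] object.
#' @param u length-n non-negative vaccination rates at this instant.
#' @param w length-n cumulative doses so far (at most `N`).
#' @return Length-6n rate vector in the same block order.
#' @export
model_derivative <- function(state, params, u = NULL, w = NULL) {
  n <- params$n
  if (is.null(u)) u <- numeric(n)
  if (is.null(w)) w <- numeric(n)
  if (any(u < 0)) stop("vaccination rates must be non-negative", call. = FALSE)
  if (any(w > params$N + 1e-9)) {
    stop("cumulative doses exceed group size", call. = FALSE)
  }
  S <- state[1:n]; I <- state[(n + 1):(2 * n)]
  SV <- state[(3 * n + 1):(4 * n)]; IV <- state[(4 * n + 1):(5 * n)]
  lamU <- as.numeric(params$beta1 %*% I + params$beta2 %*% IV)
  lamV <- as.numeric(params$beta3 %*% I + params$beta4 %*% IV)
  head <- params$N - w
  v <- ifelse(head > 1e-12 * params$N, u * S / head, 0)
  c(-lamU * S - v,
    lamU * S - params$mu1 * I,
    params$mu1 * I,
    -lamV * SV + v,
    lamV * SV - params$mu2 * IV,
    params$mu2 * IV)
}

state_names <- function(n) {
  as.vector(vapply(c("S", "I", "R", "SV", "IV", "RV"),
                   function(b) paste0(b, seq_len(n)), character(n)))
}

#' Simulate the epidemic under a vaccination policy
#'
#' Integrates the 6n-compartment system with `deSolve` (`lsoda`, stiff-safe
#' adaptive stepping), restarting the integration at every breakpoint of the
#' piecewise-constant policy so rate discontinuities are respected exactly.
#' Cumulative doses inside a segment are evaluated in closed form. After the
#' policy's support ends, integration continues with a root stop when the
#' total infected fraction `sum(I + IV)` falls below `infection_threshold`
#' (the numerical stand-in for "time infinity"), or until `t_max`.
#'
#' @param params an [epidemic_parameters()] object.
#' @param policy a [vaccination_policy()]; default: no vaccination.
#' @param infection_threshold extinction threshold defining convergence
#'   (default `1e-10`).
#' @param t_max horizon, in units of the mean infectious period
#'   (default 200).
#' @param rtol,atol solver tolerances (defaults `1e-9`, `1e-12`).
#' @param n_out approximate number of output rows (default 201).
#' @return An object of class `sir_trajectory`: a data frame with columns
#'   `t`, `S1..Sn`, `I1..In`, `R1..Rn`, `SV1..SVn`, `IV1..IVn`, `RV1..RVn`
#'   and `W1..Wn`, with attributes `params`, `policy`, `converged` and
#'   `terminal` (the last state row).
#' @examples
#' par <- epidemic_parameters(beta1 = 2, beta2 = 1, beta3 = 1, beta4 = 0.5,
#'                            mu1 = 1, mu2 = 1, N = 1,
#'                            S0 = 1 - 1e-4, I0 = 1e-4)
#' traj <- simulate_epidemic(par)
#' attack_fraction <- tail(traj$R1, 1)
#' @export
simulate_epidemic <- function(params, policy = NULL,
                              infection_threshold = 1e-10, t_max = 200,
                              rtol = 1e-9, atol = 1e-12, n_out = 201) {
  stopifnot(inherits(params, "epidemic_parameters"))
  n <- params$n
  if (is.null(policy)) policy <- zero_policy(n)
  stopifnot(inherits(policy, "vaccination_policy"), policy$n == n)
  y0 <- c(params$S0, params$I0, params$R0, params$SV0, params$IV0, params$RV0)
  names(y0) <- state_names(n)

  seg_ends <- policy$times[policy$times > 0 & policy$times < t_max]
  seg_bounds <- unique(c(0, seg_ends, min(policy$support_end, t_max), t_max))
  seg_bounds <- seg_bounds[seg_bounds <= t_max]

  rhs <- function(t, y, parms) {
    w <- pmin(parms$w0 + parms$u * (t - parms$t0), params$N)
    list(model_derivative(y, params, parms$u, w))
  }
  rootfun <- function(t, y, parms) {
    sum(y[(n + 1):(2 * n)]) + sum(y[(4 * n + 1):(5 * n)]) - infection_threshold
  }

  out_all <- NULL
  y <- y0
  converged <- FALSE
  dt_out <- t_max / max(n_out - 1, 1)
  for (k in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[k]; t1 <- seg_bounds[k + 1]
    u <- policy_rate_at(policy, t0)
    w0 <- cumulative_doses(policy, t0)
    in_tail <- t0 >= policy$support_end
    times <- seq(t0, t1, length.out = max(2L, min(400L, ceiling((t1 - t0) / dt_out) + 1L)))
    parms <- list(u = u, w0 = w0, t0 = t0)
    if (in_tail) {
      if (rootfun(t0, y, parms) <= 0) { converged <- TRUE; break }
      sol <- deSolve::lsodar(y, times, rhs, parms, rtol = rtol, atol = atol,
                             rootfunc = rootfun)
    } else {
      sol <- deSolve::lsoda(y, times, rhs, parms, rtol = rtol, atol = atol)
    }
    sol <- as.matrix(sol)
    y <- sol[nrow(sol), -1]
    out_all <- rbind(out_all, if (is.null(out_all)) sol else sol[-1, , drop = FALSE])
    if (in_tail && !is.null(attr(sol, "troot"))) { converged <- TRUE; break }
  }
  if (!converged) {
    tot_inf <- sum(y[(n + 1):(2 * n)]) + sum(y[(4 * n + 1):(5 * n)])
    converged <- tot_inf < infection_threshold
  }
  if (is.null(out_all)) {           # extinct before any integration step
    out_all <- matrix(c(0, y0), nrow = 1)
  }

  df <- as.data.frame(out_all)
  names(df) <- c("t", state_names(n))
  W <- cumulative_doses(policy, df$t)
  if (is.null(dim(W))) W <- matrix(W, ncol = n, byrow = TRUE)
  colnames(W) <- paste0("W", seq_len(n))
  df <- cbind(df, W)
  attr(df, "params") <- params
  attr(df, "policy") <- policy
  attr(df, "converged") <- converged
  attr(df, "terminal") <- df[nrow(df), ]
  class(df) <- c("sir_trajectory", "data.frame")
  df
}

#' Terminal state of a trajectory
#' @param trajectory a `sir_trajectory`.
#' @return One-row data frame with the final solver state.
#' @export
terminal_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "sir_trajectory"))
  attr(trajectory, "terminal")
}

#' Weighted final-size objective
#'
#' The cost of an epidemic is the weighted number of infections accumulated
#' over its whole course,
#' \deqn{H = \sum_i p_i (R_i(\infty) - R_i(0)) + p_i \kappa_i (R^V_i(\infty) - R^V_i(0)),}
#' evaluated from the terminal state of a converged simulation. Initially
#' recovered individuals are subtracted so that an epidemic that never takes
#' off has cost exactly 0.
#'
#' @param trajectory a `sir_trajectory` from [simulate_epidemic()].
#' @param params optional [epidemic_parameters()]; defaults to the ones the
#'   trajectory was simulated with.
#' @return Non-negative scalar cost. If the simulation did not converge a
#'   warning is raised and the value at `t_max` is returned.
#' @export
objective_H <- function(trajectory, params = NULL) {
  stopifnot(inherits(trajectory, "sir_trajectory"))
  if (is.null(params)) params <- attr(trajectory, "params")
  if (!isTRUE(attr(trajectory, "converged"))) {
    warning("trajectory did not reach the extinction threshold; ",
            "objective evaluated at the simulation horizon", call. = FALSE)
  }
  n <- params$n
  fin <- attr(trajectory, "terminal")
  R_inf <- as.numeric(fin[paste0("R", seq_len(n))])
  RV_inf <- as.numeric(fin[paste0("RV", seq_len(n))])
  sum(params$p * (R_inf - params$R0 + params$kappa * (RV_inf - params$RV0)))
}

#' Write a trajectory to CSV
#' @param trajectory a `sir_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sir_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
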