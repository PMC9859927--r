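#' Stack the model into a 2n-group SIR system
#'
#' Once dosing has ceased there is no flow between the unvaccinated and
#' vaccinated branches, so the model is an ordinary 2n-group SIR: groups
#' 1..n are the unvaccinated compartments and n+1..2n the vaccinated ones.
#' The stacked transmission matrix has block structure
#' `rbind(cbind(beta1, beta2), cbind(beta3, beta4))`, recovery rates are
#' `c(mu1, mu2)` and infection costs `c(p, kappa * p)`.
#'
#' `W_final` places doses given (instantaneously, at time 0) into the
#' stacked initial conditions: vaccinating `W_i` of group i's unvaccinated
#' pool at random moves the susceptible share `S0_i * W_i / N_i` from slot i
#' to slot n+i.
#'
#' @param params an [epidemic_parameters()] object.
#' @param W_final length-n doses per group (default 0: the unvaccinated
#'   baseline).
#' @return An object of class `stacked_system` with fields `beta_prime`
#'   (2n x 2n), `mu_prime`, `p_prime`, `S0`, `I0`, `R0` (length 2n), `N`
#'   and `n`.
#' @export
stack_parameters <- function(params, W_final = NULL) {
  stopifnot(inherits(params, "epidemic_parameters"))
  n <- params$n
  if (is.null(W_final)) W_final <- numeric(n)
  W_final <- as.numeric(W_final)
  if (length(W_final) != n || any(W_final < 0)) {
    stop("'W_final' must be a non-negative length-n vector", call. = FALSE)
  }
  if (any(W_final > params$N + 1e-12)) {
    stop("'W_final' cannot exceed group sizes", call. = FALSE)
  }
  moved <- params$S0 * W_final / params$N
  structure(list(
    n = n,
    beta_prime = rbind(cbind(params$beta1, params$beta2),
                       cbind(params$beta3, params$beta4)),
    mu_prime = c(params$mu1, params$mu2),
    p_prime = c(params$p, params$kappa * params$p),
    S0 = c(params$S0 - moved, params$SV0 + moved),
    I0 = c(params$I0, params$IV0),
    R0 = c(params$R0, params$RV0),
    N = c(params$N, params$N)
  ), class = "stacked_system")
}

#' Solve the SIR final-size fixed point
#'
#' For a multi-group SIR system without vaccination flow, the total ever
#' infected per group satisfies
#' \deqn{S_i(\infty) = S_i(0) \exp(-\sum_k (\beta'_{ik}/\mu'_k)(R_k(\infty) - R_k(0)))}
#' with \eqn{R_i(\infty) = S_i(0) + I_i(0) + R_i(0) - S_i(\infty)}. The
#' epidemiologically realized root is found by damped fixed-point iteration
#' started from `S = 0` (the attack-maximal side), which descends to the
#' root reached by the ODE dynamics; cross-validation against the simulator
#' is part of the test suite. If plain iteration stalls, the damping factor
#' is halved adaptively. Slots that no chain of transmission connects to an
#' initially infected slot are pinned to their initial state (the
#' fixed-point relation would otherwise admit a spurious epidemic root for
#' unseeded disconnected components).
#'
#' @param system a `stacked_system` from [stack_parameters()] (any list
#'   with fields `beta_prime`, `mu_prime`, `S0`, `I0`, `R0` works).
#' @param tol fixed-point residual tolerance (default `1e-12`).
#' @param max_iter iteration cap (default 10000).
#' @return An object of class `final_size_solution`: list with `R_inf`
#'   (length 2n, total recovered including initial), `S_inf`, `residual`
#'   and `iterations`.
#' @export
solve_final_size <- function(system, tol = 1e-12, max_iter = 10000L) {
  M <- sweep(system$beta_prime, 2, system$mu_prime, "/")
  S0 <- system$S0; I0 <- system$I0; R0 <- system$R0
  top <- S0 + I0 + R0                      # attack-size upper bound per slot
  if (sum(I0) == 0) {
    return(structure(list(R_inf = R0, S_inf = S0, residual = 0,
                          iterations = 0L), class = "final_size_solution"))
  }
  # slots that can ever see infection: transitive closure of transmission
  # (edge k -> i when beta'_ik > 0) from the initially infected slots;
  # everything else keeps its initial state (no epidemic reaches it)
  m2 <- length(S0)
  reached <- I0 > 0
  repeat {
    grow <- (M[, reached, drop = FALSE] %*% rep(1, sum(reached))) > 0
    new_reached <- reached | as.vector(grow)
    if (identical(new_reached, reached)) break
    reached <- new_reached
  }
  step <- function(R) {
    R_new <- top - S0 * exp(-as.numeric(M %*% (R - R0)))
    R_new[!reached] <- R0[!reached]
    R_new
  }
  R <- ifelse(reached, top, R0)
  damp <- 1
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    R_new <- (1 - damp) * R + damp * step(R)
    res <- max(abs(R_new - R))
    if (res < tol) {
      R <- R_new
      return(structure(list(R_inf = R, S_inf = top - R, residual = res,
                            iterations = it), class = "final_size_solution"))
    }
    if (res > res_prev) damp <- max(damp / 2, 1e-3)
    res_prev <- res
    R <- R_new
  }
  stop(sprintf(paste0("final-size iteration did not converge ",
                      "(residual %.3g after %d iterations)"), res_prev,
               max_iter), call. = FALSE)
}
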