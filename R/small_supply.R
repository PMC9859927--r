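#' Linearization matrix Q of the stacked final-size equations
#'
#' Differentiating the stacked final-size fixed point
#' \eqn{R_i = S_i(0) + I_i(0) - S_i(0) e^{-E_i}} around the unvaccinated
#' baseline gives a linear system with matrix
#' \deqn{Q_{ij} = \frac{\delta_{ij} - S_i(0) e^{-E_i} \beta'_{ij} / \mu'_j}{1 - e^{-E_i}},}
#' where \eqn{E_i = \sum_k (\beta'_{ik}/\mu'_k) R_k(\infty)} is the total
#' infectious exposure of stacked group i at baseline. (The off-diagonal
#' term enters with a minus sign: it is the Jacobian `I - D M` of the
#' fixed-point map, `D = diag(S_i(0) e^{-E_i})`, row-scaled by
#' `1/(1 - e^{-E_i})`; the sign is pinned down by agreement with
#' finite-difference simulation, part of the test suite.) The row factor is
#' singular for a group that receives no infectious force at baseline
#' (`E_i = 0`); such a group makes the linearization ill-posed and raises
#' an error naming it.
#'
#' @param system a `stacked_system` from [stack_parameters()].
#' @param baseline a `final_size_solution` for that system at zero doses.
#' @param singular_tol exposures below this are treated as zero
#'   (default `1e-14`).
#' @return A 2n x 2n matrix.
#' @export
build_Q <- function(system, baseline, singular_tol = 1e-14) {
  stopifnot(inherits(baseline, "final_size_solution"))
  M <- sweep(system$beta_prime, 2, system$mu_prime, "/")
  E <- as.numeric(M %*% baseline$R_inf)
  if (any(E < singular_tol)) {
    bad <- which(E < singular_tol)
    stop(sprintf(paste0("stacked group(s) %s receive no infectious force ",
                        "at baseline; the final-size linearization is ",
                        "singular there"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m2 <- length(E)
  (diag(m2) - system$S0 * exp(-E) * M) / (1 - exp(-E))
}

#' Per-dose marginal cost of vaccinating each group
#'
#' The small-supply gradient of the weighted final-size objective: solving
#' the transposed linear system `t(Q) x = p'` and setting
#' \deqn{y_i = \frac{S_i(0)}{N_i}\,(x_{i+n} - x_i)}
#' gives the leading-order change in the objective per dose delivered to
#' group i. For a weakly protective vaccine the `y_i` are non-positive
#' (checked, with a warning if violated numerically); the most effective
#' single target for a vanishing supply is `which.min(y)`.
#'
#' @param params an [epidemic_parameters()] object.
#' @return An object of class `small_supply_linearization`: list with `y`
#'   (length n), `x` (length 2n), `Q`, `H0` (baseline objective), `N`,
#'   `baseline` (the `final_size_solution`), `best_group` and `unique_min`.
#' @examples
#' par <- epidemic_parameters(beta1 = 2, beta2 = 1, beta3 = 1, beta4 = 0.5,
#'                            mu1 = 1, mu2 = 1, N = 1,
#'                            S0 = 1 - 1e-4, I0 = 1e-4)
#' gradient_y(par)$y
#' @export
gradient_y <- function(params) {
  stopifnot(inherits(params, "epidemic_parameters"))
  n <- params$n
  sys <- stack_parameters(params)
  fs <- solve_final_size(sys)
  Q <- build_Q(sys, fs)
  x <- tryCatch(solve(t(Q), sys$p_prime), error = function(e) {
    stop("linearization matrix Q is numerically singular: ",
         conditionMessage(e), call. = FALSE)
  })
  y <- (sys$S0[1:n] / params$N) * (x[(n + 1):(2 * n)] - x[1:n])
  if (any(y > 1e-8)) {
    warning("positive marginal cost y despite a weakly protective vaccine; ",
            "check parameters", call. = FALSE)
  }
  H0 <- sum(sys$p_prime * (fs$R_inf - sys$R0))
  ymin <- min(y)
  near <- which(y - ymin <= 1e-10 * max(1, abs(ymin)))
  structure(list(y = y, x = x, Q = Q, H0 = H0, N = params$N, baseline = fs,
                 best_group = near[1], unique_min = length(near) == 1L),
            class = "small_supply_linearization")
}

#' @export
print.small_supply_linearization <- function(x, ...) {
  cat("Small-supply final-size linearization\n")
  cat(sprintf("  baseline objective H0 = %.6g\n", x$H0))
  df <- data.frame(group = seq_along(x$y), y = x$y,
                   effectiveness = x$y / min(x$y))
  print(df, row.names = FALSE)
  cat(sprintf("  best single target: group %d%s\n", x$best_group,
              if (x$unique_min) "" else " (minimum not unique)"))
  invisible(x)
}

#' Leading-order objective under a small supply
#'
#' First-order prediction `H0 + sum(y * W_final)` of the objective when
#' `W_final` doses are delivered per group, valid for supplies small
#' relative to the population.
#'
#' @param lin a `small_supply_linearization` from [gradient_y()].
#' @param W_final length-n doses vector.
#' @return Predicted cost scalar.
#' @export
leading_order_objective <- function(lin, W_final) {
  stopifnot(inherits(lin, "small_supply_linearization"))
  W_final <- as.numeric(W_final)
  stopifnot(length(W_final) == length(lin$y))
  lin$H0 + sum(lin$y * W_final)
}

#' Knapsack-optimal policy for a small supply
#'
#' To leading order, the optimal use of a small supply `epsilon` is to give
#' all of it, at the maximal rate `A(t)`, to the single group with the most
#' negative marginal cost `y`. Ties are broken by lowest index, with a
#' warning, since equal minima are a measure-zero degenerate case.
#'
#' @param lin a `small_supply_linearization` from [gradient_y()].
#' @param schedule a [supply_schedule()]; its rate cap `A` must be positive
#'   at time 0.
#' @param epsilon total doses to deliver (at most the chosen group's size).
#' @return A [vaccination_policy()] with attribute `"group"` (the chosen
#'   group index).
#' @export
optimal_small_supply_policy <- function(lin, schedule, epsilon) {
  stopifnot(inherits(lin, "small_supply_linearization"),
            inherits(schedule, "supply_schedule"), epsilon >= 0)
  if (schedule_A(schedule, 0) <= 0) {
    stop("the rate cap A(t) must be positive at time 0", call. = FALSE)
  }
  if (!lin$unique_min) {
    warning("minimum of y is not unique; breaking the tie by lowest index",
            call. = FALSE)
  }
  k <- lin$best_group
  if (epsilon > lin$N[k] + 1e-12) {
    stop("supply epsilon exceeds the size of the chosen group", call. = FALSE)
  }
  n <- length(lin$y)
  if (epsilon == 0) {
    pol <- zero_policy(n)
  } else {
    caps <- numeric(n); caps[k] <- epsilon
    fake_params <- structure(list(n = n, N = lin$N), class = "epidemic_parameters")
    pol <- prioritized_policy(c(k, setdiff(seq_len(n), k)), schedule,
                              fake_params, caps)
  }
  attr(pol, "group") <- k
  pol
}

#' Next-generation matrix and infectious-force summaries
#'
#' For the disease-free, fully unvaccinated population the next-generation
#' matrix is `R[i, j] = N_i * beta1[i, j] / mu1[j]`: the expected number of
#' group-i infections caused by one group-j infected over its infectious
#' period. Its spectral radius is the population-level basic reproduction
#' number. The total infectious force of group j is the j-th column sum;
#' the external force excludes the diagonal term.
#'
#' @param params an [epidemic_parameters()] object.
#' @return An object of class `next_generation_summary`: list with
#'   `R_matrix`, `spectral_radius`, `total_force` and `external_force`.
#' @export
next_generation_matrix <- function(params) {
  stopifnot(inherits(params, "epidemic_parameters"))
  R <- params$N * sweep(params$beta1, 2, params$mu1, "/")
  ev <- eigen(R, only.values = TRUE)$values
  total <- colSums(R)
  structure(list(R_matrix = R,
                 spectral_radius = max(Mod(ev)),
                 total_force = total,
                 external_force = total - diag(R)),
            class = "next_generation_summary")
}

#' @export
print.next_generation_summary <- function(x, ...) {
  cat(sprintf("Next-generation matrix (%d groups): R0 = %.4f\n",
              nrow(x$R_matrix), x$spectral_radius))
  df <- data.frame(group = seq_along(x$total_force),
                   total_force = x$total_force,
                   external_force = x$external_force)
  print(df, row.names = FALSE)
  invisible(x)
}

# crude strong-connectivity check on the support of a non-negative matrix
is_irreducible <- function(A) {
  n <- nrow(A)
  P <- (A > 0) + diag(n)
  reach <- P
  for (k in seq_len(n)) reach <- (reach %*% P) > 0
  all(reach > 0)
}

#' Calibrate the transmission scale to a target reproduction number
#'
#' Given a contact matrix `Lambda` (entry `[i, j]`: contacts of a group-i
#' individual with group-j individuals) and group sizes `N`, the
#' transmission matrix is taken proportional to contacts per capita,
#' `beta1[i, j] = beta * Lambda[i, j] / N[j]`. The scalar `beta` is chosen
#' so that the next-generation matrix `N_i beta1[i, j] / mu1[j]` has
#' spectral radius `target_R0`. Since the spectral radius is linear in
#' `beta`, the calibration is exact: `beta = target_R0 / rho(beta = 1)`.
#'
#' With `tiered = TRUE` the remaining matrices follow the halving
#' convention `beta2 = beta3 = 0.5 * beta1`, `beta4 = 0.25 * beta1`
#' (a vaccine that halves both susceptibility and infectiousness).
#'
#' @param contact_matrix n x n non-negative contact matrix.
#' @param N length-n group sizes.
#' @param mu1 length-n recovery rates (scalar recycled).
#' @param target_R0 desired spectral radius (default 4).
#' @param tiered build `beta2`..`beta4` by the halving convention
#'   (default `TRUE`).
#' @return List with `beta` (the scalar), `beta1` (and, if tiered,
#'   `beta2`..`beta4`) and `spectral_radius` (recomputed, equals
#'   `target_R0`).
#' @export
calibrate_beta <- function(contact_matrix, N, mu1, target_R0 = 4,
                           tiered = TRUE) {
  Lambda <- as.matrix(contact_matrix)
  N <- as.numeric(N)
  n <- length(N)
  stopifnot(nrow(Lambda) == n, ncol(Lambda) == n)
  if (any(Lambda < 0)) stop("contact matrix must be non-negative", call. = FALSE)
  if (!is_irreducible(Lambda)) {
    warning("contact matrix is reducible; R0 is driven by one block",
            call. = FALSE)
  }
  mu1 <- rep(as.numeric(mu1), length.out = n)
  beta1_unit <- sweep(Lambda, 2, N, "/")
  ngm_unit <- N * sweep(beta1_unit, 2, mu1, "/")
  rho <- max(Mod(eigen(ngm_unit, only.values = TRUE)$values))
  if (rho <= 0) stop("contact matrix has zero spectral radius", call. = FALSE)
  beta <- target_R0 / rho
  beta1 <- beta * beta1_unit
  out <- list(beta = beta, beta1 = beta1,
              spectral_radius = beta * rho)
  if (tiered) {
    out$beta2 <- 0.5 * beta1
    out$beta3 <- 0.5 * beta1
    out$beta4 <- 0.25 * beta1
  }
  out
}
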