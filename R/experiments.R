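#' Two-group vulnerable/infectious example
#'
#' A stylized population with a small, vulnerable, non-infectious group 1
#' (size `epsilon`, infection cost `1/epsilon`) and a large, invulnerable,
#' infectious group 2 (size 1, cost `p_star`). The transmission matrix for
#' unvaccinated pairs is `rbind(c(1, 2), c(2, 4))`; a vaccine with
#' infection-blocking effectiveness `chi_eff` and transmission-blocking
#' effectiveness `rho_eff` multiplies it by `chi_eff` (vaccinated
#' susceptible), `rho_eff` (vaccinated infector) or their product (both).
#' All recovery rates are 1, both `kappa` are 1, the epidemic is seeded
#' with `I_star` infections in group 2, and doses arrive at rate 1 with
#' total supply 1 (so only one population-sized group can ever be covered).
#'
#' Two bang-bang policies are attached: `policy_U` vaccinates the
#' infectious group 2 first (and, the supply being exactly 1, exclusively),
#' and `policy_tilde` is its vulnerable-first swap via
#' [build_tilde_policy()]: group 1 at rate 1 until fully covered at time
#' `epsilon`, then group 2 with the remaining supply.
#'
#' @param epsilon size of the vulnerable group, in (0, 1].
#' @param I_star initial infected fraction in group 2 (default 0.01).
#' @param p_star infection cost of group 2 (default 1).
#' @param chi_eff,rho_eff vaccine effectiveness multipliers in \[0, 1\]
#'   (default 0.5; 0 = complete effectiveness, 1 = no effect).
#' @return An object of class `two_group_example`: list with `params`,
#'   `schedule`, `policy_U`, `policy_tilde` and the scalar settings.
#' @export
two_group_example <- function(epsilon, I_star = 0.01, p_star = 1,
                              chi_eff = 0.5, rho_eff = 0.5) {
  stopifnot(epsilon > 0, epsilon <= 1, I_star > 0, I_star <= 1,
            p_star >= 0, chi_eff >= 0, chi_eff <= 1,
            rho_eff >= 0, rho_eff <= 1)
  beta1 <- rbind(c(1, 2), c(2, 4))
  params <- withCallingHandlers(
    epidemic_parameters(
      beta1 = beta1, beta2 = chi_eff * beta1, beta3 = rho_eff * beta1,
      beta4 = chi_eff * rho_eff * beta1,
      mu1 = c(1, 1), mu2 = c(1, 1), N = c(epsilon, 1),
      p = c(1 / epsilon, p_star), kappa = c(1, 1),
      S0 = c(epsilon, 1 - I_star), I0 = c(0, I_star)
    ),
    warning = function(w) {
      if (grepl("group sizes sum", conditionMessage(w))) {
        invokeRestart("muffleWarning")     # the unnormalised total is intended
      }
    }
  )
  schedule <- supply_schedule(A_breaks = 0, A_rates = 1,
                              B_knots = c(0, 1), B_values = c(0, 1),
                              B_final_slope = 0)
  U <- prioritized_policy(c(2, 1), schedule, params,
                          per_group_caps = c(epsilon, 1))
  U_tilde <- build_tilde_policy(U, epsilon, params)
  structure(list(params = params, schedule = schedule,
                 policy_U = U, policy_tilde = U_tilde,
                 epsilon = epsilon, I_star = I_star, p_star = p_star,
                 chi_eff = chi_eff, rho_eff = rho_eff),
            class = "two_group_example")
}

#' Crossover group size between the two-group policies
#'
#' Scans the vulnerable-group size `epsilon` over a log-spaced grid,
#' simulating both two-group policies at each point, and returns
#' \deqn{\epsilon^* = \inf(\{\epsilon : H(\tilde U) > H(U)\} \cup \{1\}),}
#' the smallest group size at which vaccinating the infectious group first
#' beats vaccinating the vulnerable group first. The first sign change of
#' `H(tilde) - H(U)` on the grid is refined by bisection; if the
#' vulnerable-first policy wins everywhere the diagnostic is capped at 1.
#' If the swap already loses at the smallest grid point, that grid point is
#' returned (the grid floor resolves the infimum).
#'
#' @param I_star,p_star,chi_eff,rho_eff passed to [two_group_example()].
#' @param grid increasing epsilon grid in (0, 1]; default 25 log-spaced
#'   points on `[1e-3, 1]`.
#' @param bisect_steps bisection refinements of the bracketing interval
#'   (default 20).
#' @param ... further arguments to [simulate_epidemic()].
#' @return An object of class `crossover_result`: list with `epsilon_star`,
#'   `capped` (TRUE when no crossover was found below 1) and `grid`, a data
#'   frame of the evaluated `epsilon`, `H_U` and `H_tilde`.
#' @export
epsilon_star <- function(I_star = 0.01, p_star = 1, chi_eff = 0.5,
                         rho_eff = 0.5, grid = NULL, bisect_steps = 20L,
                         ...) {
  if (is.null(grid)) grid <- 10^seq(-3, 0, length.out = 25)
  stopifnot(!is.unsorted(grid, strictly = TRUE), all(grid > 0),
            max(grid) <= 1)
  gap <- function(eps) {
    ex <- two_group_example(eps, I_star, p_star, chi_eff, rho_eff)
    H_U <- objective_H(simulate_epidemic(ex$params, ex$policy_U, ...))
    H_T <- objective_H(simulate_epidemic(ex$params, ex$policy_tilde, ...))
    c(H_U = H_U, H_tilde = H_T)
  }
  vals <- t(vapply(grid, gap, numeric(2)))
  d <- vals[, "H_tilde"] - vals[, "H_U"]
  idx <- which(d > 0)
  if (length(idx) == 0) {
    eps_star <- 1
    capped <- TRUE
  } else {
    i <- idx[1]
    capped <- FALSE
    if (i == 1L) {
      eps_star <- grid[1]
    } else {
      lo <- grid[i - 1]; hi <- grid[i]
      for (k in seq_len(bisect_steps)) {
        mid <- sqrt(lo * hi)
        g <- gap(mid)
        if (g["H_tilde"] - g["H_U"] > 0) hi <- mid else lo <- mid
      }
      eps_star <- hi
    }
  }
  structure(list(epsilon_star = eps_star, capped = capped,
                 grid = data.frame(epsilon = grid, H_U = vals[, "H_U"],
                                   H_tilde = vals[, "H_tilde"])),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("Crossover group size epsilon* = %.4g%s\n", x$epsilon_star,
              if (x$capped) " (capped: vulnerable-first wins everywhere)" else ""))
  invisible(x)
}

#' Homogeneous one-group example
#'
#' A single well-mixed group of size 1: transmission `beta` between
#' unvaccinated pairs, halved once for each vaccinated party (`beta/2`
#' mixed, `beta/4` both vaccinated), unit recovery rates and costs,
#' epidemic seeded with `1e-4` infected. The supply schedule offers rate 1
#' and a fixed total `epsilon`.
#'
#' @param beta unvaccinated transmission rate (equals the basic
#'   reproduction number here, since `mu = N = 1`).
#' @param epsilon total vaccine supply in \[0, 1\].
#' @return List with `params` ([epidemic_parameters()]) and `schedule`
#'   ([supply_schedule()]).
#' @export
homogeneous_example <- function(beta, epsilon = 0.01) {
  stopifnot(beta > 0, epsilon >= 0, epsilon <= 1)
  params <- epidemic_parameters(
    beta1 = beta, beta2 = 0.5 * beta, beta3 = 0.5 * beta,
    beta4 = 0.25 * beta,
    mu1 = 1, mu2 = 1, N = 1, p = 1, kappa = 1,
    S0 = 1 - 1e-4, I0 = 1e-4
  )
  list(params = params,
       schedule = constant_supply_schedule(rate = 1, total = epsilon))
}

#' Age-structured example from a contact matrix
#'
#' Builds a full model from an inter-group contact matrix and a population
#' vector (given directly or as CSV paths in the layout written by
#' [write_fixture_csv()]): the transmission scale is calibrated so the
#' next-generation matrix has spectral radius `target_R0`, vaccine tiers
#' follow the halving convention (`beta2 = beta3 = beta1/2`,
#' `beta4 = beta1/4`), recovery rates are 1, a fraction `1e-4` of every
#' group is initially infected, infection costs are the per-group case
#' fatality ratios and vaccination multiplies them by `kappa_scalar`.
#' The small-supply gradient is evaluated and reported per group together
#' with the effectiveness proportion `y_i / min(y)`.
#'
#' @param contact n x n contact matrix, or path to its CSV.
#' @param population length-n population vector (any scale; normalised to
#'   total 1), or path to its CSV.
#' @param cfr per-group case fatality ratio (scalar recycled; default 1,
#'   i.e. count infections).
#' @param target_R0 calibration target for the spectral radius (default 4).
#' @param kappa_scalar vaccinated cost multiplier (default 0.1: vaccination
#'   removes 90% of the fatality risk).
#' @return List with `params`, `linearization` (a
#'   `small_supply_linearization`), `report` (data frame: group, y,
#'   effectiveness proportion), `beta` and `ngm`.
#' @export
age_structured_example <- function(contact, population, cfr = 1,
                                   target_R0 = 4, kappa_scalar = 0.1) {
  if (is.character(contact)) contact <- read_contact_matrix(contact)
  if (is.character(population)) population <- read_population(population)
  Lambda <- as.matrix(contact)
  N <- as.numeric(population)
  n <- length(N)
  if (nrow(Lambda) != n || ncol(Lambda) != n) {
    stop("contact matrix and population vector dimensions do not match",
         call. = FALSE)
  }
  N <- N / sum(N)
  cfr <- rep(as.numeric(cfr), length.out = n)
  if (any(cfr < 0)) stop("'cfr' must be non-negative", call. = FALSE)
  cal <- calibrate_beta(Lambda, N, mu1 = 1, target_R0 = target_R0,
                        tiered = TRUE)
  params <- epidemic_parameters(
    beta1 = cal$beta1, beta2 = cal$beta2, beta3 = cal$beta3,
    beta4 = cal$beta4,
    mu1 = 1, mu2 = 1, N = N, p = cfr, kappa = kappa_scalar,
    S0 = (1 - 1e-4) * N, I0 = 1e-4 * N
  )
  lin <- gradient_y(params)
  report <- data.frame(group = seq_len(n), y = lin$y,
                       effectiveness = lin$y / min(lin$y))
  list(params = params, linearization = lin, report = report,
       beta = cal$beta, ngm = next_generation_matrix(params))
}

#' Synthetic assortative contact-matrix fixture
#'
#' Generates a deterministic (seeded) contact matrix and population vector
#' emulating the qualitative features of survey-based age-structured
#' contact data: strongly assortative mixing (within-group contact
#' dominates), declining contact rates for older groups, declining group
#' sizes with age, and reciprocity (`Lambda[i, j] * N[i]` symmetric, so
#' total contacts between any two groups balance).
#'
#' Construction: per-capita contact activity decays geometrically across
#' groups, `a_i = exp(-3 * decay * (i - 1) / (n - 1))`; the symmetric
#' total-contact matrix is a proportionate-mixing term weighted
#' `(1 - assortativity)` plus a purely diagonal term weighted
#' `assortativity`, scaled so the per-capita row sums are exactly `a_i`;
#' a small symmetric log-normal jitter (sd 0.5%) makes the fixture less
#' regular without disturbing those orderings.
#'
#' @param n_groups number of groups, at least 2 (default 8).
#' @param assortativity weight in \[0, 1\] of the diagonal component
#'   (1 = fully disconnected groups; default 0.7).
#' @param elderly_contact_decay decay in \[0, 1\] of contact activity
#'   across group index (0 = uniform; default 0.3).
#' @param seed integer seed fixing the jitter.
#' @return List with `contact` (n x n matrix, dimnames `group_1` ...) and
#'   `population` (named, sums to 1).
#' @export
synthetic_contact_fixture <- function(n_groups = 8, assortativity = 0.7,
                                      elderly_contact_decay = 0.3,
                                      seed = 1) {
  stopifnot(n_groups >= 2, assortativity >= 0, assortativity <= 1,
            elderly_contact_decay >= 0, elderly_contact_decay <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n <- n_groups
  idx <- seq_len(n)
  # age-pyramid-like population, mildly jittered, older groups smaller
  popw <- seq(1.15, 0.55, length.out = n) * exp(stats::rnorm(n, sd = 0.02))
  N <- popw / sum(popw)
  a <- exp(-3 * elderly_contact_decay * (idx - 1) / (n - 1))
  aN <- a * N
  T_mat <- (1 - assortativity) * outer(aN, aN) / sum(aN) +
    assortativity * diag(aN, nrow = n)
  jit <- matrix(exp(stats::rnorm(n * n, sd = 0.005)), n, n)
  jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
  diag(jit) <- 1
  T_mat <- T_mat * jit
  Lambda <- T_mat / N                      # per-capita contacts, row i
  labels <- paste0("group_", idx)
  dimnames(Lambda) <- list(labels, labels)
  names(N) <- labels
  list(contact = Lambda, population = N)
}

#' Write a contact fixture as CSV files
#'
#' The contact CSV has group labels in the first row and column with a
#' square numeric block; the population CSV has columns `group` and
#' `population`.
#'
#' @param fixture list with `contact` and `population`, as from
#'   [synthetic_contact_fixture()].
#' @param contact_path,population_path output file paths.
#' @return The two paths, invisibly.
#' @export
write_fixture_csv <- function(fixture, contact_path, population_path) {
  utils::write.csv(as.data.frame(fixture$contact), contact_path,
                   row.names = TRUE)
  utils::write.csv(data.frame(group = names(fixture$population),
                              population = as.numeric(fixture$population)),
                   population_path, row.names = FALSE)
  invisible(c(contact_path, population_path))
}

#' Read a contact matrix from CSV
#' @param path CSV with labels in the first row and column.
#' @return A numeric matrix with dimnames.
#' @export
read_contact_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read a population vector from CSV
#' @param path CSV with columns `group` and `population`.
#' @return A named numeric vector.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.numeric(df$population), df$group)
}

#' Groups that ever see infections
#'
#' Simulates the model and returns the indices of groups whose unvaccinated
#' infected compartment exceeds `threshold` at any output time — the
#' seeding set used in the asymptotic hypotheses (groups outside it can be
#' dropped from the model).
#'
#' @param params an [epidemic_parameters()] object.
#' @param policy optional [vaccination_policy()].
#' @param threshold detection level for "suffers infections"
#'   (default `1e-9`).
#' @param ... further arguments to [simulate_epidemic()].
#' @return Increasing integer vector of group indices.
#' @export
infected_groups <- function(params, policy = NULL, threshold = 1e-9, ...) {
  traj <- simulate_epidemic(params, policy, ...)
  n <- params$n
  peak <- vapply(seq_len(n),
                 function(i) max(traj[[paste0("I", i)]]), numeric(1))
  which(peak > threshold)
}
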