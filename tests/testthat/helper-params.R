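# Random admissible parameter sets for property-style tests.
#
# Draws an n-group model with a weakly protective vaccine: positive
# transmission matrix with boosted diagonal (irreducible, so every group is
# seeded), next-generation radius rescaled into [1.3, 2.5] (a clear but
# sub-pandemic epidemic), vaccine multipliers in (0.3, 0.9) on both the
# susceptibility and infectiousness sides, slower-or-equal clearance for
# the vaccinated, and up to 30% of each group vaccinated before t = 0.
random_admissible_params <- function(n) {
  base <- matrix(stats::runif(n * n, 0.2, 1), n, n)
  diag(base) <- diag(base) + stats::runif(n, 0.2, 0.8)
  N <- as.numeric(prop.table(stats::runif(n, 0.5, 1.5)))
  mu1 <- stats::runif(n, 0.7, 1.3)
  mu2 <- mu1 * stats::runif(n, 1, 1.3)
  ngm <- N * sweep(base, 2, mu1, "/")
  rho <- max(Mod(eigen(ngm, only.values = TRUE)$values))
  beta1 <- base * stats::runif(1, 1.3, 2.5) / rho
  r2 <- stats::runif(1, 0.3, 0.9)
  r3 <- stats::runif(1, 0.3, 0.9)
  I0 <- 1e-4 * N
  SV0 <- stats::runif(n, 0, 0.3) * N
  epidemic_parameters(beta1, r2 * beta1, r3 * beta1, r2 * r3 * beta1,
                      mu1, mu2, N,
                      p = stats::runif(n, 0.2, 1),
                      kappa = stats::runif(n, 0.1, 0.9),
                      S0 = N - I0 - SV0, I0 = I0, SV0 = SV0)
}

# Single-group bang-bang policy: eps doses to group i at rate 1 from t = 0.
single_group_policy <- function(params, i, eps) {
  caps <- numeric(params$n)
  caps[i] <- eps
  prioritized_policy(c(i, setdiff(seq_len(params$n), i)),
                     constant_supply_schedule(1, eps), params, caps)
}

# Steep, old-age-skewed case fatality profile for n groups.
steep_cfr <- function(n) 10^seq(-4, -1, length.out = n)
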