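test_that("the two-group builder matches the printed parameterization", {
  ex <- two_group_example(0.2, I_star = 0.05, p_star = 2,
                          chi_eff = 0.4, rho_eff = 0.6)
  b1 <- rbind(c(1, 2), c(2, 4))
  expect_equal(ex$params$beta1, b1)
  expect_equal(ex$params$beta2, 0.4 * b1)
  expect_equal(ex$params$beta3, 0.6 * b1)
  expect_equal(ex$params$beta4, 0.24 * b1)
  expect_equal(ex$params$N, c(0.2, 1))
  expect_equal(ex$params$p, c(5, 2))
  expect_equal(ex$params$kappa, c(1, 1))
  expect_equal(ex$params$S0, c(0.2, 0.95))
  expect_equal(ex$params$I0, c(0, 0.05))
  # complete effectiveness zeroes all vaccinated transmission
  ex0 <- two_group_example(0.2, chi_eff = 0, rho_eff = 0)
  expect_equal(ex0$params$beta2, 0 * b1)
  expect_equal(ex0$params$beta3, 0 * b1)
  expect_equal(ex0$params$beta4, 0 * b1)
})

test_that("vulnerable-first wins at small group sizes, loses at large ones", {
  H_pair <- function(eps) {
    ex <- two_group_example(eps)
    c(U = objective_H(simulate_epidemic(ex$params, ex$policy_U)),
      tilde = objective_H(simulate_epidemic(ex$params, ex$policy_tilde)))
  }
  for (eps in c(1e-3, 1e-2)) {
    h <- H_pair(eps)
    expect_lt(h["tilde"], h["U"])
  }
  h1 <- H_pair(1)
  expect_lt(h1["U"], h1["tilde"])
})

test_that("the homogeneous builder produces the one-group halving model", {
  hx <- homogeneous_example(2, 0.05)
  expect_equal(hx$params$beta1, matrix(2, 1, 1))
  expect_equal(hx$params$beta2, matrix(1, 1, 1))
  expect_equal(hx$params$beta3, matrix(1, 1, 1))
  expect_equal(hx$params$beta4, matrix(0.5, 1, 1))
  expect_equal(hx$params$S0, 1 - 1e-4)
  expect_equal(hx$params$I0, 1e-4)
  expect_equal(chi_rate(hx$schedule, c(0.01, 0.04)), c(1, 1))
  expect_equal(chi_rate(hx$schedule, 0.06), 0)

  # far below threshold, a dose is worth almost nothing
  lin_sub <- gradient_y(homogeneous_example(0.25, 0)$params)
  lin_peak <- gradient_y(homogeneous_example(1, 0)$params)
  expect_lt(abs(lin_sub$y), 0.02 * abs(lin_peak$y))
})

test_that("the synthetic contact fixture has the advertised structure", {
  fx <- synthetic_contact_fixture(n_groups = 8, assortativity = 0.7,
                                  elderly_contact_decay = 0.3, seed = 7)
  n <- 8
  expect_equal(dim(fx$contact), c(n, n))
  expect_equal(sum(fx$population), 1)
  # reciprocity: total contacts between any two groups balance
  totals <- fx$contact * fx$population
  expect_equal(totals, t(totals), tolerance = 1e-12)
  # per-capita contact activity strictly decreasing across (older) groups
  expect_true(all(diff(rowSums(fx$contact)) < 0))
  expect_true(all(diff(colSums(fx$contact)) < 0))
  # assortativity: within-group contact dominates each row
  expect_true(all(diag(fx$contact) >= apply(fx$contact, 1, max) - 1e-12))

  # determinism and full assortativity
  expect_identical(fx, synthetic_contact_fixture(8, 0.7, 0.3, seed = 7))
  fxd <- synthetic_contact_fixture(8, assortativity = 1, seed = 7)
  expect_equal(fxd$contact - diag(diag(fxd$contact)),
               matrix(0, n, n, dimnames = dimnames(fxd$contact)))

  # CSV round-trip through the loaders
  cpath <- withr::local_tempfile(fileext = ".csv")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(fx, cpath, ppath)
  expect_equal(read_contact_matrix(cpath), fx$contact, tolerance = 1e-12)
  expect_equal(read_population(ppath), fx$population, tolerance = 1e-12)
})

test_that("age-structured example calibrates and ranks groups sensibly", {
  fx <- synthetic_contact_fixture(n_groups = 6, seed = 7)
  ax <- age_structured_example(fx$contact, fx$population,
                               cfr = steep_cfr(6), target_R0 = 4,
                               kappa_scalar = 0.1)
  expect_equal(ax$ngm$spectral_radius, 4, tolerance = 1e-10)
  expect_equal(sum(ax$params$N), 1)
  expect_equal(ax$params$I0, 1e-4 * ax$params$N)
  expect_equal(ax$params$kappa, rep(0.1, 6))
  # steep old-age mortality: the oldest group is the best single target
  expect_equal(ax$linearization$best_group, 6L)
  expect_true(all(ax$report$effectiveness >= 0 &
                    ax$report$effectiveness <= 1))
  expect_equal(max(ax$report$effectiveness), 1)

  expect_error(age_structured_example(fx$contact, fx$population[-1]),
               "do not match")

  # identical groups: all y equal, non-unique minimum
  unif <- matrix(1, 3, 3)
  ax_sym <- age_structured_example(unif, c(1, 1, 1), cfr = 1, target_R0 = 2)
  expect_false(ax_sym$linearization$unique_min)
  expect_equal(max(ax_sym$linearization$y) - min(ax_sym$linearization$y), 0,
               tolerance = 1e-12)
})

test_that("infected_groups recovers the seeding set", {
  # both groups are seeded through the irreducible contact structure
  ex <- two_group_example(0.05)
  expect_equal(infected_groups(ex$params), c(1L, 2L))
  # in the vanishing-group limit, group 1's epidemic vanishes with it
  ex_tiny <- two_group_example(1e-6)
  expect_equal(infected_groups(ex_tiny$params, threshold = 1e-4), 2L)
  # a group that nothing transmits into is excluded
  par_iso <- suppressWarnings(epidemic_parameters(
    beta1 = rbind(c(1.8, 0), c(0, 1.8)), beta2 = rbind(c(0.9, 0), c(0, 0.9)),
    beta3 = rbind(c(0.9, 0), c(0, 0.9)), beta4 = rbind(c(0.45, 0), c(0, 0.45)),
    mu1 = 1, mu2 = 1, N = c(0.5, 0.5),
    S0 = c(0.5 - 1e-4, 0.5), I0 = c(1e-4, 0)
  ))
  expect_equal(infected_groups(par_iso), 1L)
})

test_that("the crossover size responds to seeding and weights as expected", {
  es <- function(I_star, p_star, ...) {
    epsilon_star(I_star = I_star, p_star = p_star, t_max = 600,
                 ...)$epsilon_star
  }
  base <- es(0.01, 1)
  # raising group 2's weight makes infectious-first more attractive:
  # epsilon* non-increasing in p*
  expect_lte(base, es(0.01, 0.5) + 1e-9)
  # fewer initial infections leave more time to vaccinate the infectious
  # group before the epidemic grows, extending the region where
  # infectious-first wins: epsilon* non-decreasing in I*
  expect_lte(base, es(0.02, 1) + 1e-9)
  # small-seeding plateau under complete effectiveness: once vaccination
  # outpaces the (subcritical-after-vaccination) epidemic, shrinking the
  # seed no longer moves the crossover
  lo <- es(1e-4, 1, chi_eff = 0, rho_eff = 0)
  hi <- es(1e-3, 1, chi_eff = 0, rho_eff = 0)
  expect_lt(abs(lo - hi) / hi, 0.10)
})
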