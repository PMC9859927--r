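two_group_schedule <- function() {
  # rate cap 1, supply ramping linearly to a total of 1
  supply_schedule(A_breaks = 0, A_rates = 1,
                  B_knots = c(0, 1), B_values = c(0, 1), B_final_slope = 0)
}

test_that("chi_rate follows the rate cap until supply binds", {
  # unbounded supply growth: the cumulative cap never binds
  s1 <- supply_schedule(A_breaks = 0, A_rates = 1,
                        B_knots = c(0, 1), B_values = c(1, 1),
                        B_final_slope = 1)       # B(t) = max(t, 1)
  expect_equal(chi_rate(s1, c(0, 0.5, 1, 2, 10)), rep(1, 5))

  # fixed small supply eps: full rate until exhaustion, then zero
  eps <- 0.3
  s2 <- constant_supply_schedule(rate = 1, total = eps)
  expect_equal(chi_rate(s2, c(0, 0.1, 0.29)), rep(1, 3))
  expect_equal(chi_rate(s2, c(0.31, 5)), c(0, 0))

  # linear ramp to 1: rate 1 while supply arrives, zero afterwards
  s3 <- two_group_schedule()
  expect_equal(chi_rate(s3, c(0, 0.5, 0.99)), rep(1, 3))
  expect_equal(chi_rate(s3, c(1, 2)), c(0, 0))
})

test_that("cumulative doses integrate piecewise-constant rates exactly", {
  pol_U <- vaccination_policy(c(0, 1), matrix(c(0, 1), 1, 2))
  expect_equal(cumulative_doses(pol_U, 0), c(0, 0))
  expect_equal(cumulative_doses(pol_U, 0.5), c(0, 0.5))
  expect_equal(cumulative_doses(pol_U, 3), c(0, 1))

  eps <- 0.3
  pol_T <- vaccination_policy(c(0, eps, 1),
                              rbind(c(1, 0), c(0, 1)))
  expect_equal(cumulative_doses(pol_T, 1), c(0.3, 0.7))
  # non-decreasing and piecewise-linear in t
  tt <- seq(0, 1.5, by = 0.01)
  W <- cumulative_doses(pol_T, tt)
  expect_true(all(diff(W[, 1]) >= 0) && all(diff(W[, 2]) >= 0))
})

test_that("feasibility checks rate, supply and group-size constraints", {
  set.seed(21)
  par2 <- suppressWarnings(
    epidemic_parameters(beta1 = rbind(c(1, 2), c(2, 4)),
                        beta2 = rbind(c(1, 2), c(2, 4)) / 2,
                        beta3 = rbind(c(1, 2), c(2, 4)) / 2,
                        beta4 = rbind(c(1, 2), c(2, 4)) / 4,
                        mu1 = 1, mu2 = 1, N = c(0.3, 1),
                        S0 = c(0.3, 0.99), I0 = c(0, 0.01))
  )
  sched <- two_group_schedule()
  expect_true(is_feasible(zero_policy(2), sched, par2)$feasible)

  pol_U <- vaccination_policy(c(0, 1), matrix(c(0, 1), 1, 2))
  expect_true(is_feasible(pol_U, sched, par2)$feasible)

  # halved rate cap: total rate 1 violates A(t) = 0.5 immediately
  slow <- supply_schedule(A_breaks = 0, A_rates = 0.5,
                          B_knots = c(0, 1), B_values = c(0, 1))
  bad <- is_feasible(pol_U, slow, par2)
  expect_false(bad$feasible)
  expect_match(bad$violation$constraint, "rate")
  expect_equal(bad$violation$time, 0)

  # over-vaccinating a group beyond its size
  pol_big <- vaccination_policy(c(0, 0.5), matrix(c(1, 0), 1, 2))
  bad2 <- is_feasible(pol_big, sched, par2)
  expect_false(bad2$feasible)
  expect_match(bad2$violation$constraint, "group size")
})

test_that("the vulnerable-first swap redirects exactly eps doses to group 1", {
  pol_U <- vaccination_policy(c(0, 1), matrix(c(0, 1), 1, 2))

  for (eps in c(0.05, 0.3, 1)) {
    tilde <- build_tilde_policy(pol_U, eps)
    # matches the printed two-phase form: group 1 at rate 1 until
    # min(1, eps), then group 2 on (eps, 1]
    expect_equal(cumulative_doses(tilde, min(1, eps)),
                 c(min(1, eps), 0))
    expect_equal(cumulative_doses(tilde, 1), c(eps, 1 - eps))
    # total doses by any time never exceed the original's
    tt <- seq(0, 1.2, by = 0.05)
    expect_true(all(rowSums(cumulative_doses(tilde, tt)) <=
                      rowSums(cumulative_doses(pol_U, tt)) + 1e-12))
  }

  # eps = 0: group 1 untouched, others keep their schedule
  t0 <- build_tilde_policy(pol_U, 0)
  expect_equal(cumulative_doses(t0, 2), c(0, 1))

  # zero policy stays zero
  expect_equal(cumulative_doses(build_tilde_policy(zero_policy(2), 0.5), 1),
               c(0, 0))

  # swapping more than group 1's size is an error
  par2 <- suppressWarnings(
    epidemic_parameters(beta1 = rbind(c(1, 2), c(2, 4)),
                        beta2 = rbind(c(1, 2), c(2, 4)) / 2,
                        beta3 = rbind(c(1, 2), c(2, 4)) / 2,
                        beta4 = rbind(c(1, 2), c(2, 4)) / 4,
                        mu1 = 1, mu2 = 1, N = c(0.3, 1),
                        S0 = c(0.3, 0.99), I0 = c(0, 0.01))
  )
  expect_error(build_tilde_policy(pol_U, 0.5, par2), "over-vaccinated")
})

test_that("prioritized bang-bang policies realize the supply identity", {
  ex <- two_group_example(0.3)
  sched <- ex$schedule
  par <- ex$params

  # infectious-first ordering reproduces the one-group unit-rate policy
  U <- prioritized_policy(c(2, 1), sched, par, per_group_caps = c(0.3, 1))
  expect_equal(U$times, c(0, 1))
  expect_equal(unname(U$rates), matrix(c(0, 1), 1, 2))

  # vulnerable-first ordering reproduces the two-phase swap policy
  T2 <- prioritized_policy(c(1, 2), sched, par, per_group_caps = c(0.3, 1))
  expect_equal(T2$times, c(0, 0.3, 1))
  expect_equal(unname(T2$rates), rbind(c(1, 0), c(0, 1)))

  # all-zero caps give the zero policy
  Z <- prioritized_policy(c(1, 2), sched, par, per_group_caps = c(0, 0))
  expect_equal(cumulative_doses(Z, 5), c(0, 0))

  # supply identity: total administered = min(integral of chi, total caps),
  # and the output is always feasible
  set.seed(31)
  for (rep in 1:5) {
    par_r <- random_admissible_params(3)
    caps <- stats::runif(3, 0, 1) * par_r$N
    total <- stats::runif(1, 0.05, 1.5)
    rate <- stats::runif(1, 0.5, 2)
    sch <- constant_supply_schedule(rate = rate, total = total)
    pol <- prioritized_policy(sample(3), sch, par_r, caps)
    expect_true(is_feasible(pol, sch, par_r)$feasible)
    for (tt in c(0.1, 0.5, 2, 10)) {
      int_chi <- min(rate * tt, total)
      expect_equal(sum(cumulative_doses(pol, tt)),
                   min(int_chi, sum(caps)), tolerance = 1e-10)
    }
  }
})

test_that("policies and schedules survive a JSON round-trip", {
  pol <- vaccination_policy(c(0, 0.3, 1), rbind(c(1, 0), c(0, 1)))
  back <- policy_from_json(policy_to_json(pol))
  expect_equal(back$times, pol$times)
  expect_equal(back$rates, pol$rates)

  sch <- two_group_schedule()
  sch_back <- policy_from_json(policy_to_json(sch))
  expect_equal(chi_rate(sch_back, c(0.2, 0.8, 1.5)),
               chi_rate(sch, c(0.2, 0.8, 1.5)))
})
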