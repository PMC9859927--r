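#' Vaccine supply schedule
#'
#' A schedule has two constraints: a maximal administration rate `A(t)`
#' (doses per unit time, as population fraction) and a maximal cumulative
#' supply `B(t)` (population fraction). Any feasible policy must satisfy
#' `sum_i U_i(t) <= A(t)` and `sum_i W_i(t) <= B(t)` at all times.
#'
#' `A` is represented as a right-continuous step function (piecewise
#' constant), `B` as a continuous piecewise-linear function extended beyond
#' its last knot with slope `B_final_slope`. `B` must be non-decreasing.
#'
#' @param A_breaks non-decreasing times at which the rate cap changes; must
#'   start at 0.
#' @param A_rates rate cap on each interval `[A_breaks[k], A_breaks[k+1])`;
#'   the last value extends to infinity.
#' @param B_knots knot times of the supply cap; must start at 0.
#' @param B_values supply cap at each knot.
#' @param B_final_slope slope of `B` beyond the last knot (default 0,
#'   i.e. no further supply).
#' @return An object of class `supply_schedule`.
#' @examples
#' # rate cap 1, total supply ramping linearly to 1 and then fixed
#' sched <- supply_schedule(A_rates = 1, B_knots = c(0, 1),
#'                          B_values = c(0, 1))
#' chi_rate(sched, c(0.5, 2))
#' @export
supply_schedule <- function(A_breaks = 0, A_rates = 1,
                            B_knots = 0, B_values = Inf,
                            B_final_slope = 0) {
  A_breaks <- as.numeric(A_breaks); A_rates <- as.numeric(A_rates)
  B_knots <- as.numeric(B_knots); B_values <- as.numeric(B_values)
  stopifnot(length(A_breaks) == length(A_rates),
            length(B_knots) == length(B_values),
            A_breaks[1] == 0, B_knots[1] == 0,
            !is.unsorted(A_breaks, strictly = TRUE),
            !is.unsorted(B_knots, strictly = TRUE))
  if (any(A_rates < 0)) stop("rate cap A must be non-negative", call. = FALSE)
  if (is.unsorted(B_values) || B_final_slope < 0) {
    stop("supply cap B must be non-decreasing", call. = FALSE)
  }
  structure(list(A_breaks = A_breaks, A_rates = A_rates,
                 B_knots = B_knots, B_values = B_values,
                 B_final_slope = B_final_slope),
            class = "supply_schedule")
}

#' Constant-rate, fixed-supply schedule
#'
#' Convenience constructor: administration rate cap `rate` at all times and
#' a fixed total supply `total` available from time 0 (the small-supply
#' setting `B(t) = eps`).
#'
#' @param rate maximal administration rate.
#' @param total total available supply; `Inf` for unlimited.
#' @return A [supply_schedule()].
#' @export
constant_supply_schedule <- function(rate = 1, total = Inf) {
  supply_schedule(A_breaks = 0, A_rates = rate,
                  B_knots = 0, B_values = total, B_final_slope = 0)
}

schedule_A <- function(schedule, t) {
  k <- findInterval(t, schedule$A_breaks)
  k[k < 1L] <- 1L
  schedule$A_rates[k]
}

schedule_cumA <- function(schedule, t) {
  br <- schedule$A_breaks
  r <- schedule$A_rates
  m <- length(br)
  ends <- c(br[-1], Inf)
  vapply(t, function(tt) {
    dur <- pmin(tt, ends) - br
    sum(r * pmax(dur, 0))
  }, numeric(1))
}

schedule_B <- function(schedule, t) {
  kn <- schedule$B_knots
  v <- schedule$B_values
  m <- length(kn)
  k <- findInterval(t, kn)
  k[k < 1L] <- 1L
  slope <- if (m > 1) c(diff(v) / diff(kn), schedule$B_final_slope)
           else schedule$B_final_slope
  v[k] + slope[k] * (t - kn[k])
}

schedule_B_rderiv <- function(schedule, t) {
  kn <- schedule$B_knots
  v <- schedule$B_values
  m <- length(kn)
  slope <- if (m > 1) c(diff(v) / diff(kn), schedule$B_final_slope)
           else schedule$B_final_slope
  k <- findInterval(t, kn)
  k[k < 1L] <- 1L
  slope[k]
}

#' Maximal administrable vaccination rate
#'
#' The fastest rate at which doses can actually be given at time `t`:
#' while the running integral of the rate cap `A` is below the supply cap
#' `B(t)`, doses can flow at `A(t)`; once cumulative capacity has caught up
#' with supply, the rate is limited by how fast new supply arrives,
#' `min(A(t), B'(t))`, with the right-hand derivative used at kinks of `B`.
#'
#' @param schedule a [supply_schedule()].
#' @param t time (vectorized).
#' @return Non-negative rate(s).
#' @export
chi_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "supply_schedule"))
  A <- schedule_A(schedule, t)
  cumA <- schedule_cumA(schedule, t)
  B <- schedule_B(schedule, t)
  ifelse(cumA < B, A, pmin(A, schedule_B_rderiv(schedule, t)))
}

# Piecewise-constant representation of chi(t) from time 0 until the
# administered total reaches `total_cap` (or chi becomes permanently 0).
# Returns list(t0, t1, rate, cum_end) per piece; last piece may be clipped
# exactly at the time the cap is reached.
chi_pieces <- function(schedule, total_cap) {
  knots <- sort(unique(c(schedule$A_breaks, schedule$B_knots)))
  pieces <- list()
  cum_chi <- 0
  add_piece <- function(t0, t1, rate) {
    if (t1 <= t0 || rate < 0) return(FALSE)   # skip empty
    # clip at cap
    if (rate > 0 && cum_chi + rate * (t1 - t0) >= total_cap - 1e-15) {
      t1 <- t0 + (total_cap - cum_chi) / rate
      pieces[[length(pieces) + 1L]] <<- list(t0 = t0, t1 = t1, rate = rate)
      cum_chi <<- total_cap
      return(TRUE)                             # cap reached
    }
    pieces[[length(pieces) + 1L]] <<- list(t0 = t0, t1 = t1, rate = rate)
    cum_chi <<- cum_chi + rate * (t1 - t0)
    FALSE
  }
  n_kn <- length(knots)
  for (k in seq_len(n_kn)) {
    a <- knots[k]
    b <- if (k < n_kn) knots[k + 1] else Inf
    r <- schedule_A(schedule, a)
    s <- schedule_B_rderiv(schedule, a)
    g0 <- schedule_cumA(schedule, a) - schedule_B(schedule, a)
    gslope <- r - s
    chi_lo <- if (g0 < 0) r else min(r, s)       # chi while g keeps its sign
    # crossing time of g within (a, b)
    t_c <- if (gslope != 0) a - g0 / gslope else Inf
    if (g0 < 0 && gslope > 0 && t_c < b) {
      if (add_piece(a, t_c, r)) return(pieces)
      if (is.infinite(b)) {
        chi_inf <- min(r, s)
        if (chi_inf <= 0) return(pieces)
        if (add_piece(t_c, Inf, chi_inf)) return(pieces)
        return(pieces)
      }
      if (add_piece(t_c, b, min(r, s))) return(pieces)
    } else if (g0 >= 0 && gslope < 0 && t_c < b && t_c > a) {
      if (add_piece(a, t_c, min(r, s))) return(pieces)
      if (is.infinite(b)) {
        if (r <= 0) return(pieces)
        if (add_piece(t_c, Inf, r)) return(pieces)
        return(pieces)
      }
      if (add_piece(t_c, b, r)) return(pieces)
    } else {
      if (is.infinite(b)) {
        if (chi_lo <= 0) return(pieces)
        if (add_piece(a, Inf, chi_lo)) return(pieces)
        return(pieces)
      }
      if (add_piece(a, b, chi_lo)) return(pieces)
    }
  }
  pieces
}

#' Piecewise-constant vaccination policy
#'
#' Per-group vaccination rates `U_i(t)` that are constant on each interval
#' `[times[k], times[k+1])` and zero after the last breakpoint (finite
#' support). Cumulative doses `W_i(t)` are then exactly piecewise linear.
#'
#' @param times strictly increasing breakpoints starting at 0, length m + 1.
#' @param rates m x n matrix of non-negative rates (row k applies on
#'   `[times[k], times[k+1])`). A vector is taken as a single-group policy.
#' @return An object of class `vaccination_policy`.
#' @examples
#' # vaccinate group 2 of a two-group model at rate 1 for one time unit
#' pol <- vaccination_policy(c(0, 1), matrix(c(0, 1), 1, 2))
#' cumulative_doses(pol, c(0.5, 2))
#' @export
vaccination_policy <- function(times, rates) {
  times <- as.numeric(times)
  if (is.vector(rates)) rates <- matrix(rates, nrow = length(times) - 1L)
  rates <- as.matrix(rates)
  if (length(times) != nrow(rates) + 1L) {
    stop("need length(times) == nrow(rates) + 1", call. = FALSE)
  }
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  if (any(rates < 0)) stop("vaccination rates must be non-negative", call. = FALSE)
  structure(list(times = times, rates = rates, n = ncol(rates),
                 support_end = times[length(times)]),
            class = "vaccination_policy")
}

#' The all-zero policy
#' @param n number of groups.
#' @return A [vaccination_policy()] with no vaccination.
#' @export
zero_policy <- function(n) {
  structure(list(times = 0, rates = matrix(0, 0, n), n = n, support_end = 0),
            class = "vaccination_policy")
}

#' @export
print.vaccination_policy <- function(x, ...) {
  cat(sprintf("Vaccination policy: %d group(s), %d segment(s), support ends t = %g\n",
              x$n, nrow(x$rates), x$support_end))
  if (nrow(x$rates) > 0) {
    seg <- data.frame(from = x$times[-length(x$times)], to = x$times[-1])
    colnames_r <- paste0("U", seq_len(x$n))
    seg[colnames_r] <- x$rates
    print(seg, row.names = FALSE)
  }
  cat(sprintf("Total doses: %s\n",
              paste(signif(cumulative_doses(x, x$support_end), 6),
                    collapse = ", ")))
  invisible(x)
}

# rate vector at time t (right-continuous; zero outside support)
policy_rate_at <- function(policy, t) {
  m <- nrow(policy$rates)
  if (m == 0L || t < 0 || t >= policy$support_end) return(numeric(policy$n))
  k <- findInterval(t, policy$times)
  k <- min(max(k, 1L), m)
  policy$rates[k, ]
}

#' Cumulative doses delivered by a policy
#'
#' Exact (closed-form) integral `W_i(t)` of the piecewise-constant rates.
#'
#' @param policy a [vaccination_policy()].
#' @param t time, vectorized.
#' @return For scalar `t`, a length-n vector; otherwise an
#'   `length(t)` x n matrix.
#' @export
cumulative_doses <- function(policy, t) {
  stopifnot(inherits(policy, "vaccination_policy"))
  m <- nrow(policy$rates)
  one <- function(tt) {
    if (m == 0L) return(numeric(policy$n))
    dur <- pmax(pmin(tt, policy$times[-1]) - policy$times[-length(policy$times)], 0)
    as.numeric(crossprod(policy$rates, dur))
  }
  if (length(t) == 1L) return(one(t))
  res <- vapply(t, one, numeric(policy$n))
  if (policy$n == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Check a policy against a supply schedule and group sizes
#'
#' Verifies, on a grid refined at all breakpoints of the policy and the
#' schedule (plus interval midpoints), that the total rate never exceeds
#' `A(t)`, the total doses never exceed `B(t)`, no group receives more doses
#' than its size, and all rates are non-negative. Since rates and caps are
#' piecewise constant / linear, this grid is exhaustive up to the tolerance.
#'
#' @param policy a [vaccination_policy()].
#' @param schedule a [supply_schedule()].
#' @param params an [epidemic_parameters()] object (for group sizes).
#' @param tol slack allowed on each constraint (default `1e-9`).
#' @return A list with `feasible` (logical) and, when infeasible,
#'   `violation` naming the first violated constraint and the time.
#' @export
is_feasible <- function(policy, schedule, params, tol = 1e-9) {
  stopifnot(inherits(policy, "vaccination_policy"),
            inherits(schedule, "supply_schedule"),
            inherits(params, "epidemic_parameters"))
  pts <- sort(unique(c(policy$times, schedule$A_breaks, schedule$B_knots,
                       policy$support_end + 1)))
  pts <- pts[pts >= 0]
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  grid <- sort(unique(c(pts, mids)))
  fail <- function(what, tt) list(feasible = FALSE,
                                  violation = list(constraint = what, time = tt))
  for (tt in grid) {
    u <- policy_rate_at(policy, tt)
    if (sum(u) > schedule_A(schedule, tt) + tol) {
      return(fail("total rate exceeds A(t)", tt))
    }
    W <- cumulative_doses(policy, tt)
    if (sum(W) > schedule_B(schedule, tt) + tol) {
      return(fail("total doses exceed B(t)", tt))
    }
    if (any(W > params$N + tol)) {
      return(fail("group doses exceed group size", tt))
    }
  }
  list(feasible = TRUE, violation = NULL)
}

#' Redirect a policy's early doses to the vulnerable group
#'
#' Given any finite-support policy `U`, builds the swapped policy in which
#' group 1 is vaccinated first: the *total* rate `sum_i U_i(t)` is directed
#' entirely to group 1 until `epsilon` doses have been given in total, after
#' which group 1 receives nothing and every other group resumes its original
#' schedule. Doses the original policy assigned to group 1 after the switch
#' are dropped. The swapped policy never exceeds the original total rate at
#' any time, so it is feasible whenever the original is (and
#' `epsilon <= N_1`).
#'
#' @param policy a [vaccination_policy()].
#' @param epsilon doses to direct to group 1 (its size, typically).
#' @param params optional [epidemic_parameters()]; when supplied,
#'   `epsilon > N_1` is an error.
#' @return A [vaccination_policy()].
#' @export
build_tilde_policy <- function(policy, epsilon, params = NULL) {
  stopifnot(inherits(policy, "vaccination_policy"), epsilon >= 0)
  if (!is.null(params) && epsilon > params$N[1] + 1e-12) {
    stop("epsilon exceeds the size of group 1; it would be over-vaccinated",
         call. = FALSE)
  }
  n <- policy$n
  m <- nrow(policy$rates)
  if (epsilon == 0 || m == 0L) {
    rates <- policy$rates
    if (m > 0L) rates[, 1] <- 0
    return(vaccination_policy(policy$times, rates))
  }
  tot_rate <- rowSums(policy$rates)
  seg_doses <- tot_rate * diff(policy$times)
  cum_end <- cumsum(seg_doses)
  # switch time: first t with total cumulative doses == epsilon
  k_sw <- which(cum_end >= epsilon - 1e-15)[1]
  if (is.na(k_sw)) {
    t_star <- Inf                         # supply never reaches epsilon
  } else {
    cum_before <- if (k_sw == 1L) 0 else cum_end[k_sw - 1L]
    t_star <- policy$times[k_sw] + (epsilon - cum_before) / tot_rate[k_sw]
  }
  new_times <- sort(unique(c(policy$times, min(t_star, policy$support_end))))
  starts <- new_times[-length(new_times)]
  rates <- matrix(0, length(starts), n)
  for (k in seq_along(starts)) {
    u <- policy_rate_at(policy, starts[k])
    if (starts[k] < t_star) {
      rates[k, 1] <- sum(u)
    } else {
      rates[k, -1] <- u[-1]
    }
  }
  # drop trailing all-zero segments
  keep <- rev(cumsum(rev(rowSums(rates))) > 0)
  if (!any(keep)) return(zero_policy(n))
  last <- max(which(keep))
  vaccination_policy(new_times[seq_len(last + 1L)],
                     rates[seq_len(last), , drop = FALSE])
}

#' Bang-bang policy filling groups in priority order
#'
#' Vaccinates at the maximal administrable rate [chi_rate()] at all times,
#' directing all of it to the first group in `order` until that group has
#' received its cap, then to the next, and so on. The resulting cumulative
#' total administered by time t equals `min(integral of chi, sum(caps))`.
#'
#' @param order permutation of `1:n`; groups are filled in this order.
#' @param schedule a [supply_schedule()].
#' @param params an [epidemic_parameters()] object.
#' @param per_group_caps length-n dose caps (at most `N`); default `N`
#'   (vaccinate everyone, supply permitting).
#' @return A [vaccination_policy()].
#' @export
prioritized_policy <- function(order, schedule, params, per_group_caps = NULL) {
  stopifnot(inherits(schedule, "supply_schedule"),
            inherits(params, "epidemic_parameters"))
  n <- params$n
  if (!setequal(order, seq_len(n))) {
    stop("'order' must be a permutation of 1:n", call. = FALSE)
  }
  caps <- if (is.null(per_group_caps)) params$N else as.numeric(per_group_caps)
  if (any(caps > params$N + 1e-12)) {
    stop("per-group caps cannot exceed group sizes", call. = FALSE)
  }
  total_cap <- sum(caps[order])
  if (total_cap <= 0) return(zero_policy(n))
  pieces <- chi_pieces(schedule, total_cap)
  segs_t0 <- numeric(0); segs_t1 <- numeric(0); segs_rates <- NULL
  gi <- 1L                          # position in the priority order
  given <- 0                        # doses given to current group
  skip_full <- function() {
    while (gi <= n && caps[order[gi]] - given <= 1e-15) {
      gi <<- gi + 1L; given <<- 0
    }
  }
  skip_full()
  for (pc in pieces) {
    t0 <- pc$t0
    while (t0 < pc$t1 - 1e-15 && gi <= n) {
      if (pc$rate <= 0) break
      g <- order[gi]
      room <- caps[g] - given
      t_fill <- t0 + room / pc$rate
      t1 <- min(t_fill, pc$t1)
      rv <- numeric(n); rv[g] <- pc$rate
      segs_t0 <- c(segs_t0, t0); segs_t1 <- c(segs_t1, t1)
      segs_rates <- rbind(segs_rates, rv)
      given <- given + pc$rate * (t1 - t0)
      t0 <- t1
      skip_full()
    }
    if (gi > n) break
  }
  if (length(segs_t0) == 0) return(zero_policy(n))
  # assemble breakpoints, inserting explicit zero segments across gaps
  times <- 0
  rates <- NULL
  cur <- 0
  for (k in seq_along(segs_t0)) {
    if (segs_t0[k] > cur + 1e-14) {      # idle gap (chi was 0)
      times <- c(times, segs_t0[k])
      rates <- rbind(rates, numeric(n))
      cur <- segs_t0[k]
    }
    times <- c(times, segs_t1[k])
    rates <- rbind(rates, segs_rates[k, ])
    cur <- segs_t1[k]
  }
  vaccination_policy(times, rates)
}

#' Serialize a policy or schedule to JSON
#'
#' @param x a [vaccination_policy()] or [supply_schedule()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
policy_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "vaccination_policy")) {
    list(type = "vaccination_policy", times = x$times,
         rates = x$rates, n = x$n)
  } else if (inherits(x, "supply_schedule")) {
    list(type = "supply_schedule", A_breaks = x$A_breaks, A_rates = x$A_rates,
         B_knots = x$B_knots, B_values = x$B_values,
         B_final_slope = x$B_final_slope)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a policy or schedule from JSON
#' @param path file path or JSON string written by [policy_to_json()].
#' @return A [vaccination_policy()] or [supply_schedule()].
#' @export
policy_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (identical(obj$type, "vaccination_policy")) {
    rates <- matrix(as.numeric(as.matrix(obj$rates)), ncol = obj$n)
    vaccination_policy(obj$times, rates)
  } else if (identical(obj$type, "supply_schedule")) {
    supply_schedule(obj$A_breaks, obj$A_rates, obj$B_knots, obj$B_values,
                    obj$B_final_slope)
  } else {
    stop("unrecognized JSON payload", call. = FALSE)
  }
}
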