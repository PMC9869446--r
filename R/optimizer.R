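#' Total net intake of a switch schedule
#'
#' Rolls the schedule forward in expected mode and returns the objective
#' `sum(intake) - T * N * q`, or `-Inf` when the schedule drives the nectar
#' stores negative at any step (infeasible).
#'
#' @param schedule Numeric vector of length `cp$T` of newly switched
#'   foragers per step.
#' @param cp,lc Parameter objects.
#' @return A single number (reward units), `-Inf` if infeasible.
#' @export
#' @examples
#' cp <- colony_params(); lc <- learning_params()
#' schedule_value(numeric(cp$T), cp, lc)  # all-simple baseline
schedule_value <- function(schedule, cp, lc) {
  traj <- simulate_schedule(schedule, cp, lc, mode = "expected")
  if (!attr(traj, "feasible")) return(-Inf)
  attr(traj, "objective")
}

# survival-discounted learning-curve increments:
# delta[k+1] = sum_{j=0..k} sigma_j * (c(j) - s), sigma_j = (1-mu)^j.
# delta[k+1] is the effect on the stores at the end of step t+k of one
# additional forager switched at step t; delta[rem] is the marginal value V_t.
switch_deltas <- function(rem, mu, lc) {
  sigma <- (1 - mu)^(0:(rem - 1))
  cumsum(sigma * (complex_reward(0:(rem - 1), lc) - lc$s))
}

# forward stores assuming the given cohorts (masses m at switch steps ct)
# and no further switches, from stores B at the start of step t0
baseline_stores <- function(B, t0, cohorts, ct, cp, lc, mu) {
  rem <- cp$T - t0
  out <- numeric(rem)
  for (k in 0:(rem - 1)) {
    u <- t0 + k
    if (length(cohorts)) {
      alive <- cohorts * (1 - mu)^(u - ct)
      intake_c <- sum(alive * complex_reward(u - ct, lc))
      n_simple <- cp$N_f - sum(alive)
    } else {
      intake_c <- 0
      n_simple <- cp$N_f
    }
    B <- B + n_simple * lc$s + intake_c - cp$N * cp$q
    out[k + 1] <- B
  }
  out
}

# greedy: at each step switch the largest m_t that (i) keeps the whole
# remaining horizon solvent assuming no further switches and (ii) has a
# positive survival-discounted marginal value
greedy_schedule <- function(cp, lc, integer = TRUE) {
  T <- cp$T
  mu <- per_step_mortality(cp)
  sched <- numeric(T)
  cohorts <- numeric(0)
  ct <- integer(0)
  B <- cp$initial_stores
  for (t in 0:(T - 1)) {
    rem <- T - t
    delta <- switch_deltas(rem, mu, lc)
    V <- delta[rem]
    alive <- if (length(cohorts)) sum(cohorts * (1 - mu)^(t - ct)) else 0
    pool <- cp$N_f - alive
    m_t <- 0
    if (V > 1e-12 && pool > 0) {
      Bu <- baseline_stores(B, t, cohorts, ct, cp, lc, mu)
      neg <- delta < -1e-12
      cap <- if (any(neg)) min(Bu[neg] / (-delta[neg])) else Inf
      m_t <- max(0, min(cap, pool))
      if (integer) m_t <- floor(m_t + 1e-9)
    }
    if (m_t > 0) {
      cohorts <- c(cohorts, m_t)
      ct <- c(ct, t)
    }
    # advance stores one step with the new cohort included
    if (length(cohorts)) {
      al <- cohorts * (1 - mu)^(t - ct)
      intake_c <- sum(al * complex_reward(t - ct, lc))
      n_simple <- cp$N_f - sum(al)
    } else {
      intake_c <- 0
      n_simple <- cp$N_f
    }
    B <- B + n_simple * lc$s + intake_c - cp$N * cp$q
    sched[t + 1] <- m_t
  }
  sched
}

# LP over permanent-switch schedules (continuous relaxation), solved with a
# dense simplex. Objective sum_t V_t m_t; constraints keep stores and the
# forager pool non-negative at every step.
lp_schedule <- function(cp, lc) {
  T <- cp$T
  mu <- per_step_mortality(cp)
  delta <- switch_deltas(T, mu, lc)
  sigma <- (1 - mu)^(0:(T - 1))
  V <- vapply(0:(T - 1), function(t) delta[T - t], numeric(1))
  per_step_surplus <- cp$N_f * lc$s - cp$N * cp$q
  A1 <- matrix(0, 2 * T, T)
  b1 <- numeric(2 * T)
  for (u in 0:(T - 1)) {
    A1[u + 1, 1:(u + 1)] <- -delta[(u:0) + 1]
    b1[u + 1] <- cp$initial_stores + (u + 1) * per_step_surplus
    A1[T + u + 1, 1:(u + 1)] <- sigma[(u:0) + 1]
    b1[T + u + 1] <- cp$N_f
  }
  res <- boot::simplex(a = V, A1 = A1, b1 = b1, maxi = TRUE)
  if (res$solved < 0) stop("LP solver reported infeasibility", call. = FALSE)
  if (res$solved == 0) {
    res <- boot::simplex(a = V, A1 = A1, b1 = b1, maxi = TRUE,
                         n.iter = 50 * (3 * T))
    if (res$solved != 1) stop("LP solver failed to converge", call. = FALSE)
  }
  as.numeric(res$soln)
}

new_forage_policy <- function(schedule, trajectory, method, integer, cp, lc) {
  structure(
    list(
      schedule = tibble::tibble(t = 0:(cp$T - 1), m = schedule),
      trajectory = trajectory,
      objective = attr(trajectory, "objective"),
      all_complex_step = all_complex_step(trajectory),
      method = method,
      integer = integer,
      colony = cp,
      learning = lc
    ),
    class = "forage_policy"
  )
}

#' Optimal allocation of foragers between simple and complex flowers
#'
#' Computes the switch schedule that maximizes total colony net intake over
#' the horizon subject to the nectar stores staying non-negative at every
#' step. Production methods restrict the policy to "switch once,
#' permanently" per bee: the learning curve is monotone and experience is
#' never forgotten, so interrupting complex foraging can never raise a
#' bee's future reward, and the only reason to stay on simple flowers is
#' the energy budget, which is handled by delaying switches. The
#' restriction is validated (not assumed) against [bruteforce_oracle()] on
#' small instances in the test suite.
#'
#' * `"greedy"`: at each step, permanently switch the largest number of
#'   unswitched foragers such that the whole-horizon forward simulation
#'   stays solvent (assuming no further switches) and the survival-weighted
#'   marginal value of switching now is positive,
#'   `sum_j sigma_j * (c(j) - s) > 0` with `sigma_j = (1 - mu)^j`.
#' * `"lp"`: the same policy class as a linear program in the per-step
#'   switch counts (objective and stores constraints are linear). When
#'   `integer = TRUE` the cumulative switch curve of the continuous
#'   solution is rounded down to whole bees and the result re-checked for
#'   feasibility; it then tracks the relaxation within one bee per step.
#' * `"bruteforce"`: exact enumeration over the *unrestricted* allocation
#'   space via [bruteforce_oracle()]; only for tiny instances.
#'
#' @param cp,lc Parameter objects ([colony_params()], [learning_params()]).
#' @param method One of `"greedy"`, `"lp"`, `"bruteforce"`.
#' @param integer Force integer switch counts. Defaults to `TRUE` when the
#'   colony has at least two foragers; a single forager (the solitary-bee
#'   limit) is optimized in fractions of foraging time instead.
#' @return An object of class `forage_policy`: a list with `schedule`
#'   (tibble `t`, `m`), `trajectory` (see [simulate_schedule()]),
#'   `objective`, `all_complex_step`, `method` and the input parameters.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' sol <- optimize_foraging(colony_params(), learning_params())
#' glance(sol)
optimize_foraging <- function(cp, lc, method = c("greedy", "lp", "bruteforce"),
                              integer = NULL) {
  stopifnot(inherits(cp, "colony_params"), inherits(lc, "learning_params"))
  method <- match.arg(method)
  check_feasible(cp, lc)
  if (is.null(integer)) integer <- cp$N_f >= 2

  if (method == "bruteforce") {
    return(bruteforce_oracle(cp, lc))
  }
  sched <- switch(method,
    greedy = greedy_schedule(cp, lc, integer = integer),
    lp = {
      m <- lp_schedule(cp, lc)
      # round the *cumulative* switch curve down to whole bees: the
      # cumulative counts then track the relaxation within one bee at
      # every step, which wastes far less value than flooring each m_t
      if (integer) m <- diff(c(0, floor(cumsum(m) + 1e-9)))
      m
    }
  )
  traj <- simulate_schedule(sched, cp, lc, mode = "expected")
  if (!attr(traj, "feasible")) {
    stop("internal error: optimizer produced an infeasible schedule",
         call. = FALSE)
  }
  new_forage_policy(sched, traj, method, integer, cp, lc)
}

#' First step at which the whole forager pool is on complex flowers
#'
#' @param x A `forage_policy` or `forage_trajectory`.
#' @param tol Foragers-on-simple below this count as zero (expected-value
#'   dynamics use fractional bees).
#' @return The 0-based time step, or `NA_integer_` if the pool is never
#'   fully on complex flowers (e.g. under mortality, where naive
#'   replacements keep joining the simple pool).
#' @export
all_complex_step <- function(x, tol = 1e-9) {
  traj <- if (inherits(x, "forage_policy")) x$trajectory else x
  stopifnot(inherits(traj, "forage_trajectory"))
  idx <- which(traj$n_simple <= tol)
  if (length(idx) == 0) NA_integer_ else as.integer(traj$t[idx[1]])
}

#' Exhaustive-enumeration oracle for tiny colonies
#'
#' Finds the globally optimal per-step, per-experience-level allocation —
#' *not* restricted to permanent switching — by exact forward dynamic
#' programming over experience multisets. Because cumulative net intake
#' equals the gain in stores, two histories reaching the same experience
#' multiset at the same step are comparable by stores alone, and keeping
#' the maximum-stores history per state is lossless; every reachable
#' allocation path is thereby accounted for. Used to validate that the
#' permanent-switch policy class (and the greedy solver) attain the
#' unrestricted optimum.
#'
#' @param cp,lc Parameter objects. Requires `N_f <= 3`, `T <= 6` and
#'   `survival = 1` (deterministic dynamics); larger instances error.
#' @return A `forage_policy` (method `"bruteforce"`) whose trajectory
#'   replays the optimal allocation path; `schedule$m` reports the naive
#'   foragers newly sent to complex flowers at each step.
#' @export
bruteforce_oracle <- function(cp, lc) {
  stopifnot(inherits(cp, "colony_params"), inherits(lc, "learning_params"))
  if (cp$N_f > 3 || cp$T > 6 || cp$survival < 1) {
    stop("bruteforce_oracle requires N_f <= 3, T <= 6 and survival = 1",
         call. = FALSE)
  }
  check_feasible(cp, lc)
  T <- cp$T
  skey <- function(ev) paste(sort(ev, decreasing = TRUE), collapse = ",")
  # states[[key]] = list(B, parent_key, alloc) per layer
  layer <- list()
  layer[[skey(rep(0, cp$N_f))]] <- list(B = cp$initial_stores,
                                        parent = NA, alloc = NULL)
  layers <- vector("list", T + 1)
  layers[[1]] <- layer
  for (t in 1:T) {
    nxt <- list()
    for (k in names(layer)) {
      ev <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
      B <- layer[[k]]$B
      tab <- table(ev)
      lv <- as.integer(names(tab))
      cnt <- as.integer(tab)
      combs <- expand.grid(lapply(cnt, function(n) 0:n))
      for (i in seq_len(nrow(combs))) {
        acls <- as.integer(combs[i, ])
        intake <- sum((cnt - acls) * lc$s) +
          sum(acls * complex_reward(lv, lc))
        B2 <- B + intake - cp$N * cp$q
        if (B2 < -1e-9) next
        ev2 <- c(rep(lv, cnt - acls), rep(lv + 1, acls))
        k2 <- skey(ev2)
        if (is.null(nxt[[k2]]) || B2 > nxt[[k2]]$B) {
          nxt[[k2]] <- list(B = B2, parent = k,
                            alloc = list(levels = lv, complex = acls))
        }
      }
    }
    if (length(nxt) == 0) {
      stop("no feasible allocation path exists for this configuration",
           call. = FALSE)
    }
    layer <- nxt
    layers[[t + 1]] <- layer
  }
  best_key <- names(layer)[which.max(vapply(layer, function(s) s$B, numeric(1)))]
  # walk parents back to recover the allocation sequence
  allocs <- vector("list", T)
  k <- best_key
  for (t in T:1) {
    st <- layers[[t + 1]][[k]]
    allocs[[t]] <- st$alloc
    k <- st$parent
  }
  # replay through the generic dynamics to build the trajectory
  state <- colony_state(cp)
  rows <- vector("list", T)
  cum <- 0
  for (t in 1:T) {
    al <- allocs[[t]]
    a <- numeric(length(state$h))
    # map class allocations onto the histogram (classes are exact here)
    a[al$levels + 1] <- al$complex
    m_t <- a[1]
    cum <- cum + m_t
    n_complex <- sum(a)
    n_simple <- sum(state$h) - n_complex
    mean_exp <- sum(state$h * (seq_along(state$h) - 1)) / sum(state$h)
    state <- advance_colony(state, a, cp, lc, mode = "expected")
    rows[[t]] <- c(t = t - 1, new_switchers = m_t, n_complex = n_complex,
                   n_simple = n_simple, cum_switched = cum,
                   intake = attr(state, "intake"), stores = state$B,
                   mean_experience = mean_exp)
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  objective <- sum(out$intake) - T * cp$N * cp$q
  traj <- structure(
    out, class = c("forage_trajectory", class(out)),
    feasible = TRUE, objective = objective, mode = "expected",
    colony = cp, learning = lc
  )
  new_forage_policy(out$new_switchers, traj, "bruteforce", TRUE, cp, lc)
}

#' @export
print.forage_policy <- function(x, ...) {
  cat(sprintf("Forager switch policy (%s method)\n", x$method))
  cat(sprintf("  objective (total net intake): %.4f\n", x$objective))
  first <- which(x$schedule$m > 0)
  cat(sprintf("  first switch at step %s; all foragers on complex at step %s\n",
              if (length(first)) x$schedule$t[first[1]] else "never",
              ifelse(is.na(x$all_complex_step), "never", x$all_complex_step)))
  cat(sprintf("  total ever switched: %.4g of %g foragers\n",
              sum(x$schedule$m), x$colony$N_f))
  invisible(x)
}

#' @describeIn optimize_foraging Per-step trajectory of a fitted policy as
#'   a tibble.
#' @param x A `forage_policy`.
#' @param ... Unused.
#' @method tidy forage_policy
#' @export
tidy.forage_policy <- function(x, ...) {
  tibble::as_tibble(x$trajectory)
}

#' @describeIn optimize_foraging One-row summary of a fitted policy.
#' @method glance forage_policy
#' @export
glance.forage_policy <- function(x, ...) {
  tr <- x$trajectory
  first <- which(x$schedule$m > 0)
  tibble::tibble(
    method = x$method,
    objective = x$objective,
    all_complex_step = x$all_complex_step,
    first_switch_step = if (length(first)) as.integer(x$schedule$t[first[1]]) else NA_integer_,
    total_switched = sum(x$schedule$m),
    complex_bee_steps = sum(tr$n_complex),
    feasible = attr(tr, "feasible")
  )
}

#' @describeIn optimize_foraging Plot foragers on each flower type over
#'   time.
#' @param object A `forage_policy`.
#' @method autoplot forage_policy
#' @export
autoplot.forage_policy <- function(object, ...) {
  autoplot(object$trajectory, ...)
}

#' @export
autoplot.forage_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("n_complex", "n_simple"),
                        names_to = "flower_type", values_to = "foragers") |>
    dplyr::mutate(flower_type = dplyr::recode(.data$flower_type,
                                              n_complex = "complex",
                                              n_simple = "simple"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$foragers,
                                   colour = .data$flower_type)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time step", y = "foragers", colour = "flower type") +
    ggplot2::theme_minimal()
}
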