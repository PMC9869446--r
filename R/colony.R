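#' Initial colony state
#'
#' The colony state tracks the time step, the experience histogram of the
#' forager pool (counts of foragers at each experience level `0..T`,
#' fractional in expected-value mode), and the current nectar stores. All
#' foragers start naive, with stores at `initial_stores`.
#'
#' @param cp A [colony_params()] object.
#' @return An object of class `colony_state`: a list with `t` (current
#'   step), `h` (experience histogram, index 1 = experience 0) and `B`
#'   (stores).
#' @export
colony_state <- function(cp) {
  stopifnot(inherits(cp, "colony_params"))
  h <- numeric(cp$T + 1)
  h[1] <- cp$N_f
  structure(list(t = 0L, h = h, B = cp$initial_stores), class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  occ <- which(x$h > 0) - 1
  cat(sprintf("Colony state at t = %d: %g foragers, stores = %.4g\n",
              x$t, sum(x$h), x$B))
  cat("  experience levels in use:",
      paste(sprintf("%d (%g)", occ, x$h[occ + 1]), collapse = ", "), "\n")
  invisible(x)
}

# pad/validate an allocation vector against a histogram
check_allocation <- function(state, a, tol = 1e-9) {
  if (length(a) > length(state$h)) {
    stop("allocation longer than the experience histogram", call. = FALSE)
  }
  a <- c(a, numeric(length(state$h) - length(a)))
  if (any(a < -tol) || any(a > state$h + tol)) {
    stop("allocation must satisfy 0 <= a_e <= h_e for every experience level",
         call. = FALSE)
  }
  pmin(pmax(a, 0), state$h)
}

#' Gross colony intake for one step
#'
#' Given an allocation of foragers to complex flowers (by experience
#' level), the colony's gross intake for the step is
#' `(N_f - sum(a)) * s + sum(a_e * c(e))`: everyone not sent to complex
#' flowers forages simple.
#'
#' @param state A [colony_state()] object.
#' @param a Numeric vector: `a[i]` foragers of experience `i - 1` assigned
#'   to complex flowers (shorter vectors are zero-padded).
#' @param lc A [learning_params()] object.
#' @return Gross intake in reward units.
#' @export
#' @examples
#' cp <- colony_params(); lc <- learning_params()
#' step_intake(colony_state(cp), 50, lc)  # 50 simple + 50 naive complex
step_intake <- function(state, a, lc) {
  stopifnot(inherits(state, "colony_state"), inherits(lc, "learning_params"))
  a <- check_allocation(state, a)
  n_simple <- sum(state$h) - sum(a)
  e <- seq_along(a) - 1
  used <- a > 0
  n_simple * lc$s + sum(a[used] * complex_reward(e[used], lc))
}

#' Advance the colony state by one time step
#'
#' Applies, in order: foraging intake, consumption by all `N` bees,
#' mortality with immediate naive replacement, and the experience increment
#' for the bees that foraged on complex flowers. Experience is never
#' forgotten: a bee assigned to simple flowers keeps its level, and the only
#' downward movement of histogram mass is death-replacement into level 0.
#'
#' In `"expected"` mode each histogram bin loses the deterministic fraction
#' `mu = 1 - survival^(1/T)` to level 0 (fractional bees); in
#' `"stochastic"` mode deaths are independent binomial draws per bin (the
#' histogram and allocation must then be integer-valued).
#'
#' @param state A [colony_state()] object.
#' @param a Allocation vector as in [step_intake()].
#' @param cp,lc Parameter objects.
#' @param mode `"expected"` (default) or `"stochastic"`.
#' @return A new `colony_state` with attributes `intake` (gross intake of
#'   the step) and `feasible` (`FALSE` when the updated stores fell below
#'   zero; the state is still returned so callers can prune or raise).
#' @export
advance_colony <- function(state, a, cp, lc, mode = c("expected", "stochastic")) {
  stopifnot(inherits(state, "colony_state"), inherits(cp, "colony_params"),
            inherits(lc, "learning_params"))
  mode <- match.arg(mode)
  if (state$t >= cp$T) stop("state is already at the horizon", call. = FALSE)
  a <- check_allocation(state, a)
  h <- state$h
  intake <- step_intake(state, a, lc)
  B <- state$B + intake - cp$N * cp$q
  feasible <- B >= -1e-6

  mu <- per_step_mortality(cp)
  n_lvl <- length(h)
  simple_h <- h - a
  if (mode == "expected") {
    dead <- mu * sum(h)
    a_surv <- a * (1 - mu)
    s_surv <- simple_h * (1 - mu)
  } else {
    if (any(abs(h - round(h)) > 1e-9) || any(abs(a - round(a)) > 1e-9)) {
      stop("stochastic mode requires integer-valued histogram and allocation",
           call. = FALSE)
    }
    d_a <- stats::rbinom(n_lvl, round(a), mu)
    d_s <- stats::rbinom(n_lvl, round(simple_h), mu)
    dead <- sum(d_a) + sum(d_s)
    a_surv <- round(a) - d_a
    s_surv <- round(simple_h) - d_s
  }
  h2 <- s_surv
  h2[1] <- h2[1] + dead
  # complex survivors gain one experience level (capped at T, never reached
  # in practice since experience <= t < T)
  shifted <- c(0, a_surv[-n_lvl])
  shifted[n_lvl] <- shifted[n_lvl] + a_surv[n_lvl]
  h2 <- h2 + shifted

  structure(
    list(t = state$t + 1L, h = h2, B = B),
    class = "colony_state", intake = intake, feasible = feasible
  )
}

#' Roll a switch schedule forward through the colony dynamics
#'
#' A switch schedule gives, for each step `t = 0..T-1`, the number of
#' foragers `m_t` newly and *permanently* reassigned from simple to complex
#' flowers. Once switched, a bee forages complex for the rest of its life;
#' when it dies its naive replacement joins the simple pool (and can only
#' move to complex via a later `m_t`). Within a step the order of events is
#' the one documented in [advance_colony()].
#'
#' @param schedule Numeric vector of length `cp$T`, `m_t >= 0`. Entries may
#'   be fractional in expected mode. A requested `m_t` larger than the
#'   current simple pool is clamped to the pool (the realized value is
#'   reported in the trajectory).
#' @param cp,lc Parameter objects.
#' @param mode `"expected"` (deterministic, fractional bees) or
#'   `"stochastic"` (binomial mortality; requires integer schedule).
#' @param seed Optional integer seed used for stochastic mortality draws.
#' @return A tibble of class `forage_trajectory` with one row per step:
#'   `t` (0-based), `new_switchers` (realized `m_t`), `n_complex`,
#'   `n_simple` (forager counts at allocation time), `cum_switched`
#'   (ever-switched total, not reduced by deaths), `intake`, `stores`
#'   (balance at the end of the step) and `mean_experience` (over the
#'   forager pool at allocation time). Attributes: `feasible` (stores
#'   `>= 0` at every step, to 1e-6), `objective` (total net intake
#'   `sum(intake) - T*N*q`), and the input parameters.
#' @seealso [optimize_foraging()], [schedule_value()]
#' @export
#' @examples
#' cp <- colony_params(); lc <- learning_params()
#' traj <- simulate_schedule(c(50, numeric(cp$T - 1)), cp, lc)
#' attr(traj, "feasible")
simulate_schedule <- function(schedule, cp, lc,
                              mode = c("expected", "stochastic"), seed = NULL) {
  stopifnot(inherits(cp, "colony_params"), inherits(lc, "learning_params"))
  mode <- match.arg(mode)
  if (length(schedule) != cp$T) {
    stop("`schedule` must have length T = ", cp$T, call. = FALSE)
  }
  if (any(!is.finite(schedule)) || any(schedule < 0)) {
    stop("`schedule` entries must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  state <- colony_state(cp)
  T <- cp$T
  rows <- vector("list", T)
  feasible <- TRUE
  cum <- 0
  for (t in 0:(T - 1)) {
    # previously switched bees all have experience >= 1 (they forage complex
    # every step); replacements sit naive in the simple pool
    a <- state$h
    a[1] <- 0
    m_t <- min(schedule[t + 1], state$h[1])
    if (mode == "stochastic") m_t <- floor(m_t)
    a[1] <- m_t
    cum <- cum + m_t
    n_complex <- sum(a)
    n_simple <- sum(state$h) - n_complex
    mean_exp <- sum(state$h * (seq_along(state$h) - 1)) / sum(state$h)
    state <- advance_colony(state, a, cp, lc, mode = mode)
    feasible <- feasible && attr(state, "feasible")
    rows[[t + 1]] <- c(t = t, new_switchers = m_t, n_complex = n_complex,
                       n_simple = n_simple, cum_switched = cum,
                       intake = attr(state, "intake"), stores = state$B,
                       mean_experience = mean_exp)
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  objective <- sum(out$intake) - T * cp$N * cp$q
  structure(
    out,
    class = c("forage_trajectory", class(out)),
    feasible = feasible, objective = objective, mode = mode,
    colony = cp, learning = lc
  )
}
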