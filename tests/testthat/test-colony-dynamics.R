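test_that("step intake matches hand-computed values", {
  cp <- default_cp(); lc <- default_lc()
  st <- colony_state(cp)
  # all 100 foragers on simple flowers
  expect_equal(step_intake(st, numeric(0), lc), 5000)
  # 50 simple + 50 naive complex: 2500 + 50 * c(0)
  expect_equal(step_intake(st, 50, lc), 3000.22698934351, tolerance = 1e-10)
  expect_equal(step_intake(st, 50, lc), 2500 + 50 * ref_curve(0))
  # allocation beyond the histogram is rejected
  expect_error(step_intake(st, 101, lc), "0 <= a_e <= h_e")
  expect_error(step_intake(st, c(0, 1), lc), "0 <= a_e <= h_e")
})

test_that("advancing applies intake, consumption, mortality, then experience", {
  cp <- default_cp(); lc <- default_lc()
  st <- colony_state(cp)
  # all-simple step from B = 0: B' = 5000 - 3000 = 2000, histogram untouched
  st2 <- advance_colony(st, numeric(0), cp, lc)
  expect_equal(st2$B, 2000)
  expect_equal(st2$h[1], 100)
  expect_true(attr(st2, "feasible"))

  # with survival = 1, complex-assigned bees move up one experience level
  st3 <- advance_colony(st, 30, cp, lc)
  expect_equal(st3$h[1], 70)
  expect_equal(st3$h[2], 30)
  expect_equal(sum(st3$h), cp$N_f)

  # per-step retention under survival = 0.5 over T = 100 (closed form)
  cp2 <- default_cp(survival = 0.5)
  expect_equal(1 - per_step_mortality(cp2), 0.993092495437036, tolerance = 1e-12)
  st4 <- advance_colony(colony_state(cp2), 40, cp2, lc)
  keep <- 0.5^(1 / 100)
  expect_equal(st4$h[2], 40 * keep)
  # all lost mass is replaced at experience 0
  expect_equal(sum(st4$h), cp2$N_f)
})

test_that("trajectory bookkeeping conserves stores and forager mass", {
  cp <- default_cp(T = 40, survival = 0.8); lc <- default_lc()
  set.seed(21)
  for (rep in 1:5) {
    sched <- pmin(rpois(cp$T, 2), 5)
    traj <- simulate_schedule(sched, cp, lc)
    # B_{t+1} - B_t = intake_t - N*q exactly
    expect_equal(diff(c(cp$initial_stores, traj$stores)),
                 traj$intake - cp$N * cp$q, tolerance = 1e-9)
    # forager mass is constant
    expect_equal(traj$n_simple + traj$n_complex, rep(cp$N_f, cp$T),
                 tolerance = 1e-9)
  }
})

test_that("experience is never forgotten", {
  cp <- default_cp(T = 15, survival = 0.7); lc <- default_lc()
  st <- colony_state(cp)
  sched <- c(10, 5, 0, 3, rep(0, 11))
  for (t in 1:15) {
    a <- st$h; a[1] <- min(sched[t], a[1])
    st_new <- advance_colony(st, a, cp, lc)
    # mass at experience >= e never drops except into bin 0 (death-replacement):
    # above any level e >= 1, the outflow can only be deaths
    for (e in 1:(t)) {
      upper_before <- sum(st$h[(e + 1):length(st$h)])
      upper_after <- sum(st_new$h[(e + 1):length(st_new$h)])
      mu <- per_step_mortality(cp)
      expect_gte(upper_after + 1e-9, upper_before * (1 - mu))
    }
    st <- st_new
  }
})

test_that("all-zero and boundary schedules reproduce the arithmetic", {
  cp <- default_cp(); lc <- default_lc()
  zero <- numeric(cp$T)
  traj <- simulate_schedule(zero, cp, lc)
  expect_true(attr(traj, "feasible"))
  expect_equal(traj$stores[cp$T], 100 * 2000)   # T * (5000 - 3000)
  expect_equal(attr(traj, "objective"), 200000)

  # 51 naive switchers at step 0 bankrupt the colony immediately
  s51 <- c(51, numeric(cp$T - 1))
  t51 <- simulate_schedule(s51, cp, lc)
  expect_false(attr(t51, "feasible"))
  expect_equal(t51$stores[1], 49 * 50 + 51 * ref_curve(0) - 3000,
               tolerance = 1e-9)
  expect_lt(t51$stores[1], 0)

  # 50 switchers just clear the budget
  s50 <- c(50, numeric(cp$T - 1))
  t50 <- simulate_schedule(s50, cp, lc)
  expect_true(t50$stores[1] >= 0)
  expect_equal(t50$stores[1], 0.226989343512287, tolerance = 1e-9)
})

test_that("stochastic mode is seed-reproducible and matches expected mode in mean", {
  cp <- default_cp(N = 30, T = 10, q = 20, survival = 0.6)
  lc <- default_lc()
  sched <- c(10, rep(0, 4), 5, rep(0, 4))

  t1 <- simulate_schedule(sched, cp, lc, mode = "stochastic", seed = 99)
  t2 <- simulate_schedule(sched, cp, lc, mode = "stochastic", seed = 99)
  expect_identical(t1$stores, t2$stores)
  # integer bees throughout in stochastic mode
  expect_true(all(t1$n_complex == round(t1$n_complex)))

  exp_traj <- simulate_schedule(sched, cp, lc, mode = "expected")
  set.seed(123)
  finals <- replicate(1000, {
    tr <- simulate_schedule(sched, cp, lc, mode = "stochastic")
    tr$stores[cp$T]
  })
  mc_se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - exp_traj$stores[cp$T]), 4 * mc_se + 1e-9)
})

test_that("stochastic mode refuses fractional histograms", {
  cp <- default_cp(N = 10, T = 5, q = 10, survival = 0.5)
  lc <- default_lc()
  st <- colony_state(cp)
  st$h[1] <- 9.5; st$h[2] <- 0.5
  expect_error(advance_colony(st, numeric(0), cp, lc, mode = "stochastic"),
               "integer")
})

test_that("infeasible configurations are rejected up front", {
  lc <- default_lc()
  expect_error(check_feasible(default_cp(r = 0.5), lc), "infeasible")
  expect_silent(check_feasible(default_cp(r = 0.3), lc))
  expect_error(colony_params(N = 10, r = 0.99), "N_f")
  expect_error(colony_params(r = 1), "`r` must be")
  expect_error(colony_params(T = 0), "`T` must be")
  expect_error(colony_params(survival = 0), "`survival`")
})
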