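test_that("schedule value matches closed-form roll-ups", {
  cp <- default_cp(); lc <- default_lc()
  expect_equal(schedule_value(numeric(cp$T), cp, lc), 200000)
  expect_identical(schedule_value(c(51, numeric(cp$T - 1)), cp, lc), -Inf)

  # everyone switches at step 0 in a colony with no consumption:
  # objective = sum_t N_f * c(t)
  cp0 <- colony_params(N = 4, q = 1e-9, T = 12, initial_stores = 1)
  expect_equal(
    schedule_value(c(4, numeric(11)), cp0, lc),
    sum(4 * ref_curve(0:11)) - 12 * 4 * 1e-9,
    tolerance = 1e-9
  )
})

test_that("defaults send half the foragers to complex flowers at step 0", {
  sol <- optimize_foraging(default_cp(), default_lc())
  expect_equal(sol$schedule$m[1], 50)
  # the budget bound is sharp: 50 switchers keep stores non-negative,
  # 51 do not
  expect_gte(50 * 50 + 50 * ref_curve(0) - 3000, 0)
  expect_lt(49 * 50 + 51 * ref_curve(0) - 3000, 0)
})

test_that("the whole pool is on complex flowers at step 22, for any colony size", {
  lc <- default_lc()
  steps <- vapply(c(50, 100, 200), function(N) {
    sol <- optimize_foraging(default_cp(N = N), lc)
    sol$all_complex_step
  }, integer(1))
  expect_identical(steps, rep(22L, 3))
})

test_that("a short horizon keeps the colony split roughly in half, never all-complex", {
  sol <- optimize_foraging(default_cp(T = 50), default_lc())
  expect_identical(sol$all_complex_step, NA_integer_)
  share <- sol$trajectory$n_complex / default_cp(T = 50)$N_f
  expect_gte(mean(share >= 0.4 & share <= 0.6), 0.8)
  expect_true(all(share < 1))
})

test_that("greedy equals the exhaustive oracle on random small instances", {
  set.seed(2024)
  for (i in 1:50) {
    inst <- rand_small_instance()
    g <- optimize_foraging(inst$cp, inst$lc, method = "greedy", integer = TRUE)
    o <- bruteforce_oracle(inst$cp, inst$lc)
    expect_equal(g$objective, o$objective, tolerance = 1e-6)
    # returned trajectories stay solvent
    expect_true(all(g$trajectory$stores >= -1e-6))
    expect_true(all(o$trajectory$stores >= -1e-6))
  }
})

test_that("the LP relaxation equals continuous greedy on random small instances", {
  set.seed(515)
  for (i in 1:50) {
    inst <- rand_small_instance()
    g <- optimize_foraging(inst$cp, inst$lc, method = "greedy", integer = FALSE)
    l <- optimize_foraging(inst$cp, inst$lc, method = "lp", integer = FALSE)
    expect_equal(l$objective, g$objective, tolerance = 1e-6)
  }
})

test_that("the DP oracle agrees with a plain recursive enumeration", {
  set.seed(88)
  for (i in 1:4) {
    inst <- rand_small_instance()
    o <- bruteforce_oracle(inst$cp, inst$lc)
    expect_equal(o$objective, dfs_enumerate(inst$cp, inst$lc), tolerance = 1e-9)
  }
})

test_that("oracle rejects large instances; tiny degenerate cases solve in closed form", {
  expect_error(bruteforce_oracle(default_cp(), default_lc()), "N_f <= 3")

  # complex flowers dominated: tiny K keeps c below s at all experience
  cp <- colony_params(N = 1, q = 10, T = 3)
  lc_dom <- suppressWarnings(
    learning_params(K = 1e-6, m = 10, alpha = 0.45, beta = 10, s = 50)
  )
  o <- bruteforce_oracle(cp, lc_dom)
  expect_equal(o$objective, 3 * (50 - 10), tolerance = 1e-9)
  expect_equal(o$trajectory$n_complex, rep(0, 3))

  # simple flowers dominated: m > s, no consumption pressure
  cp2 <- colony_params(N = 1, q = 1e-9, T = 3)
  lc_dom2 <- suppressWarnings(
    learning_params(K = 100, m = 60, alpha = 0.45, beta = 10, s = 50)
  )
  o2 <- bruteforce_oracle(cp2, lc_dom2)
  expect_equal(o2$trajectory$n_complex, rep(1, 3))
  expect_identical(all_complex_step(o2), 0L)
})

test_that("optimal policies beat the all-simple baseline and stay feasible", {
  set.seed(911)
  for (i in 1:10) {
    inst <- rand_small_instance()
    sol <- optimize_foraging(inst$cp, inst$lc)
    base <- schedule_value(numeric(inst$cp$T), inst$cp, inst$lc)
    expect_gte(sol$objective + 1e-9, base)
    expect_true(attr(sol$trajectory, "feasible"))
  }
  sol <- optimize_foraging(default_cp(), default_lc())
  expect_gte(sol$objective, 200000)
  # objective is recomputable from the trajectory
  expect_equal(sol$objective,
               sum(sol$trajectory$intake) - 100 * 100 * 30, tolerance = 1e-6)
})

test_that("integer LP tracks greedy within one bee per step at full scale", {
  cp <- default_cp(); lc <- default_lc()
  g <- optimize_foraging(cp, lc, method = "greedy")
  l <- optimize_foraging(cp, lc, method = "lp")
  expect_true(attr(l$trajectory, "feasible"))
  expect_lte(max(abs(cumsum(l$schedule$m) - cumsum(g$schedule$m))), 1)
  expect_lt(abs(l$objective - g$objective) / g$objective, 0.005)
  # continuous agreement is exact
  gc <- optimize_foraging(cp, lc, method = "greedy", integer = FALSE)
  lcont <- optimize_foraging(cp, lc, method = "lp", integer = FALSE)
  expect_equal(lcont$objective, gc$objective, tolerance = 1e-6)
})

test_that("all_complex_step reads the trajectory correctly", {
  cp <- default_cp(); lc <- default_lc()
  expect_identical(all_complex_step(simulate_schedule(numeric(cp$T), cp, lc)),
                   NA_integer_)
  full <- c(cp$N_f, numeric(cp$T - 1))
  cp_rich <- default_cp(initial_stores = 1e5)
  expect_identical(all_complex_step(simulate_schedule(full, cp_rich, lc)), 0L)
})

test_that("a single-forager colony is optimized in fractions of foraging time", {
  cp <- colony_params(N = 1, q = 20, T = 100)
  sol <- optimize_foraging(cp, default_lc())
  expect_false(sol$integer)
  m <- sol$schedule$m
  expect_true(any(m > 0 & m < 1))  # genuinely fractional switching
  expect_true(all(sol$trajectory$stores >= -1e-6))
  expect_lte(sum(m), 1 + 1e-9)
})

test_that("policy accessors are consistent", {
  sol <- optimize_foraging(default_cp(), default_lc())
  td <- tidy(sol)
  gl <- glance(sol)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 100L)
  expect_identical(gl$all_complex_step, 22L)
  expect_equal(gl$total_switched, 100)
  expect_s3_class(autoplot(sol), "ggplot")
})
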