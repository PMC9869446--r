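# shared fixtures for the foraging-model tests

default_lc <- function(...) learning_params(...)
default_cp <- function(...) colony_params(...)

# a random feasible small instance for oracle comparisons (N_f <= 3, T <= 6,
# survival = 1, zero initial stores)
rand_small_instance <- function() {
  N <- sample(1:3, 1)
  T <- sample(3:6, 1)
  K <- runif(1, 20, 150)
  m <- runif(1, 0, 20)
  alpha <- runif(1, 0.3, 1.2)
  beta <- runif(1, 0.5, 5)
  s <- runif(1, m + 1, m + K - 1)
  q <- runif(1, 0.1, s)  # all-simple allocation stays solvent
  list(
    cp = colony_params(N = N, r = 0, q = q, T = T, survival = 1),
    lc = learning_params(K = K, m = m, alpha = alpha, beta = beta, s = s)
  )
}

# independent plain-recursion enumerator over every per-step, per-experience
# allocation (no dominance pruning); used to cross-check the DP oracle
dfs_enumerate <- function(cp, lc) {
  best <- -Inf
  recurse <- function(ev, B, t) {
    if (t == cp$T) {
      best <<- max(best, B - cp$initial_stores)
      return(invisible())
    }
    tab <- table(ev)
    lv <- as.integer(names(tab))
    cnt <- as.integer(tab)
    combs <- expand.grid(lapply(cnt, function(n) 0:n))
    for (i in seq_len(nrow(combs))) {
      acls <- as.integer(combs[i, ])
      intake <- sum((cnt - acls) * lc$s) + sum(acls * complex_reward(lv, lc))
      B2 <- B + intake - cp$N * cp$q
      if (B2 < -1e-9) next
      recurse(c(rep(lv, cnt - acls), rep(lv + 1, acls)), B2, t + 1)
    }
  }
  recurse(rep(0L, cp$N_f), cp$initial_stores, 0L)
  best
}

# reference logistic curve written out directly (independent of the package's
# vectorized implementation)
ref_curve <- function(e, K = 100, m = 10, alpha = 0.45, beta = 10) {
  m + K / (1 + exp(-(alpha * e - beta)))
}
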