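#' Learning-curve parameters
#'
#' Bundle the parameters of the logistic learning curve for complex flowers
#' together with the (flat) per-step reward on simple flowers. The per-step
#' reward of a bee with experience `e` on complex flowers is
#' `m + K / (1 + exp(-(alpha * e - beta)))`: it starts near `m` for a naive
#' bee and saturates at `K + m` once learning is complete. `beta / alpha` is
#' the experience at the inflection point, so larger `beta` means a slower
#' learner.
#'
#' @param K Maximum learning progress, in reward units. The asymptotic
#'   complex-flower reward is `K + m`.
#' @param m Minimal complex-flower reward without any learning, reward units.
#' @param alpha Shape (steepness) parameter of the logistic, per time step.
#' @param beta Position parameter; the inflection sits at experience
#'   `beta / alpha`. Interpreted as the (inverse) learning rate: higher
#'   `beta` = slower learning.
#' @param s Reward per bee per time step on simple flowers, reward units.
#'
#' @details The simple/complex trade-off is only meaningful when
#'   `m < s < K + m`: a naive bee should do worse on complex flowers than on
#'   simple ones, and a fully trained bee better. Values outside that range
#'   are accepted (the curve itself is still well defined) but trigger a
#'   warning, because every downstream optimization degenerates to a
#'   single-flower-type policy.
#'
#' @return An object of class `learning_params` (a named list).
#' @seealso [complex_reward()], [simple_reward()], [breakeven_experience()]
#' @export
#' @examples
#' lc <- learning_params()
#' complex_reward(c(0, 22, 50), lc)
learning_params <- function(K = 100, m = 10, alpha = 0.45, beta = 10, s = 50) {
  vals <- c(K = K, m = m, alpha = alpha, beta = beta, s = s)
  if (!all(is.finite(vals))) {
    stop("learning curve parameters must all be finite numbers", call. = FALSE)
  }
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (s <= 0) stop("`s` must be > 0", call. = FALSE)
  if (!(m < s && s < K + m)) {
    warning(
      "degenerate trade-off: `s` should satisfy m < s < K + m so that ",
      "complex flowers start worse and end better than simple ones ",
      "(got m = ", m, ", s = ", s, ", K + m = ", K + m, ")",
      call. = FALSE
    )
  }
  structure(
    list(K = K, m = m, alpha = alpha, beta = beta, s = s),
    class = "learning_params"
  )
}

#' @export
print.learning_params <- function(x, ...) {
  cat("Logistic learning curve: c(e) = m + K / (1 + exp(-(alpha*e - beta)))\n")
  cat(sprintf(
    "  K = %g, m = %g, alpha = %g, beta = %g (inflection at e = %.4g)\n",
    x$K, x$m, x$alpha, x$beta, x$beta / x$alpha
  ))
  cat(sprintf("  simple-flower reward s = %g\n", x$s))
  invisible(x)
}

#' Colony-level parameters
#'
#' @param N Total number of bees in the colony (foragers + sedentary).
#' @param r Proportion of bees that remain sedentary in the hive, in
#'   `[0, 1)`. The forager count is `N_f = N - round(N * r)` (ties rounded
#'   half away from zero).
#' @param q Per-capita nectar consumption per time step, reward units. Every
#'   bee consumes, sedentary ones included.
#' @param T Time horizon: number of time steps until colony activity ends.
#' @param survival Probability that an individual bee is still alive at the
#'   horizon, in `(0, 1]`. Converted internally to a constant per-step
#'   mortality hazard `mu = 1 - survival^(1/T)`; a dead bee is replaced
#'   immediately by a naive individual.
#' @param initial_stores Nectar stores at the start of step 0, reward
#'   units, `>= 0`. Defaults to 0, which makes the step-0 energy budget the
#'   binding constraint on early switching.
#'
#' @return An object of class `colony_params` (a named list, with the
#'   derived forager count stored as `N_f`).
#' @seealso [optimize_foraging()], [simulate_schedule()]
#' @export
#' @examples
#' cp <- colony_params()
#' cp$N_f
colony_params <- function(N = 100, r = 0, q = 30, T = 100, survival = 1,
                          initial_stores = 0) {
  vals <- c(N = N, r = r, q = q, T = T, survival = survival,
            initial_stores = initial_stores)
  if (!all(is.finite(vals))) {
    stop("colony parameters must all be finite numbers", call. = FALSE)
  }
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  if (r < 0 || r >= 1) stop("`r` must be in [0, 1)", call. = FALSE)
  if (q <= 0) stop("`q` must be > 0", call. = FALSE)
  if (T < 1 || T != round(T)) stop("`T` must be a positive integer", call. = FALSE)
  if (survival <= 0 || survival > 1) stop("`survival` must be in (0, 1]", call. = FALSE)
  if (initial_stores < 0) stop("`initial_stores` must be >= 0", call. = FALSE)
  N_f <- N - round_half_away(N * r)
  if (N_f < 1) {
    stop("forager count N_f = N - round(N*r) must be >= 1 (got ", N_f, ")",
         call. = FALSE)
  }
  structure(
    list(N = N, r = r, q = q, T = as.integer(T), survival = survival,
         initial_stores = initial_stores, N_f = N_f),
    class = "colony_params"
  )
}

#' @export
print.colony_params <- function(x, ...) {
  cat(sprintf(
    "Colony: N = %g bees (%g foragers, r = %g sedentary), horizon T = %d\n",
    x$N, x$N_f, x$r, x$T
  ))
  cat(sprintf(
    "  consumption q = %g per bee per step, survival to horizon = %g, initial stores = %g\n",
    x$q, x$survival, x$initial_stores
  ))
  invisible(x)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-step mortality hazard
#'
#' Converts the survival-to-horizon probability into the constant per-step
#' death probability `mu = 1 - survival^(1/T)`, so that surviving every one
#' of the `T` steps happens with probability exactly `survival`.
#'
#' @param cp A [colony_params()] object.
#' @return A single probability in `[0, 1)`.
#' @export
#' @examples
#' per_step_mortality(colony_params(survival = 0.5, T = 100))
per_step_mortality <- function(cp) {
  stopifnot(inherits(cp, "colony_params"))
  1 - cp$survival^(1 / cp$T)
}

#' Check that a configuration can sustain the colony at all
#'
#' A colony starting from zero stores can only stay solvent if putting every
#' forager on simple flowers at least covers consumption:
#' `N_f * s >= N * q`. Violations are a configuration error: no allocation
#' policy keeps the nectar balance non-negative.
#'
#' @param cp A [colony_params()] object.
#' @param lc A [learning_params()] object.
#' @return Invisibly `TRUE`; errors if the configuration is infeasible.
#' @export
check_feasible <- function(cp, lc) {
  stopifnot(inherits(cp, "colony_params"), inherits(lc, "learning_params"))
  if (cp$N_f * lc$s < cp$N * cp$q) {
    stop(
      "infeasible configuration: all-simple intake N_f*s = ", cp$N_f * lc$s,
      " cannot cover consumption N*q = ", cp$N * cp$q,
      " (requires r <= 1 - q/s)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Read model parameters from a YAML or JSON config file
#'
#' The config mirrors the model's standard parameter names:
#' `T, N, K, m, alpha, beta, s, q, r, survival` plus the optional
#' `initial_stores`. Missing entries fall back to the defaults of
#' [colony_params()] and [learning_params()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `colony` ([colony_params()]) and
#'   `learning` ([learning_params()]).
#' @seealso [write_model_config()]
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("T", "N", "K", "m", "alpha", "beta", "s", "q", "r", "survival",
             "initial_stores")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config entries: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  pick <- function(nm) raw[[nm]]
  cp_args <- Filter(Negate(is.null),
                    list(N = pick("N"), r = pick("r"), q = pick("q"),
                         T = pick("T"), survival = pick("survival"),
                         initial_stores = pick("initial_stores")))
  lc_args <- Filter(Negate(is.null),
                    list(K = pick("K"), m = pick("m"), alpha = pick("alpha"),
                         beta = pick("beta"), s = pick("s")))
  list(
    colony = do.call(colony_params, cp_args),
    learning = do.call(learning_params, lc_args)
  )
}

#' Write a provenance echo of the model configuration
#'
#' @param cp A [colony_params()] object.
#' @param lc A [learning_params()] object.
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return The path, invisibly.
#' @export
write_model_config <- function(cp, lc, path) {
  stopifnot(inherits(cp, "colony_params"), inherits(lc, "learning_params"))
  cfg <- list(
    T = cp$T, N = cp$N, K = lc$K, m = lc$m, alpha = lc$alpha, beta = lc$beta,
    s = lc$s, q = cp$q, r = cp$r, survival = cp$survival,
    initial_stores = cp$initial_stores
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
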