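#' Per-step reward on complex flowers
#'
#' Evaluates the logistic learning curve
#' `c(e) = m + K / (1 + exp(-(alpha * e - beta)))` at experience `e`, the
#' number of time steps a bee has already spent foraging on complex flowers.
#' The reward a bee earns during a step is evaluated at its experience at
#' the *start* of that step, so a naive bee's first complex step pays
#' `c(0)`.
#'
#' @param e Experience in time steps; any non-negative numeric vector
#'   (integer in the colony dynamics).
#' @param params A [learning_params()] object.
#' @return Reward units, same length as `e`; strictly increasing in `e` and
#'   bounded in `(m, K + m)`.
#' @export
#' @examples
#' lc <- learning_params()
#' complex_reward(lc$beta / lc$alpha, lc)  # logistic midpoint: m + K/2
complex_reward <- function(e, params) {
  stopifnot(inherits(params, "learning_params"))
  if (length(e) == 0) return(numeric(0))
  if (any(!is.finite(e)) || any(e < 0)) {
    stop("experience `e` must be finite and >= 0", call. = FALSE)
  }
  params$m + params$K / (1 + exp(-(params$alpha * e - params$beta)))
}

#' Per-step reward on simple flowers
#'
#' Simple flowers need no learning: the reward is the constant `s`
#' regardless of a bee's experience.
#'
#' @param params A [learning_params()] object.
#' @return A single number, `params$s`.
#' @export
simple_reward <- function(params) {
  stopifnot(inherits(params, "learning_params"))
  params$s
}

#' Break-even experience on complex flowers
#'
#' The smallest integer experience at which a bee earns strictly more per
#' step on complex flowers than on simple ones, i.e. the least integer `e`
#' with `complex_reward(e) > s`. Computed in closed form from the logistic
#' inverse and then verified by a local scan (guards against boundary
#' rounding).
#'
#' @param params A [learning_params()] object.
#' @return A non-negative integer number of time steps.
#' @export
#' @examples
#' breakeven_experience(learning_params())  # 22 with the default curve
breakeven_experience <- function(params) {
  stopifnot(inherits(params, "learning_params"))
  K <- params$K; m <- params$m; a <- params$alpha; b <- params$beta; s <- params$s
  if (s >= K + m) {
    stop("complex flowers never beat simple ones: s >= K + m", call. = FALSE)
  }
  if (s <= m) return(0L)
  # c(e) > s  <=>  e > (beta - log(K/(s - m) - 1)) / alpha
  x <- (b - log(K / (s - m) - 1)) / a
  e <- max(0L, as.integer(ceiling(x - 1e-9)))
  while (e > 0 && complex_reward(e - 1, params) > s) e <- e - 1L
  while (complex_reward(e, params) <= s) e <- e + 1L
  e
}
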