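#' Heaviside unit step function
#'
#' Threshold convention used throughout the collective-risk dilemma payoffs
#' and success probabilities: `heaviside(x)` is 0 for `x < 0` and 1 otherwise,
#' so `heaviside(0) = 1` (the threshold is met when exactly `M` cooperate).
#' All threshold comparisons in the package route through this function so the
#' convention lives in one place.
#'
#' @param x Integer-valued numeric vector.
#' @return Numeric vector of 0s and 1s.
#' @examples
#' heaviside(c(-1, 0, 5))
#' @export
heaviside <- function(x) {
  as.numeric(x >= 0)
}

#' Expected one-shot CRD payoffs for defectors and cooperators
#'
#' In a group where `j` of the `N` seats cooperate, a defector keeps its full
#' endowment `b` if the threshold `M` is met, and otherwise keeps it only with
#' probability `1 - r`:
#' `pi_D(j) = b * (1 - r + r * heaviside(j - M))`.
#' A cooperator earns the same minus its contribution:
#' `pi_C(j) = pi_D(j) - c * b`. The cooperator's payoff can be negative when
#' the goal is missed under full risk; no clamping is applied.
#'
#' @param j Number of cooperators in the group (vectorized). Must satisfy
#'   `0 <= j <= N` for a defector and `1 <= j <= N` for a cooperator (a
#'   cooperator is itself present in the group).
#' @param model A [crd_model()] (only `N`, `M`, `r`, `b`, `c` are used).
#' @return Numeric vector of payoffs (currency units).
#' @examples
#' m <- crd_model(N = 6, M = 3, r = 0.5)
#' payoff_defector(0:6, m)
#' payoff_cooperator(1:6, m) - payoff_defector(1:6, m)  # constant -c*b
#' @export
payoff_defector <- function(j, model) {
  stopifnot(inherits(model, "crd_model"))
  if (any(j < 0 | j > model$N | j != round(j))) {
    stop("`j` must be an integer count of cooperators in 0..N.")
  }
  model$b * (1 - model$r + model$r * heaviside(j - model$M))
}

#' @rdname payoff_defector
#' @export
payoff_cooperator <- function(j, model) {
  stopifnot(inherits(model, "crd_model"))
  if (any(j < 1 | j > model$N | j != round(j))) {
    stop("`j` must be an integer count of cooperators in 1..N (the focal cooperator is present).")
  }
  model$b * (1 - model$r + model$r * heaviside(j - model$M)) - model$c * model$b
}

#' Expected payoff in a hybrid group
#'
#' The agent block acts all-or-none: with probability `p` all `a` agents in
#' the group cooperate, with probability `1 - p` none do. Given `i` adaptive
#' cooperators in the group (including the focal player when it cooperates),
#' the focal player's expected payoff is the two-point mixture
#' `p * pi_s(i + a) + (1 - p) * pi_s(i)` where `pi_s` is [payoff_cooperator()]
#' or [payoff_defector()]. The caller resolves whether the focal player is
#' counted in `i`; this function does not add the focal player itself.
#'
#' @param strategy `"C"` or `"D"` — the focal player's strategy.
#' @param i Number of adaptive cooperators in the group under the stated
#'   convention (vectorized); `0 <= i <= N - a`, and `i >= 1` for a cooperator.
#' @param model A [crd_model()].
#' @return Numeric vector of expected payoffs.
#' @examples
#' m <- crd_model(N = 6, M = 3, r = 0.7, a = 2, p = 0.5)
#' expected_payoff("C", 1:4, m)
#' expected_payoff("D", 0:4, m)
#' @export
expected_payoff <- function(strategy, i, model) {
  stopifnot(inherits(model, "crd_model"))
  strategy <- match.arg(strategy, c("C", "D"))
  n_adapt <- model$N - model$a
  if (any(i < 0 | i > n_adapt | i != round(i))) {
    stop("`i` must be an integer in 0..(N - a).")
  }
  pay <- if (strategy == "C") {
    if (any(i < 1)) stop("a cooperator is present in its own group, so `i` >= 1.")
    function(j) payoff_cooperator(j, model)
  } else {
    function(j) payoff_defector(j, model)
  }
  model$p * pay(i + model$a) + (1 - model$p) * pay(i)
}
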