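#' Define a hybrid collective-risk dilemma model
#'
#' Bundles all parameters of one model instance: the one-shot collective-risk
#' dilemma (CRD) played in groups of size `N`, the fixed-behavior agent block
#' attached to every group, and the finite adaptive population whose strategies
#' evolve by mutation and payoff-biased imitation.
#'
#' A group holds `N - a` adaptive individuals sampled from the population of
#' size `Z`, plus `a` stochastic agents that cooperate as a single block with
#' probability `p` in each interaction (all `a` cooperate, or none do). If
#' fewer than `M` of the `N` seats cooperate, every member loses its remaining
#' endowment with probability `r`.
#'
#' @param N Group size (integer, >= 2).
#' @param M Cooperator threshold needed to avoid the risk (integer, >= 1).
#'   `M > N` is allowed and encodes a group that can never meet the threshold
#'   unaided — the configuration of the addition control when more agents were
#'   added than the original team could spare (e.g. a control of 2 adaptive
#'   members facing a threshold of 3).
#' @param r Risk probability of collective loss when the threshold is missed,
#'   in \[0, 1\].
#' @param b Endowment of each player (currency units, > 0).
#' @param c Fraction of the endowment a cooperator contributes, in (0, 1).
#' @param a Number of fixed-behavior agents per group (integer, 0 <= a < N).
#' @param p Probability that the agent block cooperates in an interaction,
#'   in \[0, 1\].
#' @param Z Size of the adaptive population (integer, >= 2, and >= N - a so a
#'   group of adaptive seats can be sampled).
#' @param mu Mutation probability per strategy-revision event, in \[0, 1\].
#' @param beta Selection strength of the Fermi imitation rule (>= 0).
#' @param transitions Transition-probability convention: `"with-mutation"`
#'   (default) includes the additive mutation inflow so the chain is ergodic
#'   for `mu > 0`; `"printed"` is the imitation-only form in which the
#'   boundary states are absorbing (kept inspectable, but its stationary
#'   distribution is degenerate and is refused by [stationary_distribution()]).
#'
#' @return An object of class `crd_model`: a named list with the validated
#'   parameters.
#'
#' @examples
#' m <- crd_model(N = 6, M = 3, r = 0.7, a = 2, p = 0.5)
#' m
#' @seealso [stationary_distribution()], [crd_metrics()], [crd_scenario()]
#' @export
crd_model <- function(N = 6, M = 3, r = 0.5, b = 1, c = 0.1,
                      a = 0, p = 0, Z = 100, mu = 0.01, beta = 2,
                      transitions = c("with-mutation", "printed")) {
  transitions <- match.arg(transitions)
  stopifnot(
    "N must be an integer >= 2" = is_count(N) && N >= 2,
    "M must be an integer >= 1" = is_count(M) && M >= 1,
    "r must lie in [0, 1]" = is_prob(r),
    "b must be > 0" = is.numeric(b) && length(b) == 1 && b > 0,
    "c must lie in (0, 1)" = is.numeric(c) && length(c) == 1 && c > 0 && c < 1,
    "a must be an integer with 0 <= a < N" = is_count(a, zero_ok = TRUE) && a < N,
    "p must lie in [0, 1]" = is_prob(p),
    "Z must be an integer >= 2" = is_count(Z) && Z >= 2,
    "Z must be >= N - a (a group of adaptive seats must be sampleable)" =
      Z >= N - a,
    "mu must lie in [0, 1]" = is_prob(mu),
    "beta must be >= 0" = is.numeric(beta) && length(beta) == 1 && beta >= 0
  )
  structure(
    list(N = as.integer(N), M = as.integer(M), r = r, b = b, c = c,
         a = as.integer(a), p = p, Z = as.integer(Z), mu = mu, beta = beta,
         transitions = transitions),
    class = "crd_model"
  )
}

is_count <- function(x, zero_ok = FALSE) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) &&
    (x > 0 || (zero_ok && x == 0))
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

#' @export
print.crd_model <- function(x, ...) {
  cat("<crd_model>\n")
  cat(sprintf("  game:       N = %d, M = %d, r = %g, b = %g, c = %g\n",
              x$N, x$M, x$r, x$b, x$c))
  cat(sprintf("  agents:     a = %d, p = %g\n", x$a, x$p))
  cat(sprintf("  population: Z = %d, mu = %g, beta = %g\n", x$Z, x$mu, x$beta))
  cat(sprintf("  transitions: %s\n", x$transitions))
  invisible(x)
}

#' Update parameters of an existing model
#'
#' Returns a copy of `model` with the named parameters replaced, re-validated.
#'
#' @param model A [crd_model()].
#' @param ... Named parameters to replace (any argument of [crd_model()]).
#' @return A new `crd_model`.
#' @examples
#' base <- crd_model(a = 2, p = 0.5)
#' update_model(base, r = 0.9)
#' @export
update_model <- function(model, ...) {
  stopifnot(inherits(model, "crd_model"))
  args <- utils::modifyList(unclass(model), list(...))
  do.call(crd_model, args)
}

#' Build the non-hybrid control model for a hybrid team
#'
#' A hybrid team of `N - a` adaptive members and `a` agents is compared with a
#' non-hybrid control population that plays the same game with `a = 0`. Under
#' the *substitution* view the hybrid team replaced `a` of `N` adaptive
#' members, so the control keeps group size `N`; under the *addition* view the
#' agents were appended to an existing team of `N - a` adaptive members, so the
#' control group size is `N - a`. The agent cooperation probability `p` is
#' inert once `a = 0` and is set to 0.
#'
#' @param model A hybrid [crd_model()] with `a >= 1`.
#' @param mode `"substitution"` or `"addition"`.
#' @return A `crd_model` describing the control population.
#' @examples
#' hyb <- crd_model(N = 6, M = 3, a = 2, p = 0.8, r = 0.7)
#' control_model(hyb, "substitution")$N  # 6
#' control_model(hyb, "addition")$N     # 4
#' @export
control_model <- function(model, mode = c("substitution", "addition")) {
  stopifnot(inherits(model, "crd_model"))
  mode <- match.arg(mode)
  if (model$a == 0) {
    stop("`model` has no fixed-behavior agents (a = 0); nothing to control for.")
  }
  if (mode == "substitution") {
    update_model(model, a = 0, p = 0)
  } else {
    update_model(model, a = 0, p = 0, N = model$N - model$a)
  }
}
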