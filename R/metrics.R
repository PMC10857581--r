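#' Average cooperation level of the adaptive population
#'
#' The stationary mean fraction of cooperators,
#' `C_bar = sum_k P(k) * k / Z`.
#'
#' @param stat A `crd_stationary` from [stationary_distribution()].
#' @return A scalar in \[0, 1\].
#' @export
avg_cooperation <- function(stat) {
  stopifnot(inherits(stat, "crd_stationary"))
  Z <- stat$model$Z
  sum(stat$distribution * (0:Z) / Z)
}

#' Probability that a random group meets the threshold, per population state
#'
#' With `k` cooperators in the adaptive population, the `N - a` adaptive seats
#' of a group are filled without replacement (multivariate hypergeometric),
#' and the agent block cooperates all-or-none with probability `p`:
#'
#' `s_G(k) = choose(Z, N-a)^-1 * sum_h choose(k, h) choose(Z-k, N-a-h) *
#'           (p * heaviside(h + a - M) + (1-p) * heaviside(h - M))`
#'
#' Non-decreasing in `k`, and affine non-decreasing in `p` at fixed `k`.
#'
#' @param k Population cooperator count, `0 <= k <= Z` (vectorized).
#' @param model A [crd_model()].
#' @return Numeric vector of success probabilities in \[0, 1\].
#' @examples
#' m <- crd_model(a = 2, p = 0.5, r = 0.7, Z = 20)
#' group_success_state(0:20, m)
#' @export
group_success_state <- function(k, model) {
  stopifnot(inherits(model, "crd_model"))
  check_state(k, model$Z)
  n_adapt <- model$N - model$a
  h <- 0:n_adapt
  succ <- model$p * heaviside(h + model$a - model$M) +
    (1 - model$p) * heaviside(h - model$M)
  norm <- choose(model$Z, n_adapt)
  vapply(k, function(kk) {
    sum(binom_safe(kk, h) * binom_safe(model$Z - kk, n_adapt - h) * succ) / norm
  }, numeric(1))
}

#' Average group success over the stationary distribution
#'
#' `s_bar_G = sum_k P(k) * s_G(k)` with `s_G` from [group_success_state()].
#'
#' @param stat A `crd_stationary` from [stationary_distribution()].
#' @return A scalar in \[0, 1\].
#' @export
avg_group_success <- function(stat) {
  stopifnot(inherits(stat, "crd_stationary"))
  sum(stat$distribution * group_success_state(0:stat$model$Z, stat$model))
}

#' Stationary cooperation and success metrics for one model
#'
#' Solves the stationary distribution once and reports the population-level
#' observables: the average cooperation level, the average group success, and
#' the per-state table `(k, prob, success)` from which both are derived.
#'
#' @param model A [crd_model()].
#' @return An object of class `crd_metrics`: list with `coop_level`,
#'   `group_success`, `states` (a tibble with columns `k`, `prob`,
#'   `success`), `model`, and the underlying `stationary` result.
#' @examples
#' crd_metrics(crd_model(a = 2, p = 0.5, r = 0.7))
#' @export
crd_metrics <- function(model) {
  stopifnot(inherits(model, "crd_model"))
  st <- stationary_distribution(model)
  k <- 0:model$Z
  sg <- group_success_state(k, model)
  structure(
    list(coop_level = avg_cooperation(st),
         group_success = sum(st$distribution * sg),
         states = tibble::tibble(k = k, prob = unname(st$distribution),
                                 success = sg),
         model = model, stationary = st),
    class = "crd_metrics"
  )
}

#' @export
print.crd_metrics <- function(x, ...) {
  cat("<crd_metrics>\n")
  cat(sprintf("  cooperation level: %.4f\n  group success:     %.4f\n",
              x$coop_level, x$group_success))
  invisible(x)
}

#' Gain of a hybrid team over its non-hybrid control
#'
#' Evaluates the hybrid model and its control (see [control_model()]) and
#' reports the differences in cooperation level and group success,
#' `delta = hybrid - control`. Under *substitution* the control keeps group
#' size `N` with all seats adaptive; under *addition* the control has group
#' size `N - a`.
#'
#' @param model A hybrid [crd_model()] with `a >= 1`.
#' @param mode `"substitution"` or `"addition"`.
#' @return An object of class `crd_delta`: list with `mode`, `delta_coop`,
#'   `delta_success`, and the full `hybrid` and `control` [crd_metrics()]
#'   reports.
#' @examples
#' control_delta(crd_model(a = 2, p = 0.8, r = 0.3), "addition")
#' @export
control_delta <- function(model, mode = c("substitution", "addition")) {
  mode <- match.arg(mode)
  hybrid <- crd_metrics(model)
  control <- crd_metrics(control_model(model, mode))
  structure(
    list(mode = mode,
         delta_coop = hybrid$coop_level - control$coop_level,
         delta_success = hybrid$group_success - control$group_success,
         hybrid = hybrid, control = control),
    class = "crd_delta"
  )
}

#' @export
print.crd_delta <- function(x, ...) {
  cat(sprintf("<crd_delta: %s>\n", x$mode))
  cat(sprintf("  delta cooperation: %+.4f  (hybrid %.4f, control %.4f)\n",
              x$delta_coop, x$hybrid$coop_level, x$control$coop_level))
  cat(sprintf("  delta success:     %+.4f  (hybrid %.4f, control %.4f)\n",
              x$delta_success, x$hybrid$group_success, x$control$group_success))
  invisible(x)
}

#' Evaluate one parameter point, optionally against its controls
#'
#' One-stop evaluation used by the sweep machinery and the command-line
#' front end: solves the hybrid model and any requested controls and returns
#' a tidy tibble with one row per evaluated population. Control rows carry
#' the hybrid-minus-control differences in `delta_coop` / `delta_success`.
#'
#' @param model A [crd_model()].
#' @param controls Character vector, subset of
#'   `c("substitution", "addition")`; requires `model$a >= 1`.
#' @return A tibble with columns `role`, `N`, `a`, `p`, `r`, `coop_level`,
#'   `group_success`, `delta_coop`, `delta_success`.
#' @examples
#' evaluate_point(crd_model(a = 2, p = 0.5, r = 0.7),
#'                controls = c("substitution", "addition"))
#' @export
evaluate_point <- function(model, controls = character()) {
  stopifnot(inherits(model, "crd_model"))
  if (length(controls)) {
    controls <- match.arg(controls, c("substitution", "addition"),
                          several.ok = TRUE)
  }
  hyb <- crd_metrics(model)
  row <- function(role, met, ref = NULL) {
    m <- met$model
    tibble::tibble(
      role = role, N = m$N, a = m$a, p = m$p, r = m$r,
      coop_level = met$coop_level, group_success = met$group_success,
      delta_coop = if (is.null(ref)) NA_real_ else ref$coop_level - met$coop_level,
      delta_success = if (is.null(ref)) NA_real_ else ref$group_success - met$group_success
    )
  }
  out <- list(row("hybrid", hyb))
  for (mode in controls) {
    ctl <- crd_metrics(control_model(model, mode))
    out <- c(out, list(row(paste0("control_", mode), ctl, ref = hyb)))
  }
  dplyr::bind_rows(out)
}
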