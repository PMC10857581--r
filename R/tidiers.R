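#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for stationary-distribution results
#'
#' `tidy()` returns the per-state table: one row per population state `k`
#' with its stationary probability, the fraction of cooperators and the
#' per-state group success probability. `glance()` returns the one-row
#' summary with the derived scalars.
#'
#' @param x A `crd_stationary` from [stationary_distribution()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crd_stationary <- function(x, ...) {
  Z <- x$model$Z
  tibble::tibble(
    k = 0:Z,
    prob = unname(x$distribution),
    coop_fraction = (0:Z) / Z,
    success = group_success_state(0:Z, x$model)
  )
}

#' @rdname tidy.crd_stationary
#' @export
glance.crd_stationary <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    coop_level = avg_cooperation(x),
    group_success = avg_group_success(x),
    Z = m$Z, N = m$N, M = m$M, a = m$a, p = m$p, r = m$r,
    mu = m$mu, beta = m$beta,
    method = x$method, residual = x$residual
  )
}

#' @rdname tidy.crd_stationary
#' @export
tidy.crd_metrics <- function(x, ...) x$states

#' @rdname tidy.crd_stationary
#' @export
glance.crd_metrics <- function(x, ...) glance(x$stationary)

#' Tidiers for control-delta results
#'
#' `tidy()` returns one row per population (hybrid and control) with its
#' metrics; `glance()` the one-row comparison with both deltas.
#'
#' @param x A `crd_delta` from [control_delta()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crd_delta <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$hybrid), role = "hybrid", .before = 1),
    dplyr::mutate(glance(x$control), role = paste0("control_", x$mode), .before = 1)
  )
}

#' @rdname tidy.crd_delta
#' @export
glance.crd_delta <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    delta_coop = x$delta_coop,
    delta_success = x$delta_success,
    hybrid_coop = x$hybrid$coop_level,
    hybrid_success = x$hybrid$group_success,
    control_coop = x$control$coop_level,
    control_success = x$control$group_success
  )
}

#' Tidiers for agent-based simulation traces
#'
#' `tidy()` returns the empirical occupancy (one row per state `k`);
#' `glance()` the one-row summary with empirical cooperation level and group
#' success.
#'
#' @param x A `crd_abm` from [run_abm()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crd_abm <- function(x, ...) x$occupancy

#' @rdname tidy.crd_abm
#' @export
glance.crd_abm <- function(x, ...) {
  tibble::tibble(
    coop_level = x$coop_level,
    success_estimate = x$success_estimate,
    Z = x$model$Z, steps = x$steps, burn_in = x$burn_in,
    seed = x$seed, fitness = x$fitness
  )
}

#' @rdname tidy.crd_stationary
#' @export
tidy.crd_sweep <- function(x, ...) x$grid

#' Heatmap of a parameter sweep
#'
#' Renders a [run_sweep()] grid as a `ggplot2` tile map with the agent
#' cooperation probability `p` on the x-axis and the risk probability `r` on
#' the y-axis. Delta metrics get a diverging palette centered at zero.
#'
#' @param object A `crd_sweep`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @examples
#' sw <- run_sweep(crd_scenario("a2"), "group_success",
#'                 r_values = seq(0, 1, length.out = 6),
#'                 p_values = seq(0, 1, length.out = 6))
#' autoplot(sw)
#' @export
autoplot.crd_sweep <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$p, y = .data$r,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "agent cooperation probability p",
                  y = "risk probability r", fill = object$metric)
  if (grepl("^delta_", object$metric)) {
    lim <- max(abs(object$grid$value), 1e-12)
    g + ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                      high = "#2166ac", limits = c(-lim, lim))
  } else {
    g + ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
}

#' Plot a stationary distribution
#'
#' Column plot of `P(k)` over the population states.
#'
#' @param object A `crd_stationary`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.crd_stationary <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k, y = .data$prob)) +
    ggplot2::geom_col(width = 1, fill = "#2166ac") +
    ggplot2::labs(x = "cooperators k", y = "stationary probability P(k)")
}

#' Compare empirical ABM occupancy with the analytical stationary distribution
#'
#' @param object A `crd_abm`.
#' @param ... Unused.
#' @return A `ggplot` object overlaying the empirical occupancy (columns) and
#'   the analytical `P(k)` (line + points).
#' @export
autoplot.crd_abm <- function(object, ...) {
  st <- stationary_distribution(object$model)
  dat <- dplyr::mutate(object$occupancy,
                       analytical = unname(st$distribution))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prob), width = 1,
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytical),
                       color = "#b2182b") +
    ggplot2::geom_point(ggplot2::aes(y = .data$analytical),
                        color = "#b2182b", size = 0.8) +
    ggplot2::labs(x = "cooperators k", y = "probability",
                  title = "empirical occupancy vs analytical stationary distribution")
}

#' @importFrom rlang .data
NULL
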