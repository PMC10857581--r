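#' Scenario presets for the three hybrid-team configurations
#'
#' Base models for the three studied group compositions, all with `N = 6`,
#' `M = 3`, `Z = 100`, `mu = 0.01`, `beta = 2`, `b = 1`, `c = 0.1`:
#' * `"a2"` — 4 adaptive members + 2 agents (`a < M < N - a`: the adaptive
#'   members can meet the threshold alone, the agents cannot);
#' * `"a3"` — 3 + 3 (`a = M = N - a`: either side can meet it alone);
#' * `"a4"` — 2 + 4 (`a > M > N - a`: only the agents can meet it alone).
#'
#' The risk `r` and agent cooperativeness `p` are left at placeholder values
#' and are meant to be swept or overridden with [update_model()].
#'
#' @param scenario `"a2"`, `"a3"` or `"a4"`.
#' @param ... Overrides passed to [update_model()] (e.g. `r`, `p`, `Z`).
#' @return A [crd_model()].
#' @examples
#' crd_scenario("a3", r = 0.9, p = 0.2)
#' @export
crd_scenario <- function(scenario = c("a2", "a3", "a4"), ...) {
  scenario <- match.arg(scenario)
  a <- c(a2 = 2L, a3 = 3L, a4 = 4L)[[scenario]]
  base <- crd_model(N = 6, M = 3, r = 0.5, b = 1, c = 0.1,
                    a = a, p = 0.5, Z = 100, mu = 0.01, beta = 2)
  if (...length()) update_model(base, ...) else base
}

sweep_metrics <- c("coop_level", "group_success",
                   "delta_coop_substitution", "delta_success_substitution",
                   "delta_coop_addition", "delta_success_addition")

#' Sweep cooperation/success metrics over a risk x agent-cooperation grid
#'
#' Evaluates the stationary metrics of a base model on a rectangular lattice
#' of risk probabilities `r` and agent cooperation probabilities `p`. For the
#' delta metrics the non-hybrid control (substitution or addition, see
#' [control_model()]) is solved once per `r` value — the control has `a = 0`,
#' so its metrics do not depend on `p`. The sweep is fully deterministic.
#'
#' @param base A [crd_model()] whose `r` and `p` are overridden per grid
#'   point, or a scenario name accepted by [crd_scenario()].
#' @param metric One of `"coop_level"`, `"group_success"`,
#'   `"delta_coop_substitution"`, `"delta_success_substitution"`,
#'   `"delta_coop_addition"`, `"delta_success_addition"`.
#' @param r_values,p_values Numeric grids in \[0, 1\], each of length >= 2.
#' @param progress Print one line per completed `r` row.
#' @return An object of class `crd_sweep`: list with `grid` (a tibble with
#'   columns `r`, `p`, `coop_level`, `group_success`, the control/delta
#'   columns when a delta metric was requested, and `value` — the requested
#'   metric), `metric`, `base` model, and the grid axes.
#' @examples
#' sw <- run_sweep(crd_scenario("a2"), "group_success",
#'                 r_values = seq(0, 1, length.out = 5),
#'                 p_values = seq(0, 1, length.out = 5))
#' sw$grid
#' @export
run_sweep <- function(base, metric = "group_success",
                      r_values = seq(0, 1, length.out = 51),
                      p_values = seq(0, 1, length.out = 51),
                      progress = FALSE) {
  if (is.character(base)) base <- crd_scenario(base)
  stopifnot(inherits(base, "crd_model"))
  metric <- match.arg(metric, sweep_metrics)
  stopifnot(
    "r_values must be a grid of length >= 2 in [0, 1]" =
      length(r_values) >= 2 && all(r_values >= 0 & r_values <= 1),
    "p_values must be a grid of length >= 2 in [0, 1]" =
      length(p_values) >= 2 && all(p_values >= 0 & p_values <= 1)
  )
  is_delta <- grepl("^delta_", metric)
  mode <- if (is_delta) sub("^delta_(coop|success)_", "", metric)

  rows <- purrr::map(r_values, function(r) {
    ctl <- if (is_delta) crd_metrics(control_model(update_model(base, r = r), mode))
    row <- purrr::map(p_values, function(p) {
      hyb <- crd_metrics(update_model(base, r = r, p = p))
      out <- tibble::tibble(r = r, p = p,
                            coop_level = hyb$coop_level,
                            group_success = hyb$group_success)
      if (is_delta) {
        out$control_coop <- ctl$coop_level
        out$control_success <- ctl$group_success
        out$delta_coop <- hyb$coop_level - ctl$coop_level
        out$delta_success <- hyb$group_success - ctl$group_success
      }
      out
    })
    if (progress) message(sprintf("sweep: r = %.3f done", r))
    dplyr::bind_rows(row)
  })
  grid <- dplyr::bind_rows(rows)
  grid$value <- switch(
    metric,
    coop_level = grid$coop_level,
    group_success = grid$group_success,
    grid[[sub("_(substitution|addition)$", "", metric)]]
  )
  structure(
    list(grid = grid, metric = metric, base = base,
         r_values = r_values, p_values = p_values),
    class = "crd_sweep"
  )
}

#' @export
print.crd_sweep <- function(x, ...) {
  cat("<crd_sweep>\n")
  cat(sprintf("  metric: %s   grid: %d r-values x %d p-values\n",
              x$metric, length(x$r_values), length(x$p_values)))
  cat(sprintf("  base: N = %d, M = %d, a = %d, Z = %d, mu = %g, beta = %g\n",
              x$base$N, x$base$M, x$base$a, x$base$Z, x$base$mu, x$base$beta))
  cat(sprintf("  value range: [%.4f, %.4f]\n",
              min(x$grid$value), max(x$grid$value)))
  invisible(x)
}

#' Extract the sweep as a value matrix
#'
#' @param sweep A [run_sweep()] result.
#' @return A numeric matrix indexed `[r, p]` with axis values as dimnames.
#' @export
sweep_matrix <- function(sweep) {
  stopifnot(inherits(sweep, "crd_sweep"))
  matrix(sweep$grid$value,
         nrow = length(sweep$r_values), byrow = TRUE,
         dimnames = list(r = format(sweep$r_values),
                         p = format(sweep$p_values)))
}

#' Write and re-read sweep grids
#'
#' `write_grid()` serializes a sweep either as long-form CSV (columns `r`,
#' `p`, `metric`, `value`, full round-trip precision) or as JSON carrying the
#' grid axes, the value matrix, the complete base model (including the
#' transition-probability convention used) and the package version.
#' `read_grid()` reads either format back into a `crd_sweep`; a write/read
#' round trip reproduces the value matrix bit-exactly.
#'
#' @param sweep A [run_sweep()] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns a
#'   `crd_sweep` (from CSV, only the long grid and metric are recoverable;
#'   from JSON the base model is restored too).
#' @examples
#' sw <- run_sweep(crd_scenario("a2"), "coop_level",
#'                 r_values = c(0, 1), p_values = c(0, 1))
#' f <- tempfile(fileext = ".json")
#' write_grid(sw, f)
#' identical(sweep_matrix(read_grid(f)), sweep_matrix(sw))
#' @export
write_grid <- function(sweep, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(sweep, "crd_sweep"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write grid: directory '%s' does not exist.", dir))
  }
  if (format == "csv") {
    # %.17g keeps the doubles bit-exact through a write/read round trip
    long <- tibble::tibble(r = sprintf("%.17g", sweep$grid$r),
                           p = sprintf("%.17g", sweep$grid$p),
                           metric = sweep$metric,
                           value = sprintf("%.17g", sweep$grid$value))
    readr::write_csv(long, path)
  } else {
    payload <- list(
      metric = sweep$metric,
      r_values = sweep$r_values,
      p_values = sweep$p_values,
      values = sweep_matrix(sweep),
      model = unclass(sweep$base),
      package = "hybridcrd",
      version = as.character(utils::packageVersion("hybridcrd"))
    )
    jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    # parse numerics with strtod (correctly rounded) for a bit-exact round trip
    long <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
    stopifnot(all(c("r", "p", "metric", "value") %in% names(long)))
    metric <- long$metric[[1]]
    grid <- tibble::tibble(r = as.numeric(long$r), p = as.numeric(long$p),
                           value = as.numeric(long$value))
    structure(
      list(grid = grid, metric = metric, base = NULL,
           r_values = unique(grid$r), p_values = unique(grid$p)),
      class = "crd_sweep"
    )
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    vals <- matrix(unlist(x$values), nrow = length(x$r_values), byrow = FALSE)
    grid <- tibble::tibble(
      r = rep(x$r_values, each = length(x$p_values)),
      p = rep(x$p_values, times = length(x$r_values)),
      value = as.vector(t(vals))
    )
    base <- do.call(crd_model, x$model[setdiff(names(x$model), character())])
    structure(
      list(grid = grid, metric = x$metric, base = base,
           r_values = x$r_values, p_values = x$p_values),
      class = "crd_sweep"
    )
  }
}
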