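#' Agent-based Monte Carlo simulation of the social-learning process
#'
#' Simulates the exact stochastic process whose stationary behavior the
#' analytical chain computes: at each update step a focal individual is drawn
#' uniformly from the `Z` adaptive individuals; with probability `mu` it flips
#' its strategy; otherwise it draws a role model uniformly among the other
#' `Z - 1` individuals — a no-op if their strategies match — and imitates with
#' the Fermi probability. Because individuals are exchangeable and fitness in
#' the default `"exact"` mode depends only on the population state `k`, the
#' draws are realized by strategy type (the focal is a cooperator with
#' probability `k/Z`, the role model from the remaining composition), which is
#' the same agent-level process and fully reproducible under a seed.
#'
#' With `fitness = "exact"` the imitation probabilities use the hypergeometric
#' expected fitness of [fitness_cooperator()]/[fitness_defector()], so the
#' simulation isolates the update rule and shares its transition probabilities
#' with the analytical chain. With `fitness = "sampled"` each fitness is
#' re-estimated at every imitation event by averaging the focal's payoff over
#' `groups_per_fitness` freshly sampled groups (robustness probes only).
#'
#' @param model A [crd_model()].
#' @param steps Total update steps (after the initial state; > `burn_in`).
#' @param burn_in Discarded initial steps (>= 0).
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   traces.
#' @param init Initial cooperator count (default `Z %/% 2`).
#' @param thin Record the cooperation time series and sample one group for
#'   the empirical success estimate every `thin` retained steps.
#' @param fitness `"exact"` (default) or `"sampled"`.
#' @param groups_per_fitness Number of sampled groups per fitness estimate in
#'   `"sampled"` mode.
#' @return An object of class `crd_abm`: list with `occupancy` (tibble `k`,
#'   `prob` over `0..Z`), `coop_level` (mean of `k/Z` over retained steps),
#'   `success_estimate` (fraction of sampled groups meeting the threshold),
#'   `coop_series` (tibble `step`, `k`), `transitions` (tibble `k`, `visits`,
#'   `up`, `down` of one-step moves out of each state after burn-in), and the
#'   configuration.
#' @examples
#' m <- crd_model(Z = 20, a = 2, p = 0.5, r = 0.7)
#' sim <- run_abm(m, steps = 20000, burn_in = 2000, seed = 1)
#' sim$coop_level
#' @seealso [stationary_distribution()] for the analytical counterpart.
#' @export
run_abm <- function(model, steps, burn_in = 0, seed = 1,
                    init = model$Z %/% 2, thin = 10,
                    fitness = c("exact", "sampled"), groups_per_fitness = 10) {
  stopifnot(inherits(model, "crd_model"))
  fitness <- match.arg(fitness)
  stopifnot(
    "steps must exceed burn_in >= 0" =
      is_count(steps) && is_count(burn_in, zero_ok = TRUE) && steps > burn_in,
    "init must be a state in 0..Z" =
      is_count(init, zero_ok = TRUE) && init <= model$Z,
    "thin must be a positive integer" = is_count(thin),
    "groups_per_fitness must be a positive integer" =
      is_count(groups_per_fitness)
  )
  Z <- model$Z
  mu <- model$mu
  exact <- fitness == "exact"
  if (exact) {
    fc <- fitness_cooperator(0:Z, model)
    fd <- fitness_defector(0:Z, model)
    p_dc <- fermi_probability(fc, fd, model$beta)  # D focal imitates C
    p_cd <- fermi_probability(fd, fc, model$beta)  # C focal imitates D
  }
  succ_prob <- group_success_probs(model)  # success prob given h and block draw

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  k <- as.integer(init)
  counts <- integer(Z + 1)
  up <- integer(Z + 1)
  down <- integer(Z + 1)
  visits <- integer(Z + 1)
  kept <- steps - burn_in
  n_series <- kept %/% thin
  series_k <- integer(n_series)
  succ_draws <- integer(n_series)
  series_i <- 0L
  coop_sum <- 0
  chunk <- 100000L
  done <- 0L
  while (done < steps) {
    n <- min(chunk, steps - done)
    u <- matrix(stats::runif(4L * n), nrow = 4L)
    for (s in seq_len(n)) {
      step_id <- done + s
      k_from <- k
      focal_c <- u[1L, s] < k / Z
      if (u[2L, s] < mu) {
        k <- if (focal_c) k - 1L else k + 1L
      } else {
        # role model uniform among the other Z - 1; no-op on same strategy
        if (focal_c) {
          if (u[3L, s] < (Z - k) / (Z - 1)) {   # role model defects
            pr <- if (exact) p_cd[k + 1L] else
              fermi_sampled(model, k, focal_c = TRUE, groups_per_fitness)
            if (u[4L, s] < pr) k <- k - 1L
          }
        } else {
          if (u[3L, s] < k / (Z - 1)) {          # role model cooperates
            pr <- if (exact) p_dc[k + 1L] else
              fermi_sampled(model, k, focal_c = FALSE, groups_per_fitness)
            if (u[4L, s] < pr) k <- k + 1L
          }
        }
      }
      if (step_id > burn_in) {
        counts[k + 1L] <- counts[k + 1L] + 1L
        coop_sum <- coop_sum + k
        visits[k_from + 1L] <- visits[k_from + 1L] + 1L
        if (k == k_from + 1L) up[k_from + 1L] <- up[k_from + 1L] + 1L
        if (k == k_from - 1L) down[k_from + 1L] <- down[k_from + 1L] + 1L
        rec <- step_id - burn_in
        if (rec %% thin == 0L && series_i < n_series) {
          series_i <- series_i + 1L
          series_k[series_i] <- k
          succ_draws[series_i] <- draw_group_success(model, k, succ_prob)
        }
      }
    }
    done <- done + n
  }

  structure(
    list(occupancy = tibble::tibble(k = 0:Z, prob = counts / kept),
         coop_level = coop_sum / (kept * Z),
         success_estimate = mean(succ_draws[seq_len(series_i)]),
         coop_series = tibble::tibble(step = burn_in + thin * seq_len(series_i),
                                      k = series_k[seq_len(series_i)]),
         transitions = tibble::tibble(k = 0:Z, visits = visits,
                                      up = up, down = down),
         model = model, steps = steps, burn_in = burn_in, seed = seed,
         thin = thin, fitness = fitness),
    class = "crd_abm"
  )
}

# success indicator for h adaptive cooperators with/without the agent block
group_success_probs <- function(model) {
  h <- 0:(model$N - model$a)
  list(with_block = heaviside(h + model$a - model$M),
       without = heaviside(h - model$M))
}

# draw one group from state k and report threshold attainment (0/1)
draw_group_success <- function(model, k, succ_prob) {
  h <- stats::rhyper(1, k, model$Z - k, model$N - model$a)
  block <- stats::runif(1) < model$p
  if (block) succ_prob$with_block[h + 1L] else succ_prob$without[h + 1L]
}

# sampled-fitness Fermi probability: payoffs averaged over freshly drawn groups
fermi_sampled <- function(model, k, focal_c, n_groups) {
  Z <- model$Z
  s <- model$N - model$a - 1
  if (focal_c) {
    # focal C: co-players from the other Z-1 (k-1 Cs); role model is a D whose
    # co-players come from its own other Z-1 (k Cs, Z-k-1 Ds)
    i_c <- stats::rhyper(n_groups, k - 1, Z - k, s)
    f_focal <- mean(block_payoff("C", i_c + 1, model))
    i_d <- stats::rhyper(n_groups, k, Z - k - 1, s)
    f_rm <- mean(block_payoff("D", i_d, model))
    fermi_probability(f_rm, f_focal, model$beta)
  } else {
    i_d <- stats::rhyper(n_groups, k, Z - k - 1, s)
    f_focal <- mean(block_payoff("D", i_d, model))
    i_c <- stats::rhyper(n_groups, k - 1, Z - k, s)
    f_rm <- mean(block_payoff("C", i_c + 1, model))
    fermi_probability(f_rm, f_focal, model$beta)
  }
}

# payoff with a fresh agent-block realization per group
block_payoff <- function(strategy, i, model) {
  block <- stats::runif(length(i)) < model$p
  j <- i + ifelse(block, model$a, 0L)
  if (strategy == "C") payoff_cooperator(j, model) else payoff_defector(j, model)
}

#' @export
print.crd_abm <- function(x, ...) {
  cat("<crd_abm>\n")
  cat(sprintf("  Z = %d, %d steps (%d burn-in), seed %d, fitness = %s\n",
              x$model$Z, x$steps, x$burn_in, x$seed, x$fitness))
  cat(sprintf("  empirical cooperation level: %.4f\n", x$coop_level))
  cat(sprintf("  empirical group success:     %.4f\n", x$success_estimate))
  invisible(x)
}

#' Monte Carlo estimate of the per-state group success probability
#'
#' Draws `n_samples` groups of `N - a` adaptive members without replacement
#' from a population with `k` cooperators, realizes the agent block
#' (all-cooperate with probability `p`, fresh per group), and reports the
#' fraction meeting the threshold `M`. Unbiased estimator of
#' [group_success_state()].
#'
#' @param model A [crd_model()].
#' @param k Population cooperator count.
#' @param n_samples Number of groups to sample (>= 1).
#' @param seed Integer RNG seed.
#' @return A scalar estimate in \[0, 1\].
#' @examples
#' m <- crd_model(Z = 20, a = 2, p = 0.5)
#' sample_group_success(m, k = 10, n_samples = 1000, seed = 1)
#' group_success_state(10, m)
#' @export
sample_group_success <- function(model, k, n_samples, seed = 1) {
  stopifnot(inherits(model, "crd_model"), is_count(n_samples))
  check_state(k, model$Z)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  h <- stats::rhyper(n_samples, k, model$Z - k, model$N - model$a)
  block <- stats::runif(n_samples) < model$p
  mean(heaviside(h + ifelse(block, model$a, 0L) - model$M))
}
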