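#' Binomial coefficient with out-of-range convention
#'
#' Returns `choose(n, r)` when `0 <= r <= n` and 0 otherwise. Every
#' hypergeometric sum in the package routes through this so that boundary
#' population states (e.g. no cooperators left for a cooperating focal player
#' to be grouped with) contribute zero weight instead of erroring. Exact in
#' double precision for the population sizes used here (group seats <= N, so
#' coefficients stay far below 2^53).
#'
#' @param n,r Integer-valued numeric vectors (recycled).
#' @return Numeric vector of binomial coefficients.
#' @examples
#' binom_safe(5, 2)    # 10
#' binom_safe(-1, 0)   # 0, not choose(-1, 0) = 1
#' binom_safe(3, 5)    # 0
#' @export
binom_safe <- function(n, r) {
  len <- max(length(n), length(r))
  n <- rep_len(as.numeric(n), len)
  r <- rep_len(as.numeric(r), len)
  out <- numeric(len)
  ok <- r >= 0 & r <= n
  out[ok] <- choose(n[ok], r[ok])
  out
}

#' Hypergeometric expected fitness of cooperators and defectors
#'
#' The fitness of a strategy in population state `k` (cooperators among the
#' `Z` adaptive individuals) is its expected payoff over all groups the focal
#' player can be sampled into: the `N - a - 1` co-players are drawn without
#' replacement from the other `Z - 1` individuals, giving hypergeometric
#' weights over the number `i` of cooperating co-players. For a cooperator the
#' focal player adds itself to the cooperator count:
#'
#' `f_C(k) = choose(Z-1, N-a-1)^-1 * sum_i choose(k-1, i) choose(Z-k, N-a-1-i) Pi_C(i+1)`
#' `f_D(k) = choose(Z-1, N-a-1)^-1 * sum_i choose(k, i) choose(Z-k-1, N-a-1-i) Pi_D(i)`
#'
#' where `Pi_s` is [expected_payoff()]. The boundary values `f_C(0)` and
#' `f_D(Z)` are undefined (no such focal player exists) and are returned as 0;
#' the transition probabilities never consume them because the corresponding
#' pair-selection factors vanish exactly there.
#'
#' @param k Population cooperator count, `0 <= k <= Z` (vectorized).
#' @param model A [crd_model()].
#' @return Numeric vector of expected fitness values (currency units).
#' @examples
#' m <- crd_model(Z = 10, N = 6, M = 3, a = 2, r = 0.7, p = 0.5)
#' fitness_cooperator(0:10, m)
#' fitness_defector(0:10, m)
#' @export
fitness_cooperator <- function(k, model) {
  stopifnot(inherits(model, "crd_model"))
  check_state(k, model$Z)
  s <- model$N - model$a - 1      # co-player seats
  i <- 0:s
  pi_c <- expected_payoff("C", i + 1, model)
  norm <- choose(model$Z - 1, s)
  vapply(k, function(kk) {
    if (kk == 0) return(0)
    sum(binom_safe(kk - 1, i) * binom_safe(model$Z - kk, s - i) * pi_c) / norm
  }, numeric(1))
}

#' @rdname fitness_cooperator
#' @export
fitness_defector <- function(k, model) {
  stopifnot(inherits(model, "crd_model"))
  check_state(k, model$Z)
  s <- model$N - model$a - 1
  i <- 0:s
  pi_d <- expected_payoff("D", i, model)
  norm <- choose(model$Z - 1, s)
  vapply(k, function(kk) {
    if (kk == model$Z) return(0)
    sum(binom_safe(kk, i) * binom_safe(model$Z - kk - 1, s - i) * pi_d) / norm
  }, numeric(1))
}

check_state <- function(k, Z) {
  if (any(k < 0 | k > Z | k != round(k))) {
    stop("population state `k` must be an integer in 0..Z.")
  }
  invisible(k)
}

#' Fermi pairwise-comparison imitation probability
#'
#' Probability that a focal player imitates a role model:
#' `1 / (1 + exp(-beta * (f_role_model - f_focal)))`. Strictly increasing in
#' the fitness difference; equals 1/2 at equal fitness or at `beta = 0`
#' (neutral drift). Computed overflow-safely.
#'
#' @param f_role_model,f_focal Fitness of the role model and of the focal
#'   player (vectorized).
#' @param beta Selection strength (>= 0).
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' fermi_probability(1, 1, beta = 2)    # 0.5
#' fermi_probability(0.9, 1, beta = 2)  # 1 / (1 + exp(0.2))
#' @export
fermi_probability <- function(f_role_model, f_focal, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stats::plogis(beta * (f_role_model - f_focal))
}

#' Birth-death transition probabilities of the social-learning chain
#'
#' One strategy-revision event: a focal individual is drawn uniformly from the
#' `Z` adaptive individuals; with probability `mu` it mutates to the opposite
#' strategy; otherwise it draws a role model uniformly among the other `Z - 1`
#' individuals (a no-op if their strategies match) and imitates with the Fermi
#' probability of [fermi_probability()]. The probability that the cooperator
#' count moves from `k` to `k + 1` (`transition_plus`) or `k - 1`
#' (`transition_minus`) is, in the default `"with-mutation"` convention,
#'
#' `T+(k) = ((Z-k)/Z) * (mu + (1-mu) * (k/(Z-1)) * P(D->C))`
#' `T-(k) = (k/Z)     * (mu + (1-mu) * ((Z-k)/(Z-1)) * P(C->D))`
#'
#' The `"printed"` convention drops the additive `mu` inflow, leaving only the
#' imitation term; its boundary states are then absorbing.
#'
#' @param k Population cooperator count, `0 <= k <= Z` (vectorized).
#' @param model A [crd_model()]; `model$transitions` selects the convention.
#' @return Numeric vector of probabilities.
#' @examples
#' m <- crd_model(Z = 10, a = 2, p = 0.5, r = 0.7)
#' transition_plus(0, m)   # mu: only mutation creates the first cooperator
#' transition_plus(10, m)  # 0: no defectors left
#' @export
transition_plus <- function(k, model) {
  stopifnot(inherits(model, "crd_model"))
  check_state(k, model$Z)
  Z <- model$Z
  p_dc <- fermi_probability(fitness_cooperator(k, model),
                            fitness_defector(k, model), model$beta)
  imit <- (1 - model$mu) * (k / (Z - 1)) * p_dc
  core <- if (model$transitions == "with-mutation") model$mu + imit else imit
  ((Z - k) / Z) * core
}

#' @rdname transition_plus
#' @export
transition_minus <- function(k, model) {
  stopifnot(inherits(model, "crd_model"))
  check_state(k, model$Z)
  Z <- model$Z
  p_cd <- fermi_probability(fitness_defector(k, model),
                            fitness_cooperator(k, model), model$beta)
  imit <- (1 - model$mu) * ((Z - k) / (Z - 1)) * p_cd
  core <- if (model$transitions == "with-mutation") model$mu + imit else imit
  (k / Z) * core
}

#' Row-stochastic transition matrix of the (Z+1)-state chain
#'
#' Tridiagonal matrix over states `k = 0..Z` with off-diagonals
#' `T+(k)`, `T-(k)` and diagonal `1 - T+(k) - T-(k)`; every row sums to 1.
#'
#' @param model A [crd_model()].
#' @return A `(Z+1) x (Z+1)` numeric matrix; rows/columns named `k0..kZ`.
#' @examples
#' S <- transition_matrix(crd_model(Z = 5, N = 3, M = 2, a = 1, p = 0.5, r = 0.5))
#' rowSums(S)
#' @export
transition_matrix <- function(model) {
  stopifnot(inherits(model, "crd_model"))
  Z <- model$Z
  k <- 0:Z
  tp <- transition_plus(k, model)
  tm <- transition_minus(k, model)
  S <- diag(1 - tp - tm)
  S[cbind(1:Z, 2:(Z + 1))] <- tp[1:Z]
  S[cbind(2:(Z + 1), 1:Z)] <- tm[2:(Z + 1)]
  dimnames(S) <- list(paste0("k", k), paste0("k", k))
  S
}

#' Stationary distribution of the social-learning Markov chain
#'
#' Computes the long-run probability `P(k)` of observing `k` cooperators among
#' the `Z` adaptive individuals. Two routes are computed:
#' * the closed-form birth-death product solution
#'   `P(k) proportional to prod_{j<k} T+(j) / T-(j+1)`, accumulated in log
#'   space — for a reversible birth-death chain this is exact and satisfies
#'   detailed balance to machine rounding, including in the far tails where
#'   `P(k)` underflows any dense eigen solve's per-component accuracy;
#' * the eigenvector of the transposed row-stochastic matrix whose eigenvalue
#'   is closest to 1, with numerical dust clipped at 0 and the vector
#'   renormalized.
#'
#' With the default `method = "eigen"` both routes are computed, a sup-norm
#' disagreement above `1e-8` is an error, and the product-form values are
#' returned as `distribution` (the eigenvector is kept in
#' `eigen_distribution`). `method = "product"` skips the eigen cross-check.
#' The chain must be ergodic: `mu > 0` and the `"with-mutation"` transition
#' convention.
#'
#' @param model A [crd_model()] with `mu > 0`.
#' @param method `"eigen"` (default; eigen-decomposition cross-check against
#'   the product form) or `"product"` (closed form only).
#' @return An object of class `crd_stationary`: list with `distribution`
#'   (numeric vector over `k = 0..Z`), `model`, `method`, `residual` (sup-norm
#'   difference between the two routes, `NA` for `method = "product"`),
#'   `eigen_distribution` (for `method = "eigen"`), and the transition
#'   vectors `tplus`, `tminus`.
#' @examples
#' st <- stationary_distribution(crd_model(a = 2, p = 0.5, r = 0.7))
#' sum(st$distribution)
#' avg_cooperation(st)
#' @export
stationary_distribution <- function(model, method = c("eigen", "product")) {
  stopifnot(inherits(model, "crd_model"))
  method <- match.arg(method)
  if (model$mu == 0) {
    stop("mu = 0: the boundary states are absorbing and the stationary ",
         "distribution is not unique. Use mu > 0.")
  }
  if (model$transitions == "printed") {
    stop("transitions = \"printed\": with no mutation inflow the boundary ",
         "states k = 0 and k = Z are absorbing, so the stationary ",
         "distribution is degenerate. Use transitions = \"with-mutation\".")
  }
  Z <- model$Z
  k <- 0:Z
  tp <- transition_plus(k, model)
  tm <- transition_minus(k, model)

  # closed-form birth-death solution, in log space
  log_ratio <- log(tp[1:Z]) - log(tm[2:(Z + 1)])
  log_pi <- c(0, cumsum(log_ratio))
  log_pi <- log_pi - max(log_pi)
  prod_form <- exp(log_pi) / sum(exp(log_pi))

  eigen_dist <- NULL
  residual <- NA_real_
  if (method == "eigen") {
    S <- transition_matrix(model)
    e <- eigen(t(S))
    idx <- which.min(abs(e$values - 1))
    v <- abs(Re(e$vectors[, idx]))
    eigen_dist <- v / sum(v)
    residual <- max(abs(eigen_dist - prod_form))
    if (residual > 1e-8) {
      stop(sprintf(
        "eigenvector and product-form stationary solutions disagree (sup-norm %.3e > 1e-8).",
        residual
      ))
    }
  }
  structure(
    list(distribution = stats::setNames(prod_form, paste0("k", k)),
         model = model, method = method, residual = residual,
         eigen_distribution = eigen_dist,
         tplus = tp, tminus = tm),
    class = "crd_stationary"
  )
}

#' @export
print.crd_stationary <- function(x, ...) {
  m <- x$model
  cat("<crd_stationary>\n")
  cat(sprintf("  states: k = 0..%d   method: %s", m$Z, x$method))
  if (!is.na(x$residual)) cat(sprintf("   (cross-check residual %.2e)", x$residual))
  cat("\n")
  cat(sprintf("  cooperation level: %.4f   group success: %.4f\n",
              avg_cooperation(x), avg_group_success(x)))
  invisible(x)
}
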