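# Independent oracles used across the suite.

# Expected fitness by exhaustive enumeration of every co-player subset:
# the focal player's N-a-1 co-players are all subsets of the other Z-1
# individuals; average the hybrid expected payoff over them. No
# hypergeometric shortcut.
brute_fitness <- function(strategy, k, model) {
  Z <- model$Z
  seats <- model$N - model$a - 1
  # others: 1 = cooperator, 0 = defector, with the focal player removed
  others <- if (strategy == "C") {
    c(rep(1L, k - 1L), rep(0L, Z - k))
  } else {
    c(rep(1L, k), rep(0L, Z - k - 1L))
  }
  sets <- utils::combn(Z - 1L, seats)
  vals <- apply(sets, 2, function(idx) {
    i <- sum(others[idx])
    if (strategy == "C") expected_payoff("C", i + 1L, model)
    else expected_payoff("D", i, model)
  })
  mean(vals)
}

# Stationary vector of a small chain by direct linear solve of pi S = pi
# with the normalization constraint (independent of both package routes).
linear_solve_stationary <- function(S) {
  n <- nrow(S)
  A <- rbind(t(S) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  qr.solve(A, b)
}

# Total variation distance between two distributions on the same support.
tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# A small model used repeatedly: cheap to enumerate, still hybrid.
toy_model <- function(...) {
  args <- utils::modifyList(
    list(Z = 10, N = 6, M = 3, a = 2, r = 0.7, p = 0.5, mu = 0.01, beta = 2),
    list(...)
  )
  do.call(crd_model, args)
}
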