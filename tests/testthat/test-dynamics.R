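test_that("binom_safe returns 0 outside the binomial domain", {
  expect_equal(binom_safe(5, 2), 10)
  expect_equal(binom_safe(-1, 0), 0)   # choose(-1, 0) would be 1
  expect_equal(binom_safe(3, 5), 0)
  expect_equal(binom_safe(0, 0), 1)
  expect_equal(binom_safe(c(5, -1, 3), c(2, 0, 5)), c(10, 0, 0))
})

test_that("hypergeometric fitness matches exhaustive co-player enumeration", {
  m <- toy_model()
  for (k in c(1, 4, 9)) {
    expect_equal(fitness_cooperator(k, m), brute_fitness("C", k, m),
                 tolerance = 1e-12)
  }
  for (k in c(0, 4, 9)) {
    expect_equal(fitness_defector(k, m), brute_fitness("D", k, m),
                 tolerance = 1e-12)
  }
})

test_that("fitness boundary and degenerate cases follow the conventions", {
  m <- toy_model()
  expect_equal(fitness_cooperator(0, m), 0)   # no such focal player
  expect_equal(fitness_defector(m$Z, m), 0)
  # k = Z: every co-player cooperates
  expect_equal(fitness_cooperator(m$Z, m),
               expected_payoff("C", m$N - m$a, m))
  # k = 0: every co-player defects
  expect_equal(fitness_defector(0, m), expected_payoff("D", 0, m))
  # risk-free game: payoffs composition-independent
  m0 <- update_model(m, r = 0, a = 0)
  expect_equal(fitness_cooperator(1:10, m0), rep(0.9, 10))
  expect_equal(fitness_defector(0:9, m0), rep(1, 10))
  expect_error(fitness_cooperator(11, m), "0..Z")
})

test_that("fitness hypergeometric weights are a probability distribution", {
  # Vandermonde: sum_i C(k-1,i) C(Z-k, N-a-1-i) = C(Z-1, N-a-1)
  for (m in list(toy_model(), crd_model(Z = 30, N = 6, M = 3, a = 3, r = .5, p = .5),
                 crd_model(Z = 100, N = 6, M = 3, a = 0, r = .5))) {
    s <- m$N - m$a - 1
    for (k in c(1, m$Z %/% 2, m$Z)) {
      expect_equal(sum(binom_safe(k - 1, 0:s) * binom_safe(m$Z - k, s - (0:s))),
                   choose(m$Z - 1, s))
    }
  }
})

test_that("Fermi probability behaves as a logistic in the fitness difference", {
  expect_equal(fermi_probability(1, 1, beta = 2), 0.5)
  expect_equal(fermi_probability(0.3, 0.9, beta = 0), 0.5)
  expect_equal(fermi_probability(0.9, 1.0, beta = 2), 1 / (1 + exp(0.2)))
  d <- seq(-1, 1, by = 0.1)
  pr <- fermi_probability(d, 0, beta = 3)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr > 0 & pr < 1))
  # overflow-safe at extreme differences
  expect_equal(fermi_probability(1e6, 0, beta = 700), 1)
  expect_equal(fermi_probability(-1e6, 0, beta = 700), 0)
})

test_that("transition probabilities have the correct structure and limits", {
  m <- toy_model()
  Z <- m$Z
  expect_equal(transition_plus(Z, m), 0)       # no defectors left
  expect_equal(transition_plus(0, m), m$mu)    # mutation creates the first C
  expect_equal(transition_minus(0, m), 0)
  expect_equal(transition_minus(Z, m), m$mu)
  # neutral imitation only: mu = 0, beta = 0 at k = Z/2
  m00 <- update_model(m, mu = 0, beta = 0)
  expect_equal(transition_plus(Z / 2, m00), (1 / 2) * ((Z / 2) / (Z - 1)) * (1 / 2))
  # neutrality relabeling symmetry T-(k) = T+(Z-k)
  mb0 <- update_model(m, beta = 0)
  expect_equal(transition_minus(0:Z, mb0), transition_plus(Z - (0:Z), mb0))
  # printed convention drops the mutation inflow
  mp <- update_model(m, transitions = "printed")
  expect_equal(transition_plus(0, mp), 0)
  k <- 3
  expect_equal(transition_plus(k, mp),
               transition_plus(k, m) - ((Z - k) / Z) * m$mu)
})

test_that("transition matrix is row-stochastic and tridiagonal", {
  m <- toy_model()
  S <- transition_matrix(m)
  expect_equal(rowSums(S), rep(1, m$Z + 1), ignore_attr = TRUE)
  expect_true(all(S >= 0 & S <= 1))
  off <- abs(row(S) - col(S)) > 1
  expect_true(all(S[off] == 0))
  # mu = 0: boundary states absorbing
  S0 <- transition_matrix(update_model(m, mu = 0))
  expect_equal(S0[1, 1], 1)
  expect_equal(S0[m$Z + 1, m$Z + 1], 1)
})

test_that("stationary distribution matches a direct linear solve on a tiny chain", {
  m <- crd_model(Z = 2, N = 3, M = 2, a = 1, p = 0.5, r = 0.5,
                 mu = 0.5, beta = 0)
  st <- stationary_distribution(m)
  oracle <- linear_solve_stationary(transition_matrix(m))
  expect_equal(unname(st$distribution), unname(oracle), tolerance = 1e-12)
})

test_that("eigenvector and product-form routes agree and satisfy detailed balance", {
  for (m in list(toy_model(), crd_scenario("a3", r = 0.9, p = 0.2),
                 crd_scenario("a2", r = 0.2, p = 0.8))) {
    st <- stationary_distribution(m)
    Z <- m$Z
    expect_equal(sum(st$distribution), 1, tolerance = 1e-12)
    expect_true(all(st$distribution >= 0))
    expect_lt(st$residual, 1e-10)
    expect_equal(unname(st$distribution),
                 unname(stationary_distribution(m, method = "product")$distribution))
    # detailed balance, relative per state
    lhs <- st$distribution[1:Z] * st$tplus[1:Z]
    rhs <- st$distribution[2:(Z + 1)] * st$tminus[2:(Z + 1)]
    expect_lt(max(abs(lhs - rhs) / rhs), 1e-10)
  }
})

test_that("stationary solve refuses non-ergodic chains", {
  expect_error(stationary_distribution(toy_model(mu = 0)), "mu = 0")
  expect_error(stationary_distribution(toy_model(transitions = "printed")),
               "printed")
})

test_that("neutral selection gives the symmetric chain and half cooperation", {
  st <- stationary_distribution(crd_scenario("a2", r = 0.7, p = 0.5, beta = 0))
  expect_equal(unname(st$distribution), rev(unname(st$distribution)),
               tolerance = 1e-12)
  expect_equal(avg_cooperation(st), 0.5, tolerance = 1e-12)
})
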