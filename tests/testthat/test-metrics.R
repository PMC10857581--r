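test_that("average cooperation is the stationary mean fraction of cooperators", {
  m <- toy_model()
  st <- stationary_distribution(m)
  # hand-weighted mean over the same vector
  expect_equal(avg_cooperation(st),
               sum(st$distribution * (0:m$Z) / m$Z))
  # point mass / uniform limits via a doctored copy
  point <- st
  point$distribution[] <- 0
  point$distribution[m$Z + 1] <- 1
  expect_equal(avg_cooperation(point), 1)
  unif <- st
  unif$distribution[] <- 1 / (m$Z + 1)
  expect_equal(avg_cooperation(unif), 0.5)
})

test_that("per-state group success handles the degenerate compositions", {
  # a >= M and p = 1: the block alone always meets the threshold
  m1 <- crd_model(Z = 20, N = 6, M = 3, a = 3, p = 1, r = 0.5)
  expect_equal(group_success_state(0:20, m1), rep(1, 21))
  # k = 0: only h = 0 has weight
  m2 <- crd_model(Z = 20, N = 6, M = 3, a = 4, p = 0.3, r = 0.5)
  expect_equal(group_success_state(0, m2), 0.3 * heaviside(4 - 3))
  expect_equal(group_success_state(0, update_model(m2, a = 2, p = 0.3)), 0)
  # k = Z with N - a >= M: full groups always succeed
  m3 <- crd_model(Z = 20, N = 6, M = 3, a = 2, p = 0, r = 0.5)
  expect_equal(group_success_state(20, m3), 1)
})

test_that("per-state group success matches Monte Carlo hypergeometric sampling", {
  m <- toy_model()          # Z = 10, N - a = 4, M = 3, p = 0.5
  set.seed(421)
  n <- 2e5
  for (k in c(3, 6, 9)) {
    h <- rhyper(n, k, m$Z - k, m$N - m$a)
    block <- runif(n) < m$p
    est <- mean(heaviside(h + ifelse(block, m$a, 0) - m$M))
    exact <- group_success_state(k, m)
    se <- sqrt(exact * (1 - exact) / n)
    expect_lt(abs(est - exact), 4 * se + 1e-12)
  }
})

test_that("per-state success is monotone in k and affine in p", {
  set.seed(77)
  for (i in 1:5) {
    a <- sample(0:4, 1)
    m <- crd_model(Z = 30, N = 6, M = sample(1:6, 1), a = a,
                   p = runif(1), r = runif(1))
    sg <- group_success_state(0:30, m)
    expect_true(all(diff(sg) >= -1e-14))
    # affine in p at fixed k: midpoint equals mean of endpoints
    k <- sample(0:30, 1)
    lo <- group_success_state(k, update_model(m, p = 0))
    hi <- group_success_state(k, update_model(m, p = 1))
    expect_equal(group_success_state(k, update_model(m, p = 0.5)),
                 (lo + hi) / 2)
  }
})

test_that("success weights satisfy the Vandermonde identity", {
  m <- toy_model()
  nad <- m$N - m$a
  for (k in 0:m$Z) {
    expect_equal(sum(binom_safe(k, 0:nad) * binom_safe(m$Z - k, nad - (0:nad))),
                 choose(m$Z, nad))
  }
})

test_that("average group success is the stationary-weighted per-state success", {
  m <- toy_model()
  st <- stationary_distribution(m)
  expect_equal(avg_group_success(st),
               sum(st$distribution * group_success_state(0:m$Z, m)))
  # constant per-state success propagates unchanged
  m1 <- update_model(m, a = 3, p = 1)
  expect_equal(avg_group_success(stationary_distribution(m1)), 1)
  rep <- crd_metrics(m)
  expect_equal(rep$group_success, sum(rep$states$prob * rep$states$success))
  expect_equal(rep$coop_level, avg_cooperation(st))
  expect_true(all(rep$states$prob >= 0 & rep$states$success >= 0 &
                    rep$states$success <= 1))
})

test_that("control deltas compare hybrid and control populations correctly", {
  m <- toy_model(Z = 30)
  for (mode in c("substitution", "addition")) {
    d <- control_delta(m, mode)
    expect_equal(d$delta_coop, d$hybrid$coop_level - d$control$coop_level)
    expect_equal(d$delta_success,
                 d$hybrid$group_success - d$control$group_success)
    # antisymmetry: swapping the roles negates the deltas
    expect_equal(d$control$coop_level - d$hybrid$coop_level, -d$delta_coop)
  }
  sub <- control_delta(m, "substitution")
  add <- control_delta(m, "addition")
  expect_equal(sub$control$model$N, m$N)
  expect_equal(add$control$model$N, m$N - m$a)
  # identical specs give exactly zero delta
  ctl <- control_model(m, "substitution")
  expect_identical(crd_metrics(ctl)$coop_level, crd_metrics(ctl)$coop_level)
  expect_equal(crd_metrics(ctl)$coop_level - crd_metrics(ctl)$coop_level, 0)
})

test_that("evaluate_point returns a tidy row per population", {
  m <- toy_model(Z = 30)
  tab <- evaluate_point(m, controls = c("substitution", "addition"))
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$role,
               c("hybrid", "control_substitution", "control_addition"))
  expect_equal(tab$N, c(6, 6, 4))
  expect_true(is.na(tab$delta_coop[1]))
  d <- control_delta(m, "addition")
  expect_equal(tab$delta_coop[3], d$delta_coop)
  expect_equal(tab$delta_success[3], d$delta_success)
  # a = 0 control rows are independent of the hybrid's p
  tab2 <- evaluate_point(update_model(m, p = 0.9), controls = "substitution")
  expect_equal(tab2$coop_level[2], tab$coop_level[2])
})
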