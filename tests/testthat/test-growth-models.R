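test_that("growth_params validates its invariants", {
  expect_s3_class(growth_params(0.5, 1e6, 1e4), "growth_params")
  expect_error(growth_params(NA, 1e6, 1e4), "finite")
  expect_error(growth_params(Inf, 1e6, 1e4), "finite")
  expect_error(growth_params(-0.1, 1e6, 1e4), "non-negative")
  expect_error(growth_params(0.5, 0, 1e4), "positive")
  expect_error(growth_params(0.5, 1e6, 0), "positive")
  expect_error(growth_params(0.5, 1e6, 1e4, v = 0), "positive")
})

test_that("Verhulst closed form: equilibria and the analytic midpoint", {
  # seeded at capacity: stays at capacity
  p_eq <- growth_params(r = 0.7, K = 5e5, N0 = 5e5)
  expect_equal(verhulst_solution(p_eq, c(0, 3, 40)), rep(5e5, 3))
  # no growth
  p0 <- growth_params(r = 0, K = 5e5, N0 = 2e4)
  expect_equal(verhulst_solution(p0, c(0, 10, 40)), rep(2e4, 3))
  # N0=1, K=100, r=1: N(ln 99) = K/2 = 50 exactly
  p <- growth_params(r = 1, K = 100, N0 = 1)
  expect_equal(verhulst_solution(p, log(99)), 50)
  # and the closed form agrees with direct numerical integration
  num <- rk4_fixed(function(t, y) y * 1 * (1 - y / 100), 1, log(99), 1e-4)
  expect_equal(verhulst_solution(p, log(99)), num, tolerance = 1e-8)
  expect_error(verhulst_solution(p, -1), "non-negative")
})

test_that("growth-law right-hand sides match their defining forms", {
  p <- growth_params(r = 0.9, K = 2e6, N0 = 1e4, v = 2.5)
  expect_equal(growth_rhs("richards", p, 2e6), 0)  # at capacity
  expect_equal(growth_rhs("verhulst", p, 0), 0)
  expect_equal(growth_rhs("gompertz", p, 0), 0)    # defined limit
  expect_error(growth_rhs("verhulst", p, -5), "non-negative")

  # Richards with v = 1 is the Verhulst model, pointwise
  set.seed(11)
  for (i in 1:20) {
    r <- runif(1, 0.1, 2); K <- runif(1, 1e4, 1e7); N <- runif(1, 0, K)
    p1 <- growth_params(r, K, N0 = 1, v = 1)
    expect_equal(growth_rhs("richards", p1, N), growth_rhs("verhulst", p1, N))
  }

  # Gompertz at N = K/e with r = 1, K = e gives dN/dt = 1
  pg <- growth_params(r = 1, K = exp(1), N0 = 0.1)
  expect_equal(growth_rhs("gompertz", pg, exp(1) / exp(1)), 1)
  # and matches a central finite difference of the Gompertz closed form
  h <- 1e-6
  t_star <- 1.3
  slope_fd <- (growth_solution("gompertz", pg, t_star + h) -
                 growth_solution("gompertz", pg, t_star - h)) / (2 * h)
  N_star <- growth_solution("gompertz", pg, t_star)
  expect_equal(growth_rhs("gompertz", pg, N_star), slope_fd,
               tolerance = 1e-7)
})

test_that("ODE trajectories agree with closed forms and an RK4 oracle", {
  set.seed(21)
  # Verhulst: sup-norm relative error < 1e-6 across random parameter sets
  worst <- 0
  for (i in 1:100) {
    p <- growth_params(r = runif(1, 0.1, 1.5), K = 10^runif(1, 4, 7),
                       N0 = 10^runif(1, 2, 4))
    tg <- seq(0, 40, length.out = 41)
    sim <- simulate_growth("verhulst", p, tg)
    worst <- max(worst, max(abs(sim$count - verhulst_solution(p, tg))) / p$K)
  }
  expect_lt(worst, 1e-6)

  # r = 0: flat trajectory
  pf <- growth_params(r = 0, K = 1e6, N0 = 5e3)
  expect_equal(simulate_growth("verhulst", pf, 0:10)$count, rep(5e3, 11))

  # Richards v=2 at t=10 against a fine fixed-step RK4 oracle
  p2 <- growth_params(r = 0.5, K = 1000, N0 = 10, v = 2)
  sim2 <- simulate_growth("richards", p2, c(0, 10))
  oracle <- rk4_fixed(function(t, y) growth_rhs("richards", p2, y),
                      10, 10, 1e-4)
  expect_equal(sim2$count[2], oracle, tolerance = 1e-5)
  expect_error(simulate_growth("verhulst", p2, 1:5), "start at 0")
})

test_that("clone system validates inputs and reduces to the logistic case", {
  expect_error(clone_system(c("a", "a"), c(1, 1), c(1e6, 1e6)), "unique")
  expect_error(clone_system(c("a", "b"), c(1, 1), c(1e6, -1)), "> 0")
  sys <- clone_system(c("a", "b"), c(1, 0.5), c(1e6, 2e6))
  expect_error(simulate_clones(sys, 0:5, state = c(1e3, 1e3, 1e3)),
               "does not match")

  # n = 1 reduces exactly to the Verhulst solution
  one <- clone_system("solo", r = 0.8, K = 1e6, state = 1e4)
  traj <- simulate_clones(one, 0:20)
  p <- growth_params(0.8, 1e6, 1e4)
  expect_equal(as.numeric(traj[, 1]), verhulst_solution(p, 0:20),
               tolerance = 1e-7)
})

test_that("symmetric clones split the capacity; inert clones stay put", {
  sys <- clone_system(c("x", "y"), r = c(0.6, 0.6), K = c(1e6, 1e6),
                      state = c(1e4, 1e4))
  tg <- seq(0, 60, 2)
  traj <- simulate_clones(sys, tg)
  expect_equal(traj[, "x"], traj[, "y"])  # exact symmetry
  expect_equal(as.numeric(traj[nrow(traj), ]), c(5e5, 5e5), tolerance = 1e-4)
  # against the RK4 oracle at the final time
  oracle <- rk4_fixed(function(t, y) y * 0.6 * (1 - sum(y / 1e6)),
                      c(1e4, 1e4), 60, 1e-3)
  expect_equal(as.numeric(traj[nrow(traj), ]), oracle, tolerance = 1e-6)

  # a clone with r = 0 is inert while the other grows; zero-size stays zero
  sys2 <- clone_system(c("grow", "inert", "absent"), r = c(1, 0, 1),
                       K = c(1e6, 1e6, 1e6), state = c(1e4, 5e3, 0))
  tr2 <- simulate_clones(sys2, 0:30)
  expect_equal(tr2[, "inert"], rep(5e3, 31))
  expect_equal(tr2[, "absent"], rep(0, 31))
  expect_gt(tr2[31, "grow"], 1e4)
})

test_that("growth is never negative below the capacity surface", {
  # numerical check of the nonnegativity guarantee: with occupancy
  # sum N_i(0)/K_i < 1, dN_i/dt >= 0 along the whole trajectory
  set.seed(31)
  min_deriv <- Inf
  for (i in 1:100) {
    n <- sample(2:5, 1)
    K <- 10^runif(n, 5, 7)
    r <- runif(n, 0.05, 1.5)
    occ0 <- runif(1, 0.05, 0.95)
    w <- runif(n); w <- w / sum(w)
    state <- occ0 * w * K  # sum(state/K) = occ0 < 1
    sys <- clone_system(paste0("c", 1:n), r, K, state = state)
    traj <- simulate_clones(sys, seq(0, 30, 0.5))
    for (row in seq_len(nrow(traj))) {
      min_deriv <- min(min_deriv, min(clonesteer:::clone_rhs(sys, traj[row, ])))
    }
  }
  expect_gte(min_deriv, -1e-9)
})

test_that("the long-time limit sits on the capacity surface", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    K <- 10^runif(n, 5, 6)
    r <- runif(n, 0.4, 1.2)
    sys <- clone_system(paste0("c", 1:n), r, K,
                        state = runif(n, 1e2, 1e3))
    traj <- simulate_clones(sys, c(0, 200))
    occ <- sum(traj[2, ] / K)
    expect_lt(abs(occ - 1), 1e-4)
  }
})
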