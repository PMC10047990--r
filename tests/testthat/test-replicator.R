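test_that("mean fitness and fitness variance match hand-computed values", {
  cases <- list(
    list(p = c(0.5, 0.5), f = c(1, 0), mean = 0.5, var = 0.25),
    list(p = c(1, 0), f = c(3, 7), mean = 3, var = 0),
    list(p = c(0.2, 0.3, 0.5), f = c(1, 2, 3), mean = 2.3, var = 0.61),
    list(p = c(0.2, 0.3, 0.5), f = c(4, 4, 4), mean = 4, var = 0)
  )
  for (cs in cases) {
    m <- constant_fitness(cs$f)
    expect_equal(mean_fitness(cs$p, m), cs$mean, tolerance = 1e-12)
    expect_equal(fitness_variance(cs$p, m), cs$var, tolerance = 1e-12)
  }
})

test_that("replicator right-hand side matches hand values and conserves mass", {
  expect_equal(replicator_rhs(c(0.5, 0.5), constant_fitness(c(1, 0))),
               c(0.25, -0.25))
  expect_equal(replicator_rhs(c(1, 0), constant_fitness(c(5, -2))), c(0, 0))
  expect_equal(replicator_rhs(c(0.2, 0.3, 0.5), constant_fitness(c(2, 2, 2))),
               c(0, 0, 0))

  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    p <- rand_simplex(n)
    m <- if (i %% 2) constant_fitness(rnorm(n))
         else payoff_fitness(matrix(rnorm(n * n), n, n))
    expect_lt(abs(sum(replicator_rhs(p, m))), 1e-14)
  }
})

test_that("Lotka-Volterra right-hand side is the componentwise growth law", {
  expect_equal(lotka_volterra_rhs(c(1, 1), constant_fitness(c(1, 0))),
               c(1, 0))
  expect_equal(lotka_volterra_rhs(c(2, 3), constant_fitness(c(0, 0))),
               c(0, 0))
  expect_equal(lotka_volterra_rhs(c(1, 2), constant_fitness(c(1, 1))),
               c(1, 2))
  expect_error(lotka_volterra_rhs(c(1, 0), constant_fitness(c(1, 0))),
               class = "NonPositiveCount")
})

test_that("closed-form constant-fitness solution behaves as an exact oracle", {
  expect_equal(as.numeric(
    constant_fitness_closed_form(c(0.5, 0.5), c(1, 0), log(3))),
    c(0.75, 0.25), tolerance = 1e-14)
  expect_equal(as.numeric(
    constant_fitness_closed_form(c(0.3, 0.7), c(2, -1), 0)),
    c(0.3, 0.7))
  # common growth cancels
  expect_equal(as.numeric(
    constant_fitness_closed_form(c(0.3, 0.7), c(5, 5), 12.3)),
    c(0.3, 0.7), tolerance = 1e-14)
  # log-sum-exp shift keeps huge f*t finite
  p_far <- constant_fitness_closed_form(c(0.5, 0.5), c(100, 0), 50)
  expect_equal(as.numeric(p_far), c(1, 0), tolerance = 1e-12)
})

test_that("the integrator reproduces the closed-form solution", {
  sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
                 t_span = c(0, 10), n_points = 201)
  traj <- simulate_replicator(sc)
  exact <- constant_fitness_closed_form(c(0.5, 0.5), c(1, 0), traj$times)
  expect_lt(max(abs(traj$states - exact)), 1e-6)

  set.seed(22)
  for (i in 1:5) {
    n <- sample(2:5, 1)
    sc <- generate_random_scenario(n, "constant", seed = 100 + i)
    traj <- simulate_replicator(sc)
    exact <- constant_fitness_closed_form(sc$p0, sc$fitness$f, traj$times)
    expect_lt(max(abs(traj$states - exact)), 1e-6)
  }
})

test_that("neutral landscapes and vertices are stationary", {
  sc <- scenario(constant_fitness(c(2, 2, 2)), p0 = c(0.2, 0.3, 0.5),
                 t_span = c(0, 5), n_points = 21)
  traj <- simulate_replicator(sc)
  expect_lt(max(abs(sweep(traj$states, 2, c(0.2, 0.3, 0.5)))), 1e-9)

  sc_v <- scenario(constant_fitness(c(0, 3)), p0 = c(1, 0),
                   t_span = c(0, 5), n_points = 21)
  traj_v <- simulate_replicator(sc_v)
  expect_lt(max(abs(sweep(traj_v$states, 2, c(1, 0)))), 1e-9)
})

test_that("probability mass is conserved along random trajectories", {
  kinds <- c("constant", "linear-symmetric", "linear-zero-sum")
  for (i in 1:15) {
    sc <- generate_random_scenario(2 + i %% 4, kinds[1 + i %% 3],
                                   seed = 300 + i)
    traj <- simulate_replicator(sc)
    expect_lt(max(abs(rowSums(traj$states) - 1)), 1e-8)
  }
})

test_that("normalized Lotka-Volterra integration matches the replicator route", {
  sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
                 t_span = c(0, log(3)), n_points = 51)
  lv <- simulate_lv_normalized(sc, c(1, 1))
  expect_equal(as.numeric(lv$states[51, ]), c(0.75, 0.25), tolerance = 1e-6)

  for (i in 1:6) {
    sc <- generate_random_scenario(2 + i %% 3,
                                   c("constant", "linear-symmetric",
                                     "linear-zero-sum")[1 + i %% 3],
                                   seed = 400 + i)
    traj <- simulate_replicator(sc)
    lv <- simulate_lv_normalized(sc, 10 * as.numeric(sc$p0))
    expect_lt(max(abs(traj$states - lv$states)), 1e-6)
  }

  expect_error(simulate_lv_normalized(sc, c(1, 1, 1)),
               class = "DimensionMismatch")
})

test_that("the abundance overflow guard leaves normalized states unchanged", {
  # strong sustained growth drives sum(P) far past the rescaling threshold
  sc <- scenario(constant_fitness(c(4, 3.5)), p0 = c(0.5, 0.5),
                 t_span = c(0, 12), n_points = 61)
  lv <- simulate_lv_normalized(sc, c(1e10, 1e10))
  traj <- simulate_replicator(sc)
  expect_lt(max(abs(traj$states - lv$states)), 1e-6)
})

test_that("equilibria are reported with residuals, kinds and flags", {
  rep_c <- find_equilibria(constant_fitness(c(1, 0)), 2)
  expect_equal(rep_c$kinds, c("vertex", "vertex"))
  expect_false(rep_c$neutral)
  expect_true(all(rep_c$residuals < 1e-8))

  rep_n <- find_equilibria(constant_fitness(c(2, 2)), 2)
  expect_true(rep_n$neutral)

  rep_rps <- find_equilibria(payoff_fitness(rps_payoff()), 3)
  expect_true("interior" %in% rep_rps$kinds)
  p_int <- rep_rps$points[[which(rep_rps$kinds == "interior")]]
  expect_equal(as.numeric(p_int), rep(1 / 3, 3), tolerance = 1e-12)
  expect_true(all(rep_rps$residuals < 1e-8))

  rep_sing <- find_equilibria(payoff_fitness(matrix(0, 3, 3)), 3)
  expect_true(rep_sing$singular)
  expect_equal(rep_sing$kinds, rep("vertex", 3))

  expect_error(find_equilibria(custom_fitness(identity, 3), 3),
               class = "SchemaError")
  expect_error(find_equilibria(constant_fitness(c(1, 0)), 3),
               class = "DimensionMismatch")
})

test_that("rate of mean-fitness increase equals the fitness variance", {
  # Fisher's fundamental theorem under a constant landscape
  sc <- scenario(constant_fitness(c(1, 0.4, 0)), p0 = c(0.2, 0.3, 0.5),
                 t_span = c(0, 2), n_points = 2001,
                 solver = solver_settings(rtol = 1e-10, atol = 1e-12))
  traj <- simulate_replicator(sc)
  dt <- diff(traj$times[1:2])
  dphi <- central_diff(traj$observables$mean_fitness, dt)
  interior <- 2:(length(traj$times) - 1)
  expect_lt(max(abs(dphi - traj$observables$fitness_variance[interior])),
            1e-5)
})

test_that("the fittest type's share increases monotonically to fixation", {
  sc <- scenario(constant_fitness(c(0.2, 1.1, 0.7)), p0 = c(0.5, 0.2, 0.3),
                 t_span = c(0, 25), n_points = 301)
  traj <- simulate_replicator(sc)
  p_best <- traj$states[, 2]
  interior <- p_best > 0 & p_best < 1 - 1e-12
  expect_true(all(diff(p_best[interior]) > 0))
  expect_gt(p_best[length(p_best)], 0.999)
})
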