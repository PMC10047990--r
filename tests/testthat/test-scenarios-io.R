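test_that("scenario JSON round-trips byte-identically", {
  sc <- scenario(payoff_fitness(rps_payoff()), p0 = c(0.2, 0.3, 0.5),
                 q = rep(1 / 3, 3), t_span = c(0, 50), n_points = 501)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f1)
  sc2 <- read_scenario(f1)
  write_scenario(sc2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.numeric(sc2$p0), as.numeric(sc$p0), tolerance = 1e-15)
  expect_equal(sc2$fitness$payoff, sc$fitness$payoff)
  expect_equal(sc2$t_span, sc$t_span)
})

test_that("malformed scenario JSON yields field-level schema errors", {
  good <- list(n = 2,
               fitness = list(kind = "constant", f_const = c(1, 0)),
               p0 = c(0.5, 0.5), t_span = c(0, 1), n_points = 11)
  write_case <- function(mod) {
    obj <- utils::modifyList(good, mod)
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(obj, f, auto_unbox = TRUE)
    f
  }
  expect_error(read_scenario(write_case(list(p0 = NULL))),
               class = "SchemaError", regexp = "p0")
  expect_error(
    read_scenario(write_case(list(
      fitness = list(kind = "linear",
                     payoff = list(c(0, 1, 2), c(1, 0, 1)))))),
    class = "SchemaError", regexp = "payoff")
  expect_error(
    read_scenario(write_case(list(fitness = list(kind = "quadratic")))),
    class = "SchemaError", regexp = "kind")
  expect_error(read_scenario(tempfile()), class = "SchemaError")
})

test_that("registered custom fitness survives the JSON round trip", {
  register_fitness("io_test_neglog", function(p) -log(pmax(p, 1e-12)))
  sc <- scenario(fitness_model("custom", name = "io_test_neglog", n = 3),
                 p0 = c(0.2, 0.3, 0.5), t_span = c(0, 1), n_points = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(fitness_values(sc2$fitness, c(0.2, 0.3, 0.5)),
               -log(c(0.2, 0.3, 0.5)))
})

test_that("trajectory CSV round-trips to 12 significant digits", {
  sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5), q = c(1, 0),
                 t_span = c(0, 1), n_points = 3)
  traj <- simulate_replicator(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  traj2 <- read_trajectory(f)
  expect_equal(traj2$times, traj$times, tolerance = 1e-12)
  expect_equal(traj2$states, traj$states, tolerance = 1e-12)
  expect_equal(traj2$observables$S, traj$observables$S, tolerance = 1e-12)
  expect_equal(traj2$observables$I_qp, traj$observables$I_qp,
               tolerance = 1e-12)
})

test_that("a target-free trajectory writes empty I columns and reads back NA", {
  sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
                 t_span = c(0, 1), n_points = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(simulate_replicator(sc), f)
  header <- readLines(f, n = 2)
  expect_match(header[1], "^t,p_1,p_2,S,S_dot,I_qp,I_dot,lagrangian")
  expect_match(header[2], ",,")   # empty fields for the missing observables
  traj2 <- read_trajectory(f)
  expect_true(all(is.na(traj2$observables$I_qp)))
  expect_false(anyNA(traj2$observables$S))
})

test_that("a malformed trajectory header raises FormatError", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time,a,b", "0,0.5,0.5"), f)
  expect_error(read_trajectory(f), class = "FormatError")
})

test_that("the random-scenario generator is seed-deterministic and exact", {
  s1 <- generate_random_scenario(4, "linear-zero-sum", seed = 99)
  s2 <- generate_random_scenario(4, "linear-zero-sum", seed = 99)
  expect_identical(s1$fitness$payoff, s2$fitness$payoff)
  expect_identical(as.numeric(s1$p0), as.numeric(s2$p0))
  expect_identical(s1$fitness$payoff, -t(s1$fitness$payoff))

  s3 <- generate_random_scenario(4, "linear-symmetric", seed = 7)
  expect_identical(s3$fitness$payoff, t(s3$fitness$payoff))

  for (seed in 1:5) {
    sc <- generate_random_scenario(3, "constant", seed = seed)
    expect_equal(sum(sc$p0), 1, tolerance = 1e-12)
    expect_true(all(sc$p0 >= 0))
  }

  # the caller's RNG stream is not disturbed
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_random_scenario(3, "constant", seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("the shipped scenario library is consistent", {
  lib <- scenario_library()
  expect_setequal(names(lib), c("two_type_selection", "neutral",
                                "rock_paper_scissors", "potential_game"))
  expect_false(anyDuplicated(vapply(lib, `[[`, "", "name")) > 0)
  for (entry in lib) {
    expect_s3_class(entry$scenario, "scenario")
    expect_true(nzchar(entry$description))
  }
})

test_that("the packaged example scenario loads and simulates", {
  path <- system.file("extdata", "two_type_selection.json",
                      package = "biocontinuum")
  expect_true(file.exists(path))
  sc <- read_scenario(path)
  traj <- simulate_replicator(sc)
  expect_lt(max(abs(rowSums(traj$states) - 1)), 1e-8)
})

test_that("the CLI subcommands run end to end with correct exit codes", {
  scf <- withr::local_tempfile(fileext = ".json")
  write_scenario(scenario_library()$two_type_selection$scenario, scf)

  out_csv <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--scenario", scf, "--out", out_csv))), 0L)
  traj <- read_trajectory(out_csv)
  expect_equal(nrow(traj$states), 201)

  out_json <- withr::local_tempfile(fileext = ".json")
  expect_equal(suppressMessages(
    run_cli(c("action", "--scenario", scf, "--out", out_json))), 0L)
  res <- jsonlite::read_json(out_json)
  expect_true(is.numeric(res$action))
  expect_equal(res$n_grid, 201)

  gen_json <- withr::local_tempfile(fileext = ".json")
  expect_equal(suppressMessages(
    run_cli(c("generate", "--n", "3", "--kind", "linear-zero-sum",
              "--seed", "11", "--out", gen_json))), 0L)
  expect_s3_class(read_scenario(gen_json), "scenario")

  geo_csv <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    run_cli(c("geometry", "--out", geo_csv, "--steps", "50"))), 0L)
  flow <- utils::read.csv(geo_csv)
  expect_true(all(c("step", "mu", "sigma", "objective") %in% names(flow)))
  expect_true(all(diff(flow$objective) <= 1e-14))

  # validation failures exit 2
  expect_equal(suppressMessages(run_cli(c("simulate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--scenario", tempfile(), "--out", out_csv))), 2L)
})
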