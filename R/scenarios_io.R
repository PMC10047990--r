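#' Read and write scenario JSON
#'
#' Scenarios are serialized as a JSON object
#' `{"n", "fitness": {"kind", "f_const" | "payoff" | "name"}, "p0", "q",
#'  "t_span", "n_points", "solver"}` with a fixed field order, so
#' write-then-read is the identity on canonical files.  Malformed files
#' raise `SchemaError` with a field-level message.
#'
#' @param path File path.
#' @return `read_scenario()` returns a [scenario()]; `write_scenario()`
#'   invisibly returns `path`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    bc_stop("SchemaError", sprintf("scenario file '%s' does not exist", path))
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  bc_stop("SchemaError",
                          sprintf("not valid JSON: %s", conditionMessage(e))))
  need <- function(field) {
    if (is.null(j[[field]]))
      bc_stop("SchemaError", sprintf("missing required field '%s'", field))
    j[[field]]
  }
  n <- as.integer(need("n"))
  fit <- need("fitness")
  if (is.null(fit$kind))
    bc_stop("SchemaError", "missing required field 'fitness.kind'")
  fitness <- switch(as.character(fit$kind),
    constant = {
      f <- fit$f_const
      if (is.null(f) || length(f) != n)
        bc_stop("SchemaError",
                sprintf("'fitness.f_const' must be a length-%d vector", n))
      constant_fitness(as.numeric(f))
    },
    linear = {
      A <- fit$payoff
      if (is.list(A)) A <- do.call(rbind, lapply(A, as.numeric))
      if (!is.matrix(A) || !all(dim(A) == c(n, n)))
        bc_stop("SchemaError",
                sprintf("'fitness.payoff' must be a %d x %d matrix", n, n))
      payoff_fitness(A)
    },
    custom = {
      if (is.null(fit$name))
        bc_stop("SchemaError", "'fitness.name' required for custom fitness")
      fitness_model("custom", name = fit$name, n = n)
    },
    bc_stop("SchemaError",
            sprintf("unknown fitness kind '%s'", fit$kind)))
  p0 <- as.numeric(need("p0"))
  if (length(p0) != n)
    bc_stop("SchemaError", sprintf("'p0' must have length %d", n))
  q <- if (!is.null(j$q) && length(j$q)) as.numeric(j$q) else NULL
  if (!is.null(q) && length(q) != n)
    bc_stop("SchemaError", sprintf("'q' must have length %d", n))
  t_span <- as.numeric(need("t_span"))
  if (length(t_span) != 2)
    bc_stop("SchemaError", "'t_span' must have length 2")
  solver <- if (!is.null(j$solver)) {
    s <- j$solver
    solver_settings(rtol = s$rtol %||% 1e-8, atol = s$atol %||% 1e-10,
                    prob_floor = s$prob_floor %||% 1e-12,
                    max_step = as.numeric(s$max_step %||% Inf))
  } else solver_settings()
  scenario(fitness, p0 = p0, q = q, t_span = t_span,
           n_points = as.integer(need("n_points")), solver = solver)
}

#' @rdname read_scenario
#' @param x A [scenario()] to serialize.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario"))
  fit <- switch(x$fitness$kind,
    constant = list(kind = "constant", f_const = x$fitness$f),
    linear   = list(kind = "linear",
                    payoff = apply(x$fitness$payoff, 1, as.numeric,
                                   simplify = FALSE)),
    custom   = {
      if (is.null(x$fitness$name))
        bc_stop("SchemaError",
                "only named (registered) custom fitness can be serialized")
      list(kind = "custom", name = x$fitness$name)
    })
  solver <- x$solver
  obj <- list(n = x$n, fitness = fit, p0 = as.numeric(x$p0),
              q = if (is.null(x$q)) NULL else as.numeric(x$q),
              t_span = x$t_span, n_points = x$n_points,
              solver = list(rtol = solver$rtol, atol = solver$atol,
                            prob_floor = solver$prob_floor,
                            max_step = solver$max_step))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export and import trajectories as CSV
#'
#' Columns `t, p_1..p_n, S, S_dot, I_qp, I_dot, lagrangian, mean_fitness,
#' fitness_variance`; the target-dependent columns are written empty when
#' the scenario had no q.  Values survive a round trip to at least 12
#' significant digits.  A malformed header raises `FormatError`.
#'
#' @param traj A `biocontinuum_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` invisibly returns `path`;
#'   `read_trajectory()` returns a `biocontinuum_trajectory` (without a
#'   scenario attached).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "biocontinuum_trajectory"))
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(col)
    ifelse(is.na(col), "", sprintf("%.15g", col)))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    bc_stop("FormatError", sprintf("trajectory file '%s' does not exist", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   bc_stop("FormatError",
                           sprintf("not valid CSV: %s", conditionMessage(e))))
  nm <- names(df)
  p_cols <- grep("^p_[0-9]+$", nm, value = TRUE)
  obs_cols <- c("S", "S_dot", "I_qp", "I_dot", "lagrangian",
                "mean_fitness", "fitness_variance")
  if (nm[1] != "t" || length(p_cols) < 2 || !all(obs_cols %in% nm))
    bc_stop("FormatError",
            "header must be t,p_1..p_n,S,S_dot,I_qp,I_dot,lagrangian,mean_fitness,fitness_variance")
  states <- as.matrix(df[, p_cols, drop = FALSE])
  dimnames(states) <- NULL
  obs <- df[, obs_cols]
  obs[] <- lapply(obs, as.numeric)
  new_trajectory(df$t, project_rows(states), obs, scenario = NULL)
}

#' Generate a random scenario with a fixed seed
#'
#' Draws the initial state from a flat Dirichlet distribution and the
#' landscape from standard-normal entries: a constant fitness vector, a
#' symmetrized payoff `(M + M') / 2` (potential game) or an antisymmetrized
#' payoff `(M - M') / 2` (zero-sum game).  The same seed always yields the
#' same scenario; the caller's RNG state is left untouched.
#'
#' @param n Number of types (>= 2).
#' @param kind `"constant"`, `"linear-symmetric"` or `"linear-zero-sum"`.
#' @param seed Integer seed.
#' @param t_span,n_points Output grid (defaults `c(0, 5)`, 101 points).
#' @param with_q If `TRUE`, attach a flat-Dirichlet target q.
#' @return A [scenario()].
#' @export
generate_random_scenario <- function(n, kind = c("constant",
                                                 "linear-symmetric",
                                                 "linear-zero-sum"),
                                     seed, t_span = c(0, 5),
                                     n_points = 101L, with_q = FALSE) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  rdirichlet1 <- function() {
    g <- stats::rgamma(n, shape = 1)
    g / sum(g)
  }
  p0 <- rdirichlet1()
  fitness <- switch(kind,
    "constant" = constant_fitness(stats::rnorm(n)),
    "linear-symmetric" = {
      M <- matrix(stats::rnorm(n * n), n, n)
      payoff_fitness((M + t(M)) / 2)
    },
    "linear-zero-sum" = {
      M <- matrix(stats::rnorm(n * n), n, n)
      payoff_fitness((M - t(M)) / 2)
    })
  q <- if (with_q) rdirichlet1() else NULL
  scenario(fitness, p0 = p0, q = q, t_span = t_span, n_points = n_points)
}

#' Shipped scenario library
#'
#' Named reference scenarios used throughout the documentation and tests:
#'
#' * `two_type_selection`: constant fitness `c(1, 0)` from the uniform
#'   state with the dominant vertex as target — textbook selective sweep
#'   with a closed-form solution;
#' * `neutral`: equal constant fitness — the drift-free flow that leaves
#'   every state fixed;
#' * `rock_paper_scissors`: the antisymmetric cyclic payoff with uniform
#'   interior equilibrium; I(q, p(t)) is conserved around it;
#' * `potential_game`: a symmetric payoff whose mean fitness ascends
#'   monotonically along the flow.
#'
#' @return Named list of entries, each `list(name, scenario, description)`.
#' @export
scenario_library <- function() {
  rps <- rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))
  entries <- list(
    two_type_selection = list(
      name = "two_type_selection",
      scenario = scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
                          q = c(1, 0), t_span = c(0, 10), n_points = 201L),
      description = "selective sweep toward the fitter of two types"),
    neutral = list(
      name = "neutral",
      scenario = scenario(constant_fitness(c(1, 1)), p0 = c(0.3, 0.7),
                          t_span = c(0, 10), n_points = 201L),
      description = "neutral landscape; the state never moves"),
    rock_paper_scissors = list(
      name = "rock_paper_scissors",
      scenario = scenario(payoff_fitness(rps), p0 = c(0.2, 0.3, 0.5),
                          q = rep(1 / 3, 3), t_span = c(0, 50),
                          n_points = 1001L,
                          solver = solver_settings(rtol = 1e-10,
                                                   atol = 1e-12)),
      description = "zero-sum cycling; I(q, p) conserved around the interior equilibrium"),
    potential_game = list(
      name = "potential_game",
      scenario = scenario(payoff_fitness(rbind(c(1, 0), c(0, 2))),
                          p0 = c(0.7, 0.3), t_span = c(0, 20),
                          n_points = 201L),
      description = "symmetric payoff; mean fitness ascends under the Shahshahani gradient")
  )
  entries
}
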