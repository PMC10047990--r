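#' Validate a probability vector as a state distribution
#'
#' A state distribution is a point on the (n-1)-simplex: the probability
#' fractions of the n discernible state types of the biological continuum
#' (equivalently, the proportions of n competing types in a population).
#' Entries must be non-negative and sum to one; tiny numerical deviations
#' are repaired by renormalization.
#'
#' @param v Numeric vector of length >= 2.  Entries may be exactly 0
#'   (vertices and faces of the simplex are legal states).
#' @param labels Optional character vector of type labels, same length.
#' @return A numeric vector of class `"state_distribution"`, summing to 1.
#'   Negative entries below `-1e-12` raise a `NegativeProbability` error;
#'   a sum off 1 by more than `1e-6` raises `NotNormalized`.
#' @examples
#' validate_distribution(c(0.5, 0.5))
#' validate_distribution(c(1, 0))      # degenerate vertex is valid
#' @export
validate_distribution <- function(v, labels = NULL) {
  if (!is.numeric(v) || length(v) < 2)
    bc_stop("DimensionMismatch",
            "a state distribution needs at least 2 numeric entries")
  if (anyNA(v))
    bc_stop("NegativeProbability", "probabilities must not be NA")
  if (any(v < -1e-12))
    bc_stop("NegativeProbability",
            sprintf("negative probability entry: min = %g", min(v)))
  s <- sum(v)
  if (abs(s - 1) > 1e-6)
    bc_stop("NotNormalized",
            sprintf("probabilities sum to %.12g, not 1", s))
  p <- pmax(v, 0)
  p <- p / sum(p)
  if (!is.null(labels)) {
    if (length(labels) != length(p))
      bc_stop("DimensionMismatch", "labels length must match probabilities")
    names(p) <- labels
  }
  structure(p, class = "state_distribution")
}

#' Normalize raw population counts to a state distribution
#'
#' Converts unnormalized abundances P to probability fractions
#' p_i = P_i / sum(P): the normalization that turns the Lotka-Volterra
#' system into the replicator equation.
#'
#' @param P Numeric vector of strictly positive counts, length >= 2.
#' @return A `state_distribution`.
#' @examples
#' normalize_population(c(1, 3))  # c(0.25, 0.75)
#' @export
normalize_population <- function(P) {
  if (!is.numeric(P) || length(P) < 2)
    bc_stop("DimensionMismatch", "need at least 2 population counts")
  if (anyNA(P) || any(P <= 0))
    bc_stop("NonPositiveCount", "all population counts must be > 0")
  validate_distribution(P / sum(P))
}

#' Fitness models for the state-type landscape
#'
#' A fitness model assigns each of the n state types a growth rate
#' (units 1/time), possibly depending on the current distribution p:
#' the fitness landscape of the biocontinuum.  Three kinds are supported:
#'
#' * `constant`: a fixed vector f, independent of p;
#' * `linear`: a payoff matrix A with f_i(p) = (A p)_i, the
#'   evolutionary-game form;
#' * `custom`: an arbitrary function p -> f(p), either passed directly or
#'   named in the registry (see [register_fitness()]) so scenarios using it
#'   can round-trip through JSON.
#'
#' @param kind One of `"constant"`, `"linear"`, `"custom"`.
#' @param f Numeric fitness vector (for `constant`).
#' @param payoff Square numeric payoff matrix (for `linear`).
#' @param fn Function of a probability vector returning a fitness vector
#'   (for `custom`), or `NULL` if `name` refers to a registered function.
#' @param name Registry name of a custom fitness function.
#' @param n Number of types (required for `custom`, inferred otherwise).
#' @return An object of class `"fitness_model"`.
#' @seealso [constant_fitness()], [payoff_fitness()], [fitness_values()]
#' @export
fitness_model <- function(kind = c("constant", "linear", "custom"),
                          f = NULL, payoff = NULL, fn = NULL,
                          name = NULL, n = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    constant = {
      if (!is.numeric(f) || length(f) < 2)
        bc_stop("DimensionMismatch",
                "constant fitness needs a numeric vector of length >= 2")
      list(kind = "constant", f = as.numeric(f), n = length(f))
    },
    linear = {
      if (!is.matrix(payoff) || nrow(payoff) != ncol(payoff) ||
          nrow(payoff) < 2 || !is.numeric(payoff))
        bc_stop("DimensionMismatch", "payoff must be a square numeric matrix")
      list(kind = "linear", payoff = payoff, n = nrow(payoff))
    },
    custom = {
      if (is.null(fn)) {
        if (is.null(name))
          bc_stop("SchemaError", "custom fitness needs fn or a registered name")
        fn <- get_registered_fitness(name)
      }
      if (is.null(n))
        bc_stop("DimensionMismatch", "custom fitness needs n")
      list(kind = "custom", fn = fn, name = name, n = as.integer(n))
    })
  structure(m, class = "fitness_model")
}

#' @rdname fitness_model
#' @export
constant_fitness <- function(f) fitness_model("constant", f = f)

#' @rdname fitness_model
#' @export
payoff_fitness <- function(payoff) fitness_model("linear", payoff = payoff)

#' @rdname fitness_model
#' @export
custom_fitness <- function(fn, n, name = NULL)
  fitness_model("custom", fn = fn, name = name, n = n)

# Registry of named custom fitness functions, so JSON scenarios can refer
# to them by name.
.fitness_registry <- new.env(parent = emptyenv())

#' Register a named custom fitness function
#'
#' @param name Registry key used by scenario JSON (`fitness.kind = "custom"`).
#' @param fn Function mapping a probability vector to a fitness vector of
#'   the same length.
#' @return Invisibly, `name`.
#' @export
register_fitness <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .fitness_registry)
  invisible(name)
}

get_registered_fitness <- function(name) {
  if (!exists(name, envir = .fitness_registry, inherits = FALSE))
    bc_stop("SchemaError",
            sprintf("no custom fitness registered under name '%s'", name))
  get(name, envir = .fitness_registry, inherits = FALSE)
}

#' Evaluate a fitness model at a state
#'
#' @param model A `fitness_model`.
#' @param p A probability vector (state distribution) of matching length.
#' @return Numeric vector of per-type fitness values (1/time).
#' @export
fitness_values <- function(model, p) {
  stopifnot(inherits(model, "fitness_model"))
  if (length(p) != model$n)
    bc_stop("DimensionMismatch",
            sprintf("state has %d types but fitness model expects %d",
                    length(p), model$n))
  f <- switch(model$kind,
    constant = model$f,
    linear   = drop(model$payoff %*% p),
    custom   = {
      out <- model$fn(as.numeric(p))
      if (!is.numeric(out) || length(out) != model$n)
        bc_stop("DimensionMismatch",
                "custom fitness function returned a vector of wrong length")
      out
    })
  as.numeric(f)
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("<fitness_model>", x$kind, "on", x$n, "types\n")
  if (x$kind == "constant") cat("  f =", format(x$f, digits = 6), "\n")
  if (x$kind == "linear")   cat("  payoff matrix", x$n, "x", x$n, "\n")
  if (x$kind == "custom")   cat("  name:", x$name %||% "<anonymous>", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerical settings for trajectory integration
#'
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param prob_floor Smallest probability substituted inside logarithms
#'   (entropy and Kullback-Leibler terms); states themselves may contain
#'   exact zeros.
#' @param max_step Maximum internal solver step (default unrestricted).
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10,
                            prob_floor = 1e-12, max_step = Inf) {
  for (v in c(rtol = rtol, atol = atol, prob_floor = prob_floor))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      bc_stop("SchemaError", "rtol, atol and prob_floor must lie in (0, 1)")
  structure(list(rtol = rtol, atol = atol, prob_floor = prob_floor,
                 max_step = max_step),
            class = "solver_settings")
}

#' Define a simulation scenario
#'
#' Bundles everything a run needs: the fitness landscape, the initial
#' distribution p0, an optional fixed target distribution q (the goal
#' state against which Kullback-Leibler information is measured), the
#' output time grid and solver settings.
#'
#' @param fitness A [fitness_model()].
#' @param p0 Initial state distribution (validated).
#' @param q Optional fixed target distribution, same number of types.
#' @param t_span Length-2 numeric `c(t0, t1)`, `t1 > t0`.
#' @param n_points Number of output grid points (>= 2).
#' @param solver A [solver_settings()] object.
#' @return An object of class `"scenario"`.
#' @examples
#' sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
#'                q = c(1, 0), t_span = c(0, 10))
#' sc
#' @export
scenario <- function(fitness, p0, q = NULL, t_span = c(0, 10),
                     n_points = 201L, solver = solver_settings()) {
  stopifnot(inherits(fitness, "fitness_model"),
            inherits(solver, "solver_settings"))
  p0 <- validate_distribution(p0)
  if (length(p0) != fitness$n)
    bc_stop("DimensionMismatch", "p0 length must match the fitness model")
  if (!is.null(q)) {
    q <- validate_distribution(q)
    if (length(q) != length(p0))
      bc_stop("DimensionMismatch", "q must have the same number of types as p0")
  }
  if (length(t_span) != 2 || !is.numeric(t_span) || t_span[2] <= t_span[1])
    bc_stop("SchemaError", "t_span must be c(t0, t1) with t1 > t0")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    bc_stop("SchemaError", "n_points must be an integer >= 2")
  structure(list(n = length(p0), fitness = fitness, p0 = p0, q = q,
                 t_span = as.numeric(t_span), n_points = n_points,
                 solver = solver),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$n, "types,", x$fitness$kind, "fitness\n")
  cat("  p0:", format(as.numeric(x$p0), digits = 4), "\n")
  if (!is.null(x$q)) cat("  q :", format(as.numeric(x$q), digits = 4), "\n")
  cat("  t in [", x$t_span[1], ",", x$t_span[2], "],",
      x$n_points, "output points\n")
  invisible(x)
}

# Internal constructor for trajectory objects.  `states` is an
# n_points x n matrix of simplex points; `observables` a data.frame with
# the information-theoretic columns.
new_trajectory <- function(times, states, observables, scenario = NULL) {
  stopifnot(length(times) == nrow(states),
            nrow(observables) == nrow(states),
            all(diff(times) > 0))
  structure(list(times = as.numeric(times), states = states,
                 observables = observables, scenario = scenario),
            class = "biocontinuum_trajectory")
}

#' @export
print.biocontinuum_trajectory <- function(x, ...) {
  n <- ncol(x$states)
  cat("<biocontinuum trajectory>", length(x$times), "time points,",
      n, "types, t in [", min(x$times), ",", max(x$times), "]\n")
  last <- x$states[nrow(x$states), ]
  cat("  final state:", format(last, digits = 4), "\n")
  cat("  final entropy:", format(x$observables$S[nrow(x$states)], digits = 6),
      "nats\n")
  if (!all(is.na(x$observables$I_qp)))
    cat("  final I(q,p):",
        format(x$observables$I_qp[nrow(x$states)], digits = 6), "nats\n")
  invisible(x)
}

#' @export
summary.biocontinuum_trajectory <- function(object, ...) {
  obs <- object$observables
  out <- list(
    n_types = ncol(object$states),
    n_points = length(object$times),
    t_span = range(object$times),
    initial_state = object$states[1, ],
    final_state = object$states[nrow(object$states), ],
    entropy_range = range(obs$S),
    max_simplex_deviation = max(abs(rowSums(object$states) - 1)),
    has_target = !all(is.na(obs$I_qp)),
    final_I = if (!all(is.na(obs$I_qp))) obs$I_qp[length(object$times)] else NA_real_
  )
  class(out) <- "summary.biocontinuum_trajectory"
  out
}

#' @export
print.summary.biocontinuum_trajectory <- function(x, ...) {
  cat("Replicator trajectory:", x$n_points, "points,", x$n_types,
      "types, t in [", x$t_span[1], ",", x$t_span[2], "]\n")
  cat("  initial state:", format(x$initial_state, digits = 4), "\n")
  cat("  final state:  ", format(x$final_state, digits = 4), "\n")
  cat("  entropy range:", format(x$entropy_range, digits = 6), "nats\n")
  cat("  max |sum(p) - 1|:", format(x$max_simplex_deviation, digits = 3), "\n")
  if (x$has_target)
    cat("  final I(q,p):", format(x$final_I, digits = 6), "nats\n")
  invisible(x)
}

#' @export
as.data.frame.biocontinuum_trajectory <- function(x, ...) {
  states <- as.data.frame(x$states)
  names(states) <- paste0("p_", seq_len(ncol(x$states)))
  cbind(data.frame(t = x$times), states, x$observables)
}

#' Plot a trajectory's state fractions and information observables
#'
#' Two stacked base-graphics panels: the state fractions p_i(t), and the
#' entropy S(t) together with I(q, p(t)) when a target is present.
#'
#' @param x A trajectory from [simulate_replicator()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.biocontinuum_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = expression(p[i](t)), ...)
  obs <- x$observables
  if (all(is.na(obs$I_qp))) {
    graphics::plot(x$times, obs$S, type = "l", xlab = "time",
                   ylab = "S (nats)")
  } else {
    graphics::matplot(x$times, cbind(obs$S, obs$I_qp), type = "l", lty = 1,
                      col = c(1, 2), xlab = "time", ylab = "nats")
    graphics::legend("topright", legend = c("S(p)", "I(q,p)"),
                     col = c(1, 2), lty = 1, bty = "n")
  }
  invisible(x)
}
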