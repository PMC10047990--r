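#' Mean population fitness
#'
#' The probability-weighted average fitness `<f> = sum(p_i f_i(p))` of the
#' current state: the quantity each type's growth rate is measured against
#' in the replicator equation.
#'
#' @param p A state distribution (probability vector).
#' @param fitness A [fitness_model()].
#' @return Scalar mean fitness (1/time).
#' @export
mean_fitness <- function(p, fitness) {
  f <- fitness_values(fitness, p)
  sum(p * f)
}

#' Variance of fitness across the population
#'
#' `Var(f) = sum(p_i f_i^2) - <f>^2 >= 0`.  By Fisher's fundamental
#' theorem, for a constant fitness landscape this equals the rate of
#' increase of the mean fitness along the replicator flow.
#'
#' @inheritParams mean_fitness
#' @return Scalar fitness variance (1/time^2); tiny negative rounding is
#'   clamped to 0.
#' @export
fitness_variance <- function(p, fitness) {
  f <- fitness_values(fitness, p)
  m <- sum(p * f)
  max(sum(p * f^2) - m^2, 0)
}

#' Replicator-equation right-hand side
#'
#' `dp_i/dt = (f_i(p) - <f(p)>) p_i`: each type's share grows at a rate
#' proportional to its fitness excess over the population mean.  The
#' components sum to zero analytically, so the flow preserves the simplex.
#'
#' @inheritParams mean_fitness
#' @return Numeric vector `dp/dt` (1/time).
#' @export
replicator_rhs <- function(p, fitness) {
  f <- fitness_values(fitness, p)
  phi <- sum(p * f)
  (f - phi) * p
}

#' Lotka-Volterra right-hand side on raw abundances
#'
#' `dP_i/dt = f_i P_i`, the unnormalized growth law whose normalization
#' `p = P / sum(P)` obeys the replicator equation.  Fitness is evaluated at
#' the normalized state.
#'
#' @param P Vector of strictly positive abundances.
#' @param fitness A [fitness_model()].
#' @return Numeric vector `dP/dt` (abundance/time).
#' @export
lotka_volterra_rhs <- function(P, fitness) {
  p <- normalize_population(P)
  f <- fitness_values(fitness, p)
  f * P
}

#' Closed-form replicator solution for constant fitness
#'
#' With a constant landscape f the replicator equation integrates exactly
#' to the exponential reweighting
#' `p_i(t) = p_i(0) exp(f_i t) / sum_j p_j(0) exp(f_j t)`.
#' Used as an independent oracle for the numerical integrator; computed
#' with a log-sum-exp shift so large `f t` cannot overflow.
#'
#' @param p0 Initial state distribution.
#' @param f Constant fitness vector, same length.
#' @param t Time (scalar or vector).
#' @return For scalar `t` a `state_distribution`; for vector `t` a matrix
#'   with one row per time.
#' @export
constant_fitness_closed_form <- function(p0, f, t) {
  p0 <- validate_distribution(p0)
  if (length(f) != length(p0))
    bc_stop("DimensionMismatch", "f must match p0 in length")
  one <- function(tt) {
    w <- log(ifelse(p0 > 0, p0, 1)) + f * tt
    w[p0 == 0] <- -Inf
    w <- w - max(w)
    e <- exp(w)
    e / sum(e)
  }
  if (length(t) == 1L) return(validate_distribution(one(t)))
  t(vapply(t, one, numeric(length(p0))))
}

# Shared post-processing: clip tiny negative drift and renormalize each
# output row onto the simplex.
project_rows <- function(states) {
  states <- pmax(states, 0)
  states / rowSums(states)
}

# Fill the observable table for a state matrix under a fitness model and
# optional target q.
build_observables <- function(times, states, fitness, q, prob_floor) {
  n_pts <- nrow(states)
  S <- S_dot <- mf <- fv <- numeric(n_pts)
  I_qp <- I_dot <- lag <- rep(NA_real_, n_pts)
  for (k in seq_len(n_pts)) {
    p <- states[k, ]
    f <- fitness_values(fitness, p)
    phi <- sum(p * f)
    mf[k] <- phi
    fv[k] <- max(sum(p * f^2) - phi^2, 0)
    lp <- log(pmax(p, prob_floor))
    S[k] <- -sum(p * lp)
    S_dot[k] <- -sum((f - phi) * p * lp)
    if (!is.null(q)) {
      I_qp[k] <- kl_divergence(q, p, prob_floor = prob_floor)
      I_dot[k] <- sum(f * (p - q))
      lag[k] <- I_dot[k] - I_qp[k]
    }
  }
  data.frame(S = S, S_dot = S_dot, I_qp = I_qp, I_dot = I_dot,
             lagrangian = lag, mean_fitness = mf, fitness_variance = fv)
}

#' Integrate a replicator scenario
#'
#' Integrates the replicator equation from `p0` over the scenario's time
#' span with an adaptive solver ([deSolve::ode()], `lsoda`), renormalizing
#' onto the simplex, and fills the information observables at every output
#' time: entropy S and its exact rate, Kullback-Leibler divergence from the
#' target q and its rate `sum(f_i (p_i - q_i))`, the Lagrangian integrand
#' (kinetic minus potential information), mean fitness and fitness
#' variance.
#'
#' @param scenario A [scenario()].
#' @return A `biocontinuum_trajectory`.
#' @examples
#' sc <- scenario(constant_fitness(c(1, 0)), p0 = c(0.5, 0.5),
#'                t_span = c(0, log(3)), n_points = 11)
#' traj <- simulate_replicator(sc)
#' traj$states[11, ]   # c(0.75, 0.25): exponential reweighting
#' @export
simulate_replicator <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sv <- scenario$solver
  times <- seq(scenario$t_span[1], scenario$t_span[2],
               length.out = scenario$n_points)
  rhs <- function(t, y, parms) {
    p <- pmax(y, 0)
    p <- p / sum(p)
    f <- fitness_values(scenario$fitness, p)
    list((f - sum(p * f)) * p)
  }
  out <- deSolve::ode(y = as.numeric(scenario$p0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = sv$rtol, atol = sv$atol,
                      hmax = if (is.finite(sv$max_step)) sv$max_step else NULL,
                      maxsteps = 100000)
  if (anyNA(out) || nrow(out) < length(times))
    bc_stop("IntegrationFailure",
            "ODE solver failed to reach the requested tolerances")
  states <- project_rows(unname(out[, -1, drop = FALSE]))
  obs <- build_observables(times, states, scenario$fitness, scenario$q,
                           sv$prob_floor)
  new_trajectory(times, states, obs, scenario)
}

#' @rdname simulate_replicator
#' @param object A `scenario` (S3 method for [stats::simulate()]).
#' @param nsim,seed Ignored; the dynamics are deterministic.
#' @param ... Unused.
#' @export
simulate.scenario <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_replicator(object)
}

#' Integrate the Lotka-Volterra system and normalize
#'
#' Integrates the raw-abundance law `dP_i/dt = f_i(p) P_i` on the output
#' grid and normalizes each state, giving an independent route to the
#' replicator trajectory (the quotient rule guarantees equivalence).
#' Between grid intervals the counts are rescaled by their sum whenever
#' the total leaves `[1e-12, 1e12]`; rescaling leaves normalized states
#' unchanged and prevents overflow under sustained growth.
#'
#' @param scenario A [scenario()]; `normalize_population(P0)` must equal
#'   the scenario's `p0`.
#' @param P0 Initial abundances (strictly positive).
#' @return A `biocontinuum_trajectory` of the normalized states.
#' @export
simulate_lv_normalized <- function(scenario, P0) {
  stopifnot(inherits(scenario, "scenario"))
  p0 <- normalize_population(P0)
  if (length(p0) != scenario$n || max(abs(p0 - scenario$p0)) > 1e-9)
    bc_stop("DimensionMismatch",
            "normalize_population(P0) must equal the scenario's p0")
  sv <- scenario$solver
  times <- seq(scenario$t_span[1], scenario$t_span[2],
               length.out = scenario$n_points)
  rhs <- function(t, y, parms) {
    p <- pmax(y, .Machine$double.xmin)
    p <- p / sum(p)
    f <- fitness_values(scenario$fitness, p)
    list(f * y)
  }
  n <- scenario$n
  states <- matrix(NA_real_, nrow = length(times), ncol = n)
  P <- as.numeric(P0)
  states[1, ] <- P / sum(P)
  for (k in seq_along(times)[-1]) {
    seg <- deSolve::ode(y = P, times = times[(k - 1):k], func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = sv$rtol, atol = sv$atol, maxsteps = 100000)
    if (anyNA(seg) || nrow(seg) < 2)
      bc_stop("IntegrationFailure",
              "Lotka-Volterra solver failed on a grid interval")
    P <- unname(seg[2, -1])
    tot <- sum(P)
    if (tot > 1e12 || tot < 1e-12) P <- P / tot  # overflow/underflow guard
    states[k, ] <- P / sum(P)
  }
  states <- project_rows(states)
  obs <- build_observables(times, states, scenario$fitness, scenario$q,
                           sv$prob_floor)
  new_trajectory(times, states, obs, scenario)
}

#' Locate equilibria of the replicator flow
#'
#' Every vertex of the simplex is a fixed point.  For a linear (payoff)
#' landscape, an interior equilibrium additionally solves
#' `(A p)_i = <f>` for all i on the simplex; it is found by a linear solve
#' and reported when strictly positive.  For a constant landscape with
#' equal entries every point is fixed (neutral) and the report is flagged.
#'
#' @param fitness A `constant` or `linear` [fitness_model()].
#' @param n Number of types (checked against the model).
#' @return An `equilibrium_report`: lists of points, their kinds
#'   (`"vertex"` or `"interior"`), residuals `max |p_i (f_i - <f>)|`, and
#'   `neutral` / `singular` flags.
#' @examples
#' A <- rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))  # rock-paper-scissors
#' find_equilibria(payoff_fitness(A), 3)              # interior point 1/3,1/3,1/3
#' @export
find_equilibria <- function(fitness, n) {
  stopifnot(inherits(fitness, "fitness_model"))
  if (fitness$kind == "custom")
    bc_stop("SchemaError",
            "equilibrium finding supports constant and linear fitness only")
  if (n != fitness$n)
    bc_stop("DimensionMismatch", "n must match the fitness model")
  residual_at <- function(p) {
    f <- fitness_values(fitness, p)
    max(abs(p * (f - sum(p * f))))
  }
  points <- lapply(seq_len(n), function(i) {
    v <- numeric(n); v[i] <- 1
    validate_distribution(v)
  })
  kinds <- rep("vertex", n)
  residuals <- vapply(points, residual_at, numeric(1))
  neutral <- FALSE
  singular <- FALSE
  if (fitness$kind == "constant") {
    neutral <- diff(range(fitness$f)) < 1e-12
  } else {
    A <- fitness$payoff
    # (A p)_i - (A p)_n = 0 for i < n, together with sum(p) = 1
    M <- rbind(A[-n, , drop = FALSE] -
                 matrix(A[n, ], nrow = n - 1, ncol = n, byrow = TRUE),
               rep(1, n))
    b <- c(rep(0, n - 1), 1)
    p_int <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(p_int) || rcond(M) < 1e-12) {
      singular <- TRUE
    } else if (all(p_int > 1e-10)) {
      p_int <- validate_distribution(p_int / sum(p_int))
      r <- residual_at(p_int)
      if (r < 1e-8) {
        points <- c(points, list(p_int))
        kinds <- c(kinds, "interior")
        residuals <- c(residuals, r)
      }
    }
  }
  structure(list(points = points, kinds = kinds, residuals = residuals,
                 neutral = neutral, singular = singular),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium report>", length(x$points), "fixed points\n")
  for (i in seq_along(x$points))
    cat(sprintf("  %-8s [%s]  residual %.2e\n", x$kinds[i],
                paste(format(as.numeric(x$points[[i]]), digits = 4),
                      collapse = ", "),
                x$residuals[i]))
  if (x$neutral)
    cat("  neutral landscape: every point of the simplex is fixed\n")
  if (x$singular)
    cat("  interior system singular: no unique interior solution\n")
  invisible(x)
}
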