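#' A point on the Gaussian location-scale manifold
#'
#' The two-dimensional statistical manifold whose points `(mu, sigma)`
#' index the family of normal distributions; `sigma` is the standard
#' deviation and must be positive.
#'
#' @param mu Location (arbitrary units).
#' @param sigma Scale (same units), strictly positive.
#' @return An object of class `"manifold_point"`.
#' @export
manifold_point <- function(mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    bc_stop("NonPositiveSigma", "sigma must be a positive scalar")
  stopifnot(is.numeric(mu), length(mu) == 1, !is.na(mu))
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "manifold_point")
}

#' @export
print.manifold_point <- function(x, ...) {
  cat(sprintf("<manifold point> mu = %g, sigma = %g\n", x$mu, x$sigma))
  invisible(x)
}

#' Fisher information metric of the Gaussian family
#'
#' In `(mu, sigma)` coordinates the Fisher metric of the normal family is
#' `diag(1 / sigma^2, 2 / sigma^2)`: a hyperbolic (constant negative
#' curvature) geometry in which distinguishability shrinks as the
#' distribution broadens.
#'
#' @param x A [manifold_point()].
#' @return A 2x2 symmetric positive-definite matrix (the metric tensor).
#' @export
gaussian_fisher_metric <- function(x) {
  stopifnot(inherits(x, "manifold_point"))
  diag(c(1, 2)) / x$sigma^2
}

#' Fisher (Shahshahani) metric on the probability simplex
#'
#' The Fisher information metric of the categorical family in the
#' probability coordinates: `g = diag(1/p_1, ..., 1/p_n)`, to be applied
#' to tangent vectors summing to zero.  This is the metric under which the
#' replicator flow for a symmetric payoff landscape is a natural-gradient
#' ascent of mean fitness.
#'
#' @param p Interior state distribution (all entries >= `prob_floor`).
#' @param prob_floor Interior threshold.
#' @return An n x n diagonal metric tensor.
#' @export
simplex_fisher_metric <- function(p, prob_floor = 1e-12) {
  p <- validate_distribution(p)
  if (any(p < prob_floor))
    bc_stop("BoundaryPoint",
            "the Fisher metric degenerates on the simplex boundary")
  diag(1 / as.numeric(p), nrow = length(p))
}

#' Kullback-Leibler divergence between two normal distributions
#'
#' `KL(N(a) || N(b)) = ln(sigma_b/sigma_a)
#'  + (sigma_a^2 + (mu_a - mu_b)^2) / (2 sigma_b^2) - 1/2` (nats).
#' Its second-order expansion in the displacement recovers the Gaussian
#' Fisher metric, which is how the metric is cross-checked.
#'
#' @param a,b [manifold_point()]s.
#' @return Divergence in nats.
#' @export
gaussian_kl <- function(a, b) {
  stopifnot(inherits(a, "manifold_point"), inherits(b, "manifold_point"))
  log(b$sigma / a$sigma) +
    (a$sigma^2 + (a$mu - b$mu)^2) / (2 * b$sigma^2) - 0.5
}

#' Fisher-Rao geodesic distance on the Gaussian manifold
#'
#' The Gaussian manifold with the Fisher metric is a hyperbolic half-plane
#' (after rescaling the location coordinate), and the geodesic distance has
#' the closed form
#' `d = sqrt(2) * acosh(1 + ((mu_a - mu_b)^2 / 2 + (sigma_a - sigma_b)^2)
#'  / (2 sigma_a sigma_b))`.
#' Along a purely vertical path this reduces to
#' `sqrt(2) * |ln(sigma_b / sigma_a)|`.
#'
#' @param a,b [manifold_point()]s.
#' @return Non-negative geodesic distance (dimensionless).
#' @examples
#' gaussian_geodesic_distance(manifold_point(0, 1), manifold_point(0, exp(1)))
#' # sqrt(2)
#' @export
gaussian_geodesic_distance <- function(a, b) {
  stopifnot(inherits(a, "manifold_point"), inherits(b, "manifold_point"))
  arg <- 1 + ((a$mu - b$mu)^2 / 2 + (a$sigma - b$sigma)^2) /
    (2 * a$sigma * b$sigma)
  sqrt(2) * acosh(max(arg, 1))
}

# Central-difference gradient with relative step h.
numerical_gradient <- function(fn, x, h_rel = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

#' Natural-gradient descent flow on a statistical manifold
#'
#' Iterates steepest descent measured in the Fisher metric,
#' `x <- x - step * g(x)^{-1} grad(objective)(x)`, with gradients by
#' central differences and backtracking line search (the step is halved,
#' up to 30 times, until the objective does not increase).  Two manifolds
#' are supported:
#'
#' * the Gaussian `(mu, sigma)` half-plane, where
#'   `g^{-1} = diag(sigma^2, sigma^2 / 2)` and sigma is kept positive;
#' * the probability simplex under the Shahshahani metric, where the
#'   natural-gradient step takes the replicator-like form
#'   `p_i (d_i - sum(p_j d_j))` with `d = grad(objective)` and each iterate
#'   is re-projected onto the (interior of the) simplex.
#'
#' The flow stops early once the natural-gradient norm falls below
#' `grad_tol` (converged) and raises `StalledFlow` if the objective cannot
#' be decreased at the minimum step while the gradient is still large.
#'
#' @param objective For the Gaussian manifold, a function of a
#'   [manifold_point()]; for the simplex, a function of a probability
#'   vector.  Values in nats (or any scalar units).
#' @param start A [manifold_point()] or an interior probability vector.
#' @param step Initial step size (> 0).
#' @param n_steps Maximum number of iterations.
#' @param grad_tol Natural-gradient norm below which the flow is declared
#'   converged.
#' @param prob_floor Interior floor used on the simplex.
#' @return A `flow_path`: list of visited points, the non-increasing
#'   `objective_values`, and a `converged` flag.
#' @examples
#' q <- c(0.2, 0.5, 0.3)
#' fp <- natural_gradient_flow(function(p) kl_divergence(q, p),
#'                             start = rep(1 / 3, 3), step = 0.5,
#'                             n_steps = 200)
#' fp$objective_values[length(fp$objective_values)]  # ~0: converged to q
#' @export
natural_gradient_flow <- function(objective, start, step = 0.2,
                                  n_steps = 200, grad_tol = 1e-12,
                                  prob_floor = 1e-12) {
  stopifnot(is.function(objective), step > 0, n_steps >= 1)
  if (inherits(start, "manifold_point")) {
    flow_gaussian(objective, start, step, n_steps, grad_tol)
  } else {
    flow_simplex(objective, validate_distribution(start), step, n_steps,
                 grad_tol, prob_floor)
  }
}

flow_gaussian <- function(objective, start, step, n_steps, grad_tol) {
  obj_xy <- function(x) objective(manifold_point(x[1], x[2]))
  x <- c(start$mu, start$sigma)
  pts <- vector("list", n_steps + 1)
  vals <- numeric(n_steps + 1)
  pts[[1]] <- start
  vals[1] <- obj_xy(x)
  converged <- FALSE
  k <- 1
  while (k <= n_steps) {
    grad <- numerical_gradient(obj_xy, x)
    nat <- c(x[2]^2, x[2]^2 / 2) * grad  # g^{-1} grad
    if (sqrt(sum(nat^2)) < grad_tol) { converged <- TRUE; break }
    s <- step
    ok <- FALSE
    for (halving in 0:30) {
      cand <- x - s * nat
      if (cand[2] > 0) {
        v <- obj_xy(cand)
        if (v <= vals[k] + 1e-15 * max(1, abs(vals[k]))) {
          x <- cand
          vals[k + 1] <- min(v, vals[k])
          pts[[k + 1]] <- manifold_point(x[1], x[2])
          ok <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!ok)
      bc_stop("StalledFlow",
              "no objective decrease possible at the minimum step size")
    k <- k + 1
  }
  new_flow_path(pts[seq_len(k)], vals[seq_len(k)], converged)
}

flow_simplex <- function(objective, start, step, n_steps, grad_tol,
                         prob_floor) {
  p <- pmax(as.numeric(start), prob_floor)
  p <- p / sum(p)
  pts <- vector("list", n_steps + 1)
  vals <- numeric(n_steps + 1)
  pts[[1]] <- p
  vals[1] <- objective(p)
  converged <- FALSE
  # Finite-difference probes leave the simplex; evaluating on the
  # renormalized probe keeps the objective defined and leaves the
  # tangential gradient component (the only one used below) unchanged.
  obj_renorm <- function(x) objective(x / sum(x))
  k <- 1
  while (k <= n_steps) {
    grad <- numerical_gradient(obj_renorm, p)
    # Shahshahani natural gradient restricted to the tangent space:
    nat <- p * (grad - sum(p * grad))
    if (sqrt(sum(nat^2)) < grad_tol) { converged <- TRUE; break }
    s <- step
    ok <- FALSE
    for (halving in 0:30) {
      cand <- p - s * nat
      cand <- pmax(cand, prob_floor)
      cand <- cand / sum(cand)
      v <- objective(cand)
      if (v <= vals[k] + 1e-15 * max(1, abs(vals[k]))) {
        p <- cand
        vals[k + 1] <- min(v, vals[k])
        pts[[k + 1]] <- p
        ok <- TRUE
        break
      }
      s <- s / 2
    }
    if (!ok)
      bc_stop("StalledFlow",
              "no objective decrease possible at the minimum step size")
    k <- k + 1
  }
  new_flow_path(pts[seq_len(k)], vals[seq_len(k)], converged)
}

new_flow_path <- function(points, objective_values, converged) {
  structure(list(points = points, objective_values = objective_values,
                 converged = converged),
            class = "flow_path")
}

#' @export
print.flow_path <- function(x, ...) {
  n <- length(x$points)
  cat("<flow path>", n, "points, objective",
      format(x$objective_values[1], digits = 6), "->",
      format(x$objective_values[n], digits = 6),
      if (x$converged) "(converged)" else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.flow_path <- function(x, ...) {
  if (inherits(x$points[[1]], "manifold_point")) {
    data.frame(step = seq_along(x$points) - 1L,
               mu = vapply(x$points, function(p) p$mu, numeric(1)),
               sigma = vapply(x$points, function(p) p$sigma, numeric(1)),
               objective = x$objective_values)
  } else {
    m <- do.call(rbind, x$points)
    colnames(m) <- paste0("p_", seq_len(ncol(m)))
    cbind(data.frame(step = seq_along(x$points) - 1L), as.data.frame(m),
          data.frame(objective = x$objective_values))
  }
}

#' Check the gradient-flow character of the replicator dynamics
#'
#' For a symmetric payoff matrix A the replicator flow is the natural
#' (Shahshahani) gradient ascent of the potential `V(p) = p' A p / 2`, so
#' mean fitness must be non-decreasing along every trajectory.  This
#' diagnostic simulates the scenario and verifies the ascent numerically.
#'
#' @param payoff Symmetric payoff matrix.
#' @param p0 Initial distribution.
#' @param t_span Time span of the check.
#' @param n_points Output grid size.
#' @param tol Largest tolerated per-step decrease of the potential.
#' @return A list with `ascending` (logical), `min_increment`,
#'   `potential_series` and the trajectory, of class
#'   `"gradient_check_report"`.
#' @export
replicator_is_natural_gradient_check <- function(payoff, p0,
                                                 t_span = c(0, 10),
                                                 n_points = 201,
                                                 tol = 1e-9) {
  if (!is.matrix(payoff) || max(abs(payoff - t(payoff))) > 1e-12)
    bc_stop("AsymmetricPayoff",
            "the gradient-flow property requires a symmetric payoff matrix")
  sc <- scenario(payoff_fitness(payoff), p0 = p0, t_span = t_span,
                 n_points = n_points)
  traj <- simulate_replicator(sc)
  V <- apply(traj$states, 1, function(p) 0.5 * sum(p * drop(payoff %*% p)))
  inc <- diff(V)
  structure(list(ascending = all(inc >= -tol),
                 min_increment = min(inc),
                 potential_series = V,
                 trajectory = traj),
            class = "gradient_check_report")
}

#' @export
print.gradient_check_report <- function(x, ...) {
  cat("<gradient check> potential p'Ap/2 along the replicator flow\n")
  cat("  non-decreasing:", x$ascending,
      sprintf(" (min increment %.3e)\n", x$min_increment))
  cat(sprintf("  potential %.6g -> %.6g\n", x$potential_series[1],
              x$potential_series[length(x$potential_series)]))
  invisible(x)
}
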