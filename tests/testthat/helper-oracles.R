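# Shared fixtures and independent oracles used across the test files.

# Random interior simplex point (flat Dirichlet), optionally bounded away
# from the boundary by mixing with the uniform distribution.
rand_simplex <- function(n, interior_weight = 0) {
  g <- rgamma(n, shape = 1)
  p <- g / sum(g)
  if (interior_weight > 0)
    p <- (1 - interior_weight) * p + interior_weight / n
  p / sum(p)
}

# Independent geodesic-length oracle for the Gaussian Fisher manifold:
# shoot the geodesic ODE (unit speed) from `a` at departure angle theta,
# stop when mu crosses the target's mu, and root-find theta so the crossing
# hits the target sigma.  The distance is the elapsed arc-length parameter.
# Uses only the metric's geodesic equations, never the closed form.
geodesic_shoot_distance <- function(a, b, t_max = 10) {
  stopifnot(b$mu > a$mu)  # shooting in +mu direction is enough for tests
  geo_rhs <- function(t, y, parms) {
    # y = (mu, sigma, dmu, dsigma) for the metric diag(1/s^2, 2/s^2)
    s <- y[2]
    list(c(y[3], y[4],
           2 * y[3] * y[4] / s,
           y[4]^2 / s - y[3]^2 / (2 * s)))
  }
  crossing <- function(theta) {
    y0 <- c(a$mu, a$sigma,
            a$sigma * cos(theta), a$sigma * sin(theta) / sqrt(2))
    out <- deSolve::ode(y = y0, times = c(0, t_max), func = geo_rhs,
                        parms = NULL, method = "lsodar",
                        rootfunc = function(t, y, parms) y[1] - b$mu,
                        rtol = 1e-12, atol = 1e-12)
    troot <- attr(out, "troot")
    if (is.null(troot) || length(troot) == 0) return(NULL)
    # lsodar halts at the root, so the final output row is the crossing
    list(t = troot[1], sigma = out[nrow(out), 3])
  }
  miss <- function(theta) {
    cr <- tryCatch(crossing(theta), error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(cr) || length(cr$sigma) != 1 || !is.finite(cr$sigma))
      return(NA_real_)
    cr$sigma - b$sigma
  }
  # bracket the departure angle: scan for a finite sign change, then refine
  thetas <- seq(-1.4, 1.4, length.out = 57)
  vals <- vapply(thetas, miss, numeric(1))
  ok <- which(!is.na(vals))
  flip <- ok[which(diff(sign(vals[ok])) != 0)[1]]
  stopifnot(length(flip) == 1, !is.na(flip))
  nxt <- ok[which(ok == flip) + 1]
  root <- uniroot(miss, lower = thetas[flip], upper = thetas[nxt],
                  tol = 1e-12)
  crossing(root$root)$t
}

# Finite-difference derivative of a series on a uniform grid (central in
# the interior); returns values at interior indices only.
central_diff <- function(x, dt) {
  n <- length(x)
  (x[3:n] - x[1:(n - 2)]) / (2 * dt)
}

rps_payoff <- function() rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))
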