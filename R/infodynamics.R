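#' Shannon entropy of a state distribution
#'
#' `S(p) = -sum(p_i ln p_i)` in nats: the average surprisal, the
#' uncertainty an observer has about which state type the system occupies.
#' Zero-probability terms contribute 0 (the limit `0 ln 0 = 0`); positive
#' probabilities below `prob_floor` are floored inside the logarithm.
#'
#' @param p A probability vector.
#' @param prob_floor Floor applied inside logarithms.
#' @return Entropy in nats, between 0 and `ln n`.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # ln 2
#' shannon_entropy(c(1, 0))       # 0: certainty
#' @export
shannon_entropy <- function(p, prob_floor = 1e-12) {
  p <- validate_distribution(p)
  -sum(p * log(pmax(p, prob_floor)))
}

#' Exact entropy production rate along the replicator flow
#'
#' Substituting the replicator equation into `dS/dt = -sum(dp_i ln p_i)`
#' gives the closed form
#' `S_dot = -sum((f_i - <f>) p_i ln p_i)` (nats/time): entropy changes
#' only insofar as fitness differences reweight the surprisals.
#'
#' @inheritParams shannon_entropy
#' @param fitness A [fitness_model()].
#' @return Entropy rate in nats per unit time.
#' @export
entropy_rate <- function(p, fitness, prob_floor = 1e-12) {
  p <- validate_distribution(p)
  f <- fitness_values(fitness, p)
  phi <- sum(p * f)
  -sum((f - phi) * p * log(pmax(p, prob_floor)))
}

#' Kullback-Leibler divergence I(q, p)
#'
#' `I(q, p) = sum(q_i ln(q_i / p_i))` in nats: the relative information
#' between a fixed target state q and the current state p — the
#' information still to be assimilated before the system reaches its goal
#' state.  Non-negative, zero iff `q == p`.  The sum runs over the support
#' of q; if q puts mass where p (after flooring) has essentially none, the
#' divergence is infinite and a `SupportMismatch` warning is raised.
#'
#' @param q Target distribution.
#' @param p Current distribution, same length.
#' @param prob_floor Floor applied to p inside the logarithm.
#' @return Divergence in nats (possibly `Inf`).
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))        # ln 2
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # 0.1438410
#' @export
kl_divergence <- function(q, p, prob_floor = 1e-12) {
  q <- validate_distribution(q)
  p <- validate_distribution(p)
  if (length(q) != length(p))
    bc_stop("DimensionMismatch", "q and p must have the same length")
  bad <- q > 0 & p < prob_floor
  if (any(bad)) {
    bc_warn("SupportMismatch",
            "q has mass where p is below prob_floor; divergence is infinite")
    return(Inf)
  }
  pos <- q > 0
  sum(q[pos] * (log(q[pos]) - log(pmax(p[pos], prob_floor))))
}

#' Exact rate of change of I(q, p) along the replicator flow
#'
#' Because q is fixed, `dI/dt = -sum(q_i dp_i / p_i)`, and substituting
#' the replicator equation collapses this to
#' `dI/dt = sum(f_i(p) (p_i - q_i))` (nats/time) — no logarithms remain.
#' This is the kinetic information of the action functional.
#'
#' @inheritParams kl_divergence
#' @param fitness A [fitness_model()], evaluated at `p`.
#' @return Rate in nats per unit time (negative while p approaches q
#'   along fitness gradients).
#' @export
kl_rate <- function(q, p, fitness) {
  q <- validate_distribution(q)
  p <- validate_distribution(p)
  if (length(q) != length(p))
    bc_stop("DimensionMismatch", "q and p must have the same length")
  f <- fitness_values(fitness, p)
  sum(f * (p - q))
}

#' Lyapunov analysis of I(q, p(t)) along a trajectory
#'
#' Evaluates the divergence from a fixed target on the trajectory grid and
#' reports whether it behaves as a Lyapunov function (non-increasing up to
#' a per-step tolerance) or as a conserved quantity (constant within a
#' global tolerance), as it is for zero-sum landscapes around an interior
#' equilibrium.
#'
#' @param traj A `biocontinuum_trajectory`.
#' @param q Fixed target distribution.
#' @param tolerance Per-step increase tolerated before monotonicity is
#'   rejected (nats).
#' @param conservation_tol Global drift tolerated for the conserved flag
#'   (nats).
#' @param prob_floor Floor for logarithms.
#' @return A `lyapunov_report` with fields `monotone_nonincreasing`,
#'   `max_positive_increment`, `conserved`, `final_I` and the series `I`.
#' @export
lyapunov_analysis <- function(traj, q, tolerance = 1e-7,
                              conservation_tol = 1e-6,
                              prob_floor = 1e-12) {
  stopifnot(inherits(traj, "biocontinuum_trajectory"),
            length(traj$times) >= 2)
  q <- validate_distribution(q)
  I <- apply(traj$states, 1, function(p)
    kl_divergence(q, p, prob_floor = prob_floor))
  inc <- diff(I)
  max_pos <- max(c(0, inc))
  structure(list(
    monotone_nonincreasing = max_pos <= tolerance,
    max_positive_increment = max_pos,
    conserved = max(abs(I - I[1])) <= conservation_tol,
    final_I = I[length(I)],
    I = I,
    times = traj$times),
    class = "lyapunov_report")
}

#' @export
print.lyapunov_report <- function(x, ...) {
  cat("<Lyapunov report> I(q, p(t)) over", length(x$I), "points\n")
  cat("  monotone non-increasing:", x$monotone_nonincreasing,
      sprintf(" (max positive increment %.3e nats)\n",
              x$max_positive_increment))
  cat("  conserved:", x$conserved, "\n")
  cat(sprintf("  I(0) = %.6g, final I = %.6g nats\n", x$I[1], x$final_I))
  invisible(x)
}
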