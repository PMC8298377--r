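# Damage (plasticity) and remodeling internal-variable updates
#
# Damage is driven by the history maximum of the tissue stretch along the
# fiber divided by the current remodeling stretch. Above the threshold
# lambda_bar_p the damage variable grows linearly with that maximum and is
# clamped to [0,1] and held monotone. The plastic flow transfers damage
# growth into permanent fiber stretch, limited so the elastic stretch never
# drops below one. Remodeling relaxes the elastic collagen stretch toward
# the deposition prestretch. All updates are backward Euler; the scalar
# implicit equations are solved by Newton with a bisection fallback.

#' Create a plastic (damage) internal-variable state
#'
#' @param lambda_p Plastic fiber stretch (>= 1).
#' @param lambda_max History maximum collagen stretch.
#' @param d Damage variable in `[0, 1]`.
#' @return An object of class `plastic_state`.
#' @export
plastic_state <- function(lambda_p = 1, lambda_max = 1, d = 0) {
  stopifnot(lambda_p >= 1, d >= 0, d <= 1)
  structure(list(lambda_p = lambda_p, lambda_max = lambda_max, d = d),
            class = "plastic_state")
}

#' Update the history maximum collagen stretch
#'
#' The quantity driving damage is `max_tau lambda(tau) / lambda_r(t)`: the
#' history maximum of the tissue stretch along the fiber, divided by the
#' current remodeling stretch (remodeling does not contribute to damage).
#'
#' @param lambda_max_prev Previous maximum collagen stretch.
#' @param lambda_total Current tissue stretch along the fiber.
#' @param lambda_r Current remodeling stretch.
#' @return Updated (non-decreasing) maximum collagen stretch.
#' @export
update_max_stretch <- function(lambda_max_prev, lambda_total, lambda_r) {
  stopifnot(lambda_max_prev > 0, lambda_total > 0, lambda_r > 0)
  max(lambda_max_prev, lambda_total / lambda_r)
}

#' Damage variable from the maximum collagen stretch
#'
#' `d = min(1, m_p * <lambda_max - lambda_bar_p>)`. The linear law is
#' clamped at full damage; monotonicity over a loading history follows from
#' the monotone `lambda_max` (and is additionally enforced by callers that
#' keep `d` non-decreasing).
#'
#' @param lambda_max Maximum collagen stretch (> 0).
#' @inheritParams collagen_energy
#' @return Damage value in `[0, 1]`.
#' @export
damage_value <- function(lambda_max, params) {
  if (any(lambda_max <= 0)) stop("lambda_max must be positive")
  pmin(1, params$m_p * pmax(lambda_max - params$lambda_bar_p, 0))
}

#' Backward-Euler plastic flow increment
#'
#' Integrates the flow rule `dot(lambda_p) = d dot(lambda_max) / lambda_e`
#' (active for `lambda_e > 1`) implicitly over one increment of the
#' maximum collagen stretch, with `lambda_e = lambda / (lambda_r lambda_p)`
#' evaluated at the end of the step. The plastic stretch never exceeds the
#' value that makes the elastic stretch equal to one.
#'
#' @param state A [plastic_state()].
#' @param delta_lambda_max Increment of the maximum collagen stretch (>= 0).
#' @param lambda_total Tissue stretch along the fiber at the end of the step.
#' @param lambda_r Remodeling stretch at the end of the step.
#' @inheritParams collagen_energy
#' @return Updated `plastic_state` with `lambda_max` and `d` advanced
#'   consistently with the increment.
#' @export
plastic_increment <- function(state, delta_lambda_max, lambda_total,
                              lambda_r, params) {
  if (delta_lambda_max < 0) stop("delta_lambda_max must be non-negative")
  lam_max_new <- state$lambda_max + delta_lambda_max
  d_new <- max(state$d, damage_value(lam_max_new, params))
  lambda_p <- state$lambda_p
  lam_e_trial <- lambda_total / (lambda_r * lambda_p)
  if (delta_lambda_max > 0 && d_new > 0 && lam_e_trial > 1) {
    # implicit: lp = lp_old + d * dlmax * lr * lp / lambda  (linear in lp)
    denom <- 1 - d_new * delta_lambda_max * lambda_r / lambda_total
    lambda_p_new <- if (denom > 0) lambda_p / denom else Inf
    # cap so that lambda_e >= 1
    lambda_p <- min(lambda_p_new, lambda_total / lambda_r)
    lambda_p <- max(lambda_p, state$lambda_p)
  }
  plastic_state(lambda_p = lambda_p, lambda_max = lam_max_new, d = d_new)
}

#' Backward-Euler remodeling increment
#'
#' Integrates `dot(lambda_r) = k_rem (lambda_e - lambda_pre) /
#' (lambda_pre - 1)` implicitly with `lambda_e = lambda / (lambda_r
#' lambda_p)` at the end of the step (scalar Newton, bisection fallback).
#' The fixed point is `lambda_e = lambda_pre`.
#'
#' @param lambda_r_prev Remodeling stretch at the start of the step.
#' @param lambda_total Tissue stretch along the fiber (held over the step).
#' @param lambda_p Plastic stretch (frozen during remodeling).
#' @param dt Time step, s (>= 0).
#' @inheritParams collagen_energy
#' @return Updated remodeling stretch.
#' @export
remodeling_increment <- function(lambda_r_prev, lambda_total, lambda_p, dt,
                                 params) {
  if (dt < 0) stop("dt must be non-negative")
  if (dt == 0) return(lambda_r_prev)
  k <- params$k_rem / (params$lambda_pre - 1)
  f <- function(x) x - lambda_r_prev -
    dt * k * (lambda_total / (x * lambda_p) - params$lambda_pre)
  fp <- function(x) 1 + dt * k * lambda_total / (x^2 * lambda_p)
  scalar_newton(f, fp, x0 = lambda_r_prev,
                lower = 1e-8, upper = lambda_r_prev + 10,
                what = "remodeling update")
}

# Scalar Newton iteration with bracketing bisection fallback.
# Relative tolerance 1e-12, at most 50 iterations.
scalar_newton <- function(f, fp, x0, lower, upper, tol = 1e-12, maxit = 50,
                          what = "scalar solve") {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- f(x)
    if (abs(fx) <= tol * max(1, abs(x))) return(x)
    step <- fx / fp(x)
    x_new <- x - step
    if (!is.finite(x_new) || x_new <= lower || x_new >= upper) {
      # bisection fallback on [lower, upper], expanding if needed
      fl <- f(lower)
      if (sign(fl) == sign(fx)) {
        x_new <- (x + upper) / 2
      } else {
        x_new <- (lower + x) / 2
      }
    }
    if (abs(x_new - x) <= tol * max(1, abs(x))) {
      x <- x_new
      break
    }
    x <- x_new
  }
  fx <- f(x)
  if (abs(fx) > 1e-8 * max(1, abs(x)))
    stop(sprintf("%s did not converge: residual %.3e after %d iterations",
                 what, fx, maxit))
  x
}
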