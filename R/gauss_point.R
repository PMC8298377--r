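# Staggered Gauss-point driver
#
# The internal variables split into three sets evolved in consecutive
# phases: a prestretch phase (remodeling only, establishing the collagen
# deposition prestretch), a short damage phase (damage/plastic flow only,
# biology and growth frozen) and a long healing phase (biology, growth and
# remodeling; damage frozen). A step covers [t, t + dt); its phase is the
# phase of the step start, and phase boundaries belong to the later phase.

#' Phase schedule of a healing simulation
#'
#' @param t0 End of the prestretch phase, s.
#' @param t_star End of the damage phase / start of healing, s.
#' @param t_end End of the healing phase, s.
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(t0, t_star, t_end) {
  if (!(t0 < t_star && t_star < t_end))
    stop("phase schedule requires t0 < t_star < t_end")
  structure(list(t0 = t0, t_star = t_star, t_end = t_end),
            class = "phase_schedule")
}

#' Phase of a time point
#'
#' @param t Time, s (>= 0 relative to the start of the prestretch phase).
#' @param schedule A [phase_schedule()].
#' @return One of `"prestretch"`, `"damage"`, `"healing"`; boundaries
#'   belong to the later phase.
#' @export
phase_of <- function(t, schedule) {
  if (t < schedule$t0) "prestretch"
  else if (t < schedule$t_star) "damage"
  else "healing"
}

#' Fresh Gauss-point state
#'
#' All internal variables at their reference values: no plastic stretch or
#' damage, unit remodeling stretch, homeostatic species, all collagen
#' intact at the initial collagen density.
#'
#' @param params A [heal_params()] object.
#' @return An object of class `gp_state`.
#' @export
gp_state <- function(params) {
  rc <- params$material$rho0_init * params$material$phi_c0
  structure(list(
    plastic = plastic_state(),
    hist_lambda = 1,
    lambda_r = 1,
    bio = bio_state(M = params$bio$M0, G = params$bio$G0, i_M = 0,
                    t_star = 0, t_heal = 0, rho_cd = 0, rho_ci = rc,
                    rho_c_star = rc),
    heal_init = FALSE), class = "gp_state")
}

gp_composition <- function(state, params) {
  mixture_composition(state$bio$rho_cd + state$bio$rho_ci,
                      params$material$rho0_init *
                        (1 - params$material$phi_c0))
}

# Second PK stress directly from C and the scalar internal variables.
# The structural direction a0 is an eigenvector of both inelastic
# gradients, so the chain-rule vector is w = a0 / (lambda_p lambda_r).
stress_from_C <- function(C, lambda_p, lambda_r, a0, composition, params,
                          pressure = NULL) {
  m <- params$material
  detC <- det(C)
  if (detC <= 0) stop("inverted element: det(C) <= 0")
  J <- sqrt(detC)
  Cinv <- solve(C)
  lp2 <- (lambda_p * lambda_r)^2
  Ie <- as.numeric(t(a0) %*% C %*% a0) / lp2
  S <- 2 * composition$rho_c * collagen_energy_d1(Ie, m) / lp2 *
    tcrossprod(a0) +
    composition$rho_m * m$mu * J^(-2 / 3) *
      (diag(3) - sum(diag(C)) / 3 * Cinv)
  if (is.null(pressure)) {
    g <- growth_target(composition$rho_0, m$rho0_init)
    S <- S + composition$rho_0 * m$kappa * (J - g) * J * Cinv
  } else {
    S <- S + composition$rho_0 * pressure * J * Cinv
  }
  (S + t(S)) / 2
}

#' Staggered local update at a Gauss point
#'
#' Advances the internal variables over `[t, t + dt)` for the given right
#' Cauchy-Green tensor at the end of the step, then evaluates the second
#' Piola-Kirchhoff stress at the converged internal state. Which
#' internal-variable set evolves depends on the phase: prestretch evolves
#' only the remodeling stretch (by default through the closed-form
#' steady-state `lambda_r = lambda / (lambda_p lambda_pre)`), the damage
#' phase evolves the plastic set (biology and growth frozen; remodeling
#' optionally active, its effect over seconds is negligible), and the
#' healing phase evolves biology and remodeling with the plastic set
#' frozen. On the first healing call the damaged/intact collagen pools are
#' initialized from the final damage variable.
#'
#' @param C Right Cauchy-Green tensor at the end of the step (SPD).
#' @param t Step start time, s.
#' @param dt Step size, s (the step must not straddle a phase boundary).
#' @param state A [gp_state()].
#' @param params A [heal_params()] object.
#' @param schedule A [phase_schedule()].
#' @param a0 Unit reference fiber direction.
#' @param prestretch_mode `"closed_form"` (default) sets the remodeling
#'   stretch to its steady state during prestretch; `"rate"` integrates the
#'   remodeling rate equation instead.
#' @param pressure Optional element pressure for the mixed-element stress;
#'   `NULL` selects the material-point penalty stress.
#' @return List with the advanced `state`, the stress `S`, the fiber
#'   stretch `lambda`, the elastic invariant `Ie`, and the `composition`.
#' @export
local_update <- function(C, t, dt, state, params, schedule, a0 = c(1, 0, 0),
                         prestretch_mode = c("closed_form", "rate"),
                         pressure = NULL) {
  prestretch_mode <- match.arg(prestretch_mode)
  m <- params$material
  lambda <- sqrt(as.numeric(t(a0) %*% C %*% a0))
  phase <- phase_of(t, schedule)
  st <- state

  if (dt == 0) {
    # zero-length step: pure stress evaluation, state untouched
    comp <- gp_composition(st, params)
    S <- stress_from_C(C, st$plastic$lambda_p, st$lambda_r, a0, comp,
                       params, pressure = pressure)
    return(list(state = st, S = S, lambda = lambda,
                Ie = (lambda / (st$plastic$lambda_p * st$lambda_r))^2,
                composition = comp))
  }

  if (phase == "prestretch") {
    if (prestretch_mode == "closed_form") {
      st$lambda_r <- lambda / (st$plastic$lambda_p * m$lambda_pre)
    } else {
      st$lambda_r <- remodeling_increment(st$lambda_r, lambda,
                                          st$plastic$lambda_p, dt, m)
    }
  } else if (phase == "damage") {
    st$hist_lambda <- max(st$hist_lambda, lambda)
    lr <- st$lambda_r
    pl <- st$plastic
    for (i in 1:20) {
      lmax_new <- update_max_stretch(state$plastic$lambda_max,
                                     st$hist_lambda, lr)
      pl <- plastic_increment(state$plastic,
                              lmax_new - state$plastic$lambda_max,
                              lambda, lr, m)
      lr_new <- if (m$remodel_in_damage)
        remodeling_increment(state$lambda_r, lambda, pl$lambda_p, dt, m)
      else state$lambda_r
      if (abs(lr_new - lr) < 1e-14) { lr <- lr_new; break }
      lr <- lr_new
    }
    st$plastic <- pl
    st$lambda_r <- lr
  } else { # healing
    if (!st$heal_init) {
      rc_star <- st$bio$rho_cd + st$bio$rho_ci
      pools <- init_pools(st$plastic$d, rc_star)
      st$bio <- bio_state(M = params$bio$M0, G = params$bio$G0, i_M = 0,
                          t_star = schedule$t_star, t_heal = 0,
                          rho_cd = pools[["rho_cd"]],
                          rho_ci = pools[["rho_ci"]],
                          rho_c_star = rc_star)
      st$heal_init <- TRUE
    }
    st$bio <- step_biology(st$bio, dt, params$bio)
    attr(st$bio, "increments") <- NULL
    st$lambda_r <- remodeling_increment(st$lambda_r, lambda,
                                        st$plastic$lambda_p, dt, m)
  }

  comp <- gp_composition(st, params)
  S <- stress_from_C(C, st$plastic$lambda_p, st$lambda_r, a0, comp, params,
                     pressure = pressure)
  list(state = st, S = S, lambda = lambda,
       Ie = (lambda / (st$plastic$lambda_p * st$lambda_r))^2,
       composition = comp)
}

#' Algorithmically consistent material tangent
#'
#' Central finite differences of the stress returned by [local_update()]
#' with respect to `C`, re-solving the internal variables at every
#' perturbed state so the internal-variable sensitivity is included. The
#' result has the minor and major symmetries expected of `2 dS/dC`.
#'
#' @inheritParams local_update
#' @param h Relative perturbation (default `1e-6` of the mean diagonal).
#' @return A `3 x 3 x 3 x 3` array `D` with `D[i,j,k,l] = 2 dS_ij / dC_kl`.
#' @export
consistent_tangent <- function(C, t, dt, state, params, schedule,
                               a0 = c(1, 0, 0),
                               prestretch_mode = "closed_form",
                               pressure = NULL, h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(1, mean(diag(C)))
  D <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (l in k:3) {
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[l, k] <- h
    Sp <- local_update(C + dC, t, dt, state, params, schedule, a0,
                       prestretch_mode, pressure)$S
    Sm <- local_update(C - dC, t, dt, state, params, schedule, a0,
                       prestretch_mode, pressure)$S
    dS <- (Sp - Sm) / (2 * h)
    # perturbing C_kl and C_lk together: dS = (dS/dC_kl + dS/dC_lk)
    fac <- if (k == l) 1 else 0.5
    D[, , k, l] <- 2 * fac * dS
    D[, , l, k] <- 2 * fac * dS
  }
  D
}

#' Drive a Gauss point through a deformation history
#'
#' Runs the staggered local update along a prescribed sequence of times
#' and deformation gradients (the deformation-history protocol shared with
#' the finite-element solver). Step `k` covers `[times[k], times[k+1])`
#' with the deformation gradient `F_list[[k+1]]` at the step end.
#'
#' @param F_list List of 3x3 deformation gradients, one per time point.
#' @param times Numeric vector of time points, s (strictly increasing,
#'   aligned with the phase boundaries of `schedule`).
#' @inheritParams local_update
#' @param record Function `(step_result) -> named numeric` of extra columns
#'   to record, or `NULL`.
#' @return List with `history` (data.frame: `t`, `lambda`, `lambda_p`,
#'   `lambda_r`, `lambda_e`, `d`, `lambda_max`, `M`, `G`, `rho_c`,
#'   `rho_0`, `S11`, `sigma11`, ...) and the final `state`.
#' @export
run_point_history <- function(F_list, times, params, schedule,
                              a0 = c(1, 0, 0),
                              prestretch_mode = "closed_form",
                              state = gp_state(params), record = NULL) {
  stopifnot(length(F_list) == length(times), !is.unsorted(times))
  n <- length(times)
  rows <- vector("list", n)
  snapshot <- function(t, res) {
    sig <- cauchy_stress(F_list[[match(t, times)]], res$S)
    base <- c(t = t, lambda = res$lambda,
              lambda_p = res$state$plastic$lambda_p,
              lambda_r = res$state$lambda_r,
              lambda_e = sqrt(res$Ie),
              d = res$state$plastic$d,
              lambda_max = res$state$plastic$lambda_max,
              M = res$state$bio$M, G = res$state$bio$G,
              rho_c = res$state$bio$rho_cd + res$state$bio$rho_ci,
              rho_0 = res$composition$rho_0,
              S11 = res$S[1, 1], S22 = res$S[2, 2], S33 = res$S[3, 3],
              sigma11 = sig[1, 1], sigma22 = sig[2, 2], sigma33 = sig[3, 3])
    if (!is.null(record)) base <- c(base, record(res))
    base
  }
  res <- local_update(crossprod(F_list[[1]]), times[1], 0, state, params,
                      schedule, a0, prestretch_mode)
  rows[[1]] <- snapshot(times[1], res)
  for (k in seq_len(n - 1)) {
    dt <- times[k + 1] - times[k]
    res <- local_update(crossprod(F_list[[k + 1]]), times[k], dt, state,
                        params, schedule, a0, prestretch_mode)
    state <- res$state
    rows[[k + 1]] <- snapshot(times[k + 1], res)
  }
  list(history = as.data.frame(do.call(rbind, rows)), state = state)
}
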