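# Damage-stimulated MMP / growth-factor dynamics and collagen turnover
#
# At the start of healing the collagen pool is split by the damage variable
# into damaged and intact fractions. Damaged collagen produces MMP, which
# degrades it; the accumulated MMP signal (a decaying running average)
# produces growth factor, which deposits new intact collagen. The net
# change of the collagen reference density sets the volumetric growth
# target. All rates vanish at homeostasis (M = M0, G = G0, no damaged
# collagen), which is an exact fixed point of the integrator.

#' Biological state at a material point
#'
#' @param M,G MMP and growth factor concentrations, kg/m^3.
#' @param i_M Running integral of the MMP excess `M - M0` over the healing
#'   window, kg s/m^3. (Storing the excess rather than the raw integral
#'   makes homeostasis an exact fixed point in floating point; the window
#'   average of `M` in the accumulated-MMP signal is recovered as
#'   `i_M/(t - t*) + M0`.)
#' @param t_star Healing start time, s.
#' @param t_heal Time elapsed since `t_star`, s.
#' @param rho_cd,rho_ci Damaged / intact collagen reference densities.
#' @param rho_c_star Collagen density at the end of the damage phase.
#' @return An object of class `bio_state`.
#' @export
bio_state <- function(M, G, i_M = 0, t_star = 0, t_heal = 0,
                      rho_cd = 0, rho_ci, rho_c_star) {
  stopifnot(M > 0, G > 0, rho_cd >= 0, rho_ci >= 0, rho_c_star > 0)
  structure(list(M = M, G = G, i_M = i_M, t_star = t_star, t_heal = t_heal,
                 rho_cd = rho_cd, rho_ci = rho_ci, rho_c_star = rho_c_star),
            class = "bio_state")
}

#' Initial damaged / intact collagen pools
#'
#' Splits the collagen density at the end of the damage phase by the final
#' damage variable: `rho_cd* = d* rho_c*`, `rho_ci* = (1 - d*) rho_c*`.
#'
#' @param d_star Damage variable at the end of the damage phase, in `[0,1]`.
#' @param rho_c_star Collagen reference density at that time, kg/m^3.
#' @return Named numeric vector `c(rho_cd, rho_ci)` summing to `rho_c_star`.
#' @export
init_pools <- function(d_star, rho_c_star) {
  if (d_star < 0 || d_star > 1) stop("d_star must lie in [0, 1]")
  if (rho_c_star <= 0) stop("rho_c_star must be positive")
  c(rho_cd = d_star * rho_c_star, rho_ci = (1 - d_star) * rho_c_star)
}

#' Species and mass rates
#'
#' `mmp_rate()`: MMP production by damaged collagen with decay toward the
#' homeostatic level, `m1 rho_cd / rho_c* - m2 (M - M0)`.
#' `accumulated_mmp()`: decaying running average of the MMP excess,
#' `(i_M / (t - t*) - M0) exp(-(t - t*)/t_decay)`; defined by its right
#' limit (zero) at `t = t*`. `gf_rate()`: growth-factor production from the
#' accumulated MMP signal, `g1 I_M - g2 (G - G0)`. `degradation_rate()`:
#' damaged-collagen removal, saturating at `-kd1`, active only for
#' `M > M0`. `production_rate()`: intact-collagen deposition, saturating at
#' `ki1`.
#'
#' @param state A [bio_state()].
#' @param params A [bio_params()] object.
#' @return Rates in kg/(m^3 s); `accumulated_mmp()` returns kg/m^3.
#' @export
mmp_rate <- function(state, params) {
  params$m1 * state$rho_cd / state$rho_c_star -
    params$m2 * (state$M - params$M0)
}

#' @rdname mmp_rate
#' @param t Absolute time, s (`t >= t_star`).
#' @export
accumulated_mmp <- function(state, t, params) {
  s <- t - state$t_star
  if (s < 0) stop("t must not precede the healing start time")
  if (s == 0) return(0)
  (state$i_M / s) * exp(-s / params$t_decay)
}

#' @rdname mmp_rate
#' @param I_M Accumulated MMP signal, kg/m^3.
#' @export
gf_rate <- function(state, I_M, params) {
  params$g1 * I_M - params$g2 * (state$G - params$G0)
}

#' @rdname mmp_rate
#' @param M MMP concentration, kg/m^3.
#' @export
degradation_rate <- function(M, params) {
  if (any(M <= 0)) stop("M must be positive")
  ifelse(M > params$M0,
         params$kd1 * (exp(-params$kd2 * (M - params$M0) / params$M0) - 1),
         0)
}

#' @rdname mmp_rate
#' @param G Growth factor concentration, kg/m^3.
#' @export
production_rate <- function(G, params) {
  if (any(G <= 0)) stop("G must be positive")
  params$ki1 * (1 - exp(-params$ki2 * (G - params$G0) / params$G0))
}

#' One backward-Euler step of the healing biology
#'
#' Advances `(M, rho_cd)` as a coupled implicit pair (fixed-point iteration
#' on the scalar nonlinearity), accumulates `i_M` by the same backward-
#' Euler rule, evaluates the accumulated-MMP signal at the end of the step,
#' then advances `G` (implicit, linear) and the intact-collagen deposition.
#' The damaged pool is clamped at zero; degradation stops once it is
#' exhausted. If `G` ever drops below its homeostatic value a warning is
#' emitted (the unclamped production law then removes mass).
#'
#' @param state A [bio_state()].
#' @param dt Time step, s (> 0).
#' @inheritParams mmp_rate
#' @return The advanced `bio_state`; attribute `increments` carries the
#'   produced and removed collagen mass of the step.
#' @export
step_biology <- function(state, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  p <- params
  rcd_old <- state$rho_cd
  # coupled implicit (M, rho_cd)
  # increment form: M = M0 + (M_prev - M0 + dt m1 rho_cd/rho_c*)/(1 + dt m2)
  # keeps the homeostatic state an exact floating-point fixed point
  rcd <- rcd_old
  M <- state$M
  for (i in 1:100) {
    M_new <- p$M0 +
      (state$M - p$M0 + dt * p$m1 * rcd / state$rho_c_star) /
        (1 + dt * p$m2)
    if (M_new > p$M0 && rcd_old > 0) {
      rcd_new <- max(rcd_old + dt * degradation_rate(M_new, p), 0)
    } else {
      rcd_new <- rcd_old
    }
    if (abs(rcd_new - rcd) <= 1e-13 * max(1, rcd) &&
        abs(M_new - M) <= 1e-18) {
      M <- M_new; rcd <- rcd_new
      break
    }
    M <- M_new; rcd <- rcd_new
    if (i == 100) stop("biology update did not converge (M, rho_cd loop)")
  }
  t_heal <- state$t_heal + dt
  i_M <- state$i_M + dt * (M - p$M0)
  I_M <- (i_M / t_heal) * exp(-t_heal / p$t_decay)
  G <- p$G0 + (state$G - p$G0 + dt * p$g1 * I_M) / (1 + dt * p$g2)
  if (G < p$G0 - 1e-12 * p$G0)
    warning("growth factor fell below its homeostatic level; ",
            "collagen production is negative")
  produced <- dt * production_rate(G, p)
  removed <- rcd_old - rcd
  rci <- state$rho_ci + produced
  out <- bio_state(M = M, G = G, i_M = i_M, t_star = state$t_star,
                   t_heal = t_heal, rho_cd = rcd, rho_ci = rci,
                   rho_c_star = state$rho_c_star)
  attr(out, "increments") <- c(produced = produced, removed = removed)
  out
}

#' Volumetric growth target
#'
#' The dilatation the penalty energy drives the tissue toward:
#' `rho_0 / rho_0(0)`.
#'
#' @param rho_0 Current total reference density, kg/m^3.
#' @param rho0_init Initial total reference density, kg/m^3.
#' @return Target volume ratio (dimensionless).
#' @export
growth_target <- function(rho_0, rho0_init) {
  if (rho_0 <= 0 || rho0_init <= 0) stop("densities must be positive")
  rho_0 / rho0_init
}

#' Integrate the healing biology at a material point
#'
#' Runs the species system for a fixed damage value, as in the
#' single-material-point species study: pools are initialized from
#' `d_star`, then advanced by [step_biology()] with constant step `dt`.
#'
#' @param d_star Damage value in `[0, 1]`.
#' @param params A [bio_params()] object.
#' @param rho_c_star Collagen density at healing start, kg/m^3.
#' @param rho_m Matrix reference density (constant), kg/m^3.
#' @param t_end Healing horizon, s.
#' @param dt Time step, s (default 0.1 day).
#' @return A data.frame with columns `t` (s), `M`, `G`, `I_M`, `rho_cd`,
#'   `rho_ci`, `rho_c`, `rho_0`.
#' @export
integrate_biology <- function(d_star, params, rho_c_star = 840,
                              rho_m = 210, t_end = SECONDS_PER_YEAR,
                              dt = 0.1 * SECONDS_PER_DAY) {
  pools <- init_pools(d_star, rho_c_star)
  st <- bio_state(M = params$M0, G = params$G0, i_M = 0, t_star = 0,
                  t_heal = 0, rho_cd = pools[["rho_cd"]],
                  rho_ci = pools[["rho_ci"]], rho_c_star = rho_c_star)
  n <- ceiling(t_end / dt - 1e-9)
  out <- matrix(NA_real_, nrow = n + 1, ncol = 8,
                dimnames = list(NULL, c("t", "M", "G", "I_M", "rho_cd",
                                        "rho_ci", "rho_c", "rho_0")))
  record <- function(i, st, t) {
    I_M <- accumulated_mmp(st, t, params)
    out[i, ] <<- c(t, st$M, st$G, I_M, st$rho_cd, st$rho_ci,
                   st$rho_cd + st$rho_ci, st$rho_cd + st$rho_ci + rho_m)
  }
  record(1, st, 0)
  for (k in seq_len(n)) {
    h <- min(dt, t_end - (k - 1) * dt)
    st <- step_biology(st, h, params)
    record(k + 1, st, st$t_heal)
  }
  as.data.frame(out)
}
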