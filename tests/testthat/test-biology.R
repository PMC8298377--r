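test_that("collagen pools are split by the damage variable", {
  expect_equal(init_pools(0, 840), c(rho_cd = 0, rho_ci = 840))
  expect_equal(init_pools(1, 840), c(rho_cd = 840, rho_ci = 0))
  expect_equal(init_pools(0.56, 840), c(rho_cd = 470.4, rho_ci = 369.6))
  expect_equal(sum(init_pools(0.37, 777)), 777)
  expect_error(init_pools(1.2, 840), "0, 1")
})

test_that("species rates vanish at homeostasis and have the stated limits", {
  p <- params_species()
  st <- bio_state(M = p$M0, G = p$G0, rho_cd = 0, rho_ci = 840,
                  rho_c_star = 840)
  expect_equal(mmp_rate(st, p), 0)
  expect_equal(gf_rate(st, 0, p), 0)
  expect_equal(degradation_rate(p$M0, p), 0)
  expect_equal(production_rate(p$G0, p), 0)

  st$rho_cd <- 0.5 * st$rho_c_star
  expect_equal(mmp_rate(st, p), 2e-11)
  st$G <- 2 * p$G0
  expect_lt(gf_rate(st, 0, p), 0)
  expect_equal(gf_rate(st, 1e-5, p) + p$g2 * p$G0, 1e-9)

  # saturation limits of removal and deposition
  expect_equal(degradation_rate(2 * p$M0, p),
               1e-4 * (exp(-10) - 1), tolerance = 1e-12)
  expect_gte(degradation_rate(100 * p$M0, p), -p$kd1)
  expect_equal(production_rate(2 * p$G0, p), p$ki1 * (1 - exp(-2)),
               tolerance = 1e-12)
  expect_lte(production_rate(100 * p$G0, p), p$ki1)
})

test_that("accumulated MMP signal is the decaying window average", {
  p <- params_species()
  # M identically at homeostasis: zero excess integral, zero signal
  st <- bio_state(M = p$M0, G = p$G0, i_M = 0, t_star = 0,
                  t_heal = 1e6, rho_cd = 0, rho_ci = 840,
                  rho_c_star = 840)
  expect_equal(accumulated_mmp(st, 1e6, p), 0)
  expect_equal(accumulated_mmp(st, 0, p), 0)  # right limit at t = t*
  # constant excess c over the window: I_M = c exp(-t / t_decay)
  cexc <- 2e-5
  st$i_M <- cexc * 1e6
  expect_equal(accumulated_mmp(st, 1e6, p), cexc * exp(-1e6 / p$t_decay),
               tolerance = 1e-12)
  # vanishing for t >> t_decay
  st$i_M <- cexc * 20 * p$t_decay
  expect_lt(accumulated_mmp(st, 20 * p$t_decay, p), 1e-12)
})

test_that("homeostasis is an exact fixed point of the integrator", {
  p <- params_species()
  tr <- integrate_biology(0, p, t_end = 100 * SECONDS_PER_DAY,
                          dt = SECONDS_PER_DAY)
  expect_true(all(tr$M == p$M0))
  expect_true(all(tr$G == p$G0))
  expect_true(all(tr$rho_c == 840))
})

test_that("damage triggers the delayed MMP/GF cascade and mass turnover", {
  p <- params_species()
  tr <- integrate_biology(0.5, p, dt = 0.25 * SECONDS_PER_DAY)
  iM <- which.max(tr$M); iG <- which.max(tr$G)
  expect_gt(tr$M[iM], p$M0)         # MMP peaks above homeostasis ...
  expect_lt(tr$M[nrow(tr)], 1.001 * tr$M[iM])
  expect_gt(tr$t[iG], tr$t[iM])     # ... and GF peaks later
  expect_lt(abs(tr$M[nrow(tr)] - p$M0), 0.02 * p$M0)  # M back toward M0
  expect_equal(min(tr$rho_cd), 0)   # damaged collagen fully removed
  expect_gt(tr$rho_c[nrow(tr)], tr$rho_c[1])
  # removal reaches zero in finite time
  expect_lt(min(tr$t[tr$rho_cd == 0]), SECONDS_PER_YEAR / 2)
})

test_that("bookkeeping of a biology step is exactly conservative", {
  p <- params_species()
  pools <- init_pools(0.5, 840)
  st <- bio_state(M = p$M0, G = p$G0, rho_cd = pools[["rho_cd"]],
                  rho_ci = pools[["rho_ci"]], rho_c_star = 840)
  for (k in 1:50) {
    st_new <- step_biology(st, 0.1 * SECONDS_PER_DAY, p)
    inc <- attr(st_new, "increments")
    d_rho <- (st_new$rho_cd + st_new$rho_ci) - (st$rho_cd + st$rho_ci)
    expect_lt(abs(d_rho - (inc[["produced"]] - inc[["removed"]])), 1e-12)
    st <- st_new
  }
})

test_that("MMP reaches its analytic fixed point under a pinned damaged pool", {
  # with negligible degradation the damaged pool stays at rho_c*, and the
  # linear MMP equation has the fixed point M0 + m1/m2
  p <- params_species()
  p$kd1 <- 1e-30
  pools <- init_pools(1, 840)
  st <- bio_state(M = p$M0, G = p$G0, rho_cd = pools[["rho_cd"]],
                  rho_ci = pools[["rho_ci"]], rho_c_star = 840)
  for (k in 1:365) st <- step_biology(st, SECONDS_PER_DAY, p)
  M_ss <- p$M0 + p$m1 / p$m2
  expect_equal(M_ss, 9.6e-5)
  expect_lt(abs(st$M - M_ss) / M_ss, 0.001)
})

test_that("backward Euler agrees with an adaptive stiff integrator", {
  p <- params_species()
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      dM <- p$m1 * rcd / 840 - p$m2 * (M - p$M0)
      IM <- if (t > 0) (iM / t - p$M0) * exp(-t / p$t_decay) else 0
      dG <- p$g1 * IM - p$g2 * (G - p$G0)
      drcd <- if (M > p$M0 && rcd > 0)
        p$kd1 * (exp(-p$kd2 * (M - p$M0) / p$M0) - 1) else 0
      if (rcd + 1e4 * drcd < 0) drcd <- -rcd / 1e4
      drci <- p$ki1 * (1 - exp(-p$ki2 * (G - p$G0) / p$G0))
      list(c(dM, iM = M, dG, drcd, drci))
    })
  }
  y0 <- c(M = p$M0, iM = 0, G = p$G0, rcd = 0.5 * 840, rci = 0.5 * 840)
  out <- deSolve::lsoda(y0, c(0, SECONDS_PER_YEAR), rhs, NULL,
                        rtol = 1e-10, atol = 1e-14)
  rho_ref <- sum(out[nrow(out), c("rcd", "rci")])
  tr <- integrate_biology(0.5, p, dt = 0.05 * SECONDS_PER_DAY)
  expect_lt(abs(tr$rho_c[nrow(tr)] - rho_ref) / rho_ref, 0.003)
})

test_that("self-convergence: halving the step changes the yearly mass < 0.5%", {
  p <- params_species()
  r1 <- integrate_biology(0.5, p, dt = 0.2 * SECONDS_PER_DAY)
  r2 <- integrate_biology(0.5, p, dt = 0.1 * SECONDS_PER_DAY)
  expect_lt(abs(r1$rho_c[nrow(r1)] - r2$rho_c[nrow(r2)]) /
              r2$rho_c[nrow(r2)], 0.005)
})

test_that("response intensity is monotone in the damage value", {
  p <- params_species()
  runs <- lapply(c(0, 0.1, 0.4, 0.7, 1),
                 function(d) integrate_biology(d, p,
                                               dt = 0.5 * SECONDS_PER_DAY))
  peak_M <- vapply(runs, function(r) max(r$M), numeric(1))
  peak_G <- vapply(runs, function(r) max(r$G), numeric(1))
  final_rc <- vapply(runs, function(r) r$rho_c[nrow(r)], numeric(1))
  expect_true(all(diff(peak_M) >= 0))
  expect_true(all(diff(peak_G) >= 0))
  expect_true(all(diff(final_rc) >= 0))
})

test_that("growth target is the reference density ratio", {
  expect_equal(growth_target(1050, 1050), 1)
  expect_equal(growth_target(1.2 * 1050, 1050), 1.2)
  # bookkeeping identity after a healing run
  p <- params_species()
  tr <- integrate_biology(0.5, p, dt = 0.5 * SECONDS_PER_DAY)
  n <- nrow(tr)
  expect_equal(growth_target(tr$rho_0[n], tr$rho_0[1]),
               1 + (tr$rho_c[n] - tr$rho_c[1]) / tr$rho_0[1],
               tolerance = 1e-12)
})
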