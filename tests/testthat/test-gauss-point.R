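test_that("phases partition time with boundaries in the later phase", {
  s <- phase_schedule(60, 120, 1000)
  expect_equal(phase_of(0, s), "prestretch")
  expect_equal(phase_of(59.999, s), "prestretch")
  expect_equal(phase_of(60, s), "damage")
  expect_equal(phase_of(119.999, s), "damage")
  expect_equal(phase_of(120, s), "healing")
  expect_equal(phase_of(1e9, s), "healing")
  expect_error(phase_schedule(60, 60, 100), "t0 < t_star")
})

test_that("reference state is stress-free and inert in every phase", {
  p <- params_biaxial()
  s <- test_schedule()
  st <- gp_state(p)
  for (t in c(0, 60, 120)) {
    res <- local_update(diag(3), t, 0, st, p, s)
    expect_lt(max(abs(res$S)), 1e-10)
    expect_identical(res$state, st)
  }
})

test_that("phase freezing of the staggered scheme is exact", {
  p <- params_biaxial()
  s <- test_schedule()
  st <- gp_state(p)
  # prestretch then a damaging stretch
  st <- local_update(diag(c(1.34^2, 1.25^2, 0.36)), 0, 60, st, p, s)$state
  bio_before <- st$bio
  st <- local_update(diag(c(1.83^2, 1.25^2, 0.36)), 60, 30, st, p, s)$state
  expect_identical(st$bio, bio_before)        # biology frozen in damage
  expect_gt(st$plastic$d, 0)
  # healing freezes the plastic set bitwise
  pl_before <- st$plastic
  C_hold <- diag(c(1.34^2, 1.25^2, 0.36))
  for (k in 1:10)
    st <- local_update(C_hold, 120 + (k - 1) * 8640, 8640, st, p, s)$state
  expect_identical(st$plastic, pl_before)
  expect_true(st$heal_init)
  # pools were initialized from the collagen density at the end of the
  # damage phase (unchanged through prestretch and damage)
  expect_equal(st$bio$rho_c_star, 840)
})

test_that("homeostatic healing keeps the stress trajectory constant", {
  p <- params_biaxial()
  s <- test_schedule()
  st <- gp_state(p)
  C <- diag(c(1.1^2, 1, 1 / 1.1^2))
  # prestretch establishes the remodeling fixed point lambda_e = lambda_pre;
  # healing then starts with d* = 0 (no damage ever occurred)
  st <- local_update(C, 0, 60, st, p, s)$state
  res0 <- local_update(C, 120, 8640, st, p, s)
  st <- res0$state
  for (k in 1:20) {
    res <- local_update(C, 120 + k * 8640, 8640, st, p, s)
    st <- res$state
    expect_equal(res$S, res0$S, tolerance = 1e-12)
  }
})

test_that("consistent tangent matches extrapolated directional derivatives", {
  p <- params_biaxial()
  s <- test_schedule()
  set.seed(41)
  for (case_k in 1:6) {
    lam <- stats::runif(1, 1.3, 1.9)
    C <- crossprod(diag(c(lam, 1.25, 0.62)) +
                     0.02 * matrix(stats::rnorm(9), 3))
    st <- gp_state(p)
    st$lambda_r <- 1.34 / 1.062
    t <- sample(c(80, 200), 1)   # a damage-phase and a healing-phase case
    dt <- if (t < 120) 0.25 else 8640
    D <- consistent_tangent(C, t, dt, st, p, s)
    # independent route: Richardson-extrapolated central differences of
    # the updated stress along random directions
    for (r in 1:3) {
      dC <- matrix(stats::rnorm(9), 3); dC <- (dC + t(dC)) / 2
      dC <- dC / max(abs(dC))
      gh <- function(h) {
        Sp <- local_update(C + h * dC, t, dt, st, p, s)$S
        Sm <- local_update(C - h * dC, t, dt, st, p, s)$S
        (Sp - Sm) / (2 * h)
      }
      h <- 2e-5
      rich <- (4 * gh(h) - gh(2 * h)) / 3
      pred <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3)
        pred[i, j] <- 0.5 * sum(D[i, j, , ] * dC)
      expect_lt(max(abs(pred - rich)) / max(abs(rich)), 1e-5)
    }
  }
})

test_that("compiled kernel reproduces the R local update bitwise", {
  p <- params_biaxial()
  s <- test_schedule()
  a0 <- c(1, 0, 0)
  stR <- gp_state(p)
  stC <- mechanoheal:::gp_state_vector(stR)
  pv <- mechanoheal:::param_vector(p)
  steps <- list(list(0, 30, 1.2), list(30, 30, 1.34), list(60, 20, 1.7),
                list(80, 20, 1.83), list(100, 20, 1.34),
                list(120, 8640, 1.34), list(120 + 8640, 8640, 1.34))
  for (stp in steps) {
    C <- diag(c(stp[[3]]^2, 1.25^2, 0.36))
    phase <- mechanoheal:::phase_code(phase_of(stp[[1]], s))
    resR <- local_update(C, stp[[1]], stp[[2]], stR, p, s, a0)
    resC <- mechanoheal:::.cpp_gp_update(stC, C, phase, stp[[2]], pv, a0,
                                         0, TRUE, 1L)
    stR <- resR$state
    stC <- resC$state
    expect_equal(max(abs(mechanoheal:::gp_state_vector(stR) - stC)), 0)
    expect_lt(max(abs(resR$S - resC$S)), 1e-9 * max(1, max(abs(resR$S))))
  }
})

test_that("plastic dissipation is non-negative at every damage step", {
  p <- params_biaxial()
  s <- test_schedule()
  st <- gp_state(p)
  st <- local_update(diag(c(1.34^2, 1.25^2, 0.36)), 0, 60, st, p, s)$state
  lp_prev <- st$plastic$lambda_p
  for (lam in seq(1.34, 1.93, by = 0.01)) {
    res <- local_update(diag(c(lam^2, 1.25^2, 0.36)), 60, 0.25, st, p, s)
    dlp <- res$state$plastic$lambda_p - lp_prev
    if (dlp > 0) {
      S_fiber <- res$S[1, 1]
      expect_gte(S_fiber * dlp, 0)
      expect_gt(S_fiber, 0)   # flow only under fiber tension
    }
    st <- res$state
    lp_prev <- st$plastic$lambda_p
  }
})
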