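test_that("plate mesh has the stated counts, tags and positive Jacobians", {
  m <- make_plate_mesh(0.06, 0.06, 0.012, 22, 22, 8, grading = 1 / 0.7)
  expect_equal(nrow(m$nodes), 23 * 23 * 9)
  expect_equal(nrow(m$elems), 22 * 22 * 8)
  expect_equal(length(m$sets$top), 23 * 23)
  # grading preserves the total dimensions
  expect_lt(abs(max(m$nodes[, 1]) - 0.06), 1e-12)
  expect_lt(abs(max(m$nodes[, 2]) - 0.06), 1e-12)
  # smallest elements sit at the loaded corner
  gx <- sort(unique(m$nodes[, 1]))
  expect_true(all(diff(diff(gx)) > 0))
  # positive reference Jacobians everywhere (volumes sum to the box)
  p <- params_biaxial()
  s <- test_schedule()
  vol <- 0
  sol <- fem_solution(m, p)
  for (e in sample(nrow(m$elems), 25)) {
    ert <- element_residual_tangent(m$nodes[m$elems[e, ], ], numeric(24),
                                    1, 0, sol$states[, , e], 0, 0, p, s,
                                    want_tangent = FALSE)
    expect_gt(ert$volume, 0)
  }
  m1 <- make_plate_mesh(1, 1, 1, 1, 1, 1)
  expect_equal(nrow(m1$nodes), 8)
  expect_equal(nrow(m1$elems), 1)
})

test_that("element tangent is consistent with the residual", {
  p <- params_biaxial()
  s <- test_schedule()
  m <- make_plate_mesh(1, 1, 1, 1, 1, 1)
  sol <- fem_solution(m, p)
  set.seed(51)
  Xe <- m$nodes[m$elems[1, ], ]
  ue <- 0.1 * stats::rnorm(24)
  st <- sol$states[, , 1]
  ert <- element_residual_tangent(Xe, ue, 1.02, 300, st, 70, 0.5, p, s)
  h <- 1e-7
  for (a in sample(24, 8)) {
    up <- ue; up[a] <- up[a] + h
    um <- ue; um[a] <- um[a] - h
    rp <- element_residual_tangent(Xe, up, 1.02, 300, st, 70, 0.5, p, s,
                                   want_tangent = FALSE)$res
    rm <- element_residual_tangent(Xe, um, 1.02, 300, st, 70, 0.5, p, s,
                                   want_tangent = FALSE)$res
    expect_lt(max(abs((rp - rm) / (2 * h) - ert$K[, a])) / max(abs(ert$K)),
              1e-5)
  }
})

test_that("element forces transform objectively under rigid rotation", {
  p <- params_biaxial()
  s <- test_schedule()
  m <- make_plate_mesh(1, 1.2, 0.8, 1, 1, 1)
  sol <- fem_solution(m, p)
  set.seed(52)
  Xe <- m$nodes[m$elems[1, ], ]
  ue <- 0.1 * stats::rnorm(24)
  r0 <- element_residual_tangent(Xe, ue, 1.01, 100, sol$states[, , 1],
                                 70, 0.5, p, s, want_tangent = FALSE)$res
  Q <- rrot()
  XeQ <- Xe %*% t(Q)
  x_cur <- Xe + matrix(ue, 8, 3, byrow = TRUE)
  ueQ <- as.numeric(t(x_cur %*% t(Q) - XeQ))
  rQ <- element_residual_tangent(XeQ, ueQ, 1.01, 100, sol$states[, , 1],
                                 70, 0.5, p, s, a0 = as.numeric(Q %*% c(1, 0, 0)),
                                 want_tangent = FALSE)$res
  for (I in 1:8) {
    fI <- r0[(3 * I - 2):(3 * I)]
    fQ <- rQ[(3 * I - 2):(3 * I)]
    expect_lt(max(abs(fQ - Q %*% fI)), 1e-9 * max(abs(r0)))
  }
  expect_equal(rQ[25:26], r0[25:26], tolerance = 1e-10)
})

test_that("distorted mesh passes the patch test under affine boundary data", {
  p <- params_biaxial()
  p$material$remodel_in_damage <- FALSE   # purely elastic damage-phase step
  s <- test_schedule()
  m <- make_plate_mesh(1, 1, 1, 2, 2, 2)
  set.seed(53)
  interior <- which(apply(m$nodes, 1, function(x)
    all(x > 1e-9 & x < 1 - 1e-9)))
  m$nodes[interior, ] <- m$nodes[interior, ] + 0.08 * stats::rnorm(3)
  sol <- fem_solution(m, p)
  Fa <- matrix(c(1.12, 0.03, 0, 0.02, 1.05, 0, 0, 0, 0.9), 3, 3,
               byrow = TRUE)
  boundary <- setdiff(seq_len(nrow(m$nodes)), interior)
  ub <- t(Fa %*% t(m$nodes[boundary, ])) - m$nodes[boundary, ]
  dirichlet <- data.frame(
    dof = as.integer(outer(3 * (boundary - 1), 1:3, "+")),
    value = as.numeric(ub))
  res <- solve_step(m, sol, dirichlet, numeric(3 * nrow(m$nodes)),
                    60, 0.5, p, s)
  # homogeneous deformation reproduced exactly: every Gauss point sees the
  # same J, stretch and elastic state
  flds <- fem_fields(m, res, p, s)
  expect_lt(diff(range(flds$J)), 1e-9)
  expect_lt(diff(range(flds$lambda)), 1e-9)
  expect_equal(res$theta, rep(det(Fa), 8), tolerance = 1e-9)
  # interior node displacement is the affine map too
  u_int <- res$u[interior, ]
  expect_equal(as.numeric(u_int),
               as.numeric(t(Fa %*% m$nodes[interior, ]) - m$nodes[interior, ]),
               tolerance = 1e-8)
})

test_that("zero load increment converges immediately and changes nothing", {
  p <- params_biaxial()
  p$material$remodel_in_damage <- FALSE
  s <- test_schedule()
  m <- make_plate_mesh(6e-3, 3e-3, 0.225e-3, 1, 1, 1)
  sol <- fem_solution(m, p)
  dirichlet <- rbind(
    data.frame(dof = 3 * (m$sets$x0 - 1) + 1, value = 0),
    data.frame(dof = 3 * (m$sets$y0 - 1) + 2, value = 0),
    data.frame(dof = 3 * (m$sets$z0 - 1) + 3, value = 0))
  # the undeformed reference with fresh internal state is in equilibrium
  res <- solve_step(m, sol, dirichlet, numeric(3 * nrow(m$nodes)),
                    60, 1, p, s)
  expect_equal(attr(res, "iterations"), 1)
  expect_equal(res$u, sol$u)
})

test_that("surface pressure integrates the conical load profile", {
  m <- make_plate_mesh(0.06, 0.06, 0.012, 16, 16, 2, grading = 1 / 0.7)
  expect_equal(apply_surface_pressure(m, 0, 1e-2),
               numeric(3 * nrow(m$nodes)))
  f <- apply_surface_pressure(m, 36e3, 1e-2)
  fz <- f[seq(3, length(f), by = 3)]
  expect_true(all(fz <= 0))
  # quarter-plate resultant of the cone: pi * pbar * r_p^2 / 12
  expect_equal(-sum(fz), pi * 36e3 * 1e-4 / 12, tolerance = 0.02)
  # no load outside the disk
  far <- which(sqrt(rowSums(m$nodes[, 1:2]^2)) > 1.5e-2 |
                 abs(m$nodes[, 3] - 0.012) > 1e-9)
  expect_equal(f[3 * (far - 1) + 3], numeric(length(far)))
})

test_that("single-element solution reproduces the material-point driver", {
  p <- params_biaxial()
  rep <- run_biaxial(p, "prestretched", t_heal = 20 * SECONDS_PER_DAY,
                     dt_heal = 2 * SECONDS_PER_DAY, dt_damage = 1)
  h <- rep$history
  sched <- rep$schedule
  F_list <- lapply(seq_len(nrow(h)), function(i)
    diag(c(h$lambda_x[i], h$lambda_y[i], h$thickness[i] / 0.225e-3)))
  drv <- run_point_history(F_list, h$t, p, sched)
  # fiber Cauchy stress along the whole trajectory, relative to its peak
  scale <- max(abs(h$sigma_xx))
  expect_lt(max(abs(drv$history$sigma11 - h$sigma_xx)) / scale, 1e-6)
  expect_lt(max(abs(drv$history$d - h$d)), 1e-9)
  expect_lt(max(abs(drv$history$lambda_r - h$lambda_r)), 1e-8)
  expect_lt(max(abs(drv$history$rho_0 - h$rho_0)) / 1050, 1e-9)
})

test_that("traction release leaves the prestretched plate in equilibrium", {
  p <- params_indentation()
  s <- test_schedule()
  m <- make_plate_mesh(0.06, 0.06, 0.012, 3, 3, 2)
  sol <- fem_solution(m, p)
  nn <- nrow(m$nodes)
  sym <- rbind(
    data.frame(dof = 3 * (m$sets$x0 - 1) + 1, value = 0),
    data.frame(dof = 3 * (m$sets$y0 - 1) + 2, value = 0),
    data.frame(dof = 3 * (m$sets$z0 - 1) + 3, value = 0))
  loadfun <- function(t) {
    fr <- min(t / 60, 1)
    list(dirichlet = rbind(
      sym,
      data.frame(dof = 3 * (m$sets$xl - 1) + 1,
                 value = 0.34 * fr * m$nodes[m$sets$xl, 1]),
      data.frame(dof = 3 * (m$sets$yl - 1) + 2,
                 value = 0.25 * fr * m$nodes[m$sets$yl, 2])),
      fext = numeric(3 * nn))
  }
  run <- run_fem(m, sol, seq(0, 60, length.out = 5), loadfun, p, s)
  sol <- run$sol
  # collagen remodeled to the deposition prestretch at every Gauss point
  flds <- fem_fields(m, sol, p, s)
  expect_equal(flds$lambda_e, rep(1.062, nrow(flds)), tolerance = 1e-9)
  rel_dofs <- c(3 * (m$sets$xl - 1) + 1, 3 * (m$sets$yl - 1) + 2)
  fext <- release_to_tractions(attr(sol, "reactions"), rel_dofs)
  expect_equal(release_to_tractions(numeric(3 * nn) * 0, rel_dofs),
               numeric(3 * nn))   # zero prestretch -> zero tractions
  u_before <- sol$u
  res <- solve_step(m, sol, sym, fext, 60, 0.25, p, s)
  expect_lt(max(abs(res$u - u_before)), 1e-8)
})

test_that("growth constraint error decreases monotonically with kappa", {
  # single-element biaxial healing at a shortened horizon; the constraint
  # error e(kappa) = |J - rho_0/rho_0(0)| at the end must fall as the
  # penalty stiffens
  sweep <- run_kappa_sweep(kappas = 10^(4:8),
                           dt_damage = 1,
                           dt_heal = 5 * SECONDS_PER_DAY,
                           t_heal = 60 * SECONDS_PER_DAY)
  expect_true(all(diff(log(sweep$e)) < 0))
})
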