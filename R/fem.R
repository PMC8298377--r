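# Mixed H1-P0 finite-element solver on hexahedral meshes
#
# Trilinear displacements with an element-wise constant dilatation theta
# and pressure-like multiplier p (Hu-Washizu three-field form of the
# volumetric term). theta and p are condensed at element level, so the
# global Newton system is displacement-only; element residual/tangent
# evaluation (including the staggered Gauss-point update and the
# finite-difference consistent tangent) runs in compiled code.

#' Structured hexahedral plate mesh
#'
#' Generates an `nx x ny x nz` hexahedral mesh of the box
#' `[0,lx] x [0,ly] x [0,lz]` with optional geometric grading of the
#' element sizes in x and y toward the corner at the origin (where the
#' indentation load is centered). Boundary node sets are tagged.
#'
#' @param lx,ly,lz Plate dimensions, m.
#' @param nx,ny,nz Number of elements per direction.
#' @param grading Ratio of successive element sizes moving away from the
#'   refined corner (1 = uniform; the indentation study uses `1/0.7`).
#' @param fiber Unit reference fiber direction, applied to every element.
#' @return An object of class `hex_mesh`: list with `nodes` (N x 3),
#'   `elems` (E x 8 connectivity), `sets` (node index vectors `x0`, `xl`,
#'   `y0`, `yl`, `z0`, `top`), `a0`, and `dims`.
#' @export
make_plate_mesh <- function(lx, ly, lz, nx, ny, nz, grading = 1,
                            fiber = c(1, 0, 0)) {
  gx <- graded_coords(lx, nx, grading)
  gy <- graded_coords(ly, ny, grading)
  gz <- graded_coords(lz, nz, 1)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))[, 1:3]
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  elems <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                    nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  tol <- 1e-12 * max(lx, ly, lz)
  sets <- list(
    x0 = which(abs(nodes[, 1]) < tol),
    xl = which(abs(nodes[, 1] - lx) < tol),
    y0 = which(abs(nodes[, 2]) < tol),
    yl = which(abs(nodes[, 2] - ly) < tol),
    z0 = which(abs(nodes[, 3]) < tol),
    top = which(abs(nodes[, 3] - lz) < tol))
  structure(list(nodes = nodes, elems = elems, sets = sets,
                 a0 = fiber / sqrt(sum(fiber^2)),
                 dims = c(lx = lx, ly = ly, lz = lz),
                 n_el = c(nx = nx, ny = ny, nz = nz)),
            class = "hex_mesh")
}

# node coordinates with geometric size grading (smallest element at 0)
graded_coords <- function(L, n, grading) {
  if (grading == 1) return(seq(0, L, length.out = n + 1))
  sizes <- grading^(0:(n - 1))
  sizes <- sizes / sum(sizes) * L
  c(0, cumsum(sizes))
}

#' Initial field solution on a mesh
#'
#' Zero displacements, unit dilatation, zero pressure and fresh
#' Gauss-point internal states everywhere.
#'
#' @param mesh A [make_plate_mesh()] mesh.
#' @param params A [heal_params()] object.
#' @return An object of class `fem_solution`.
#' @export
fem_solution <- function(mesh, params) {
  ne <- nrow(mesh$elems)
  st0 <- gp_state_vector(gp_state(params))
  structure(list(
    u = matrix(0, nrow(mesh$nodes), 3),
    theta = rep(1, ne),
    p = rep(0, ne),
    states = array(rep(st0, 8 * ne), dim = c(length(st0), 8, ne))),
    class = "fem_solution")
}

# gp_state (R list) <-> flat numeric state vector used by the kernel
gp_state_vector <- function(state) {
  c(lambda_p = state$plastic$lambda_p, hist_lambda = state$hist_lambda,
    lambda_max = state$plastic$lambda_max, d = state$plastic$d,
    lambda_r = state$lambda_r, M = state$bio$M, G = state$bio$G,
    i_M = state$bio$i_M, rho_cd = state$bio$rho_cd,
    rho_ci = state$bio$rho_ci, t_heal = state$bio$t_heal,
    heal_init = as.numeric(state$heal_init))
}

gp_state_from_vector <- function(v, params, t_star = 0) {
  rc_star <- if (v[12] > 0.5) params$material$rho0_init *
    params$material$phi_c0 else v[9] + v[10]
  structure(list(
    plastic = plastic_state(lambda_p = v[[1]], lambda_max = v[[3]],
                            d = v[[4]]),
    hist_lambda = v[[2]], lambda_r = v[[5]],
    bio = bio_state(M = v[[6]], G = v[[7]], i_M = v[[8]], t_star = t_star,
                    t_heal = v[[11]], rho_cd = v[[9]], rho_ci = v[[10]],
                    rho_c_star = rc_star),
    heal_init = v[12] > 0.5), class = "gp_state")
}

phase_code <- function(phase) {
  match(phase, c("prestretch", "damage", "healing")) - 1L
}

#' Element residual and consistent tangent
#'
#' Evaluates the stationarity conditions of the three-field element
#' functional for one hexahedral element, advancing the Gauss-point
#' internal variables over `[t, t + dt)` from the committed `states`
#' (which are not modified; the advanced states are returned).
#'
#' @param Xe 8 x 3 reference node coordinates.
#' @param ue Length-24 element displacement vector (node-major xyz).
#' @param theta,p Element dilatation and pressure.
#' @param states 12 x 8 matrix of committed Gauss-point state vectors.
#' @param t,dt Step start and size, s.
#' @inheritParams local_update
#' @param want_tangent Assemble the 26 x 26 consistent tangent?
#' @return List with `res` (length 26), `K` (26 x 26), `states_new`,
#'   element `volume`, `theta_target`, `Jbar` and a per-Gauss-point
#'   diagnostics matrix.
#' @export
element_residual_tangent <- function(Xe, ue, theta, p, states, t, dt,
                                     params, schedule, a0 = c(1, 0, 0),
                                     prestretch_mode = "closed_form",
                                     want_tangent = TRUE) {
  .cpp_element_rt(Xe, ue, theta, p, states, a0,
                  phase_code(phase_of(t, schedule)), dt,
                  param_vector(params),
                  as.integer(prestretch_mode == "closed_form"),
                  want_tangent)
}

#' Dead surface pressure on the top face
#'
#' Consistent nodal forces of a pressure field `p(r) = pbar * (1 - r/r_p)`
#' for `r <= r_p` (zero outside) acting in `-z` on the reference top
#' surface, with `r = sqrt(x^2 + y^2)` in reference coordinates (dead
#' load). Integration by 2 x 2 Gauss quadrature per top facet.
#'
#' @param mesh A [make_plate_mesh()] mesh.
#' @param pbar Peak pressure at the center, Pa.
#' @param r_p Load radius, m.
#' @return External force vector of length `3 * n_nodes`.
#' @export
apply_surface_pressure <- function(mesh, pbar, r_p) {
  f <- numeric(3 * nrow(mesh$nodes))
  if (pbar == 0) return(f)
  lz <- mesh$dims[["lz"]]
  tol <- 1e-9 * lz
  top_el <- which(apply(mesh$elems, 1, function(conn)
    all(abs(mesh$nodes[conn[5:8], 3] - lz) < tol)))
  gp <- c(-1, 1) / sqrt(3)
  for (e in top_el) {
    conn <- mesh$elems[e, 5:8]  # top facet, counter-clockwise
    X <- mesh$nodes[conn, 1:2]
    for (gx in gp) for (gy in gp) {
      N <- 0.25 * c((1 - gx) * (1 - gy), (1 + gx) * (1 - gy),
                    (1 + gx) * (1 + gy), (1 - gx) * (1 + gy))
      dNdxi <- 0.25 * cbind(c(-(1 - gy), (1 - gy), (1 + gy), -(1 + gy)),
                            c(-(1 - gx), -(1 + gx), (1 + gx), (1 - gx)))
      Jf <- crossprod(dNdxi, X)        # 2x2 facet Jacobian
      dA <- abs(det(Jf))
      xy <- as.numeric(crossprod(N, X))
      r <- sqrt(sum(xy^2))
      pr <- if (r <= r_p) pbar * (1 - r / r_p) else 0
      if (pr > 0) {
        idx <- 3 * (conn - 1) + 3
        f[idx] <- f[idx] - pr * N * dA
      }
    }
  }
  f
}

#' One global Newton step of the mixed solver
#'
#' Solves the displacement-only system obtained by condensing the element
#' (theta, p) pair, with internal variables re-solved locally at every
#' iteration (nested Newton). Internal states, theta and p are committed
#' only on convergence.
#'
#' @param mesh A [make_plate_mesh()] mesh.
#' @param sol Converged [fem_solution()] of the previous step.
#' @param dirichlet Data frame with columns `dof` (global displacement dof,
#'   `3*(node-1)+i`) and `value` (total prescribed displacement at the end
#'   of the step).
#' @param fext External force vector (length `3 * n_nodes`).
#' @param t,dt Step start and size, s.
#' @inheritParams local_update
#' @param control List of solver controls: `tol_rel` (default 1e-8),
#'   `max_iter` (25).
#' @return The converged `fem_solution`; attributes `iterations` and
#'   `residual_norm`.
#' @export
solve_step <- function(mesh, sol, dirichlet, fext, t, dt, params, schedule,
                       prestretch_mode = "closed_form", control = list()) {
  tol_rel <- control$tol_rel %||% 1e-8
  max_iter <- control$max_iter %||% 25
  nn <- nrow(mesh$nodes)
  ndof <- 3 * nn
  fixed <- dirichlet$dof
  free <- setdiff(seq_len(ndof), fixed)

  u <- as.numeric(t(sol$u))          # dof-ordered: node-major xyz
  u[fixed] <- dirichlet$value
  theta <- sol$theta
  p <- sol$p
  ne <- nrow(mesh$elems)
  par_vec <- param_vector(params)
  phase <- phase_code(phase_of(t, schedule))
  pcf <- as.integer(prestretch_mode == "closed_form")

  edof <- lapply(seq_len(ne), function(e) {
    conn <- mesh$elems[e, ]
    as.integer(rep(3 * (conn - 1), each = 3) + rep(1:3, 8))
  })
  # column-major flattening of the 24x24 element blocks
  ii <- unlist(lapply(edof, function(d) rep(d, times = 24)))
  jj <- unlist(lapply(edof, function(d) rep(d, each = 24)))

  states_new <- sol$states
  r_full <- NULL
  norm0 <- NULL
  du_norm <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    vals <- numeric(576 * ne)
    r_int <- numeric(ndof)
    cond <- vector("list", ne)
    for (e in seq_len(ne)) {
      conn <- mesh$elems[e, ]
      ert <- .cpp_element_rt(mesh$nodes[conn, , drop = FALSE], u[edof[[e]]],
                             theta[e], p[e], sol$states[, , e], mesh$a0,
                             phase, dt, par_vec, pcf, TRUE)
      states_new[, , e] <- ert$states_new
      K <- ert$K
      A <- K[1:24, 1:24]; B <- K[1:24, 25:26]
      Ct <- K[25:26, 1:24]; Dm <- K[25:26, 25:26]
      # Dm = [[a, b], [b, 0]] exactly (no p-p coupling); invert in closed
      # form -- the generic solve() misjudges the extreme kappa scaling
      Dinv <- matrix(c(0, 1 / Dm[1, 2], 1 / Dm[2, 1],
                       -Dm[1, 1] / (Dm[1, 2] * Dm[2, 1])), 2, 2)
      BD <- B %*% Dinv
      Kc <- A - BD %*% Ct
      rc <- ert$res[1:24] - as.numeric(BD %*% ert$res[25:26])
      vals[(576 * (e - 1) + 1):(576 * e)] <- Kc  # column-major = ii/jj order
      r_int[edof[[e]]] <- r_int[edof[[e]]] + rc
      cond[[e]] <- list(Dinv = Dinv, Ct = Ct, r_tp = ert$res[25:26])
    }
    r_full <- r_int - fext
    rn <- sqrt(sum(r_full[free]^2))
    if (is.null(norm0)) {
      norm0 <- rn
      fscale <- max(sqrt(sum(r_int^2)), sqrt(sum(fext^2)), 1e-300)
    }
    # converged: sufficient relative reduction, or residual negligible on
    # the scale of the internal forces, or stagnation at machine precision
    if (rn <= max(tol_rel * norm0, 1e-9 * fscale) ||
        (iter > 1 && rn <= 1e-6 * fscale &&
         du_norm <= 1e-10 * (1 + sqrt(sum(u^2))))) {
      converged <- TRUE
      break
    }
    Kg <- Matrix::sparseMatrix(i = ii, j = jj, x = vals,
                               dims = c(ndof, ndof))
    du <- numeric(ndof)
    du[free] <- as.numeric(Matrix::solve(Kg[free, free, drop = FALSE],
                                         -r_full[free]))
    du_norm <- sqrt(sum(du^2))
    u <- u + du
    for (e in seq_len(ne)) {
      dtp <- -cond[[e]]$Dinv %*%
        (cond[[e]]$r_tp + cond[[e]]$Ct %*% du[edof[[e]]])
      theta[e] <- theta[e] + dtp[1]
      p[e] <- p[e] + dtp[2]
    }
  }
  if (!converged)
    stop(sprintf(paste0("global Newton did not converge at t = %.6g s ",
                        "(dt = %.3g, phase %s): residual %.3e after %d ",
                        "iterations"),
                 t, dt, phase_of(t, schedule), sqrt(sum(r_full[free]^2)),
                 max_iter))
  out <- structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                        theta = theta, p = p, states = states_new),
                   class = "fem_solution")
  attr(out, "iterations") <- iter
  attr(out, "residual_norm") <- sqrt(sum(r_full[free]^2))
  attr(out, "reactions") <- r_full
  out
}

#' Run a transient finite-element simulation
#'
#' Marches [solve_step()] over a time grid, obtaining boundary conditions
#' from a load function. On Newton failure the step is bisected (up to 4
#' levels) before giving up.
#'
#' @inheritParams solve_step
#' @param times Strictly increasing time points, s (aligned with the phase
#'   boundaries of `schedule`).
#' @param loadfun Function `t -> list(dirichlet = data.frame(dof, value),
#'   fext = numeric)` giving the boundary state at time `t`.
#' @param monitor Optional function `(t, sol, mesh) -> named numeric` of
#'   quantities to record after every step.
#' @return List with the final `sol` and a data.frame `history` of the
#'   monitored quantities.
#' @export
run_fem <- function(mesh, sol, times, loadfun, params, schedule,
                    prestretch_mode = "closed_form", control = list(),
                    monitor = NULL) {
  rows <- list()
  push <- function(t, sol) {
    if (!is.null(monitor))
      rows[[length(rows) + 1]] <<- c(t = t, monitor(t, sol, mesh))
  }
  push(times[1], sol)
  for (k in seq_len(length(times) - 1)) {
    sol <- solve_window(mesh, sol, times[k], times[k + 1], loadfun, params,
                        schedule, prestretch_mode, control, depth = 0)
    push(times[k + 1], sol)
  }
  list(sol = sol,
       history = if (length(rows)) as.data.frame(do.call(rbind, rows))
                 else NULL)
}

solve_window <- function(mesh, sol, t_a, t_b, loadfun, params, schedule,
                         prestretch_mode, control, depth) {
  load <- loadfun(t_b)
  res <- tryCatch(
    solve_step(mesh, sol, load$dirichlet, load$fext, t_a, t_b - t_a,
               params, schedule, prestretch_mode, control),
    error = function(e) e)
  if (!inherits(res, "error")) return(res)
  if (depth >= 4)
    stop(sprintf("step [%.6g, %.6g] failed after 4 bisections: %s",
                 t_a, t_b, conditionMessage(res)))
  t_m <- (t_a + t_b) / 2
  sol <- solve_window(mesh, sol, t_a, t_m, loadfun, params, schedule,
                      prestretch_mode, control, depth + 1)
  solve_window(mesh, sol, t_m, t_b, loadfun, params, schedule,
               prestretch_mode, control, depth + 1)
}

#' Replace prestretch displacement control by boundary tractions
#'
#' After the prestretch phase the essential boundary conditions on the
#' outer faces are swapped for the equivalent nodal reaction forces
#' (natural boundary conditions), leaving the deformation state in
#' equilibrium and free to grow in all directions afterwards.
#'
#' @inheritParams solve_step
#' @param reactions Residual vector at the constrained dofs (attribute
#'   `reactions` of the converged prestretch solution).
#' @param release_dofs Global dofs to convert from essential to natural.
#' @return External force vector holding the boundary tractions.
#' @export
release_to_tractions <- function(reactions, release_dofs, fext = NULL) {
  if (is.null(fext)) fext <- numeric(length(reactions))
  fext[release_dofs] <- reactions[release_dofs]
  fext
}
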