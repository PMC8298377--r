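# End-to-end reference studies
#
# Three studies exercise the model: (i) the species study integrates the
# biology at a single material point for fixed damage values; (ii) the
# biaxial tension test drives a single-element quarter sample through
# prestretch, a two-cycle overstretch damage phase and a year of healing
# in a held configuration; (iii) the indentation test damages a prestretched
# quarter plate by a conical surface pressure and follows the heterogeneous
# healing response. All runs are deterministic.

#' Species study: biology response to fixed damage values
#'
#' Integrates the MMP/GF/collagen system at a single material point for a
#' set of fixed damage values over one year.
#'
#' @param d_values Damage values.
#' @param params A [bio_params()] object.
#' @param rho_c_star,rho_m Collagen / matrix reference densities, kg/m^3.
#' @param t_end Horizon, s.
#' @param dt Time step, s.
#' @return Data frame with columns `d`, `t`, `M`, `G`, `I_M`, `rho_cd`,
#'   `rho_ci`, `rho_c`, `rho_0`.
#' @export
run_species_study <- function(d_values = c(0, 0.1, 0.4, 0.7, 1),
                              params = params_species(),
                              rho_c_star = 840, rho_m = 210,
                              t_end = SECONDS_PER_YEAR,
                              dt = 0.1 * SECONDS_PER_DAY) {
  do.call(rbind, lapply(d_values, function(d) {
    tr <- integrate_biology(d, params, rho_c_star = rho_c_star,
                            rho_m = rho_m, t_end = t_end, dt = dt)
    cbind(d = d, tr)
  }))
}

#' Sensitivity sweep of the biology parameters
#'
#' Scales each of the eight species parameters by the given factors at
#' constant damage and summarizes each run (peak concentrations, final
#' collagen mass, deviation of the MMP trajectory from the reference run).
#'
#' @param parameters Names of the parameters to sweep.
#' @param factors Multiplicative scalings.
#' @param d Fixed damage value.
#' @inheritParams run_species_study
#' @return Data frame with one row per (parameter, factor): `peak_M`,
#'   `peak_G`, `final_rho_c`, `max_dev_M` (max absolute deviation of the
#'   MMP trajectory from the unscaled run).
#' @export
run_sensitivity <- function(parameters = c("m1", "m2", "g1", "g2",
                                           "kd1", "kd2", "ki1", "ki2"),
                            factors = c(1 / 4, 1 / 2, 1, 2, 4), d = 0.5,
                            params = params_species(),
                            rho_c_star = 840, rho_m = 210,
                            t_end = SECONDS_PER_YEAR,
                            dt = 0.1 * SECONDS_PER_DAY) {
  ref <- integrate_biology(d, params, rho_c_star = rho_c_star,
                           rho_m = rho_m, t_end = t_end, dt = dt)
  rows <- list()
  for (pn in parameters) for (f in factors) {
    p2 <- unclass(params)
    p2[[pn]] <- p2[[pn]] * f
    tr <- integrate_biology(d, do.call(bio_params, p2),
                            rho_c_star = rho_c_star, rho_m = rho_m,
                            t_end = t_end, dt = dt)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = pn, factor = f,
      peak_M = max(tr$M), peak_G = max(tr$G),
      t_peak_M = tr$t[which.max(tr$M)], t_peak_G = tr$t[which.max(tr$G)],
      final_rho_c = tr$rho_c[nrow(tr)],
      max_dev_M = max(abs(tr$M - ref$M)))
  }
  do.call(rbind, rows)
}

# piecewise-linear interpolation of the biaxial stretch waveform
biaxial_stretch_x <- function(t, schedule, heal_config,
                              peaks = c(1.83, 1.93), base = 1.34) {
  t0 <- schedule$t0; ts <- schedule$t_star
  q <- (ts - t0) / 4
  knots <- c(0, t0, t0 + q, t0 + 2 * q, t0 + 3 * q, ts)
  vals <- c(1, base, peaks[1], base, peaks[2],
            if (heal_config == "max") peaks[2] else base)
  if (t >= ts) return(vals[6])
  stats::approx(knots, vals, xout = t, rule = 2)$y
}

#' Biaxial tension test: damage and healing of a flat tissue sample
#'
#' Runs the quarter sample (one H1-P0 element, fibers along x, symmetry
#' planes at x=0, y=0, z=0) through (1) prestretch to x-stretch 1.34 /
#' y-stretch 1.25 with collagen remodeled to its deposition prestretch,
#' (2) a 60 s damage phase of two x-stretch cycles with tissue-stretch
#' maxima 1.83 and 1.93 (four equal ramps; y held), and (3) healing for
#' `t_heal` with the in-plane stretches held either at the prestretched
#' configuration (`heal_config = "prestretched"`, x back at 1.34) or at
#' the maximum-stretch configuration (`"max"`, x held at 1.93).
#'
#' @param params A [heal_params()] set, by default [params_biaxial()].
#' @param heal_config `"prestretched"` or `"max"`.
#' @param kappa Optional penalty modulus override, J/kg.
#' @param dt_damage Damage-phase step, s (default 0.25).
#' @param dt_heal Healing-phase step, s (default 0.1 day).
#' @param t_heal Healing horizon, s (default 1 year).
#' @param n_pre Prestretch ramp steps.
#' @param control Passed to [solve_step()].
#' @return An object of class `biaxial_report`: list with `history`
#'   (per-step data frame), scalars `d_star`, `lambda_max_cycle1`,
#'   `lambda_max_cycle2`, `thickness_increase_pct`, `e_kappa` (volume
#'   constraint error at the end), final `lambda_e`, and the final
#'   solution objects.
#' @export
run_biaxial <- function(params = params_biaxial(),
                        heal_config = c("prestretched", "max"),
                        kappa = NULL, dt_damage = 0.25,
                        dt_heal = 0.1 * SECONDS_PER_DAY,
                        t_heal = SECONDS_PER_YEAR, n_pre = 5,
                        control = list()) {
  heal_config <- match.arg(heal_config)
  if (!is.null(kappa)) params$material$kappa <- kappa
  geom <- attr(params, "geometry") %||% c(lx = 6e-3, ly = 3e-3,
                                          lz = 0.225e-3)
  schedule <- phase_schedule(60, 120, 120 + t_heal)
  mesh <- make_plate_mesh(geom[["lx"]], geom[["ly"]], geom[["lz"]],
                          1, 1, 1)
  sol <- fem_solution(mesh, params)
  lz <- geom[["lz"]]
  top_center <- mesh$sets$top[1]

  dir_template <- function(lx_s, ly_s) {
    rbind(
      data.frame(dof = 3 * (mesh$sets$x0 - 1) + 1, value = 0),
      data.frame(dof = 3 * (mesh$sets$y0 - 1) + 2, value = 0),
      data.frame(dof = 3 * (mesh$sets$z0 - 1) + 3, value = 0),
      data.frame(dof = 3 * (mesh$sets$xl - 1) + 1,
                 value = (lx_s - 1) * mesh$nodes[mesh$sets$xl, 1]),
      data.frame(dof = 3 * (mesh$sets$yl - 1) + 2,
                 value = (ly_s - 1) * mesh$nodes[mesh$sets$yl, 2]))
  }
  loadfun <- function(t) {
    frac <- min(t / schedule$t0, 1)
    lx_s <- if (t < schedule$t0) 1 + 0.34 * frac
            else biaxial_stretch_x(t, schedule, heal_config)
    ly_s <- 1 + 0.25 * frac
    list(dirichlet = dir_template(lx_s, ly_s),
         fext = numeric(3 * nrow(mesh$nodes)))
  }
  monitor <- function(t, sol, mesh) {
    st <- sol$states[, 1, 1]
    h <- lz + sol$u[top_center, 3]
    lam_x <- 1 + sol$u[mesh$sets$xl[1], 1] / mesh$nodes[mesh$sets$xl[1], 1]
    lam_y <- 1 + sol$u[mesh$sets$yl[1], 2] / mesh$nodes[mesh$sets$yl[1], 2]
    F <- diag(c(lam_x, lam_y, h / lz))
    state <- gp_state_from_vector(st, params)
    comp <- gp_composition(state, params)
    S <- stress_from_C(crossprod(F), st[1], st[5], mesh$a0, comp, params,
                       pressure = sol$p[1])
    sig <- cauchy_stress(F, S)
    c(lambda_x = lam_x, lambda_y = lam_y, thickness = h,
      J = lam_x * lam_y * h / lz, theta = sol$theta[1], p = sol$p[1],
      lambda_p = st[[1]], lambda_max = st[[3]], d = st[[4]],
      lambda_r = st[[5]], lambda_e = lam_x / (st[[1]] * st[[5]]),
      M = st[[6]], G = st[[7]], rho_c = st[[9]] + st[[10]],
      rho_0 = st[[9]] + st[[10]] + params$material$rho0_init *
        (1 - params$material$phi_c0),
      sigma_xx = sig[1, 1], sigma_zz = sig[3, 3])
  }

  times <- c(seq(0, schedule$t0, length.out = n_pre + 1),
             time_grid(schedule$t0, schedule$t_star, dt_damage)[-1],
             time_grid(schedule$t_star, schedule$t_end, dt_heal)[-1])
  run <- run_fem(mesh, sol, times, loadfun, params, schedule,
                 control = control, monitor = monitor)
  h <- run$history
  i_star <- which.min(abs(h$t - schedule$t_star))
  i_c1 <- which.min(abs(h$t - (schedule$t0 + 30)))
  structure(list(
    history = h, sol = run$sol, mesh = mesh, schedule = schedule,
    params = params, heal_config = heal_config,
    d_star = h$d[i_star],
    lambda_max_cycle1 = h$lambda_max[i_c1],
    lambda_max_cycle2 = h$lambda_max[i_star],
    lambda_p_star = h$lambda_p[i_star],
    thickness_star = h$thickness[i_star],
    thickness_end = h$thickness[nrow(h)],
    thickness_increase_pct =
      100 * (h$thickness[nrow(h)] / h$thickness[i_star] - 1),
    lambda_e_end = h$lambda_e[nrow(h)],
    e_kappa = abs(h$J[nrow(h)] -
                    h$rho_0[nrow(h)] / params$material$rho0_init)),
    class = "biaxial_report")
}

time_grid <- function(a, b, dt) {
  g <- seq(a, b, by = dt)
  if (g[length(g)] < b - 1e-9 * dt) g <- c(g, b)
  g
}

#' Volume-constraint quality versus penalty modulus
#'
#' Repeats the biaxial healing run for a set of penalty moduli and
#' records the end-of-simulation constraint error
#' `e(kappa) = |J(t_end) - rho_0(t_end)/rho_0(0)|`.
#'
#' @param kappas Penalty moduli, J/kg.
#' @inheritParams run_biaxial
#' @return Data frame with `kappa` and `e`.
#' @export
run_kappa_sweep <- function(kappas = 10^(4:8), params = params_biaxial(),
                            heal_config = "prestretched",
                            dt_damage = 0.25,
                            dt_heal = 0.5 * SECONDS_PER_DAY,
                            t_heal = SECONDS_PER_YEAR, control = list()) {
  data.frame(kappa = kappas,
             e = vapply(kappas, function(k)
               run_biaxial(params, heal_config, kappa = k,
                           dt_damage = dt_damage, dt_heal = dt_heal,
                           t_heal = t_heal, control = control)$e_kappa,
               numeric(1)))
}

#' Indentation test: localized damage and heterogeneous healing
#'
#' A quarter plate (fibers along x) is prestretched to x/y stretches
#' 1.34/1.25, the stretch control is swapped for the equivalent boundary
#' tractions, and a conical surface pressure (peak `p_max` at the plate
#' center, radius `r_p`, triangular in time with maximum at the middle of
#' the damage phase) injures the plate. Healing follows for `t_heal` under
#' the constant boundary tractions. Nominal probe strains are referenced
#' to the configuration at the end of the damage phase.
#'
#' @param params A [heal_params()] set, by default [params_indentation()].
#' @param nx,ny,nz Mesh resolution (the reference study uses 22 x 22 x 8;
#'   scaled-down meshes reproduce the qualitative response).
#' @param grading Element size ratio away from the center (default 1/0.7).
#' @param p_max Peak pressure, Pa.
#' @param r_p Load radius, m.
#' @param n_pre,n_damage Prestretch / damage phase steps.
#' @param dt_heal Healing step, s.
#' @param t_heal Healing horizon, s.
#' @param snapshot_days Healing times (days) at which fields are stored.
#' @param control Passed to [solve_step()].
#' @return An object of class `indentation_report`: list with `history`
#'   (probe strains and damage extrema per step), `snapshots` (list of
#'   field data frames), scalars `strain_C_min_pct`, `strain_C_end_pct`,
#'   the mesh and final solution.
#' @export
run_indentation <- function(params = params_indentation(),
                            nx = 22, ny = 22, nz = 8, grading = 1 / 0.7,
                            p_max = 36e3, r_p = 1e-2,
                            n_pre = 5, n_damage = 24,
                            dt_heal = 1 * SECONDS_PER_DAY,
                            t_heal = SECONDS_PER_YEAR,
                            snapshot_days = c(0, 50, 150, 300, 365),
                            control = list()) {
  geom <- attr(params, "geometry") %||% c(lx = 6e-2, ly = 6e-2, lz = 1.2e-2)
  schedule <- phase_schedule(60, 120, 120 + t_heal)
  mesh <- make_plate_mesh(geom[["lx"]], geom[["ly"]], geom[["lz"]],
                          nx, ny, nz, grading = grading)
  sol <- fem_solution(mesh, params)
  nn <- nrow(mesh$nodes)

  sym_dirichlet <- rbind(
    data.frame(dof = 3 * (mesh$sets$x0 - 1) + 1, value = 0),
    data.frame(dof = 3 * (mesh$sets$y0 - 1) + 2, value = 0),
    data.frame(dof = 3 * (mesh$sets$z0 - 1) + 3, value = 0))
  stretch_dofs_x <- 3 * (mesh$sets$xl - 1) + 1
  stretch_dofs_y <- 3 * (mesh$sets$yl - 1) + 2
  pre_dirichlet <- function(frac) rbind(
    sym_dirichlet,
    data.frame(dof = stretch_dofs_x,
               value = 0.34 * frac * mesh$nodes[mesh$sets$xl, 1]),
    data.frame(dof = stretch_dofs_y,
               value = 0.25 * frac * mesh$nodes[mesh$sets$yl, 2]))

  # phase 1: prestretch under displacement control
  pre_load <- function(t) list(dirichlet = pre_dirichlet(min(t / schedule$t0, 1)),
                               fext = numeric(3 * nn))
  run <- run_fem(mesh, sol, seq(0, schedule$t0, length.out = n_pre + 1),
                 pre_load, params, schedule, control = control)
  sol <- run$sol

  # swap essential for natural boundary conditions on the outer faces
  release_dofs <- c(stretch_dofs_x, stretch_dofs_y)
  tractions <- release_to_tractions(attr(sol, "reactions"), release_dofs)

  pbar <- function(t) {
    tm <- (schedule$t0 + schedule$t_star) / 2
    if (t <= schedule$t0 || t >= schedule$t_star) 0
    else if (t <= tm) p_max * (t - schedule$t0) / (tm - schedule$t0)
    else p_max * (schedule$t_star - t) / (schedule$t_star - tm)
  }
  load_after <- function(t) list(
    dirichlet = sym_dirichlet,
    fext = tractions + apply_surface_pressure(mesh, pbar(t), r_p))

  probe_ids <- c(A = nearest_node(mesh, c(geom[["lx"]], 0, geom[["lz"]])),
                 B = nearest_node(mesh, c(0, geom[["ly"]], geom[["lz"]])),
                 C = nearest_node(mesh, c(0, 0, geom[["lz"]])))
  monitor <- function(t, sol, mesh) {
    d_all <- sol$states[4, , ]
    c(x_A = mesh$nodes[probe_ids["A"], 1] + sol$u[probe_ids["A"], 1],
      y_B = mesh$nodes[probe_ids["B"], 2] + sol$u[probe_ids["B"], 2],
      z_C = mesh$nodes[probe_ids["C"], 3] + sol$u[probe_ids["C"], 3],
      d_max = max(d_all), d_mean = mean(d_all))
  }

  t_dmg <- seq(schedule$t0, schedule$t_star, length.out = n_damage + 1)
  run <- run_fem(mesh, sol, t_dmg, load_after, params, schedule,
                 control = control, monitor = monitor)
  sol <- run$sol
  hist_dmg <- run$history
  ref <- hist_dmg[nrow(hist_dmg), ]  # configuration at t = t*

  snapshots <- list()
  take_snapshot <- function(day, sol)
    snapshots[[sprintf("day_%03d", day)]] <<- fem_fields(mesh, sol, params,
                                                         schedule)
  if (0 %in% snapshot_days) take_snapshot(0, sol)
  t_heal_grid <- time_grid(schedule$t_star, schedule$t_end, dt_heal)
  snap_times <- schedule$t_star + snapshot_days * SECONDS_PER_DAY
  hist_heal <- list()
  for (k in seq_len(length(t_heal_grid) - 1)) {
    sol <- solve_window(mesh, sol, t_heal_grid[k], t_heal_grid[k + 1],
                        load_after, params, schedule, "closed_form",
                        control, depth = 0)
    hist_heal[[k]] <- c(t = t_heal_grid[k + 1],
                        monitor(t_heal_grid[k + 1], sol, mesh))
    hit <- which(abs(snap_times - t_heal_grid[k + 1]) < dt_heal / 2)
    for (s in hit) take_snapshot(snapshot_days[s], sol)
  }
  hist_heal <- as.data.frame(do.call(rbind, hist_heal))
  hist_heal$strain_A_x_pct <- 100 * (hist_heal$x_A / ref$x_A - 1)
  hist_heal$strain_B_y_pct <- 100 * (hist_heal$y_B / ref$y_B - 1)
  hist_heal$strain_C_z_pct <- 100 * (hist_heal$z_C / ref$z_C - 1)

  structure(list(
    history_damage = hist_dmg, history = hist_heal,
    snapshots = snapshots, mesh = mesh, sol = sol, schedule = schedule,
    params = params, probe_ids = probe_ids,
    d_star_max = ref$d_max,
    strain_C_min_pct = min(hist_heal$strain_C_z_pct),
    strain_C_end_pct = hist_heal$strain_C_z_pct[nrow(hist_heal)],
    strain_A_end_pct = hist_heal$strain_A_x_pct[nrow(hist_heal)],
    strain_B_end_pct = hist_heal$strain_B_y_pct[nrow(hist_heal)]),
    class = "indentation_report")
}

nearest_node <- function(mesh, x) {
  which.min(colSums((t(mesh$nodes) - x)^2))
}

#' Per-element field summary of a solution
#'
#' Evaluates the Gauss-point diagnostics (volume ratio, stretches, damage,
#' species, densities) at the current solution without advancing the state
#' and averages them per element.
#'
#' @inheritParams solve_step
#' @return Data frame with one row per element.
#' @export
fem_fields <- function(mesh, sol, params, schedule) {
  ne <- nrow(mesh$elems)
  par_vec <- param_vector(params)
  out <- matrix(0, ne, 10)
  for (e in seq_len(ne)) {
    conn <- mesh$elems[e, ]
    ue <- as.numeric(t(sol$u[conn, ]))
    ert <- .cpp_element_rt(mesh$nodes[conn, , drop = FALSE], ue,
                           sol$theta[e], sol$p[e], sol$states[, , e],
                           mesh$a0, 2L, 0, par_vec, 1L, FALSE)
    out[e, ] <- colMeans(ert$diag)
  }
  colnames(out) <- c("J", "lambda", "lambda_e", "d", "lambda_p",
                     "lambda_r", "M", "G", "rho_c", "rho_0")
  as.data.frame(out)
}

#' Write a solution snapshot as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK: hexahedral cells, nodal displacement vectors, and the
#' per-element fields of [fem_fields()] as cell data.
#'
#' @inheritParams fem_fields
#' @param fields Data frame from [fem_fields()] (recomputed if `NULL`).
#' @param path Output file path (`.vtk`).
#' @export
write_vtk <- function(mesh, sol, path, fields = NULL, params = NULL,
                      schedule = NULL) {
  if (is.null(fields)) fields <- fem_fields(mesh, sol, params, schedule)
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("tissue healing simulation")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nn)
  utils::write.table(mesh$nodes, con, row.names = FALSE,
                     col.names = FALSE)
  wl("CELLS %d %d", ne, 9 * ne)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  wl("CELL_TYPES %d", ne)
  writeLines(rep("12", ne), con)
  wl("POINT_DATA %d", nn)
  wl("VECTORS displacement double")
  utils::write.table(sol$u, con, row.names = FALSE, col.names = FALSE)
  wl("CELL_DATA %d", ne)
  for (nm in colnames(fields)) {
    wl("SCALARS %s double 1", nm)
    wl("LOOKUP_TABLE default")
    writeLines(format(fields[[nm]], digits = 10), con)
  }
  invisible(path)
}

#' Write study outputs to disk
#'
#' CSV time series for any data-frame components, a JSON summary of the
#' scalar results, and (for reports carrying a mesh/solution) a VTK
#' snapshot of the final state.
#'
#' @param report A `biaxial_report`, `indentation_report`, or a data frame.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  save_csv <- function(df, name) {
    pth <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, pth, row.names = FALSE)
    paths <<- c(paths, pth)
  }
  if (is.data.frame(report)) {
    save_csv(report, "timeseries")
    return(invisible(paths))
  }
  for (nm in names(report))
    if (is.data.frame(report[[nm]])) save_csv(report[[nm]], nm)
  scalars <- Filter(function(x) is.numeric(x) && length(x) == 1,
                    unclass(report))
  if (length(scalars)) {
    pth <- file.path(dir, "summary.json")
    jsonlite::write_json(scalars, pth, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pth)
  }
  if (!is.null(report$mesh) && !is.null(report$sol)) {
    pth <- file.path(dir, "final_state.vtk")
    write_vtk(report$mesh, report$sol, pth, params = report$params,
              schedule = report$schedule)
    paths <- c(paths, pth)
  }
  if (!is.null(report$snapshots)) {
    for (nm in names(report$snapshots))
      save_csv(report$snapshots[[nm]], paste0("fields_", nm))
  }
  invisible(paths)
}
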