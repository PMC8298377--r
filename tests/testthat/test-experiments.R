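test_that("species study: homeostasis is flat, cascade is ordered, small damage heals", {
  df <- run_species_study(d_values = c(0, 0.1, 0.5),
                          dt = 0.25 * SECONDS_PER_DAY)
  p <- params_species()
  d0 <- df[df$d == 0, ]
  expect_true(all(d0$M == p$M0) && all(d0$G == p$G0) &&
                all(d0$rho_c == 840))
  for (dv in c(0.1, 0.5)) {
    tr <- df[df$d == dv, ]
    expect_lt(tr$t[which.max(tr$M)], tr$t[which.max(tr$G)])
  }
  # small damage: near-complete recovery of the initial collagen mass
  # after about 100 days
  tr <- df[df$d == 0.1, ]
  i100 <- which.min(abs(tr$t - 100 * SECONDS_PER_DAY))
  expect_lt(abs(tr$rho_c[i100] - 840) / 840, 0.05)
})

test_that("sensitivity sweep reproduces the monotone parameter orderings", {
  sw <- run_sensitivity(d = 0.5, dt = 0.5 * SECONDS_PER_DAY)
  get <- function(pn, col) {
    s <- sw[sw$parameter == pn, ]
    s[order(s$factor), col]
  }
  # MMP production/decay
  expect_true(all(diff(get("m1", "peak_M")) > 0))
  expect_true(all(diff(get("m2", "peak_M")) < 0))
  expect_true(all(diff(get("m1", "final_rho_c")) > 0))
  expect_true(all(diff(get("m2", "final_rho_c")) < 0))
  # GF production/decay
  expect_true(all(diff(get("g1", "peak_G")) > 0))
  expect_true(all(diff(get("g2", "peak_G")) < 0))
  expect_true(all(diff(get("g1", "final_rho_c")) > 0))
  expect_true(all(diff(get("g2", "final_rho_c")) < 0))
  # collagen removal / deposition
  expect_true(all(diff(get("kd1", "final_rho_c")) < 0))
  expect_true(all(diff(get("kd2", "final_rho_c")) < 0))
  expect_true(all(diff(get("ki1", "final_rho_c")) > 0))
  expect_true(all(diff(get("ki2", "final_rho_c")) > 0))
  # deposition and GF-production parameters leave the MMP trajectory alone
  for (pn in c("g1", "ki1", "ki2"))
    expect_equal(max(sw$max_dev_M[sw$parameter == pn]), 0)
  # removal saturation constant is the less sensitive of the pair
  ref <- sw$final_rho_c[sw$parameter == "kd1" & sw$factor == 1]
  dev <- function(pn) max(abs(sw$final_rho_c[sw$parameter == pn] - ref))
  expect_lt(dev("kd2"), dev("kd1"))
})

test_that("biaxial pipeline is deterministic and self-consistent", {
  r1 <- run_biaxial(t_heal = 2 * SECONDS_PER_DAY,
                    dt_heal = SECONDS_PER_DAY, dt_damage = 1)
  r2 <- run_biaxial(t_heal = 2 * SECONDS_PER_DAY,
                    dt_heal = SECONDS_PER_DAY, dt_damage = 1)
  expect_identical(r1$history, r2$history)
  # the damage phase leaves the densities untouched
  h <- r1$history
  i_star <- which.min(abs(h$t - r1$schedule$t_star))
  expect_true(all(h$rho_0[1:i_star] == 1050))
  # two stretch cycles: the second maximum dominates the history
  expect_gt(r1$lambda_max_cycle2, r1$lambda_max_cycle1)
  expect_equal(r1$d_star,
               min(1, 2.5 * (r1$lambda_max_cycle2 - 1.3)),
               tolerance = 1e-9)
})

test_that("indentation localizes damage at the center and heals anisotropically", {
  rep <- run_indentation(nx = 6, ny = 6, nz = 3, n_damage = 12,
                         dt_heal = 20 * SECONDS_PER_DAY,
                         snapshot_days = c(365))
  flds <- rep$snapshots[["day_365"]]
  mesh <- rep$mesh
  # element centers
  cx <- vapply(seq_len(nrow(mesh$elems)), function(e)
    mean(mesh$nodes[mesh$elems[e, ], 1]), numeric(1))
  cy <- vapply(seq_len(nrow(mesh$elems)), function(e)
    mean(mesh$nodes[mesh$elems[e, ], 2]), numeric(1))
  r <- sqrt(cx^2 + cy^2)
  # damage is maximal in the center column under the load (any depth) and
  # absent far outside the loaded disk
  expect_lt(r[which.max(flds$d)], min(r) + 1e-12)
  expect_gt(max(flds$d), 0)
  expect_equal(max(flds$d[r > 3e-2]), 0)
  # thickness strain at the center probe: removal-driven shrinkage first,
  # net growth at the end
  expect_lt(rep$strain_C_min_pct, 0)
  expect_gt(rep$strain_C_end_pct, 0)
  # growth anisotropy: z softest, fiber direction x stiffest
  expect_gt(rep$strain_C_end_pct, rep$strain_B_end_pct)
  expect_gt(rep$strain_B_end_pct, rep$strain_A_end_pct)
})

test_that("configuration round-trips and outputs are written", {
  tmp <- tempfile(fileext = ".yaml")
  write_config(list(experiment = "biaxial",
                    material = list(kappa = 1e6),
                    schedule = list(t_star = 90)), tmp)
  cfg <- read_config(tmp)
  expect_equal(cfg$experiment, "biaxial")
  expect_equal(cfg$params$material$kappa, 1e6)
  expect_equal(cfg$params$material$mu, 115)      # preset default retained
  expect_equal(cfg$params$bio$ki1, 2e-4)         # biaxial preset
  expect_equal(cfg$schedule$t_star, 90)

  rep <- run_biaxial(t_heal = 2 * SECONDS_PER_DAY,
                     dt_heal = SECONDS_PER_DAY, dt_damage = 2)
  out <- tempfile()
  paths <- write_outputs(rep, out)
  expect_true(file.exists(file.path(out, "history.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  smry <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(smry$d_star, rep$d_star, tolerance = 1e-12)
  vtk <- file.path(out, "final_state.vtk")
  expect_true(file.exists(vtk))
  lines <- readLines(vtk)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl("POINTS 8 double", lines)))
  expect_true(any(grepl("SCALARS d double 1", lines)))
})
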