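#' Seconds in one simulation year
#'
#' All internal computations use SI seconds; rate constants quoted per year
#' (remodeling gain, decay times) are converted with 1 year = 365 days =
#' 3.1536e7 s.
#' @export
SECONDS_PER_YEAR <- 3.1536e7

#' Seconds in one day
#' @export
SECONDS_PER_DAY <- 86400

#' Material parameters of the tissue mixture
#'
#' Bundles the constitutive constants of the collagen/matrix mixture, the
#' collagen damage (plasticity) law and the remodeling law. All values are
#' SI: energies per unit mass in J/kg, densities in kg/m^3, rates in 1/s.
#'
#' @param mu Matrix (neo-Hookean) shear-type modulus, J/kg.
#' @param k1,k2 Collagen exponential fiber law constants (`k1` J/kg, `k2`
#'   dimensionless).
#' @param kappa Volumetric growth penalty modulus, J/kg.
#' @param rho0_init Initial total reference mass density rho_0(0), kg/m^3.
#' @param phi_c0 Initial collagen mass fraction, in (0,1).
#' @param lambda_pre Collagen deposition prestretch (> 1).
#' @param k_rem Remodeling gain, 1/s.
#' @param m_p Damage slope (dimensionless).
#' @param lambda_bar_p Collagen stretch threshold for damage (> 1).
#' @param remodel_in_damage Keep remodeling active during the (short) damage
#'   phase? Its effect there is O(1e-5); a switch is exposed so the
#'   contribution can be probed.
#' @return An object of class `material_params` (named list).
#' @export
material_params <- function(mu = 115, k1 = 2, k2 = 3.2, kappa = 1e7,
                            rho0_init = 1050, phi_c0 = 0.8,
                            lambda_pre = 1.062,
                            k_rem = 0.8 / SECONDS_PER_YEAR,
                            m_p = 2.5, lambda_bar_p = 1.3,
                            remodel_in_damage = TRUE) {
  p <- list(mu = mu, k1 = k1, k2 = k2, kappa = kappa,
            rho0_init = rho0_init, phi_c0 = phi_c0,
            lambda_pre = lambda_pre, k_rem = k_rem,
            m_p = m_p, lambda_bar_p = lambda_bar_p,
            remodel_in_damage = isTRUE(remodel_in_damage))
  num <- p[!(names(p) %in% "remodel_in_damage")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all material parameters must be positive scalars")
  if (phi_c0 <= 0 || phi_c0 >= 1) stop("phi_c0 must lie in (0,1)")
  if (lambda_pre <= 1) stop("lambda_pre must exceed 1")
  if (lambda_bar_p <= 1) stop("lambda_bar_p must exceed 1")
  structure(p, class = "material_params")
}

#' Biological (MMP / growth factor) parameters
#'
#' Constants of the damage-stimulated species system: MMP concentration `M`
#' is produced by damaged collagen and degrades it; the accumulated MMP
#' signal drives growth factor `G`, which deposits new (intact) collagen.
#'
#' @param M0,G0 Homeostatic MMP / GF concentrations, kg/m^3.
#' @param m1 MMP production rate from damaged collagen, kg/(m^3 s).
#' @param m2 MMP decay rate toward `M0`, 1/s.
#' @param g1 GF production rate from accumulated MMP, 1/s.
#' @param g2 GF decay rate toward `G0`, 1/s.
#' @param t_decay Saturation time of the accumulated-MMP signal, s.
#' @param kd1,kd2 Damaged-collagen degradation constants (`kd1` kg/(m^3 s),
#'   saturation level; `kd2` dimensionless sensitivity).
#' @param ki1,ki2 Intact-collagen production constants (`ki1` kg/(m^3 s),
#'   saturation level; `ki2` dimensionless sensitivity).
#' @return An object of class `bio_params`.
#' @export
bio_params <- function(M0 = 5.6e-5, G0 = 3.5e-5,
                       m1 = 4e-11, m2 = 1e-6,
                       g1 = 1e-4, g2 = 4.63e-5,
                       t_decay = 0.5 * SECONDS_PER_YEAR,
                       kd1 = 1e-4, kd2 = 10,
                       ki1 = 1e-4, ki2 = 2) {
  p <- list(M0 = M0, G0 = G0, m1 = m1, m2 = m2, g1 = g1, g2 = g2,
            t_decay = t_decay, kd1 = kd1, kd2 = kd2, ki1 = ki1, ki2 = ki2)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all biological parameters must be positive scalars")
  structure(p, class = "bio_params")
}

#' Combined parameter set for a healing simulation
#'
#' @param material A [material_params()] object.
#' @param bio A [bio_params()] object.
#' @return An object of class `heal_params`.
#' @export
heal_params <- function(material = material_params(), bio = bio_params()) {
  stopifnot(inherits(material, "material_params"), inherits(bio, "bio_params"))
  structure(list(material = material, bio = bio), class = "heal_params")
}

#' Preset parameter sets for the three reference studies
#'
#' `params_species()` returns the biology constants of the single-material-
#' point species study; `params_biaxial()` the biaxial-tension study set
#' (collagen-rich flat sample, quarter dimensions 6 x 3 x 0.225 mm, damage
#' slope m_p = 2.5, threshold 1.3, penalty 1e7 J/kg, elevated collagen
#' production ki1 = 2e-4 kg/(m^3 s)); `params_indentation()` the indentation
#' study set (quarter plate 6 x 6 x 1.2 cm, m_p = 4.5, threshold 1.1,
#' penalty 1e8 J/kg, faster GF dynamics).
#'
#' @return `params_species()` a `bio_params`; the others a `heal_params`
#'   with a `geometry` attribute holding the quarter-sample dimensions in
#'   meters.
#' @export
params_species <- function() bio_params()

#' @rdname params_species
#' @export
params_biaxial <- function() {
  p <- heal_params(
    material = material_params(mu = 115, k1 = 2, k2 = 3.2, kappa = 1e7,
                               rho0_init = 1050, phi_c0 = 0.8,
                               lambda_pre = 1.062,
                               k_rem = 0.8 / SECONDS_PER_YEAR,
                               m_p = 2.5, lambda_bar_p = 1.3),
    bio = bio_params(ki1 = 2e-4))
  attr(p, "geometry") <- c(lx = 6e-3, ly = 3e-3, lz = 0.225e-3)
  p
}

#' @rdname params_species
#' @export
params_indentation <- function() {
  p <- heal_params(
    material = material_params(mu = 115, k1 = 10, k2 = 3.2, kappa = 1e8,
                               rho0_init = 1050, phi_c0 = 0.8,
                               lambda_pre = 1.062,
                               k_rem = 0.8 / SECONDS_PER_YEAR,
                               m_p = 4.5, lambda_bar_p = 1.1),
    bio = bio_params(g1 = 2e-4, g2 = 6.94e-5, ki1 = 1e-4))
  attr(p, "geometry") <- c(lx = 6e-2, ly = 6e-2, lz = 1.2e-2)
  p
}

# Flat numeric vector consumed by the compiled Gauss-point kernel.
# Index layout must match PAR_* constants in src/gp_kernel.cpp.
param_vector <- function(params) {
  m <- params$material; b <- params$bio
  c(mu = m$mu, k1 = m$k1, k2 = m$k2, kappa = m$kappa,
    rho0_init = m$rho0_init, phi_c0 = m$phi_c0,
    lambda_pre = m$lambda_pre, k_rem = m$k_rem,
    m_p = m$m_p, lambda_bar_p = m$lambda_bar_p,
    M0 = b$M0, G0 = b$G0, m1 = b$m1, m2 = b$m2, g1 = b$g1, g2 = b$g2,
    t_decay = b$t_decay, kd1 = b$kd1, kd2 = b$kd2, ki1 = b$ki1, ki2 = b$ki2,
    rho_m = m$rho0_init * (1 - m$phi_c0),
    rho_c_init = m$rho0_init * m$phi_c0,
    remodel_in_damage = as.numeric(m$remodel_in_damage))
}

#' Read / write simulation configuration files
#'
#' Configurations are YAML (or JSON) files with keys `experiment`
#' (`"species"`, `"sensitivity"`, `"biaxial"` or `"indentation"`),
#' `material`, `bio`, `schedule` (`t0`, `t_star`, `t_end`, seconds) and
#' optional `numerics` / `geometry` blocks. Missing parameter keys default
#' to the preset for the selected experiment.
#'
#' @param path File path.
#' @return `read_config()` returns a list with elements `experiment`,
#'   `params`, `schedule` and `numerics`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  exp <- match.arg(cfg$experiment %||% "biaxial",
                   c("species", "sensitivity", "biaxial", "indentation"))
  base <- switch(exp,
                 species = , sensitivity = heal_params(bio = params_species()),
                 biaxial = params_biaxial(),
                 indentation = params_indentation())
  mat <- utils::modifyList(unclass(base$material), cfg$material %||% list())
  bio <- utils::modifyList(unclass(base$bio), cfg$bio %||% list())
  params <- heal_params(do.call(material_params, mat),
                        do.call(bio_params, bio))
  attr(params, "geometry") <- attr(base, "geometry")
  if (!is.null(cfg$geometry))
    attr(params, "geometry") <- unlist(cfg$geometry)[c("lx", "ly", "lz")]
  sched <- utils::modifyList(
    list(t0 = 0, t_star = 60, t_end = SECONDS_PER_YEAR + 60),
    cfg$schedule %||% list())
  list(experiment = exp, params = params,
       schedule = phase_schedule(sched$t0, sched$t_star, sched$t_end),
       numerics = cfg$numerics %||% list())
}

#' @rdname read_config
#' @param config A list as returned by [read_config()] (or any list of
#'   YAML-serializable values).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
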