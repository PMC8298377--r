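# Strain energies and stresses of the collagen/matrix mixture
#
# Free energy per unit reference volume:
#   Psi = rho_0^c W^c(Ie_c) + rho_0^m W^m(I1_bar) + rho_0 W^L(J)
# with energies per unit mass weighted by reference densities. Collagen
# carries an exponential fiber law in the full anisotropic invariant, the
# matrix a neo-Hookean law in the isochoric invariant (volume changes do
# not load the matrix), and W^L penalizes deviation of the volume ratio
# from the growth target rho_0/rho_0(0).

#' Collagen strain energy per unit mass
#'
#' Exponential fiber law `W^c = k1/(2 k2) (exp(k2 <Ie - 1>^2) - 1)` with a
#' Macaulay bracket: collagen stores no energy in compression (`Ie_c <= 1`).
#'
#' @param Ie_c Anisotropic invariant (squared elastic fiber stretch), > 0.
#' @param params A [material_params()] object.
#' @return Energy in J/kg.
#' @export
collagen_energy <- function(Ie_c, params) {
  if (any(Ie_c <= 0)) stop("Ie_c must be positive")
  h <- pmax(Ie_c - 1, 0)
  params$k1 / (2 * params$k2) * (exp(params$k2 * h^2) - 1)
}

# dW^c / dIe_c
collagen_energy_d1 <- function(Ie_c, params) {
  h <- pmax(Ie_c - 1, 0)
  params$k1 * h * exp(params$k2 * h^2)
}

#' Matrix strain energy per unit mass
#'
#' Neo-Hookean law `W^m = mu/2 (I1_bar - 3)` in the isochoric first
#' invariant; insensitive to pure volume changes.
#'
#' @param I1_bar Isochoric first invariant (>= 3 up to round-off).
#' @inheritParams collagen_energy
#' @return Energy in J/kg.
#' @export
matrix_energy <- function(I1_bar, params) {
  params$mu / 2 * (I1_bar - 3)
}

#' Volumetric growth penalty energy per unit mass
#'
#' `W^L = kappa/2 (vol - rho_0/rho_0(0))^2`: quadratic penalty forcing the
#' volume ratio (kinematic `J` at a material point, independent dilatation
#' `theta` in the mixed finite element) toward the growth target set by the
#' current reference density.
#'
#' @param vol Volume ratio (J or theta), > 0.
#' @param rho_0 Current total reference density, kg/m^3.
#' @inheritParams collagen_energy
#' @return Energy in J/kg.
#' @export
penalty_energy <- function(vol, rho_0, params) {
  if (any(vol <= 0)) stop("volume ratio must be positive")
  params$kappa / 2 * (vol - rho_0 / params$rho0_init)^2
}

#' Mixture composition by reference densities
#'
#' @param rho_c Collagen reference density (intact + damaged), kg/m^3.
#' @param rho_m Matrix reference density, kg/m^3.
#' @return An object of class `mixture_composition` with densities and mass
#'   fractions; `rho_0 = rho_c + rho_m` exactly.
#' @export
mixture_composition <- function(rho_c, rho_m) {
  if (rho_c < 0 || rho_m < 0) stop("densities must be non-negative")
  rho_0 <- rho_c + rho_m
  structure(list(rho_c = rho_c, rho_m = rho_m, rho_0 = rho_0,
                 phi_c = rho_c / rho_0, phi_m = rho_m / rho_0),
            class = "mixture_composition")
}

#' Free energy of the mixture per unit reference volume
#'
#' @param invariants An [elastic_invariants()] object.
#' @param composition A [mixture_composition()] object.
#' @inheritParams collagen_energy
#' @return Energy in J/m^3 of reference volume.
#' @export
mixture_free_energy <- function(invariants, composition, params) {
  composition$rho_c * collagen_energy(invariants$Ie_c, params) +
    composition$rho_m * matrix_energy(invariants$I1_bar, params) +
    composition$rho_0 * penalty_energy(invariants$J, composition$rho_0, params)
}

#' Second Piola-Kirchhoff stress of the mixture
#'
#' Analytic `S = 2 dPsi/dC` at frozen internal variables, via the chain
#' rule through `C_e^c = F_r^-T F_p^-T C F_p^-1 F_r^-1` for collagen and
#' the isochoric projection for the matrix. The volumetric term is either
#' the penalty stress `rho_0 kappa (J - g) J C^-1` (material-point mode,
#' `pressure = NULL`) or the mixed-element Lagrange term
#' `rho_0 p J C^-1` when an element pressure `p` is supplied.
#'
#' @param deformation A [decomposed_deformation()] object.
#' @param frame Its fiber frame (defaults to `deformation$frame`).
#' @param composition A [mixture_composition()] object.
#' @inheritParams collagen_energy
#' @param pressure Optional element pressure (Pa); `NULL` selects the
#'   penalty form with target `rho_0 / rho_0(0)`.
#' @return Symmetric 3x3 stress tensor (Pa). Attribute `parts` carries the
#'   collagen / matrix / volumetric contributions.
#' @export
second_pk_stress <- function(deformation, frame = deformation$frame,
                             composition, params, pressure = NULL) {
  F <- deformation$F
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  C <- crossprod(F)
  Cinv <- solve(C)
  w <- as.numeric(deformation$Fp_inv %*% deformation$Fr_inv %*% frame$ar)
  Ie <- as.numeric(t(w) %*% C %*% w)
  S_c <- 2 * composition$rho_c * collagen_energy_d1(Ie, params) * tcrossprod(w)
  S_m <- composition$rho_m * params$mu * J^(-2 / 3) *
    (diag(3) - sum(diag(C)) / 3 * Cinv)
  if (is.null(pressure)) {
    g <- composition$rho_0 / params$rho0_init
    S_L <- composition$rho_0 * params$kappa * (J - g) * J * Cinv
  } else {
    S_L <- composition$rho_0 * pressure * J * Cinv
  }
  S <- S_c + S_m + S_L
  S <- (S + t(S)) / 2
  attr(S, "parts") <- list(collagen = S_c, matrix = S_m, volumetric = S_L)
  S
}

#' Cauchy stress by push-forward
#'
#' `sigma = (1/J) F S F^T`.
#'
#' @param F Deformation gradient (det > 0).
#' @param S Second Piola-Kirchhoff stress.
#' @return Symmetric 3x3 Cauchy stress (Pa).
#' @export
cauchy_stress <- function(F, S) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  sig <- F %*% S %*% t(F) / J
  (sig + t(sig)) / 2
}
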