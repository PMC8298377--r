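# Tensor algebra of the multiplicative split
#
# Total deformation F = F_e^c F_r^c F_p^c = F_e^m. The plastic (damage) and
# remodeling gradients are rank-one updates of the identity built from a
# fiber stretch and a structural tensor; both are exactly unimodular, so
# their inverses are formed in closed form rather than by general inversion.

#' Inelastic fiber stretch tensor
#'
#' Builds the unimodular tensor `lam * M + lam^(-1/2) * (I - M)` used for
#' both the plastic and the remodeling deformation gradient: stretch `lam`
#' along the fiber, `lam^(-1/2)` transversely, determinant exactly one.
#'
#' @param lam Positive fiber stretch.
#' @param M Rank-one symmetric structural tensor (outer product of a unit
#'   fiber direction with itself).
#' @return A 3x3 matrix with unit determinant.
#' @export
inelastic_stretch_tensor <- function(lam, M) {
  check_structural_tensor(M)
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0)
    stop("fiber stretch must be a positive scalar")
  lam * M + lam^(-0.5) * (diag(3) - M)
}

# Closed-form inverse of an inelastic stretch tensor given (lam, M).
inelastic_stretch_inverse <- function(lam, M) {
  (1 / lam) * M + sqrt(lam) * (diag(3) - M)
}

check_structural_tensor <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || !all(dim(M) == c(3, 3)))
    stop("structural tensor must be a 3x3 matrix")
  if (max(abs(M - t(M))) > tol) stop("structural tensor must be symmetric")
  if (abs(sum(diag(M)) - 1) > tol) stop("structural tensor must have unit trace")
  if (max(abs(M %*% M - M)) > tol) stop("structural tensor must be rank-one idempotent")
  invisible(TRUE)
}

#' Fiber frame across the intermediate configurations
#'
#' Maps the reference fiber direction `a_0` through the plastic and
#' remodeling gradients and renormalizes, so that the fiber stretch (like
#' the deformation gradient) decomposes multiplicatively. Returns the three
#' unit directions and their structural tensors.
#'
#' @param F_p,F_r Plastic and remodeling deformation gradients.
#' @param a_0 Unit reference fiber direction.
#' @return An object of class `fiber_frame`: list with `a0`, `ap`, `ar`,
#'   `M0`, `Mp`, `Mr`.
#' @export
fiber_frames <- function(F_p, F_r, a_0) {
  a_0 <- as.numeric(a_0)
  if (abs(sqrt(sum(a_0^2)) - 1) > 1e-12) stop("a_0 must be a unit vector")
  if (det(F_p) <= 0 || det(F_r) <= 0)
    stop("inelastic deformation gradients must have positive determinant")
  vp <- as.numeric(F_p %*% a_0)
  np <- sqrt(sum(vp^2))
  if (np < 1e-12) stop("degenerate deformation: fiber direction collapsed")
  ap <- vp / np
  vr <- as.numeric(F_r %*% ap)
  nr <- sqrt(sum(vr^2))
  if (nr < 1e-12) stop("degenerate deformation: fiber direction collapsed")
  ar <- vr / nr
  structure(list(a0 = a_0, ap = ap, ar = ar,
                 M0 = tcrossprod(a_0), Mp = tcrossprod(ap),
                 Mr = tcrossprod(ar)),
            class = "fiber_frame")
}

#' Decomposed deformation state
#'
#' Assembles the multiplicative split from the total deformation gradient
#' and the scalar inelastic fiber stretches. The elastic collagen gradient
#' is `F_e^c = F F_p^{-1} F_r^{-1}`; the matrix deforms purely elastically,
#' `F_e^m = F`.
#'
#' @param F Total deformation gradient (det > 0).
#' @param lambda_p,lambda_r Plastic and remodeling fiber stretches.
#' @param a_0 Unit reference fiber direction.
#' @return An object of class `decomposed_deformation`: list with `F`,
#'   `F_p`, `F_r`, `F_e_c`, `F_e_m` and the `frame`.
#' @export
decomposed_deformation <- function(F, lambda_p, lambda_r, a_0) {
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  M0 <- tcrossprod(as.numeric(a_0))
  F_p <- inelastic_stretch_tensor(lambda_p, M0)
  frame0 <- fiber_frames(F_p, diag(3), a_0)
  Mp <- frame0$Mp
  F_r <- inelastic_stretch_tensor(lambda_r, Mp)
  frame <- fiber_frames(F_p, F_r, a_0)
  Fp_inv <- inelastic_stretch_inverse(lambda_p, M0)
  Fr_inv <- inelastic_stretch_inverse(lambda_r, Mp)
  structure(list(F = F, F_p = F_p, F_r = F_r,
                 F_e_c = F %*% Fp_inv %*% Fr_inv, F_e_m = F,
                 Fp_inv = Fp_inv, Fr_inv = Fr_inv, frame = frame),
            class = "decomposed_deformation")
}

#' Elastic invariants of the mixture
#'
#' Computes the kinematic quantities the free energy depends on: the volume
#' ratio `J = det(F)`, the isochoric first matrix invariant
#' `I1_bar = det(C)^(-1/3) tr(C)`, the anisotropic collagen invariant
#' `Ie_c = C_e^c : M_r` (squared elastic fiber stretch) and the fiber
#' stretches of the multiplicative chain.
#'
#' @param F Total deformation gradient.
#' @param F_p,F_r Plastic and remodeling gradients.
#' @param frame A [fiber_frames()] object consistent with `F_p`, `F_r`.
#' @return An object of class `elastic_invariants`: list with `J`,
#'   `I1_bar`, `Ie_c`, `lambda_total`, `lambda_p`, `lambda_r`, `lambda_e`.
#' @export
elastic_invariants <- function(F, F_p, F_r, frame) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  C <- crossprod(F)
  I1_bar <- det(C)^(-1 / 3) * sum(diag(C))
  lambda_total <- sqrt(sum((F %*% frame$a0)^2))
  lambda_p <- sqrt(sum((F_p %*% frame$a0)^2))
  lambda_r <- sqrt(sum((F_r %*% frame$ap)^2))
  # C_e^c : M_r = |F_e^c a_r|^2 with F_e^c = F (F_r F_p)^{-1}
  Fe <- F %*% solve(F_r %*% F_p)
  ve <- as.numeric(Fe %*% frame$ar)
  Ie_c <- sum(ve^2)
  structure(list(J = J, I1_bar = I1_bar, Ie_c = Ie_c,
                 lambda_total = lambda_total, lambda_p = lambda_p,
                 lambda_r = lambda_r, lambda_e = sqrt(Ie_c)),
            class = "elastic_invariants")
}
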