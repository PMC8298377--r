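# Shared fixtures: all inputs are generated in code.

# random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix via QR with positive determinant
rrot <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random admissible deformation gradient (det > 0, moderate strain)
rdefgrad <- function(scale = 0.3) {
  F <- diag(3) + scale * matrix(stats::rnorm(9), 3)
  if (det(F) <= 0.05) rdefgrad(scale) else F
}

# random internal/mixture state for stress checks; keeps the collagen
# invariant away from the Macaulay kink at Ie = 1
random_stress_case <- function(params = params_biaxial()) {
  a0 <- runit()
  F <- rdefgrad()
  lambda_p <- stats::runif(1, 1, 1.3)
  lambda <- sqrt(sum((F %*% a0)^2))
  # choose lambda_r so that lambda_e is clearly tensile or compressive
  lambda_e <- sample(c(stats::runif(1, 1.03, 1.25),
                       stats::runif(1, 0.7, 0.97)), 1)
  lambda_r <- lambda / (lambda_p * lambda_e)
  rho_c <- stats::runif(1, 400, 1200)
  rho_m <- stats::runif(1, 100, 300)
  list(F = F, a0 = a0, lambda_p = lambda_p, lambda_r = lambda_r,
       comp = mixture_composition(rho_c, rho_m), params = params)
}

# free energy as a function of C alone (internal variables frozen);
# independent oracle route for stress finite-difference checks
psi_of_C <- function(C, case) {
  ee <- eigen(C, symmetric = TRUE)
  Fs <- ee$vectors %*% diag(sqrt(ee$values)) %*% t(ee$vectors)
  d <- decomposed_deformation(Fs, case$lambda_p, case$lambda_r, case$a0)
  inv <- elastic_invariants(Fs, d$F_p, d$F_r, d$frame)
  mixture_free_energy(inv, case$comp, case$params$material)
}

# central finite difference of psi w.r.t. C -> second PK stress
fd_stress <- function(case, h = 1e-6) {
  C <- crossprod(case$F)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[j, i] <- h
    d <- (psi_of_C(C + dC, case) - psi_of_C(C - dC, case)) / (2 * h)
    fac <- if (i == j) 1 else 0.5
    S[i, j] <- S[j, i] <- 2 * fac * d
  }
  S
}

# short biaxial schedule used across FEM tests
test_schedule <- function(t_heal = SECONDS_PER_YEAR)
  phase_schedule(60, 120, 120 + t_heal)
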