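// Gauss-point constitutive kernel and H1-P0 element residual/tangent.
//
// Mirrors the R module surface (local_update / stress_from_C) operation by
// operation so the compiled FEM path and the pure-R material-point path
// stay numerically identical; tests pin them together.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// parameter vector layout -- keep in step with param_vector() in R/params.R
enum {
  PAR_MU, PAR_K1, PAR_K2, PAR_KAPPA, PAR_RHO0_INIT, PAR_PHI_C0,
  PAR_LAMBDA_PRE, PAR_K_REM, PAR_M_P, PAR_LAMBDA_BAR_P,
  PAR_M0, PAR_G0, PAR_M1, PAR_M2, PAR_G1, PAR_G2, PAR_T_DECAY,
  PAR_KD1, PAR_KD2, PAR_KI1, PAR_KI2,
  PAR_RHO_M, PAR_RHO_C_INIT, PAR_REMODEL_IN_DAMAGE, PAR_N
};

// state vector layout -- keep in step with gp_state_vector() in R
enum {
  ST_LAMBDA_P, ST_HIST_LAMBDA, ST_LAMBDA_MAX, ST_D, ST_LAMBDA_R,
  ST_M, ST_G, ST_IM, ST_RHO_CD, ST_RHO_CI, ST_T_HEAL, ST_HEAL_INIT, ST_N
};

enum { PHASE_PRESTRETCH = 0, PHASE_DAMAGE = 1, PHASE_HEALING = 2 };

static double remodel_implicit(double lr0, double lambda, double lp,
                               double dt, const vec &par) {
  const double k = par[PAR_K_REM] / (par[PAR_LAMBDA_PRE] - 1.0);
  double x = lr0;
  for (int i = 0; i < 50; ++i) {
    double f = x - lr0 - dt * k * (lambda / (x * lp) - par[PAR_LAMBDA_PRE]);
    if (std::abs(f) <= 1e-12 * std::max(1.0, std::abs(x))) return x;
    double fp = 1.0 + dt * k * lambda / (x * x * lp);
    double xn = x - f / fp;
    if (!std::isfinite(xn) || xn <= 1e-8) xn = 0.5 * x;
    if (std::abs(xn - x) <= 1e-12 * std::max(1.0, std::abs(x))) return xn;
    x = xn;
  }
  Rcpp::stop("remodeling update did not converge");
  return x;
}

// staggered internal-variable update over [t, t+dt); modifies st in place
static void gp_update_internal(vec &st, double lambda, int phase, double dt,
                               const vec &par, int prestretch_closed_form) {
  if (dt == 0.0) return;
  if (phase == PHASE_PRESTRETCH) {
    if (prestretch_closed_form) {
      st[ST_LAMBDA_R] = lambda / (st[ST_LAMBDA_P] * par[PAR_LAMBDA_PRE]);
    } else {
      st[ST_LAMBDA_R] = remodel_implicit(st[ST_LAMBDA_R], lambda,
                                         st[ST_LAMBDA_P], dt, par);
    }
  } else if (phase == PHASE_DAMAGE) {
    const double hist = std::max(st[ST_HIST_LAMBDA], lambda);
    st[ST_HIST_LAMBDA] = hist;
    const double lmax_old = st[ST_LAMBDA_MAX];
    const double lp_old = st[ST_LAMBDA_P];
    const double lr_old = st[ST_LAMBDA_R];
    double lr = lr_old, lp = lp_old, lmax = lmax_old, d = st[ST_D];
    for (int i = 0; i < 20; ++i) {
      lmax = std::max(lmax_old, hist / lr);
      d = std::max(st[ST_D], std::min(1.0,
            par[PAR_M_P] * std::max(lmax - par[PAR_LAMBDA_BAR_P], 0.0)));
      const double dl = lmax - lmax_old;
      lp = lp_old;
      const double le_trial = lambda / (lr * lp_old);
      if (dl > 0.0 && d > 0.0 && le_trial > 1.0) {
        const double denom = 1.0 - d * dl * lr / lambda;
        double lp_new = denom > 0.0 ? lp_old / denom
                                    : std::numeric_limits<double>::infinity();
        lp = std::min(lp_new, lambda / lr);
        lp = std::max(lp, lp_old);
      }
      double lr_new = par[PAR_REMODEL_IN_DAMAGE] > 0.5
        ? remodel_implicit(lr_old, lambda, lp, dt, par) : lr_old;
      if (std::abs(lr_new - lr) < 1e-14) { lr = lr_new; break; }
      lr = lr_new;
    }
    st[ST_LAMBDA_MAX] = lmax;
    st[ST_D] = d;
    st[ST_LAMBDA_P] = lp;
    st[ST_LAMBDA_R] = lr;
  } else { // healing
    if (st[ST_HEAL_INIT] < 0.5) {
      const double rc_star = st[ST_RHO_CD] + st[ST_RHO_CI];
      st[ST_RHO_CD] = st[ST_D] * rc_star;
      st[ST_RHO_CI] = (1.0 - st[ST_D]) * rc_star;
      st[ST_M] = par[PAR_M0];
      st[ST_G] = par[PAR_G0];
      st[ST_IM] = 0.0;
      st[ST_T_HEAL] = 0.0;
      st[ST_HEAL_INIT] = 1.0;
    }
    // backward-Euler biology step (mirrors step_biology in R)
    const double rc_star = par[PAR_RHO_C_INIT];
    const double M0 = par[PAR_M0], G0 = par[PAR_G0];
    const double rcd_old = st[ST_RHO_CD];
    double rcd = rcd_old, M = st[ST_M];
    for (int i = 0; i < 100; ++i) {
      // increment form keeps homeostasis an exact fixed point
      double M_new = M0 + (st[ST_M] - M0 +
                           dt * par[PAR_M1] * rcd / rc_star) /
                          (1.0 + dt * par[PAR_M2]);
      double rcd_new;
      if (M_new > M0 && rcd_old > 0.0) {
        double rate = par[PAR_KD1] *
          (std::exp(-par[PAR_KD2] * (M_new - M0) / M0) - 1.0);
        rcd_new = std::max(rcd_old + dt * rate, 0.0);
      } else {
        rcd_new = rcd_old;
      }
      bool done = std::abs(rcd_new - rcd) <= 1e-13 * std::max(1.0, rcd) &&
                  std::abs(M_new - M) <= 1e-18;
      M = M_new; rcd = rcd_new;
      if (done) break;
      if (i == 99) Rcpp::stop("biology update did not converge");
    }
    const double t_heal = st[ST_T_HEAL] + dt;
    const double iM = st[ST_IM] + dt * (M - M0);  // excess integral
    const double IM = (iM / t_heal) * std::exp(-t_heal / par[PAR_T_DECAY]);
    const double G = G0 + (st[ST_G] - G0 + dt * par[PAR_G1] * IM) /
                          (1.0 + dt * par[PAR_G2]);
    const double produced = dt * par[PAR_KI1] *
      (1.0 - std::exp(-par[PAR_KI2] * (G - G0) / G0));
    st[ST_M] = M;
    st[ST_G] = G;
    st[ST_IM] = iM;
    st[ST_T_HEAL] = t_heal;
    st[ST_RHO_CD] = rcd;
    st[ST_RHO_CI] += produced;
    st[ST_LAMBDA_R] = remodel_implicit(st[ST_LAMBDA_R], lambda,
                                       st[ST_LAMBDA_P], dt, par);
  }
}

// second PK stress at frozen internal state; pressure = NA selects the
// material-point penalty form
static mat33 gp_stress(const mat33 &C, const vec &st, const vec &par,
                       const vec3 &a0, double pressure, bool use_penalty) {
  const double detC = det(C);
  if (detC <= 0.0) Rcpp::stop("inverted element: det(C) <= 0");
  const double J = std::sqrt(detC);
  const mat33 Cinv = inv(C);
  const double rho_c = st[ST_RHO_CD] + st[ST_RHO_CI];
  const double rho_m = par[PAR_RHO_M];
  const double rho_0 = rho_c + rho_m;
  const double lplr = st[ST_LAMBDA_P] * st[ST_LAMBDA_R];
  const double lp2 = lplr * lplr;
  const double Ie = as_scalar(a0.t() * C * a0) / lp2;
  const double h = std::max(Ie - 1.0, 0.0);
  const double dWc = par[PAR_K1] * h * std::exp(par[PAR_K2] * h * h);
  mat33 S = 2.0 * rho_c * dWc / lp2 * (a0 * a0.t());
  S += rho_m * par[PAR_MU] * std::pow(J, -2.0 / 3.0) *
       (eye(3, 3) - trace(C) / 3.0 * Cinv);
  if (use_penalty) {
    const double g = rho_0 / par[PAR_RHO0_INIT];
    S += rho_0 * par[PAR_KAPPA] * (J - g) * J * Cinv;
  } else {
    S += rho_0 * pressure * J * Cinv;
  }
  return 0.5 * (S + S.t());
}

// update + stress for a trial C starting from the committed state
static mat33 gp_trial_stress(const mat33 &C, const vec &st_committed,
                             int phase, double dt, const vec &par,
                             const vec3 &a0, double pressure,
                             bool use_penalty, int pcf, vec &st_out) {
  st_out = st_committed;
  const double lambda = std::sqrt(as_scalar(a0.t() * C * a0));
  gp_update_internal(st_out, lambda, phase, dt, par, pcf);
  return gp_stress(C, st_out, par, a0, pressure, use_penalty);
}

// consistent tangent D[i][j][k][l] = 2 dS_ij/dC_kl by central differences,
// re-solving the internal variables at each perturbed state
static void gp_tangent(const mat33 &C, const vec &st_committed, int phase,
                       double dt, const vec &par, const vec3 &a0,
                       double pressure, bool use_penalty, int pcf,
                       double D[3][3][3][3]) {
  const double h = 1e-6 * std::max(1.0, trace(C) / 3.0);
  vec tmp;
  for (int k = 0; k < 3; ++k) {
    for (int l = k; l < 3; ++l) {
      mat33 Cp = C, Cm = C;
      Cp(k, l) += h; Cp(l, k) = Cp(k, l);
      Cm(k, l) -= h; Cm(l, k) = Cm(k, l);
      if (k == l) { Cp(k, k) = C(k, k) + h; Cm(k, k) = C(k, k) - h; }
      mat33 Sp = gp_trial_stress(Cp, st_committed, phase, dt, par, a0,
                                 pressure, use_penalty, pcf, tmp);
      mat33 Sm = gp_trial_stress(Cm, st_committed, phase, dt, par, a0,
                                 pressure, use_penalty, pcf, tmp);
      mat33 dS = (Sp - Sm) / (2.0 * h);
      const double fac = (k == l) ? 1.0 : 0.5;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          D[i][j][k][l] = 2.0 * fac * dS(i, j);
          D[i][j][l][k] = D[i][j][k][l];
        }
    }
  }
}

// [[Rcpp::export(name = ".cpp_gp_update")]]
Rcpp::List cpp_gp_update(const arma::vec &state, const arma::mat &C,
                         int phase, double dt, const arma::vec &par,
                         const arma::vec &a0, double pressure,
                         bool use_penalty, int prestretch_closed_form) {
  vec st;
  vec3 a = a0;
  mat33 Cm = C;
  mat33 S = gp_trial_stress(Cm, state, phase, dt, par, a, pressure,
                            use_penalty, prestretch_closed_form, st);
  return Rcpp::List::create(Rcpp::Named("state") = st,
                            Rcpp::Named("S") = S);
}

// [[Rcpp::export(name = ".cpp_gp_tangent")]]
arma::mat cpp_gp_tangent(const arma::vec &state, const arma::mat &C,
                         int phase, double dt, const arma::vec &par,
                         const arma::vec &a0, double pressure,
                         bool use_penalty, int prestretch_closed_form) {
  double D[3][3][3][3];
  vec3 a = a0;
  mat33 Cm = C;
  gp_tangent(Cm, state, phase, dt, par, a, pressure, use_penalty,
             prestretch_closed_form, D);
  mat out(9, 9);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l)
          out(3 * i + j, 3 * k + l) = D[i][j][k][l];
  return out;
}

static const double GP1 = 1.0 / std::sqrt(3.0);

// trilinear shape-function derivatives at a quadrature point
static void shape_deriv(double xi, double eta, double zeta, mat &dN) {
  const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int I = 0; I < 8; ++I) {
    dN(I, 0) = 0.125 * sx[I] * (1 + sy[I] * eta) * (1 + sz[I] * zeta);
    dN(I, 1) = 0.125 * sy[I] * (1 + sx[I] * xi) * (1 + sz[I] * zeta);
    dN(I, 2) = 0.125 * sz[I] * (1 + sx[I] * xi) * (1 + sy[I] * eta);
  }
}

// H1-P0 element: residual and consistent tangent of the three-field
// functional, 26 dofs = 24 displacements + (theta, p). Internal variables
// are advanced from `states` (committed) and returned in `states_new`;
// the caller commits them only on global convergence.
// [[Rcpp::export(name = ".cpp_element_rt")]]
Rcpp::List cpp_element_rt(const arma::mat &Xe, const arma::vec &ue,
                          double theta, double p, const arma::mat &states,
                          const arma::vec &a0, int phase, double dt,
                          const arma::vec &par, int prestretch_closed_form,
                          bool want_tangent) {
  vec3 a = a0;
  vec res(26, fill::zeros);
  mat K(26, 26, fill::zeros);
  mat states_new(ST_N, 8);
  mat diag_out(8, 10);
  mat dN(8, 3), G(8, 3);
  double vol = 0.0, int_rho = 0.0, int_rho_g = 0.0, int_rho_J = 0.0;

  const double pts[2] = {-GP1, GP1};
  int gp = 0;
  for (int kz = 0; kz < 2; ++kz)
    for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx, ++gp) {
        shape_deriv(pts[kx], pts[ky], pts[kz], dN);
        mat33 Jac = dN.t() * Xe;           // Jac(a,j) = dx_j / dxi_a
        const double detJ = det(Jac);
        if (detJ <= 0.0) Rcpp::stop("inverted reference element");
        G = dN * inv(Jac).t();             // dN/dX_j = dN/dxi_a dxi_a/dX_j
        const double w = detJ;             // unit quadrature weights

        mat33 F(fill::eye);
        for (int I = 0; I < 8; ++I)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              F(i, j) += ue[3 * I + i] * G(I, j);
        mat33 C = F.t() * F;
        const double J = det(F);
        if (J <= 0.0) Rcpp::stop("inverted element");

        vec st;
        mat33 S = gp_trial_stress(C, states.col(gp), phase, dt, par, a, p,
                                  false, prestretch_closed_form, st);
        states_new.col(gp) = st;

        const double rho_c = st[ST_RHO_CD] + st[ST_RHO_CI];
        const double rho_0 = rho_c + par[PAR_RHO_M];
        const double g = rho_0 / par[PAR_RHO0_INIT];

        // displacement residual: r_Ii = w * (F S)_{iA} G_{IA}
        mat33 P = F * S;
        for (int I = 0; I < 8; ++I)
          for (int i = 0; i < 3; ++i)
            res[3 * I + i] += w * dot(P.row(i), G.row(I));
        // theta / p residuals
        res[24] += w * rho_0 * (par[PAR_KAPPA] * (theta - g) - p);
        res[25] += w * rho_0 * (J - theta);

        vol += w;
        int_rho += w * rho_0;
        int_rho_g += w * rho_0 * g;
        int_rho_J += w * rho_0 * J;

        const double lambda = std::sqrt(as_scalar(a.t() * C * a));
        const double le = lambda / (st[ST_LAMBDA_P] * st[ST_LAMBDA_R]);
        diag_out(gp, 0) = J;
        diag_out(gp, 1) = lambda;
        diag_out(gp, 2) = le;
        diag_out(gp, 3) = st[ST_D];
        diag_out(gp, 4) = st[ST_LAMBDA_P];
        diag_out(gp, 5) = st[ST_LAMBDA_R];
        diag_out(gp, 6) = st[ST_M];
        diag_out(gp, 7) = st[ST_G];
        diag_out(gp, 8) = rho_c;
        diag_out(gp, 9) = rho_0;

        if (!want_tangent) continue;

        double D[3][3][3][3];
        gp_tangent(C, states.col(gp), phase, dt, par, a, p, false,
                   prestretch_closed_form, D);

        // R_{Ii} = sym(F_i. (x) G_I.) per dof; T = D : R
        mat R(24, 9), T(24, 9);
        for (int I = 0; I < 8; ++I)
          for (int i = 0; i < 3; ++i) {
            const int a1 = 3 * I + i;
            for (int A = 0; A < 3; ++A)
              for (int B = 0; B < 3; ++B)
                R(a1, 3 * A + B) = 0.5 * (F(i, A) * G(I, B) +
                                          F(i, B) * G(I, A));
          }
        for (int a1 = 0; a1 < 24; ++a1)
          for (int A = 0; A < 3; ++A)
            for (int B = 0; B < 3; ++B) {
              double s = 0.0;
              for (int Cc = 0; Cc < 3; ++Cc)
                for (int Dd = 0; Dd < 3; ++Dd)
                  s += D[A][B][Cc][Dd] * R(a1, 3 * Cc + Dd);
              T(a1, 3 * A + B) = s;
            }
        // material part + geometric part
        mat33 GS;  // G_I . S . G_J^T pieces
        for (int I = 0; I < 8; ++I)
          for (int Jn = 0; Jn < 8; ++Jn) {
            const double geo = w * as_scalar(G.row(I) * S * G.row(Jn).t());
            for (int i = 0; i < 3; ++i) {
              const int a1 = 3 * I + i;
              for (int j = 0; j < 3; ++j) {
                const int a2 = 3 * Jn + j;
                double s = 0.0;
                for (int idx = 0; idx < 9; ++idx)
                  s += R(a1, idx) * T(a2, idx);
                K(a1, a2) += w * s;
                if (i == j) K(a1, a2) += geo;
              }
            }
          }
        // pressure coupling: dS/dp = rho_0 J C^{-1}
        mat33 dSdp = rho_0 * J * inv(C);
        for (int a1 = 0; a1 < 24; ++a1) {
          double s = 0.0;
          for (int A = 0; A < 3; ++A)
            for (int B = 0; B < 3; ++B)
              s += R(a1, 3 * A + B) * dSdp(A, B);
          K(a1, 25) += w * s;
          K(25, a1) += w * s;   // dJ/du term of the p-equation
        }
        K(24, 24) += w * rho_0 * par[PAR_KAPPA];
        K(24, 25) += -w * rho_0;
        K(25, 24) += -w * rho_0;
      }

  return Rcpp::List::create(
    Rcpp::Named("res") = res,
    Rcpp::Named("K") = K,
    Rcpp::Named("states_new") = states_new,
    Rcpp::Named("volume") = vol,
    Rcpp::Named("int_rho") = int_rho,
    Rcpp::Named("theta_target") = int_rho_g / int_rho,
    Rcpp::Named("Jbar") = int_rho_J / int_rho,
    Rcpp::Named("diag") = diag_out);
}
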