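#include <Rcpp.h>
using namespace Rcpp;

// Coulomb constant, kcal * Angstrom / (mol * e^2)
static const double KCOUL = 332.0637;

// ---- 1-d toy potentials ------------------------------------------------
//
// kind codes: 0 flat, 1 harmonic1d (k, x0), 2 doublewell1d (h, m, d),
// 3 ion_pair_continuum (C12, C6, C4, qprod, dielectric)

static inline double u1d(int kind, const double *p, double x) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1: {
    double d = x - p[1];
    return 0.5 * p[0] * d * d;
  }
  case 2: {
    double d = (x - p[1]) * (x - p[1]) - p[2] * p[2];
    return p[0] * d * d / (p[2] * p[2] * p[2] * p[2]);
  }
  case 3: {
    double r2 = x * x, r4 = r2 * r2, r6 = r4 * r2, r12 = r6 * r6;
    return p[0] / r12 - p[1] / r6 - p[2] / r4 + KCOUL * p[3] / (p[4] * x);
  }
  default:
    stop("unknown 1-d potential kind code");
  }
  return 0.0; // not reached
}

// Metropolis chain on a scalar coordinate with optional harmonic bias and
// hard walls at [lo, hi] (moves outside are rejected).
// [[Rcpp::export]]
List mc1d_cpp(int kind, NumericVector pars, double x0, double temperature,
              int n_steps, double step_size, int burn_in, int thin,
              double bias_k, double bias_r0, double lo, double hi) {
  const double *p = pars.begin();
  double beta = 1.0 / (1.9872e-3 * temperature);
  double x = x0;
  double u = u1d(kind, p, x);
  if (bias_k > 0) u += 0.5 * bias_k * (x - bias_r0) * (x - bias_r0);
  if (!R_finite(u)) stop("non-finite energy at the initial state");

  int n_keep = (n_steps - burn_in) / thin;
  NumericVector out(n_keep);
  long accepted = 0;
  int kept = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    double xp = x + step_size * (unif_rand() * 2.0 - 1.0);
    if (xp >= lo && xp <= hi) {
      double up = u1d(kind, p, xp);
      if (bias_k > 0) up += 0.5 * bias_k * (xp - bias_r0) * (xp - bias_r0);
      if (!R_finite(up)) stop("non-finite energy encountered during sampling");
      if (up <= u || unif_rand() < std::exp(-beta * (up - u))) {
        x = xp;
        u = up;
        ++accepted;
      }
    }
    if (s > burn_in && (s - burn_in) % thin == 0 && kept < n_keep)
      out[kept++] = x;
  }
  return List::create(_["values"] = out,
                      _["acceptance"] = (double)accepted / n_steps);
}

// Linear alchemical mixing of two 1-d potentials:
// U(lambda) = (1-lambda) U_A + lambda U_B; records dU/dlambda = U_B - U_A.
// [[Rcpp::export]]
List mc1d_dudl_cpp(int kindA, NumericVector parsA, int kindB,
                   NumericVector parsB, double lambda, double x0,
                   double temperature, int n_steps, double step_size,
                   int burn_in, int thin, double lo, double hi) {
  const double *pa = parsA.begin(), *pb = parsB.begin();
  double beta = 1.0 / (1.9872e-3 * temperature);
  double x = x0;
  double u = (1 - lambda) * u1d(kindA, pa, x) + lambda * u1d(kindB, pb, x);
  if (!R_finite(u)) stop("non-finite energy at the initial state");

  int n_keep = (n_steps - burn_in) / thin;
  NumericVector out(n_keep);
  long accepted = 0;
  int kept = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    double xp = x + step_size * (unif_rand() * 2.0 - 1.0);
    if (xp >= lo && xp <= hi) {
      double up =
          (1 - lambda) * u1d(kindA, pa, xp) + lambda * u1d(kindB, pb, xp);
      if (!R_finite(up)) stop("non-finite energy encountered during sampling");
      if (up <= u || unif_rand() < std::exp(-beta * (up - u))) {
        x = xp;
        u = up;
        ++accepted;
      }
    }
    if (s > burn_in && (s - burn_in) % thin == 0 && kept < n_keep)
      out[kept++] = u1d(kindB, pb, x) - u1d(kindA, pa, x);
  }
  return List::create(_["values"] = out,
                      _["acceptance"] = (double)accepted / n_steps);
}

// ---- micro-solvation box -----------------------------------------------
//
// Particle 0 is the solute; the rest are solvent beads. Solvent-solvent
// pairs interact through the full 12-6 + Coulomb potential. Solute-solvent
// pairs are alchemically coupled: soft-core vdW at lam_vdw, C4 at lam_pol,
// Coulomb at lam_ele. With shared_softcore the r^-4 and r^-1 tails use the
// same soft-core denominator as the 12-6 part (one-step protocol); without
// it they are bare linear terms (two-step legs, hard core fully on).

struct BoxPair {
  double c12, c6, c4, alpha, sig6, sig4, sig, eps;
  bool null_vdw; // no solute-solvent interaction at all (null solute)
};

static inline double minimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Solute-solvent pair energy at squared distance r2.
static inline double upair_sol(const BoxPair &P, double r2, double qq,
                               double lv, double lp, double le,
                               bool shared_sc) {
  if (P.null_vdw) return 0.0;
  double r6 = r2 * r2 * r2;
  double s6 = r6 / P.sig6;
  double A = P.alpha * (1.0 - lv) + s6;
  double u = 4.0 * P.eps * lv * (1.0 / (A * A) - 1.0 / A);
  if (shared_sc) {
    double A13 = std::cbrt(A); // A^(1/3)
    u += -lp * P.c4 / (P.sig4 * A13 * A13);
    u += le * KCOUL * qq / (P.sig * std::sqrt(A13));
  } else {
    double r = std::sqrt(r2), r4 = r2 * r2;
    u += -lp * P.c4 / r4 + le * KCOUL * qq / r;
  }
  return u;
}

// Analytic dU/dlambda components for a solute-solvent pair.
static inline void dudl_pair_sol(const BoxPair &P, double r2, double qq,
                                 double lv, double lp, double le,
                                 bool shared_sc, double &dv, double &dp,
                                 double &de) {
  if (P.null_vdw) return;
  double r6 = r2 * r2 * r2;
  double s6 = r6 / P.sig6;
  double A = P.alpha * (1.0 - lv) + s6;
  double A2 = A * A, A3 = A2 * A;
  dv += 4.0 * P.eps * (1.0 / A2 - 1.0 / A) +
        4.0 * P.eps * lv * P.alpha * (2.0 / A3 - 1.0 / A2);
  if (shared_sc) {
    double A13 = std::cbrt(A);
    double A23 = A13 * A13;          // A^(2/3)
    double A53 = A23 * A;            // A^(5/3)
    double A16 = std::sqrt(A13);     // A^(1/6)
    double A76 = A16 * A;            // A^(7/6)
    dp += -P.c4 / P.sig4 * (1.0 / A23 + 2.0 * P.alpha * lp / (3.0 * A53));
    de += KCOUL * qq / P.sig * (1.0 / A16 + P.alpha * lp / (6.0 * A76));
  } else {
    double r = std::sqrt(r2), r4 = r2 * r2;
    dp += -P.c4 / r4;
    de += KCOUL * qq / r;
  }
}

// [[Rcpp::export]]
List mcbox_cpp(NumericMatrix coords0, NumericVector q, double c12ss,
               double c6ss, double c12us, double c6us, double c4us,
               double box, double cutoff, double temperature, double lam_vdw,
               double lam_pol, double lam_ele, bool shared_sc,
               double alpha_sc, int n_steps, double step_size, int burn_in,
               int thin) {
  int N = coords0.nrow();
  if (N < 2) stop("micro-solvation box needs at least two particles");
  bool null_sol = (c12us <= 0 && c6us <= 0);
  if (null_sol && (c4us != 0 || q[0] != 0))
    stop("a solute without 12-6 coefficients must also have zero C4 and "
         "charge (no soft-core reference distance exists)");
  if (!null_sol && (c12us <= 0 || c6us <= 0))
    stop("solute-solvent C12 and C6 must be positive (soft-core reference)");
  std::vector<double> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) {
    X[i] = coords0(i, 0);
    Y[i] = coords0(i, 1);
    Z[i] = coords0(i, 2);
  }
  BoxPair P;
  P.c12 = c12us;
  P.c6 = c6us;
  P.c4 = c4us;
  P.alpha = alpha_sc;
  P.null_vdw = null_sol;
  P.sig6 = null_sol ? 1.0 : c12us / c6us;
  P.sig = std::pow(P.sig6, 1.0 / 6.0);
  P.sig4 = P.sig * P.sig * P.sig * P.sig;
  P.eps = null_sol ? 0.0 : c6us * c6us / (4.0 * c12us);
  double beta = 1.0 / (1.9872e-3 * temperature);
  double rc2 = cutoff * cutoff;

  // interaction energy of particle i with all others
  auto epart = [&](int i, double xi, double yi, double zi) {
    double e = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double dx = minimg(xi - X[j], box);
      double dy = minimg(yi - Y[j], box);
      double dz = minimg(zi - Z[j], box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rc2) continue;
      if (i == 0 || j == 0) {
        e += upair_sol(P, r2, q[i] * q[j], lam_vdw, lam_pol, lam_ele,
                       shared_sc);
      } else {
        double r6 = r2 * r2 * r2, r12 = r6 * r6;
        e += c12ss / r12 - c6ss / r6 +
             KCOUL * q[i] * q[j] / std::sqrt(r2);
      }
    }
    return e;
  };

  int n_keep = (n_steps - burn_in) / thin;
  NumericVector dvdw(n_keep), dpol(n_keep), dele(n_keep), obs(n_keep);
  long accepted = 0;
  int kept = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    int i = (int)std::floor(unif_rand() * N);
    if (i == N) i = N - 1;
    double xo = X[i], yo = Y[i], zo = Z[i];
    double e0 = epart(i, xo, yo, zo);
    double xn = xo + step_size * (unif_rand() * 2.0 - 1.0);
    double yn = yo + step_size * (unif_rand() * 2.0 - 1.0);
    double zn = zo + step_size * (unif_rand() * 2.0 - 1.0);
    double e1 = epart(i, xn, yn, zn);
    if (!R_finite(e1)) stop("non-finite energy encountered during sampling");
    if (e1 <= e0 || unif_rand() < std::exp(-beta * (e1 - e0))) {
      X[i] = xn;
      Y[i] = yn;
      Z[i] = zn;
      ++accepted;
    }
    if (s > burn_in && (s - burn_in) % thin == 0 && kept < n_keep) {
      double dv = 0, dp = 0, de = 0, rmin2 = R_PosInf;
      for (int j = 1; j < N; ++j) {
        double dx = minimg(X[0] - X[j], box);
        double dy = minimg(Y[0] - Y[j], box);
        double dz = minimg(Z[0] - Z[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rmin2) rmin2 = r2;
        if (r2 > rc2) continue;
        dudl_pair_sol(P, r2, q[0] * q[j], lam_vdw, lam_pol, lam_ele,
                      shared_sc, dv, dp, de);
      }
      dvdw[kept] = dv;
      dpol[kept] = dp;
      dele[kept] = de;
      obs[kept] = std::sqrt(rmin2);
      ++kept;
    }
  }
  NumericMatrix cf(N, 3);
  for (int i = 0; i < N; ++i) {
    cf(i, 0) = X[i];
    cf(i, 1) = Y[i];
    cf(i, 2) = Z[i];
  }
  return List::create(_["dudl_vdw"] = dvdw, _["dudl_pol"] = dpol,
                      _["dudl_ele"] = dele, _["obs"] = obs,
                      _["acceptance"] = (double)accepted / n_steps,
                      _["coords"] = cf);
}
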