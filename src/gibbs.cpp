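// Blocked Gibbs sampler for the multi-response Gaussian mixed model
//
//   y_i = x_i' b + u_{line(i), sex(i)} + w_{vial(i)} + e_i
//
// with a 2x2 unstructured cross-sex line covariance G, per-sex vial
// variances (no cross-sex vial or residual covariance: each vial and fly is
// one sex), and per-sex residual variances.  The line term uses parameter
// expansion: u = diag(a) * eta with eta_l ~ N(0, Psi), Psi inverse-Wishart
// and a_s ~ N(0, alpha_var); the implied prior on G = diag(a) Psi diag(a)
// is the scaled non-central-F family that mixes well when variances are
// near zero.  The residual prior is a (near-flat) scaled inverse
// chi-squared.
//
// The sampler runs on vial-level sufficient statistics (mean, count,
// within-vial sum of squares), which is exact for this Gaussian model and
// makes paper-scale chains cheap.  All randomness flows through R's RNG so
// set.seed() in R makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvchisq(double df, double scale_sum) {
  double g = R::rchisq(df);
  if (g <= 0) g = 1e-300;
  return scale_sum / g;
}

// inverse-Wishart via Bartlett decomposition of W ~ Wishart(df, S^{-1})
static arma::mat riwish(double df, const arma::mat& S) {
  int p = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export]]
List gibbs_chain_cpp(const arma::vec& ybar, const arma::vec& n,
                     const arma::vec& ss, const arma::ivec& sex,
                     const arma::ivec& line, const arma::mat& X,
                     int n_lines, bool vial_effect,
                     int n_iter, int burn, int thin,
                     double nu_g, double v0_g, double nu_r, double v0_r,
                     double alpha_var, bool px, double beta_prior_var) {
  const int G = ybar.n_elem;
  const int p = X.n_cols;
  const int L = n_lines;

  // fixed-design cross products per sex
  arma::mat XtX0(p, p, arma::fill::zeros), XtX1(p, p, arma::fill::zeros);
  double N0 = 0.0, N1 = 0.0;
  int Gs0 = 0, Gs1 = 0;
  for (int g = 0; g < G; ++g) {
    arma::rowvec xg = X.row(g);
    if (sex[g] == 0) { XtX0 += n[g] * xg.t() * xg; N0 += n[g]; Gs0++; }
    else             { XtX1 += n[g] * xg.t() * xg; N1 += n[g]; Gs1++; }
  }

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::mat eta(L, 2, arma::fill::zeros);
  arma::vec a(2); a.fill(1.0);
  arma::mat Psi = arma::eye(2, 2);
  arma::vec zeta(G, arma::fill::zeros);
  arma::vec av(2); av.fill(1.0);
  arma::vec psi_v(2); psi_v.fill(1.0);
  arma::vec s2(2);

  // data-driven variance inits, small seed-dependent jitter on the rest
  double ymean = arma::dot(ybar, n) / (N0 + N1);
  double vtot = 0.0;
  for (int g = 0; g < G; ++g) {
    vtot += ss[g] + n[g] * (ybar[g] - ymean) * (ybar[g] - ymean);
  }
  vtot /= (N0 + N1);
  if (vtot <= 0) vtot = 1.0;
  s2.fill(vtot);
  Psi *= vtot / 4.0 + 1e-6;
  psi_v.fill(vtot / 10.0 + 1e-6);
  for (int l = 0; l < L; ++l) {
    eta(l, 0) = 0.1 * std::sqrt(vtot) * R::norm_rand();
    eta(l, 1) = 0.1 * std::sqrt(vtot) * R::norm_rand();
  }

  const int n_keep = (n_iter - burn) / thin;
  const int n_store = p + 3 + (vial_effect ? 2 : 0) + 2;
  arma::mat out(n_keep, n_store);

  arma::vec u(G, arma::fill::zeros), w(G, arma::fill::zeros), Xb(G);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // contributions
    for (int g = 0; g < G; ++g) {
      u[g] = a[sex[g]] * eta(line[g], sex[g]);
      w[g] = vial_effect ? av[sex[g]] * zeta[g] : 0.0;
    }

    // --- fixed effects ---
    arma::mat P = XtX0 / s2[0] + XtX1 / s2[1];
    P.diag() += 1.0 / beta_prior_var;
    arma::vec rhs(p, arma::fill::zeros);
    for (int g = 0; g < G; ++g) {
      double r = ybar[g] - u[g] - w[g];
      rhs += (n[g] * r / s2[sex[g]]) * X.row(g).t();
    }
    arma::mat Pc = arma::chol(arma::symmatu(P));            // upper
    arma::vec mu_b = arma::solve(arma::trimatu(Pc),
                     arma::solve(arma::trimatl(Pc.t()), rhs));
    arma::vec zb(p);
    for (int j = 0; j < p; ++j) zb[j] = R::norm_rand();
    beta = mu_b + arma::solve(arma::trimatu(Pc), zb);
    Xb = X * beta;

    // --- line effects eta ---
    arma::mat T(L, 2, arma::fill::zeros), Nls(L, 2, arma::fill::zeros);
    for (int g = 0; g < G; ++g) {
      double r = ybar[g] - Xb[g] - w[g];
      T(line[g], sex[g]) += n[g] * r;
      Nls(line[g], sex[g]) += n[g];
    }
    arma::mat Psi_inv = arma::inv_sympd(arma::symmatu(Psi));
    for (int l = 0; l < L; ++l) {
      arma::mat Pl = Psi_inv;
      Pl(0, 0) += a[0] * a[0] * Nls(l, 0) / s2[0];
      Pl(1, 1) += a[1] * a[1] * Nls(l, 1) / s2[1];
      arma::vec rl(2);
      rl[0] = a[0] * T(l, 0) / s2[0];
      rl[1] = a[1] * T(l, 1) / s2[1];
      arma::mat Plc = arma::chol(arma::symmatu(Pl));
      arma::vec mu_l = arma::solve(arma::trimatu(Plc),
                       arma::solve(arma::trimatl(Plc.t()), rl));
      arma::vec zl(2);
      zl[0] = R::norm_rand(); zl[1] = R::norm_rand();
      arma::vec el = mu_l + arma::solve(arma::trimatu(Plc), zl);
      eta(l, 0) = el[0];
      eta(l, 1) = el[1];
    }

    // --- expansion scales a (line term) ---
    if (px) {
      for (int s = 0; s < 2; ++s) {
        double den = 1.0 / alpha_var, num = 0.0;
        for (int g = 0; g < G; ++g) {
          if (sex[g] != s) continue;
          double x = eta(line[g], s);
          double r = ybar[g] - Xb[g] - w[g];
          den += n[g] * x * x / s2[s];
          num += n[g] * x * r / s2[s];
        }
        a[s] = num / den + R::norm_rand() / std::sqrt(den);
      }
    }

    // --- working line covariance Psi ---
    arma::mat Se = nu_g * v0_g * arma::eye(2, 2);
    Se += eta.t() * eta;
    Psi = riwish(nu_g + L, Se);

    for (int g = 0; g < G; ++g) u[g] = a[sex[g]] * eta(line[g], sex[g]);

    // --- vial effects ---
    if (vial_effect) {
      for (int g = 0; g < G; ++g) {
        int s = sex[g];
        double r = ybar[g] - Xb[g] - u[g];
        double prec = 1.0 / psi_v[s] + av[s] * av[s] * n[g] / s2[s];
        double mu_z = (av[s] * n[g] * r / s2[s]) / prec;
        zeta[g] = mu_z + R::norm_rand() / std::sqrt(prec);
      }
      if (px) {
        for (int s = 0; s < 2; ++s) {
          double den = 1.0 / alpha_var, num = 0.0;
          for (int g = 0; g < G; ++g) {
            if (sex[g] != s) continue;
            double r = ybar[g] - Xb[g] - u[g];
            den += n[g] * zeta[g] * zeta[g] / s2[s];
            num += n[g] * zeta[g] * r / s2[s];
          }
          av[s] = num / den + R::norm_rand() / std::sqrt(den);
        }
      }
      for (int s = 0; s < 2; ++s) {
        double ssz = 0.0;
        int cnt = (s == 0) ? Gs0 : Gs1;
        for (int g = 0; g < G; ++g) {
          if (sex[g] == s) ssz += zeta[g] * zeta[g];
        }
        psi_v[s] = rinvchisq(nu_g + cnt, nu_g * v0_g + ssz);
      }
      for (int g = 0; g < G; ++g) w[g] = av[sex[g]] * zeta[g];
    }

    // --- residual variances ---
    double sse0 = 0.0, sse1 = 0.0;
    for (int g = 0; g < G; ++g) {
      double r = ybar[g] - Xb[g] - u[g] - w[g];
      double contrib = ss[g] + n[g] * r * r;
      if (sex[g] == 0) sse0 += contrib; else sse1 += contrib;
    }
    s2[0] = rinvchisq(nu_r + N0, nu_r * v0_r + sse0);
    s2[1] = rinvchisq(nu_r + N1, nu_r * v0_r + sse1);

    // --- record ---
    if (it > burn && (it - burn) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int j = 0; j < p; ++j) out(kept, c++) = beta[j];
      arma::mat Gm = Psi;
      Gm(0, 0) *= a[0] * a[0];
      Gm(1, 1) *= a[1] * a[1];
      Gm(0, 1) *= a[0] * a[1];
      out(kept, c++) = Gm(0, 0);
      out(kept, c++) = Gm(0, 1);
      out(kept, c++) = Gm(1, 1);
      if (vial_effect) {
        out(kept, c++) = av[0] * av[0] * psi_v[0];
        out(kept, c++) = av[1] * av[1] * psi_v[1];
      }
      out(kept, c++) = s2[0];
      out(kept, c++) = s2[1];
      kept++;
    }
  }

  return List::create(Named("samples") = out, Named("n_kept") = kept);
}
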