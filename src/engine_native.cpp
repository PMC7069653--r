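// Native inner solver for the three structural stage models.
//
// Mirrors the R reference implementation in R/engine.R: per subject, a
// damped Gauss-Newton search for the conditional mode of the random
// effects (exponential parameterisation), followed by the Laplace
// contribution q(b) + log det(J'WJ + P) - nb log(2pi) with the residual
// variance evaluated at the conditional prediction. Analytic Jacobians
// are hardcoded per model. The generic R path stays available for custom
// models; both paths are asserted equal in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int MODEL_PK = 1;      // params: cl, v, ka        X: dose, tad
static const int MODEL_CIRC = 2;    // params: bsl0, amp, tpeak,
                                    //         trend, s0, period X: clock, c5htp
static const int MODEL_POWER = 3;   // params: beta, gamma       X: ccol

static inline double hfun(double x) {
  if (std::fabs(x) < 1e-8) return 0.5 + x / 6.0;
  return (std::expm1(x) - x) / (x * x);
}
static inline double hpfun(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 / 6.0 + x / 12.0 + x * x / 40.0;
  double em = std::expm1(x);
  return (x * em - 2.0 * (em - x)) / (x * x * x);
}

// predictions f and, when D != nullptr, derivative columns df/dP for the
// RE-carrying parameters (column order = re_pars entries)
static void model_eval(int model, const arma::mat& P, const arma::mat& X,
                       const arma::ivec& re_pars, arma::vec& f,
                       arma::mat* D) {
  const arma::uword n = X.n_rows;
  if (model == MODEL_PK) {
    for (arma::uword i = 0; i < n; ++i) {
      double cl = P(i, 0), v = P(i, 1), ka = P(i, 2);
      double dose = X(i, 0), t = X(i, 1);
      double ke = cl / v;
      double x = (ka - ke) * t;
      double h = hfun(x);
      double base = 1000.0 * dose / v * t * t * std::exp(-ka * t);
      f(i) = base * ka * ka * h;
      if (D) {
        double hp = hpfun(x);
        for (arma::uword j = 0; j < re_pars.n_elem; ++j) {
          int pj = re_pars(j);
          if (pj == 0) {           // cl
            (*D)(i, j) = -base * ka * ka * hp * t / v;
          } else if (pj == 2) {    // ka
            (*D)(i, j) = f(i) * (2.0 / ka - t) + base * ka * ka * hp * t;
          } else {
            (*D)(i, j) = 0.0;
          }
        }
      }
    }
  } else if (model == MODEL_CIRC) {
    for (arma::uword i = 0; i < n; ++i) {
      double bsl0 = P(i, 0), amp = P(i, 1), tpeak = P(i, 2);
      double trend = P(i, 3), s0 = P(i, 4), period = P(i, 5);
      double clock = X(i, 0), c5 = X(i, 1);
      double w = 2.0 * M_PI / period;
      double dt = clock - tpeak;
      double cs = std::cos(w * dt);
      double level = bsl0 - trend * dt;
      double C = 1.0 + amp * cs;
      f(i) = level * C + s0 * c5;
      if (D) {
        for (arma::uword j = 0; j < re_pars.n_elem; ++j) {
          int pj = re_pars(j);
          double d;
          switch (pj) {
          case 0: d = C; break;
          case 1: d = level * cs; break;
          case 2: d = trend * C + level * amp * std::sin(w * dt) * w; break;
          case 3: d = -dt * C; break;
          case 4: d = c5; break;
          default: d = 0.0;
          }
          (*D)(i, j) = d;
        }
      }
    }
  } else if (model == MODEL_POWER) {
    for (arma::uword i = 0; i < n; ++i) {
      double beta = P(i, 0), gamma = P(i, 1);
      double c = X(i, 0);
      double cg = std::pow(c, gamma);
      f(i) = beta * cg;
      if (D) {
        for (arma::uword j = 0; j < re_pars.n_elem; ++j) {
          int pj = re_pars(j);
          if (pj == 0) (*D)(i, j) = cg;
          else if (pj == 1) (*D)(i, j) = (c > 0.0)
            ? beta * cg * std::log(c) : 0.0;
          else (*D)(i, j) = 0.0;
        }
      }
    }
  } else {
    stop("unknown native model id");
  }
}

struct SubjData {
  arma::vec y;
  arma::mat X;
  arma::ivec occ;    // 1-based occasion index per row
  int n_occ;
};

// per-row parameter matrix from theta and the random-effect vector b
static void build_P(const arma::vec& theta, const arma::vec& b,
                    const arma::ivec& iiv_par, const arma::ivec& iov_par,
                    const SubjData& s, arma::mat& P) {
  const arma::uword n = s.X.n_rows;
  const int n_iiv = iiv_par.n_elem;
  for (arma::uword j = 0; j < theta.n_elem; ++j) {
    P.col(j).fill(theta(j));
  }
  for (int j = 0; j < n_iiv; ++j) {
    P.col(iiv_par(j)) *= std::exp(b(j));
  }
  for (arma::uword j = 0; j < (arma::uword)iov_par.n_elem; ++j) {
    int pj = iov_par(j);
    for (arma::uword i = 0; i < n; ++i) {
      P(i, pj) *= std::exp(b(n_iiv + j * s.n_occ + (s.occ(i) - 1)));
    }
  }
}

static double q_of(const arma::vec& f, const arma::vec& y,
                   const arma::vec& b, const arma::vec& prec,
                   double lpn, double sp2, double sa2) {
  double q = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    if (!std::isfinite(f(i))) return 1e10;
    double v = f(i) * f(i) * sp2 + sa2;
    if (v <= 0.0) return 1e10;
    double r = y(i) - f(i);
    q += std::log(2.0 * M_PI * v) + r * r / v;
  }
  for (arma::uword k = 0; k < b.n_elem; ++k) q += prec(k) * b(k) * b(k);
  return q + lpn;
}

// Gauss-Newton MAP solve + Laplace contribution for one subject.
// Returns the contribution and leaves the mode in b.
static double subject_contrib(int model, const SubjData& s,
                              const arma::vec& theta,
                              const arma::ivec& iiv_par,
                              const arma::ivec& iov_par,
                              const arma::ivec& re_pars,
                              const arma::vec& omega2,
                              const arma::vec& iov2,
                              double sp2, double sa2, arma::vec& b) {
  const int n_iiv = iiv_par.n_elem;
  const int n_iov = iov_par.n_elem;
  const int nb = n_iiv + n_iov * s.n_occ;
  const arma::uword n = s.y.n_elem;
  arma::vec prec(nb);
  for (int j = 0; j < n_iiv; ++j) prec(j) = 1.0 / omega2(j);
  for (int j = 0; j < n_iov; ++j) {
    for (int k = 0; k < s.n_occ; ++k) {
      prec(n_iiv + j * s.n_occ + k) = 1.0 / iov2(j);
    }
  }
  double lpn = 0.0;
  for (int k = 0; k < nb; ++k) lpn += std::log(2.0 * M_PI / prec(k));

  arma::mat P(n, theta.n_elem);
  arma::mat D(n, re_pars.n_elem);
  arma::vec f(n), fc(n);
  arma::mat Pc(n, theta.n_elem);

  b.zeros(nb);
  build_P(theta, b, iiv_par, iov_par, s, P);
  model_eval(model, P, s.X, re_pars, f, nullptr);
  double q = q_of(f, s.y, b, prec, lpn, sp2, sa2);

  double lam = 1e-4;
  arma::mat J(n, nb), H(nb, nb), Hl(nb, nb);
  arma::vec g(nb), delta(nb), bc(nb);
  for (int it = 0; it < 40; ++it) {
    model_eval(model, P, s.X, re_pars, f, &D);
    // chain rule: dP/d(eta) = P for the exponential parameterisation
    J.zeros();
    for (arma::uword j = 0; j < re_pars.n_elem; ++j) {
      int pj = re_pars(j);
      // eta column
      for (int je = 0; je < n_iiv; ++je) {
        if (iiv_par(je) == pj) {
          for (arma::uword i = 0; i < n; ++i) {
            J(i, je) += D(i, j) * P(i, pj);
          }
        }
      }
      // kappa columns (per occasion)
      for (int jv = 0; jv < n_iov; ++jv) {
        if (iov_par(jv) == pj) {
          for (arma::uword i = 0; i < n; ++i) {
            J(i, n_iiv + jv * s.n_occ + (s.occ(i) - 1)) +=
              D(i, j) * P(i, pj);
          }
        }
      }
    }
    g.zeros();
    H.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      double v = f(i) * f(i) * sp2 + sa2;
      if (v < 1e-12) v = 1e-12;
      double w = 1.0 / v;
      double r = s.y(i) - f(i);
      for (int k = 0; k < nb; ++k) {
        g(k) -= J(i, k) * w * r;
        for (int l = 0; l <= k; ++l) H(k, l) += J(i, k) * w * J(i, l);
      }
    }
    for (int k = 0; k < nb; ++k) {
      H(k, k) += prec(k);
      g(k) += prec(k) * b(k);
      for (int l = 0; l < k; ++l) H(l, k) = H(k, l);
    }
    bool accepted = false;
    double qn = q;
    for (int tries = 0; tries < 12; ++tries) {
      Hl = H;
      for (int k = 0; k < nb; ++k) Hl(k, k) = H(k, k) * (1.0 + lam);
      bool ok = arma::solve(delta, Hl, -g,
                            arma::solve_opts::no_approx +
                            arma::solve_opts::likely_sympd);
      if (ok) {
        bc = b + delta;
        build_P(theta, bc, iiv_par, iov_par, s, Pc);
        model_eval(model, Pc, s.X, re_pars, fc, nullptr);
        qn = q_of(fc, s.y, bc, prec, lpn, sp2, sa2);
        if (std::isfinite(qn) && qn <= q + 1e-12) { accepted = true; break; }
      }
      lam *= 8.0;
    }
    if (!accepted) break;
    double improve = q - qn;
    b = bc;
    P = Pc;
    f = fc;
    q = qn;
    lam = std::max(lam / 8.0, 1e-8);
    if (improve < 1e-12 && arma::abs(delta).max() < 1e-7) break;
  }

  // curvature at the mode
  model_eval(model, P, s.X, re_pars, f, &D);
  J.zeros();
  for (arma::uword j = 0; j < re_pars.n_elem; ++j) {
    int pj = re_pars(j);
    for (int je = 0; je < n_iiv; ++je) {
      if (iiv_par(je) == pj) {
        for (arma::uword i = 0; i < n; ++i) {
          J(i, je) += D(i, j) * P(i, pj);
        }
      }
    }
    for (int jv = 0; jv < n_iov; ++jv) {
      if (iov_par(jv) == pj) {
        for (arma::uword i = 0; i < n; ++i) {
          J(i, n_iiv + jv * s.n_occ + (s.occ(i) - 1)) +=
            D(i, j) * P(i, pj);
        }
      }
    }
  }
  H.zeros();
  for (arma::uword i = 0; i < n; ++i) {
    double v = f(i) * f(i) * sp2 + sa2;
    if (v < 1e-12) v = 1e-12;
    double w = 1.0 / v;
    for (int k = 0; k < nb; ++k) {
      for (int l = 0; l <= k; ++l) H(k, l) += J(i, k) * w * J(i, l);
    }
  }
  for (int k = 0; k < nb; ++k) {
    H(k, k) += prec(k);
    for (int l = 0; l < k; ++l) H(l, k) = H(k, l);
  }
  arma::mat R;
  if (!arma::chol(R, H)) return 1e10;
  double logdet = 0.0;
  for (int k = 0; k < nb; ++k) logdet += 2.0 * std::log(R(k, k));
  return q + logdet - nb * std::log(2.0 * M_PI);
}

static std::vector<SubjData> unpack_subjects(const List& subjects) {
  std::vector<SubjData> out(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) {
    List si = subjects[i];
    out[i].y = as<arma::vec>(si["y"]);
    out[i].X = as<arma::mat>(si["X"]);
    out[i].occ = as<arma::ivec>(si["occ"]);
    out[i].n_occ = as<int>(si["n_occ"]);
  }
  return out;
}

// [[Rcpp::export(name = ".engine_ofv_native")]]
double engine_ofv_native(int model, List subjects, NumericVector theta,
                         IntegerVector iiv_par, IntegerVector iov_par,
                         NumericVector omega2, NumericVector iov2,
                         double sigma_prop, double sigma_add) {
  std::vector<SubjData> ss = unpack_subjects(subjects);
  arma::vec th = as<arma::vec>(theta);
  arma::ivec iiv = as<arma::ivec>(iiv_par);
  arma::ivec iov = as<arma::ivec>(iov_par);
  arma::vec om = as<arma::vec>(omega2);
  arma::vec ov = as<arma::vec>(iov2);
  // union of RE-carrying parameter indices, preserving first appearance
  std::vector<int> rp;
  for (arma::uword j = 0; j < iiv.n_elem; ++j) {
    if (std::find(rp.begin(), rp.end(), iiv(j)) == rp.end())
      rp.push_back(iiv(j));
  }
  for (arma::uword j = 0; j < iov.n_elem; ++j) {
    if (std::find(rp.begin(), rp.end(), iov(j)) == rp.end())
      rp.push_back(iov(j));
  }
  arma::ivec re_pars(rp.size());
  for (size_t j = 0; j < rp.size(); ++j) re_pars(j) = rp[j];
  double sp2 = sigma_prop * sigma_prop;
  double sa2 = sigma_add * sigma_add;
  double total = 0.0;
  arma::vec b;
  for (size_t i = 0; i < ss.size(); ++i) {
    double c = subject_contrib(model, ss[i], th, iiv, iov, re_pars,
                               om, ov, sp2, sa2, b);
    if (!std::isfinite(c) || c >= 1e10) return 1e10;
    total += c;
  }
  return total;
}

// [[Rcpp::export(name = ".engine_ebes_native")]]
List engine_ebes_native(int model, List subjects, NumericVector theta,
                        IntegerVector iiv_par, IntegerVector iov_par,
                        NumericVector omega2, NumericVector iov2,
                        double sigma_prop, double sigma_add) {
  std::vector<SubjData> ss = unpack_subjects(subjects);
  arma::vec th = as<arma::vec>(theta);
  arma::ivec iiv = as<arma::ivec>(iiv_par);
  arma::ivec iov = as<arma::ivec>(iov_par);
  arma::vec om = as<arma::vec>(omega2);
  arma::vec ov = as<arma::vec>(iov2);
  std::vector<int> rp;
  for (arma::uword j = 0; j < iiv.n_elem; ++j) {
    if (std::find(rp.begin(), rp.end(), iiv(j)) == rp.end())
      rp.push_back(iiv(j));
  }
  for (arma::uword j = 0; j < iov.n_elem; ++j) {
    if (std::find(rp.begin(), rp.end(), iov(j)) == rp.end())
      rp.push_back(iov(j));
  }
  arma::ivec re_pars(rp.size());
  for (size_t j = 0; j < rp.size(); ++j) re_pars(j) = rp[j];
  double sp2 = sigma_prop * sigma_prop;
  double sa2 = sigma_add * sigma_add;
  List out(ss.size());
  arma::vec b;
  for (size_t i = 0; i < ss.size(); ++i) {
    subject_contrib(model, ss[i], th, iiv, iov, re_pars, om, ov,
                    sp2, sa2, b);
    out[i] = NumericVector(b.begin(), b.end());
  }
  return out;
}
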