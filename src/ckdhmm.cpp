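// Core numerics for the kidney-function progression HMM:
//  - matrix exponential of (upper-triangular) CTMC generators,
//  - Frechet-derivative adjoints for gradient backpropagation,
//  - forward-algorithm log-likelihood for panel records with exactly
//    observed death times and optional alive-at-censor information.
//
// Generators here are upper triangular (uni-directional progression plus an
// absorbing death state), so exp(A) admits a Parlett / triangular
// eigendecomposition fast path; whenever two total exit rates are nearly
// confluent we fall back to scaling-and-squaring (arma::expmat). The hot
// path works on the 5x5 living-state block with fixed-size matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GAP_RTOL = 1e-6;
static const int NL = 5;
typedef mat::fixed<NL, NL> M5;
typedef vec::fixed<NL> V5;

static bool diag_gaps_ok(const mat& A) {
  const uword n = A.n_rows;
  double scale = 1.0;
  for (uword i = 0; i < n; ++i) scale = std::max(scale, std::abs(A(i, i)));
  const double tol = GAP_RTOL * scale;
  for (uword i = 0; i < n; ++i)
    for (uword j = i + 1; j < n; ++j)
      if (std::abs(A(i, i) - A(j, j)) < tol) return false;
  return true;
}

static bool is_upper_tri(const mat& A) {
  const uword n = A.n_rows;
  for (uword j = 0; j < n; ++j)
    for (uword i = j + 1; i < n; ++i)
      if (A(i, j) != 0.0) return false;
  return true;
}

// Scaling-and-squaring with a Taylor evaluation of the scaled exponential.
// Never throws (unlike arma::expmat, which refuses ill-conditioned input);
// NaN/Inf inputs propagate to NaN outputs, which callers treat as an
// impossible/infeasible parameter point.
static mat expm_ss(const mat& A) {
  const double nrm = norm(A, "inf");
  if (!std::isfinite(nrm)) {
    mat F(A.n_rows, A.n_cols); F.fill(datum::nan); return F;
  }
  int s = 0;
  double sc = 1.0;
  while (nrm * sc > 0.5 && s < 60) { sc *= 0.5; ++s; }
  mat B = A * sc;
  mat F = eye(A.n_rows, A.n_cols);
  mat T = eye(A.n_rows, A.n_cols);
  for (int k = 1; k <= 18; ++k) {  // ||B|| <= 0.5: remainder < 1e-17
    T = (T * B) / double(k);
    F += T;
  }
  for (int k = 0; k < s; ++k) F = F * F;
  return F;
}

// Parlett recurrence for exp(A), A upper triangular with well-separated
// diagonal. Cost O(n^3), no squaring needed.
template <class MatT>
static void expm_parlett_t(const MatT& A, MatT& F, const uword n) {
  F.zeros();
  for (uword i = 0; i < n; ++i) F(i, i) = std::exp(A(i, i));
  for (uword d = 1; d < n; ++d) {
    for (uword i = 0; i + d < n; ++i) {
      const uword j = i + d;
      double num = A(i, j) * (F(i, i) - F(j, j));
      for (uword k = i + 1; k < j; ++k)
        num += F(i, k) * A(k, j) - A(i, k) * F(k, j);
      F(i, j) = num / (A(i, i) - A(j, j));
    }
  }
}

// [[Rcpp::export]]
arma::mat expm_tri_cpp(const arma::mat& A) {
  if (A.n_rows != A.n_cols) Rcpp::stop("matrix must be square");
  if (is_upper_tri(A) && diag_gaps_ok(A)) {
    mat F(A.n_rows, A.n_rows);
    expm_parlett_t(A, F, A.n_rows);
    return F;
  }
  return expm_ss(A);
}

static bool gaps_ok5(const M5& A) {
  double scale = 1.0;
  for (int i = 0; i < NL; ++i) scale = std::max(scale, std::abs(A(i, i)));
  const double tol = GAP_RTOL * scale;
  for (int i = 0; i < NL; ++i)
    for (int j = i + 1; j < NL; ++j)
      if (std::abs(A(i, i) - A(j, j)) < tol) return false;
  return true;
}

static void expm5(const M5& A, M5& F, const bool fast) {
  if (fast) {
    expm_parlett_t(A, F, NL);
  } else {
    mat Fa = expm_ss(mat(A));
    F = Fa;
  }
}

// Upper-triangular eigenvector matrix V (A V = V diag(A)), unit diagonal,
// and its inverse W. Requires well-separated diagonal.
static void tri_eigvecs5(const M5& A, M5& V, M5& W) {
  V.eye();
  for (int j = 1; j < NL; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      double s = 0.0;
      for (int k = i + 1; k <= j; ++k) s += A(i, k) * V(k, j);
      V(i, j) = s / (A(j, j) - A(i, i));
    }
  }
  W.eye();
  for (int j = 0; j < NL; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      double s = 0.0;
      for (int k = i + 1; k <= j; ++k) s += V(i, k) * W(k, j);
      W(i, j) = -s;  // V has unit diagonal
    }
  }
}

// Adjoint of the Frechet derivative of expm at A: K with
// <G, L(A,E)> = <K, E> for all E (Daleckii-Krein on the fast path, block
// scaling-and-squaring fallback otherwise).
static void frechet_adjoint5(const M5& A, const M5& G, M5& K,
                             const bool fast) {
  if (fast) {
    M5 V, W, Phi;
    tri_eigvecs5(A, V, W);
    double el[NL];
    for (int i = 0; i < NL; ++i) el[i] = std::exp(A(i, i));
    for (int i = 0; i < NL; ++i) {
      Phi(i, i) = el[i];
      for (int j = i + 1; j < NL; ++j) {
        const double d = A(i, i) - A(j, j);
        Phi(i, j) = Phi(j, i) = (el[i] - el[j]) / d;
      }
    }
    const M5 H = V.t() * G * W.t();
    K = W.t() * (H % Phi) * V.t();
  } else {
    mat B(2 * NL, 2 * NL, fill::zeros);
    B.submat(0, 0, NL - 1, NL - 1) = mat(A).t();
    B.submat(NL, NL, 2 * NL - 1, 2 * NL - 1) = mat(A).t();
    B.submat(0, NL, NL - 1, 2 * NL - 1) = mat(G);
    mat EB = expm_ss(B);
    K = EB.submat(0, NL, NL - 1, 2 * NL - 1);
  }
}

// Specialised adjoint for the forward-backward chain rule: the sensitivity
// G = a wb^T is rank one and only the diagonal and superdiagonal entries of
// K = L*(A, G) are consumed (they carry the chain rule to the progression
// and exit rates). Uses the Daleckii-Krein representation with
// Phi(k,l) = (e^{lam_k} - e^{lam_l})/(lam_k - lam_l) read off the already
// computed exponential's diagonal. Valid on the separated-diagonal fast
// path only.
static void frechet_adjoint5_rank1(const M5& A, const M5& P, const V5& a,
                                   const V5& wb, double* Kdiag,
                                   double* Ksup) {
  M5 V, W;
  tri_eigvecs5(A, V, W);
  V5 u, v;
  for (int i = 0; i < NL; ++i) {            // u = V^T a (V upper triangular)
    double s = 0.0;
    for (int k = 0; k <= i; ++k) s += V(k, i) * a(k);
    u(i) = s;
  }
  for (int i = 0; i < NL; ++i) {            // v = W wb (W upper triangular)
    double s = 0.0;
    for (int k = i; k < NL; ++k) s += W(i, k) * wb(k);
    v(i) = s;
  }
  M5 Phi;
  for (int k = 0; k < NL; ++k) {
    Phi(k, k) = P(k, k);                     // e^{lam_k}
    for (int l = k + 1; l < NL; ++l) {
      Phi(k, l) = Phi(l, k) = (P(k, k) - P(l, l)) / (A(k, k) - A(l, l));
    }
  }
  // K(i,j) = sum_{k<=i} sum_{l>=j} W(k,i) u(k) Phi(k,l) v(l) V(j,l)
  for (int i = 0; i < NL; ++i) {
    double s = 0.0;
    for (int k = 0; k <= i; ++k) {
      const double wu = W(k, i) * u(k);
      for (int l = i; l < NL; ++l) s += wu * Phi(k, l) * v(l) * V(i, l);
    }
    Kdiag[i] = s;
  }
  for (int i = 0; i < 4; ++i) {
    const int j = i + 1;
    double s = 0.0;
    for (int k = 0; k <= i; ++k) {
      const double wu = W(k, i) * u(k);
      for (int l = j; l < NL; ++l) s += wu * Phi(k, l) * v(l) * V(j, l);
    }
    Ksup[i] = s;
  }
}

// [[Rcpp::export]]
arma::mat expm_frechet_adjoint_cpp(const arma::mat& A, const arma::mat& G) {
  if (A.n_rows == NL && A.n_cols == NL) {
    M5 A5 = A, G5 = G, K;
    frechet_adjoint5(A5, G5, K, is_upper_tri(A) && gaps_ok5(A5));
    return mat(K);
  }
  mat B(2 * A.n_rows, 2 * A.n_rows, fill::zeros);
  B.submat(0, 0, A.n_rows - 1, A.n_rows - 1) = A.t();
  B.submat(A.n_rows, A.n_rows, 2 * A.n_rows - 1, 2 * A.n_rows - 1) = A.t();
  B.submat(0, A.n_rows, A.n_rows - 1, 2 * A.n_rows - 1) = G;
  mat EB = expm_ss(B);
  return EB.submat(0, A.n_rows, A.n_rows - 1, 2 * A.n_rows - 1);
}

// ---------------------------------------------------------------------------
// Forward algorithm over a cohort (flattened record arrays).
//
// Intensities for record r in a step starting at time u:
//   q_prog[i] * mult_prog[r] * am_prog^(age-60),
//   q_death[i] * mult_death[r] * am_death^(age-60),
// with age = age_entry[r] + u held constant over the step. With
// annual_split, observation intervals are subdivided at integer age
// anniversaries. Death times are exactly observed (density term); patients
// known alive at censoring contribute a living-state survival factor.
// ---------------------------------------------------------------------------

struct Step {
  double dt;
  double agec;       // age at step start minus 60
  int wtype;         // 0 none, 1 emission, 2 death, 3 censor(alive)
  int obs;           // observed stage (0-based) when wtype == 1
};

// [[Rcpp::export]]
Rcpp::List cohort_loglik_cpp(const Rcpp::IntegerVector& n_obs,
                             const arma::vec& t_all,
                             const Rcpp::IntegerVector& s_all,
                             const Rcpp::IntegerVector& died,
                             const arma::vec& tdeath,
                             const arma::vec& censor,
                             const arma::vec& age_entry,
                             const arma::vec& q_prog,
                             const arma::vec& q_death,
                             double am_prog, double am_death,
                             const arma::vec& mult_prog,
                             const arma::vec& mult_death,
                             const arma::mat& E5in,
                             bool init_emission,
                             const arma::vec& initp,
                             bool annual_split,
                             bool use_censor,
                             bool want_grad) {
  const int nrec = n_obs.size();
  const M5 E5 = E5in;
  vec ll_rec(nrec, fill::zeros);
  vec gqp(4, fill::zeros), gqd(5, fill::zeros);
  double g_amp = 0.0, g_amd = 0.0;
  vec gp_rec(nrec, fill::zeros), gd_rec(nrec, fill::zeros);
  mat gE(NL, NL, fill::zeros);
  const double lamp = std::log(am_prog), lamd = std::log(am_death);

  std::vector<Step> steps;
  std::vector<M5> Ps;
  std::vector<V5> alphas;
  std::vector<double> cs;
  std::vector<bool> fastf;
  steps.reserve(128); Ps.reserve(128); alphas.reserve(129); cs.reserve(128);
  fastf.reserve(128);

  int off = 0;
  for (int r = 0; r < nrec; ++r) {
    const int m = n_obs[r];
    const double* tt = t_all.memptr() + off;
    const int* ss = &s_all[off];
    off += m;
    const bool rdied = died[r] != 0;
    const double age0 = age_entry(r);

    // build steps
    steps.clear();
    int n_anchor = m - 1 + 1;  // upper bound
    (void)n_anchor;
    double prev = tt[0];
    const int n_extra = (rdied || (use_censor &&
                                   censor(r) > tt[m - 1] + 1e-12)) ? 1 : 0;
    for (int a = 1; a < m + n_extra; ++a) {
      const bool is_obs = a < m;
      const double hi = is_obs ? tt[a] : (rdied ? tdeath(r) : censor(r));
      const int wt = is_obs ? 1 : (rdied ? 2 : 3);
      const int ob = is_obs ? ss[a] - 1 : -1;
      double lo = prev;
      if (annual_split) {
        double b = std::ceil(age0 + lo + 1e-9) - age0;
        while (b < hi - 1e-9) {
          Step st; st.dt = b - lo; st.agec = age0 + lo - 60.0;
          st.wtype = 0; st.obs = -1;
          steps.push_back(st);
          lo = b; b += 1.0;
        }
      }
      Step st; st.dt = hi - lo; st.agec = age0 + lo - 60.0;
      st.wtype = wt; st.obs = ob;
      steps.push_back(st);
      prev = hi;
    }
    const int J = steps.size();

    // forward pass with per-step scaling
    Ps.assign(J, M5());
    alphas.assign(J + 1, V5());
    cs.assign(J, 0.0);
    fastf.assign(J, true);
    V5 alpha; alpha.zeros();
    if (init_emission) {
      for (int i = 0; i < NL; ++i) alpha(i) = initp(i) * E5(i, ss[0] - 1);
    } else {
      alpha(ss[0] - 1) = 1.0;
    }
    const double c0 = accu(alpha);
    if (!(c0 > 0.0)) { ll_rec(r) = -datum::inf; continue; }
    double ll = std::log(c0);
    alpha /= c0;
    alphas[0] = alpha;

    bool impossible = false;
    M5 A, P;
    for (int j = 0; j < J; ++j) {
      const Step& st = steps[j];
      const double sp = mult_prog(r) * std::exp(lamp * st.agec);
      const double sd = mult_death(r) * std::exp(lamd * st.agec);
      A.zeros();
      for (int i = 0; i < 4; ++i) A(i, i + 1) = q_prog(i) * sp;
      for (int i = 0; i < NL; ++i)
        A(i, i) = -((i < 4 ? q_prog(i) * sp : 0.0) + q_death(i) * sd);
      A *= st.dt;
      const bool fast = gaps_ok5(A);
      fastf[j] = fast;
      expm5(A, P, fast);
      Ps[j] = P;
      V5 v = P.t() * alpha;
      if (st.wtype == 1) {
        for (int i = 0; i < NL; ++i) v(i) *= E5(i, st.obs);
      } else if (st.wtype == 2) {
        for (int i = 0; i < NL; ++i) v(i) *= q_death(i) * sd;
      }
      const double c = accu(v);
      if (!(c > 0.0)) { impossible = true; break; }
      cs[j] = c;
      ll += std::log(c);
      alpha = v / c;
      alphas[j + 1] = alpha;
    }
    if (impossible) { ll_rec(r) = -datum::inf; continue; }
    ll_rec(r) = ll;

    if (!want_grad) continue;

    // backward pass: bhat_J = 1; bhat_{j-1} = P_j (w_j o bhat_j) / c_j
    V5 bhat; bhat.ones();
    M5 G, K;
    for (int j = J - 1; j >= 0; --j) {
      const Step& st = steps[j];
      const double sp = mult_prog(r) * std::exp(lamp * st.agec);
      const double sd = mult_death(r) * std::exp(lamd * st.agec);
      V5 w; w.ones();
      if (st.wtype == 1) {
        for (int i = 0; i < NL; ++i) w(i) = E5(i, st.obs);
      } else if (st.wtype == 2) {
        for (int i = 0; i < NL; ++i) w(i) = q_death(i) * sd;
      }
      const V5 wb = w % bhat;
      if (st.wtype == 1 || st.wtype == 2) {
        const V5 Pta = Ps[j].t() * alphas[j];
        const V5 wgrad = (Pta % bhat) / cs[j];
        if (st.wtype == 1) {
          for (int i = 0; i < NL; ++i) gE(i, st.obs) += wgrad(i);
        } else {
          double tot = 0.0;
          for (int i = 0; i < NL; ++i) {
            const double c = wgrad(i) * q_death(i) * sd;  // d ll/d log qdeath_i
            gqd(i) += c; tot += c;
          }
          gd_rec(r) += tot;
          g_amd += st.agec * tot;
        }
      }
      // d ll / d P_j = alpha_{j-1} (w o bhat_j)^T / c_j, then adjoint to A_j
      A.zeros();
      for (int i = 0; i < 4; ++i) A(i, i + 1) = q_prog(i) * sp;
      for (int i = 0; i < NL; ++i)
        A(i, i) = -((i < 4 ? q_prog(i) * sp : 0.0) + q_death(i) * sd);
      A *= st.dt;
      double Kdiag[NL], Ksup[4];
      if (fastf[j]) {
        const V5 a = alphas[j] / cs[j];
        frechet_adjoint5_rank1(A, Ps[j], a, wb, Kdiag, Ksup);
      } else {
        G = (alphas[j] / cs[j]) * wb.t();
        frechet_adjoint5(A, G, K, false);
        for (int i = 0; i < NL; ++i) Kdiag[i] = K(i, i);
        for (int i = 0; i < 4; ++i) Ksup[i] = K(i, i + 1);
      }
      // scale by dt: d ll / d Q entries of this step
      double totp = 0.0, totd = 0.0;
      for (int i = 0; i < 4; ++i) {
        const double cq = q_prog(i) * sp * (Ksup[i] - Kdiag[i]) * st.dt;
        gqp(i) += cq; totp += cq;
      }
      for (int i = 0; i < NL; ++i) {
        const double cq = q_death(i) * sd * (-Kdiag[i]) * st.dt;
        gqd(i) += cq; totd += cq;
      }
      gp_rec(r) += totp; gd_rec(r) += totd;
      g_amp += st.agec * totp; g_amd += st.agec * totd;
      bhat = (Ps[j] * wb) / cs[j];
    }
    if (init_emission) {
      for (int i = 0; i < NL; ++i) {
        gE(i, ss[0] - 1) += initp(i) * bhat(i) / c0;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("loglik") = accu(ll_rec),
    Rcpp::Named("ll_rec") = ll_rec,
    Rcpp::Named("gqp") = gqp,
    Rcpp::Named("gqd") = gqd,
    Rcpp::Named("g_am_prog") = g_amp,
    Rcpp::Named("g_am_death") = g_amd,
    Rcpp::Named("gp_rec") = gp_rec,
    Rcpp::Named("gd_rec") = gd_rec,
    Rcpp::Named("gE") = gE);
}
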