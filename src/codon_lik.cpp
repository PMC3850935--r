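// Felsenstein pruning over the 61 sense-codon states under the GY94 model.
// Per-site, per-class likelihoods are returned; mixing over site classes and
// taking logs happens on the R side so the same kernel serves M0, the
// discrete/beta site models and branch-site model A.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat gy94_unscaled(const imat& pairs, const vec& pi, double kappa,
                         double omega) {
  mat Q(61, 61, fill::zeros);
  for (uword r = 0; r < pairs.n_rows; ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    double rate = (pairs(r, 2) == 1 ? kappa : 1.0) *
                  (pairs(r, 3) == 1 ? 1.0 : omega);
    Q(i, j) = rate * pi(j);
    Q(j, i) = rate * pi(i);
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

struct Spectral {
  mat U;     // D^{-1/2} V
  mat Uinv;  // V' D^{1/2}
  vec ev;
};

static Spectral decompose(const mat& Q, const vec& pi) {
  vec sp = sqrt(pi);
  mat B = Q;
  B.each_col() %= sp;
  B.each_row() /= sp.t();
  B = 0.5 * (B + B.t());
  vec ev;
  mat V;
  eig_sym(ev, V, B);
  Spectral s;
  s.U = V;
  s.U.each_col() /= sp;
  s.Uinv = V.t();
  s.Uinv.each_row() %= sp.t();
  s.ev = ev;
  return s;
}

static mat probmat(const Spectral& s, double t) {
  if (t == 0.0) return eye(61, 61);
  mat P = s.U * diagmat(exp(s.ev * t)) * s.Uinv;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// [[Rcpp::export]]
arma::mat codon_site_lik_cpp(const arma::imat& tips, const arma::imat& edge,
                             const arma::vec& elen, int nnode, int root,
                             const arma::vec& pi, double kappa,
                             const arma::vec& omegas,
                             const arma::imat& omega_idx, double normfactor,
                             const arma::imat& pairs) {
  const uword ntax = tips.n_rows, npat = tips.n_cols;
  const uword nedge = edge.n_rows, K = omega_idx.n_rows;
  const uword nom = omegas.n_elem;

  std::vector<Spectral> spec(nom);
  for (uword w = 0; w < nom; ++w)
    spec[w] = decompose(gy94_unscaled(pairs, pi, kappa, omegas(w)), pi);

  // lazily filled transition-matrix cache keyed by (omega index, edge)
  std::vector<mat> pcache(nom * nedge);
  std::vector<bool> have(nom * nedge, false);

  mat out(npat, K);
  cube part(61, npat, nnode);
  for (uword k = 0; k < K; ++k) {
    part.ones();
    for (uword t = 0; t < ntax; ++t) {
      part.slice(t).zeros();
      for (uword s = 0; s < npat; ++s) {
        int st = tips(t, s);
        if (st == 0)
          part.slice(t).col(s).ones();
        else
          part.slice(t)(st - 1, s) = 1.0;
      }
    }
    for (uword e = 0; e < nedge; ++e) {
      uword w = omega_idx(k, e) - 1;
      uword key = w * nedge + e;
      if (!have[key]) {
        pcache[key] = probmat(spec[w], elen(e) / normfactor);
        have[key] = true;
      }
      int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      part.slice(p) %= pcache[key] * part.slice(c);
    }
    out.col(k) = (pi.t() * part.slice(root - 1)).t();
  }
  return out;
}
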