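// GY94 codon-model kernels: transition probabilities via symmetric
// eigendecomposition of the reversible rate matrix, and log-likelihoods for
// pairwise and unrooted 3-taxon star topologies (pruning over the single
// internal node).  Codon states are the 61 sense codons; indices are 0-based
// on the C++ side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Gy94Decomp {
  arma::vec eval;   // eigenvalues of the symmetrized, scaled rate matrix
  arma::mat evec;   // eigenvectors (columns)
  arma::vec sqpi;   // sqrt(pi), for (de)symmetrization
};

// Build the scaled GY94 rate matrix and eigendecompose its symmetrization.
// edges give the single-nucleotide sense-codon pairs (i -> j); ts = 1 for
// transitions, syn = 1 for synonymous changes.  Matrix is scaled so that
// -sum_i pi_i q_ii = 1, i.e. branch length t is expected substitutions per
// codon.
Gy94Decomp gy94_decompose(double kappa, double omega, const arma::vec& pi,
                          const arma::uvec& ei, const arma::uvec& ej,
                          const arma::uvec& ts, const arma::uvec& syn) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword k = 0; k < ei.n_elem; ++k) {
    double r = pi(ej(k));
    if (ts(k)) r *= kappa;
    if (!syn(k)) r *= omega;
    Q(ei(k), ej(k)) = r;
  }
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() -= rs;
  double scale = arma::dot(pi, rs);
  if (scale <= 0.0) scale = 1.0;
  Q /= scale;

  Gy94Decomp d;
  d.sqpi = arma::sqrt(pi);
  arma::mat S = Q;
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      S(i, j) *= d.sqpi(i) / d.sqpi(j);
  S = 0.5 * (S + S.t());  // exact up to round-off for a reversible Q
  arma::eig_sym(d.eval, d.evec, S);
  return d;
}

arma::mat pmat_from_decomp(const Gy94Decomp& d, double t) {
  arma::mat P = d.evec * arma::diagmat(arma::exp(d.eval * t)) * d.evec.t();
  const arma::uword n = d.sqpi.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j) {
      double v = P(i, j) * d.sqpi(j) / d.sqpi(i);
      P(i, j) = (v < 1e-300) ? 1e-300 : v;
    }
  return P;
}

// Small cache of decompositions keyed by (kappa, omega).  The optimizer's
// finite-difference gradients re-evaluate the likelihood at unchanged
// (kappa, omega) for every branch-length perturbation, so hit rates are
// high.  pi and the edge structure are fixed within one optimization; the
// cache is invalidated when pi changes.
struct DecompCache {
  double pi_tag = -1.0;
  std::vector<std::pair<std::pair<double, double>, Gy94Decomp>> entries;

  Gy94Decomp get(double kappa, double omega, const arma::vec& pi,
                        const arma::uvec& ei, const arma::uvec& ej,
                        const arma::uvec& ts, const arma::uvec& syn) {
    double tag = arma::dot(pi, arma::linspace(1.0, 2.0, pi.n_elem));
    if (tag != pi_tag) { entries.clear(); pi_tag = tag; }
    for (auto& e : entries)
      if (e.first.first == kappa && e.first.second == omega) return e.second;
    if (entries.size() >= 16) entries.erase(entries.begin());
    entries.emplace_back(std::make_pair(kappa, omega),
                         gy94_decompose(kappa, omega, pi, ei, ej, ts, syn));
    return entries.back().second;
  }
};

static DecompCache g_cache;

}  // namespace

// [[Rcpp::export(name = ".gy94_pmat_cpp")]]
arma::mat gy94_pmat_cpp(double t, double kappa, double omega,
                        const arma::vec& pi, const arma::uvec& ei,
                        const arma::uvec& ej, const arma::uvec& ts,
                        const arma::uvec& syn) {
  return pmat_from_decomp(gy94_decompose(kappa, omega, pi, ei, ej, ts, syn), t);
}

// Negative log-likelihood of a pairwise alignment summarized as site
// patterns: codon index vectors ia, ib (0-based) with counts w.
// L_site = pi_{ia} * P(ia -> ib, t).
// [[Rcpp::export(name = ".gy94_pair_nll_cpp")]]
double gy94_pair_nll_cpp(double t, double kappa, double omega,
                         const arma::vec& pi, const arma::uvec& ei,
                         const arma::uvec& ej, const arma::uvec& ts,
                         const arma::uvec& syn, const arma::uvec& ia,
                         const arma::uvec& ib, const arma::vec& w) {
  Gy94Decomp d = g_cache.get(kappa, omega, pi, ei, ej, ts, syn);
  arma::mat P = pmat_from_decomp(d, t);
  double nll = 0.0;
  for (arma::uword k = 0; k < ia.n_elem; ++k) {
    double L = pi(ia(k)) * P(ia(k), ib(k));
    if (L < 1e-300) L = 1e-300;
    nll -= w(k) * std::log(L);
  }
  return nll;
}

// Negative log-likelihood of a 3-taxon star: branches 1..3 with lengths
// t1..t3; branch `focal` (1-based; 0 = none) evolves with omega_focal, the
// others with omega_bg.  L_site = sum_k pi_k P1(k,x1) P2(k,x2) P3(k,x3).
// [[Rcpp::export(name = ".gy94_trio_nll_cpp")]]
double gy94_trio_nll_cpp(double t1, double t2, double t3, double kappa,
                         double omega_bg, double omega_focal, int focal,
                         const arma::vec& pi, const arma::uvec& ei,
                         const arma::uvec& ej, const arma::uvec& ts,
                         const arma::uvec& syn, const arma::uvec& i1,
                         const arma::uvec& i2, const arma::uvec& i3,
                         const arma::vec& w) {
  Gy94Decomp bg = g_cache.get(kappa, omega_bg, pi, ei, ej, ts, syn);
  arma::mat P1, P2, P3;
  if (focal >= 1 && focal <= 3 && omega_focal != omega_bg) {
    Gy94Decomp fc = g_cache.get(kappa, omega_focal, pi, ei, ej, ts, syn);
    P1 = pmat_from_decomp(focal == 1 ? fc : bg, t1);
    P2 = pmat_from_decomp(focal == 2 ? fc : bg, t2);
    P3 = pmat_from_decomp(focal == 3 ? fc : bg, t3);
  } else {
    P1 = pmat_from_decomp(bg, t1);
    P2 = pmat_from_decomp(bg, t2);
    P3 = pmat_from_decomp(bg, t3);
  }
  const arma::uword npat = i1.n_elem;
  double nll = 0.0;
  for (arma::uword k = 0; k < npat; ++k) {
    double L = arma::dot(pi, P1.col(i1(k)) % P2.col(i2(k)) % P3.col(i3(k)));
    if (L < 1e-300) L = 1e-300;
    nll -= w(k) * std::log(L);
  }
  return nll;
}
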