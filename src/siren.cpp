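// Compiled core of the SIREN displacement network: forward-mode evaluation of
// the field and its first/second spatial derivatives, and the reverse pass
// that accumulates weight gradients of losses depending on u, grad u and
// hess u. Mirrors the pure-R reference implementation (.net_forward_r /
// .net_backward_r) exactly; the pair order of second derivatives is
// (11, 22, 33, 23, 13, 12). The forward cache lives on the C++ side and is
// handed back to R as an external pointer to avoid copying per step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int PAIR_A[6] = {0, 1, 2, 1, 0, 0};
static const int PAIR_B[6] = {0, 1, 2, 2, 2, 1};

static arma::mat as_arma(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false);
}

struct SirenCache {
  int L = 0;
  int deriv = 0;
  double w0 = 0.0;
  arma::mat Z;
  arma::mat Wo;
  std::vector<arma::mat> W;      // hidden weights
  std::vector<arma::mat> H, C;   // sin / cos activations
  std::vector<std::array<arma::mat, 3>> P, G;
  std::vector<std::array<arma::mat, 6>> Q, S;
};

// [[Rcpp::export(name = ".siren_forward_cpp")]]
List siren_forward_cpp(List Ws, List bs, NumericMatrix Wo_, NumericVector bo_,
                       NumericMatrix Z_, double w0, int deriv,
                       bool want_cache) {
  const int L = Ws.size();
  XPtr<SirenCache> cp(new SirenCache(), true);
  SirenCache& cc = *cp;
  cc.L = L;
  cc.deriv = deriv;
  cc.w0 = w0;
  cc.Z = as_arma(Z_);
  cc.Wo = as_arma(Wo_);
  arma::rowvec bo(bo_.begin(), bo_.size());
  const arma::uword N = cc.Z.n_rows;

  cc.W.resize(L);
  cc.H.resize(L);
  cc.C.resize(L);
  cc.P.resize(L);
  cc.G.resize(L);
  cc.Q.resize(L);
  cc.S.resize(L);

  const arma::mat* IN = &cc.Z;
  for (int l = 0; l < L; ++l) {
    NumericMatrix Wl_ = Ws[l];
    NumericVector bl_ = bs[l];
    cc.W[l] = as_arma(Wl_);
    const arma::mat& W = cc.W[l];
    arma::rowvec b(bl_.begin(), bl_.size());
    arma::mat A = (*IN) * W.t();
    A.each_row() += b;
    cc.H[l] = arma::sin(w0 * A);
    cc.C[l] = arma::cos(w0 * A);
    if (deriv >= 1) {
      arma::mat wC = w0 * cc.C[l];
      for (int j = 0; j < 3; ++j) {
        if (l == 0) {
          cc.P[l][j].set_size(N, W.n_rows);
          cc.P[l][j].each_row() = W.col(j).t();
        } else {
          cc.P[l][j] = cc.G[l - 1][j] * W.t();
        }
        cc.G[l][j] = wC % cc.P[l][j];
      }
    }
    if (deriv >= 2) {
      arma::mat mw2H = (-w0 * w0) * cc.H[l];
      arma::mat wC = w0 * cc.C[l];
      for (int pr = 0; pr < 6; ++pr) {
        if (l == 0) {
          cc.Q[l][pr].zeros(N, cc.H[l].n_cols);
        } else {
          cc.Q[l][pr] = cc.S[l - 1][pr] * W.t();
        }
        cc.S[l][pr] = mw2H % cc.P[l][PAIR_A[pr]] % cc.P[l][PAIR_B[pr]] +
          wC % cc.Q[l][pr];
      }
    }
    IN = &cc.H[l];
  }

  arma::mat U = cc.H[L - 1] * cc.Wo.t();
  U.each_row() += bo;

  List Gout(3), Sout(6);
  if (deriv >= 1) {
    for (int j = 0; j < 3; ++j)
      Gout[j] = wrap(arma::mat(cc.G[L - 1][j] * cc.Wo.t()));
  }
  if (deriv >= 2) {
    for (int pr = 0; pr < 6; ++pr)
      Sout[pr] = wrap(arma::mat(cc.S[L - 1][pr] * cc.Wo.t()));
  }
  List out = List::create(_["U"] = wrap(U), _["Gout"] = Gout,
                          _["Sout"] = Sout, _["deriv"] = deriv);
  if (want_cache) out["cache"] = cp;
  return out;
}

// [[Rcpp::export(name = ".siren_backward_cpp")]]
List siren_backward_cpp(SEXP cache_, NumericMatrix ubar_,
                        Nullable<List> Goutbar_, Nullable<List> Soutbar_) {
  XPtr<SirenCache> cp(cache_);
  const SirenCache& cc = *cp;
  const int L = cc.L;
  const double w0 = cc.w0;
  const int deriv = cc.deriv;
  arma::mat ubar = as_arma(ubar_);
  const arma::uword N = cc.Z.n_rows;

  const bool use_g = Goutbar_.isNotNull();
  const bool use_s = Soutbar_.isNotNull();
  const bool has_g = use_g || use_s;
  if ((use_g && deriv < 1) || (use_s && deriv < 2))
    stop("cache lacks derivative state for the requested adjoints");

  arma::mat Wo_bar = ubar.t() * cc.H[L - 1];
  arma::rowvec bo_bar = arma::sum(ubar, 0);

  std::array<arma::mat, 3> Gbar;
  std::array<arma::mat, 6> Sbar;
  if (use_g) {
    List Gb(Goutbar_.get());
    for (int j = 0; j < 3; ++j) {
      arma::mat gb = as_arma((NumericMatrix)Gb[j]);
      Wo_bar += gb.t() * cc.G[L - 1][j];
      Gbar[j] = gb * cc.Wo;
    }
  } else if (has_g) {
    for (int j = 0; j < 3; ++j) Gbar[j].zeros(N, cc.Wo.n_cols);
  }
  if (use_s) {
    List Sb(Soutbar_.get());
    for (int pr = 0; pr < 6; ++pr) {
      arma::mat sb = as_arma((NumericMatrix)Sb[pr]);
      Wo_bar += sb.t() * cc.S[L - 1][pr];
      Sbar[pr] = sb * cc.Wo;
    }
  }
  arma::mat Hbar = ubar * cc.Wo;

  List W_bar(L), b_bar(L);
  arma::mat Zbar;
  for (int l = L - 1; l >= 0; --l) {
    const arma::mat& H = cc.H[l];
    const arma::mat& W = cc.W[l];
    arma::mat wC = w0 * cc.C[l];
    arma::mat Cbar(N, H.n_cols, arma::fill::zeros);

    std::array<arma::mat, 3> Pbar;
    std::array<arma::mat, 6> Qbar;
    if (has_g) {
      for (int j = 0; j < 3; ++j) Pbar[j] = wC % Gbar[j];
    }
    if (use_s) {
      arma::mat mw2H = (-w0 * w0) * H;
      for (int pr = 0; pr < 6; ++pr) {
        const arma::mat& sb = Sbar[pr];
        Qbar[pr] = wC % sb;
        arma::mat term = mw2H % sb;
        Pbar[PAIR_A[pr]] += term % cc.P[l][PAIR_B[pr]];
        Pbar[PAIR_B[pr]] += term % cc.P[l][PAIR_A[pr]];
        Hbar += sb % ((-w0 * w0) * (cc.P[l][PAIR_A[pr]] % cc.P[l][PAIR_B[pr]]));
        Cbar += sb % (w0 * cc.Q[l][pr]);
      }
    }
    if (has_g) {
      for (int j = 0; j < 3; ++j) Cbar += Gbar[j] % (w0 * cc.P[l][j]);
    }
    arma::mat Abar = Hbar % wC - Cbar % (w0 * H);

    const arma::mat& INl = (l == 0) ? cc.Z : cc.H[l - 1];
    arma::mat Wb = Abar.t() * INl;
    if (has_g) {
      if (l == 0) {
        for (int j = 0; j < 3; ++j) Wb.col(j) += arma::sum(Pbar[j], 0).t();
      } else {
        for (int j = 0; j < 3; ++j) Wb += Pbar[j].t() * cc.G[l - 1][j];
      }
    }
    if (use_s && l > 0) {
      for (int pr = 0; pr < 6; ++pr) Wb += Qbar[pr].t() * cc.S[l - 1][pr];
    }
    W_bar[l] = wrap(Wb);
    b_bar[l] = wrap(arma::rowvec(arma::sum(Abar, 0)));

    if (l > 0) {
      Hbar = Abar * W;
      if (has_g) for (int j = 0; j < 3; ++j) Gbar[j] = Pbar[j] * W;
      if (use_s) for (int pr = 0; pr < 6; ++pr) Sbar[pr] = Qbar[pr] * W;
    } else {
      Zbar = Abar * W;
    }
  }
  return List::create(_["W_bar"] = W_bar, _["b_bar"] = b_bar,
                      _["Wo_bar"] = wrap(Wo_bar), _["bo_bar"] = wrap(bo_bar),
                      _["Zbar"] = wrap(Zbar));
}
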