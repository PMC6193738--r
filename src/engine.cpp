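// Compiled inner loop of the dual reservoir-computing system: millisecond
// Euler-Maruyama integration of both rate reservoirs, trailing-window output
// normalization, mutual teaching signals, and recursive-least-squares (FORCE)
// readout updates. All randomness comes from R's RNG stream so runs are
// reproducible with set.seed().
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

namespace {

struct Normalizer {
  arma::mat buf;     // win x K ring buffer of raw outputs
  arma::rowvec sum, sumsq;
  int count, pos, win;
  double eps;

  arma::rowvec push(const arma::rowvec& z) {
    if (count == win) {
      arma::rowvec old = buf.row(pos);
      sum += z - old;
      sumsq += z % z - old % old;
    } else {
      sum += z;
      sumsq += z % z;
      ++count;
    }
    buf.row(pos) = z;
    pos = (pos + 1) % win;
    arma::rowvec mu = sum / count;
    arma::rowvec v = sumsq / count - mu % mu;
    arma::rowvec sd = arma::sqrt(arma::clamp(v, 0.0, arma::datum::inf));
    sd = arma::clamp(sd, eps, arma::datum::inf);
    return (z - mu) / sd;
  }
};

struct RCModule {
  arma::mat J, J_fb, J_in, w, P;
  arma::uvec sub;          // 0-based readout subset
  arma::vec x, r, y;       // y: interneuron low-pass of own zhat
  arma::rowvec z_prev;
  Normalizer norm;
};

RCModule unpack(List m, int norm_win, double eps) {
  RCModule mod;
  mod.J = as<arma::mat>(m["J"]);
  mod.J_fb = as<arma::mat>(m["J_fb"]);
  mod.J_in = as<arma::mat>(m["J_in"]);
  mod.w = as<arma::mat>(m["w"]);
  mod.P = as<arma::mat>(m["P"]);
  mod.sub = as<arma::uvec>(m["subset"]) - 1;
  mod.x = as<arma::vec>(m["x"]);
  mod.r = arma::tanh(mod.x);
  int K = mod.w.n_cols;
  mod.y = as<arma::vec>(m["y"]);
  mod.z_prev = as<arma::rowvec>(m["z_prev"]);
  mod.norm.win = norm_win;
  mod.norm.eps = eps;
  mod.norm.buf = as<arma::mat>(m["nbuf"]);
  mod.norm.sum = as<arma::rowvec>(m["nsum"]);
  mod.norm.sumsq = as<arma::rowvec>(m["nsumsq"]);
  mod.norm.count = as<int>(m["ncount"]);
  mod.norm.pos = as<int>(m["npos"]);
  if ((int)mod.norm.buf.n_rows != norm_win || (int)mod.norm.buf.n_cols != K)
    stop("normalizer buffer shape mismatch");
  return mod;
}

List pack(const RCModule& mod) {
  return List::create(
    _["w"] = mod.w, _["P"] = mod.P, _["x"] = mod.x,
    _["y"] = mod.y, _["z_prev"] = mod.z_prev,
    _["nbuf"] = mod.norm.buf, _["nsum"] = mod.norm.sum,
    _["nsumsq"] = mod.norm.sumsq, _["ncount"] = mod.norm.count,
    _["npos"] = mod.norm.pos);
}

// teaching signal for one module given the partner's normalized outputs (or
// their interneuron-filtered versions in `comp`)
arma::rowvec teaching(const arma::rowvec& zhat_partner, const arma::vec& comp,
                      double beta, double gamma) {
  int K = zhat_partner.n_elem;
  arma::rowvec f(K);
  if (K == 1) {
    f(0) = std::tanh(zhat_partner(0) / beta);
  } else {
    double total = arma::accu(comp);
    for (int k = 0; k < K; ++k)
      f(k) = std::tanh((zhat_partner(k) - gamma * (total - comp(k))) / beta);
  }
  return arma::clamp(f, 0.0, arma::datum::inf);
}

// P is kept symmetric but only its upper triangle is maintained inside a
// block (dsymv/dsyr); symmetrize() restores the full matrix before returning.
void rls(RCModule& mod, const arma::rowvec& e, arma::vec& k) {
  arma::vec rs = mod.r.elem(mod.sub);
  const int n = rs.n_elem, ione = 1;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dsymv)("U", &n, &one, mod.P.memptr(), &n, rs.memptr(), &ione,
                  &zero, k.memptr(), &ione FCONE);
  double c = 1.0 / (1.0 + arma::dot(rs, k));
  double mc = -c;
  F77_CALL(dsyr)("U", &n, &mc, k.memptr(), &ione, mod.P.memptr(), &n FCONE);
  // with P already updated, P r = c k, so dw_j = -e_j * c * k
  for (unsigned j = 0; j < mod.w.n_cols; ++j)
    mod.w.col(j) -= e(j) * c * k;
}

void symmetrize_upper(arma::mat& P) {
  for (arma::uword i = 1; i < P.n_rows; ++i)
    for (arma::uword j = 0; j < i; ++j)
      P(i, j) = P(j, i);
}

} // namespace

// [[Rcpp::export]]
List engine_run(List m1_in, List m2_in, const arma::mat& drive, List opts,
                SEXP cross12_in, SEXP cross21_in) {
  const double g = as<double>(opts["gain"]);
  const double tau = as<double>(opts["tau"]);
  const double sigma = as<double>(opts["sigma"]);
  const double dt = as<double>(opts["dt"]);
  const double beta = as<double>(opts["beta"]);
  const double gamma = as<double>(opts["gamma"]);
  const double tau_y = as<double>(opts["tau_y"]);
  const double eps = as<double>(opts["eps"]);
  const bool learn = as<bool>(opts["learn"]);
  const bool inter = as<bool>(opts["interneurons"]);
  const int rls_every = as<int>(opts["rls_every"]);
  const int norm_win = as<int>(opts["norm_win"]);
  const bool keep_rates = opts.containsElementNamed("keep_rates") &&
    as<bool>(opts["keep_rates"]);

  RCModule m1 = unpack(m1_in, norm_win, eps);
  RCModule m2 = unpack(m2_in, norm_win, eps);
  const bool coupled = !Rf_isNull(cross12_in);
  arma::mat cross12, cross21;
  if (coupled) {
    cross12 = as<arma::mat>(cross12_in);
    cross21 = as<arma::mat>(cross21_in);
  }

  const int T = drive.n_rows;
  const int K = m1.w.n_cols;
  const double a = dt / tau;
  const double ns = sigma * std::sqrt(dt / tau);
  const int N = m1.x.n_elem;

  arma::mat z1(T, K), z2(T, K), f1(T, K), f2(T, K);
  arma::mat r1store, r2store;
  if (keep_rates) {
    r1store.set_size(T, N);
    r2store.set_size(T, N);
  }
  arma::vec kbuf1(m1.P.n_rows), kbuf2(m2.P.n_rows);
  RNGScope scope;

  for (int t = 0; t < T; ++t) {
    arma::vec u = drive.row(t).t();
    arma::vec I1 = m1.J_in * u;
    arma::vec I2 = m2.J_in * u;
    if (coupled) {
      I1 += g * (cross12 * m2.r);
      I2 += g * (cross21 * m1.r);
    }
    arma::vec d1 = -m1.x + g * (m1.J * m1.r) + m1.J_fb * m1.z_prev.t() + I1;
    arma::vec d2 = -m2.x + g * (m2.J * m2.r) + m2.J_fb * m2.z_prev.t() + I2;
    if (sigma > 0) {
      m1.x += a * d1 + ns * as<arma::vec>(rnorm(N));
      m2.x += a * d2 + ns * as<arma::vec>(rnorm(N));
    } else {
      m1.x += a * d1;
      m2.x += a * d2;
    }
    m1.r = arma::tanh(m1.x);
    m2.r = arma::tanh(m2.x);
    if (keep_rates) {
      r1store.row(t) = m1.r.t();
      r2store.row(t) = m2.r.t();
    }

    arma::rowvec zz1 = (m1.w.t() * m1.r.elem(m1.sub)).t();
    arma::rowvec zz2 = (m2.w.t() * m2.r.elem(m2.sub)).t();
    arma::rowvec zh1 = m1.norm.push(zz1);
    arma::rowvec zh2 = m2.norm.push(zz2);

    // interneurons low-pass the module's own normalized outputs
    m1.y += (dt / tau_y) * (-m1.y + zh1.t());
    m2.y += (dt / tau_y) * (-m2.y + zh2.t());

    arma::rowvec ff1 = teaching(zh2, inter ? m2.y : arma::vec(zh2.t()), beta, gamma);
    arma::rowvec ff2 = teaching(zh1, inter ? m1.y : arma::vec(zh1.t()), beta, gamma);

    z1.row(t) = zz1; z2.row(t) = zz2;
    f1.row(t) = ff1; f2.row(t) = ff2;

    if (learn && ((t + 1) % rls_every == 0)) {
      rls(m1, zz1 - ff1, kbuf1);
      rls(m2, zz2 - ff2, kbuf2);
    }
    m1.z_prev = zz1;
    m2.z_prev = zz2;

    if ((t & 1023) == 0 && (!m1.x.is_finite() || !m2.x.is_finite()))
      stop("non-finite reservoir state at step %d", t);
  }
  symmetrize_upper(m1.P);
  symmetrize_upper(m2.P);
  if (!m1.x.is_finite() || !m2.x.is_finite() || !m1.w.is_finite() ||
      !m2.w.is_finite())
    stop("non-finite state after block");

  List out = List::create(_["m1"] = pack(m1), _["m2"] = pack(m2),
                          _["z1"] = z1, _["z2"] = z2,
                          _["f1"] = f1, _["f2"] = f2);
  if (keep_rates) {
    out["rates1"] = r1store;
    out["rates2"] = r2store;
  }
  return out;
}
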