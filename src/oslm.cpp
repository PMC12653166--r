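// Joint log posterior, analytic gradient and a No-U-Turn sampler for the
// LLTM / RWLLTM / OSLM / RWOSLM model family.
//
// Unconstrained parameter vector layout (offsets are built in R, 0-based,
// and passed in as part of the model list; C++ trusts them):
//   theta                     n
//   difficulty block:
//     fixed:  alpha           M
//     random: mu_e, ls_e      M, M          (ls = log sigma)
//             y_e             M(M-1)/2      (corr Cholesky, tanh transform)
//             z_e             n*M           (non-centred, column-major n x M)
//   delta_fixed               F
//   random practice block (R > 0):
//     mu_d, ls_d              R, R
//     y_d                     R(R-1)/2
//     z_d                     n*R
//
// Priors: theta ~ N(0,1); alpha, delta_fixed ~ N(0, var 100);
// mu ~ N(0,1); sigma ~ half-Cauchy(0,5); Omega ~ LKJ(2); z ~ N(0,1).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double FIXED_VAR = 100.0;  // N(0, 100), 100 = variance
static const double CAUCHY_SCALE = 5.0;
static const double LKJ_ETA = 2.0;

struct Model {
  mat X, mask;          // n x J
  mat W, V, Vf, Vr;     // J x M, J x M, J x F, J x R
  int n, J, M, F, R;
  bool diff_random;
  // offsets, 0-based
  int off_theta, off_alpha, off_mu_e, off_ls_e, off_y_e, off_z_e;
  int off_df, off_mu_d, off_ls_d, off_y_d, off_z_d;
  int P;
};

static Model make_model(const List& m) {
  Model md;
  md.X = Rcpp::as<mat>(m["X"]);
  md.mask = Rcpp::as<mat>(m["mask"]);
  md.W = Rcpp::as<mat>(m["W"]);
  md.V = Rcpp::as<mat>(m["V"]);
  md.Vf = Rcpp::as<mat>(m["Vf"]);
  md.Vr = Rcpp::as<mat>(m["Vr"]);
  md.n = Rcpp::as<int>(m["n"]);
  md.J = Rcpp::as<int>(m["J"]);
  md.M = Rcpp::as<int>(m["M"]);
  md.F = Rcpp::as<int>(m["F"]);
  md.R = Rcpp::as<int>(m["R"]);
  md.diff_random = Rcpp::as<bool>(m["diff_random"]);
  List off = m["offsets"];
  md.off_theta = off["theta"]; md.off_alpha = off["alpha"];
  md.off_mu_e = off["mu_e"]; md.off_ls_e = off["ls_e"];
  md.off_y_e = off["y_e"]; md.off_z_e = off["z_e"];
  md.off_df = off["df"]; md.off_mu_d = off["mu_d"];
  md.off_ls_d = off["ls_d"]; md.off_y_d = off["y_d"];
  md.off_z_d = off["z_d"];
  md.P = Rcpp::as<int>(m["P"]);
  return md;
}

// ---- correlation Cholesky transform ---------------------------------------
// y (K(K-1)/2) -> lower-triangular L with unit-norm rows; returns LKJ(eta)
// log density plus the log Jacobian of the transform; stores intermediates
// for the reverse pass.

struct CorrWork {
  int K;
  mat L;
  mat z, s;       // z(i,j), s(i,j) = sum of squares of L(i,0..j-1), j < i
  double logextra;
};

static void corr_forward(const vec& y, int K, CorrWork& cw) {
  cw.K = K;
  cw.L = eye<mat>(K, K);
  cw.z.zeros(K, K);
  cw.s.zeros(K, K);
  cw.logextra = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < i; ++j) {
      double zz = std::tanh(y(idx++));
      double w = std::sqrt(1.0 - s);
      cw.z(i, j) = zz;
      cw.s(i, j) = s;
      cw.L(i, j) = zz * w;
      // log|J|: tanh term + dL_ij/dz_ij = sqrt(1-s)
      cw.logextra += std::log1p(-zz * zz) + 0.5 * std::log1p(-s);
      s += cw.L(i, j) * cw.L(i, j);
    }
    cw.L(i, i) = std::sqrt(std::max(1.0 - s, 1e-300));
    // LKJ(eta) density on the Cholesky factor (1-based row i+1):
    // coefficient K - (i+1) + 2*eta - 2
    cw.logextra += (K - (i + 1) + 2.0 * LKJ_ETA - 2.0) * std::log(cw.L(i, i));
  }
}

// dL_in: df/dL from the likelihood (lower incl. diagonal). Writes df/dy.
static void corr_backward(const CorrWork& cw, const mat& dL_in, vec& dy) {
  int K = cw.K;
  int idx = (K * (K - 1)) / 2;
  for (int i = K - 1; i >= 1; --i) {
    // seed with diagonal: L_ii = sqrt(1 - s_i); density term added here
    double coef = K - (i + 1) + 2.0 * LKJ_ETA - 2.0;
    double dLii = dL_in(i, i) + coef / cw.L(i, i);
    double ds = dLii * (-0.5 / cw.L(i, i));
    for (int j = i - 1; j >= 0; --j) {
      double zz = cw.z(i, j), s = cw.s(i, j);
      double w = std::sqrt(1.0 - s);
      double Lij = cw.L(i, j);
      // s_{j+1} = s_j + Lij^2
      double dL = dL_in(i, j) + ds * 2.0 * Lij;
      double dz = dL * w - 2.0 * zz / (1.0 - zz * zz);     // + jacobian d/dz
      double ds_j = ds + dL * zz * (-0.5 / w) - 0.5 / (1.0 - s); // + jacobian d/ds
      --idx;
      dy(idx) += dz * (1.0 - zz * zz);
      ds = ds_j;
    }
  }
}

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

// ---- random-effect block --------------------------------------------------

struct BlockWork {
  vec mu, sig;
  mat Z;        // n x K
  mat D;        // n x K realized effects: mu + sig o (L z)
  CorrWork cw;
};

static void block_forward(const Model& md, const vec& q, int off_mu, int off_ls,
                          int off_y, int off_z, int K, BlockWork& bw,
                          double& lp) {
  bw.mu = q.subvec(off_mu, off_mu + K - 1);
  vec ls = q.subvec(off_ls, off_ls + K - 1);
  bw.sig = exp(ls);
  int ny = (K * (K - 1)) / 2;
  vec y = ny > 0 ? q.subvec(off_y, off_y + ny - 1) : vec();
  corr_forward(y, K, bw.cw);
  bw.Z = md.n > 0 ? mat(&q[off_z], md.n, K) : mat(0, K);
  mat T = bw.Z * bw.cw.L.t();            // n x K, (L z_i)_k
  bw.D = T.each_row() % bw.sig.t();
  bw.D.each_row() += bw.mu.t();
  // priors
  lp += -0.5 * dot(bw.mu, bw.mu);
  for (int k = 0; k < K; ++k) {
    double s = bw.sig(k);
    lp += -std::log1p((s / CAUCHY_SCALE) * (s / CAUCHY_SCALE)) + ls(k);
  }
  lp += bw.cw.logextra;
  lp += -0.5 * accu(bw.Z % bw.Z);
}

// G: n x K likelihood gradient wrt the realized effect d_ik.
static void block_backward(const Model& md, const BlockWork& bw, const mat& G,
                           int off_mu, int off_ls, int off_y, int off_z, int K,
                           vec& grad) {
  // mu
  for (int k = 0; k < K; ++k)
    grad(off_mu + k) += accu(G.col(k)) - bw.mu(k);
  // sigma (via log sigma) ; T = Z L'
  mat T = bw.Z * bw.cw.L.t();
  for (int k = 0; k < K; ++k) {
    double dsig = dot(G.col(k), T.col(k));
    double s = bw.sig(k);
    grad(off_ls + k) += s * dsig - 2.0 * s * s / (CAUCHY_SCALE * CAUCHY_SCALE + s * s) + 1.0;
  }
  // correlation Cholesky
  if (K > 1) {
    mat Gs = G.each_row() % bw.sig.t();   // n x K
    mat dL = Gs.t() * bw.Z;               // K x K ; dL(r,s) = sum_i sig_r g_ir z_is
    dL = trimatl(dL);
    vec dy(((K * (K - 1)) / 2), fill::zeros);
    corr_backward(bw.cw, dL, dy);
    int ny = dy.n_elem;
    for (int t = 0; t < ny; ++t) grad(off_y + t) += dy(t);
    // z
    mat dZ = Gs * bw.cw.L - bw.Z;         // (Gs L)_is = sum_r g_ir sig_r L_rs
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < md.n; ++i)
        grad(off_z + k * md.n + i) += dZ(i, k);
  } else {
    mat dZ = (G.each_row() % bw.sig.t()) - bw.Z;
    for (int i = 0; i < md.n; ++i) grad(off_z + i) += dZ(i, 0);
  }
}

// ---- joint log posterior + gradient ---------------------------------------

static double logpost_grad(const Model& md, const vec& q, vec& grad,
                           double& loglik_out) {
  grad.zeros(md.P);
  double lp = 0.0;
  int n = md.n, J = md.J;

  vec theta = n > 0 ? q.subvec(md.off_theta, md.off_theta + n - 1) : vec();
  lp += -0.5 * dot(theta, theta);

  vec alpha;
  BlockWork be, bd;
  vec cfix(J, fill::zeros);
  if (md.diff_random) {
    block_forward(md, q, md.off_mu_e, md.off_ls_e, md.off_y_e, md.off_z_e,
                  md.M, be, lp);
  } else {
    alpha = q.subvec(md.off_alpha, md.off_alpha + md.M - 1);
    lp += -dot(alpha, alpha) / (2.0 * FIXED_VAR);
    cfix -= md.W * alpha;
  }
  vec df;
  if (md.F > 0) {
    df = q.subvec(md.off_df, md.off_df + md.F - 1);
    lp += -dot(df, df) / (2.0 * FIXED_VAR);
    cfix += md.Vf * df;
  }
  if (md.R > 0) {
    block_forward(md, q, md.off_mu_d, md.off_ls_d, md.off_y_d, md.off_z_d,
                  md.R, bd, lp);
  }

  double ll = 0.0;
  mat E;
  if (n > 0) {
    mat Lg = repmat(theta, 1, J);
    Lg.each_row() += cfix.t();
    if (md.diff_random) Lg -= be.D * md.W.t();
    if (md.R > 0) Lg += bd.D * md.Vr.t();
    // one exp + one log1p per cell: p = sigmoid(l) and
    // softplus(l) = max(l, 0) + log1p(exp(-|l|)) share exp(-|l|)
    mat P1(n, J);
    const double* lg = Lg.memptr();
    const double* x = md.X.memptr();
    const double* mk = md.mask.memptr();
    double* pp = P1.memptr();
    const int NJ = n * J;
    for (int t = 0; t < NJ; ++t) {
      double l = lg[t];
      double e = std::exp(-std::abs(l));
      pp[t] = (l >= 0.0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
      if (mk[t] != 0.0)
        ll += x[t] * l - (std::max(l, 0.0) + std::log1p(e));
    }
    E = md.mask % (md.X - P1);
    // gradients
    vec e_person = sum(E, 1);             // n
    vec e_item = sum(E, 0).t();           // J
    for (int i = 0; i < n; ++i)
      grad(md.off_theta + i) += e_person(i) - theta(i);
    if (md.diff_random) {
      mat Ge = -(E * md.W);               // n x M
      block_backward(md, be, Ge, md.off_mu_e, md.off_ls_e, md.off_y_e,
                     md.off_z_e, md.M, grad);
    } else {
      vec da = -(md.W.t() * e_item) - alpha / FIXED_VAR;
      for (int m = 0; m < md.M; ++m) grad(md.off_alpha + m) += da(m);
    }
    if (md.F > 0) {
      vec dd = md.Vf.t() * e_item - df / FIXED_VAR;
      for (int f = 0; f < md.F; ++f) grad(md.off_df + f) += dd(f);
    }
    if (md.R > 0) {
      mat Gd = E * md.Vr;                 // n x R
      block_backward(md, bd, Gd, md.off_mu_d, md.off_ls_d, md.off_y_d,
                     md.off_z_d, md.R, grad);
    }
  } else {
    // prior-only: gradients of prior terms for active global blocks
    if (md.diff_random) {
      mat Ge(0, md.M);
      block_backward(md, be, Ge, md.off_mu_e, md.off_ls_e, md.off_y_e,
                     md.off_z_e, md.M, grad);
    } else {
      for (int m = 0; m < md.M; ++m)
        grad(md.off_alpha + m) += -alpha(m) / FIXED_VAR;
    }
    if (md.F > 0)
      for (int f = 0; f < md.F; ++f)
        grad(md.off_df + f) += -df(f) / FIXED_VAR;
    if (md.R > 0) {
      mat Gd(0, md.R);
      block_backward(md, bd, Gd, md.off_mu_d, md.off_ls_d, md.off_y_d,
                     md.off_z_d, md.R, grad);
    }
  }
  loglik_out = ll;
  return lp + ll;
}

// [[Rcpp::export]]
List oslm_logpost(List model, arma::vec q) {
  Model md = make_model(model);
  vec grad;
  double ll;
  double lp = logpost_grad(md, q, grad, ll);
  return List::create(Named("lp") = lp, Named("grad") = grad,
                      Named("loglik") = ll);
}

// ---- NUTS -----------------------------------------------------------------

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> nd;
  std::uniform_real_distribution<double> ud;
  Rng(uint64_t seed) : gen(seed), nd(0, 1), ud(0, 1) {}
  double normal() { return nd(gen); }
  double unif() { return ud(gen); }
};

struct Point {
  vec q, p, grad;
  double lp;
};

struct Sampler {
  const Model& md;
  vec minv;          // metric diagonal (estimated posterior variances)
  double eps;
  int n_grad = 0;
  Sampler(const Model& m) : md(m), minv(m.P, fill::ones), eps(0.1) {}

  double eval(Point& pt) {
    double ll;
    pt.lp = logpost_grad(md, pt.q, pt.grad, ll);
    ++n_grad;
    return pt.lp;
  }
  void leapfrog(Point& pt, double e) {
    pt.p += 0.5 * e * pt.grad;
    pt.q += e * (minv % pt.p);
    eval(pt);
    pt.p += 0.5 * e * pt.grad;
  }
  double logw(const Point& pt) const {
    return pt.lp - 0.5 * dot(pt.p, minv % pt.p);
  }
  bool uturn(const vec& qm, const vec& qp, const vec& pm, const vec& pp) const {
    vec dq = qp - qm;
    return dot(dq, minv % pm) < 0.0 || dot(dq, minv % pp) < 0.0;
  }
};

struct Tree {
  Point minus, plus, prop;
  double logw;
  bool ok;
  double sum_alpha = 0.0;
  int n_alpha = 0;
  bool divergent = false;
};

static void build_tree(Sampler& S, Rng& rng, const Point& start, int depth,
                       int dir, double logw0, Tree& out) {
  if (depth == 0) {
    Point pt = start;
    S.leapfrog(pt, dir * S.eps);
    double lw = std::isfinite(pt.lp) ? S.logw(pt) : -datum::inf;
    bool div = !(lw > logw0 - 1000.0);
    out.minus = pt; out.plus = pt; out.prop = pt;
    out.logw = lw;
    out.divergent = div;
    out.ok = !div;
    out.sum_alpha = std::isfinite(lw) ? std::min(1.0, std::exp(lw - logw0)) : 0.0;
    out.n_alpha = 1;
    return;
  }
  Tree t1, t2;
  build_tree(S, rng, start, depth - 1, dir, logw0, t1);
  if (!t1.ok) { out = t1; return; }
  const Point& edge = (dir == 1) ? t1.plus : t1.minus;
  build_tree(S, rng, edge, depth - 1, dir, logw0, t2);
  out.sum_alpha = t1.sum_alpha + t2.sum_alpha;
  out.n_alpha = t1.n_alpha + t2.n_alpha;
  out.divergent = t1.divergent || t2.divergent;
  if (!t2.ok) { out.ok = false; out.prop = t1.prop; out.logw = t1.logw;
    out.minus = (dir == 1) ? t1.minus : t2.minus;
    out.plus = (dir == 1) ? t2.plus : t1.plus;
    return; }
  double tot = std::max(t1.logw, t2.logw) +
    std::log(std::exp(t1.logw - std::max(t1.logw, t2.logw)) +
             std::exp(t2.logw - std::max(t1.logw, t2.logw)));
  out.prop = (std::log(rng.unif()) < t2.logw - tot) ? t2.prop : t1.prop;
  out.logw = tot;
  out.minus = (dir == 1) ? t1.minus : t2.minus;
  out.plus = (dir == 1) ? t2.plus : t1.plus;
  out.ok = !S.uturn(out.minus.q, out.plus.q, out.minus.p, out.plus.p);
}

// one NUTS transition; returns accept-stat average
static double nuts_transition(Sampler& S, Rng& rng, Point& cur,
                              int max_depth, int& depth_out, bool& div_out) {
  for (uword i = 0; i < cur.q.n_elem; ++i)
    cur.p(i) = rng.normal() / std::sqrt(S.minv(i));
  double logw0 = S.logw(cur);
  Point qm = cur, qp = cur, prop = cur;
  double logw_tree = logw0;
  double sum_alpha = 0.0; int n_alpha = 0;
  bool divergent = false;
  int depth = 0;
  for (; depth < max_depth; ++depth) {
    int dir = rng.unif() < 0.5 ? -1 : 1;
    Tree sub;
    build_tree(S, rng, dir == 1 ? qp : qm, depth, dir, logw0, sub);
    sum_alpha += sub.sum_alpha; n_alpha += sub.n_alpha;
    divergent = divergent || sub.divergent;
    if (!sub.ok) break;
    if (std::log(rng.unif()) < sub.logw - logw_tree) prop = sub.prop;
    logw_tree = std::max(logw_tree, sub.logw) +
      std::log(std::exp(logw_tree - std::max(logw_tree, sub.logw)) +
               std::exp(sub.logw - std::max(logw_tree, sub.logw)));
    if (dir == 1) qp = sub.plus; else qm = sub.minus;
    if (S.uturn(qm.q, qp.q, qm.p, qp.p)) break;
  }
  cur = prop;
  depth_out = depth;
  div_out = divergent;
  return n_alpha > 0 ? sum_alpha / n_alpha : 0.0;
}

// [[Rcpp::export]]
List oslm_nuts(List model, int iter, int warmup, arma::vec init,
               double adapt_delta, int max_treedepth, int seed) {
  Model md = make_model(model);
  Sampler S(md);
  Rng rng((uint64_t)seed);

  Point cur;
  cur.q = init;
  cur.p.zeros(md.P);
  cur.grad.zeros(md.P);
  S.eval(cur);
  if (!std::isfinite(cur.lp))
    Rcpp::stop("non-finite log posterior at initial values");

  // crude reasonable step size: scale until one-step accept prob ~ 0.5
  {
    for (uword i = 0; i < cur.q.n_elem; ++i) cur.p(i) = rng.normal();
    double h0 = S.logw(cur);
    Point tmp = cur;
    S.leapfrog(tmp, S.eps);
    double a = std::isfinite(tmp.lp) ? S.logw(tmp) - h0 : -datum::inf;
    int dir2 = a > std::log(0.5) ? 1 : -1;
    for (int t = 0; t < 50; ++t) {
      S.eps *= dir2 == 1 ? 2.0 : 0.5;
      tmp = cur;
      S.leapfrog(tmp, S.eps);
      a = std::isfinite(tmp.lp) ? S.logw(tmp) - h0 : -datum::inf;
      if ((dir2 == 1 && a < std::log(0.5)) || (dir2 == -1 && a > std::log(0.5)))
        break;
    }
  }

  // dual averaging state
  double mu_da = std::log(10.0 * S.eps), log_eps_bar = std::log(S.eps),
         h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;
  auto da_reset = [&]() {
    mu_da = std::log(10.0 * S.eps); log_eps_bar = std::log(S.eps);
    h_bar = 0.0; da_count = 0;
  };

  // metric adaptation windows
  int w_init = std::max(1, (int)std::round(0.15 * warmup));
  int w_term_start = std::max(w_init + 1, (int)std::round(0.9 * warmup));
  std::vector<int> window_ends;
  {
    int start = w_init, len = std::max(10, (warmup >= 300) ? 25 : 10);
    while (start < w_term_start) {
      int end = std::min(start + len, w_term_start);
      if (w_term_start - end < len) end = w_term_start;
      window_ends.push_back(end);
      start = end;
      len *= 2;
    }
  }
  vec welford_m(md.P, fill::zeros), welford_s(md.P, fill::zeros);
  int welford_n = 0;
  size_t win_idx = 0;

  int n_keep = iter - warmup;
  mat draws(n_keep, md.P);
  ivec depths(iter);
  int n_div = 0;

  for (int it = 1; it <= iter; ++it) {
    int depth; bool div;
    double astat = nuts_transition(S, rng, cur, max_treedepth, depth, div);
    depths(it - 1) = depth;
    if (it > warmup && div) ++n_div;
    if (it <= warmup) {
      // dual averaging
      ++da_count;
      double eta = 1.0 / (da_count + t0);
      h_bar = (1.0 - eta) * h_bar + eta * (adapt_delta - astat);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      S.eps = std::exp(log_eps);
      // metric windows
      if (it > w_init && it <= w_term_start) {
        ++welford_n;
        vec d = cur.q - welford_m;
        welford_m += d / welford_n;
        welford_s += d % (cur.q - welford_m);
      }
      if (win_idx < window_ends.size() && it == window_ends[win_idx]) {
        if (welford_n > 4) {
          vec v = welford_s / (welford_n - 1);
          S.minv = (welford_n / (welford_n + 5.0)) * v +
                   1e-3 * (5.0 / (welford_n + 5.0));
          welford_m.zeros(); welford_s.zeros(); welford_n = 0;
          S.eps = std::exp(log_eps_bar);
          da_reset();
        }
        ++win_idx;
      }
      if (it == warmup) S.eps = std::exp(log_eps_bar);
    } else {
      draws.row(it - warmup - 1) = cur.q.t();
    }
  }

  return List::create(
      Named("draws") = draws,
      Named("stepsize") = S.eps,
      Named("inv_metric") = S.minv,
      Named("divergences") = n_div,
      Named("max_depth_hits") = (int)accu(depths == max_treedepth),
      Named("n_grad") = S.n_grad);
}

// Cholesky factor of a correlation matrix from unconstrained y (for
// transforming draws back to Omega on the user scale).
// [[Rcpp::export]]
arma::mat oslm_corr_chol(arma::vec y, int K) {
  CorrWork cw;
  corr_forward(y, K, cw);
  return cw.L;
}
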