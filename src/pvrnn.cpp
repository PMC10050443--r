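#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Multiple-timescale variational RNN core.
//
// Layer l (0-based, 0 = lowest/fastest) has nd[l] deterministic units d,
// nz[l] stochastic latents z and time constant tau[l].  Per step:
//   h^l_t = (1 - 1/tau_l) h^l_{t-1}
//         + (1/tau_l) ( sum_{m in nbrs(l)} W_dd[l,m] d^m_{t-1}
//                       + W_zd[l] z^l_t + b_d[l] )
//   d^l_t = tanh(h^l_t)
// nbrs(l) = {l-1, l, l+1} intersected with valid layers.
// Prior:      mu_p = tanh(W_pm d^l_{t-1} + b_pm), sig_p = exp(W_ps d^l_{t-1} + b_ps)
// Posterior:  mu_q = tanh(a_mu_t),                sig_q = exp(a_sig_t)
// Output:     xhat_t = tanh(W_out d^0_t + b_out)
//
// Parameters live in one flat vector; the layout below must match
// param_layout() on the R side.

static const double LOGSIG_CAP = 30.0;  // overflow guard, never binding in practice

struct Arch {
  int L, nx, nd_total, nz_total, npar;
  std::vector<int> nd, nz, od, oz;
  std::vector<double> tau;
  // parameter offsets
  std::vector<std::vector<int>> o_Wdd; // per layer, per neighbour (ascending m)
  std::vector<std::vector<int>> nbrs;
  std::vector<int> o_Wzd, o_bd, o_Wpm, o_bpm, o_Wps, o_bps;
  int o_Wout, o_bout;
};

static Arch make_arch(const IntegerVector& nd, const IntegerVector& nz,
                      const NumericVector& tau, int nx) {
  Arch A;
  A.L = nd.size();
  A.nx = nx;
  A.nd.assign(nd.begin(), nd.end());
  A.nz.assign(nz.begin(), nz.end());
  A.tau.assign(tau.begin(), tau.end());
  A.od.resize(A.L); A.oz.resize(A.L);
  int sd = 0, sz = 0;
  for (int l = 0; l < A.L; ++l) { A.od[l] = sd; sd += A.nd[l]; A.oz[l] = sz; sz += A.nz[l]; }
  A.nd_total = sd; A.nz_total = sz;
  A.o_Wdd.resize(A.L); A.nbrs.resize(A.L);
  A.o_Wzd.resize(A.L); A.o_bd.resize(A.L);
  A.o_Wpm.resize(A.L); A.o_bpm.resize(A.L);
  A.o_Wps.resize(A.L); A.o_bps.resize(A.L);
  int off = 0;
  for (int l = 0; l < A.L; ++l) {
    for (int m = l - 1; m <= l + 1; ++m) {
      if (m < 0 || m >= A.L) continue;
      A.nbrs[l].push_back(m);
      A.o_Wdd[l].push_back(off);
      off += A.nd[l] * A.nd[m];
    }
    A.o_Wzd[l] = off; off += A.nd[l] * A.nz[l];
    A.o_bd[l]  = off; off += A.nd[l];
    A.o_Wpm[l] = off; off += A.nz[l] * A.nd[l];
    A.o_bpm[l] = off; off += A.nz[l];
    A.o_Wps[l] = off; off += A.nz[l] * A.nd[l];
    A.o_bps[l] = off; off += A.nz[l];
  }
  A.o_Wout = off; off += nx * A.nd[0];
  A.o_bout = off; off += nx;
  A.npar = off;
  return A;
}

// y += M v, M col-major (nr x nc)
static inline void mv(const double* M, int nr, int nc, const double* v, double* y) {
  for (int c = 0; c < nc; ++c) {
    const double vc = v[c];
    const double* col = M + (size_t)c * nr;
    for (int r = 0; r < nr; ++r) y[r] += col[r] * vc;
  }
}
// y += M^T g
static inline void mtv(const double* M, int nr, int nc, const double* g, double* y) {
  for (int c = 0; c < nc; ++c) {
    const double* col = M + (size_t)c * nr;
    double s = 0.0;
    for (int r = 0; r < nr; ++r) s += col[r] * g[r];
    y[c] += s;
  }
}
// G += g v^T
static inline void outer(double* G, int nr, int nc, const double* g, const double* v) {
  for (int c = 0; c < nc; ++c) {
    const double vc = v[c];
    double* col = G + (size_t)c * nr;
    for (int r = 0; r < nr; ++r) col[r] += g[r] * vc;
  }
}

// Posterior-driven forward pass over an observed sequence, with the
// meta-prior-weighted free energy and (optionally) its analytic gradients
// with respect to all weights and the adaptive variables a.
// [[Rcpp::export]]
List pvrnn_forward_cpp(NumericVector params,
                       IntegerVector nd, IntegerVector nz, NumericVector tau,
                       NumericMatrix x,
                       NumericMatrix a_mu, NumericMatrix a_sig,
                       NumericMatrix eps,
                       NumericVector w,
                       NumericVector h0, NumericVector d0,
                       bool grad_params, bool grad_a, bool keep_trace) {
  const int T = x.nrow(), nx = x.ncol();
  Arch A = make_arch(nd, nz, tau, nx);
  if (params.size() != A.npar) stop("parameter vector has wrong length");
  if (a_mu.nrow() != T || a_mu.ncol() != A.nz_total) stop("a_mu has wrong shape");
  const double* P = params.begin();

  NumericMatrix h(T, A.nd_total), d(T, A.nd_total);
  NumericMatrix mu_p(T, A.nz_total), sig_p(T, A.nz_total);
  NumericMatrix mu_q(T, A.nz_total), sig_q(T, A.nz_total), zm(T, A.nz_total);
  NumericMatrix xhat(T, nx);
  NumericVector klL(A.L);
  double recon = 0.0;

  std::vector<double> dprev(A.nd_total), hprev(A.nd_total);
  for (int j = 0; j < A.nd_total; ++j) { dprev[j] = d0[j]; hprev[j] = h0[j]; }
  std::vector<double> tmp(A.nd_total);
  const int nz_max = *std::max_element(A.nz.begin(), A.nz.end());
  std::vector<double> u(nz_max), v(nz_max), zl(nz_max);
  std::vector<double> o(nx), d0b(A.nd[0]);

  for (int t = 0; t < T; ++t) {
    // prior and posterior per layer
    for (int l = 0; l < A.L; ++l) {
      const int oz = A.oz[l], od = A.od[l], nzl = A.nz[l], ndl = A.nd[l];
      for (int i = 0; i < nzl; ++i) { u[i] = P[A.o_bpm[l] + i]; v[i] = P[A.o_bps[l] + i]; }
      mv(P + A.o_Wpm[l], nzl, ndl, &dprev[od], u.data());
      mv(P + A.o_Wps[l], nzl, ndl, &dprev[od], v.data());
      for (int i = 0; i < nzl; ++i) {
        double vv = v[i];
        if (vv > LOGSIG_CAP) vv = LOGSIG_CAP; else if (vv < -LOGSIG_CAP) vv = -LOGSIG_CAP;
        mu_p(t, oz + i) = std::tanh(u[i]);
        sig_p(t, oz + i) = std::exp(vv);
        double as = a_sig(t, oz + i);
        if (as > LOGSIG_CAP) as = LOGSIG_CAP; else if (as < -LOGSIG_CAP) as = -LOGSIG_CAP;
        mu_q(t, oz + i) = std::tanh(a_mu(t, oz + i));
        sig_q(t, oz + i) = std::exp(as);
        zm(t, oz + i) = mu_q(t, oz + i) + sig_q(t, oz + i) * eps(t, oz + i);
        // KL(q || p), diagonal Gaussians; log(sp/sq) = vv - as (log-sigmas)
        const double mq = mu_q(t, oz + i), sq = sig_q(t, oz + i);
        const double mp = mu_p(t, oz + i), sp = sig_p(t, oz + i);
        klL[l] += (vv - as) + (sq * sq + (mq - mp) * (mq - mp)) / (2.0 * sp * sp) - 0.5;
      }
    }
    // MTRNN step
    for (int l = 0; l < A.L; ++l) {
      const int od = A.od[l], ndl = A.nd[l];
      const double r = 1.0 / A.tau[l];
      std::fill(tmp.begin(), tmp.begin() + ndl, 0.0);
      for (size_t k = 0; k < A.nbrs[l].size(); ++k) {
        const int m = A.nbrs[l][k];
        mv(P + A.o_Wdd[l][k], ndl, A.nd[m], &dprev[A.od[m]], tmp.data());
      }
      for (int i = 0; i < A.nz[l]; ++i) zl[i] = zm(t, A.oz[l] + i);
      mv(P + A.o_Wzd[l], ndl, A.nz[l], zl.data(), tmp.data());
      for (int j = 0; j < ndl; ++j) {
        const double hv = (1.0 - r) * hprev[od + j] + r * (tmp[j] + P[A.o_bd[l] + j]);
        h(t, od + j) = hv;
        d(t, od + j) = std::tanh(hv);
      }
    }
    // output from lowest layer
    {
      for (int k = 0; k < nx; ++k) o[k] = P[A.o_bout + k];
      for (int j = 0; j < A.nd[0]; ++j) d0b[j] = d(t, j);
      mv(P + A.o_Wout, nx, A.nd[0], d0b.data(), o.data());
      for (int k = 0; k < nx; ++k) {
        xhat(t, k) = std::tanh(o[k]);
        const double e = xhat(t, k) - x(t, k);
        recon += 0.5 * e * e;
      }
    }
    for (int j = 0; j < A.nd_total; ++j) { dprev[j] = d(t, j); hprev[j] = h(t, j); }
  }

  double loss = recon;
  for (int l = 0; l < A.L; ++l) loss += w[l] * klL[l];

  List out = List::create(
    _["loss"] = loss, _["recon"] = recon, _["kl"] = klL,
    _["xhat"] = xhat,
    _["h_final"] = NumericVector(h(T - 1, _)),
    _["d_final"] = NumericVector(d(T - 1, _)));
  if (keep_trace) {
    out["trace"] = List::create(
      _["h"] = h, _["d"] = d, _["z"] = zm,
      _["mu_p"] = mu_p, _["sig_p"] = sig_p,
      _["mu_q"] = mu_q, _["sig_q"] = sig_q);
  }
  if (!grad_params && !grad_a) return out;

  // ---- backward pass (BPTT) ----
  NumericVector gP(grad_params ? A.npar : 0);
  NumericMatrix ga_mu(grad_a ? T : 0, grad_a ? A.nz_total : 0);
  NumericMatrix ga_sig(grad_a ? T : 0, grad_a ? A.nz_total : 0);

  std::vector<double> gd_cur(A.nd_total, 0.0), gd_prev(A.nd_total, 0.0);
  std::vector<double> ghn(A.nd_total, 0.0);  // dL/dh_{t+1}
  std::vector<double> gh(A.nd_total), gz(A.nz_total);
  std::vector<double> dtm1(A.nd_total), dout(nx), gtmp(A.nd[0]);
  std::vector<double> grh(*std::max_element(A.nd.begin(), A.nd.end()));
  std::vector<double> du(nz_max), dv(nz_max), gzl(nz_max);

  for (int t = T - 1; t >= 0; --t) {
    for (int j = 0; j < A.nd_total; ++j) dtm1[j] = (t == 0) ? d0[j] : d(t - 1, j);

    // output layer
    {
      for (int k = 0; k < nx; ++k) {
        const double xh = xhat(t, k);
        dout[k] = (xh - x(t, k)) * (1.0 - xh * xh);
      }
      for (int j = 0; j < A.nd[0]; ++j) d0b[j] = d(t, j);
      if (grad_params) {
        outer(&gP[A.o_Wout], nx, A.nd[0], dout.data(), d0b.data());
        for (int k = 0; k < nx; ++k) gP[A.o_bout + k] += dout[k];
      }
      std::fill(gtmp.begin(), gtmp.end(), 0.0);
      mtv(P + A.o_Wout, nx, A.nd[0], dout.data(), gtmp.data());
      for (int j = 0; j < A.nd[0]; ++j) gd_cur[j] += gtmp[j];
    }

    // recurrent step backward
    std::fill(gz.begin(), gz.end(), 0.0);
    for (int l = 0; l < A.L; ++l) {
      const int od = A.od[l], ndl = A.nd[l];
      const double r = 1.0 / A.tau[l];
      for (int j = 0; j < ndl; ++j) {
        const double dv = d(t, od + j);
        gh[od + j] = gd_cur[od + j] * (1.0 - dv * dv) + (1.0 - r) * ghn[od + j];
      }
      for (int j = 0; j < ndl; ++j) grh[j] = r * gh[od + j];
      for (size_t k = 0; k < A.nbrs[l].size(); ++k) {
        const int m = A.nbrs[l][k];
        if (grad_params)
          outer(&gP[A.o_Wdd[l][k]], ndl, A.nd[m], grh.data(), &dtm1[A.od[m]]);
        mtv(P + A.o_Wdd[l][k], ndl, A.nd[m], grh.data(), &gd_prev[A.od[m]]);
      }
      for (int i = 0; i < A.nz[l]; ++i) { zl[i] = zm(t, A.oz[l] + i); gzl[i] = 0.0; }
      if (grad_params) {
        outer(&gP[A.o_Wzd[l]], ndl, A.nz[l], grh.data(), zl.data());
        for (int j = 0; j < ndl; ++j) gP[A.o_bd[l] + j] += grh[j];
      }
      mtv(P + A.o_Wzd[l], ndl, A.nz[l], grh.data(), gzl.data());
      for (int i = 0; i < A.nz[l]; ++i) gz[A.oz[l] + i] += gzl[i];
      for (int j = 0; j < ndl; ++j) ghn[od + j] = gh[od + j];
    }

    // latents: reparameterized z path + KL terms
    for (int l = 0; l < A.L; ++l) {
      const int oz = A.oz[l], od = A.od[l], nzl = A.nz[l];
      for (int i = 0; i < nzl; ++i) {
        const double mq = mu_q(t, oz + i), sq = sig_q(t, oz + i);
        const double mp = mu_p(t, oz + i), sp = sig_p(t, oz + i);
        const double sp2 = sp * sp;
        double dmu_q = gz[oz + i];
        double dsig_q = gz[oz + i] * eps(t, oz + i);
        dmu_q += w[l] * (mq - mp) / sp2;
        dsig_q += w[l] * (-1.0 / sq + sq / sp2);
        const double dmu_p = -w[l] * (mq - mp) / sp2;
        const double dsig_p = w[l] * (1.0 / sp - (sq * sq + (mq - mp) * (mq - mp)) / (sp2 * sp));
        if (grad_a) {
          ga_mu(t, oz + i) = dmu_q * (1.0 - mq * mq);
          ga_sig(t, oz + i) = dsig_q * sq;
        }
        du[i] = dmu_p * (1.0 - mp * mp);
        dv[i] = dsig_p * sp;
      }
      if (grad_params) {
        outer(&gP[A.o_Wpm[l]], nzl, A.nd[l], du.data(), &dtm1[od]);
        outer(&gP[A.o_Wps[l]], nzl, A.nd[l], dv.data(), &dtm1[od]);
        for (int i = 0; i < nzl; ++i) { gP[A.o_bpm[l] + i] += du[i]; gP[A.o_bps[l] + i] += dv[i]; }
      }
      mtv(P + A.o_Wpm[l], nzl, A.nd[l], du.data(), &gd_prev[od]);
      mtv(P + A.o_Wps[l], nzl, A.nd[l], dv.data(), &gd_prev[od]);
    }

    gd_cur.swap(gd_prev);
    std::fill(gd_prev.begin(), gd_prev.end(), 0.0);
  }

  if (grad_params) out["grad_params"] = gP;
  if (grad_a) { out["grad_a_mu"] = ga_mu; out["grad_a_sig"] = ga_sig; }
  return out;
}

// Closed-loop generation with z drawn from the prior (eps = 0 gives the
// prior-mean rollout).  A single latent unit may be clamped:
// channel 0 (mean): the sampled z entry is replaced by `value`;
// channel 1 (variance): sigma_p is replaced by exp(value) before sampling.
// [[Rcpp::export]]
List pvrnn_generate_cpp(NumericVector params,
                        IntegerVector nd, IntegerVector nz, NumericVector tau,
                        int T, int nx,
                        NumericMatrix eps,
                        NumericVector h0, NumericVector d0,
                        int clamp_layer, int clamp_unit, int clamp_channel,
                        double clamp_value) {
  Arch A = make_arch(nd, nz, tau, nx);
  if (params.size() != A.npar) stop("parameter vector has wrong length");
  const double* P = params.begin();

  NumericMatrix d(T, A.nd_total), zm(T, A.nz_total);
  NumericMatrix mu_p(T, A.nz_total), sig_p(T, A.nz_total);
  NumericMatrix xhat(T, nx);

  std::vector<double> dprev(A.nd_total), hprev(A.nd_total), hcur(A.nd_total);
  for (int j = 0; j < A.nd_total; ++j) { dprev[j] = d0[j]; hprev[j] = h0[j]; }
  std::vector<double> tmp(A.nd_total);
  const int nz_max = *std::max_element(A.nz.begin(), A.nz.end());
  std::vector<double> u(nz_max), v(nz_max), zl(nz_max);
  std::vector<double> o(nx), d0b(A.nd[0]);

  for (int t = 0; t < T; ++t) {
    for (int l = 0; l < A.L; ++l) {
      const int oz = A.oz[l], od = A.od[l], nzl = A.nz[l], ndl = A.nd[l];
      for (int i = 0; i < nzl; ++i) { u[i] = P[A.o_bpm[l] + i]; v[i] = P[A.o_bps[l] + i]; }
      mv(P + A.o_Wpm[l], nzl, ndl, &dprev[od], u.data());
      mv(P + A.o_Wps[l], nzl, ndl, &dprev[od], v.data());
      for (int i = 0; i < nzl; ++i) {
        double vv = v[i];
        if (vv > LOGSIG_CAP) vv = LOGSIG_CAP; else if (vv < -LOGSIG_CAP) vv = -LOGSIG_CAP;
        double mp = std::tanh(u[i]), sp = std::exp(vv);
        if (l == clamp_layer && i == clamp_unit && clamp_channel == 1)
          sp = std::exp(clamp_value);
        double zv = mp + sp * eps(t, oz + i);
        if (l == clamp_layer && i == clamp_unit && clamp_channel == 0)
          zv = clamp_value;
        mu_p(t, oz + i) = mp; sig_p(t, oz + i) = sp; zm(t, oz + i) = zv;
      }
    }
    for (int l = 0; l < A.L; ++l) {
      const int od = A.od[l], ndl = A.nd[l];
      const double r = 1.0 / A.tau[l];
      std::fill(tmp.begin(), tmp.begin() + ndl, 0.0);
      for (size_t k = 0; k < A.nbrs[l].size(); ++k) {
        const int m = A.nbrs[l][k];
        mv(P + A.o_Wdd[l][k], ndl, A.nd[m], &dprev[A.od[m]], tmp.data());
      }
      for (int i = 0; i < A.nz[l]; ++i) zl[i] = zm(t, A.oz[l] + i);
      mv(P + A.o_Wzd[l], ndl, A.nz[l], zl.data(), tmp.data());
      for (int j = 0; j < ndl; ++j) {
        hcur[od + j] = (1.0 - r) * hprev[od + j] + r * (tmp[j] + P[A.o_bd[l] + j]);
        d(t, od + j) = std::tanh(hcur[od + j]);
      }
    }
    {
      for (int k = 0; k < nx; ++k) o[k] = P[A.o_bout + k];
      for (int j = 0; j < A.nd[0]; ++j) d0b[j] = d(t, j);
      mv(P + A.o_Wout, nx, A.nd[0], d0b.data(), o.data());
      for (int k = 0; k < nx; ++k) xhat(t, k) = std::tanh(o[k]);
    }
    for (int j = 0; j < A.nd_total; ++j) { dprev[j] = d(t, j); hprev[j] = hcur[j]; }
  }

  return List::create(
    _["xhat"] = xhat,
    _["trace"] = List::create(_["d"] = d, _["z"] = zm,
                              _["mu_p"] = mu_p, _["sig_p"] = sig_p),
    _["h_final"] = NumericVector(hprev.begin(), hprev.end()),
    _["d_final"] = NumericVector(dprev.begin(), dprev.end()));
}

// Total number of parameters for a given architecture (layout check).
// [[Rcpp::export]]
int pvrnn_n_params_cpp(IntegerVector nd, IntegerVector nz, NumericVector tau, int nx) {
  return make_arch(nd, nz, tau, nx).npar;
}
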