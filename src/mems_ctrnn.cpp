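// Hot loops for the MEMS-CTRNN and reference CTRNN simulators: hard-step
// forward integration, smooth (surrogate) forward, and backpropagation
// through time. Networks are small (N <= ~20) but trajectories are long
// (thousands of Euler substeps), so these live in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sig1(double x) {
  if (x > 40.0) return 1.0;
  if (x < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

static vec sigv(const vec& x) {
  vec out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) out(i) = sig1(x(i));
  return out;
}

// Fixed point of the voltage recursion with the firing/gating pattern held
// fixed: (I - W diag(gate)) V = theta.
static vec solve_voltages(const mat& W, const vec& gate, const vec& theta) {
  uword N = W.n_rows;
  mat A = eye(N, N) - W * diagmat(gate);
  vec V;
  bool ok = solve(V, A, theta, solve_opts::no_approx);
  if (!ok || !V.is_finite()) {
    uword bad = 0;
    if (ok) bad = index_max(abs(V));
    Rcpp::stop("voltage recursion diverged at neuron %d: gated linear system is singular or ill-conditioned",
               (int)(bad + 1));
  }
  return V;
}

struct MemsPhys {
  double tau, c1, d, zc, zf, invw2;
};

// One full-window forward pass of the MEMS network. `hard` selects the unit
// step firing; otherwise the logistic surrogate with steepness `beta` gates
// both the voltage matrix and the activity summary. Returns the
// window-averaged firing activity per neuron; optionally records the
// trajectory (z, V, activity per substep).
static vec mems_forward_core(const mat& X, const mat& W, const mat& Win,
                             const vec& theta, const MemsPhys& ph, double dt,
                             int substeps, bool hard, double beta,
                             double max_step, const vec& z0, bool record,
                             mat* Ztr, mat* Vtr, mat* Atr) {
  const uword L = X.n_cols, N = W.n_rows;
  const uword T = L * (uword)substeps;
  vec z = z0;
  vec summary(N, fill::zeros);
  vec fired = conv_to<vec>::from(z >= ph.zf);
  vec V(N, fill::zeros), pat(N);
  bool haveV = false;
  uword t = 0;
  for (uword l = 0; l < L; ++l) {
    vec inp = ph.invw2 * (Win * X.col(l));
    for (int s = 0; s < substeps; ++s, ++t) {
      if (hard) {
        if (!haveV || accu(fired != pat) > 0) {
          V = solve_voltages(W, fired, theta);
          pat = fired;
          haveV = true;
        }
      } else {
        vec gate = sigv(beta * (z - ph.zf));
        V = solve_voltages(W, gate, theta);
      }
      vec gap = ph.d - z;
      vec F = ph.c1 * square(V) / square(gap) + inp;
      vec dz = (dt / ph.tau) * (F - z);
      if (std::isfinite(max_step)) {
        dz = clamp(dz, -max_step, max_step);
      } else {
        vec zraw = z + dz;
        if (zraw.max() > 2.0 * ph.d)
          Rcpp::stop("displacement overshoot beyond 2*d at neuron %d: dt too large for stability, increase substeps",
                     (int)(index_max(zraw) + 1));
      }
      z = clamp(z + dz, 0.0, ph.zc);
      fired = conv_to<vec>::from(z >= ph.zf);
      vec act = hard ? fired : sigv(beta * (z - ph.zf));
      summary += act;
      if (record) {
        Ztr->col(t) = z;
        Vtr->col(t) = V;
        Atr->col(t) = act;
      }
    }
  }
  return summary / (double)T;
}

// [[Rcpp::export]]
Rcpp::List cpp_mems_forward(const arma::mat& X, const arma::mat& W,
                            const arma::mat& Win, const arma::vec& theta,
                            double tau, double c1, double d, double zc,
                            double zf, double invw2, double dt, int substeps,
                            bool hard, double beta, double max_step,
                            const arma::vec& z0, bool record) {
  MemsPhys ph{tau, c1, d, zc, zf, invw2};
  const uword T = X.n_cols * (uword)substeps, N = W.n_rows;
  mat Ztr, Vtr, Atr;
  if (record) {
    Ztr.set_size(N, T);
    Vtr.set_size(N, T);
    Atr.set_size(N, T);
  }
  vec summary = mems_forward_core(X, W, Win, theta, ph, dt, substeps, hard,
                                  beta, max_step, z0, record, &Ztr, &Vtr, &Atr);
  return Rcpp::List::create(Rcpp::Named("summary") = summary,
                            Rcpp::Named("z") = Ztr, Rcpp::Named("V") = Vtr,
                            Rcpp::Named("activity") = Atr);
}

// [[Rcpp::export]]
arma::mat cpp_mems_forward_batch(const arma::cube& X, const arma::mat& W,
                                 const arma::mat& Win, const arma::vec& theta,
                                 double tau, double c1, double d, double zc,
                                 double zf, double invw2, double dt,
                                 int substeps, bool hard, double beta,
                                 double max_step) {
  MemsPhys ph{tau, c1, d, zc, zf, invw2};
  const uword B = X.n_slices, N = W.n_rows;
  vec z0(N, fill::zeros);
  mat out(N, B);
  for (uword b = 0; b < B; ++b) {
    out.col(b) = mems_forward_core(X.slice(b), W, Win, theta, ph, dt, substeps,
                                   hard, beta, max_step, z0, false, nullptr,
                                   nullptr, nullptr);
  }
  return out;
}

// Smooth forward + BPTT over a batch of windows. Cross-entropy of the
// softmaxed readout scores; gradients for every weight group. Step codes per
// (neuron, substep): 1 = plain Euler update (differentiable), 2 = increment
// capped (unit dependence on previous state only), 0 = clamped at a stop
// (no dependence on this step's inputs).
// [[Rcpp::export]]
Rcpp::List cpp_mems_train_batch(const arma::cube& X, const arma::ivec& y,
                                const arma::mat& W, const arma::mat& Win,
                                const arma::vec& theta, const arma::mat& Wout,
                                const arma::vec& bout, double tau, double c1,
                                double d, double zc, double zf, double invw2,
                                double dt, int substeps, double beta,
                                double max_step, bool want_grad) {
  const uword O = X.n_rows, L = X.n_cols, B = X.n_slices, N = W.n_rows;
  const uword T = L * (uword)substeps;
  const double dtt = dt / tau;
  mat gW(N, N, fill::zeros), gWin(N, O, fill::zeros), gWout(2, N, fill::zeros);
  vec gtheta(N, fill::zeros), gbout(2, fill::zeros);
  double loss = 0.0;
  ivec pred(B);
  mat scores(2, B);

  mat zh(N, T + 1), Vh(N, T);
  Mat<unsigned char> code(N, T);

  for (uword b = 0; b < B; ++b) {
    // ---- forward (smooth), recording history for BPTT ----
    zh.col(0).zeros();
    vec z = zh.col(0);
    vec summary(N, fill::zeros);
    uword t = 0;
    for (uword l = 0; l < L; ++l) {
      vec inp = invw2 * (Win * X.slice(b).col(l));
      for (int s = 0; s < substeps; ++s, ++t) {
        vec gate = sigv(beta * (z - zf));
        vec V = solve_voltages(W, gate, theta);
        vec gap = d - z;
        vec F = c1 * square(V) / square(gap) + inp;
        for (uword i = 0; i < N; ++i) {
          double dz = dtt * (F(i) - z(i));
          unsigned char ci = 1;
          if (std::isfinite(max_step) && std::fabs(dz) > max_step) {
            dz = (dz > 0 ? max_step : -max_step);
            ci = 2;
          }
          double zn = z(i) + dz;
          if (zn <= 0.0) { zn = 0.0; ci = 0; }
          else if (zn >= zc) { zn = zc; ci = 0; }
          z(i) = zn;
          code(i, t) = ci;
        }
        Vh.col(t) = V;
        zh.col(t + 1) = z;
        summary += sigv(beta * (z - zf));
      }
    }
    summary /= (double)T;

    // ---- loss / readout ----
    vec sc = Wout * summary + bout;
    scores.col(b) = sc;
    double m = sc.max();
    vec e = exp(sc - m);
    vec p = e / accu(e);
    int yi = y(b);
    loss += -std::log(std::max(p(yi), 1e-300));
    pred(b) = (sc(1) > sc(0)) ? 1 : 0;
    if (!want_grad) continue;

    vec gsc = p;
    gsc(yi) -= 1.0;
    gWout += gsc * summary.t();
    gbout += gsc;
    vec gsum = (Wout.t() * gsc) / (double)T;  // per-substep summary weight

    // ---- backward through time ----
    vec gz(N, fill::zeros);
    for (uword tt = T; tt >= 1; --tt) {
      uword ti = tt - 1;
      vec zt = zh.col(tt), zp = zh.col(ti), V = Vh.col(ti);
      vec st = sigv(beta * (zt - zf));
      vec gzt = gz + gsum % (beta * st % (1.0 - st));
      vec gzp(N, fill::zeros), gF(N, fill::zeros);
      bool anyF = false;
      for (uword i = 0; i < N; ++i) {
        unsigned char ci = code(i, ti);
        if (ci == 0) continue;
        if (ci == 2) { gzp(i) += gzt(i); continue; }
        gzp(i) += gzt(i) * (1.0 - dtt);
        gF(i) = gzt(i) * dtt;
        if (gF(i) != 0.0) anyF = true;
      }
      if (anyF) {
        vec gap = d - zp;
        vec gV = gF % (2.0 * c1 * V / square(gap));
        gzp += gF % (2.0 * c1 * square(V) / pow(gap, 3));
        uword l = ti / (uword)substeps;
        gWin += invw2 * (gF * X.slice(b).col(l).t());
        vec sp = sigv(beta * (zp - zf));
        mat A = eye(N, N) - W * diagmat(sp);
        vec u;
        if (!solve(u, A.t(), gV, solve_opts::no_approx))
          Rcpp::stop("voltage adjoint solve failed");
        gtheta += u;
        gW += u * (sp % V).t();
        vec gsp = (W.t() * u) % V;
        gzp += gsp % (beta * sp % (1.0 - sp));
      }
      gz = gzp;
    }
  }

  double nb = (double)B;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss / nb, Rcpp::Named("scores") = scores,
      Rcpp::Named("pred") = pred, Rcpp::Named("gW") = gW / nb,
      Rcpp::Named("gWin") = gWin / nb, Rcpp::Named("gtheta") = gtheta / nb,
      Rcpp::Named("gWout") = gWout / nb, Rcpp::Named("gbout") = gbout / nb);
}

// ---------------- reference CTRNN ----------------

static vec ctrnn_forward_core(const mat& X, const mat& W, const mat& Win,
                              const vec& h, const vec& tau, double dt,
                              int substeps, const vec& y0, bool record,
                              mat* Ytr) {
  const uword L = X.n_cols, N = W.n_rows;
  const uword T = L * (uword)substeps;
  vec y = y0;
  vec dtt = dt / tau;
  vec summary(N, fill::zeros);
  uword t = 0;
  for (uword l = 0; l < L; ++l) {
    vec inp = Win * X.col(l);
    for (int s = 0; s < substeps; ++s, ++t) {
      vec dy = dtt % (-y + W * sigv(y) + h + inp);
      y += dy;
      if (!y.is_finite())
        Rcpp::stop("CTRNN state diverged at neuron %d", (int)(index_max(abs(y)) + 1));
      summary += sigv(y);
      if (record) Ytr->col(t) = y;
    }
  }
  return summary / (double)T;
}

// [[Rcpp::export]]
Rcpp::List cpp_ctrnn_forward(const arma::mat& X, const arma::mat& W,
                             const arma::mat& Win, const arma::vec& h,
                             const arma::vec& tau, double dt, int substeps,
                             const arma::vec& y0, bool record) {
  const uword T = X.n_cols * (uword)substeps, N = W.n_rows;
  mat Ytr;
  if (record) Ytr.set_size(N, T);
  vec summary =
      ctrnn_forward_core(X, W, Win, h, tau, dt, substeps, y0, record, &Ytr);
  return Rcpp::List::create(Rcpp::Named("summary") = summary,
                            Rcpp::Named("y") = Ytr);
}

// [[Rcpp::export]]
arma::mat cpp_ctrnn_forward_batch(const arma::cube& X, const arma::mat& W,
                                  const arma::mat& Win, const arma::vec& h,
                                  const arma::vec& tau, double dt,
                                  int substeps) {
  const uword B = X.n_slices, N = W.n_rows;
  vec y0(N, fill::zeros);
  mat out(N, B);
  for (uword b = 0; b < B; ++b)
    out.col(b) = ctrnn_forward_core(X.slice(b), W, Win, h, tau, dt, substeps,
                                    y0, false, nullptr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_ctrnn_train_batch(const arma::cube& X, const arma::ivec& y,
                                 const arma::mat& W, const arma::mat& Win,
                                 const arma::vec& h, const arma::mat& Wout,
                                 const arma::vec& bout, const arma::vec& tau,
                                 double dt, int substeps, bool want_grad) {
  const uword O = X.n_rows, L = X.n_cols, B = X.n_slices, N = W.n_rows;
  const uword T = L * (uword)substeps;
  vec dtt = dt / tau;
  mat gW(N, N, fill::zeros), gWin(N, O, fill::zeros), gWout(2, N, fill::zeros);
  vec gh(N, fill::zeros), gbout(2, fill::zeros);
  double loss = 0.0;
  ivec pred(B);
  mat scores(2, B);
  mat yh(N, T + 1);

  for (uword b = 0; b < B; ++b) {
    yh.col(0).zeros();
    vec yy = yh.col(0);
    vec summary(N, fill::zeros);
    uword t = 0;
    for (uword l = 0; l < L; ++l) {
      vec inp = Win * X.slice(b).col(l);
      for (int s = 0; s < substeps; ++s, ++t) {
        yy += dtt % (-yy + W * sigv(yy) + h + inp);
        if (!yy.is_finite())
          Rcpp::stop("CTRNN state diverged at neuron %d",
                     (int)(index_max(abs(yy)) + 1));
        yh.col(t + 1) = yy;
        summary += sigv(yy);
      }
    }
    summary /= (double)T;

    vec sc = Wout * summary + bout;
    scores.col(b) = sc;
    double m = sc.max();
    vec e = exp(sc - m);
    vec p = e / accu(e);
    int yi = y(b);
    loss += -std::log(std::max(p(yi), 1e-300));
    pred(b) = (sc(1) > sc(0)) ? 1 : 0;
    if (!want_grad) continue;

    vec gsc = p;
    gsc(yi) -= 1.0;
    gWout += gsc * summary.t();
    gbout += gsc;
    vec gsum = (Wout.t() * gsc) / (double)T;

    vec gy(N, fill::zeros);
    for (uword tt = T; tt >= 1; --tt) {
      uword ti = tt - 1;
      vec yt = yh.col(tt), yp = yh.col(ti);
      vec st = sigv(yt);
      vec gyt = gy + gsum % (st % (1.0 - st));
      vec sp = sigv(yp);
      vec spd = sp % (1.0 - sp);
      vec gdy = dtt % gyt;
      uword l = ti / (uword)substeps;
      gW += gdy * sp.t();
      gh += gdy;
      gWin += gdy * X.slice(b).col(l).t();
      gy = gyt % (1.0 - dtt) + spd % (W.t() * gdy);
    }
  }

  double nb = (double)B;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss / nb, Rcpp::Named("scores") = scores,
      Rcpp::Named("pred") = pred, Rcpp::Named("gW") = gW / nb,
      Rcpp::Named("gWin") = gWin / nb, Rcpp::Named("gh") = gh / nb,
      Rcpp::Named("gWout") = gWout / nb, Rcpp::Named("gbout") = gbout / nb);
}
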