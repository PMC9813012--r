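// Core dynamics of the two-module echo-state simulator.
//
// The hot loop (per-ms Euler integration of both reservoirs plus the
// per-step recursive-least-squares readout update) lives here; all
// orchestration, stimulus synthesis and analysis stay in R.

#include <RcppArmadillo.h>

#include <R_ext/BLAS.h>

#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

namespace {

// Draw i.i.d. standard normals through R's RNG so that set.seed() in R
// controls every stochastic element of a simulation.
arma::vec rnorm_vec(const arma::uword n) {
  arma::vec out(n);
  for (arma::uword i = 0; i < n; ++i) out[i] = R::norm_rand();
  return out;
}

// Fast internal normal generator for the per-step reservoir noise
// (~10^8 draws per training run, too hot for R's RNG). Seeded from R's
// RNG stream on entry to the simulation loop, so set.seed() still
// controls it; mt19937_64 plus Box-Muller keeps the stream portable.
struct NormalRng {
  std::mt19937_64 eng;
  bool cached = false;
  double cache = 0.0;

  void seed_from_r() {
    const uint64_t hi = uint64_t(unif_rand() * 4294967296.0);
    const uint64_t lo = uint64_t(unif_rand() * 4294967296.0);
    eng.seed((hi << 32) ^ lo);
    cached = false;
  }
  double uniform() {  // in (0, 1)
    return (double(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double next() {
    if (cached) {
      cached = false;
      return cache;
    }
    const double rho = std::sqrt(-2.0 * std::log(uniform()));
    const double th = 6.283185307179586476925286766559 * uniform();
    cache = rho * std::sin(th);
    cached = true;
    return rho * std::cos(th);
  }
  void fill(arma::vec& v) {
    for (arma::uword i = 0; i < v.n_elem; ++i) v[i] = next();
  }
};

// Soft winner-take-all teaching signal:
//   f_i = [ tanh( (zh_i - gamma * (sum_j zh_j - zh_i)) / beta ) ]_+
arma::vec teaching_vec(const arma::vec& zhat, const double beta,
                       const double gamma) {
  const double total = arma::accu(zhat);
  arma::vec f(zhat.n_elem);
  for (arma::uword i = 0; i < zhat.n_elem; ++i) {
    const double num = zhat[i] - gamma * (total - zhat[i]);
    const double v = std::tanh(num / beta);
    f[i] = v > 0.0 ? v : 0.0;
  }
  return f;
}

// Sliding-window running statistics over the last `win` samples
// (growing window while fewer samples have been seen).
struct RunningStats {
  arma::mat buf;     // win x O circular buffer
  arma::rowvec sum, sumsq;
  arma::uword win = 0, pos = 0, n = 0;

  void init(const arma::uword w, const arma::uword O) {
    win = w;
    buf.zeros(w, O);
    sum.zeros(O);
    sumsq.zeros(O);
    pos = 0;
    n = 0;
  }
  void push(const arma::rowvec& z) {
    if (n == win) {
      sum -= buf.row(pos);
      sumsq -= arma::square(buf.row(pos));
    } else {
      ++n;
    }
    buf.row(pos) = z;
    sum += z;
    sumsq += arma::square(z);
    pos = (pos + 1) % win;
  }
  arma::rowvec mu() const { return sum / double(n); }
  arma::rowvec sigma() const {
    arma::rowvec v = sumsq / double(n) - arma::square(sum / double(n));
    v.transform([](double x) { return x > 0.0 ? std::sqrt(x) : 0.0; });
    return v;
  }
};

arma::vec normalize_z(const arma::vec& z, const arma::rowvec& mu,
                      const arma::rowvec& sg, const double floor_) {
  arma::vec zh(z.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < z.n_elem; ++i)
    if (sg[i] > floor_) zh[i] = (z[i] - mu[i]) / sg[i];
  return zh;
}

// One reservoir module. W_out is stored compactly: row i of `wout`
// holds the weights onto readout i from its S support neurons
// (indices in column i of `support`, 0-based here).
struct RcModule {
  arma::mat W, Win, Wback;
  arma::mat wout;      // O x S
  arma::umat support;  // S x O
  arma::cube P;        // S x S x O
  double tau, g, k;
  arma::vec x, r, z, zhat;
  arma::vec drive, noise, rs_ws, Pr_ws;  // preallocated workspaces
  // The recurrent matvec (the single dominant cost) runs in single
  // precision: its rounding error (~1e-7 relative) is five orders of
  // magnitude below the injected per-step noise k*xi.
  arma::fmat Wf;
  arma::fvec rf, yf;

  void alloc_ws() {
    const arma::uword N = W.n_rows, S = support.n_rows;
    drive.zeros(N);
    noise.zeros(N);
    rs_ws.zeros(S);
    Pr_ws.zeros(S);
    Wf = arma::conv_to<arma::fmat>::from(W);
    rf.zeros(N);
    yf.zeros(N);
  }

  void load(const List& m) {
    W = as<arma::mat>(m["W"]);
    Win = as<arma::mat>(m["W_in"]);
    Wback = as<arma::mat>(m["W_back"]);
    wout = as<arma::mat>(m["wout"]);
    support = as<arma::umat>(m["support"]) - 1;  // to 0-based
    P = as<arma::cube>(m["P"]);
    List pr = m["params"];
    tau = as<double>(pr["tau"]);
    g = as<double>(pr["g"]);
    k = as<double>(pr["k"]);
    alloc_ws();
  }

  arma::vec readout() {
    arma::vec out(wout.n_rows);
    for (arma::uword i = 0; i < wout.n_rows; ++i) {
      const arma::uword* sp = support.colptr(i);
      double acc = 0.0;
      for (arma::uword j = 0; j < support.n_rows; ++j)
        acc += wout.at(i, j) * r[sp[j]];
      out[i] = acc;
    }
    return out;
  }

  // Euler step of tau dx/dt = -x + g W r + W_in i + W_back z + k xi (+ cross)
  void step(const arma::vec& input, const arma::vec& fb,
            const arma::vec& cross, const double dt, NormalRng* rng) {
    if (rng) {  // fast path used by the simulation loop
      for (arma::uword i = 0; i < r.n_elem; ++i) rf[i] = float(r[i]);
      yf = Wf * rf;  // sgemv
      for (arma::uword i = 0; i < r.n_elem; ++i) drive[i] = double(yf[i]);
    } else {
      drive = W * r;
    }
    drive *= g;
    drive -= x;
    drive += Win * input;
    drive += Wback * fb;
    if (cross.n_elem == x.n_elem) drive += cross;
    if (k > 0.0) {
      if (rng) rng->fill(noise); else noise = rnorm_vec(x.n_elem);
      drive += k * noise;
    }
    x += (dt / tau) * drive;
    r = arma::tanh(x);
  }

  // FORCE / RLS update of readout i for scalar error e; all in place.
  // P is symmetric: the loop maintains only its lower triangle via
  // dsymv/dsyr (half the memory traffic); sync_P() mirrors it on exit.
  void rls(const arma::uword i, const double e) {
    const int S = int(support.n_rows);
    const arma::uword* sp = support.colptr(i);
    for (int j = 0; j < S; ++j) rs_ws[j] = r[sp[j]];
    double* Ps = P.slice_memptr(i);
    const char lo = 'L';
    const int inc = 1;
    const double one = 1.0, zero = 0.0;
    F77_CALL(dsymv)(&lo, &S, &one, Ps, &S, rs_ws.memptr(), &inc, &zero,
                    Pr_ws.memptr(), &inc FCONE);
    const double c = 1.0 / (1.0 + arma::dot(rs_ws, Pr_ws));
    const double negc = -c;
    F77_CALL(dsyr)(&lo, &S, &negc, Pr_ws.memptr(), &inc, Ps, &S FCONE);
    const double ec = e * c;
    for (int j = 0; j < S; ++j) wout.at(i, j) -= ec * Pr_ws[j];
  }

  void sync_P() {  // restore full symmetric storage after lower-only updates
    for (arma::uword i = 0; i < P.n_slices; ++i)
      P.slice(i) = arma::symmatl(P.slice(i));
  }

  double wout_norm() const { return arma::norm(wout, "fro"); }
};

}  // namespace

//' @noRd
// [[Rcpp::export]]
List rc_step_cpp(const arma::vec& x, const arma::mat& W, const arma::mat& W_in,
                 const arma::mat& W_back, const arma::vec& input,
                 const arma::vec& feedback_z, const double tau, const double g,
                 const double k, const double dt) {
  arma::vec r = arma::tanh(x);
  arma::vec drive =
      -x + g * (W * r) + W_in * input + W_back * feedback_z;
  if (k > 0.0) drive += k * rnorm_vec(x.n_elem);
  arma::vec xn = x + (dt / tau) * drive;
  return List::create(_["x"] = xn, _["r"] = arma::tanh(xn));
}

//' @noRd
// [[Rcpp::export]]
List rls_update_cpp(const arma::mat& P, const arma::rowvec& w,
                    const arma::vec& rs, const double e) {
  const arma::vec Pr = P * rs;
  const double c = 1.0 / (1.0 + arma::dot(rs, Pr));
  arma::mat Pn = P - c * (Pr * Pr.t());
  arma::rowvec wn = w - (e * c) * Pr.t();
  return List::create(_["P"] = Pn, _["w"] = wn);
}

//' @noRd
// [[Rcpp::export]]
List running_stats_cpp(const arma::mat& z_history, const int window) {
  RunningStats st;
  st.init(window, z_history.n_cols);
  arma::mat mu(z_history.n_rows, z_history.n_cols);
  arma::mat sg(z_history.n_rows, z_history.n_cols);
  for (arma::uword t = 0; t < z_history.n_rows; ++t) {
    st.push(z_history.row(t));
    mu.row(t) = st.mu();
    sg.row(t) = st.sigma();
  }
  return List::create(_["mu"] = mu, _["sigma"] = sg);
}

// Joint simulation of the coupled two-module model.
//
// variant: 0 original (cross-fed teaching), 1 A1 (reservoir->reservoir),
//          2 A2 (readout->partner reservoir feedback), 3 A3 (readout
//          cross-coupling). For variants 1-3 the teaching signal is
//          module-local and the association layer learns by Hebb.
//' @noRd
// [[Rcpp::export]]
List rc_simulate_cpp(const List mod1, const List mod2, const arma::mat& inp1,
                     const arma::mat& inp2, const List teach, const List ctrl) {
  RcModule m1, m2;
  m1.load(mod1);
  m2.load(mod2);

  const double dt = as<double>(ctrl["dt"]);
  const bool learn = as<bool>(ctrl["learn"]);
  const int warmup = as<int>(ctrl["warmup"]);
  const int upd_int = as<int>(ctrl["update_interval"]);
  const int rec_stride = as<int>(ctrl["record_stride"]);
  const bool record_r = as<bool>(ctrl["record_r"]);
  const bool record_teach = as<bool>(ctrl["record_teach"]);

  const double beta = as<double>(teach["beta"]);
  const double gamma = as<double>(teach["gamma"]);
  const double delta = as<double>(teach["delta"]);
  const int win = as<int>(teach["window"]);
  const double floor_ = as<double>(teach["sigma_floor"]);
  const int variant = as<int>(teach["variant"]);
  const double assoc_lr = as<double>(teach["assoc_lr"]);
  const double assoc_cap = as<double>(teach["assoc_cap"]);
  // exponential smoothing of zhat before the teaching transform
  // (tau_f in steps; 0 disables)
  const double smooth = as<double>(teach["smooth_steps"]);
  const double sm_a = smooth > 0 ? dt / smooth : 1.0;
  // optional externally supplied teacher (T x O per module) overriding the
  // self-organized teaching signal; used for supervised probes
  arma::mat f_ext1, f_ext2;
  const bool has_fext = teach.containsElementNamed("f_ext1");
  if (has_fext) {
    f_ext1 = as<arma::mat>(teach["f_ext1"]);
    f_ext2 = as<arma::mat>(teach["f_ext2"]);
  }

  arma::mat cross12, cross21;  // matrices feeding module1 <- module2 etc.
  if (variant == 1 || variant == 2) {
    cross12 = as<arma::mat>(teach["cross12"]);
    cross21 = as<arma::mat>(teach["cross21"]);
  }
  arma::mat A12, A21;  // A3 readout coupling
  if (variant == 3) {
    A12 = as<arma::mat>(teach["cross12"]);
    A21 = as<arma::mat>(teach["cross21"]);
  }
  arma::mat aw1 = as<arma::mat>(teach["assoc_w1"]);
  arma::mat aw2 = as<arma::mat>(teach["assoc_w2"]);

  const arma::uword T = inp1.n_rows;
  const arma::uword O = m1.wout.n_rows;

  const bool fb_norm = as<bool>(ctrl["fb_normalized"]);

  m1.x = as<arma::vec>(ctrl["x0_1"]);
  m2.x = as<arma::vec>(ctrl["x0_2"]);
  m1.zhat.zeros(O);
  m2.zhat.zeros(O);
  m1.r = arma::tanh(m1.x);
  m2.r = arma::tanh(m2.x);
  m1.z = m1.readout();
  m2.z = m2.readout();

  RunningStats st1, st2;
  st1.init(win, O);
  st2.init(win, O);

  arma::mat Z1(T, O), Z2(T, O), Oo(T, O);
  arma::mat F1, F2, ZH1, ZH2;
  if (record_teach) {
    F1.zeros(T, O);
    F2.zeros(T, O);
    ZH1.zeros(T, O);
    ZH2.zeros(T, O);
  }
  const arma::uword n_rec = (T + rec_stride - 1) / rec_stride;
  arma::mat R1, R2;
  if (record_r) {
    R1.set_size(n_rec, m1.W.n_rows);
    R2.set_size(n_rec, m2.W.n_rows);
  }
  std::vector<double> norm_t, norm1, norm2;

  NormalRng rng;
  rng.seed_from_r();

  arma::vec c1, c2;  // empty = no cross drive
  arma::vec in1(inp1.n_cols), in2(inp2.n_cols);
  arma::vec zs1(O, arma::fill::zeros), zs2(O, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    // cross-module drive computed from the previous step's partner state
    if (variant == 1) {
      c1 = cross12 * m2.r;
      c2 = cross21 * m1.r;
    } else if (variant == 2) {
      c1 = cross12 * (fb_norm ? m2.zhat : m2.z);
      c2 = cross21 * (fb_norm ? m1.zhat : m1.z);
    }
    const arma::vec z1_prev = fb_norm ? m1.zhat : m1.z;
    const arma::vec z2_prev = fb_norm ? m2.zhat : m2.z;
    in1 = inp1.row(t).t();
    in2 = inp2.row(t).t();
    m1.step(in1, z1_prev, c1, dt, &rng);
    m2.step(in2, z2_prev, c2, dt, &rng);

    arma::vec z1 = m1.readout(), z2 = m2.readout();
    if (variant == 3) {
      const arma::vec z1r = z1, z2r = z2;
      z1 = z1r + A12 * z2r;
      z2 = z2r + A21 * z1r;
    }
    m1.z = z1;
    m2.z = z2;

    st1.push(z1.t());
    st2.push(z2.t());
    const arma::vec zh1 = normalize_z(z1, st1.mu(), st1.sigma(), floor_);
    const arma::vec zh2 = normalize_z(z2, st2.mu(), st2.sigma(), floor_);
    m1.zhat = zh1;
    m2.zhat = zh2;
    // leaky integration of the normalized readouts for the teacher:
    // chunk ownership is an epoch-timescale decision, so the WTA reads
    // evidence integrated over ~tau_f rather than instantaneous noise
    zs1 = (1.0 - sm_a) * zs1 + sm_a * zh1;
    zs2 = (1.0 - sm_a) * zs2 + sm_a * zh2;

    arma::vec f1(O, arma::fill::zeros), f2(O, arma::fill::zeros);
    const bool updating =
        learn && int(t) >= warmup && (int(t) % upd_int == 0);
    if (learn) {
      if (has_fext) {
        f1 = f_ext1.row(t).t();
        f2 = f_ext2.row(t).t();
      } else if (variant == 0) {  // cross-fed teaching
        f1 = teaching_vec(zs2, beta, gamma);
        f2 = teaching_vec(zs1, beta, gamma);
      } else {  // module-local teaching
        f1 = teaching_vec(zs1, beta, gamma);
        f2 = teaching_vec(zs2, beta, gamma);
      }
      if (updating) {
        for (arma::uword i = 0; i < O; ++i) {
          m1.rls(i, z1[i] - f1[i]);
          m2.rls(i, z2[i] - f2[i]);
        }
      }
    }

    // association-layer output
    arma::vec o(O);
    if (variant == 0) {
      o = delta * (z1 + z2);
    } else {
      o = aw1 * z1 + aw2 * z2;
      if (learn && int(t) >= warmup) {
        // Hebb with subtractive normalization, Euler at dt
        const double mz1 = arma::accu(z1) / double(O);
        const double mz2 = arma::accu(z2) / double(O);
        aw1 += (dt * assoc_lr) * (o * z1.t() - o * arma::rowvec(O).fill(mz1));
        aw2 += (dt * assoc_lr) * (o * z2.t() - o * arma::rowvec(O).fill(mz2));
        // plain Hebbian growth is unbounded (subtractive normalization
        // conserves row sums, not norms): clamp to keep o finite
        aw1.clamp(-assoc_cap, assoc_cap);
        aw2.clamp(-assoc_cap, assoc_cap);
      }
    }

    Z1.row(t) = z1.t();
    Z2.row(t) = z2.t();
    Oo.row(t) = o.t();
    if (record_teach) {
      F1.row(t) = f1.t();
      F2.row(t) = f2.t();
      ZH1.row(t) = zh1.t();
      ZH2.row(t) = zh2.t();
    }
    if (t % arma::uword(rec_stride) == 0) {
      if (record_r) {
        R1.row(t / rec_stride) = m1.r.t();
        R2.row(t / rec_stride) = m2.r.t();
      }
      norm_t.push_back(double(t + 1) * dt);
      norm1.push_back(m1.wout_norm());
      norm2.push_back(m2.wout_norm());
    }

    if (t % 200 == 0 && (!m1.x.is_finite() || !m2.x.is_finite()))
      stop("reservoir state diverged (non-finite x) at step %d", int(t));
  }
  if (!m1.x.is_finite() || !m2.x.is_finite())
    stop("reservoir state diverged (non-finite x) at final step");

  m1.sync_P();
  m2.sync_P();

  List out = List::create(
      _["z1"] = Z1, _["z2"] = Z2, _["o"] = Oo, _["wout1"] = m1.wout,
      _["wout2"] = m2.wout, _["P1"] = m1.P, _["P2"] = m2.P,
      _["assoc_w1"] = aw1, _["assoc_w2"] = aw2, _["x1"] = m1.x,
      _["x2"] = m2.x,
      _["wout_norm"] = DataFrame::create(_["time_ms"] = norm_t,
                                         _["rc1"] = norm1, _["rc2"] = norm2));
  if (record_teach) {
    out["f1"] = F1;
    out["f2"] = F2;
    out["zhat1"] = ZH1;
    out["zhat2"] = ZH2;
  }
  if (record_r) {
    out["r1"] = R1;
    out["r2"] = R2;
  }
  return out;
}
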