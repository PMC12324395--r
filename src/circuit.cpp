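// Continuous-attractor grid sheet with an entorhinal-hippocampal loop:
// delayed online-pseudoinverse (RLS) plasticity from hippocampus to grid,
// heteroassociative sensory anchoring, and two-timescale consolidation.
// The attractor follows the classic purely inhibitory difference-of-
// Gaussians construction with four interleaved direction preferences and
// a small outgoing-weight shift along each preference.

#include <RcppArmadillo.h>
#include <deque>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GridNet {
  int n;                 // sheet side
  double a_amp, beta_k, gamma_k, alpha, dt, w_amp;
  int ell, krad;
  vec kg, kb;            // 1D Gaussian kernel taps (gamma, beta)
  mat s;                 // activity, n x n
  imat dirx, diry;       // preferred direction per neuron
  mat env;               // aperiodic envelope
  mat u, t1, t2, tmp;    // work buffers

  GridNet(int n_, double lambda, double alpha_, int ell_, double dt_,
          double w_amp_ = 3.0)
      : n(n_), a_amp(1.0), alpha(alpha_), dt(dt_), w_amp(w_amp_), ell(ell_) {
    beta_k = 3.0 / (lambda * lambda);
    gamma_k = 1.05 * beta_k;
    krad = std::min(n / 2 - 1, 18);
    kg.set_size(2 * krad + 1);
    kb.set_size(2 * krad + 1);
    for (int k = -krad; k <= krad; ++k) {
      kg(k + krad) = std::exp(-gamma_k * k * k);
      kb(k + krad) = std::exp(-beta_k * k * k);
    }
    s.zeros(n, n);
    u.zeros(n, n); t1.zeros(n, n); t2.zeros(n, n); tmp.zeros(n, n);
    dirx.set_size(n, n); diry.set_size(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        int d = (i % 2) + 2 * (j % 2);  // E, W, N, S
        dirx(i, j) = (d == 0) ? 1 : (d == 1) ? -1 : 0;
        diry(i, j) = (d == 2) ? 1 : (d == 3) ? -1 : 0;
      }
    env.set_size(n, n);
    double R = n / 2.0, dR = n / 4.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double r = std::sqrt(std::pow(i - R + 0.5, 2) +
                             std::pow(j - R + 0.5, 2));
        env(i, j) = (r < R - dR) ? 1.0
          : std::exp(-4.0 * std::pow((r - R + dR) / dR, 2));
      }
  }

  // separable Gaussian convolution via padded buffers (no per-tap modulo);
  // periodic wraps, aperiodic zero-pads
  void conv_sep(const mat& in, const vec& ker, mat& out, bool periodic) {
    const int K = krad, L = n + 2 * K;
    std::vector<double> pad(L);
    const double* kp = ker.memptr();
    // pass 1: along columns (contiguous in memory)
    for (int j = 0; j < n; ++j) {
      const double* col = in.colptr(j);
      for (int i = 0; i < K; ++i) {
        pad[i] = periodic ? col[n - K + i] : 0.0;
        pad[K + n + i] = periodic ? col[i] : 0.0;
      }
      std::copy(col, col + n, pad.begin() + K);
      double* oc = tmp.colptr(j);
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        const double* pp = &pad[i];
        for (int k = 0; k <= 2 * K; ++k) acc += kp[k] * pp[k];
        oc[i] = acc;
      }
    }
    // pass 2: along rows (gather with stride, then dense inner loop)
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < K; ++j) {
        pad[j] = periodic ? tmp(i, n - K + j) : 0.0;
        pad[K + n + j] = periodic ? tmp(i, j) : 0.0;
      }
      for (int j = 0; j < n; ++j) pad[K + j] = tmp(i, j);
      for (int j = 0; j < n; ++j) {
        double acc = 0;
        const double* pp = &pad[j];
        for (int k = 0; k <= 2 * K; ++k) acc += kp[k] * pp[k];
        out(i, j) = acc;
      }
    }
  }

  void step(double vx, double vy, bool periodic) {
    // shifted population activity: u[x] = sum_d s_d[x - ell*e_d]
    u.zeros();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        int ti = i + ell * dirx(i, j), tj = j + ell * diry(i, j);
        if (periodic) { ti = (ti % n + n) % n; tj = (tj % n + n) % n; }
        else if (ti < 0 || ti >= n || tj < 0 || tj >= n) continue;
        u(ti, tj) += s(i, j);
      }
    conv_sep(u, kg, t1, periodic);
    conv_sep(u, kb, t2, periodic);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double w = w_amp * (a_amp * t1(i, j) - t2(i, j));
        double A = periodic ? 1.0 : env(i, j);
        double B = A * (1.0 + alpha * (dirx(i, j) * vx + diry(i, j) * vy));
        double f = w + B;
        if (f < 0) f = 0;
        s(i, j) += dt * (f - s(i, j));
      }
  }

  void warmup(std::mt19937& rng, int aper, int per, double v0) {
    std::uniform_real_distribution<double> ur(0.0, 1.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) s(i, j) = 0.1 * ur(rng);
    for (int t = 0; t < aper; ++t) step(0, 0, false);
    for (int t = 0; t < per; ++t) step(v0, 0, true);
  }
};

// [[Rcpp::export]]
arma::mat grid_warmup_cpp(int n, int seed, int aperiodic_steps = 250,
                          int periodic_steps = 250, double lambda = 13,
                          double alpha = 0.10315, int ell = 2,
                          double dt = 0.5, double v0 = 0.1,
                          double w_amp = 3.0) {
  std::mt19937 rng(seed);
  GridNet net(n, lambda, alpha, ell, dt, w_amp);
  net.warmup(rng, aperiodic_steps, periodic_steps, v0);
  return net.s;
}

// [[Rcpp::export]]
Rcpp::List grid_drift_cpp(int n, int seed, int drift_steps, double vx,
                          double vy, double lambda = 13,
                          double alpha = 0.10315, int ell = 2,
                          double dt = 0.5, double w_amp = 3.0) {
  std::mt19937 rng(seed);
  GridNet net(n, lambda, alpha, ell, dt, w_amp);
  net.warmup(rng, 250, 250, 0.1);
  // settle with zero velocity before measuring
  for (int t = 0; t < 100; ++t) net.step(0, 0, true);
  mat before = net.s;
  for (int t = 0; t < drift_steps; ++t) net.step(vx, vy, true);
  return Rcpp::List::create(Rcpp::Named("before") = before,
                            Rcpp::Named("after") = net.s);
}


// Per-bin 1-p for the circular-rotation shuffle test: fraction of rotated
// traces whose value at the bin is below the observed value.
// [[Rcpp::export]]
Rcpp::NumericVector rotation_score_cpp(Rcpp::NumericVector trace,
                                       Rcpp::IntegerVector offsets) {
  const int n = trace.size(), m = offsets.size();
  std::vector<int> ge(n, 0);
  for (int k = 0; k < m; ++k) {
    const int o = offsets[k] % n;
    for (int i = 0; i < n; ++i) {
      int src = i + o;
      if (src >= n) src -= n;
      if (trace[src] >= trace[i]) ++ge[i];
    }
  }
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 - (double)ge[i] / m;
  return out;
}

static vec relu_vec(const vec& x) {
  vec y = x;
  y.transform([](double v) { return v > 0 ? v : 0.0; });
  return y;
}

// Recursive least-squares (online pseudoinverse) update associating the
// delayed hippocampal state h with the current grid target g.
static void rls_update(mat& W, mat& P, const vec& h, const vec& g) {
  vec ph = P * h;
  double denom = 1.0 + dot(h, ph);
  if (denom < 1e-12) return;
  vec k = ph / denom;
  vec err = g - W * h;
  W += err * k.t();
  P -= k * ph.t();
}

// [[Rcpp::export]]
Rcpp::List run_circuit_cpp(Rcpp::List cfg, int seed) {
  const int n = cfg["n"];
  const int n_h = cfg["n_h"];
  const int n_s = cfg["n_s"];
  const int steps = cfg["steps_per_run"];
  const Rcpp::IntegerVector runs_per_day = cfg["runs_per_day"];
  const int pretrain_runs = cfg["pretrain_runs"];
  const double track_len = cfg["track_length"];
  const Rcpp::NumericVector land_pos = cfg["landmark_pos"];
  const Rcpp::IntegerVector land_side = cfg["landmark_side"]; // 0 L,1 R,2 both
  const int update_period = cfg["update_period"];
  const int relax_steps = cfg["relax_steps"];
  const int tau = cfg["tau"];
  const int tau_c = cfg["tau_c"];
  const double gamma_s = cfg["gamma_s"];
  const double gamma_h = cfg["gamma_h"];
  const int sens_burst = cfg["sens_burst"];
  const double sens_gain = cfg["sens_gain"]; // zone-integrated anchor pull
  const double v_gain = cfg["v_gain"];
  const double vel_noise_sd = cfg["vel_noise_sd"];
  const double sens_noise_sd = cfg["sens_noise_sd"];
  const double whs_eta = cfg["whs_eta"];
  const double rls_delta = cfg["rls_delta"];
  const double sparsity = cfg["sparsity"];
  const bool plastic = cfg["plastic"];
  const Rcpp::IntegerVector record_cells = cfg["record_cells"]; // 1-based
  const int record_bins = cfg["record_bins"];
  const double lambda = cfg["lambda"];
  const double alpha = cfg["alpha"];
  const int ell = cfg["ell"];
  const double dt = cfg["dt"];
  const double w_amp = cfg["w_amp"];
  const int init_aper = cfg["init_aper"];
  const int init_per = cfg["init_per"];

  const int N = n * n;
  std::mt19937 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ur(0.0, 1.0);

  GridNet net(n, lambda, alpha, ell, dt, w_amp);
  net.warmup(rng, init_aper, init_per, 0.1);
  const double theta = 2.0 * M_PI * ur(rng);

  mat W_HG(n_h, N);
  for (auto& x : W_HG) x = nd(rng) / std::sqrt((double)N);
  vec g = vectorise(net.s);
  vec drive = W_HG * g;
  vec sorted = sort(drive, "descend");
  const double b = -sorted((int)std::floor(sparsity * n_h));

  mat W_GH(N, n_h, fill::zeros);
  mat P = eye(n_h, n_h) / rls_delta;
  mat W_HS(n_h, n_s, fill::zeros);

  // sensory dictionaries: one vector per event (landmarks + start + end)
  const int n_land = land_pos.size();
  const int n_events = n_land + 2;
  auto make_env = [&](void) {
    mat sv(n_s, n_events, fill::zeros);
    int half = n_s / 2;
    for (int e = 0; e < n_land; ++e) {
      int lo = (land_side[e] == 1) ? half : 0;
      int hi = (land_side[e] == 0) ? half : n_s;
      for (int i = lo; i < hi; ++i) sv(i, e) = nd(rng);
    }
    for (int e = n_land; e < n_events; ++e)      // track boundaries: strong,
      for (int i = 0; i < n_s; ++i) sv(i, e) = 2.0 * nd(rng); // both sides
    return sv;
  };
  mat sv_pre = make_env();
  mat sv_nov = make_env();

  // per-step sensory zone occupancy (uniform velocity): each landmark is
  // active over its physical span, the track boundaries over the first and
  // last 10 cm
  const double v_track = track_len / steps;       // cm per step
  const double land_width = cfg["landmark_width"];
  std::vector<int> zone(steps, -1);
  for (int t = 0; t < steps; ++t) {
    double pos = t * v_track;
    if (pos <= 10.0) { zone[t] = n_land; continue; }
    if (pos >= track_len - 10.0) { zone[t] = n_land + 1; continue; }
    for (int e = 0; e < n_land; ++e)
      if (pos >= land_pos[e] && pos <= land_pos[e] + land_width) {
        zone[t] = e; break;
      }
  }

  const int buf_len = std::max(tau, 1) + 1;
  mat gbuf(N, buf_len);
  for (int c = 0; c < buf_len; ++c) gbuf.col(c) = vectorise(net.s);
  long step_count = 0;

  struct Snap { mat W; mat P; mat WHS; };
  std::deque<Snap> snaps;  // fast-weight snapshots at end of each run

  const int total_novel = Rcpp::sum(runs_per_day);
  Rcpp::List activity(total_novel);
  vec wnorm(total_novel);
  vec recall_corr(total_novel, fill::zeros);
  Rcpp::IntegerVector day_of_run(total_novel);

  const double cphi = std::cos(theta), sphi = std::sin(theta);
  const int n_rec = record_cells.size();
  uvec rec_idx(n_rec);
  for (int i = 0; i < n_rec; ++i) rec_idx(i) = record_cells[i] - 1;
  const double bin_w = track_len / record_bins;

  double recall_corr_sum = 0; int recall_corr_n = 0;
  auto run_one = [&](const mat& sv, bool learn, bool record,
                     mat* rec_out) {
    mat acc;
    vec cnt;
    recall_corr_sum = 0; recall_corr_n = 0;
    if (record) { acc.zeros(n_rec, record_bins); cnt.zeros(record_bins); }
    for (int t = 0; t < steps; ++t) {
      double vx = v_gain * v_track * cphi + vel_noise_sd * nd(rng);
      double vy = v_gain * v_track * sphi + vel_noise_sd * nd(rng);
      net.step(vx, vy, true);
      g = vectorise(net.s);
      gbuf.col(step_count % buf_len) = g;
      const long del_col = (step_count - tau >= 0)
        ? (step_count - tau) % buf_len : step_count % buf_len;
      bool did_sensory = false;
      int zone_into = -1;
      if (zone[t] >= 0) {
        int into = 0;
        while (t - into - 1 >= 0 && zone[t - into - 1] == zone[t]) ++into;
        zone_into = into;
      }
      // sensory anchoring acts over a short burst after zone entry; the
      // remainder of the zone runs as plain path integration
      if (zone_into >= 0 && zone_into < sens_burst) {
        const int e = zone[t];
        const bool entry = zone_into == 0;
        vec s_vec = sv.col(e);
        for (auto& x : s_vec) x += sens_noise_sd * nd(rng);
        if (entry && learn) {
          // heteroassociative anchor: sensory vector -> current place code
          vec h_place = relu_vec(W_HG * g + b);
          double ss = dot(s_vec, s_vec);
          if (ss > 1e-12)
            W_HS += whs_eta * (h_place - W_HS * s_vec) * s_vec.t() / ss;
        }
        vec h = relu_vec(W_HS * s_vec);
        vec recall = relu_vec(W_GH * h);
        if (norm(recall) > 1e-8) {
          g = (1.0 - sens_gain) * g + sens_gain * recall;
          net.s = reshape(g, n, n);
        }
        if (entry && learn) {
          vec h_del = (tau > 0)
            ? relu_vec(W_HG * gbuf.col(del_col) + b)
            : relu_vec(W_HG * g + b);
          rls_update(W_GH, P, h_del, g);
        }
        did_sensory = true;
      }
      if (!did_sensory && t > 0 && t % update_period == 0) {
        vec h_now = relu_vec(W_HG * g + b);
        if (learn) {
          vec h_del = (tau > 0)
            ? relu_vec(W_HG * gbuf.col(del_col) + b) : h_now;
          rls_update(W_GH, P, h_del, g);
        }
        vec recall = relu_vec(W_GH * h_now);
        if (norm(recall) > 1e-8 && norm(g) > 1e-8) {
          double cc = as_scalar(cor(recall, g));
          if (std::isfinite(cc)) { recall_corr_sum += cc; ++recall_corr_n; }
          g = (1.0 - gamma_h) * g + gamma_h * recall;
          net.s = reshape(g, n, n);
          for (int r = 0; r < relax_steps; ++r) net.step(0, 0, true);
          g = vectorise(net.s);
        }
      }
      ++step_count;
      if (record) {
        int bin = (int)std::floor(t * v_track / bin_w);
        if (bin >= record_bins) bin = record_bins - 1;
        vec gs = vectorise(net.s);
        for (int i = 0; i < n_rec; ++i) acc(i, bin) += gs(rec_idx(i));
        cnt(bin) += 1.0;
      }
    }
    // end-of-run consolidation snapshot (all fast-plastic matrices)
    snaps.push_back(Snap{W_GH, P, W_HS});
    if ((int)snaps.size() > tau_c + 1) snaps.pop_front();
    if (record) {
      for (int bk = 0; bk < record_bins; ++bk)
        if (cnt(bk) > 0) acc.col(bk) /= cnt(bk);
      *rec_out = acc;
    }
  };

  for (int r = 0; r < pretrain_runs; ++r)
    run_one(sv_pre, plastic || true, false, nullptr); // pretrain always learns

  int run_id = 0;
  for (int d = 0; d < runs_per_day.size(); ++d) {
    // session start: fast weights reset to the consolidated (lagged) copy
    if (tau_c > 0 && !snaps.empty()) {
      W_GH = snaps.front().W;
      P = snaps.front().P;
      W_HS = snaps.front().WHS;
    }
    for (int r = 0; r < runs_per_day[d]; ++r) {
      mat rec;
      run_one(sv_nov, plastic, true, &rec);
      activity[run_id] = rec;
      wnorm(run_id) = norm(W_GH, "fro");
      recall_corr(run_id) = recall_corr_n > 0
        ? recall_corr_sum / recall_corr_n : NA_REAL;
      day_of_run[run_id] = d + 1;
      ++run_id;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("activity") = activity,
    Rcpp::Named("weight_norm") = Rcpp::NumericVector(wnorm.begin(), wnorm.end()),
    Rcpp::Named("day_of_run") = day_of_run,
    Rcpp::Named("recall_corr") =
      Rcpp::NumericVector(recall_corr.begin(), recall_corr.end()),
    Rcpp::Named("theta") = theta,
    Rcpp::Named("b") = b,
    Rcpp::Named("sheet") = net.s);
}
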