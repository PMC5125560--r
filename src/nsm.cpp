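// Event-driven simulators: modified next subvolume method (NSM) over a
// static crowded lattice, and a direct-method SSA of the effective
// two-state well-mixed model.  Only the transcription factor diffuses;
// chromatin and crowding agents are static, and mRNA/protein are global
// counters produced at the gene voxel.  Time unit: minutes.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64 (fast, reproducible, independent
// of R's global RNG state; seeds are passed in explicitly).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Exp(1)
  inline double expo() { return -std::log1p(-unif()); }
};

// ---------------------------------------------------------------------------
// Indexed binary min-heap over per-voxel tentative event times.
struct VoxelHeap {
  int n;
  std::vector<double> tau;   // key per voxel
  std::vector<int> heap;     // heap position -> voxel
  std::vector<int> pos;      // voxel -> heap position
  explicit VoxelHeap(int n_) : n(n_), tau(n_, R_PosInf), heap(n_), pos(n_) {
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  inline void swap_at(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void sift_up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (tau[heap[i]] < tau[heap[p]]) { swap_at(i, p); i = p; }
      else break;
    }
  }
  void sift_down(int i) {
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && tau[heap[l]] < tau[heap[m]]) m = l;
      if (r < n && tau[heap[r]] < tau[heap[m]]) m = r;
      if (m == i) break;
      swap_at(i, m); i = m;
    }
  }
  void update(int v, double t) {
    double old = tau[v];
    tau[v] = t;
    if (t < old) sift_up(pos[v]); else sift_down(pos[v]);
  }
  inline int top() const { return heap[0]; }
};

// ---------------------------------------------------------------------------
// NSM over the lattice.  Voxels are 0-based here (R wrappers shift).
// Propensity channels at the gene voxel, in order:
//   0 bind (k_on_eff, TF free at gene), 1 unbind (k_off, bound),
//   2 transcribe (s_A active / s_R repressed), 3 mRNA decay,
//   4 translate, 5 protein decay; then up to 6 TF diffusion directions.
// [[Rcpp::export]]
List cpp_nsm_run(IntegerVector dims, NumericVector hvec,
                 NumericVector cfield, NumericVector delta,
                 double D0,
                 double k_on, double k_off, double s_A, double s_R,
                 double s_P, double d_M, double d_P,
                 int gene, int tf0, bool bound0, bool kon_scaled,
                 double t_end, double sample_dt, double seed,
                 double max_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  if (gene < 0 || gene >= N) stop("gene voxel out of bounds");
  if (cfield[gene] >= 1.0) stop("gene voxel is fully blocked (c = 1)");
  if (!bound0 && (tf0 < 0 || tf0 >= N)) stop("TF start voxel out of bounds");
  if (!bound0 && cfield[tf0] >= 1.0) stop("TF start voxel is fully blocked");

  const double inv_h2[3] = {1.0 / (hvec[0] * hvec[0]),
                            1.0 / (hvec[1] * hvec[1]),
                            1.0 / (hvec[2] * hvec[2])};

  // static per-voxel outbound diffusion rates (destination-dependent)
  std::vector<double> out_rate(static_cast<size_t>(N) * 6, 0.0);
  std::vector<int> out_nb(static_cast<size_t>(N) * 6, -1);
  std::vector<double> out_tot(N, 0.0);
  for (int z = 0, v = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v) {
        const int nb[6] = {
          x > 0      ? v - 1       : -1,
          x < nx - 1 ? v + 1       : -1,
          y > 0      ? v - nx      : -1,
          y < ny - 1 ? v + nx      : -1,
          z > 0      ? v - nx * ny : -1,
          z < nz - 1 ? v + nx * ny : -1};
        for (int d = 0; d < 6; ++d) {
          int w = nb[d];
          out_nb[6 * v + d] = w;
          if (w >= 0) {
            double r = D0 * (1.0 - cfield[w]) * delta[w] * inv_h2[d / 2];
            out_rate[6 * v + d] = r;
            out_tot[v] += r;
          }
        }
      }

  const double kon_eff = kon_scaled ? k_on * N : k_on;

  // state
  bool bound = bound0;
  int tf = bound ? gene : tf0;
  long long M = 0, P = 0;

  Xoshiro rng(static_cast<uint64_t>(seed));
  VoxelHeap hp(N);
  double t = 0.0;

  // propensity of one voxel under the current state
  auto voxel_propensity = [&](int v) -> double {
    double a = 0.0;
    if (v == gene) {
      if (bound) a += k_off + s_A;
      else {
        a += s_R;
        if (tf == gene) a += kon_eff;
      }
      a += d_M * M + s_P * M + d_P * P;
    }
    if (!bound && tf == v) a += out_tot[v];
    return a;
  };
  auto rekey = [&](int v) {
    double a = voxel_propensity(v);
    hp.update(v, a > 0.0 ? t + rng.expo() / a : R_PosInf);
  };
  rekey(gene);
  if (!bound && tf != gene) rekey(tf);

  // sampling grid
  const int nsamp = static_cast<int>(std::floor(t_end / sample_dt + 1e-9)) + 1;
  NumericVector samp_t(nsamp);
  IntegerVector samp_M(nsamp), samp_P(nsamp), samp_prom(nsamp), samp_tf(nsamp);
  int isamp = 0;
  auto record_until = [&](double tnext) {
    while (isamp < nsamp && isamp * sample_dt <= tnext + 1e-12) {
      samp_t[isamp] = isamp * sample_dt;
      samp_M[isamp] = static_cast<int>(M);
      samp_P[isamp] = static_cast<int>(P);
      samp_prom[isamp] = bound ? 1 : 0;
      samp_tf[isamp] = tf;
      ++isamp;
    }
  };

  std::vector<double> sw_t;
  std::vector<int> sw_s;
  double n_events = 0.0;

  for (;;) {
    int v = hp.top();
    double tnext = hp.tau[v];
    if (tnext > t_end || !R_finite(tnext)) break;
    record_until(tnext);
    t = tnext;
    n_events += 1.0;
    if (n_events > max_events)
      stop("event budget exceeded (%.0f events before t = %g)", max_events, t);
    if (static_cast<long long>(n_events) % 4194304 == 0)
      Rcpp::checkUserInterrupt();

    // channel selection within voxel v
    double chem[6] = {0, 0, 0, 0, 0, 0};
    if (v == gene) {
      if (!bound && tf == gene) chem[0] = kon_eff;
      if (bound) chem[1] = k_off;
      chem[2] = bound ? s_A : s_R;
      chem[3] = d_M * M;
      chem[4] = s_P * M;
      chem[5] = d_P * P;
    }
    double chem_tot = chem[0] + chem[1] + chem[2] + chem[3] + chem[4] + chem[5];
    double diff_tot = (!bound && tf == v) ? out_tot[v] : 0.0;
    double a_tot = chem_tot + diff_tot;
    if (a_tot <= 0.0) { rekey(v); continue; }  // stale key; redraw
    double u = rng.unif() * a_tot;

    if (u < chem_tot) {
      int ch = 0;
      double acc = chem[0];
      while (u >= acc && ch < 5) acc += chem[++ch];
      switch (ch) {
      case 0:  // bind: TF + repressed -> active
        bound = true; tf = gene;
        sw_t.push_back(t); sw_s.push_back(1);
        break;
      case 1:  // unbind: TF released at the gene voxel
        bound = false; tf = gene;
        sw_t.push_back(t); sw_s.push_back(0);
        break;
      case 2: ++M; break;
      case 3: --M; break;
      case 4: ++P; break;
      case 5: --P; break;
      }
      rekey(v);
    } else {
      // TF diffusion out of v
      double ud = u - chem_tot;
      int d = 0;
      double acc = out_rate[6 * v + 0];
      while (ud >= acc && d < 5) acc += out_rate[6 * v + ++d];
      int w = out_nb[6 * v + d];
      // (w >= 0 and rate > 0 guaranteed by construction of out_rate)
      tf = w;
      rekey(v);
      rekey(w);
    }
  }
  record_until(t_end);

  return List::create(
    _["time"] = samp_t, _["M"] = samp_M, _["P"] = samp_P,
    _["promoter"] = samp_prom, _["tf_voxel"] = samp_tf,
    _["switch_time"] = NumericVector(sw_t.begin(), sw_t.end()),
    _["switch_state"] = IntegerVector(sw_s.begin(), sw_s.end()),
    _["n_events"] = n_events);
}

// ---------------------------------------------------------------------------
// Direct-method SSA of the effective two-state well-mixed model.
// [[Rcpp::export]]
List cpp_ssa_wellmixed(double k_plus, double k_minus,
                       double s_A, double s_R, double s_P,
                       double d_M, double d_P,
                       bool active0, int M0, int P0,
                       double t_end, double sample_dt, double seed) {
  bool active = active0;
  long long M = M0, P = P0;
  Xoshiro rng(static_cast<uint64_t>(seed));

  const int nsamp = static_cast<int>(std::floor(t_end / sample_dt + 1e-9)) + 1;
  NumericVector samp_t(nsamp);
  IntegerVector samp_M(nsamp), samp_P(nsamp), samp_prom(nsamp);
  int isamp = 0;
  auto record_until = [&](double tnext) {
    while (isamp < nsamp && isamp * sample_dt <= tnext + 1e-12) {
      samp_t[isamp] = isamp * sample_dt;
      samp_M[isamp] = static_cast<int>(M);
      samp_P[isamp] = static_cast<int>(P);
      samp_prom[isamp] = active ? 1 : 0;
      ++isamp;
    }
  };

  std::vector<double> sw_t;
  std::vector<int> sw_s;
  double t = 0.0, n_events = 0.0;
  for (;;) {
    double a[6] = {active ? 0.0 : k_plus,
                   active ? k_minus : 0.0,
                   active ? s_A : s_R,
                   d_M * M, s_P * M, d_P * P};
    double a_tot = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    if (a_tot <= 0.0) break;
    double tnext = t + rng.expo() / a_tot;
    if (tnext > t_end) break;
    record_until(tnext);
    t = tnext;
    n_events += 1.0;
    if (static_cast<long long>(n_events) % 4194304 == 0)
      Rcpp::checkUserInterrupt();
    double u = rng.unif() * a_tot;
    int ch = 0;
    double acc = a[0];
    while (u >= acc && ch < 5) acc += a[++ch];
    switch (ch) {
    case 0: active = true;  sw_t.push_back(t); sw_s.push_back(1); break;
    case 1: active = false; sw_t.push_back(t); sw_s.push_back(0); break;
    case 2: ++M; break;
    case 3: --M; break;
    case 4: ++P; break;
    case 5: --P; break;
    }
  }
  record_until(t_end);

  return List::create(
    _["time"] = samp_t, _["M"] = samp_M, _["P"] = samp_P,
    _["promoter"] = samp_prom,
    _["tf_voxel"] = IntegerVector(nsamp, NA_INTEGER),
    _["switch_time"] = NumericVector(sw_t.begin(), sw_t.end()),
    _["switch_state"] = IntegerVector(sw_s.begin(), sw_s.end()),
    _["n_events"] = n_events);
}
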