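#include <Rcpp.h>
using namespace Rcpp;

// 1D lattice stochastic simulation of the ParA2 nucleoid cycle.
// Species per site: 0 DD (ADP dimer), 1 D (apo), 2 DT (closed ATP dimer),
// 3 DS (active D*-ATP), 4 B (nucleoid-bound). Species 0-3 diffuse with a
// common hop rate; B is (nearly) immobile. Reflecting boundaries.
//
// Per-site reaction channels:
//  D  -> DT   k_bind        (k1 * [ATP])
//  DT -> D    k_unbind      (k_minus1)
//  DT -> DS   k_remodel     (k2)
//  DS -> B    k_on * (1 + (omega-1) * fnb) * (1 - B_i/cap)   [fnb: local
//             occupancy of sites i-1, i, i+1 relative to capacity]
//  B  -> DS   k_off         (k_minus3)
//  B  -> DD   k_hyd * focus_i  (bulk DNA-stimulated hydrolysis, boosted at the focus)
//  DD -> D    k_adp_release (k_minus5)
//  DD -> DT   k_exch        (k6_adp_to_atp * [ATP])
//
// Exact direct-method SSA; propensities are updated locally after each event.

static inline double site_prop(const IntegerMatrix& x, int i, int N,
                               double k_bind, double k_unbind,
                               double k_remodel, double k_on, double omega,
                               double cap, double k_off,
                               const NumericVector& k_hyd_site,
                               double k_adp_release, double k_exch,
                               double hop, double hop_b, double* chan) {
  int DD = x(0, i), D = x(1, i), DT = x(2, i), DS = x(3, i), B = x(4, i);
  double bl = (i > 0) ? x(4, i - 1) : x(4, i);
  double br = (i < N - 1) ? x(4, i + 1) : x(4, i);
  double fnb = (bl + x(4, i) + br) / (3.0 * cap);
  if (fnb > 1.0) fnb = 1.0;
  // nearest-neighbour pair cooperativity: recruitment scales with the
  // probability that the flanking footprints are occupied (two-dimer
  // loading unit), i.e. quadratically in the local occupancy
  double coop = 1.0 + (omega - 1.0) * fnb * fnb;
  double avail = 1.0 - (double)B / cap;
  if (avail < 0.0) avail = 0.0;
  chan[0] = k_bind * D;
  chan[1] = k_unbind * DT;
  chan[2] = k_remodel * DT;
  chan[3] = k_on * coop * avail * DS;
  chan[4] = k_off * B;
  chan[5] = k_hyd_site[i] * B;
  chan[6] = k_adp_release * DD;
  chan[7] = k_exch * DD;
  // hops: left and right for species 0..3, plus B with hop_b
  double nleft = (i > 0) ? hop : 0.0;
  double nright = (i < N - 1) ? hop : 0.0;
  chan[8] = nleft * DD;   chan[9] = nright * DD;
  chan[10] = nleft * D;   chan[11] = nright * D;
  chan[12] = nleft * DT;  chan[13] = nright * DT;
  chan[14] = nleft * DS;  chan[15] = nright * DS;
  chan[16] = (i > 0 ? hop_b : 0.0) * B;
  chan[17] = (i < N - 1 ? hop_b : 0.0) * B;
  double s = 0.0;
  for (int c = 0; c < 18; ++c) s += chan[c];
  return s;
}

// [[Rcpp::export]]
List spatial_ssa_cpp(IntegerMatrix init, double t_end, double dt_record,
                     double k_bind, double k_unbind, double k_remodel,
                     double k_on, double omega, double cap, double k_off,
                     NumericVector k_hyd_site, double k_adp_release,
                     double k_exch, double hop, double hop_b, int seed) {
  int N = init.ncol();
  IntegerMatrix x = clone(init);
  int n_frames = (int)std::floor(t_end / dt_record) + 1;
  IntegerMatrix bound(n_frames, N);
  NumericMatrix cyto(n_frames, N);
  NumericVector frame_t(n_frames);

  std::vector<double> chan(18);
  std::vector<double> site_sum(N);
  std::vector<double> chans(N * 18);
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    site_sum[i] = site_prop(x, i, N, k_bind, k_unbind, k_remodel, k_on,
                            omega, cap, k_off, k_hyd_site, k_adp_release,
                            k_exch, hop, hop_b, &chans[i * 18]);
    total += site_sum[i];
  }

  // xoshiro-free: use R's RNG for reproducibility under set.seed
  Environment base("package:base");
  Function set_seed = base["set.seed"];
  set_seed(seed);
  GetRNGstate();

  double t = 0.0;
  int frame = 0;
  long long n_events = 0;
  bool exhausted = false;

  auto record = [&](double tt) {
    while (frame < n_frames && frame * dt_record <= tt + 1e-12) {
      frame_t[frame] = frame * dt_record;
      for (int i = 0; i < N; ++i) {
        bound(frame, i) = x(4, i);
        cyto(frame, i) = x(0, i) + x(1, i) + x(2, i) + x(3, i);
      }
      ++frame;
    }
  };

  auto refresh = [&](int i) {
    total -= site_sum[i];
    site_sum[i] = site_prop(x, i, N, k_bind, k_unbind, k_remodel, k_on,
                            omega, cap, k_off, k_hyd_site, k_adp_release,
                            k_exch, hop, hop_b, &chans[i * 18]);
    total += site_sum[i];
  };

  while (t < t_end) {
    if (total <= 1e-13) { exhausted = true; break; }
    double dt = R::rexp(1.0 / total);
    double t_next = t + dt;
    record(std::min(t_next, t_end));
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;
    // pick site
    double u = unif_rand() * total;
    int i = 0;
    double acc = 0.0;
    for (; i < N; ++i) {
      acc += site_sum[i];
      if (u <= acc) break;
    }
    if (i >= N) i = N - 1;
    // pick channel within site
    double v = unif_rand() * site_sum[i];
    double* ch = &chans[i * 18];
    int c = 0;
    double a2 = 0.0;
    for (; c < 18; ++c) {
      a2 += ch[c];
      if (v <= a2) break;
    }
    if (c >= 18) c = 17;
    bool b_changed = false;
    int j = i;  // neighbour target for hops
    switch (c) {
      case 0: x(1, i)--; x(2, i)++; break;
      case 1: x(2, i)--; x(1, i)++; break;
      case 2: x(2, i)--; x(3, i)++; break;
      case 3: x(3, i)--; x(4, i)++; b_changed = true; break;
      case 4: x(4, i)--; x(3, i)++; b_changed = true; break;
      case 5: x(4, i)--; x(0, i)++; b_changed = true; break;
      case 6: x(0, i)--; x(1, i)++; break;
      case 7: x(0, i)--; x(2, i)++; break;
      case 8:  x(0, i)--; x(0, i - 1)++; j = i - 1; break;
      case 9:  x(0, i)--; x(0, i + 1)++; j = i + 1; break;
      case 10: x(1, i)--; x(1, i - 1)++; j = i - 1; break;
      case 11: x(1, i)--; x(1, i + 1)++; j = i + 1; break;
      case 12: x(2, i)--; x(2, i - 1)++; j = i - 1; break;
      case 13: x(2, i)--; x(2, i + 1)++; j = i + 1; break;
      case 14: x(3, i)--; x(3, i - 1)++; j = i - 1; break;
      case 15: x(3, i)--; x(3, i + 1)++; j = i + 1; break;
      case 16: x(4, i)--; x(4, i - 1)++; j = i - 1; b_changed = true; break;
      case 17: x(4, i)--; x(4, i + 1)++; j = i + 1; b_changed = true; break;
    }
    ++n_events;
    refresh(i);
    if (j != i) refresh(j);
    if (b_changed) {  // kon at neighbours depends on B here
      if (i > 0) refresh(i - 1);
      if (i < N - 1) refresh(i + 1);
      if (j != i) {
        if (j > 0 && j - 1 != i) refresh(j - 1);
        if (j < N - 1 && j + 1 != i) refresh(j + 1);
      }
    }
  }
  record(t_end);
  PutRNGstate();

  return List::create(_["time"] = frame_t, _["bound"] = bound,
                      _["cyto"] = cyto, _["final"] = x,
                      _["n_events"] = (double)n_events,
                      _["exhausted"] = exhausted);
}
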