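#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Counter-based per-trajectory RNG: xoshiro256++ seeded through splitmix64
// from (master seed, trajectory index), so ensembles are reproducible and
// order-independent regardless of R's RNG state.
namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)

  double unif_pos() {  // (0, 1)
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }

  double norm() {  // Box-Muller with cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif_pos(), u2 = unif();
    double rad = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = rad * std::sin(th);
    has_spare = true;
    return rad * std::cos(th);
  }

  double rexp(double mean) { return -mean * std::log(unif_pos()); }
};

inline bool inside_spherocyl(double x, double y, double z, double a, double rc2) {
  double ax = std::fabs(x);
  if (ax <= a) return y * y + z * z <= rc2;
  double dx = ax - a;
  return dx * dx + y * y + z * z <= rc2;
}

}  // namespace

// Forward simulation of an ensemble of two-state walkers confined in a
// spherocylinder, observed at the camera frame interval with motion blur
// and state-dependent Gaussian localization noise.
//
// Units: lengths in micrometres, times in milliseconds, D in um^2/s.
// fixed_state: per-trajectory -1 (draw per model), 0 = free, 1 = bound.
// init_x: per-trajectory initial axial position (NaN = uniform in cell).
// [[Rcpp::export(name = ".simEnsembleCpp")]]
List simEnsembleCpp(int n_traj, int n_frames,
                    double frame_interval, double exposure, int n_sub,
                    double total_length, double diameter,
                    double D_slow, double D_fast, double f_slow,
                    double tau_free, double tau_bound,
                    double sigma_slow, double sigma_fast,
                    bool exchange, bool blur, bool confine,
                    int max_redraws, double seed,
                    NumericVector init_x, IntegerVector fixed_state,
                    IntegerVector init_state, bool return_hidden) {
  const double a = (total_length - diameter) / 2.0;
  const double rc = diameter / 2.0;
  const double rc2 = rc * rc;
  const double half_L = total_length / 2.0;
  // substeps span the exposure; any frame-interval remainder is dead time
  const double dt_sub_ms = exposure / n_sub;
  const double dt_sub_s = dt_sub_ms * 1e-3;
  const double dead_time = frame_interval - exposure;

  (void)max_redraws;  // retained in the interface; stay-style confinement never loops
  NumericMatrix obs_x(n_frames, n_traj), obs_y(n_frames, n_traj);
  IntegerMatrix state_major(n_frames, n_traj);
  List hidden(return_hidden ? n_traj : 0);

  const uint64_t master = (uint64_t)((int64_t)std::llround(seed));

  for (int tr = 0; tr < n_traj; ++tr) {
    Xoshiro rng(master * 0x9E3779B97F4A7C15ULL + (uint64_t)(tr + 1));

    // initial position
    double x, y, z;
    bool have_init_x = init_x.size() == n_traj && !ISNAN(init_x[tr]);
    if (have_init_x) {
      x = init_x[tr];
      double ax = std::fabs(x);
      double rmax = ax <= a ? rc : std::sqrt(std::max(0.0, rc2 - (ax - a) * (ax - a)));
      double rr = rmax * std::sqrt(rng.unif());
      double th = 6.283185307179586 * rng.unif();
      y = rr * std::cos(th);
      z = rr * std::sin(th);
    } else {
      do {
        x = (rng.unif() - 0.5) * total_length;
        y = (rng.unif() - 0.5) * diameter;
        z = (rng.unif() - 0.5) * diameter;
      } while (!inside_spherocyl(x, y, z, a, rc2));
    }

    // initial state and exchange schedule
    int fs = fixed_state.size() == n_traj ? fixed_state[tr] : -1;
    int is0 = init_state.size() == n_traj ? init_state[tr] : -1;
    int state;       // 1 = bound (slow), 0 = free (fast)
    bool do_exchange = exchange && fs < 0;
    if (fs >= 0) {
      state = fs;
    } else if (is0 >= 0) {
      state = is0;   // forced initial state; exchange continues
    } else {
      state = rng.unif() < f_slow ? 1 : 0;
    }
    double t_switch = R_PosInf;
    double t_now = 0.0;
    if (do_exchange)
      t_switch = rng.rexp(state == 1 ? tau_bound : tau_free);

    NumericMatrix hid;
    if (return_hidden) hid = NumericMatrix(n_frames * n_sub, 4);

    for (int k = 0; k < n_frames; ++k) {
      double base_x = x, base_y = y;
      double sum_x = 0.0, sum_y = 0.0;
      int bound_subs = 0;
      int state_at_start = state;

      for (int j = 0; j < n_sub; ++j) {
        // advance exchange schedule to the start of this substep
        while (do_exchange && t_switch <= t_now) {
          state = 1 - state;
          t_switch += rng.rexp(state == 1 ? tau_bound : tau_free);
        }
        double D = state == 1 ? D_slow : D_fast;
        double sd = std::sqrt(2.0 * D * dt_sub_s);
        // Metropolis-style confinement: a proposal leaving the cell is
        // rejected and the walker stays put for this substep; with a
        // symmetric proposal this preserves the uniform equilibrium
        // exactly (redrawing until inside does not).
        double nx = x + sd * rng.norm();
        double ny = y + sd * rng.norm();
        double nz = z + sd * rng.norm();
        if (!confine || inside_spherocyl(nx, ny, nz, a, rc2)) {
          x = nx; y = ny; z = nz;
        }
        sum_x += x; sum_y += y;
        if (state == 1) ++bound_subs;
        if (return_hidden) {
          int row = k * n_sub + j;
          hid(row, 0) = x; hid(row, 1) = y; hid(row, 2) = z;
          hid(row, 3) = state;
        }
        t_now += dt_sub_ms;
      }
      // dead time between exposure end and next frame start
      if (dead_time > 0.0) {
        while (do_exchange && t_switch <= t_now + dead_time) {
          state = 1 - state;
          t_switch += rng.rexp(state == 1 ? tau_bound : tau_free);
        }
        double D = state == 1 ? D_slow : D_fast;
        double sd = std::sqrt(2.0 * D * dead_time * 1e-3);
        double nx = x + sd * rng.norm();
        double ny = y + sd * rng.norm();
        double nz = z + sd * rng.norm();
        if (!confine || inside_spherocyl(nx, ny, nz, a, rc2)) {
          x = nx; y = ny; z = nz;
        }
        t_now += dead_time;
      }

      // majority-occupancy state of the frame; exact tie -> state at frame start
      int maj;
      if (2 * bound_subs > n_sub) maj = 1;
      else if (2 * bound_subs < n_sub) maj = 0;
      else maj = state_at_start;
      state_major(k, tr) = maj;

      double sig = maj == 1 ? sigma_slow : sigma_fast;
      double mx = blur ? sum_x / n_sub : base_x;
      double my = blur ? sum_y / n_sub : base_y;
      obs_x(k, tr) = mx + sig * rng.norm();
      obs_y(k, tr) = my + sig * rng.norm();
    }
    if (return_hidden) hidden[tr] = hid;

    (void)half_L;
  }

  List out = List::create(_["x"] = obs_x, _["y"] = obs_y,
                          _["state"] = state_major);
  if (return_hidden) out["hidden"] = hidden;
  return out;
}
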