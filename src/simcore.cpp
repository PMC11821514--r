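// Brownian-dynamics core for receptor-subcomplex particles around a static
// cargo body.  Reduced units: particle diameter = 1, kT = 1, d^2/D = 1 time.
// All randomness comes from R's RNG (RNGScope), so set.seed() in R gives
// bit-reproducible trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  int dim;
  double L;               // box edge, box is [0, L]^dim
  double Rc;              // cargo radius
  std::vector<double> cc; // cargo centre
  double eps_AA, eps_AC, beta;
  int n_max;
  double r0, a, a_cargo, r_cut, r_nb, r_bind, r_p;
  double D, dt;
};

Params unpack(const List& p) {
  Params q;
  q.dim = as<int>(p["dim"]);
  q.L = as<double>(p["box_size"]);
  q.Rc = as<double>(p["cargo_radius"]);
  NumericVector cc = p["cargo_center"];
  q.cc.assign(cc.begin(), cc.end());
  q.eps_AA = as<double>(p["eps_AA"]);
  q.eps_AC = as<double>(p["eps_AC"]);
  q.beta = as<double>(p["avidity_gain"]);
  q.n_max = as<int>(p["avidity_cap"]);
  q.r0 = as<double>(p["r0"]);
  q.a = as<double>(p["a"]);
  q.a_cargo = as<double>(p["a_cargo"]);
  q.r_cut = as<double>(p["r_cut"]);
  q.r_nb = as<double>(p["r_nb"]);
  q.r_bind = as<double>(p["r_bind"]);
  q.r_p = as<double>(p["particle_radius"]);
  q.D = as<double>(p["D"]);
  q.dt = as<double>(p["dt"]);
  return q;
}

// Truncated-shifted Morse well: U(r) = eps*((1-e^{-a(r-r0)})^2 - 1) - U_raw(r_cut)
// for r < r_cut, 0 beyond.  Force is -dU/dr (positive = repulsive).
inline double morse_force(double r, double eps, double r0, double a,
                          double r_cut) {
  if (r >= r_cut || eps == 0.0) return 0.0;
  const double e = std::exp(-a * (r - r0));
  return -2.0 * a * eps * e * (1.0 - e);
}

inline double morse_energy(double r, double eps, double r0, double a,
                           double r_cut) {
  if (r >= r_cut || eps == 0.0) return 0.0;
  const double e = std::exp(-a * (r - r0));
  const double ec = std::exp(-a * (r_cut - r0));
  return eps * ((1.0 - e) * (1.0 - e) - 1.0) -
         eps * ((1.0 - ec) * (1.0 - ec) - 1.0);
}

// Flat cell list (head/next arrays, no per-step heap churn).
struct CellList {
  int dim, nc, ncells;
  double edge;
  std::vector<int> head, nxt;

  void init(int n, const Params& p, double r_range) {
    dim = p.dim;
    nc = std::max(1, (int)std::floor(p.L / r_range));
    edge = p.L / nc;
    ncells = 1;
    for (int d = 0; d < dim; ++d) ncells *= nc;
    head.assign(ncells, -1);
    nxt.assign(n, -1);
  }
  inline int cell_of(const double* x) const {
    int idx = 0;
    for (int d = 0; d < dim; ++d) {
      int c = (int)std::floor(x[d] / edge);
      if (c < 0) c = 0;
      if (c >= nc) c = nc - 1;
      idx = idx * nc + c;
    }
    return idx;
  }
  void build(const std::vector<double>& x, int n) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(&x[(size_t)i * dim]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Core force/neighbour evaluation on flat position array x (n x dim,
// row-major).  method: 0 = cell list, 1 = all pairs.
struct Evaluator {
  Params p;
  int n, method;
  CellList cl;
  std::vector<double> forces, gap;
  std::vector<int> nb;

  void init(int n_, const Params& p_, int method_) {
    p = p_;
    n = n_;
    method = method_;
    forces.assign((size_t)n * p.dim, 0.0);
    nb.assign(n, 0);
    gap.assign(n, 0.0);
    if (method == 0) cl.init(n, p, std::max(p.r_cut, p.r_nb));
  }

  inline void pair(const std::vector<double>& x, int i, int j,
                   double rr2, double rnb2) {
    double d2 = 0.0, dx[3];
    for (int d = 0; d < p.dim; ++d) {
      dx[d] = x[(size_t)i * p.dim + d] - x[(size_t)j * p.dim + d];
      d2 += dx[d] * dx[d];
    }
    if (d2 > rr2) return;
    if (d2 <= rnb2) { ++nb[i]; ++nb[j]; }
    if (p.eps_AA != 0.0 && d2 < p.r_cut * p.r_cut && d2 > 0.0) {
      double r = std::sqrt(d2);
      double f = morse_force(r, p.eps_AA, p.r0, p.a, p.r_cut) / r;
      for (int d = 0; d < p.dim; ++d) {
        forces[(size_t)i * p.dim + d] += f * dx[d];
        forces[(size_t)j * p.dim + d] -= f * dx[d];
      }
    }
  }

  void eval(const std::vector<double>& x) {
    std::fill(forces.begin(), forces.end(), 0.0);
    std::fill(nb.begin(), nb.end(), 0);
    const double r_range = std::max(p.r_cut, p.r_nb);
    const double rr2 = r_range * r_range, rnb2 = p.r_nb * p.r_nb;

    if (method == 1) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair(x, i, j, rr2, rnb2);
    } else {
      cl.build(x, n);
      const int nc = cl.nc;
      int c[3], o[3];
      for (int idx = 0; idx < cl.ncells; ++idx) {
        if (cl.head[idx] < 0) continue;
        int t = idx;
        for (int d = p.dim - 1; d >= 0; --d) { c[d] = t % nc; t /= nc; }
        int noff = 1;
        for (int d = 0; d < p.dim; ++d) noff *= 3;
        for (int k = 0; k < noff; ++k) {
          int kk = k, jdx = 0;
          bool ok = true;
          for (int d = 0; d < p.dim; ++d) { o[d] = kk % 3 - 1; kk /= 3; }
          for (int d = 0; d < p.dim; ++d) {
            int cd = c[d] + o[d];
            if (cd < 0 || cd >= nc) { ok = false; break; }
            jdx = jdx * nc + cd;
          }
          if (!ok || jdx < idx) continue;  // each unordered cell pair once
          if (jdx == idx) {
            for (int i = cl.head[idx]; i >= 0; i = cl.nxt[i])
              for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j])
                pair(x, i, j, rr2, rnb2);
          } else {
            for (int i = cl.head[idx]; i >= 0; i = cl.nxt[i])
              for (int j = cl.head[jdx]; j >= 0; j = cl.nxt[j])
                pair(x, i, j, rr2, rnb2);
          }
        }
      }
    }

    // cargo coupling: Morse on the surface gap s = |x-c| - Rc, minimum at r_p
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int d = 0; d < p.dim; ++d) {
        double dd = x[(size_t)i * p.dim + d] - p.cc[d];
        d2 += dd * dd;
      }
      double dc = std::sqrt(d2);
      double s = dc - p.Rc;
      gap[i] = s;
      if (p.eps_AC != 0.0 && s < p.r_cut && dc > 1e-12) {
        int ncnt = nb[i] < p.n_max ? nb[i] : p.n_max;
        double eps_eff = p.eps_AC * (1.0 + p.beta * ncnt);
        double f = morse_force(s, eps_eff, p.r_p, p.a_cargo, p.r_cut) / dc;
        for (int d = 0; d < p.dim; ++d)
          forces[(size_t)i * p.dim + d] += f * (x[(size_t)i * p.dim + d] - p.cc[d]);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_morse(NumericVector r, double eps, double r0, double a,
                        double r_cut) {
  int n = r.size();
  NumericVector out(2 * n);
  for (int i = 0; i < n; ++i) {
    out[i] = morse_energy(r[i], eps, r0, a, r_cut);
    out[n + i] = morse_force(r[i], eps, r0, a, r_cut);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix positions, List params, int method) {
  Params p = unpack(params);
  const int n = positions.nrow();
  std::vector<double> x((size_t)n * p.dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < p.dim; ++d) x[(size_t)i * p.dim + d] = positions(i, d);
  Evaluator ev;
  ev.init(n, p, method);
  ev.eval(x);
  NumericMatrix forces(n, p.dim);
  IntegerVector nb(n);
  NumericVector gap(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < p.dim; ++d) forces(i, d) = ev.forces[(size_t)i * p.dim + d];
    nb[i] = ev.nb[i];
    gap[i] = ev.gap[i];
  }
  return List::create(_["forces"] = forces, _["neighbour_count"] = nb,
                      _["gap"] = gap);
}

// Euler-Maruyama integration with reflecting walls and a reflecting cargo
// hard core.  Saves every `save_every` steps (frame 0 = initial state).
// [[Rcpp::export]]
List cpp_run(NumericMatrix positions, List params, int n_steps,
             int save_every, int method) {
  RNGScope scope;
  Params p = unpack(params);
  const int n = positions.nrow(), dim = p.dim;
  const int n_frames = n_steps / save_every + 1;

  std::vector<double> x((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) x[(size_t)i * dim + d] = positions(i, d);

  Evaluator ev;
  ev.init(n, p, method);

  NumericVector traj((R_xlen_t)n_frames * n * dim);
  IntegerMatrix nb_out(n, n_frames);
  LogicalMatrix bound_out(n, n_frames);
  NumericVector times(n_frames);

  const double noise = std::sqrt(2.0 * p.D * p.dt);
  const double r0sq = p.r0 * p.r0;
  long big_moves = 0;

  ev.eval(x);
  int fr = 0;
  auto save_frame = [&](int frame, double t) {
    times[frame] = t;
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < dim; ++d)
        traj[(R_xlen_t)frame * n * dim + (R_xlen_t)i * dim + d] =
            x[(size_t)i * dim + d];
      nb_out(i, frame) = ev.nb[i];
      bound_out(i, frame) = ev.gap[i] <= p.r_bind;
    }
  };
  save_frame(fr++, 0.0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double disp2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dx = p.D * ev.forces[(size_t)i * dim + d] * p.dt +
                    noise * norm_rand();
        disp2 += dx * dx;
        double xn = x[(size_t)i * dim + d] + dx;
        if (xn < 0.0) xn = -xn;              // reflecting walls
        if (xn > p.L) xn = 2.0 * p.L - xn;
        if (xn < 0.0) xn = 0.0;              // pathological double reflection
        if (xn > p.L) xn = p.L;
        x[(size_t)i * dim + d] = xn;
      }
      if (disp2 > r0sq) ++big_moves;
      // cargo hard core: radial reflection at the surface
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dd = x[(size_t)i * dim + d] - p.cc[d];
        d2 += dd * dd;
      }
      double dc = std::sqrt(d2);
      if (dc < p.Rc) {
        if (dc < 1e-9) {  // at the exact centre: push out along axis 0
          x[(size_t)i * dim + 0] = p.cc[0] + p.Rc;
          for (int d = 1; d < dim; ++d) x[(size_t)i * dim + d] = p.cc[d];
        } else {
          double sc = (2.0 * p.Rc - dc) / dc;
          for (int d = 0; d < dim; ++d)
            x[(size_t)i * dim + d] =
                p.cc[d] + (x[(size_t)i * dim + d] - p.cc[d]) * sc;
        }
      }
    }
    ev.eval(x);
    if (step % save_every == 0) save_frame(fr++, step * p.dt);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  traj.attr("dim") = IntegerVector::create(dim, n, n_frames);
  return List::create(
      _["positions"] = traj, _["neighbour_count"] = nb_out,
      _["cargo_bound"] = bound_out, _["times"] = times,
      _["big_move_fraction"] = (double)big_moves / ((double)n * n_steps));
}
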