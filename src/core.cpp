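#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Potential / diffusion / telegraph dispatch shared by all integrators.
// Energies are handled in units of kBT, positions in micrometres, forces in
// femtoNewtons, times in seconds. Forces convert through kBT (fN um).
// ---------------------------------------------------------------------------

struct PotentialC {
  int type;            // 0 flat, 1 quartic, 2 linear, 3 gaussian traps, 4 tabulated force
  std::vector<double> par;
  std::vector<double> tx, tf; // tabulated force grid (x in um, f in fN)
  double kBT;

  double force_fN(double x) const {
    switch (type) {
    case 0:
      return 0.0;
    case 1: { // U/kBT = a/4 x^4 + b/2 x^2 + c x
      double a = par[0], b = par[1], c = par[2];
      return -(a * x * x * x + b * x + c) * kBT;
    }
    case 2: // constant force, U = -f x
      return par[0];
    case 3: { // sum of inverted Gaussian wells, U/kBT = -sum d exp(-(x-c)^2/2w^2)
      double up = 0.0; // du/dx in kBT/um
      for (size_t k = 0; k + 2 < par.size(); k += 3) {
        double c = par[k], d = par[k + 1], w = par[k + 2];
        double z = (x - c) / w;
        up += d * (x - c) / (w * w) * std::exp(-0.5 * z * z);
      }
      return -up * kBT;
    }
    case 4: { // linear interpolation of tabulated force
      size_t n = tx.size();
      if (x < tx.front() || x > tx.back())
        stop("position %g outside tabulated potential domain [%g, %g]",
             x, tx.front(), tx.back());
      size_t lo = 0, hi = n - 1;
      while (hi - lo > 1) { size_t mid = (lo + hi) / 2; if (tx[mid] <= x) lo = mid; else hi = mid; }
      double w = (x - tx[lo]) / (tx[lo + 1] - tx[lo]);
      return tf[lo] * (1.0 - w) + tf[lo + 1] * w;
    }
    default:
      stop("unknown potential type code");
    }
    return 0.0;
  }
};

static PotentialC as_potential(List p) {
  PotentialC out;
  out.type = as<int>(p["type"]);
  out.kBT = as<double>(p["kBT"]);
  NumericVector par = p["par"];
  out.par.assign(par.begin(), par.end());
  if (out.type == 4) {
    NumericVector tx = p["tx"], tf = p["tf"];
    out.tx.assign(tx.begin(), tx.end());
    out.tf.assign(tf.begin(), tf.end());
  }
  return out;
}

struct DiffusionC {
  int type; // 0 constant, 1 tabulated
  double D0;
  std::vector<double> dx, dv;

  // D(x) and local slope dD/dx (for the kinetic-convention drift correction)
  void eval(double x, double &D, double &Dslope) const {
    if (type == 0) { D = D0; Dslope = 0.0; return; }
    size_t n = dx.size();
    if (x < dx.front() || x > dx.back())
      stop("position %g outside tabulated diffusion domain", x);
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) { size_t mid = (lo + hi) / 2; if (dx[mid] <= x) lo = mid; else hi = mid; }
    double s = (dv[lo + 1] - dv[lo]) / (dx[lo + 1] - dx[lo]);
    D = dv[lo] + s * (x - dx[lo]);
    Dslope = s;
  }
};

static DiffusionC as_diffusion(List d) {
  DiffusionC out;
  out.type = as<int>(d["type"]);
  if (out.type == 0) {
    out.D0 = as<double>(d["D"]);
  } else {
    NumericVector dx = d["x"], dv = d["D"];
    out.dx.assign(dx.begin(), dx.end());
    out.dv.assign(dv.begin(), dv.end());
    out.D0 = dv[0];
  }
  return out;
}

struct TelegraphC {
  bool active;
  double f0, alpha, offset;
  int level;
  double t_next;

  void init(int init_level, double t0) {
    if (!active) return;
    level = init_level != 0 ? init_level : (R::unif_rand() < 0.5 ? 1 : -1);
    t_next = t0 + R::rexp(2.0 / alpha); // per-direction switch rate alpha/2
  }
  void advance(double t) {
    if (!active) return;
    while (t_next <= t) {
      level = -level;
      t_next += R::rexp(2.0 / alpha);
    }
  }
  double force(double) const { return active ? offset + f0 * level : 0.0; }
};

static TelegraphC as_telegraph(SEXP t) {
  TelegraphC out;
  out.active = !Rf_isNull(t);
  out.level = 1; out.t_next = R_PosInf; out.f0 = 0; out.alpha = 1; out.offset = 0;
  if (out.active) {
    List tl(t);
    out.f0 = as<double>(tl["f0"]);
    out.alpha = as<double>(tl["alpha"]);
    out.offset = as<double>(tl["offset"]);
  }
  return out;
}

static inline double reflect(double x, double lo, double hi) {
  // fold back into [lo, hi]; steps are small so one or two folds suffice
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama integration of gamma dx = fext - dU/dx + sqrt(2 kBT gamma) xi
// with gamma(x) = kBT / D(x); kinetic convention adds the dD/dx drift so the
// stationary law matches the Fokker-Planck current j = (f/gamma) rho - D rho'.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(List pot, List dif, SEXP tele, double dt, double n_steps_d,
                  double x0, int stride, NumericVector bounds, int init_level) {
  PotentialC P = as_potential(pot);
  DiffusionC Dp = as_diffusion(dif);
  TelegraphC T = as_telegraph(tele);
  bool has_bounds = bounds.size() == 2;
  double lo = has_bounds ? bounds[0] : 0.0, hi = has_bounds ? bounds[1] : 0.0;

  long long n_steps = (long long)n_steps_d;
  long long n_rec = n_steps / stride + 1;
  NumericVector xr(n_rec);
  NumericVector fr = T.active ? NumericVector(n_rec) : NumericVector(0);

  T.init(init_level, 0.0);
  double x = x0;
  xr[0] = x;
  if (T.active) fr[0] = T.force(0.0);
  double kBT = P.kBT;
  long long ri = 1;

  for (long long k = 0; k < n_steps; ++k) {
    double t = k * dt;
    T.advance(t);
    double D, Ds;
    Dp.eval(x, D, Ds);
    double f_tot = T.force(t) + P.force_fN(x); // fN
    double drift = f_tot * D / kBT + Ds;       // um/s
    x += drift * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
    if (has_bounds) x = reflect(x, lo, hi);
    if ((k + 1) % stride == 0) {
      xr[ri] = x;
      if (T.active) { T.advance((k + 1) * dt); fr[ri] = T.force((k + 1) * dt); }
      ++ri;
    }
  }
  return List::create(_["x"] = xr, _["fext"] = fr,
                      _["x_final"] = x, _["level_final"] = T.level);
}

// First exit from (xl, xr): side -1/+1, 0 if censored at max_steps.
// Crossing times linearly interpolated between the straddling samples.
// [[Rcpp::export]]
List cpp_exit_protocol(List pot, List dif, double xl, double xr, double x0,
                       double dt, double max_steps_d, int n_repeats) {
  PotentialC P = as_potential(pot);
  DiffusionC Dp = as_diffusion(dif);
  long long max_steps = (long long)max_steps_d;
  IntegerVector side(n_repeats);
  NumericVector tau(n_repeats);
  double kBT = P.kBT;

  for (int r = 0; r < n_repeats; ++r) {
    double x = x0;
    int s = 0;
    double tv = NA_REAL;
    for (long long k = 0; k < max_steps; ++k) {
      double D, Ds;
      Dp.eval(x, D, Ds);
      double drift = P.force_fN(x) * D / kBT + Ds;
      double xn = x + drift * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
      if (xn <= xl || xn >= xr) {
        double frac_l = xn <= xl ? (xl - x) / (xn - x) : 2.0;
        double frac_r = xn >= xr ? (xr - x) / (xn - x) : 2.0;
        if (frac_l <= frac_r) { s = -1; tv = (k + frac_l) * dt; }
        else                  { s = +1; tv = (k + frac_r) * dt; }
        break;
      }
      x = xn;
    }
    side[r] = s;
    tau[r] = tv;
  }
  return List::create(_["side"] = side, _["tau"] = tau);
}

// Stream of interval-boundary crossings ("touches") from one continuous run.
// Resumable: pass back x/level/t/t_next to continue the same realization.
// [[Rcpp::export]]
List cpp_touches(List pot, List dif, SEXP tele, double xl, double xr,
                 double x_init, int lev_init, double t_init, double t_next_init,
                 double dt, double max_steps_d, NumericVector bounds) {
  PotentialC P = as_potential(pot);
  DiffusionC Dp = as_diffusion(dif);
  TelegraphC T = as_telegraph(tele);
  bool has_bounds = bounds.size() == 2;
  double lo = has_bounds ? bounds[0] : 0.0, hi = has_bounds ? bounds[1] : 0.0;
  long long max_steps = (long long)max_steps_d;
  double kBT = P.kBT;

  if (T.active) {
    if (t_next_init > 0) { T.level = lev_init; T.t_next = t_next_init; }
    else T.init(lev_init, t_init);
  }

  std::vector<double> tt; std::vector<int> tb, td;
  double x = x_init;
  for (long long k = 0; k < max_steps; ++k) {
    double t = t_init + k * dt;
    T.advance(t);
    double D, Ds;
    Dp.eval(x, D, Ds);
    double drift = (T.force(t) + P.force_fN(x)) * D / kBT + Ds;
    double xn = x + drift * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
    if (has_bounds) xn = reflect(xn, lo, hi);
    if (xn != x) {
      double fl = 2.0, fr = 2.0;
      if ((x < xl) != (xn < xl)) fl = (xl - x) / (xn - x);
      if ((x < xr) != (xn < xr)) fr = (xr - x) / (xn - x);
      int dir = xn > x ? 1 : -1;
      if (fl <= fr) {
        if (fl <= 1.0) { tt.push_back(t + fl * dt); tb.push_back(-1); td.push_back(dir); }
        if (fr <= 1.0) { tt.push_back(t + fr * dt); tb.push_back(+1); td.push_back(dir); }
      } else {
        if (fr <= 1.0) { tt.push_back(t + fr * dt); tb.push_back(+1); td.push_back(dir); }
        if (fl <= 1.0) { tt.push_back(t + fl * dt); tb.push_back(-1); td.push_back(dir); }
      }
    }
    x = xn;
  }
  return List::create(
    _["t"] = wrap(tt), _["boundary"] = wrap(tb), _["dir"] = wrap(td),
    _["x_final"] = x, _["level_final"] = T.level,
    _["t_final"] = t_init + max_steps * dt,
    _["t_next_final"] = T.active ? T.t_next : -1.0);
}

// ---------------------------------------------------------------------------
// Crank-Nicolson evolution of rho(x, t | x0) with absorbing boundaries.
// Conservative finite-volume discretization of
//   d rho / dt = -d/dx [ v(x) rho - D(x) d rho/dx ],  v = -D u'(x), u = U/kBT.
// Returns boundary effluxes over a graded time grid until the surviving mass
// drops below mass_tol.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cn_fluxes(NumericVector u, NumericVector Dv, double h, int i0,
                   double dt0, double dt_max, double grow, double mass_tol,
                   double max_steps_d, int n_implicit) {
  int N = u.size();
  if (N < 5) stop("grid too small");
  int M = N - 2; // interior nodes
  long long max_steps = (long long)max_steps_d;

  std::vector<double> vh(N - 1), Dh(N - 1);
  for (int i = 0; i < N - 1; ++i) {
    Dh[i] = 0.5 * (Dv[i] + Dv[i + 1]);
    vh[i] = -Dh[i] * (u[i + 1] - u[i]) / h;
  }
  // tridiagonal generator A over interior nodes
  std::vector<double> AL(M), AC(M), AR(M);
  for (int j = 0; j < M; ++j) {
    int i = j + 1;
    AL[j] = (0.5 * vh[i - 1] + Dh[i - 1] / h) / h;
    AC[j] = (0.5 * vh[i - 1] - Dh[i - 1] / h - 0.5 * vh[i] - Dh[i] / h) / h;
    AR[j] = (-0.5 * vh[i] + Dh[i] / h) / h;
  }

  std::vector<double> rho(M, 0.0);
  if (i0 < 1 || i0 > N - 2) stop("initial node must be interior");
  rho[i0 - 1] = 1.0 / h;

  std::vector<double> a(M), b(M), c(M), r(M), cp(M), rp(M);
  std::vector<double> out_t, out_jl, out_jr, out_mass;
  out_t.reserve(4096); out_jl.reserve(4096); out_jr.reserve(4096); out_mass.reserve(4096);

  double t = 0.0, dt = dt0;
  for (long long k = 0; k < max_steps; ++k) {
    // theta scheme: a few fully implicit startup steps damp the ringing a
    // grid-delta initial condition would otherwise excite in Crank-Nicolson
    double th = k < n_implicit ? 1.0 : 0.5;
    double et = 1.0 - th;
    for (int j = 0; j < M; ++j) {
      double acc = (1.0 + et * dt * AC[j]) * rho[j];
      if (j > 0) acc += et * dt * AL[j] * rho[j - 1];
      if (j < M - 1) acc += et * dt * AR[j] * rho[j + 1];
      r[j] = acc;
      a[j] = -th * dt * AL[j];
      b[j] = 1.0 - th * dt * AC[j];
      c[j] = -th * dt * AR[j];
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    rp[0] = r[0] / b[0];
    for (int j = 1; j < M; ++j) {
      double m = b[j] - a[j] * cp[j - 1];
      cp[j] = c[j] / m;
      rp[j] = (r[j] - a[j] * rp[j - 1]) / m;
    }
    rho[M - 1] = rp[M - 1];
    for (int j = M - 2; j >= 0; --j) rho[j] = rp[j] - cp[j] * rho[j + 1];

    t += dt;
    // second-order one-sided boundary effluxes (rho = 0 on the boundary)
    double jl = Dv[0] * (4.0 * rho[0] - rho[1]) / (2.0 * h);
    double jr = Dv[N - 1] * (4.0 * rho[M - 1] - rho[M - 2]) / (2.0 * h);
    double mass = 0.0;
    for (int j = 0; j < M; ++j) mass += rho[j];
    mass *= h;
    out_t.push_back(t);
    out_jl.push_back(jl);
    out_jr.push_back(jr);
    out_mass.push_back(mass);
    if (mass < mass_tol) break;
    dt = std::min(dt * grow, dt_max);
  }
  return List::create(_["t"] = wrap(out_t), _["jl"] = wrap(out_jl),
                      _["jr"] = wrap(out_jr), _["mass"] = wrap(out_mass));
}
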