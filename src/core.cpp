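// Compiled kernels: analytic landscapes, grid-accumulated metadynamics bias,
// BAOAB Langevin samplers (landscape particle and charged bead chain),
// collective variables with analytic gradients, Kabsch RMSD and weighted
// leader (GROMOS-style) clustering.
//
// Units: kJ/mol, nm, ps, amu, elementary charge. In this unit system
// 1 kJ/mol == 1 amu nm^2 ps^-2, so no conversion constants appear in the
// integrator. Randomness comes from R's RNG so set.seed() governs runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Analytic landscapes
// ---------------------------------------------------------------------------

struct Landscape {
  int family; // 0 = double_well, 1 = gaussian_mixture, 2 = harmonic
  int dim;
  double barrier, a;        // double_well: U = barrier*((x/a)^2 - 1)^2
  arma::mat centers;        // gaussian_mixture: k x dim
  arma::mat widths;         // k x dim
  arma::vec depths;         // k
  arma::vec kspring;        // harmonic: dim
  arma::vec origin;         // harmonic: dim
};

static Landscape parse_landscape(const List& land) {
  Landscape L;
  std::string fam = as<std::string>(land["family"]);
  L.dim = as<int>(land["dimension"]);
  List par = land["parameters"];
  if (fam == "double_well") {
    L.family = 0;
    L.barrier = as<double>(par["barrier"]);
    L.a = as<double>(par["half_separation"]);
  } else if (fam == "gaussian_mixture") {
    L.family = 1;
    L.centers = as<arma::mat>(par["centers"]);
    L.widths  = as<arma::mat>(par["widths"]);
    L.depths  = as<arma::vec>(par["depths"]);
  } else if (fam == "harmonic") {
    L.family = 2;
    L.kspring = as<arma::vec>(par["stiffness"]);
    L.origin  = as<arma::vec>(par["center"]);
  } else {
    stop("unknown landscape family: %s", fam.c_str());
  }
  return L;
}

// potential energy and gradient at x (length dim)
static double land_energy(const Landscape& L, const double* x, double* grad) {
  if (L.family == 0) {
    double u = x[0] / L.a;
    double q = u * u - 1.0;
    if (grad) grad[0] = 4.0 * L.barrier * x[0] * q / (L.a * L.a);
    return L.barrier * q * q;
  }
  if (L.family == 1) {
    double U = 0.0;
    if (grad) for (int d = 0; d < L.dim; ++d) grad[d] = 0.0;
    for (arma::uword k = 0; k < L.depths.n_elem; ++k) {
      double e = 0.0;
      for (int d = 0; d < L.dim; ++d) {
        double dx = x[d] - L.centers(k, d);
        double s = L.widths(k, d);
        e += dx * dx / (2.0 * s * s);
      }
      double g = -L.depths(k) * std::exp(-e);
      U += g;
      if (grad) for (int d = 0; d < L.dim; ++d) {
        double dx = x[d] - L.centers(k, d);
        double s = L.widths(k, d);
        grad[d] += -g * dx / (s * s); // note g < 0
      }
    }
    return U;
  }
  // harmonic
  double U = 0.0;
  for (int d = 0; d < L.dim; ++d) {
    double dx = x[d] - L.origin(d);
    U += 0.5 * L.kspring(d) * dx * dx;
    if (grad) grad[d] = L.kspring(d) * dx;
  }
  return U;
}

// [[Rcpp::export]]
List cpp_landscape_eval(List land, NumericMatrix S) {
  Landscape L = parse_landscape(land);
  int n = S.nrow(), d = S.ncol();
  if (d != L.dim) stop("point dimension does not match landscape");
  NumericVector U(n);
  NumericMatrix G(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = S(i, j);
    U[i] = land_energy(L, x.data(), g.data());
    for (int j = 0; j < d; ++j) G(i, j) = g[j];
  }
  return List::create(_["energy"] = U, _["gradient"] = G);
}

// ---------------------------------------------------------------------------
// Hill sums (direct evaluation, used for FES reconstruction and oracles)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bias_eval(NumericMatrix centers, NumericMatrix widths,
                   NumericVector heights, NumericVector times,
                   NumericMatrix S, double t, bool want_grad) {
  int m = centers.nrow(), d = centers.ncol();
  int n = S.nrow();
  if (S.ncol() != d && m > 0) stop("CV dimension mismatch");
  NumericVector V(n);
  NumericMatrix G(want_grad ? n : 1, want_grad ? std::max(d, 1) : 1);
  for (int k = 0; k < m; ++k) {
    if (times[k] > t) continue;
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        double dx = S(i, j) - centers(k, j);
        double s = widths(k, j);
        e += dx * dx / (2.0 * s * s);
      }
      double g = heights[k] * std::exp(-e);
      V[i] += g;
      if (want_grad) for (int j = 0; j < d; ++j) {
        double dx = S(i, j) - centers(k, j);
        double s = widths(k, j);
        G(i, j) += -g * dx / (s * s);
      }
    }
  }
  if (want_grad) return List::create(_["energy"] = V, _["gradient"] = G);
  return List::create(_["energy"] = V);
}

// ---------------------------------------------------------------------------
// Bias accumulated on a grid (fast per-step lookup during sampling)
// ---------------------------------------------------------------------------

struct BiasGrid {
  int dim;
  double lo[2], hi[2], h[2];
  int nb[2];
  std::vector<double> V;        // node values
  std::vector<double> dV[2];    // node gradients

  void init(const NumericVector& glo, const NumericVector& ghi,
            const IntegerVector& gn, int d) {
    dim = d;
    size_t tot = 1;
    for (int j = 0; j < d; ++j) {
      lo[j] = glo[j]; hi[j] = ghi[j]; nb[j] = gn[j];
      h[j] = (hi[j] - lo[j]) / (nb[j] - 1);
      tot *= (size_t)nb[j];
    }
    V.assign(tot, 0.0);
    for (int j = 0; j < d; ++j) dV[j].assign(tot, 0.0);
  }

  void add_hill(const double* c, const double* sig, double w) {
    if (dim == 1) {
      for (int i = 0; i < nb[0]; ++i) {
        double x = lo[0] + i * h[0];
        double dx = x - c[0];
        double g = w * std::exp(-dx * dx / (2.0 * sig[0] * sig[0]));
        V[i] += g;
        dV[0][i] += -g * dx / (sig[0] * sig[0]);
      }
    } else {
      for (int j = 0; j < nb[1]; ++j) {
        double y = lo[1] + j * h[1];
        double dy = y - c[1];
        double ey = dy * dy / (2.0 * sig[1] * sig[1]);
        for (int i = 0; i < nb[0]; ++i) {
          double x = lo[0] + i * h[0];
          double dx = x - c[0];
          double g = w * std::exp(-dx * dx / (2.0 * sig[0] * sig[0]) - ey);
          size_t id = (size_t)i + (size_t)nb[0] * j;
          V[id] += g;
          dV[0][id] += -g * dx / (sig[0] * sig[0]);
          dV[1][id] += -g * dy / (sig[1] * sig[1]);
        }
      }
    }
  }

  // linear interpolation with clamped coordinates (bias flat outside grid)
  void eval(const double* s, double* Vout, double* gout) const {
    double f[2]; int i0[2];
    for (int j = 0; j < dim; ++j) {
      double u = (s[j] - lo[j]) / h[j];
      if (u < 0) u = 0;
      if (u > nb[j] - 1) u = nb[j] - 1;
      int i = (int)u;
      if (i > nb[j] - 2) i = nb[j] - 2;
      i0[j] = i;
      f[j] = u - i;
    }
    if (dim == 1) {
      int i = i0[0]; double fx = f[0];
      *Vout = V[i] * (1 - fx) + V[i + 1] * fx;
      gout[0] = dV[0][i] * (1 - fx) + dV[0][i + 1] * fx;
    } else {
      int i = i0[0], j = i0[1];
      double fx = f[0], fy = f[1];
      size_t a = (size_t)i + (size_t)nb[0] * j;
      size_t b = a + 1, c = a + nb[0], dd = c + 1;
      double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
             w01 = (1 - fx) * fy, w11 = fx * fy;
      *Vout = V[a] * w00 + V[b] * w10 + V[c] * w01 + V[dd] * w11;
      for (int q = 0; q < 2; ++q)
        gout[q] = dV[q][a] * w00 + dV[q][b] * w10 + dV[q][c] * w01 + dV[q][dd] * w11;
    }
  }
};

// ---------------------------------------------------------------------------
// BAOAB Langevin on an analytic landscape, with optional metadynamics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_langevin_landscape(List land, NumericVector x0,
                            int n_steps, double dt, double mass,
                            double friction, double kT, int save_stride,
                            bool metad, int dep_stride, double w0,
                            NumericVector sigma, bool well_tempered,
                            double bias_factor,
                            NumericVector grid_lo, NumericVector grid_hi,
                            IntegerVector grid_n,
                            NumericMatrix init_centers, NumericMatrix init_widths,
                            NumericVector init_heights, NumericVector init_times,
                            double t0,
                            NumericVector domain_lo, NumericVector domain_hi,
                            double wall_k) {
  Landscape L = parse_landscape(land);
  int d = L.dim;
  bool use_bias = metad || init_heights.size() > 0;

  BiasGrid bg;
  if (use_bias) {
    bg.init(grid_lo, grid_hi, grid_n, d);
    for (int k = 0; k < init_heights.size(); ++k) {
      std::vector<double> c(d), s(d);
      for (int j = 0; j < d; ++j) { c[j] = init_centers(k, j); s[j] = init_widths(k, j); }
      bg.add_hill(c.data(), s.data(), init_heights[k]);
    }
  }

  int n_frames = n_steps / save_stride + 1;
  NumericMatrix X(n_frames, d);
  NumericVector times(n_frames);
  std::vector<double> hc, hw, hh, ht;

  std::vector<double> x(d), v(d), g(d), bgrad(d, 0.0);
  for (int j = 0; j < d; ++j) {
    x[j] = x0[j];
    v[j] = (kT > 0) ? std::sqrt(kT / mass) * R::norm_rand() : 0.0;
  }
  double c1 = std::exp(-friction * dt);
  double c2 = (kT > 0) ? std::sqrt(kT / mass * (1.0 - c1 * c1)) : 0.0;

  // force at x
  auto force = [&](std::vector<double>& f) {
    double U = land_energy(L, x.data(), g.data());
    if (!std::isfinite(U)) stop("energy blow-up: non-finite potential");
    for (int j = 0; j < d; ++j) f[j] = -g[j];
    if (use_bias) {
      double Vb;
      bg.eval(x.data(), &Vb, bgrad.data());
      for (int j = 0; j < d; ++j) f[j] -= bgrad[j];
    }
    for (int j = 0; j < d; ++j) {      // soft walls at the domain bounds
      if (x[j] < domain_lo[j]) f[j] += wall_k * (domain_lo[j] - x[j]);
      if (x[j] > domain_hi[j]) f[j] += wall_k * (domain_hi[j] - x[j]);
    }
  };

  std::vector<double> f(d);
  force(f);
  int fr = 0;
  for (int j = 0; j < d; ++j) X(fr, j) = x[j];
  times[fr++] = t0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int j = 0; j < d; ++j) v[j] += 0.5 * dt * f[j] / mass;       // B
    for (int j = 0; j < d; ++j) x[j] += 0.5 * dt * v[j];              // A
    for (int j = 0; j < d; ++j) v[j] = c1 * v[j] + c2 * R::norm_rand(); // O
    for (int j = 0; j < d; ++j) x[j] += 0.5 * dt * v[j];              // A
    force(f);
    for (int j = 0; j < d; ++j) v[j] += 0.5 * dt * f[j] / mass;       // B

    for (int j = 0; j < d; ++j)
      if (std::abs(x[j]) > 1e6) stop("energy blow-up: coordinate diverged");

    double t = t0 + step * dt;
    if (metad && step % dep_stride == 0) {
      double w = w0;
      if (well_tempered) {
        double Vb, gtmp[2];
        bg.eval(x.data(), &Vb, gtmp);
        w = w0 * std::exp(-Vb / ((bias_factor - 1.0) * kT));
      }
      std::vector<double> sg(sigma.begin(), sigma.end());
      bg.add_hill(x.data(), sg.data(), w);
      for (int j = 0; j < d; ++j) { hc.push_back(x[j]); hw.push_back(sg[j]); }
      hh.push_back(w);
      ht.push_back(t);
      force(f);
    }
    if (step % save_stride == 0) {
      for (int j = 0; j < d; ++j) X(fr, j) = x[j];
      times[fr++] = t;
    }
  }

  int nh = hh.size();
  NumericMatrix HC(nh, d), HW(nh, d);
  for (int k = 0; k < nh; ++k)
    for (int j = 0; j < d; ++j) { HC(k, j) = hc[k * d + j]; HW(k, j) = hw[k * d + j]; }
  return List::create(_["times"] = times, _["positions"] = X,
                      _["hill_centers"] = HC, _["hill_widths"] = HW,
                      _["hill_heights"] = wrap(hh), _["hill_times"] = wrap(ht));
}

// ---------------------------------------------------------------------------
// Collective variables for the bead chain
// ---------------------------------------------------------------------------

static double switch_val(double r, double r0, int n, int m, double* dsdr) {
  double xr = r / r0;
  if (std::abs(xr - 1.0) < 1e-7) { // removable singularity: limit n/m
    if (dsdr) *dsdr = (double)n * (n - m) / (2.0 * m * r0);
    return (double)n / m;
  }
  double xn = std::pow(xr, n), xm = std::pow(xr, m);
  double den = 1.0 - xm;
  double s = (1.0 - xn) / den;
  if (dsdr) {
    double dnum = -n * xn / xr;
    double dden = -m * xm / xr;
    *dsdr = (dnum * den - (1.0 - xn) * dden) / (den * den) / r0;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_switching(NumericVector r, double r0, int n, int m) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = switch_val(r[i], r0, n, m, nullptr);
  return out;
}

// Rg and contact number of a frame (rows = beads), with gradients if requested.
static void chain_cvs(const arma::mat& X, const arma::vec& w, bool mass_weighted,
                      double r0, int nexp, int mexp, int excl,
                      double* rg, double* cn,
                      arma::mat* drg, arma::mat* dcn) {
  int N = X.n_rows;
  arma::vec ww = mass_weighted ? w : arma::vec(N, arma::fill::ones);
  double W = arma::accu(ww);
  arma::rowvec com = (ww.t() * X) / W;
  double s2 = 0.0;
  for (int i = 0; i < N; ++i) {
    arma::rowvec dr = X.row(i) - com;
    s2 += ww(i) * arma::dot(dr, dr);
  }
  double Rg = std::sqrt(s2 / W);
  *rg = Rg;
  if (drg) {
    drg->zeros(N, 3);
    if (Rg > 1e-12)
      for (int i = 0; i < N; ++i)
        drg->row(i) = ww(i) * (X.row(i) - com) / (W * Rg);
  }
  double C = 0.0;
  if (dcn) dcn->zeros(N, 3);
  for (int i = 0; i < N; ++i) {
    for (int j = i + excl; j < N; ++j) {
      arma::rowvec dv = X.row(i) - X.row(j);
      double r = std::sqrt(arma::dot(dv, dv));
      double ds;
      C += switch_val(r, r0, nexp, mexp, dcn ? &ds : nullptr);
      if (dcn && r > 1e-12) {
        arma::rowvec u = ds * dv / r;
        dcn->row(i) += u;
        dcn->row(j) -= u;
      }
    }
  }
  *cn = C;
}

// [[Rcpp::export]]
List cpp_chain_cvs(NumericMatrix frame, NumericVector masses, bool mass_weighted,
                   double r0, int nexp, int mexp, int excl) {
  arma::mat X = as<arma::mat>(frame);
  arma::vec w = as<arma::vec>(masses);
  double rg, cn;
  chain_cvs(X, w, mass_weighted, r0, nexp, mexp, excl, &rg, &cn, nullptr, nullptr);
  return List::create(_["rg"] = rg, _["contact_number"] = cn);
}

// ---------------------------------------------------------------------------
// Bead-chain Langevin sampler with optional 2D (Rg, contact number) metadynamics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_langevin_chain(NumericMatrix coords0, NumericVector masses,
                        NumericVector charges, NumericVector radii,
                        double bond_length, double bond_k,
                        double coul_pref, double screen_len, double rep_k,
                        int n_steps, double dt, double friction, double kT,
                        int save_stride,
                        bool mass_weighted_rg,
                        double sw_r0, int sw_n, int sw_m, int excl,
                        bool metad, int dep_stride, double w0,
                        NumericVector sigma, bool well_tempered,
                        double bias_factor,
                        NumericVector grid_lo, NumericVector grid_hi,
                        IntegerVector grid_n,
                        NumericMatrix init_centers, NumericMatrix init_widths,
                        NumericVector init_heights, NumericVector init_times,
                        double t0) {
  int N = coords0.nrow();
  arma::mat X = as<arma::mat>(coords0);
  arma::vec m = as<arma::vec>(masses);
  arma::vec q = as<arma::vec>(charges);
  arma::vec rad = as<arma::vec>(radii);

  bool use_bias = metad || init_heights.size() > 0;
  BiasGrid bg;
  if (use_bias) {
    bg.init(grid_lo, grid_hi, grid_n, 2);
    for (int k = 0; k < init_heights.size(); ++k) {
      double c[2] = { init_centers(k, 0), init_centers(k, 1) };
      double s[2] = { init_widths(k, 0), init_widths(k, 1) };
      bg.add_hill(c, s, init_heights[k]);
    }
  }

  arma::mat V(N, 3);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < 3; ++j)
      V(i, j) = (kT > 0) ? std::sqrt(kT / m(i)) * R::norm_rand() : 0.0;

  double c1 = std::exp(-friction * dt);

  arma::mat F(N, 3), drg, dcn;
  double rg = 0, cn = 0;

  auto forces = [&]() {
    F.zeros();
    double U = 0.0;
    for (int i = 0; i < N - 1; ++i) {             // bonds i,i+1
      arma::rowvec dv = X.row(i) - X.row(i + 1);
      double r = std::sqrt(arma::dot(dv, dv));
      double f = -bond_k * (r - bond_length);
      U += 0.5 * bond_k * (r - bond_length) * (r - bond_length);
      arma::rowvec u = f * dv / r;
      F.row(i) += u;
      F.row(i + 1) -= u;
    }
    for (int i = 0; i < N; ++i) {                 // non-bonded
      for (int j = i + 2; j < N; ++j) {
        arma::rowvec dv = X.row(i) - X.row(j);
        double r = std::sqrt(arma::dot(dv, dv));
        double f = 0.0;
        double sig = rad(i) + rad(j);
        if (r < sig) {                             // soft excluded volume
          f += rep_k * (sig - r);
          U += 0.5 * rep_k * (sig - r) * (sig - r);
        }
        if (q(i) != 0.0 && q(j) != 0.0) {          // screened Coulomb
          double pre = coul_pref * q(i) * q(j);
          double e = std::exp(-r / screen_len);
          U += pre * e / r;
          f += pre * e * (1.0 / (r * r) + 1.0 / (screen_len * r));
        }
        if (f != 0.0) {
          arma::rowvec u = f * dv / r;
          F.row(i) += u;
          F.row(j) -= u;
        }
      }
    }
    if (!std::isfinite(U)) stop("energy blow-up: non-finite potential");
    if (use_bias) {
      chain_cvs(X, m, mass_weighted_rg, sw_r0, sw_n, sw_m, excl,
                &rg, &cn, &drg, &dcn);
      double s[2] = { rg, cn }, Vb, g[2];
      bg.eval(s, &Vb, g);
      F -= g[0] * drg + g[1] * dcn;
    }
  };

  int n_frames = n_steps / save_stride + 1;
  arma::cube frames(N, 3, n_frames);
  NumericVector times(n_frames);
  NumericMatrix cvs(n_frames, 2);
  std::vector<double> hc, hw, hh, ht;

  forces();
  int fr = 0;
  frames.slice(fr) = X;
  if (!use_bias) chain_cvs(X, m, mass_weighted_rg, sw_r0, sw_n, sw_m, excl,
                           &rg, &cn, nullptr, nullptr);
  cvs(fr, 0) = rg; cvs(fr, 1) = cn;
  times[fr++] = t0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      double c2 = (kT > 0) ? std::sqrt(kT / m(i) * (1.0 - c1 * c1)) : 0.0;
      for (int j = 0; j < 3; ++j) {
        V(i, j) += 0.5 * dt * F(i, j) / m(i);
        X(i, j) += 0.5 * dt * V(i, j);
        V(i, j) = c1 * V(i, j) + c2 * R::norm_rand();
        X(i, j) += 0.5 * dt * V(i, j);
      }
    }
    forces();
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < 3; ++j)
        V(i, j) += 0.5 * dt * F(i, j) / m(i);

    if (X.has_nan() || arma::abs(X).max() > 1e5)
      stop("energy blow-up: coordinates diverged at step %d", step);

    double t = t0 + step * dt;
    if (metad && step % dep_stride == 0) {
      if (!use_bias)
        chain_cvs(X, m, mass_weighted_rg, sw_r0, sw_n, sw_m, excl,
                  &rg, &cn, nullptr, nullptr);
      double s[2] = { rg, cn };
      double w = w0;
      if (well_tempered) {
        double Vb, g[2];
        bg.eval(s, &Vb, g);
        w = w0 * std::exp(-Vb / ((bias_factor - 1.0) * kT));
      }
      double sg[2] = { sigma[0], sigma[1] };
      bg.add_hill(s, sg, w);
      hc.push_back(s[0]); hc.push_back(s[1]);
      hw.push_back(sg[0]); hw.push_back(sg[1]);
      hh.push_back(w); ht.push_back(t);
      forces();
    }
    if (step % save_stride == 0) {
      if (!use_bias) chain_cvs(X, m, mass_weighted_rg, sw_r0, sw_n, sw_m, excl,
                               &rg, &cn, nullptr, nullptr);
      frames.slice(fr) = X;
      cvs(fr, 0) = rg; cvs(fr, 1) = cn;
      times[fr++] = t;
    }
  }

  int nh = hh.size();
  NumericMatrix HC(nh, 2), HW(nh, 2);
  for (int k = 0; k < nh; ++k) {
    HC(k, 0) = hc[2 * k]; HC(k, 1) = hc[2 * k + 1];
    HW(k, 0) = hw[2 * k]; HW(k, 1) = hw[2 * k + 1];
  }
  return List::create(_["times"] = times, _["frames"] = frames,
                      _["cvs"] = cvs,
                      _["hill_centers"] = HC, _["hill_widths"] = HW,
                      _["hill_heights"] = wrap(hh), _["hill_times"] = wrap(ht));
}

// ---------------------------------------------------------------------------
// Kabsch RMSD
// ---------------------------------------------------------------------------

static double kabsch_rmsd(const arma::mat& Pc, const arma::mat& Qc,
                          double gP, double gQ) {
  // Pc, Qc centered; gP, gQ = sum of squared norms
  arma::mat H = Pc.t() * Qc;
  arma::mat U, Vm;
  arma::vec s;
  arma::svd(U, s, Vm, H);
  double dsign = arma::det(Vm * U.t()) < 0 ? -1.0 : 1.0;
  double tr = s(0) + s(1) + dsign * s(2);
  double msd = (gP + gQ - 2.0 * tr) / Pc.n_rows;
  return msd > 0 ? std::sqrt(msd) : 0.0;
}

// [[Rcpp::export]]
double cpp_kabsch_rmsd(NumericMatrix P, NumericMatrix Q) {
  arma::mat A = as<arma::mat>(P), B = as<arma::mat>(Q);
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  A.each_row() -= ca; B.each_row() -= cb;
  return kabsch_rmsd(A, B, arma::accu(A % A), arma::accu(B % B));
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_rmsd(arma::cube coords) {
  int n = coords.n_slices;
  std::vector<arma::mat> C(n);
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    arma::mat A = coords.slice(i);
    A.each_row() -= arma::mean(A, 0);
    g[i] = arma::accu(A % A);
    C[i] = A;
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r = kabsch_rmsd(C[i], C[j], g[i], g[j]);
      D(i, j) = r; D(j, i) = r;
    }
  return D;
}

// ---------------------------------------------------------------------------
// Weighted leader (GROMOS-style) clustering
// ---------------------------------------------------------------------------

// Common driver: given a distance functor, run leader clustering.
template <typename DistFun>
static List leader_cluster(int n, const NumericVector& w, double cutoff,
                           DistFun dist) {
  std::vector<int> assign(n, -1);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  std::vector<int> centers;
  std::vector<double> pops;
  int cl = 0;
  std::vector<int> count;
  while (!active.empty()) {
    int na = active.size();
    count.assign(na, 1); // self counts as neighbour
    for (int a = 0; a < na; ++a) {
      for (int b = a + 1; b < na; ++b) {
        if (dist(active[a], active[b]) <= cutoff) { ++count[a]; ++count[b]; }
      }
      Rcpp::checkUserInterrupt();
    }
    int best = 0;
    for (int a = 1; a < na; ++a)
      if (count[a] > count[best]) best = a; // ties: lowest index wins (kept)
    int centre = active[best];
    centers.push_back(centre);
    double pop = 0.0;
    std::vector<int> keep;
    keep.reserve(na);
    for (int a = 0; a < na; ++a) {
      int i = active[a];
      if (i == centre || dist(centre, i) <= cutoff) {
        assign[i] = cl;
        pop += w[i];
      } else keep.push_back(i);
    }
    pops.push_back(pop);
    active.swap(keep);
    ++cl;
  }
  return List::create(_["assignment"] = wrap(assign),
                      _["centers"] = wrap(centers),
                      _["weights"] = wrap(pops));
}

// Point version with compacted interleaved coordinates: the neighbour
// count is O(n_active^2) per round, so sequential memory access matters.
// [[Rcpp::export]]
List cpp_leader_cluster_points(NumericMatrix X, NumericVector w, double cutoff) {
  int n = X.nrow(), d = X.ncol();
  double cut2 = cutoff * cutoff;
  std::vector<double> P((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) P[(size_t)i * d + k] = X(i, k);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> assign(n, -1);
  std::vector<int> centers;
  std::vector<double> pops;
  std::vector<int> count;
  int na = n, cl = 0;
  while (na > 0) {
    count.assign(na, 1); // self counts as neighbour
    if (d == 2) {
      for (int a = 0; a < na; ++a) {
        double xa = P[2 * (size_t)a], ya = P[2 * (size_t)a + 1];
        int ca = 0;
        for (int b = a + 1; b < na; ++b) {
          double dx = P[2 * (size_t)b] - xa, dy = P[2 * (size_t)b + 1] - ya;
          if (dx * dx + dy * dy <= cut2) { ++ca; ++count[b]; }
        }
        count[a] += ca;
        if ((a & 2047) == 0) Rcpp::checkUserInterrupt();
      }
    } else {
      for (int a = 0; a < na; ++a) {
        const double* pa = &P[(size_t)a * d];
        for (int b = a + 1; b < na; ++b) {
          const double* pb = &P[(size_t)b * d];
          double s = 0.0;
          for (int k = 0; k < d; ++k) { double dd = pa[k] - pb[k]; s += dd * dd; }
          if (s <= cut2) { ++count[a]; ++count[b]; }
        }
        if ((a & 2047) == 0) Rcpp::checkUserInterrupt();
      }
    }
    int best = 0;
    for (int a = 1; a < na; ++a)
      if (count[a] > count[best]) best = a; // ties: lowest index wins
    std::vector<double> cpt(P.begin() + (size_t)best * d,
                            P.begin() + (size_t)best * d + d);
    centers.push_back(idx[best]);
    double pop = 0.0;
    int keep = 0;
    for (int a = 0; a < na; ++a) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = P[(size_t)a * d + k] - cpt[k];
        s += dd * dd;
      }
      if (a == best || s <= cut2) {
        assign[idx[a]] = cl;
        pop += w[idx[a]];
      } else {
        if (keep != a) {
          for (int k = 0; k < d; ++k)
            P[(size_t)keep * d + k] = P[(size_t)a * d + k];
          idx[keep] = idx[a];
        }
        ++keep;
      }
    }
    pops.push_back(pop);
    na = keep;
    ++cl;
  }
  return List::create(_["assignment"] = wrap(assign),
                      _["centers"] = wrap(centers),
                      _["weights"] = wrap(pops));
}

// [[Rcpp::export]]
List cpp_leader_cluster_rmsd(arma::cube coords, NumericVector w, double cutoff) {
  int n = coords.n_slices;
  std::vector<arma::mat> C(n);
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    arma::mat A = coords.slice(i);
    A.each_row() -= arma::mean(A, 0);
    g[i] = arma::accu(A % A);
    C[i] = A;
  }
  auto dist = [&](int i, int j) { return kabsch_rmsd(C[i], C[j], g[i], g[j]); };
  return leader_cluster(n, w, cutoff, dist);
}
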