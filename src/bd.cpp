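// Euler-Maruyama core for guided-particle runs: intensity-scaled propulsion,
// magnetic alignment (explicit Langevin or quasi-static von Mises), optional
// WCA pair interactions and channel-wall confinement.
#include <Rcpp.h>
using namespace Rcpp;

// Best-Fisher von Mises sampler (mean 0), on R's RNG stream.
static double rvm1(double kappa) {
  if (kappa < 1e-8) return unif_rand() * 2.0 * M_PI - M_PI;
  const double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  const double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  const double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    const double z = std::cos(M_PI * unif_rand());
    const double f = (1.0 + r * z) / (r + z);
    const double c = kappa * (r - f);
    const double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0)
      return (unif_rand() > 0.5 ? 1.0 : -1.0) * std::acos(f);
  }
}

// [[Rcpp::export]]
NumericVector rvmCpp(int n, double kappa) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(kappa);
  return out;
}

static inline double wcaMag(double r, double sigma, double eps, double cut) {
  if (r >= cut) return 0.0;
  const double sr2 = (sigma / r) * (sigma / r);
  const double sr6 = sr2 * sr2 * sr2;
  return 24.0 * eps / r * (2.0 * sr6 * sr6 - sr6);
}

struct Grid {
  NumericMatrix segs;
  double xmin, ymin, cell, halfw;
  int nx, ny;
  IntegerVector start, index;
  bool minDist(double px, double py, double &d, double &qx, double &qy) const {
    const int cx = (int)std::floor((px - xmin) / cell);
    const int cy = (int)std::floor((py - ymin) / cell);
    double best = R_PosInf;
    if (cx >= 0 && cx < nx && cy >= 0 && cy < ny) {
      const int c = cx + nx * cy;
      for (int q = start[c]; q < start[c + 1]; ++q) {
        const int j = index[q];
        const double x1 = segs(j, 0), y1 = segs(j, 1);
        const double vx = segs(j, 2) - x1, vy = segs(j, 3) - y1;
        const double L2 = vx * vx + vy * vy;
        double t = 0.0;
        if (L2 > 0.0) {
          t = ((px - x1) * vx + (py - y1) * vy) / L2;
          t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
        }
        const double ax = x1 + t * vx, ay = y1 + t * vy;
        const double dx = px - ax, dy = py - ay;
        const double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; qx = ax; qy = ay; }
      }
    }
    if (std::isinf(best)) return false;
    d = std::sqrt(best);
    return true;
  }
};

// Registration-averaged normal WCA force of a straight wall-particle chain
// at perpendicular gap g: continuum line integral (composite Simpson).
static double chainForce(double g, double sigma, double eps, double ds,
                         double cut) {
  if (g < 0.5 * sigma) g = 0.5 * sigma;
  const double smax2 = cut * cut - g * g;
  if (smax2 <= 0.0) return 0.0;
  const double smax = std::sqrt(smax2);
  const int n = 64;                       // Simpson intervals (even)
  const double h = smax / n;
  double acc = 0.0;
  for (int i = 0; i <= n; ++i) {
    const double s = i * h;
    const double r = std::sqrt(g * g + s * s);
    const double val = wcaMag(r, sigma, eps, cut) * g / r;
    acc += val * (i == 0 || i == n ? 1.0 : (i % 2 ? 4.0 : 2.0));
  }
  return 2.0 / ds * acc * h / 3.0;
}

// [[Rcpp::export]]
List bdRunCpp(NumericMatrix pos0, NumericVector phi0, int nsteps, double dt,
              NumericMatrix fpos, NumericVector thB, int focusEvery,
              double b1, double b2, double v0, double gammaT, double gammaR,
              double Dt, double Dr, double muB, double kappa,
              int orientMode, bool interactions, double sigma, double eps,
              Nullable<List> channel, double domainHalf, int recordEvery) {
  RNGScope scope;
  const int N = pos0.nrow();
  std::vector<double> x(N), y(N), phi(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); phi[i] = phi0[i];
  }
  const double cut = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double sdt = std::sqrt(2.0 * Dt * dt);
  const double sdr = std::sqrt(2.0 * Dr * dt);

  bool hasChannel = false;
  Grid grid;
  int wallMode = 0;
  double wallSpacing = 5e-8;
  if (channel.isNotNull()) {
    List ch(channel);
    grid.segs = as<NumericMatrix>(ch["segments"]);
    grid.halfw = as<double>(ch["halfw"]);
    grid.xmin = as<double>(ch["xmin"]);
    grid.ymin = as<double>(ch["ymin"]);
    grid.cell = as<double>(ch["cell"]);
    grid.nx = as<int>(ch["nx"]);
    grid.ny = as<int>(ch["ny"]);
    grid.start = as<IntegerVector>(ch["start"]);
    grid.index = as<IntegerVector>(ch["index"]);
    wallMode = as<int>(ch["wallMode"]);
    if (ch.containsElementNamed("wallSpacing"))
      wallSpacing = as<double>(ch["wallSpacing"]);
    hasChannel = true;
  }

  const int nrec = nsteps / recordEvery + 1;
  NumericVector times(nrec);
  NumericVector posRec(Dimension(nrec, N, 2));
  NumericMatrix phiRec(nrec, N);
  int irec = 0;
  auto record = [&](int step) {
    times[irec] = step * dt;
    for (int i = 0; i < N; ++i) {
      posRec[irec + nrec * i] = x[i];
      posRec[irec + nrec * (i + N)] = y[i];
      phiRec(irec, i) = phi[i];
    }
    ++irec;
  };
  record(0);

  std::vector<double> fx(N), fy(N);
  int exited = -1;
  const int nf = fpos.nrow();

  for (int step = 0; step < nsteps && exited < 0; ++step) {
    int fi = step / focusEvery;
    if (fi >= nf) fi = nf - 1;
    const double x0 = fpos(fi, 0), y0 = fpos(fi, 1), th = thB[fi];

    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    if (interactions) {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          const double dx = x[i] - x[j], dy = y[i] - y[j];
          const double r2 = dx * dx + dy * dy;
          if (r2 >= cut * cut || r2 == 0.0) continue;
          const double r = std::sqrt(r2);
          const double m = wcaMag(r, sigma, eps, cut) / r;
          fx[i] += m * dx; fy[i] += m * dy;
          fx[j] -= m * dx; fy[j] -= m * dy;
        }
    }

    for (int i = 0; i < N; ++i) {
      // orientation
      if (orientMode == 1) {
        phi[i] = th + rvm1(kappa);
      } else {
        phi[i] += muB / gammaR * std::sin(th - phi[i]) * dt +
                  sdr * norm_rand();
      }
      // propulsion at the (pre-move) position
      const double ex = (x[i] - x0) / b1, ey = (y[i] - y0) / b2;
      const double In = std::exp(-(ex * ex + ey * ey));
      fx[i] += v0 * gammaT * In * std::cos(phi[i]);
      fy[i] += v0 * gammaT * In * std::sin(phi[i]);

      if (hasChannel && wallMode == 2) {
        double d, qx, qy;
        if (grid.minDist(x[i], y[i], d, qx, qy)) {
          const double gap = grid.halfw - d;
          if (gap < cut && d > 0.0) {
            const double fmag = chainForce(gap, sigma, eps, wallSpacing, cut);
            fx[i] += fmag * (qx - x[i]) / d;   // towards the axis
            fy[i] += fmag * (qy - y[i]) / d;
          }
        }
      }

      const double nx_ = x[i] + fx[i] / gammaT * dt + sdt * norm_rand();
      const double ny_ = y[i] + fy[i] / gammaT * dt + sdt * norm_rand();

      bool accept = true;
      if (hasChannel) {
        double d, qx, qy;
        const bool found = grid.minDist(nx_, ny_, d, qx, qy);
        if (!found || d > grid.halfw) accept = false;   // bounce-back
      }
      if (accept) { x[i] = nx_; y[i] = ny_; }

      if (std::fabs(x[i]) > domainHalf || std::fabs(y[i]) > domainHalf)
        exited = step;
    }

    if ((step + 1) % recordEvery == 0 && irec < nrec) record(step + 1);
  }
  // a run aborted by a domain exit keeps its last state in the remaining slots
  while (irec < nrec) {
    const int prev = irec;
    times[irec] = times[prev - 1];
    for (int i = 0; i < N; ++i) {
      posRec[irec + nrec * i] = x[i];
      posRec[irec + nrec * (i + N)] = y[i];
      phiRec(irec, i) = phi[i];
    }
    ++irec;
  }
  return List::create(_["times"] = times, _["positions"] = posRec,
                      _["orientations"] = phiRec, _["exited"] = exited);
}
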