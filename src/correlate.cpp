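#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Count photon pairs (a in stream i, b in stream j) whose lag
// t_b - t_a falls into uniform bins covering [lag_min, lag_max).
// Both streams must be sorted ascending.  Two-pointer sweep: O(Ni + P)
// where P is the number of in-window pairs.
// [[Rcpp::export(name = ".photon_pair_counts")]]
NumericVector photon_pair_counts(NumericVector ti, NumericVector tj,
                                 double lag_min, double lag_max,
                                 double bin_width) {
  const int nbin = (int)std::round((lag_max - lag_min) / bin_width);
  NumericVector counts(nbin);
  const int ni = ti.size(), nj = tj.size();
  int lo = 0;
  for (int a = 0; a < ni; ++a) {
    const double t0 = ti[a] + lag_min;
    const double t1 = ti[a] + lag_max;
    while (lo < nj && tj[lo] < t0) ++lo;
    for (int b = lo; b < nj && tj[b] < t1; ++b) {
      int k = (int)((tj[b] - ti[a] - lag_min) / bin_width);
      if (k >= 0 && k < nbin) counts[k] += 1.0;
    }
  }
  return counts;
}

// Overdamped Brownian dynamics of a scalar coordinate r on the potential
// of mean force U(r) = -kT log P(r), with reflecting walls, emitting
// photons as a Poisson process whose acceptor probability is the
// Foerster efficiency E(r).  Used by the synthetic-data generator for
// nsFCS closed-loop tests.  Units: time ns, length nm, D nm^2/ns.
// Returns a list with photon times (ns) and channel (1 donor, 2 acceptor).
// [[Rcpp::export(name = ".simulate_diffusive_photons")]]
List simulate_diffusive_photons(NumericVector r_grid,
                                NumericVector log_p,
                                double D, double dt, double t_total,
                                double rate, double R0,
                                int seed) {
  const int n = r_grid.size();
  const double h = r_grid[1] - r_grid[0];
  // precompute dU/dr = -d log P / dr on the grid (central differences)
  std::vector<double> drift(n);
  for (int i = 0; i < n; ++i) {
    int i0 = std::max(i - 1, 0), i1 = std::min(i + 1, n - 1);
    drift[i] = D * (log_p[i1] - log_p[i0]) / ((i1 - i0) * h);
  }
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::exponential_distribution<double> expo(rate);

  // start near the density mode
  int imax = 0;
  for (int i = 1; i < n; ++i) if (log_p[i] > log_p[imax]) imax = i;
  double r = r_grid[imax];
  const double rmin = r_grid[0], rmax = r_grid[n - 1];
  const double sig = std::sqrt(2.0 * D * dt);

  std::vector<double> times;
  std::vector<int> chan;
  double t = 0.0, t_next = expo(rng);
  const double R06 = std::pow(R0, 6.0);
  while (t < t_total) {
    int i = (int)((r - rmin) / h);
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    r += drift[i] * dt + sig * gauss(rng);
    if (r < rmin) r = 2 * rmin - r;
    if (r > rmax) r = 2 * rmax - r;
    t += dt;
    while (t_next < t) {
      double E = 1.0 / (1.0 + std::pow(r, 6.0) / R06);
      times.push_back(t_next);
      chan.push_back(unif(rng) < E ? 2 : 1);
      t_next += expo(rng);
    }
  }
  return List::create(_["time"] = wrap(times), _["channel"] = wrap(chan));
}
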