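// Inner loops that dominate runtime: minimum-image pair histograms for
// radial distribution functions, geometric hydrogen-bond detection, and
// multiple-time-origin mean-squared displacement.  Everything here is a
// straight translation of the definitions; the R test-suite checks each
// kernel against a plain-R oracle.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image_1d(double d, double L) {
  // wrap into (-L/2, L/2]; the boundary maps to +L/2
  return d - L * std::ceil(d / L - 0.5);
}

// Histogram of minimum-image A-B distances.  idx_a/idx_b are global atom
// indices (to drop self-pairs when the selections overlap); mol_a/mol_b
// are molecule ids (to drop intra-molecular pairs when requested).
// [[Rcpp::export(name = ".pair_hist_pbc")]]
IntegerVector pair_hist_pbc(NumericMatrix a, NumericMatrix b,
                            NumericVector box, double bin_width,
                            double r_max, IntegerVector idx_a,
                            IntegerVector idx_b, IntegerVector mol_a,
                            IntegerVector mol_b, bool exclude_same_molecule) {
  const int na = a.nrow(), nb = b.nrow();
  const int nbins = (int)std::ceil(r_max / bin_width - 1e-9);
  IntegerVector counts(nbins);
  const double r2max = r_max * r_max;
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      if (idx_a[i] == idx_b[j]) continue;
      if (exclude_same_molecule && mol_a[i] == mol_b[j]) continue;
      double dx = min_image_1d(b(j, 0) - ax, box[0]);
      double dy = min_image_1d(b(j, 1) - ay, box[1]);
      double dz = min_image_1d(b(j, 2) - az, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > r2max || r2 == 0.0) continue;
      int bin = (int)(std::sqrt(r2) / bin_width);
      if (bin >= nbins) bin = nbins - 1;  // r == r_max edge
      counts[bin]++;
    }
  }
  return counts;
}

// Luzar-Chandler geometric criterion: donor-acceptor minimum-image
// distance <= r_da_max and the angle at the donor between donor->hydrogen
// and donor->acceptor <= angle_max (both inclusive).  Returns a 3-column
// matrix of 1-based (donor, hydrogen, acceptor) rows.
// [[Rcpp::export(name = ".hbond_detect")]]
IntegerMatrix hbond_detect(NumericMatrix coords, NumericVector box,
                           IntegerVector donor_heavy, IntegerVector hydrogen,
                           IntegerVector acceptor, IntegerVector mol,
                           double r_da_max, double angle_max_deg,
                           bool include_intra) {
  const int nd = donor_heavy.size(), na = acceptor.size();
  const double cos_min = std::cos(angle_max_deg * M_PI / 180.0);
  const double r2max = r_da_max * r_da_max;
  std::vector<int> out;
  for (int i = 0; i < nd; ++i) {
    const int d = donor_heavy[i] - 1, h = hydrogen[i] - 1;
    const double dx0 = coords(d, 0), dy0 = coords(d, 1), dz0 = coords(d, 2);
    double hx = min_image_1d(coords(h, 0) - dx0, box[0]);
    double hy = min_image_1d(coords(h, 1) - dy0, box[1]);
    double hz = min_image_1d(coords(h, 2) - dz0, box[2]);
    const double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
    for (int j = 0; j < na; ++j) {
      const int a = acceptor[j] - 1;
      if (a == d) continue;
      if (!include_intra && mol[a] == mol[d]) continue;
      double ax = min_image_1d(coords(a, 0) - dx0, box[0]);
      double ay = min_image_1d(coords(a, 1) - dy0, box[1]);
      double az = min_image_1d(coords(a, 2) - dz0, box[2]);
      double r2 = ax * ax + ay * ay + az * az;
      if (r2 > r2max + 1e-12 || r2 == 0.0) continue;  // inclusive cutoff
      double cosang = (hx * ax + hy * ay + hz * az) / (hn * std::sqrt(r2));
      if (cosang >= cos_min - 1e-12) {
        out.push_back(d + 1); out.push_back(h + 1); out.push_back(a + 1);
      }
    }
  }
  const int nb = out.size() / 3;
  IntegerMatrix res(nb, 3);
  for (int k = 0; k < nb; ++k) {
    res(k, 0) = out[3 * k];
    res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  return res;
}

// Multiple-time-origin MSD on unwrapped coordinates.
// traj: (n_frames x 3*n_entities) matrix, columns grouped x1 y1 z1 x2 ...
// Returns the mean squared displacement for lags 1..max_lag, averaging
// over origins (every `stride`-th frame) and entities.
// [[Rcpp::export(name = ".msd_kernel")]]
NumericVector msd_kernel(NumericMatrix traj, int max_lag, int stride) {
  const int nf = traj.nrow();
  const int ne = traj.ncol() / 3;
  NumericVector msd(max_lag);
  for (int lag = 1; lag <= max_lag; ++lag) {
    double acc = 0.0;
    long cnt = 0;
    for (int t0 = 0; t0 + lag < nf; t0 += stride) {
      const int t1 = t0 + lag;
      for (int e = 0; e < ne; ++e) {
        const int c = 3 * e;
        const double dx = traj(t1, c) - traj(t0, c);
        const double dy = traj(t1, c + 1) - traj(t0, c + 1);
        const double dz = traj(t1, c + 2) - traj(t0, c + 2);
        acc += dx * dx + dy * dy + dz * dz;
        ++cnt;
      }
    }
    msd[lag - 1] = acc / (double)cnt;
  }
  return msd;
}
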