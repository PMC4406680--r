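// Bottom-up multiresolution region merging.
//
// Regions start as single pixels and are merged by local mutual best
// fitting: a pair merges when each region is the other's cheapest
// neighbour and the fusion cost stays below scale^2.  The fusion cost
// mixes the increase in per-band weighted standard deviation (colour
// heterogeneity) with compactness/smoothness shape terms, the standard
// formulation for this family of segmenters.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Region {
  bool alive;
  double n;
  std::vector<double> sum;   // per band
  std::vector<double> sumsq; // per band
  double perim;              // boundary length, pixel-edge units
  int rmin, rmax, cmin, cmax;
  std::map<int, double> nb;  // neighbour id -> shared edge count
};

// n-weighted colour heterogeneity of a (possibly hypothetical) region
inline double color_h(double n, const std::vector<double>& sum,
                      const std::vector<double>& sumsq,
                      const std::vector<double>& bw) {
  double h = 0.0;
  for (size_t b = 0; b < sum.size(); ++b) {
    double m = sum[b] / n;
    double v = sumsq[b] / n - m * m;
    h += bw[b] * n * (v > 0 ? std::sqrt(v) : 0.0);
  }
  return h;
}

inline double shape_terms(double n, double perim, int rmin, int rmax,
                          int cmin, int cmax, double w_compact) {
  // compactness: n * (perim / sqrt(n)); smoothness: n * (perim / bbox perim)
  double bbox = 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
  double cmpct = perim * std::sqrt(n);
  double smooth = n * perim / bbox;
  return w_compact * cmpct + (1.0 - w_compact) * smooth;
}

}  // namespace

// labels: 0 = background (masked out), 1..K contiguous in scan order.
// bands: npix x nbands matrix, column-major pixel order (R layout),
// pixel index = (col-1)*nrow + (row-1).
// [[Rcpp::export(name = ".multires_cpp")]]
IntegerMatrix multires_cpp(NumericMatrix bands, LogicalMatrix mask,
                           double scale, double w_color, double w_compact,
                           NumericVector band_weights) {
  const int nrow = mask.nrow(), ncol = mask.ncol();
  const int npix = nrow * ncol;
  const int nb_bands = bands.ncol();
  const double scale2 = scale * scale;
  std::vector<double> bw(band_weights.begin(), band_weights.end());

  // map pixels to initial region ids (-1 = background)
  std::vector<int> pix2reg(npix, -1);
  int nreg = 0;
  for (int i = 0; i < npix; ++i)
    if (mask[i]) pix2reg[i] = nreg++;
  if (nreg == 0) stop("all pixels are masked out or nodata");

  std::vector<Region> reg(nreg);
  std::vector<int> uf(nreg);  // union-find parents for final labelling
  for (int i = 0; i < npix; ++i) {
    int id = pix2reg[i];
    if (id < 0) continue;
    int r = i % nrow, c = i / nrow;
    Region& R = reg[id];
    R.alive = true;
    R.n = 1;
    R.sum.resize(nb_bands);
    R.sumsq.resize(nb_bands);
    for (int b = 0; b < nb_bands; ++b) {
      double v = bands(i, b);
      R.sum[b] = v;
      R.sumsq[b] = v * v;
    }
    R.perim = 4;
    R.rmin = R.rmax = r;
    R.cmin = R.cmax = c;
    uf[id] = id;
  }
  // 4-adjacency with shared edge counts
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      int i = c * nrow + r, a = pix2reg[i];
      if (a < 0) continue;
      if (r + 1 < nrow) {
        int b = pix2reg[i + 1];
        if (b >= 0) { reg[a].nb[b] += 1; reg[b].nb[a] += 1; }
      }
      if (c + 1 < ncol) {
        int b = pix2reg[i + nrow];
        if (b >= 0) { reg[a].nb[b] += 1; reg[b].nb[a] += 1; }
      }
    }
  }

  // cost of merging a with b given shared edge count
  std::vector<double> msum(nb_bands), msumsq(nb_bands);
  auto pair_cost = [&](int ia, int ib, double shared) -> double {
    const Region& A = reg[ia];
    const Region& B = reg[ib];
    double n_m = A.n + B.n;
    for (int b = 0; b < nb_bands; ++b) {
      msum[b] = A.sum[b] + B.sum[b];
      msumsq[b] = A.sumsq[b] + B.sumsq[b];
    }
    double dcolor = color_h(n_m, msum, msumsq, bw) -
                    color_h(A.n, A.sum, A.sumsq, bw) -
                    color_h(B.n, B.sum, B.sumsq, bw);
    if (dcolor < 0) dcolor = 0;
    int rmin = std::min(A.rmin, B.rmin), rmax = std::max(A.rmax, B.rmax);
    int cmin = std::min(A.cmin, B.cmin), cmax = std::max(A.cmax, B.cmax);
    double dshape =
        shape_terms(n_m, A.perim + B.perim - 2.0 * shared, rmin, rmax, cmin,
                    cmax, w_compact) -
        shape_terms(A.n, A.perim, A.rmin, A.rmax, A.cmin, A.cmax, w_compact) -
        shape_terms(B.n, B.perim, B.rmin, B.rmax, B.cmin, B.cmax, w_compact);
    if (dshape < 0) dshape = 0;
    return w_color * dcolor + (1.0 - w_color) * dshape;
  };

  // cheapest neighbour of region i (ties broken by lowest id: map order)
  auto best_neighbour = [&](int i, double& best_cost) -> int {
    best_cost = R_PosInf;
    int best = -1;
    for (std::map<int, double>::const_iterator it = reg[i].nb.begin();
         it != reg[i].nb.end(); ++it) {
      double f = pair_cost(i, it->first, it->second);
      if (f < best_cost) { best_cost = f; best = it->first; }
    }
    return best;
  };

  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (int i = 0; i < nreg; ++i) {
      if (!reg[i].alive || reg[i].nb.empty()) continue;
      double fi;
      int j = best_neighbour(i, fi);
      if (j < 0 || fi >= scale2) continue;
      double fj;
      int back = best_neighbour(j, fj);
      if (back != i) continue;  // not mutual
      // merge higher id into lower id
      int keep = std::min(i, j), drop = std::max(i, j);
      Region& K = reg[keep];
      Region& D = reg[drop];
      double shared = K.nb[drop];
      K.n += D.n;
      for (int b = 0; b < nb_bands; ++b) {
        K.sum[b] += D.sum[b];
        K.sumsq[b] += D.sumsq[b];
      }
      K.perim += D.perim - 2.0 * shared;
      K.rmin = std::min(K.rmin, D.rmin);
      K.rmax = std::max(K.rmax, D.rmax);
      K.cmin = std::min(K.cmin, D.cmin);
      K.cmax = std::max(K.cmax, D.cmax);
      K.nb.erase(drop);
      for (std::map<int, double>::iterator it = D.nb.begin();
           it != D.nb.end(); ++it) {
        int c = it->first;
        if (c == keep) continue;
        K.nb[c] += it->second;
        reg[c].nb.erase(drop);
        reg[c].nb[keep] += it->second;
      }
      D.nb.clear();
      D.sum.clear();
      D.sumsq.clear();
      D.alive = false;
      uf[drop] = keep;
      merged_any = true;
    }
    Rcpp::checkUserInterrupt();
  }

  // resolve union-find and relabel contiguously in scan order
  std::vector<int> root(nreg);
  for (int i = 0; i < nreg; ++i) {
    int r = i;
    while (uf[r] != r) r = uf[r];
    // path compression
    int c = i;
    while (uf[c] != c) { int nx = uf[c]; uf[c] = r; c = nx; }
    root[i] = r;
  }
  std::vector<int> newlab(nreg, 0);
  IntegerMatrix out(nrow, ncol);
  int next = 0;
  for (int i = 0; i < npix; ++i) {
    int id = pix2reg[i];
    if (id < 0) { out[i] = 0; continue; }
    int r = root[id];
    if (newlab[r] == 0) newlab[r] = ++next;
    out[i] = newlab[r];
  }
  return out;
}
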