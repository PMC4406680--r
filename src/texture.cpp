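// Windowed first-order (occurrence) and second-order (grey-level
// co-occurrence) texture features.  Pair counts are pooled over all
// offsets into one normalised matrix per window before features are
// computed; image edges use mirrored padding.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
inline int reflect(int i, int n) {
  // symmetric (edge-inclusive) reflection
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}
const double LOG2 = 0.6931471805599453;
}  // namespace

// band: raw values; qband: quantized levels 0..(levels-1), same shape.
// offsets: k x 2 (drow, dcol).  features: subset of
// mean, variance, entropy1, contrast, ASM, entropy2, homogeneity,
// dissimilarity, correlation.
// [[Rcpp::export(name = ".texture_stack_cpp")]]
List texture_stack_cpp(NumericMatrix band, IntegerMatrix qband, int window,
                       int levels, IntegerMatrix offsets, bool symmetric,
                       CharacterVector features) {
  const int nrow = band.nrow(), ncol = band.ncol();
  const int rad = window / 2;
  const int noff = offsets.nrow();
  const int nfeat = features.size();

  bool need_glcm = false, need_hist = false;
  std::vector<std::string> fts(nfeat);
  for (int f = 0; f < nfeat; ++f) {
    fts[f] = as<std::string>(features[f]);
    if (fts[f] == "entropy1") need_hist = true;
    if (fts[f] == "contrast" || fts[f] == "ASM" || fts[f] == "entropy2" ||
        fts[f] == "homogeneity" || fts[f] == "dissimilarity" ||
        fts[f] == "correlation")
      need_glcm = true;
  }

  List out(nfeat);
  std::vector<NumericMatrix> mats(nfeat);
  for (int f = 0; f < nfeat; ++f) {
    mats[f] = NumericMatrix(nrow, ncol);
    out[f] = mats[f];
  }

  std::vector<double> counts((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve((size_t)window * window * noff * 2);
  std::vector<double> hist(levels, 0.0);
  std::vector<int> htouched;
  htouched.reserve((size_t)window * window);
  std::vector<int> qwin((size_t)window * window);
  std::vector<double> rwin((size_t)window * window);

  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      // extract mirrored window
      int k = 0;
      for (int dc = -rad; dc <= rad; ++dc) {
        int cc = reflect(c + dc, ncol);
        for (int dr = -rad; dr <= rad; ++dr) {
          int rr = reflect(r + dr, nrow);
          qwin[k] = qband(rr, cc);
          rwin[k] = band(rr, cc);
          ++k;
        }
      }
      // first-order
      double mean = 0.0;
      for (int i = 0; i < k; ++i) mean += rwin[i];
      mean /= k;
      double var = 0.0;
      for (int i = 0; i < k; ++i) {
        double d = rwin[i] - mean;
        var += d * d;
      }
      var /= k;
      double ent1 = 0.0;
      if (need_hist) {
        for (size_t i = 0; i < htouched.size(); ++i) hist[htouched[i]] = 0.0;
        htouched.clear();
        for (int i = 0; i < k; ++i) {
          if (hist[qwin[i]] == 0.0) htouched.push_back(qwin[i]);
          hist[qwin[i]] += 1.0;
        }
        for (size_t i = 0; i < htouched.size(); ++i) {
          double p = hist[htouched[i]] / k;
          ent1 -= p * std::log(p) / LOG2;
        }
      }
      // second-order: pool pair counts over offsets, within the window
      double contrast = 0, asm_ = 0, ent2 = 0, homog = 0, dissim = 0,
             corr = 0;
      if (need_glcm) {
        for (size_t i = 0; i < touched.size(); ++i) counts[touched[i]] = 0.0;
        touched.clear();
        double total = 0.0;
        for (int o = 0; o < noff; ++o) {
          int dr = offsets(o, 0), dc = offsets(o, 1);
          for (int wc = 0; wc < window; ++wc) {
            int pc = wc + dc;
            if (pc < 0 || pc >= window) continue;
            for (int wr = 0; wr < window; ++wr) {
              int pr = wr + dr;
              if (pr < 0 || pr >= window) continue;
              int q1 = qwin[wc * window + wr];
              int q2 = qwin[pc * window + pr];
              int idx = q1 * levels + q2;
              if (counts[idx] == 0.0) touched.push_back(idx);
              counts[idx] += 1.0;
              total += 1.0;
              if (symmetric) {
                int idx2 = q2 * levels + q1;
                if (counts[idx2] == 0.0) touched.push_back(idx2);
                counts[idx2] += 1.0;
                total += 1.0;
              }
            }
          }
        }
        double mi = 0, mj = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          int idx = touched[t];
          double p = counts[idx] / total;
          int i = idx / levels, j = idx % levels;
          double dij = i - j;
          contrast += p * dij * dij;
          asm_ += p * p;
          ent2 -= p * std::log(p) / LOG2;
          homog += p / (1.0 + dij * dij);
          dissim += p * std::fabs(dij);
          mi += p * i;
          mj += p * j;
        }
        double vi = 0, vj = 0, cov = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          int idx = touched[t];
          double p = counts[idx] / total;
          int i = idx / levels, j = idx % levels;
          vi += p * (i - mi) * (i - mi);
          vj += p * (j - mj) * (j - mj);
          cov += p * (i - mi) * (j - mj);
        }
        double denom = std::sqrt(vi * vj);
        corr = denom > 1e-12 ? cov / denom : 1.0;
      }
      for (int f = 0; f < nfeat; ++f) {
        double v = NA_REAL;
        const std::string& ft = fts[f];
        if (ft == "mean") v = mean;
        else if (ft == "variance") v = var;
        else if (ft == "entropy1") v = ent1;
        else if (ft == "contrast") v = contrast;
        else if (ft == "ASM") v = asm_;
        else if (ft == "entropy2") v = ent2;
        else if (ft == "homogeneity") v = homog;
        else if (ft == "dissimilarity") v = dissim;
        else if (ft == "correlation") v = corr;
        mats[f](r, c) = v;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("names") = features;
  return out;
}
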