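#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lower median: for even n the smaller of the two middle order statistics.
static double lower_median(std::vector<double>& v) {
  const R_xlen_t n = v.size();
  if (n == 0) return NA_REAL;
  const R_xlen_t k = (n - 1) / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  return v[k];
}

//' @noRd
// [[Rcpp::export(name = ".px_median_mad")]]
List px_median_mad(List frames) {
  const int nf = frames.size();
  if (nf < 1) stop("no frames");
  NumericMatrix f0 = as<NumericMatrix>(frames[0]);
  const int nr = f0.nrow(), nc = f0.ncol();
  std::vector<const double*> ptrs(nf);
  std::vector<NumericMatrix> mats;
  mats.reserve(nf);
  for (int i = 0; i < nf; ++i) {
    NumericMatrix m = as<NumericMatrix>(frames[i]);
    if (m.nrow() != nr || m.ncol() != nc) stop("frame shapes differ");
    mats.push_back(m);
    ptrs[i] = mats[i].begin();
  }
  NumericMatrix med(nr, nc), mad(nr, nc);
  std::vector<double> buf(nf), dev(nf);
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  for (R_xlen_t p = 0; p < npx; ++p) {
    for (int i = 0; i < nf; ++i) buf[i] = ptrs[i][p];
    std::vector<double> tmp(buf);
    const double m = lower_median(tmp);
    for (int i = 0; i < nf; ++i) dev[i] = std::fabs(buf[i] - m);
    const double s = lower_median(dev);
    med[p] = m;
    mad[p] = 1.4826 * s;  // consistency factor for the normal distribution
  }
  return List::create(_["location"] = med, _["spread"] = mad);
}

//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next_label = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next_label;
      while (!stack.empty()) {
        const std::pair<int, int> px = stack.back();
        stack.pop_back();
        for (int k = 0; k < nnb; ++k) {
          const int rr = px.first + dr8[k], cc = px.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next_label;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".morph")]]
LogicalMatrix morph(LogicalMatrix mask, IntegerMatrix offsets, bool erode) {
  const int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool val = erode;  // erode: AND over SE; dilate: OR over SE
      for (int i = 0; i < k; ++i) {
        const int rr = r + offsets(i, 0), cc = c + offsets(i, 1);
        const bool v = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ?
          (bool)mask(rr, cc) : false;
        if (erode) { if (!v) { val = false; break; } }
        else       { if (v)  { val = true;  break; } }
      }
      out(r, c) = val;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".segment_frame")]]
LogicalMatrix segment_frame(NumericMatrix frame, NumericMatrix location,
                            NumericMatrix threshold, IntegerMatrix offsets,
                            LogicalMatrix monitored, int polarity) {
  // polarity: 0 = dark foreground (location - frame), 1 = light, 2 = two-sided
  const int nr = frame.nrow(), nc = frame.ncol();
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  LogicalMatrix raw(nr, nc);
  std::vector<std::pair<int, int> > fg;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double dev = location(r, c) - frame(r, c);
      if (polarity == 1) dev = -dev;
      else if (polarity == 2) dev = std::fabs(dev);
      if (dev > threshold(r, c)) {
        raw(r, c) = true;
        fg.push_back(std::make_pair(r, c));
      }
    }
  }
  const int k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  if (k == 0) {
    for (R_xlen_t p = 0; p < npx; ++p) out[p] = raw[p] && monitored[p];
    return out;
  }
  // opening (erosion then dilation), visiting only foreground pixels
  std::vector<std::pair<int, int> > core;
  for (size_t i = 0; i < fg.size(); ++i) {
    const int r = fg[i].first, c = fg[i].second;
    bool keep = true;
    for (int j = 0; j < k; ++j) {
      const int rr = r + offsets(j, 0), cc = c + offsets(j, 1);
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !raw(rr, cc)) {
        keep = false; break;
      }
    }
    if (keep) core.push_back(fg[i]);
  }
  for (size_t i = 0; i < core.size(); ++i) {
    const int r = core[i].first, c = core[i].second;
    for (int j = 0; j < k; ++j) {
      const int rr = r + offsets(j, 0), cc = c + offsets(j, 1);
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && monitored(rr, cc))
        out(rr, cc) = true;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".blob_stats")]]
NumericMatrix blob_stats(IntegerMatrix lab, int nlab) {
  // columns: area, sum_x (col, 0-based), sum_y (row, 0-based)
  NumericMatrix out(nlab, 3);
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l > 0) {
        out(l - 1, 0) += 1.0;
        out(l - 1, 1) += (double)c;
        out(l - 1, 2) += (double)r;
      }
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".blob_stats_weighted")]]
NumericMatrix blob_stats_weighted(IntegerMatrix lab, int nlab,
                                  NumericMatrix w) {
  // columns: area, sum_w, sum_w*x, sum_w*y (x = col, y = row, 0-based)
  NumericMatrix out(nlab, 4);
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l > 0) {
        const double wv = std::max(w(r, c), 0.0);
        out(l - 1, 0) += 1.0;
        out(l - 1, 1) += wv;
        out(l - 1, 2) += wv * c;
        out(l - 1, 3) += wv * r;
      }
    }
  }
  return out;
}
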