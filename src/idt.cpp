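#include <Rcpp.h>
using namespace Rcpp;

// Dispersion-based (I-DT) fixation detection over valid gaze samples.
//
// Scans maximal runs of valid samples; within a run, grows a window until
// its dispersion exceeds max_dispersion_px, emitting a fixation when the
// window also spans at least min_duration_ms.  Invalid samples (blinks /
// tracking loss) terminate any open window, so blinks split fixations.
//
// dispersion_mode: 0 = (max x - min x) + (max y - min y)  [Salvucci-Goldberg]
//                  1 = max pairwise Euclidean distance
//
// Returns a 5-column matrix: start index, end index (1-based, inclusive),
// onset ms, offset ms, and member count; centroids are computed in R.

static double window_dispersion_pw(const NumericVector& x, const NumericVector& y,
                                   int i, int j) {
  double best = 0.0;
  for (int a = i; a <= j; ++a) {
    for (int b = a + 1; b <= j; ++b) {
      double dx = x[a] - x[b], dy = y[a] - y[b];
      double d2 = dx * dx + dy * dy;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export(name = ".idt_detect_cpp")]]
NumericMatrix idt_detect_cpp(NumericVector t, NumericVector x, NumericVector y,
                             LogicalVector valid, double min_duration_ms,
                             double max_dispersion_px, int dispersion_mode) {
  const int n = t.size();
  std::vector<double> out;  // rows of 5

  int i = 0;
  while (i < n) {
    if (!valid[i]) { ++i; continue; }
    // end of the current valid run
    int run_end = i;
    while (run_end + 1 < n && valid[run_end + 1]) ++run_end;

    int s = i;
    while (s <= run_end) {
      // grow window from s keeping dispersion within threshold
      double xmin = x[s], xmax = x[s], ymin = y[s], ymax = y[s];
      int e = s;
      while (e + 1 <= run_end) {
        int k = e + 1;
        bool ok;
        if (dispersion_mode == 0) {
          double nxmin = std::min(xmin, x[k]), nxmax = std::max(xmax, x[k]);
          double nymin = std::min(ymin, y[k]), nymax = std::max(ymax, y[k]);
          ok = (nxmax - nxmin) + (nymax - nymin) <= max_dispersion_px;
          if (ok) { xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax; }
        } else {
          ok = window_dispersion_pw(x, y, s, k) <= max_dispersion_px;
        }
        if (!ok) break;
        e = k;
      }
      if (t[e] - t[s] >= min_duration_ms) {
        out.push_back(s + 1);
        out.push_back(e + 1);
        out.push_back(t[s]);
        out.push_back(t[e]);
        out.push_back(e - s + 1);
        s = e + 1;
      } else {
        ++s;
      }
    }
    i = run_end + 1;
  }

  const int nf = out.size() / 5;
  NumericMatrix res(nf, 5);
  for (int r = 0; r < nf; ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = out[r * 5 + c];
  return res;
}
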