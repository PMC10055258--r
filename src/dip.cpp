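#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Hartigan & Hartigan's dip statistic for unimodality: the minimum over all
// unimodal distribution functions G of sup_x |F_n(x) - G(x)|, where F_n is
// the empirical CDF. Computed by iteratively narrowing a candidate modal
// interval: below it the fit follows the greatest convex minorant (GCM) of
// the lower CDF staircase, above it the least concave majorant (LCM) of the
// upper staircase. The attained sup-deviation is half the residual gap in
// count units, because the optimal G splits each one-sided gap symmetrically.
//
// Conventions: hull touch points are computed on the points (x_i, i)
// (0-based); the GCM is evaluated as interpolation minus 1 (lower staircase
// value i-1+1 = i at jumps), which surfaces as the +/-1 offsets in the
// deviation formulas below.

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
  const int n = xs.size();
  if (n < 1) Rcpp::stop("empty sample");
  if (n == 1) return 0.0;

  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  if (x[0] == x[n - 1]) return 0.0;  // point mass is unimodal

  std::vector<int> mn(n), mj(n), gcm(n + 1), lcm(n + 1);
  int low = 0, high = n - 1;
  double dip = 1.0;  // count units; final statistic dip/(2n)

  for (;;) {
    // previous-touch pointers of the GCM over points (x_i, i), i in [low, high]
    mn[low] = low;
    for (int j = low + 1; j <= high; ++j) {
      mn[j] = j - 1;
      for (;;) {
        int mnj = mn[j];
        if (mnj == low) break;
        int mnmnj = mn[mnj];
        if ((x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj))
          break;
        mn[j] = mnmnj;
      }
    }
    // next-touch pointers of the LCM
    mj[high] = high;
    for (int k = high - 1; k >= low; --k) {
      mj[k] = k + 1;
      for (;;) {
        int mjk = mj[k];
        if (mjk == high) break;
        int mjmjk = mj[mjk];
        if ((x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk))
          break;
        mj[k] = mjmjk;
      }
    }

    // GCM touch points, decreasing: gcm[0] = high ... gcm[icx] = low
    int icx = 0;
    gcm[0] = high;
    while (gcm[icx] > low) { gcm[icx + 1] = mn[gcm[icx]]; ++icx; }
    // LCM touch points, increasing: lcm[0] = low ... lcm[icv] = high
    int icv = 0;
    lcm[0] = low;
    while (lcm[icv] < high) { lcm[icv + 1] = mj[lcm[icv]]; ++icv; }

    // largest gap d between the LCM and GCM curves over [low, high]
    int ix = icx - 1, iv = 1;
    int ig = icx, ih = icv;
    double d = 0.0;
    if (icx != 1 || icv != 1) {
      do {
        int gcmix = gcm[ix];
        int lcmiv = lcm[iv];
        if (gcmix > lcmiv) {
          // LCM touch point under a GCM chord
          int gcmi1 = gcm[ix + 1];
          double w = x[gcmix] - x[gcmi1];
          double dx = (w > 0.0)
            ? (lcmiv - gcmi1 + 1) - (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / w
            : (lcmiv - gcmi1 + 1) - (double)(gcmix - gcmi1);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // GCM touch point under an LCM chord
          int lcmiv1 = lcm[iv - 1];
          double w = x[lcmiv] - x[lcmiv1];
          double dx = (w > 0.0)
            ? (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) / w - (gcmix - lcmiv1 - 1)
            : (double)(lcmiv - lcmiv1) - (gcmix - lcmiv1 - 1);
          --ix;
          if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 0) ix = 0;
        if (iv > icv) iv = icv;
      } while (gcm[ix] != lcm[iv]);
    } else {
      d = 1.0;
    }

    if (d < dip) break;

    // deviation of F_n above the GCM fit between old low and new low
    double dl = 0.0;
    for (int j = ig; j < icx; ++j) {
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1) {
        double w = x[je] - x[jb];
        if (w > 0.0) {
          double c = (je - jb) / w;
          for (int jr = jb + 1; jr < je; ++jr) {
            double t = (jr - jb + 1) - (x[jr] - x[jb]) * c;
            if (t > dl) dl = t;
          }
        }
      }
    }
    // deviation of the LCM fit above F_n between new high and old high
    double du = 0.0;
    for (int j = ih; j < icv; ++j) {
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1) {
        double w = x[je] - x[jb];
        if (w > 0.0) {
          double c = (je - jb) / w;
          for (int jr = jb + 1; jr < je; ++jr) {
            double t = (x[jr] - x[jb]) * c - (jr - jb - 1);
            if (t > du) du = t;
          }
        }
      }
    }
    double dipnew = (dl > du) ? dl : du;
    if (dipnew > dip) dip = dipnew;

    if (low == gcm[ig] && high == lcm[ih]) break;  // cannot narrow further
    low = gcm[ig];
    high = lcm[ih];
  }

  return dip / (2.0 * n);
}

// Monte-Carlo null dips: dip statistics of `reps` uniform(0,1) samples of
// size n, drawing from R's RNG so the seed is controlled from R.

// [[Rcpp::export]]
Rcpp::NumericVector dip_null_cpp(int n, int reps) {
  Rcpp::NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    Rcpp::NumericVector u = Rcpp::runif(n);
    out[r] = dip_stat_cpp(u);
  }
  return out;
}
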