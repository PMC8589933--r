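#include <Rcpp.h>
#include <queue>
#include <vector>

// Exact minimal transportation work between two histograms on the integer
// line 0..n-1 with ground distance |i - j| and partial matching: only
// flow = min(sum u, sum v) mass is moved; the surplus of the heavier
// histogram stays where it is, chosen to minimize the work.
//
// Reduction: let U >= V (swap otherwise) and T = U - V the mass left
// behind. Writing S_i for the cumulative discarded mass through bin i,
// the net flux across the edge between bins i and i+1 is
// cumsum(u)_i - S_i - cumsum(v)_i, and the work is the sum of |flux|
// over edges. So we minimize sum_i |D_i - S_i| over nondecreasing S with
// per-bin increments bounded by u_i and S_{n-1} = T, where
// D_i = cumsum(u)_i - cumsum(v)_i. That convex piecewise-linear DP is
// solved exactly with the classic two-heap "slope trick": widening the
// feasible window by u_i shifts the right slope set, and each |D_i - S|
// term adds one breakpoint on each side. Clamping breakpoints at 0
// encodes S >= 0 (for S >= 0 > D, |D - S| is linear S - D).
//
// Increment caps beyond the window width never bind at the optimum
// (clipping an optimal relaxed path to the cumulative caps is feasible
// and never increases the cost, because D_i <= cumsum(u)_i), so the
// relaxed slope-trick value equals the constrained optimum.

// [[Rcpp::export]]
double emd1d_work(Rcpp::NumericVector u, Rcpp::NumericVector v) {
  const int n = u.size();
  if (v.size() != n) Rcpp::stop("signatures must have equal length");
  long double U = 0.0L, V = 0.0L;
  for (int i = 0; i < n; ++i) {
    if (u[i] < 0 || v[i] < 0) Rcpp::stop("signature weights must be non-negative");
    U += u[i];
    V += v[i];
  }
  const bool swap = (U < V);
  const Rcpp::NumericVector &a = swap ? v : u;
  const Rcpp::NumericVector &b = swap ? u : v;
  const long double T = (swap ? V - U : U - V);
  if (n == 1) return 0.0;

  std::priority_queue<long double> L;  // max-heap: breakpoints left of minimum
  std::priority_queue<long double, std::vector<long double>,
                      std::greater<long double> > R;  // min-heap, lazy offset
  long double offR = 0.0L, minval = 0.0L;
  long double cu = 0.0L, cv = 0.0L;

  for (int i = 0; i < n - 1; ++i) {
    cu += a[i];
    cv += b[i];
    offR += a[i];  // window: S_i in [S_{i-1}, S_{i-1} + u_i]
    long double D = cu - cv;
    long double cst = 0.0L;
    if (D < 0) { cst = -D; D = 0.0L; }  // valid on the domain S >= 0
    minval += cst;
    // add |S - D|
    L.push(D);
    R.push(D - offR);
    long double tl = L.top(), tr = R.top() + offR;
    if (tl > tr) {
      minval += tl - tr;
      L.pop(); R.pop();
      L.push(tr);
      R.push(tl - offR);
    }
  }
  // final widening by u_{n-1}, then evaluate at S = T
  offR += a[n - 1];
  long double res = minval;
  while (!L.empty() && L.top() > T) {
    res += L.top() - T;
    L.pop();
  }
  while (!R.empty() && R.top() + offR < T) {
    res += T - (R.top() + offR);
    R.pop();
  }
  return (double)res;
}

// Pairwise partial-matching EMD (work / flow) between rows of a weight
// matrix. With joint_shift = true each pair of rows is first shifted by
// -min(both rows) so that possibly-negative feature rows become valid
// masses; with joint_shift = false rows must already be non-negative.
// [[Rcpp::export]]
Rcpp::NumericMatrix emd1d_pairwise(Rcpp::NumericMatrix x,
                                   bool joint_shift = true) {
  const int nr = x.nrow(), nc = x.ncol();
  Rcpp::NumericMatrix out(nr, nr);
  Rcpp::NumericVector ui(nc), vj(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = i + 1; j < nr; ++j) {
      double mn = 0.0;
      if (joint_shift) {
        mn = R_PosInf;
        for (int k = 0; k < nc; ++k) {
          if (x(i, k) < mn) mn = x(i, k);
          if (x(j, k) < mn) mn = x(j, k);
        }
      }
      long double su = 0.0L, sv = 0.0L;
      for (int k = 0; k < nc; ++k) {
        ui[k] = x(i, k) - mn;
        vj[k] = x(j, k) - mn;
        su += ui[k];
        sv += vj[k];
      }
      double flow = (double)(su < sv ? su : sv);
      double w = emd1d_work(ui, vj);
      double d = (flow > 0.0) ? w / flow : 0.0;
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
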