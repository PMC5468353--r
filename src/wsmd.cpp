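#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binding energies of all windows in a bag.
// sites: nwin x l matrix of base codes (1=A,2=C,3=G,4=T); W: 4 x l weight matrix.
// [[Rcpp::export]]
NumericVector cpp_window_energies(IntegerMatrix sites, NumericMatrix W) {
  const int n = sites.nrow(), l = sites.ncol();
  NumericVector e(n);
  for (int j = 0; j < l; ++j) {
    for (int i = 0; i < n; ++i) e[i] += W(sites(i, j) - 1, j);
  }
  return e;
}

// Minimal Hamming distance between a k-word and all k-windows of a sequence,
// both strands. Windows containing N (NA codes) are skipped. Returns NA if no
// valid window exists.
// [[Rcpp::export]]
IntegerVector cpp_smd_word(IntegerVector word, IntegerVector fwd, IntegerVector rc) {
  const int k = word.size();
  int best = NA_INTEGER;
  for (int pass = 0; pass < 2; ++pass) {
    const IntegerVector &c = (pass == 0) ? fwd : rc;
    const int n = c.size();
    for (int s = 0; s + k <= n; ++s) {
      int d = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        const int v = c[s + j];
        if (v == NA_INTEGER) { ok = false; break; }
        if (v != word[j]) ++d;
      }
      if (ok && (best == NA_INTEGER || d < best)) best = d;
    }
  }
  return IntegerVector::create(best);
}

// Substring minimal distance from every one of the 4^k exact k-words to one
// sequence (both strands), computed as a multi-source BFS over the Hamming
// graph of the word space: words occurring in the sequence are sources at
// distance 0, each single-base substitution is an edge.
// Word index is big-endian base-4 so that ascending index = lexicographic order.
// [[Rcpp::export]]
IntegerVector cpp_smd_all_words(IntegerVector fwd, IntegerVector rc, int k) {
  int M = 1;
  for (int i = 0; i < k; ++i) M *= 4;
  IntegerVector dist(M, NA_INTEGER);
  std::vector<int> frontier, nxt;
  for (int pass = 0; pass < 2; ++pass) {
    const IntegerVector &c = (pass == 0) ? fwd : rc;
    const int n = c.size();
    for (int s = 0; s + k <= n; ++s) {
      int idx = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        const int v = c[s + j];
        if (v == NA_INTEGER) { ok = false; break; }
        idx = idx * 4 + (v - 1);
      }
      if (ok && dist[idx] == NA_INTEGER) { dist[idx] = 0; frontier.push_back(idx); }
    }
  }
  std::vector<int> pow4(k);
  pow4[k - 1] = 1;
  for (int j = k - 2; j >= 0; --j) pow4[j] = pow4[j + 1] * 4;
  int d = 0;
  while (!frontier.empty()) {
    ++d; nxt.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      const int idx = frontier[f];
      for (int j = 0; j < k; ++j) {
        const int b = (idx / pow4[j]) % 4;
        const int base0 = idx - b * pow4[j];
        for (int nb = 0; nb < 4; ++nb) {
          if (nb == b) continue;
          const int nidx = base0 + nb * pow4[j];
          if (dist[nidx] == NA_INTEGER) { dist[nidx] = d; nxt.push_back(nidx); }
        }
      }
    }
    frontier.swap(nxt);
  }
  return dist;
}

// Exact SMO solver for the dual of
//   min_{w,b,xi}  ||w||^2 + Cbox * sum_g xi_g
//   s.t. y_g (w'x_i - b) >= 1 - xi_g  for every window i of group (sequence) g,
//        xi_g >= 0,
// where Cbox = c/N already includes the 1/N scaling. The dual is
//   min_a 1/2 a'Qa - 1'a,  Q_ij = y_i y_j (x_i.x_j)/2,
//   s.t. y'a = 0, a >= 0, sum_{i in g} a_i <= Cbox for each group g.
// All windows of one group share the group's label. Pair selection is
// max-violating-pair; within-group transfer pairs keep groups at budget
// optimizable. Deterministic given the input order.
// [[Rcpp::export]]
List cpp_smo(NumericMatrix X, NumericVector y, double Cbox, IntegerVector group,
             int ngroup, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  // dense Q cache
  std::vector<double> Q((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int t = 0; t < p; ++t) s += X(i, t) * X(j, t);
      const double q = 0.5 * y[i] * y[j] * s;
      Q[(size_t)i * n + j] = q;
      Q[(size_t)j * n + i] = q;
    }
  }
  std::vector<double> a(n, 0.0), g(n, -1.0), gsum(ngroup, 0.0);
  const double eps_a = 1e-12 * std::max(1.0, Cbox);
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    // F_i = -y_i * grad_i; want max over movable-up i, min over movable-down j
    int bi = -1, bj = -1;
    double Fup = -HUGE_VAL, Flo = HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      const double Fi = -y[i] * g[i];
      const int gi = group[i];
      const bool slack = gsum[gi] < Cbox - eps_a;
      // role i: alpha_i moves by +y_i t (t > 0)
      const bool up_ok = (y[i] > 0) ? (a[i] < Cbox - eps_a && slack) : (a[i] > eps_a);
      // role j: alpha_j moves by -y_j t
      const bool lo_ok = (y[i] > 0) ? (a[i] > eps_a) : (a[i] < Cbox - eps_a && slack);
      if (up_ok && Fi > Fup) { Fup = Fi; bi = i; }
      if (lo_ok && Fi < Flo) { Flo = Fi; bj = i; }
    }
    double gap = (bi >= 0 && bj >= 0) ? (Fup - Flo) : -HUGE_VAL;
    // within-group transfer pairs (both members share y, group may be at budget)
    int wi = -1, wj = -1;
    double wgap = -HUGE_VAL;
    if (ngroup < n) {
      std::vector<int> gmaxi(ngroup, -1), gmini(ngroup, -1);
      std::vector<double> gmax(ngroup, -HUGE_VAL), gmin(ngroup, HUGE_VAL);
      for (int i = 0; i < n; ++i) {
        const int gi = group[i];
        const double Fi = -y[i] * g[i];
        // up-role: alpha_i movable in +y_i direction; low-role: in -y_i direction
        const bool up_ok = (y[i] > 0) ? (a[i] < Cbox - eps_a) : (a[i] > eps_a);
        const bool lo_ok = (y[i] > 0) ? (a[i] > eps_a) : (a[i] < Cbox - eps_a);
        if (up_ok && Fi > gmax[gi]) { gmax[gi] = Fi; gmaxi[gi] = i; }
        if (lo_ok && Fi < gmin[gi]) { gmin[gi] = Fi; gmini[gi] = i; }
      }
      for (int gg = 0; gg < ngroup; ++gg) {
        if (gmaxi[gg] >= 0 && gmini[gg] >= 0 && gmaxi[gg] != gmini[gg]) {
          const double gp = gmax[gg] - gmin[gg];
          if (gp > wgap) { wgap = gp; wi = gmaxi[gg]; wj = gmini[gg]; }
        }
      }
    }
    if (wgap > gap) { gap = wgap; bi = wi; bj = wj; }
    if (gap < tol) { converged = true; break; }
    const int i = bi, j = bj;
    // step t >= 0: a_i += y_i t, a_j -= y_j t
    const size_t in = (size_t)i * n, jn = (size_t)j * n;
    double quad = Q[in + i] + Q[jn + j] - 2.0 * y[i] * y[j] * Q[in + j];
    if (quad <= 1e-14) quad = 1e-14;
    double t = ((-y[i] * g[i]) - (-y[j] * g[j])) / quad;
    // box limits
    double tmax = HUGE_VAL;
    if (y[i] > 0) tmax = std::min(tmax, Cbox - a[i]); else tmax = std::min(tmax, a[i]);
    if (y[j] > 0) tmax = std::min(tmax, a[j]); else tmax = std::min(tmax, Cbox - a[j]);
    // group budget limits
    const int gi = group[i], gj = group[j];
    if (gi == gj) {
      // net group change (y_i - y_j) t = 0 since labels equal within a group
    } else {
      if (y[i] > 0) tmax = std::min(tmax, Cbox - gsum[gi]);      // group i grows
      if (y[j] < 0) tmax = std::min(tmax, Cbox - gsum[gj]);      // group j grows
    }
    if (t > tmax) t = tmax;
    if (t <= 0) { converged = true; break; }  // numerically stuck at a KKT point
    const double dai = y[i] * t, daj = -y[j] * t;
    a[i] += dai; a[j] += daj;
    gsum[gi] += dai; gsum[gj] += daj;
    for (int s = 0; s < n; ++s) g[s] += Q[in + s] * dai + Q[jn + s] * daj;
  }
  NumericVector alpha(a.begin(), a.end());
  return List::create(_["alpha"] = alpha, _["iterations"] = iter,
                      _["converged"] = converged);
}
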