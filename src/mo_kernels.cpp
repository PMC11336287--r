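// Multi-objective kernels: fast non-dominated sorting (with optional
// feasibility-first constraint domination), inverted generational
// distance, incremental non-dominated archive update, and
// spread-preserving thinning of point sets.

#include <Rcpp.h>
using namespace Rcpp;

// a dominates b under feasibility-first constraint domination
static inline bool dominates(const double* F, int n, int M, int a, int b,
                             const double* viol) {
  if (viol) {
    const double va = viol[a], vb = viol[b];
    if (va == 0.0 && vb > 0.0) return true;
    if (va > 0.0 && vb == 0.0) return false;
    if (va > 0.0 && vb > 0.0) return va < vb;
  }
  bool strict = false;
  for (int m = 0; m < M; ++m) {
    const double fa = F[a + m * n], fb = F[b + m * n];
    if (fa > fb) return false;
    if (fa < fb) strict = true;
  }
  return strict;
}

// [[Rcpp::export]]
IntegerVector nds_ranks_cpp(NumericMatrix objs, NumericVector violation) {
  const int n = objs.nrow(), M = objs.ncol();
  const double* F = REAL(objs);
  const double* viol = violation.size() == n ? REAL(violation) : NULL;
  std::vector<int> np(n, 0);
  std::vector<std::vector<int> > S(n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      if (dominates(F, n, M, a, b, viol)) S[a].push_back(b);
      else if (dominates(F, n, M, b, a, viol)) ++np[a];
    }
  IntegerVector rank(n, 0);
  std::vector<int> front;
  for (int i = 0; i < n; ++i) if (np[i] == 0) { rank[i] = 1; front.push_back(i); }
  int r = 1;
  while (!front.empty()) {
    std::vector<int> nxt;
    for (size_t k = 0; k < front.size(); ++k)
      for (size_t j = 0; j < S[front[k]].size(); ++j) {
        const int q = S[front[k]][j];
        if (--np[q] == 0) { rank[q] = r + 1; nxt.push_back(q); }
      }
    front.swap(nxt);
    ++r;
  }
  return rank;
}

// [[Rcpp::export]]
double igd_cpp(NumericMatrix P, NumericMatrix Q) {
  const int np = P.nrow(), nq = Q.nrow(), M = P.ncol();
  const double* p = REAL(P);
  const double* q = REAL(Q);
  double total = 0.0;
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nq; ++j) {
      double d = 0.0;
      for (int m = 0; m < M; ++m) {
        const double diff = p[i + m * np] - q[j + m * nq];
        d += diff * diff;
      }
      if (d < best) best = d;
    }
    total += std::sqrt(best);
  }
  return total / np;
}

// Incremental non-dominated archive update. A holds mutually
// non-dominated points; C are candidates. Returns logical keep masks.
// [[Rcpp::export]]
List nd_update_cpp(NumericMatrix A, NumericMatrix C) {
  const int na = A.nrow(), nc = C.nrow(), M = A.ncol();
  LogicalVector keepA(na, true), keepC(nc, true);
  // candidate vs candidate
  for (int i = 0; i < nc; ++i) {
    if (!keepC[i]) continue;
    for (int j = 0; j < nc; ++j) {
      if (i == j || !keepC[j]) continue;
      bool iDomJ = true, strict = false, jEqI = true;
      for (int m = 0; m < M; ++m) {
        const double fi = C(i, m), fj = C(j, m);
        if (fi > fj) { iDomJ = false; }
        if (fi < fj) { strict = true; }
        if (fi != fj) jEqI = false;
      }
      if (iDomJ && strict) keepC[j] = false;
      else if (jEqI && j < i) keepC[i] = false;  // drop duplicates
    }
  }
  // candidate vs archive
  for (int i = 0; i < nc; ++i) {
    if (!keepC[i]) continue;
    for (int j = 0; j < na; ++j) {
      if (!keepA[j]) continue;
      bool cDomA = true, cStrict = false;
      bool aDomC = true, aStrict = false, equal = true;
      for (int m = 0; m < M; ++m) {
        const double fc = C(i, m), fa = A(j, m);
        if (fc > fa) { cDomA = false; aStrict = true; }
        else if (fc < fa) { aDomC = false; cStrict = true; }
        if (fc != fa) equal = false;
      }
      if (equal || (aDomC && aStrict)) { keepC[i] = false; break; }
      if (cDomA && cStrict) keepA[j] = false;
    }
  }
  return List::create(_["keepA"] = keepA, _["keepC"] = keepC);
}

// Thin a point set to `target` points by greedily removing the point
// with the smallest nearest-neighbour distance; per-objective extreme
// points are never removed. Returns kept indices (1-based).
// [[Rcpp::export]]
IntegerVector thin_points_cpp(NumericMatrix X, int target) {
  const int n = X.nrow(), M = X.ncol();
  if (n <= target) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  std::vector<bool> alive(n, true), fixed(n, false);
  for (int m = 0; m < M; ++m) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (X(i, m) < X(imin, m)) imin = i;
      if (X(i, m) > X(imax, m)) imax = i;
    }
    fixed[imin] = fixed[imax] = true;
  }
  auto dist2 = [&](int a, int b) {
    double d = 0.0;
    for (int m = 0; m < M; ++m) {
      const double diff = X(a, m) - X(b, m);
      d += diff * diff;
    }
    return d;
  };
  std::vector<double> nnd(n);
  std::vector<int> nni(n);
  auto rescan = [&](int i) {
    double best = R_PosInf; int bi = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i || !alive[j]) continue;
      const double d = dist2(i, j);
      if (d < best) { best = d; bi = j; }
    }
    nnd[i] = best; nni[i] = bi;
  };
  for (int i = 0; i < n; ++i) rescan(i);
  int n_alive = n;
  while (n_alive > target) {
    int drop = -1; double best = R_PosInf;
    for (int i = 0; i < n; ++i)
      if (alive[i] && !fixed[i] && nnd[i] < best) { best = nnd[i]; drop = i; }
    if (drop < 0) break;
    alive[drop] = false;
    --n_alive;
    for (int i = 0; i < n; ++i)
      if (alive[i] && nni[i] == drop) rescan(i);
  }
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) if (alive[i]) keep.push_back(i + 1);
  return wrap(keep);
}
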