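#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-phase dense tableau simplex for small LPs.
//
// Solves: maximize c'x  subject to  A x (rel) b,  x >= 0
// where rel[i] is -1 (<=), 0 (=), or +1 (>=).
//
// Designed for DEA envelopment problems: few constraint rows (p inputs +
// q outputs + 1 convexity), up to a few hundred columns, data pre-scaled
// to O(1) by the caller. Entering column: Dantzig rule with a
// largest-pivot tie-break in the ratio test for numerical stability,
// switching to Bland's rule after many iterations as an anti-cycling
// safeguard.

static const double RCOST_EPS = 1e-9;  // reduced-cost threshold
static const double PIVOT_EPS = 1e-7;  // minimal acceptable pivot element

struct Tableau {
  int m, ncol;                 // rows, total columns (excluding rhs)
  std::vector<double> T;       // (m+1) x (ncol+1), row-major; last row = cost
  std::vector<int> basis;      // basic variable per row
  inline double &at(int i, int j) { return T[(size_t)i * (ncol + 1) + j]; }
};

static void pivot(Tableau &tb, int pr, int pc) {
  int w = tb.ncol + 1;
  double piv = tb.at(pr, pc);
  for (int j = 0; j < w; ++j) tb.at(pr, j) /= piv;
  tb.at(pr, pc) = 1.0;
  for (int i = 0; i <= tb.m; ++i) {
    if (i == pr) continue;
    double f = tb.at(i, pc);
    if (std::fabs(f) < 1e-14) continue;
    for (int j = 0; j < w; ++j) tb.at(i, j) -= f * tb.at(pr, j);
    tb.at(i, pc) = 0.0;
  }
  // guard against drift: the rhs column stays non-negative in exact
  // arithmetic, clamp tiny negatives
  for (int i = 0; i < tb.m; ++i)
    if (tb.at(i, tb.ncol) < 0 && tb.at(i, tb.ncol) > -1e-9)
      tb.at(i, tb.ncol) = 0.0;
  tb.basis[pr] = pc;
}

// Returns 0 optimal, 1 unbounded, 2 iteration limit.
static int simplex_iterate(Tableau &tb, const std::vector<bool> &allowed) {
  const int maxit = 20000, bland_after = 2000;
  for (int it = 0; it < maxit; ++it) {
    bool bland = it >= bland_after;
    int pc = -1;
    double best_rc = RCOST_EPS;
    for (int j = 0; j < tb.ncol; ++j) {
      if (!allowed[j]) continue;
      double rc = tb.at(tb.m, j);
      if (rc > best_rc) {
        pc = j;
        if (bland) break;       // first improving index
        best_rc = rc;           // most positive reduced cost
      }
    }
    if (pc < 0) return 0;
    int pr = -1;
    double best = 0.0;
    for (int i = 0; i < tb.m; ++i) {
      double a = tb.at(i, pc);
      if (a > PIVOT_EPS) {
        double ratio = tb.at(i, tb.ncol) / a;
        if (pr < 0) { pr = i; best = ratio; continue; }
        double tol = 1e-9 * (1.0 + std::fabs(best));
        if (ratio < best - tol) { pr = i; best = ratio; }
        else if (ratio < best + tol) {
          // tie: Bland wants the smallest basis index; otherwise prefer
          // the larger pivot element for stability
          if (bland ? (tb.basis[i] < tb.basis[pr])
                    : (a > tb.at(pr, pc))) { pr = i; best = ratio; }
        }
      }
    }
    if (pr < 0) return 1;
    pivot(tb, pr, pc);
  }
  return 2;
}

// status: 0 ok, 1 infeasible, 2 unbounded, 3 numerical failure
// [[Rcpp::export(name = ".simplex_lp")]]
List simplex_lp(NumericMatrix A, IntegerVector rel, NumericVector b,
                NumericVector obj, bool maximize) {
  int m = A.nrow(), n = A.ncol();
  if (rel.size() != m || b.size() != m || obj.size() != n)
    stop("inconsistent LP dimensions");

  // normalize to non-negative rhs
  std::vector<double> bb(b.begin(), b.end());
  std::vector<int> rr(rel.begin(), rel.end());
  std::vector<std::vector<double> > AA(m, std::vector<double>(n));
  for (int i = 0; i < m; ++i) {
    double s = (bb[i] < 0.0) ? -1.0 : 1.0;
    bb[i] *= s;
    if (s < 0) rr[i] = -rr[i];
    for (int j = 0; j < n; ++j) AA[i][j] = s * A(i, j);
  }

  int nslack = 0, nart = 0;
  for (int i = 0; i < m; ++i) {
    if (rr[i] != 0) ++nslack;
    if (rr[i] >= 0) ++nart;   // >= and = rows get an artificial
  }

  Tableau tb;
  tb.m = m;
  tb.ncol = n + nslack + nart;
  tb.T.assign((size_t)(m + 1) * (tb.ncol + 1), 0.0);
  tb.basis.assign(m, -1);

  int scol = n, acol = n + nslack;
  std::vector<int> artrow(m, -1);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) tb.at(i, j) = AA[i][j];
    tb.at(i, tb.ncol) = bb[i];
    if (rr[i] == -1) {            // <= : slack basic
      tb.at(i, scol) = 1.0;
      tb.basis[i] = scol++;
    } else if (rr[i] == 1) {      // >= : surplus + artificial basic
      tb.at(i, scol) = -1.0;
      ++scol;
      tb.at(i, acol) = 1.0;
      artrow[i] = acol;
      tb.basis[i] = acol++;
    } else {                      // = : artificial basic
      tb.at(i, acol) = 1.0;
      artrow[i] = acol;
      tb.basis[i] = acol++;
    }
  }

  std::vector<bool> allowed(tb.ncol, true);

  // Phase 1: maximize -(sum of artificials). After canonicalizing on the
  // artificial basis the cost-row rhs cell equals +sum(artificials), so
  // feasibility means driving it to 0.
  if (nart > 0) {
    for (int j = n + nslack; j < tb.ncol; ++j) tb.at(m, j) = -1.0;
    for (int i = 0; i < m; ++i) {
      if (artrow[i] >= 0) {
        for (int j = 0; j <= tb.ncol; ++j) tb.at(m, j) += tb.at(i, j);
      }
    }
    int st = simplex_iterate(tb, allowed);
    if (st != 0) return List::create(_["status"] = 3); // phase 1 cannot be unbounded
    double resid = tb.at(m, tb.ncol);
    if (resid > 1e-6) return List::create(_["status"] = 1); // infeasible
    // drive remaining artificials out of the basis where possible
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= n + nslack) {
        int pc = -1;
        double bestp = PIVOT_EPS;
        for (int j = 0; j < n + nslack; ++j)
          if (std::fabs(tb.at(i, j)) > bestp) { pc = j; bestp = std::fabs(tb.at(i, j)); }
        if (pc >= 0) pivot(tb, i, pc);
        // else: redundant row, artificial stays basic at zero (harmless)
      }
    }
    for (int j = n + nslack; j < tb.ncol; ++j) allowed[j] = false;
  }

  // Phase 2: install the real objective
  double sgn = maximize ? 1.0 : -1.0;
  for (int j = 0; j <= tb.ncol; ++j) tb.at(m, j) = 0.0;
  for (int j = 0; j < n; ++j) tb.at(m, j) = sgn * obj[j];
  for (int i = 0; i < m; ++i) {
    int bv = tb.basis[i];
    double c = tb.at(m, bv);
    if (std::fabs(c) > 1e-15)
      for (int j = 0; j <= tb.ncol; ++j) tb.at(m, j) -= c * tb.at(i, j);
  }
  int st = simplex_iterate(tb, allowed);
  if (st == 1) return List::create(_["status"] = 2); // unbounded
  if (st == 2) return List::create(_["status"] = 3);

  NumericVector x(n);
  for (int i = 0; i < tb.m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.at(i, tb.ncol);
  double z = 0.0;
  for (int j = 0; j < n; ++j) z += obj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objval"] = z);
}
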