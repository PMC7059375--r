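#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Output-oriented envelopment programs, solved by a dense two-phase tableau
// simplex.  Per evaluated unit (x0, y0):
//
//   max lambda   s.t.  Xr mu <= x0,
//                      Yr mu >= lambda * y0,
//                      sum(mu) = 1 (VRS) | sum(mu) <= 1 (NIRS),
//                      mu >= 0.
//
// Problems are tiny (p + q + 1 rows, n + 1 structural columns), so a dense
// tableau with a Bland anti-cycling fallback is both fast and robust; the
// bootstrap re-solves these programs hundreds of thousands of times.

namespace {

const double TOL = 1e-9;

struct Tableau {
    int m, n;                // rows, columns (RHS excluded from n)
    std::vector<double> a;   // m x (n + 1) row-major, last column = RHS
    std::vector<int> basis;  // basic column index per row
    double &at(int i, int j) { return a[(size_t)i * (n + 1) + j]; }
};

// reduced-cost row for cost vector c given the current basis (basis columns
// are unit vectors at entry, so the tableau body equals B^-1 A throughout)
void init_costrow(Tableau &tb, const std::vector<double> &c,
                  std::vector<double> &red) {
    red.assign(tb.n + 1, 0.0);
    for (int j = 0; j <= tb.n; ++j) {
        double v = (j < tb.n) ? c[j] : 0.0;
        for (int i = 0; i < tb.m; ++i) {
            double cb = c[tb.basis[i]];
            if (cb != 0.0) v -= cb * tb.at(i, j);
        }
        red[j] = v;
    }
}

// minimise c'x from the current feasible basis; 0 = optimal, 2 = unbounded
// or iteration limit.  bland_all forces Bland's anti-cycling rule from the
// first pivot (used on retry after a stalled Dantzig run).
int simplex_iterate(Tableau &tb, std::vector<double> &red,
                    const std::vector<bool> &allowed,
                    bool bland_all = false) {
    const int maxit = bland_all ? 200000 : 10000;
    for (int iter = 0; iter < maxit; ++iter) {
        bool bland = bland_all || iter > 2000;
        int enter = -1;
        double best = -TOL;
        for (int j = 0; j < tb.n; ++j) {
            if (!allowed[j]) continue;
            if (red[j] < (bland ? -TOL : best)) {
                enter = j;
                if (bland) break;
                best = red[j];
            }
        }
        if (enter < 0) return 0;
        int leave = -1;
        double ratio = 0.0;
        for (int i = 0; i < tb.m; ++i) {
            double aij = tb.at(i, enter);
            if (aij > TOL) {
                double r = tb.at(i, tb.n) / aij;
                if (leave < 0 || r < ratio - 1e-12 ||
                    (r < ratio + 1e-12 && tb.basis[i] < tb.basis[leave])) {
                    leave = i;
                    ratio = r;
                }
            }
        }
        if (leave < 0) return 2;
        double piv = tb.at(leave, enter);
        for (int j = 0; j <= tb.n; ++j) tb.at(leave, j) /= piv;
        for (int i = 0; i < tb.m; ++i) {
            if (i == leave) continue;
            double f = tb.at(i, enter);
            if (f != 0.0)
                for (int j = 0; j <= tb.n; ++j) tb.at(i, j) -= f * tb.at(leave, j);
        }
        double f = red[enter];
        if (f != 0.0)
            for (int j = 0; j <= tb.n; ++j) red[j] -= f * tb.at(leave, j);
        tb.basis[leave] = enter;
    }
    return 2;
}

// rts: 0 = CRS, 1 = VRS, 2 = NIRS.  Returns 0 ok, 1 infeasible, 2 no optimum.
// Every constraint row is rescaled by the evaluated unit's own level
// (x0_k or y0_u) so the right-hand sides are 0/1; this equilibrates panels
// whose units differ by orders of magnitude in one dimension (the Farrell
// distance and the intensity weights are unchanged by row scaling).
int solve_unit(const NumericMatrix &Xr, const NumericMatrix &Yr,
               const double *x0, const double *y0, int rts,
               double &lambda, double *w, bool bland_all) {
    const int p = Xr.nrow(), q = Yr.nrow(), nr = Xr.ncol();
    const int m = p + q + (rts != 0 ? 1 : 0);
    const int icol_lambda = nr;
    const int icol_slack = nr + 1;            // p input slacks
    const int icol_surp = icol_slack + p;     // q output surpluses
    const int icol_extra = icol_surp + q;     // NIRS slack or VRS artificial
    const int n = icol_extra + (rts != 0 ? 1 : 0);

    Tableau tb;
    tb.m = m;
    tb.n = n;
    tb.a.assign((size_t)m * (n + 1), 0.0);
    tb.basis.assign(m, -1);

    for (int k = 0; k < p; ++k) {            // Xr mu / s + s_k = x0_k / s
        double s = (x0[k] > 0) ? x0[k] : 1.0;
        for (int j = 0; j < nr; ++j) tb.at(k, j) = Xr(k, j) / s;
        tb.at(k, icol_slack + k) = 1.0;
        tb.at(k, n) = x0[k] / s;             // 1, or 0 for a zero input
        tb.basis[k] = icol_slack + k;
    }
    for (int u = 0; u < q; ++u) {            // -Yr mu/s + lambda y0_u/s + t_u = 0
        int i = p + u;
        double s = (y0[u] > 0) ? y0[u] : 1.0;
        for (int j = 0; j < nr; ++j) tb.at(i, j) = -Yr(u, j) / s;
        tb.at(i, icol_lambda) = y0[u] / s;
        tb.at(i, icol_surp + u) = 1.0;
        tb.at(i, n) = 0.0;
        tb.basis[i] = icol_surp + u;
    }
    if (rts != 0) {                          // sum(mu) (+u) (+a) = 1
        int i = p + q;
        for (int j = 0; j < nr; ++j) tb.at(i, j) = 1.0;
        tb.at(i, icol_extra) = 1.0;
        tb.at(i, n) = 1.0;
        tb.basis[i] = icol_extra;
    }

    std::vector<bool> allowed(n, true);
    std::vector<double> red;

    if (rts == 1) {  // phase 1: drive the single VRS artificial to zero
        std::vector<double> c1(n, 0.0);
        c1[icol_extra] = 1.0;
        init_costrow(tb, c1, red);
        int st = simplex_iterate(tb, red, allowed, bland_all);
        if (st != 0) return st;
        if (-red[n] > 1e-7) return 1;        // residual artificial => infeasible
        int arow = -1;
        for (int i = 0; i < m; ++i)
            if (tb.basis[i] == icol_extra) arow = i;
        if (arow >= 0) {                     // degenerate: pivot it out
            int j = 0;
            for (; j < n; ++j)
                if (j != icol_extra && std::fabs(tb.at(arow, j)) > 1e-7) break;
            if (j == n) return 1;
            double piv = tb.at(arow, j);
            for (int jj = 0; jj <= n; ++jj) tb.at(arow, jj) /= piv;
            for (int i = 0; i < m; ++i) {
                if (i == arow) continue;
                double f = tb.at(i, j);
                if (f != 0.0)
                    for (int jj = 0; jj <= n; ++jj)
                        tb.at(i, jj) -= f * tb.at(arow, jj);
            }
            tb.basis[arow] = j;
        }
        allowed[icol_extra] = false;
    }

    std::vector<double> c(n, 0.0);
    c[icol_lambda] = -1.0;                   // maximise lambda
    init_costrow(tb, c, red);
    int st = simplex_iterate(tb, red, allowed, bland_all);
    if (st != 0) return st;

    lambda = 0.0;
    if (w) std::fill(w, w + nr, 0.0);
    for (int i = 0; i < m; ++i) {
        int b = tb.basis[i];
        if (b == icol_lambda) lambda = tb.at(i, n);
        else if (w && b < nr) w[b] = tb.at(i, n);
    }
    return 0;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".dea_solve_cpp")]]
List dea_solve_cpp(NumericMatrix Xe, NumericMatrix Ye, NumericMatrix Xr,
                   NumericMatrix Yr, int rts, bool weights) {
    const int p = Xr.nrow(), q = Yr.nrow(), ne = Xe.ncol(), nr = Xr.ncol();
    if (Xe.nrow() != p || Ye.nrow() != q || Ye.ncol() != ne)
        stop("input/output matrix dimensions do not agree");

    // normalise each input/output row to unit scale: the Farrell distance
    // is invariant to row rescaling, and the simplex tolerances are not
    Xe = clone(Xe); Ye = clone(Ye); Xr = clone(Xr); Yr = clone(Yr);
    for (int k = 0; k < p; ++k) {
        double s = 0;
        for (int j = 0; j < nr; ++j) s = std::max(s, Xr(k, j));
        for (int j = 0; j < ne; ++j) s = std::max(s, Xe(k, j));
        if (s <= 0) s = 1;
        for (int j = 0; j < nr; ++j) Xr(k, j) /= s;
        for (int j = 0; j < ne; ++j) Xe(k, j) /= s;
    }
    for (int u = 0; u < q; ++u) {
        double s = 0;
        for (int j = 0; j < nr; ++j) s = std::max(s, Yr(u, j));
        for (int j = 0; j < ne; ++j) s = std::max(s, Ye(u, j));
        if (s <= 0) s = 1;
        for (int j = 0; j < nr; ++j) Yr(u, j) /= s;
        for (int j = 0; j < ne; ++j) Ye(u, j) /= s;
    }

    NumericVector lambda(ne);
    NumericMatrix W = weights ? NumericMatrix(nr, ne) : NumericMatrix(0, 0);
    std::vector<double> x0(p), y0(q);
    for (int e = 0; e < ne; ++e) {
        for (int k = 0; k < p; ++k) x0[k] = Xe(k, e);
        bool any_y = false;
        for (int u = 0; u < q; ++u) {
            y0[u] = Ye(u, e);
            if (y0[u] > 0) any_y = true;
        }
        if (!any_y)
            stop("evaluated unit %d has an all-zero output vector", e + 1);
        double lam = NA_REAL;
        int st = solve_unit(Xr, Yr, x0.data(), y0.data(), rts, lam,
                            weights ? &W(0, e) : (double *)0, false);
        if (st == 2)  // Dantzig stalled on a degenerate panel: pure Bland
            st = solve_unit(Xr, Yr, x0.data(), y0.data(), rts, lam,
                            weights ? &W(0, e) : (double *)0, true);
        if (st == 1)
            stop("envelopment program infeasible for unit %d", e + 1);
        if (st != 0)
            stop("simplex failed to converge for unit %d", e + 1);
        lambda[e] = lam;
    }
    if (weights) return List::create(_["lambda"] = lambda, _["weights"] = W);
    return List::create(_["lambda"] = lambda);
}
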