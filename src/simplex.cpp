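// Dense bounded-variable two-phase primal simplex.
//
// Solves  max/min c'x  s.t.  A x = b,  l <= x <= u  with finite bounds.
// Constraint-based models give small dense problems (n ~ 10^2), so an
// explicit basis inverse with eta updates and periodic refactorization
// is fast and accurate; anti-cycling falls back to Bland's rule after a
// stall. Every solution is verified against the constraints before it
// is returned; on any violation the problem is re-solved in a
// conservative mode (Bland's rule throughout, refactorization every
// iteration).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double DJ_TOL   = 1e-9;   // reduced-cost optimality tolerance
const double RATIO_TOL = 1e-7;  // smallest pivot admitted by the ratio test
const double ART_TOL  = 1e-7;   // phase-1 residual => infeasible
const double BIG_ART  = 1e7;    // artificial upper bound

struct Tableau {
    mat A;            // m x (n + m), structurals then artificials
    vec b, l, u, x;
    uvec basis;       // m basic variable indices
    std::vector<char> inbasis;
    mat Binv;
    int m, ntot, nstruct;

    void refactor() {
        mat B(m, m);
        for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
        if (!inv(Binv, B)) Binv = pinv(B);  // pseudo-inverse if singular
        // recompute basic values from the nonbasic ones (one gemv)
        vec xn = x;
        for (int i = 0; i < m; ++i) xn[basis[i]] = 0.0;
        vec rhs = b - A * xn;
        vec xb = Binv * rhs;
        for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
    }
};

// One simplex phase: maximize cobj over the current tableau.
// Returns 0 optimal, 2 unbounded, 3 iteration limit.
long long g_iters = 0;

int phase(Tableau &T, const vec &cobj, int maxit, bool conservative) {
    int m = T.m, ntot = T.ntot;
    int stall = 0;
    bool bland = conservative;
    int refactor_every = conservative ? 1 : 20;
    int since_refactor = 0;
    double last_obj = dot(cobj, T.x);

    for (int it = 0; it < maxit; ++it) {
        ++g_iters;
        vec cb(m);
        for (int i = 0; i < m; ++i) cb[i] = cobj[T.basis[i]];
        vec y = T.Binv.t() * cb;
        vec dall = cobj - T.A.t() * y;   // all reduced costs in one gemv

        // pricing
        int enter = -1;
        double best = DJ_TOL;
        int dir = 0; // +1 increase from lower, -1 decrease from upper
        for (int j = 0; j < ntot; ++j) {
            if (T.inbasis[j]) continue;
            if (T.u[j] - T.l[j] < 1e-12) continue; // fixed variable
            double dj = dall[j];
            bool can_up = T.x[j] < T.u[j] - 1e-12;
            bool can_dn = T.x[j] > T.l[j] + 1e-12;
            int d = 0;
            if (dj > DJ_TOL && can_up) d = 1;
            else if (dj < -DJ_TOL && can_dn) d = -1;
            if (d != 0) {
                double gain = std::abs(dj);
                if (bland) { enter = j; dir = d; break; }
                if (gain > best) { best = gain; enter = j; dir = d; }
            }
        }
        if (enter < 0) return 0; // optimal

        vec w = T.Binv * T.A.col(enter);

        // bounded-variable ratio test; the entering variable can move
        // from its current value to the bound in its direction
        double tmax = (dir > 0) ? (T.u[enter] - T.x[enter])
                                : (T.x[enter] - T.l[enter]);
        int leave = -1;
        double leave_w = 0.0;
        for (int i = 0; i < m; ++i) {
            double wi = dir * w[i];
            double t;
            if (wi > RATIO_TOL)
                t = (T.x[T.basis[i]] - T.l[T.basis[i]]) / wi;
            else if (wi < -RATIO_TOL)
                t = (T.u[T.basis[i]] - T.x[T.basis[i]]) / (-wi);
            else continue;
            if (t < 0) t = 0;
            if (t < tmax - 1e-10) {
                tmax = t; leave = i; leave_w = w[i];
            } else if (leave >= 0 && t <= tmax + 1e-10) {
                // tie: prefer the larger pivot (stability), or the
                // smallest variable index under Bland's rule
                bool better = bland ? (T.basis[i] < T.basis[leave])
                                    : (std::abs(w[i]) > std::abs(leave_w));
                if (better) { leave = i; leave_w = w[i]; }
            }
        }
        if (!std::isfinite(tmax)) return 2;

        // apply step
        T.x[enter] += dir * tmax;
        for (int i = 0; i < m; ++i) T.x[T.basis[i]] -= dir * tmax * w[i];

        if (leave < 0) {
            // bound flip, basis unchanged
            T.x[enter] = (dir > 0) ? T.u[enter] : T.l[enter];
        } else {
            int out = T.basis[leave];
            // snap the leaving variable onto a bound only if it in fact
            // reached one; after a degenerate pivot it may leave the
            // basis at an interior value, which stays legal for a
            // nonbasic variable here (the pricing treats it as free to
            // move either way)
            double dl = std::abs(T.x[out] - T.l[out]);
            double du = std::abs(T.x[out] - T.u[out]);
            if (dl <= 1e-7) T.x[out] = T.l[out];
            else if (du <= 1e-7) T.x[out] = T.u[out];
            T.inbasis[out] = 0;
            T.inbasis[enter] = 1;
            T.basis[leave] = enter;
            if (++since_refactor >= refactor_every) {
                T.refactor();
                since_refactor = 0;
            } else {
                // eta update of Binv
                double piv = w[leave];
                rowvec br = T.Binv.row(leave) / piv;
                for (int i = 0; i < m; ++i) {
                    if (i == leave) continue;
                    T.Binv.row(i) -= w[i] * br;
                }
                T.Binv.row(leave) = br;
            }
        }

        double obj = dot(cobj, T.x);
        if (obj > last_obj + 1e-12) { stall = 0; last_obj = obj; }
        else if (++stall > m + ntot) bland = true;
    }
    return 3;
}

// full solve; returns status (0 optimal, 1 infeasible, 2 unbounded,
// 3 iteration limit) and fills xs on success
int solve_once(const mat &A, const vec &b, const vec &c, const vec &lb,
               const vec &ub, bool maximize, bool conservative, vec &xs) {
    int m = A.n_rows, n = A.n_cols;
    Tableau T;
    T.m = m; T.nstruct = n; T.ntot = n + m;
    T.A.set_size(m, n + m);
    T.A.cols(0, n - 1) = A;
    T.b = b;
    T.l.set_size(n + m); T.u.set_size(n + m); T.x.set_size(n + m);
    for (int j = 0; j < n; ++j) {
        T.l[j] = lb[j]; T.u[j] = ub[j];
        if (T.l[j] > T.u[j]) return 1;
        // start at zero when the bounds admit it (with b = 0 the zero
        // flux vector is nearly feasible, keeping phase 1 short);
        // such variables are nonbasic at an interior value and the
        // pricing below treats them as free to move either way
        T.x[j] = std::min(std::max(0.0, lb[j]), ub[j]);
    }
    vec r = b - T.A.cols(0, n - 1) * T.x.subvec(0, n - 1);
    T.basis.set_size(m);
    T.inbasis.assign(n + m, 0);
    for (int i = 0; i < m; ++i) {
        int j = n + i;
        vec e = zeros<vec>(m);
        e[i] = (r[i] >= 0) ? 1.0 : -1.0;
        T.A.col(j) = e;
        T.l[j] = 0; T.u[j] = BIG_ART;
        T.x[j] = std::abs(r[i]);
        T.basis[i] = j;
        T.inbasis[j] = 1;
    }
    T.Binv = eye<mat>(m, m);
    for (int i = 0; i < m; ++i) if (r[i] < 0) T.Binv(i, i) = -1.0;

    int maxit = 500 * (n + m + 10);

    // phase 1: drive artificials to zero
    vec c1 = zeros<vec>(n + m);
    for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
    double art = 0; for (int i = 0; i < m; ++i) art += T.x[n + i];
    if (art > ART_TOL) {
        int st = phase(T, c1, maxit, conservative);
        if (st == 3) return 3;
        art = 0; for (int i = 0; i < m; ++i) art += T.x[n + i];
        if (art > ART_TOL) {
            T.refactor();
            phase(T, c1, maxit, true);
            art = 0; for (int i = 0; i < m; ++i) art += T.x[n + i];
        }
        if (art > ART_TOL) return 1;
    }
    // lock artificials at zero
    for (int i = 0; i < m; ++i) { T.u[n + i] = 0; T.x[n + i] = 0; }
    T.refactor();

    // phase 2
    vec c2 = zeros<vec>(n + m);
    for (int j = 0; j < n; ++j) c2[j] = maximize ? c[j] : -c[j];
    int st = phase(T, c2, maxit, conservative);
    if (st == 2 || st == 3) return st;

    T.refactor(); // polish basic values before reporting
    xs = T.x.subvec(0, n - 1);
    for (int j = 0; j < n; ++j) {
        if (xs[j] < lb[j]) xs[j] = lb[j];
        if (xs[j] > ub[j]) xs[j] = ub[j];
    }
    return 0;
}

bool verified(const mat &A, const vec &b, const vec &xs) {
    vec resid = A * xs - b;
    double scale = std::max(1.0, norm(b, "inf"));
    return norm(resid, "inf") <= 1e-6 * scale;
}

} // namespace

// [[Rcpp::export(name = ".simplex_lp")]]
Rcpp::List simplex_lp(const arma::mat &A, const arma::vec &b,
                      const arma::vec &c, const arma::vec &lb,
                      const arma::vec &ub, bool maximize) {
    vec xs;
    g_iters = 0;
    int st = solve_once(A, b, c, lb, ub, maximize, false, xs);
    bool ok = (st == 0) && verified(A, b, xs);
    if (!ok && st != 2) {
        // conservative re-solve: Bland's rule, refactor every iteration
        int st2 = solve_once(A, b, c, lb, ub, maximize, true, xs);
        if (st2 == 0 && verified(A, b, xs)) st = 0;
        else if (st == 0) st = (st2 == 0) ? 3 : st2;  // unverifiable
        else st = st2 == 0 ? 3 : st2;
    }
    if (st != 0) return Rcpp::List::create(
        Rcpp::Named("status") = st, Rcpp::Named("obj") = NA_REAL,
        Rcpp::Named("x") = Rcpp::NumericVector(0));
    double obj = dot(c, xs);
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("obj") = obj,
                              Rcpp::Named("iters") = (double)g_iters,
                              Rcpp::Named("x") = Rcpp::NumericVector(xs.begin(), xs.end()));
}
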