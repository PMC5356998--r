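#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Weighted polynomial fit at one evaluation point e, over x sorted ascending.
// Neighbourhood: the q nearest points by |x - e| (a contiguous window in the
// sorted order, found by two-pointer expansion); d_max is the q-th smallest
// distance and tricube weights (1 - (d/d_max)^3)^3 vanish at d >= d_max, so
// distance ties at the boundary cannot change the fit. Robustness weights rw
// multiply the tricube weights; if they null the whole window the tricube
// weights alone are used. Returns the intercept of the centred fit, i.e. the
// fitted value at e.
static double fit_point_sorted(const arma::vec& xs, const arma::vec& ys,
                               const arma::vec& rw, double e, int q,
                               int degree) {
    const int n = (int)xs.n_elem;
    // first index with xs >= e
    int hi = (int)(std::lower_bound(xs.begin(), xs.end(), e) - xs.begin());
    int lo = hi;
    while (hi - lo < q) {
        double dl = (lo > 0) ? (e - xs(lo - 1)) : arma::datum::inf;
        double dr = (hi < n) ? (xs(hi) - e) : arma::datum::inf;
        if (dl <= dr) --lo; else ++hi;
    }
    double dmax = std::max(e - xs(lo), xs(hi - 1) - e);

    const int p = degree + 1;
    arma::mat A(p, p, arma::fill::zeros);
    arma::vec b(p, arma::fill::zeros);
    double wsum = 0.0;
    for (int pass = 0; pass < 2; ++pass) {
        // pass 0 uses tricube * rw; pass 1 (only if all zero) tricube alone
        A.zeros(); b.zeros(); wsum = 0.0;
        for (int i = lo; i < hi; ++i) {
            double d = std::abs(xs(i) - e);
            double w;
            if (dmax <= 0.0) w = 1.0;
            else if (d < dmax) {
                double u = d / dmax, t = 1.0 - u * u * u;
                w = t * t * t;
            } else w = 0.0;
            if (pass == 0) w *= rw(i);
            if (w <= 0.0) continue;
            wsum += w;
            double u = xs(i) - e;
            double pw[5];  // u^0 .. u^4 (degree <= 2)
            pw[0] = 1.0;
            for (int k = 1; k <= 2 * degree; ++k) pw[k] = pw[k - 1] * u;
            for (int r = 0; r < p; ++r) {
                for (int c = r; c < p; ++c) A(r, c) += w * pw[r + c];
                b(r) += w * pw[r] * ys(i);
            }
        }
        if (wsum > 0.0) break;
    }
    if (wsum <= 0.0) return NA_REAL;
    A = arma::symmatu(A);
    arma::vec beta;
    if (!arma::solve(beta, A, b, arma::solve_opts::no_approx))
        beta = arma::pinv(A) * b;  // collinear window: pseudo-inverse fallback
    return beta(0);
}

// [[Rcpp::export(name = ".local_regression_cpp")]]
List local_regression_cpp(NumericVector x_, NumericVector y_,
                          double span, int degree, int robust_iters,
                          NumericVector eval_) {
    arma::vec x(x_.begin(), x_.size(), false);
    arma::vec y(y_.begin(), y_.size(), false);
    arma::vec ev(eval_.begin(), eval_.size(), false);
    const arma::uword n = x.n_elem;
    int q = (int)std::ceil(span * (double)n);
    if (q > (int)n) q = (int)n;

    arma::uvec ord = arma::sort_index(x);
    arma::vec xs = x(ord), ys = y(ord);

    arma::vec rw_s(n, arma::fill::ones);   // robustness weights, sorted order
    arma::vec fit_train(n);                // fits at training x, original order
    for (int it = 0; it <= robust_iters; ++it) {
        for (arma::uword i = 0; i < n; ++i)
            fit_train(ord(i)) = fit_point_sorted(xs, ys, rw_s, xs(i), q,
                                                 degree);
        if (it == robust_iters) break;
        arma::vec r = y - fit_train;
        double s = 6.0 * arma::median(arma::abs(r));
        if (s <= 0.0) { rw_s.ones(); continue; }
        for (arma::uword i = 0; i < n; ++i) {
            double u = r(ord(i)) / s;
            if (std::abs(u) < 1.0) { double t = 1.0 - u * u; rw_s(i) = t * t; }
            else rw_s(i) = 0.0;
        }
    }
    arma::vec fit_eval(ev.n_elem);
    for (arma::uword i = 0; i < ev.n_elem; ++i)
        fit_eval(i) = fit_point_sorted(xs, ys, rw_s, ev(i), q, degree);

    arma::vec rw_orig(n);
    for (arma::uword i = 0; i < n; ++i) rw_orig(ord(i)) = rw_s(i);

    return List::create(
        _["fitted"] = NumericVector(fit_eval.begin(), fit_eval.end()),
        _["fitted_train"] = NumericVector(fit_train.begin(), fit_train.end()),
        _["robust_weights"] = NumericVector(rw_orig.begin(), rw_orig.end()),
        _["q"] = q);
}
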