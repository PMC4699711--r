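#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ordered-pair template match counts for sample entropy.
//
// Templates u_i = (x[i], ..., x[i+m-1]) with start indices restricted to
// 0..N-m-1 so that every m-template has an (m+1)-point extension; distance is
// Chebyshev and a match requires distance strictly below r. B counts matching
// ordered pairs (i, j), i != j, at template length m; A at length m+1.
//
// Organised by lag d = j - i: an m-template match at (i, i+d) is the AND of
// the pointwise indicators c_t = |x[t] - x[t+d]| < r for t = i..i+m-1, and
// the (m+1)-extension adds c_{i+m}. Template starts i = 0..M-1-d make the
// m-windows exactly the length-m all-true windows of c[0..n-d-1] and the
// extensions the length-(m+1) windows, so both counts fall out of one
// branch-free run-length scan per lag; the cost is independent of match
// density.
static void sampen_counts_core(const double *x, const int n, const int m,
                               const double r, double &B, double &A) {
    const int M = n - m;  // number of extendable templates
    long long b = 0, a = 0;
    // lags are processed four at a time: the four run-length counters are
    // independent, which breaks the sequential dependency chain of a single
    // counter and lets the four indicator streams execute in parallel
    int d = 1;
    for (; d + 3 <= M - 1; d += 4) {
        const int nt3 = n - (d + 3);  // indicator length of the longest lag
        int rl0 = 0, rl1 = 0, rl2 = 0, rl3 = 0;
        long long bb = 0, aa = 0;
        const double *h0 = x + d, *h1 = h0 + 1, *h2 = h0 + 2, *h3 = h0 + 3;
        for (int t = 0; t < nt3; ++t) {
            const double xt = x[t];
            const int c0 = std::fabs(xt - h0[t]) < r;
            const int c1 = std::fabs(xt - h1[t]) < r;
            const int c2 = std::fabs(xt - h2[t]) < r;
            const int c3 = std::fabs(xt - h3[t]) < r;
            rl0 = (rl0 + 1) * c0; bb += rl0 >= m; aa += rl0 > m;
            rl1 = (rl1 + 1) * c1; bb += rl1 >= m; aa += rl1 > m;
            rl2 = (rl2 + 1) * c2; bb += rl2 >= m; aa += rl2 > m;
            rl3 = (rl3 + 1) * c3; bb += rl3 >= m; aa += rl3 > m;
        }
        // the final position of each lag can only close an (m+1)-extension,
        // not start a new m-template (i <= M-1-d): lag d+3 is complete, the
        // other three need their remaining positions first
        bb -= rl3 >= m;
        const int rls[3] = { rl0, rl1, rl2 };
        for (int j = 0; j < 3; ++j) {
            const int lag = d + j;
            const int nt = n - lag;
            int rl = rls[j];
            for (int t = nt3; t < nt; ++t) {
                const int c = std::fabs(x[t] - x[t + lag]) < r;
                rl = (rl + 1) * c;
                bb += rl >= m;
                aa += rl > m;
            }
            bb -= rl >= m;
        }
        b += bb;
        a += aa;
    }
    for (; d <= M - 1; ++d) {  // remaining lags
        const int nt = n - d;
        int rl = 0;
        for (int t = 0; t < nt; ++t) {
            const int c = std::fabs(x[t] - x[t + d]) < r;
            rl = (rl + 1) * c;
            b += rl >= m;
            a += rl > m;
        }
        b -= rl >= m;
    }
    B = 2.0 * static_cast<double>(b);
    A = 2.0 * static_cast<double>(a);
}

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
    const int n = x.size();
    if (n < m + 2) stop("series too short: need N >= m + 2");
    double B = 0.0, A = 0.0;
    sampen_counts_core(REAL(x), n, m, r, B, A);
    return NumericVector::create(_["B"] = B, _["A"] = A);
}

// Per-column SampEn match counts for a time-by-voxel matrix. Tolerance is
// r_frac times each column's sample standard deviation (denominator n - 1).
// Returns a 3 x V matrix with rows (B, A, sd); zero-variance columns get
// NA counts.
// [[Rcpp::export(name = ".sampen_counts_matrix")]]
NumericMatrix sampen_counts_matrix(NumericMatrix X, int m, double r_frac) {
    const int n = X.nrow(), V = X.ncol();
    if (n < m + 2) stop("series too short: need N >= m + 2");
    NumericMatrix out(3, V);
    for (int v = 0; v < V; ++v) {
        const double *x = &X(0, v);
        double mean = 0.0;
        for (int t = 0; t < n; ++t) mean += x[t];
        mean /= n;
        double ss = 0.0;
        for (int t = 0; t < n; ++t) {
            const double d = x[t] - mean;
            ss += d * d;
        }
        const double sd = std::sqrt(ss / (n - 1));
        if (sd <= 0.0 || !std::isfinite(sd)) {
            out(0, v) = NA_REAL;
            out(1, v) = NA_REAL;
            out(2, v) = sd;
            continue;
        }
        double B = 0.0, A = 0.0;
        sampen_counts_core(x, n, m, r_frac * sd, B, A);
        out(0, v) = B;
        out(1, v) = A;
        out(2, v) = sd;
    }
    return out;
}
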