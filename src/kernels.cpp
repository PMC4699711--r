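#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable circular convolution of a 3D array (optionally a stack of
// nvol volumes) with per-axis symmetric unit-sum kernels; total mass is
// preserved exactly. The axis of length n sits between a contiguous block
// of size `pre` and `post` outer repetitions; convolving accumulates whole
// length-`pre` slabs so the inner loops stream over contiguous memory.
static void conv_axis(double *data, const size_t pre, const int n,
                      const size_t post, const double *kern,
                      const int radius, std::vector<double> &buf) {
    const size_t block = pre * (size_t)n;
    if (buf.size() < block) buf.resize(block);
    for (size_t p = 0; p < post; ++p) {
        double *blk = data + p * block;
        std::copy(blk, blk + block, buf.begin());
        for (int j = 0; j < n; ++j) {
            double *out = blk + (size_t)j * pre;
            {
                int src = (j - radius) % n;
                if (src < 0) src += n;
                const double *in = &buf[(size_t)src * pre];
                const double k0 = kern[0];
                for (size_t i = 0; i < pre; ++i) out[i] = k0 * in[i];
            }
            for (int k = 1; k < 2 * radius + 1; ++k) {
                int src = (j - radius + k) % n;
                if (src < 0) src += n;
                const double *in = &buf[(size_t)src * pre];
                const double kk = kern[k];
                for (size_t i = 0; i < pre; ++i) out[i] += kk * in[i];
            }
        }
    }
}

// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector arr, IntegerVector dims,
                           List kernels) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const size_t vol = (size_t)nx * ny * nz;
    const size_t nvol = arr.size() / vol;
    if (nvol * vol != (size_t)arr.size())
        stop("array size is not a multiple of the volume size");
    NumericVector out = clone(arr);
    double *d = REAL(out);
    std::vector<double> buf;
    const int ns[3] = { nx, ny, nz };
    size_t pre = 1;
    for (int ax = 0; ax < 3; ++ax) {
        NumericVector k = kernels[ax];
        const int n = ns[ax];
        if (k.size() > 1) {
            const int radius = (k.size() - 1) / 2;
            const size_t post = (size_t)arr.size() / (pre * n);
            conv_axis(d, pre, n, post, REAL(k), radius, buf);
        }
        pre *= n;
    }
    return out;
}

// AR(1)/white-noise mixture signals for one subject: column v of the
// returned t x V matrix is (1 - w[v]) * s + w[v] * e with s a unit-variance
// AR(1) (coefficient phi) and e unit-variance white noise. Draws come from
// R's RNG (voxel by voxel: t AR innovations, then t white samples), so the
// result is reproducible under set.seed().
// [[Rcpp::export(name = ".simulate_mix")]]
NumericMatrix simulate_mix(int t, NumericVector w, double phi) {
    const int V = w.size();
    NumericMatrix out(t, V);
    const double isd = std::sqrt(1.0 - phi * phi);
    for (int v = 0; v < V; ++v) {
        NumericVector innov = rnorm(t);
        NumericVector e = rnorm(t);
        double s = innov[0];
        const double wa = 1.0 - w[v], wb = w[v];
        double *col = &out(0, v);
        col[0] = wa * s + wb * e[0];
        for (int tt = 1; tt < t; ++tt) {
            s = phi * s + isd * innov[tt];
            col[tt] = wa * s + wb * e[tt];
        }
    }
    return out;
}
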