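#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array under 6-, 18- or
// 26-neighbor connectivity. Labels are 1..K in order of first (column-major)
// encounter; background is 0.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
    if (dims.size() != 3) stop("dims must have length 3");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if ((R_xlen_t)nx * ny * nz != mask.size())
        stop("mask length does not match dims");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    // neighbor offset table
    std::vector<int> dx, dy, dz;
    for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
            for (int cx = -1; cx <= 1; ++cx) {
                const int nz0 = std::abs(cx) + std::abs(cy) + std::abs(cz);
                if (nz0 == 0) continue;
                if (connectivity == 6 && nz0 > 1) continue;
                if (connectivity == 18 && nz0 > 2) continue;
                dx.push_back(cx);
                dy.push_back(cy);
                dz.push_back(cz);
            }

    IntegerVector labels(mask.size(), 0);
    std::vector<int> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < mask.size(); ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++next;
        labels[s] = next;
        stack.clear();
        stack.push_back((int)s);
        while (!stack.empty()) {
            const int idx = stack.back();
            stack.pop_back();
            const int x = idx % nx;
            const int y = (idx / nx) % ny;
            const int z = idx / (nx * ny);
            for (size_t k = 0; k < dx.size(); ++k) {
                const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                    zz >= nz)
                    continue;
                const int j = xx + nx * (yy + ny * zz);
                if (mask[j] && labels[j] == 0) {
                    labels[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    labels.attr("n_components") = next;
    return labels;
}
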