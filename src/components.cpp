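#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 6-connected component labelling of a 3-D logical array.
// Iterative flood fill; labels are 1..K in scan order of the first voxel.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector fg, IntegerVector dims) {
    if (dims.size() != 3)
        stop("dims must have length 3");
    const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = nx * ny * nz;
    if (fg.size() != n)
        stop("fg length does not match dims");

    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    const R_xlen_t sy = nx, sz = nx * ny;
    int next = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!fg[i] || lab[i])
            continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            const R_xlen_t v = stack.back();
            stack.pop_back();
            const R_xlen_t z = v / sz;
            const R_xlen_t r = v - z * sz;
            const R_xlen_t y = r / nx;
            const R_xlen_t x = r - y * nx;

            if (x > 0)      { R_xlen_t w = v - 1;  if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
            if (x < nx - 1) { R_xlen_t w = v + 1;  if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
            if (y > 0)      { R_xlen_t w = v - sy; if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
            if (y < ny - 1) { R_xlen_t w = v + sy; if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
            if (z > 0)      { R_xlen_t w = v - sz; if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
            if (z < nz - 1) { R_xlen_t w = v + sz; if (fg[w] && !lab[w]) { lab[w] = next; stack.push_back(w); } }
        }
    }
    lab.attr("dim") = dims;
    return lab;
}
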