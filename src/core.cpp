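#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm generalized to anisotropic sample spacing.  One pass per axis.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, double s) {
    const int n = (int)f.size();
    if (n == 1) return;
    std::vector<int> v(n);
    std::vector<double> z(n + 1), d(n);
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        const double xq = q * s;
        while (true) {
            const double xv = v[k] * s;
            const double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (k > 0 && sep <= z[k]) {
                k--;
            } else {
                k++;
                v[k] = q;
                z[k] = sep;
                z[k + 1] = INF;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        const double xq = q * s;
        while (z[k + 1] < xq) k++;
        const double dx = xq - v[k] * s;
        d[q] = dx * dx + f[v[k]];
    }
    for (int q = 0; q < n; q++) f[q] = d[q];
}

// Distance (mm) from every voxel to the nearest TRUE voxel of `mask`.
// Voxels are treated as point samples at origin + index * spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    // large finite sentinel instead of Inf: keeps the parabola
    // intersections finite on lines without any mask voxel
    const double BIG = 1e20;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

    std::vector<double> line;
    // axis x (stride 1)
    line.resize(nx);
    for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++) {
            const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; x++) line[x] = out[base + x];
            dt1d(line, spacing[0]);
            for (int x = 0; x < nx; x++) out[base + x] = line[x];
        }
    // axis y (stride nx)
    line.resize(ny);
    for (int z = 0; z < nz; z++)
        for (int x = 0; x < nx; x++) {
            const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
            for (int y = 0; y < ny; y++) line[y] = out[base + (R_xlen_t)y * nx];
            dt1d(line, spacing[1]);
            for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = line[y];
        }
    // axis z (stride nx*ny)
    line.resize(nz);
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
            const R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; z++) line[z] = out[base + (R_xlen_t)z * sz];
            dt1d(line, spacing[2]);
            for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * sz] = line[z];
        }
    for (R_xlen_t i = 0; i < n; i++)
        out[i] = out[i] >= 1e19 ? R_PosInf : std::sqrt(out[i]);
    return out;
}

// ---------------------------------------------------------------------------
// 6-neighbor graph Laplacian with replicate boundary (missing neighbors
// contribute nothing): sum over face neighbors of (x_j - x_i). Symmetric.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_laplacian6(NumericVector x, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++) {
            const R_xlen_t base = (R_xlen_t)z * sz + (R_xlen_t)y * sy;
            for (int x0 = 0; x0 < nx; x0++) {
                const R_xlen_t i = base + x0;
                const double v = x[i];
                double acc = 0.0;
                if (x0 > 0) acc += x[i - 1] - v;
                if (x0 < nx - 1) acc += x[i + 1] - v;
                if (y > 0) acc += x[i - sy] - v;
                if (y < ny - 1) acc += x[i + sy] - v;
                if (z > 0) acc += x[i - sz] - v;
                if (z < nz - 1) acc += x[i + sz] - v;
                out[i] = acc;
            }
        }
    return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed: priority flood of a relief image from labeled
// seeds, 26-connectivity.  Ties broken by insertion order (FIFO), which
// makes the result deterministic.
// ---------------------------------------------------------------------------

struct QItem {
    double prio;
    unsigned long order;
    R_xlen_t idx;
};
struct QCmp {
    bool operator()(const QItem &a, const QItem &b) const {
        if (a.prio != b.prio) return a.prio > b.prio;
        return a.order > b.order;
    }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector markers, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n);
    std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
    unsigned long order = 0;

    for (R_xlen_t i = 0; i < n; i++) {
        lab[i] = markers[i];
        if (markers[i] > 0) pq.push({relief[i], order++, i});
    }

    while (!pq.empty()) {
        const QItem it = pq.top();
        pq.pop();
        const int L = lab[it.idx];
        const int z0 = (int)(it.idx / ((R_xlen_t)nx * ny));
        const R_xlen_t rem = it.idx % ((R_xlen_t)nx * ny);
        const int y0 = (int)(rem / nx);
        const int x0 = (int)(rem % nx);
        for (int dz = -1; dz <= 1; dz++)
            for (int dy = -1; dy <= 1; dy++)
                for (int dx = -1; dx <= 1; dx++) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    const int x = x0 + dx, y = y0 + dy, z = z0 + dz;
                    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
                    const R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
                    if (lab[j] == 0) {
                        lab[j] = L;
                        pq.push({relief[j], order++, j});
                    }
                }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary mask, 26-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        if (!mask[i] || lab[i] != 0) continue;
        next++;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            const R_xlen_t cur = stack.back();
            stack.pop_back();
            const int z0 = (int)(cur / ((R_xlen_t)nx * ny));
            const R_xlen_t rem = cur % ((R_xlen_t)nx * ny);
            const int y0 = (int)(rem / nx);
            const int x0 = (int)(rem % nx);
            for (int dz = -1; dz <= 1; dz++)
                for (int dy = -1; dy <= 1; dy++)
                    for (int dx = -1; dx <= 1; dx++) {
                        if (dx == 0 && dy == 0 && dz == 0) continue;
                        const int x = x0 + dx, y = y0 + dy, z = z0 + dz;
                        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
                        const R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
                        if (mask[j] && lab[j] == 0) {
                            lab[j] = next;
                            stack.push_back(j);
                        }
                    }
        }
    }
    return lab;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at continuous 0-based voxel coordinates.
// Coordinates outside the grid return `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector xi, NumericVector yi, NumericVector zi,
                            double fill) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t m = xi.size();
    NumericVector out(m);
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    for (R_xlen_t k = 0; k < m; k++) {
        const double x = xi[k], y = yi[k], z = zi[k];
        if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
            out[k] = fill;
            continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 == nx - 1) x0--;
        if (y0 == ny - 1) y0--;
        if (z0 == nz - 1) z0--;
        if (nx == 1) x0 = 0;
        if (ny == 1) y0 = 0;
        if (nz == 1) z0 = 0;
        const double fx = nx == 1 ? 0.0 : x - x0;
        const double fy = ny == 1 ? 0.0 : y - y0;
        const double fz = nz == 1 ? 0.0 : z - z0;
        const int x1 = nx == 1 ? x0 : x0 + 1;
        const int y1 = ny == 1 ? y0 : y0 + 1;
        const int z1 = nz == 1 ? z0 : z0 + 1;
        const double c000 = vol[(R_xlen_t)z0 * sz + (R_xlen_t)y0 * sy + x0];
        const double c100 = vol[(R_xlen_t)z0 * sz + (R_xlen_t)y0 * sy + x1];
        const double c010 = vol[(R_xlen_t)z0 * sz + (R_xlen_t)y1 * sy + x0];
        const double c110 = vol[(R_xlen_t)z0 * sz + (R_xlen_t)y1 * sy + x1];
        const double c001 = vol[(R_xlen_t)z1 * sz + (R_xlen_t)y0 * sy + x0];
        const double c101 = vol[(R_xlen_t)z1 * sz + (R_xlen_t)y0 * sy + x1];
        const double c011 = vol[(R_xlen_t)z1 * sz + (R_xlen_t)y1 * sy + x0];
        const double c111 = vol[(R_xlen_t)z1 * sz + (R_xlen_t)y1 * sy + x1];
        const double c00 = c000 * (1 - fx) + c100 * fx;
        const double c10 = c010 * (1 - fx) + c110 * fx;
        const double c01 = c001 * (1 - fx) + c101 * fx;
        const double c11 = c011 * (1 - fx) + c111 * fx;
        const double c0 = c00 * (1 - fy) + c10 * fy;
        const double c1 = c01 * (1 - fy) + c11 * fy;
        out[k] = c0 * (1 - fz) + c1 * fz;
    }
    return out;
}
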