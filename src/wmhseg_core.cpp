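#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighbourhood offsets for 6/18/26-connectivity in 3D.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int, 3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (l1 == 0) continue;
                if (connectivity == 6 && l1 > 1) continue;
                if (connectivity == 18 && l1 > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
    std::vector<R_xlen_t> stack;
    int current = 0;
    for (R_xlen_t start = 0; start < n; ++start) {
        if (!mask[start] || labels[start] != 0) continue;
        ++current;
        labels[start] = current;
        stack.push_back(start);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < off.size(); ++k) {
                int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
                if (mask[w] && labels[w] == 0) {
                    labels[w] = current;
                    stack.push_back(w);
                }
            }
        }
    }
    return labels;
}

// Fuzzy connectedness by best-first propagation: the connectivity of a voxel
// is the maximum over paths from any seed of the minimum per-step affinity
// along the path (seeds have connectivity 1). Affinity between adjacent
// voxels c, d is the Gaussian intensity-homogeneity kernel
//   exp(-(((I(c)+I(d))/2 - mu)^2) / (2 * sigma^2)).
// Equivalent to a Dijkstra-style search with min in place of + and max in
// place of min, so it equals exhaustive max-min path enumeration.
// [[Rcpp::export]]
NumericVector cpp_fuzzy_connectivity(NumericVector img, LogicalVector region,
                                     IntegerVector dims, IntegerVector seeds,
                                     double mu, double sigma, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector conn(n, 0.0);
    std::vector<std::array<int, 3>> off = neighbour_offsets(connectivity);
    const double denom = 2.0 * sigma * sigma;

    typedef std::pair<double, R_xlen_t> Node;
    std::priority_queue<Node> queue;  // max-heap on connectivity
    for (R_xlen_t i = 0; i < seeds.size(); ++i) {
        R_xlen_t s = (R_xlen_t)seeds[i] - 1;  // 1-based from R
        conn[s] = 1.0;
        queue.push(Node(1.0, s));
    }
    while (!queue.empty()) {
        Node top = queue.top();
        queue.pop();
        double kv = top.first;
        R_xlen_t v = top.second;
        if (kv < conn[v]) continue;  // stale entry
        int x = (int)(v % nx);
        int y = (int)((v / nx) % ny);
        int z = (int)(v / ((R_xlen_t)nx * ny));
        for (size_t k = 0; k < off.size(); ++k) {
            int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (!region[w]) continue;
            double mid = 0.5 * (img[v] + img[w]) - mu;
            double aff = std::exp(-(mid * mid) / denom);
            double cand = kv < aff ? kv : aff;
            if (cand > conn[w]) {
                conn[w] = cand;
                queue.push(Node(cand, w));
            }
        }
    }
    return conn;
}
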