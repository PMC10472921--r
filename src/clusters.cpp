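#include <Rcpp.h>
using namespace Rcpp;

// Neighbour offsets for 6/18/26-connectivity on a 3-D grid.
static int buildOffsets(int connectivity, int off[26][3]) {
    int n = 0;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (man == 0) continue;
                if (connectivity == 6 && man > 1) continue;
                if (connectivity == 18 && man > 2) continue;
                off[n][0] = dx; off[n][1] = dy; off[n][2] = dz;
                ++n;
            }
    return n;
}

// Label connected components of {t > threshold} over a full 3-D grid.
// t has length prod(dims); voxels outside the mask must carry -Inf (or any
// value below the threshold). Returns integer labels (0 = background),
// components numbered in decreasing order of mass.
// [[Rcpp::export(name = ".labelClusters3d")]]
IntegerVector labelClusters3d(NumericVector t, IntegerVector dims,
                              double threshold, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int nvox = nx * ny * nz;
    if (t.size() != nvox) stop("t length must equal prod(dims)");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    int off[26][3];
    const int noff = buildOffsets(connectivity, off);

    IntegerVector labels(nvox, 0);
    std::vector<double> masses;
    std::vector<int> sizes;
    std::vector<int> stack;
    int nextLabel = 0;

    for (int v = 0; v < nvox; ++v) {
        if (labels[v] != 0 || !(t[v] > threshold)) continue;
        ++nextLabel;
        double mass = 0.0; int size = 0;
        stack.clear(); stack.push_back(v); labels[v] = nextLabel;
        while (!stack.empty()) {
            int cur = stack.back(); stack.pop_back();
            mass += t[cur]; ++size;
            int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
            for (int k = 0; k < noff; ++k) {
                int x = cx + off[k][0], y = cy + off[k][1],
                    z = cz + off[k][2];
                if (x < 0 || x >= nx || y < 0 || y >= ny ||
                    z < 0 || z >= nz) continue;
                int nb = x + nx * (y + ny * z);
                if (labels[nb] == 0 && t[nb] > threshold) {
                    labels[nb] = nextLabel;
                    stack.push_back(nb);
                }
            }
        }
        masses.push_back(mass);
        sizes.push_back(size);
    }

    // renumber so cluster 1 has the largest mass
    std::vector<int> order(nextLabel);
    for (int i = 0; i < nextLabel; ++i) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return masses[a] > masses[b]; });
    std::vector<int> rank(nextLabel);
    for (int i = 0; i < nextLabel; ++i) rank[order[i]] = i + 1;
    NumericVector outMass(nextLabel);
    IntegerVector outSize(nextLabel);
    for (int i = 0; i < nextLabel; ++i) {
        outMass[i] = masses[order[i]];
        outSize[i] = sizes[order[i]];
    }
    for (int v = 0; v < nvox; ++v)
        if (labels[v] != 0) labels[v] = rank[labels[v] - 1];

    labels.attr("masses") = outMass;
    labels.attr("sizes") = outSize;
    return labels;
}

// Maximum cluster mass of {t > threshold}; 0 when no voxel is above
// threshold. Used in the sign-flip permutation loop.
// [[Rcpp::export(name = ".maxClusterMass3d")]]
double maxClusterMass3d(NumericVector t, IntegerVector dims,
                        double threshold, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int nvox = nx * ny * nz;
    if (t.size() != nvox) stop("t length must equal prod(dims)");
    int off[26][3];
    const int noff = buildOffsets(connectivity, off);
    std::vector<char> seen(nvox, 0);
    std::vector<int> stack;
    double best = 0.0;
    for (int v = 0; v < nvox; ++v) {
        if (seen[v] || !(t[v] > threshold)) continue;
        double mass = 0.0;
        stack.clear(); stack.push_back(v); seen[v] = 1;
        while (!stack.empty()) {
            int cur = stack.back(); stack.pop_back();
            mass += t[cur];
            int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
            for (int k = 0; k < noff; ++k) {
                int x = cx + off[k][0], y = cy + off[k][1],
                    z = cz + off[k][2];
                if (x < 0 || x >= nx || y < 0 || y >= ny ||
                    z < 0 || z >= nz) continue;
                int nb = x + nx * (y + ny * z);
                if (!seen[nb] && t[nb] > threshold) {
                    seen[nb] = 1;
                    stack.push_back(nb);
                }
            }
        }
        if (mass > best) best = mass;
    }
    return best;
}

// For each query row (unit vector), the index (1-based) of the reference
// row with maximal dot product. Used for nearest-neighbour label lookup on
// spheres; ties resolved to the lowest index.
// [[Rcpp::export(name = ".nnMaxDot")]]
IntegerVector nnMaxDot(NumericMatrix query, NumericMatrix ref) {
    const int nq = query.nrow(), nr = ref.nrow();
    if (query.ncol() != 3 || ref.ncol() != 3) stop("coordinates must be n x 3");
    IntegerVector out(nq);
    for (int i = 0; i < nq; ++i) {
        const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
        double best = -2.0; int arg = 0;
        for (int j = 0; j < nr; ++j) {
            double d = qx * ref(j, 0) + qy * ref(j, 1) + qz * ref(j, 2);
            if (d > best) { best = d; arg = j; }
        }
        out[i] = arg + 1;
    }
    return out;
}
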