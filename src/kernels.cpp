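#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Disjoint-set forest with path compression (plain indices into pixel array).
// ---------------------------------------------------------------------------
static int dsu_find(std::vector<int>& parent, int i) {
    int root = i;
    while (parent[root] != root) root = parent[root];
    while (parent[i] != root) { int nxt = parent[i]; parent[i] = root; i = nxt; }
    return root;
}

// Persistence-based local maxima. Pixels are processed in decreasing
// intensity order (ties broken by row-major index) while components are
// merged with a union-find; when a component dies at level v its peak has
// prominence peak - v. Maxima with prominence >= tolerance (and > 0) are
// reported. Constant plateaus report the rounded centroid of the top
// plateau. Coordinates are 0-based, x = column, y = row.
// [[Rcpp::export]]
DataFrame cpp_find_maxima(NumericMatrix img, double tolerance) {
    const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    // linear index i = c*nr + r (column-major); row-major key = r*nc + c
    std::sort(order.begin(), order.end(), [&](int a, int b) {
        double va = img[a], vb = img[b];
        if (va != vb) return va > vb;
        int ra = a % nr, ca = a / nr, rb = b % nr, cb = b / nr;
        return (long)ra * nc + ca < (long)rb * nc + cb;
    });

    std::vector<int> parent(n, -1);
    std::vector<double> peakV(n), plSumR(n), plSumC(n);
    std::vector<int> plN(n);
    std::vector<long> peakKey(n);
    std::vector<char> plOpen(n);
    std::vector<char> active(n, 0);

    std::vector<double> out_x, out_y, out_v, out_p;
    const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
    const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};

    auto emit = [&](int root, double prom) {
        if (prom > 0.0 && prom >= tolerance) {
            out_x.push_back(std::lround(plSumC[root] / plN[root]));
            out_y.push_back(std::lround(plSumR[root] / plN[root]));
            out_v.push_back(peakV[root]);
            out_p.push_back(prom);
        }
    };

    std::vector<int> roots; roots.reserve(8);
    for (int k = 0; k < n; ++k) {
        const int p = order[k];
        const int r = p % nr, c = p / nr;
        const double v = img[p];
        roots.clear();
        for (int q = 0; q < 8; ++q) {
            const int rr = r + dr[q], cc = c + dc[q];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            const int np = cc * nr + rr;
            if (!active[np]) continue;
            const int root = dsu_find(parent, np);
            if (std::find(roots.begin(), roots.end(), root) == roots.end())
                roots.push_back(root);
        }
        if (roots.empty()) {
            parent[p] = p;
            peakV[p] = v; plSumR[p] = r; plSumC[p] = c; plN[p] = 1;
            peakKey[p] = (long)r * nc + c; plOpen[p] = 1;
        } else {
            int surv = roots[0];
            for (size_t q = 1; q < roots.size(); ++q) {
                int cand = roots[q];
                if (peakV[cand] > peakV[surv] ||
                    (peakV[cand] == peakV[surv] && peakKey[cand] < peakKey[surv]))
                    surv = cand;
            }
            for (size_t q = 0; q < roots.size(); ++q) {
                int dead = roots[q];
                if (dead == surv) continue;
                double prom = peakV[dead] - v;
                if (prom == 0.0 && peakV[surv] == v &&
                    plOpen[dead] && plOpen[surv]) {
                    // same constant plateau split across components: merge
                    plSumR[surv] += plSumR[dead]; plSumC[surv] += plSumC[dead];
                    plN[surv] += plN[dead];
                    if (peakKey[dead] < peakKey[surv]) peakKey[surv] = peakKey[dead];
                } else {
                    emit(dead, prom);
                }
                parent[dead] = surv;
            }
            parent[p] = surv;
            if (plOpen[surv]) {
                if (v == peakV[surv]) { plSumR[surv] += r; plSumC[surv] += c; plN[surv] += 1; }
                else plOpen[surv] = 0;
            }
        }
        active[p] = 1;
    }
    const double vmin = img[order[n - 1]];
    for (int i = 0; i < n; ++i) {
        if (parent[i] == i) emit(i, peakV[i] - vmin);
    }
    return DataFrame::create(_["x"] = out_x, _["y"] = out_y,
                             _["value"] = out_v, _["prominence"] = out_p);
}

// ---------------------------------------------------------------------------
// Pair displacements within a disc of radius rmax (at 1-px bin resolution):
// a pair (i -> j) is accumulated at bin (round(dx), round(dy)) when
// 0 < round(dx)^2 + round(dy)^2 <= rmax^2. Reference cells must lie at least
// `margin` from every field edge. In ordered mode only neighbours with
// t[j] > t[i] are accumulated. In unordered mode displacements are
// directionless, so every reference -> neighbour entry is accumulated
// together with its mirror -d: the map is exactly centro-symmetric and the
// per-bin expectation stays flat for uniform fields (the margin keeps every
// reference's disc fully inside the field, so no edge correction is
// needed). Spatial grid gives O(n * neighbours).
// [[Rcpp::export]]
List cpp_pair_displacements(NumericVector x, NumericVector y, NumericVector t,
                            bool ordered, int rmax, double margin,
                            double xmin, double xmax, double ymin, double ymax,
                            bool keep_pairs) {
    const int n = x.size();
    const int side = 2 * rmax + 1;
    IntegerMatrix counts(side, side);  // row = dy + rmax, col = dx + rmax
    // +1 so the 3x3 neighbour ring covers displacements that round into the
    // disc from just beyond rmax
    const double cell = (double)rmax + 1.0;
    const int ngx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
    const int ngy = std::max(1, (int)std::ceil((ymax - ymin) / cell));
    std::vector<std::vector<int>> grid((size_t)ngx * ngy);
    auto cell_of = [&](double px, double py) {
        int gx = std::min(ngx - 1, std::max(0, (int)((px - xmin) / cell)));
        int gy = std::min(ngy - 1, std::max(0, (int)((py - ymin) / cell)));
        return gy * ngx + gx;
    };
    for (int i = 0; i < n; ++i) grid[cell_of(x[i], y[i])].push_back(i);

    std::vector<int> pi, pj;
    std::vector<double> pdx, pdy;
    const long r2max = (long)rmax * rmax;
    long npairs = 0; int nref = 0;
    for (int i = 0; i < n; ++i) {
        if (x[i] < xmin + margin || x[i] > xmax - margin ||
            y[i] < ymin + margin || y[i] > ymax - margin) continue;
        ++nref;
        int gx = std::min(ngx - 1, std::max(0, (int)((x[i] - xmin) / cell)));
        int gy = std::min(ngy - 1, std::max(0, (int)((y[i] - ymin) / cell)));
        for (int ay = std::max(0, gy - 1); ay <= std::min(ngy - 1, gy + 1); ++ay) {
            for (int ax = std::max(0, gx - 1); ax <= std::min(ngx - 1, gx + 1); ++ax) {
                const std::vector<int>& bucket = grid[(size_t)ay * ngx + ax];
                for (size_t b = 0; b < bucket.size(); ++b) {
                    const int j = bucket[b];
                    if (j == i) continue;
                    if (ordered && !(t[j] > t[i])) continue;
                    const double dx = x[j] - x[i], dy = y[j] - y[i];
                    const long bdx = std::lround(dx), bdy = std::lround(dy);
                    const long rr = bdx * bdx + bdy * bdy;
                    if (rr == 0 || rr > r2max) continue;
                    counts((int)(bdy + rmax), (int)(bdx + rmax)) += 1;
                    ++npairs;
                    if (keep_pairs) {
                        pi.push_back(i + 1); pj.push_back(j + 1);
                        pdx.push_back(dx); pdy.push_back(dy);
                    }
                    if (!ordered) {
                        // directionless displacement: accumulate the mirror
                        counts((int)(-bdy + rmax), (int)(-bdx + rmax)) += 1;
                        ++npairs;
                        if (keep_pairs) {
                            pi.push_back(i + 1); pj.push_back(j + 1);
                            pdx.push_back(-dx); pdy.push_back(-dy);
                        }
                    }
                }
            }
        }
    }
    List out = List::create(_["counts"] = counts, _["n_pairs"] = (double)npairs,
                            _["n_ref"] = nref);
    if (keep_pairs)
        out["pairs"] = DataFrame::create(_["i"] = pi, _["j"] = pj,
                                         _["dx"] = pdx, _["dy"] = pdy);
    return out;
}

// ---------------------------------------------------------------------------
// Random sequential adsorption: uniform proposals, rejected when closer than
// dmin to an accepted point; stops at n accepted or max_attempts proposals.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_rsa_field(int n, double xmin, double xmax, double ymin, double ymax,
                   double dmin, int max_attempts) {
    std::vector<double> px, py;
    px.reserve(n); py.reserve(n);
    const double d2 = dmin * dmin;
    const double cell = (dmin > 0) ? dmin / std::sqrt(2.0) : (xmax - xmin);
    const int ngx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
    const int ngy = std::max(1, (int)std::ceil((ymax - ymin) / cell));
    std::vector<std::vector<int>> grid((size_t)ngx * ngy);
    int attempts = 0;
    while ((int)px.size() < n && attempts < max_attempts) {
        ++attempts;
        const double cx = xmin + R::unif_rand() * (xmax - xmin);
        const double cy = ymin + R::unif_rand() * (ymax - ymin);
        bool ok = true;
        if (dmin > 0) {
            const int gx = std::min(ngx - 1, (int)((cx - xmin) / cell));
            const int gy = std::min(ngy - 1, (int)((cy - ymin) / cell));
            for (int ay = std::max(0, gy - 2); ok && ay <= std::min(ngy - 1, gy + 2); ++ay)
                for (int ax = std::max(0, gx - 2); ok && ax <= std::min(ngx - 1, gx + 2); ++ax) {
                    const std::vector<int>& bucket = grid[(size_t)ay * ngx + ax];
                    for (size_t b = 0; b < bucket.size(); ++b) {
                        const double ddx = px[bucket[b]] - cx, ddy = py[bucket[b]] - cy;
                        if (ddx * ddx + ddy * ddy < d2) { ok = false; break; }
                    }
                }
        }
        if (ok) {
            px.push_back(cx); py.push_back(cy);
            if (dmin > 0) {
                const int gx = std::min(ngx - 1, (int)((cx - xmin) / cell));
                const int gy = std::min(ngy - 1, (int)((cy - ymin) / cell));
                grid[(size_t)gy * ngx + gx].push_back((int)px.size() - 1);
            }
        }
    }
    return List::create(_["x"] = wrap(px), _["y"] = wrap(py),
                        _["attempts"] = attempts);
}
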