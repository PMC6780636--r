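#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Average unsuccessful-search path length of a binary search tree with n
// external nodes; the standard normalizer of the isolation-forest score.
static double cFactor(int n) {
    if (n <= 1) return 0.0;
    double h = std::log((double)(n - 1)) + 0.5772156649015329;
    return 2.0 * h - 2.0 * (double)(n - 1) / (double)n;
}

// Grow one isolation tree from the subsample `sub` while routing every row
// in `pts`; accumulate terminal depths (plus the subtree-size correction)
// into `path`. Splits: random feature with nonzero range on the subsample,
// split point uniform on that range. R's RNG is used throughout so results
// are governed by set.seed().
static void growNode(const NumericMatrix &X,
                     std::vector<int> &sub, std::vector<int> &pts,
                     int depth, int depthLimit, NumericVector &path) {
    int nSub = sub.size();
    if (nSub <= 1 || depth >= depthLimit) {
        double add = depth + cFactor(nSub);
        for (size_t i = 0; i < pts.size(); ++i) path[pts[i]] += add;
        return;
    }
    int p = X.ncol();
    // try a few random features until one has spread on the subsample
    int q = -1; double lo = 0, hi = 0;
    for (int attempt = 0; attempt < 8; ++attempt) {
        int cand = (int)(unif_rand() * p); if (cand == p) cand--;
        lo = hi = X(sub[0], cand);
        for (int i = 1; i < nSub; ++i) {
            double v = X(sub[i], cand);
            if (v < lo) lo = v;
            if (v > hi) hi = v;
        }
        if (hi > lo) { q = cand; break; }
    }
    if (q < 0) {  // subsample constant on sampled features: terminal
        double add = depth + cFactor(nSub);
        for (size_t i = 0; i < pts.size(); ++i) path[pts[i]] += add;
        return;
    }
    double split = lo + unif_rand() * (hi - lo);
    std::vector<int> subL, subR, ptsL, ptsR;
    for (int i = 0; i < nSub; ++i)
        (X(sub[i], q) < split ? subL : subR).push_back(sub[i]);
    for (size_t i = 0; i < pts.size(); ++i)
        (X(pts[i], q) < split ? ptsL : ptsR).push_back(pts[i]);
    if (subL.empty() || subR.empty()) {  // degenerate split: terminal
        double add = depth + cFactor(nSub);
        for (size_t i = 0; i < pts.size(); ++i) path[pts[i]] += add;
        return;
    }
    growNode(X, subL, ptsL, depth + 1, depthLimit, path);
    growNode(X, subR, ptsR, depth + 1, depthLimit, path);
}

// [[Rcpp::export(name = ".iforestScore")]]
NumericVector iforestScore(NumericMatrix X, int nTrees, int subsampleSize) {
    int n = X.nrow();
    int psi = subsampleSize < n ? subsampleSize : n;
    if (psi < 2) stop("isolation forest needs at least 2 samples");
    int depthLimit = (int)std::ceil(std::log2((double)psi));
    NumericVector path(n);
    std::vector<int> perm(n);
    for (int t = 0; t < nTrees; ++t) {
        // partial Fisher-Yates draw of psi distinct rows
        for (int i = 0; i < n; ++i) perm[i] = i;
        std::vector<int> sub(psi);
        for (int i = 0; i < psi; ++i) {
            int j = i + (int)(unif_rand() * (n - i));
            if (j >= n) j = n - 1;
            std::swap(perm[i], perm[j]);
            sub[i] = perm[i];
        }
        std::vector<int> pts(n);
        for (int i = 0; i < n; ++i) pts[i] = i;
        growNode(X, sub, pts, 0, depthLimit, path);
    }
    double cn = cFactor(psi);
    NumericVector score(n);
    for (int i = 0; i < n; ++i)
        score[i] = std::pow(2.0, -(path[i] / nTrees) / cn);
    return score;
}
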