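#include <Rcpp.h>
using namespace Rcpp;

// Weighted multiclass decision stump: the weak learner of the SAMME
// boosting routine. `ord` holds, per feature, the 0-based row order that
// sorts that feature ascending (precomputed once per boosting run, since
// sample weights change across rounds but the data do not).
//
// Returns the split maximizing weighted accuracy with one class predicted
// on each side, encoded as (feature, threshold, leftClass, rightClass),
// all 0-based except threshold; feature = -1 encodes the no-split stump
// predicting the majority class.
// [[Rcpp::export(name = ".stumpFit")]]
List stumpFit(NumericMatrix X, IntegerVector y, NumericVector w,
              int nClass, IntegerMatrix ord) {
    int n = X.nrow(), p = X.ncol();
    std::vector<double> total(nClass, 0.0);
    for (int i = 0; i < n; ++i) total[y[i]] += w[i];
    // baseline: majority-class stump
    int baseClass = 0;
    for (int k = 1; k < nClass; ++k)
        if (total[k] > total[baseClass]) baseClass = k;
    double best = total[baseClass];
    int bestFeat = -1, bestLeft = baseClass, bestRight = baseClass;
    double bestThr = 0.0;

    std::vector<double> left(nClass);
    for (int j = 0; j < p; ++j) {
        std::fill(left.begin(), left.end(), 0.0);
        for (int s = 0; s < n - 1; ++s) {
            int i = ord(s, j);
            left[y[i]] += w[i];
            double xi = X(i, j), xnext = X(ord(s + 1, j), j);
            if (xnext <= xi) continue;  // no threshold between ties
            int lc = 0, rc = 0;
            double lbest = left[0], rbest = total[0] - left[0];
            for (int k = 1; k < nClass; ++k) {
                if (left[k] > lbest) { lbest = left[k]; lc = k; }
                double r = total[k] - left[k];
                if (r > rbest) { rbest = r; rc = k; }
            }
            if (lbest + rbest > best) {
                best = lbest + rbest;
                bestFeat = j;
                bestThr = 0.5 * (xi + xnext);
                bestLeft = lc; bestRight = rc;
            }
        }
    }
    return List::create(_["feature"] = bestFeat + 1,  // 1-based, 0 = no split
                        _["threshold"] = bestThr,
                        _["leftClass"] = bestLeft + 1,
                        _["rightClass"] = bestRight + 1);
}
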