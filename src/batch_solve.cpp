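#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solve C independent p x p symmetric positive-definite systems
// A_j beta_j = b_j, where column j of A holds vec(A_j) (column-major) and
// column j of B holds b_j. Used by the IRLS engine: one system per feature
// per iteration, p small (the reduced covariate design rank). Columns whose
// system is not positive definite are flagged 0 in the returned attribute
// "ok" and left as NA.
// [[Rcpp::export(name = ".batchCholSolve")]]
NumericMatrix batchCholSolve(NumericMatrix A, NumericMatrix B) {
    const int p = B.nrow();
    const int C = B.ncol();
    NumericMatrix beta(p, C);
    LogicalVector ok(C);
    std::vector<double> L(p * p), y(p);
    for (int j = 0; j < C; ++j) {
        const double* a = &A(0, j);
        bool good = true;
        // Cholesky factorization A = L L'
        for (int i = 0; i < p && good; ++i) {
            for (int k = 0; k <= i; ++k) {
                double s = a[i + p * k];
                for (int m = 0; m < k; ++m)
                    s -= L[i + p * m] * L[k + p * m];
                if (i == k) {
                    if (s <= 0.0 || !std::isfinite(s)) { good = false;
                                                         break; }
                    L[i + p * i] = std::sqrt(s);
                } else {
                    L[i + p * k] = s / L[k + p * k];
                }
            }
        }
        ok[j] = good;
        if (!good) {
            for (int i = 0; i < p; ++i) beta(i, j) = NA_REAL;
            continue;
        }
        // forward solve L y = b
        for (int i = 0; i < p; ++i) {
            double s = B(i, j);
            for (int m = 0; m < i; ++m) s -= L[i + p * m] * y[m];
            y[i] = s / L[i + p * i];
        }
        // back solve L' x = y
        for (int i = p - 1; i >= 0; --i) {
            double s = y[i];
            for (int m = i + 1; m < p; ++m)
                s -= L[m + p * i] * beta(m, j);
            beta(i, j) = s / L[i + p * i];
        }
    }
    beta.attr("ok") = ok;
    return beta;
}
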