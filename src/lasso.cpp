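// Cyclic coordinate descent with soft-thresholding for the LASSO
// regularization path, using covariance (Gram-matrix) updates so that the
// Gram matrix of the standardized predictors can be computed once and
// shared across the per-miRNA fits. Objective on the standardized scale:
//   (1/2n) ||y - X beta||^2 + lambda ||beta||_1
// with diag(Gram) = 1. Warm starts along the decreasing lambda sequence;
// convergence when the largest coefficient change in a full cycle falls
// below `tol`.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double l) {
    if (z > l) return z - l;
    if (z < -l) return z + l;
    return 0.0;
}

// G: p x p Gram matrix X'X/n of standardized predictors (diag = 1)
// c0: p vector X'y/n (y centered)
// Returns a sparse p x nlambda matrix of standardized coefficients.
// [[Rcpp::export(name = ".cpp_lasso_path")]]
arma::sp_mat cpp_lasso_path(const arma::mat& G, const arma::vec& c0,
                            const arma::vec& lambdas, double tol,
                            int max_cycles) {
    const int p = c0.n_elem, nl = lambdas.n_elem;
    arma::vec beta(p, arma::fill::zeros);
    std::vector<int> active;
    std::vector<bool> in_active(p, false);
    arma::sp_mat out(p, nl);

    // gradient of the smooth part at the current beta, coordinate j:
    // c0_j - sum_{k active} G_jk beta_k
    auto grad_j = [&](int j) {
        double s = c0[j];
        for (int k : active) s -= G(j, k) * beta[k];
        return s;
    };

    for (int il = 0; il < nl; ++il) {
        double lam = lambdas[il];
        for (int cycle = 0; cycle < max_cycles; ++cycle) {
            // iterate on the active set until stable
            double maxch;
            do {
                maxch = 0.0;
                for (int j : active) {
                    double old = beta[j];
                    double z = grad_j(j) + old;  // G_jj = 1
                    double nb = soft(z, lam);
                    if (nb != old) {
                        beta[j] = nb;
                        maxch = std::max(maxch, std::fabs(nb - old));
                    }
                }
            } while (maxch >= tol && !active.empty());
            // full pass over all coordinates; add violators
            bool added = false;
            maxch = 0.0;
            for (int j = 0; j < p; ++j) {
                double old = beta[j];
                double z = grad_j(j) + old;
                double nb = soft(z, lam);
                if (nb != old) {
                    beta[j] = nb;
                    maxch = std::max(maxch, std::fabs(nb - old));
                }
                if (beta[j] != 0.0 && !in_active[j]) {
                    in_active[j] = true;
                    active.push_back(j);
                    added = true;
                }
            }
            if (maxch < tol && !added) break;
        }
        for (int j : active)
            if (beta[j] != 0.0) out(j, il) = beta[j];
    }
    return out;
}
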