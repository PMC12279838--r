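// Multi-output feed-forward network for cross-omics regression.
// Architecture per hidden layer: dense -> batchnorm -> ReLU -> dropout,
// then a linear dense output layer. Trained with Adam on mean-squared
// error plus an L2 penalty on the hidden-layer kernels, with a
// reduce-on-plateau learning-rate schedule. All randomness (weight
// initialization, epoch shuffling, dropout masks) comes from R's RNG so a
// set.seed() in R makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

namespace {

struct Params {
    std::vector<mat> W;      // layer kernels, (in x out)
    std::vector<rowvec> b;   // biases
    std::vector<rowvec> gamma, beta, rmean, rvar;  // batchnorm (hidden only)
    bool use_bn;
};

struct Grads {
    std::vector<mat> W;
    std::vector<rowvec> b, gamma, beta;
};

Params params_from_list(const List& li) {
    Params p;
    List W = li["W"], b = li["b"];
    p.use_bn = as<bool>(li["use_bn"]);
    for (int l = 0; l < W.size(); ++l) {
        p.W.push_back(as<mat>(W[l]));
        p.b.push_back(as<rowvec>(b[l]));
    }
    if (p.use_bn) {
        List ga = li["gamma"], be = li["beta"], rm = li["rmean"], rv = li["rvar"];
        for (int l = 0; l < ga.size(); ++l) {
            p.gamma.push_back(as<rowvec>(ga[l]));
            p.beta.push_back(as<rowvec>(be[l]));
            p.rmean.push_back(as<rowvec>(rm[l]));
            p.rvar.push_back(as<rowvec>(rv[l]));
        }
    }
    return p;
}

List params_to_list(const Params& p) {
    List W(p.W.size()), b(p.b.size());
    for (size_t l = 0; l < p.W.size(); ++l) { W[l] = p.W[l]; b[l] = p.b[l]; }
    List out = List::create(Named("W") = W, Named("b") = b,
                            Named("use_bn") = p.use_bn);
    if (p.use_bn) {
        size_t H = p.gamma.size();
        List ga(H), be(H), rm(H), rv(H);
        for (size_t l = 0; l < H; ++l) {
            ga[l] = p.gamma[l]; be[l] = p.beta[l];
            rm[l] = p.rmean[l]; rv[l] = p.rvar[l];
        }
        out["gamma"] = ga; out["beta"] = be; out["rmean"] = rm; out["rvar"] = rv;
    }
    return out;
}

// Glorot-uniform initialization from R's RNG
Params init_params(int n_in, const arma::ivec& hidden, int n_out, bool use_bn) {
    Params p; p.use_bn = use_bn;
    std::vector<int> dims;
    dims.push_back(n_in);
    for (arma::uword i = 0; i < hidden.n_elem; ++i) dims.push_back(hidden[i]);
    dims.push_back(n_out);
    for (size_t l = 0; l + 1 < dims.size(); ++l) {
        double lim = std::sqrt(6.0 / (dims[l] + dims[l + 1]));
        mat W(dims[l], dims[l + 1]);
        for (arma::uword j = 0; j < W.n_cols; ++j)      // column-major fill
            for (arma::uword i = 0; i < W.n_rows; ++i)
                W(i, j) = R::runif(-lim, lim);
        p.W.push_back(W);
        p.b.push_back(rowvec(dims[l + 1], arma::fill::zeros));
        if (use_bn && l + 2 < dims.size()) {
            p.gamma.push_back(rowvec(dims[l + 1], arma::fill::ones));
            p.beta.push_back(rowvec(dims[l + 1], arma::fill::zeros));
            p.rmean.push_back(rowvec(dims[l + 1], arma::fill::zeros));
            p.rvar.push_back(rowvec(dims[l + 1], arma::fill::ones));
        }
    }
    return p;
}

struct Cache {  // per-layer activations needed for backprop
    std::vector<mat> A;        // inputs to each dense layer
    std::vector<mat> Zhat;     // normalized pre-activations
    std::vector<mat> H;        // post-ReLU (pre-dropout)
    std::vector<mat> mask;     // dropout masks
    std::vector<rowvec> bvar;  // batch variances
    mat out;
};

// training-mode forward pass; updates running batchnorm stats if track=true
double forward_train(const Params& p, const mat& X, const mat& Y,
                     double l2, double dropout, double bn_eps,
                     double bn_mom, bool track, bool use_dropout,
                     Params* upd, Cache& c) {
    size_t L = p.W.size() - 1;  // hidden layers
    mat A = X;
    c.A.clear(); c.Zhat.clear(); c.H.clear(); c.mask.clear(); c.bvar.clear();
    for (size_t l = 0; l < L; ++l) {
        c.A.push_back(A);
        mat Z = A * p.W[l];
        Z.each_row() += p.b[l];
        mat out;
        if (p.use_bn) {
            rowvec mu = arma::mean(Z, 0);
            rowvec va = arma::var(Z, 1, 0);  // population variance
            if (track && upd) {
                upd->rmean[l] = bn_mom * upd->rmean[l] + (1.0 - bn_mom) * mu;
                upd->rvar[l]  = bn_mom * upd->rvar[l]  + (1.0 - bn_mom) * va;
            }
            mat Zhat = Z.each_row() - mu;
            rowvec istd = 1.0 / arma::sqrt(va + bn_eps);
            Zhat.each_row() %= istd;
            c.Zhat.push_back(Zhat);
            c.bvar.push_back(va);
            out = Zhat.each_row() % p.gamma[l];
            out.each_row() += p.beta[l];
        } else {
            c.Zhat.push_back(Z);
            out = Z;
        }
        mat H = arma::clamp(out, 0.0, arma::datum::inf);  // ReLU
        c.H.push_back(H);
        if (use_dropout && dropout > 0) {
            mat m(H.n_rows, H.n_cols);
            double keep = 1.0 - dropout;
            for (arma::uword j = 0; j < m.n_cols; ++j)
                for (arma::uword i = 0; i < m.n_rows; ++i)
                    m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
            c.mask.push_back(m);
            A = H % m;
        } else {
            c.mask.push_back(mat());
            A = H;
        }
    }
    c.A.push_back(A);
    c.out = A * p.W[L];
    c.out.each_row() += p.b[L];
    double mse = arma::accu(arma::square(c.out - Y)) / (Y.n_rows * Y.n_cols);
    double pen = 0.0;
    for (size_t l = 0; l < L; ++l) pen += arma::accu(arma::square(p.W[l]));
    return mse + l2 * pen;
}

Grads backward(const Params& p, const Cache& c, const mat& Y,
               double l2, double bn_eps) {
    size_t L = p.W.size() - 1;
    Grads g;
    g.W.resize(L + 1); g.b.resize(L + 1);
    g.gamma.resize(L); g.beta.resize(L);
    double m = (double)Y.n_rows, q = (double)Y.n_cols;
    mat dZ = 2.0 * (c.out - Y) / (m * q);
    g.W[L] = c.A[L].t() * dZ;
    g.b[L] = arma::sum(dZ, 0);
    mat dA = dZ * p.W[L].t();
    for (int l = (int)L - 1; l >= 0; --l) {
        mat dH = c.mask[l].n_elem ? mat(dA % c.mask[l]) : dA;
        mat dOut = dH % arma::conv_to<mat>::from(c.H[l] > 0);  // ReLU gate
        mat dZl;
        if (p.use_bn) {
            g.gamma[l] = arma::sum(dOut % c.Zhat[l], 0);
            g.beta[l] = arma::sum(dOut, 0);
            mat dZhat = dOut.each_row() % p.gamma[l];
            rowvec istd = 1.0 / arma::sqrt(c.bvar[l] + bn_eps);
            rowvec s1 = arma::sum(dZhat, 0);
            rowvec s2 = arma::sum(dZhat % c.Zhat[l], 0);
            double mb = (double)dOut.n_rows;
            dZl = mb * dZhat;
            dZl.each_row() -= s1;
            dZl -= c.Zhat[l].each_row() % s2;
            dZl.each_row() %= istd / mb;
        } else {
            dZl = dOut;
        }
        g.W[l] = c.A[l].t() * dZl + 2.0 * l2 * p.W[l];
        g.b[l] = arma::sum(dZl, 0);
        dA = dZl * p.W[l].t();
    }
    return g;
}

// inference-mode forward (running stats, no dropout)
mat forward_infer(const Params& p, const mat& X, double bn_eps) {
    size_t L = p.W.size() - 1;
    mat A = X;
    for (size_t l = 0; l < L; ++l) {
        mat Z = A * p.W[l];
        Z.each_row() += p.b[l];
        if (p.use_bn) {
            Z.each_row() -= p.rmean[l];
            Z.each_row() %= p.gamma[l] / arma::sqrt(p.rvar[l] + bn_eps);
            Z.each_row() += p.beta[l];
        }
        A = arma::clamp(Z, 0.0, arma::datum::inf);
    }
    mat out = A * p.W[L];
    out.each_row() += p.b[L];
    return out;
}

struct AdamState {
    std::vector<mat> mW, vW;
    std::vector<rowvec> mb, vb, mg, vg, mbe, vbe;
    long t = 0;
};

void adam_step_mat(mat& w, const mat& g, mat& m, mat& v, double lr,
                   double b1, double b2, double eps, double bc1, double bc2) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * arma::square(g);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

void adam_step_vec(rowvec& w, const rowvec& g, rowvec& m, rowvec& v, double lr,
                   double b1, double b2, double eps, double bc1, double bc2) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * arma::square(g);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_mlp_train")]]
List cpp_mlp_train(const arma::mat& Xtr, const arma::mat& Ytr,
                   const arma::mat& Xval, const arma::mat& Yval,
                   const arma::ivec& hidden, bool use_bn,
                   double l2, double dropout,
                   double lr0, double plateau_factor, int plateau_patience,
                   double min_lr, int max_epochs, int batch_size,
                   double bn_eps, double bn_mom, double adam_eps) {
    int n = Xtr.n_rows;
    Params p = init_params(Xtr.n_cols, hidden, Ytr.n_cols, use_bn);
    AdamState st;
    for (size_t l = 0; l < p.W.size(); ++l) {
        st.mW.push_back(mat(arma::size(p.W[l]), arma::fill::zeros));
        st.vW.push_back(mat(arma::size(p.W[l]), arma::fill::zeros));
        st.mb.push_back(rowvec(p.b[l].n_elem, arma::fill::zeros));
        st.vb.push_back(rowvec(p.b[l].n_elem, arma::fill::zeros));
    }
    for (size_t l = 0; l < p.gamma.size(); ++l) {
        st.mg.push_back(rowvec(p.gamma[l].n_elem, arma::fill::zeros));
        st.vg.push_back(rowvec(p.gamma[l].n_elem, arma::fill::zeros));
        st.mbe.push_back(rowvec(p.beta[l].n_elem, arma::fill::zeros));
        st.vbe.push_back(rowvec(p.beta[l].n_elem, arma::fill::zeros));
    }
    const double b1 = 0.9, b2 = 0.999;
    double lr = lr0, best_val = arma::datum::inf;
    int wait = 0;
    std::vector<double> h_train, h_val, h_lr;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    Cache c;
    for (int epoch = 0; epoch < max_epochs; ++epoch) {
        // Fisher-Yates shuffle from R's RNG
        for (int i = n - 1; i > 0; --i) {
            int j = (int)std::floor(R::unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(idx[i], idx[j]);
        }
        double ep_loss = 0.0;
        int nb = 0;
        for (int start = 0; start < n; start += batch_size) {
            int end = std::min(start + batch_size, n);
            arma::uvec rows(end - start);
            for (int i = start; i < end; ++i) rows[i - start] = idx[i];
            mat Xb = Xtr.rows(rows), Yb = Ytr.rows(rows);
            double loss = forward_train(p, Xb, Yb, l2, dropout, bn_eps,
                                        bn_mom, true, true, &p, c);
            Grads g = backward(p, c, Yb, l2, bn_eps);
            st.t += 1;
            double bc1 = 1.0 - std::pow(b1, (double)st.t);
            double bc2 = 1.0 - std::pow(b2, (double)st.t);
            for (size_t l = 0; l < p.W.size(); ++l) {
                adam_step_mat(p.W[l], g.W[l], st.mW[l], st.vW[l], lr, b1, b2,
                              adam_eps, bc1, bc2);
                adam_step_vec(p.b[l], g.b[l], st.mb[l], st.vb[l], lr, b1, b2,
                              adam_eps, bc1, bc2);
            }
            for (size_t l = 0; l < p.gamma.size(); ++l) {
                adam_step_vec(p.gamma[l], g.gamma[l], st.mg[l], st.vg[l], lr,
                              b1, b2, adam_eps, bc1, bc2);
                adam_step_vec(p.beta[l], g.beta[l], st.mbe[l], st.vbe[l], lr,
                              b1, b2, adam_eps, bc1, bc2);
            }
            ep_loss += loss; nb += 1;
        }
        // epoch-end validation loss (inference mode) + L2 penalty term
        mat pred = forward_infer(p, Xval, bn_eps);
        double pen = 0.0;
        for (size_t l = 0; l + 1 < p.W.size(); ++l)
            pen += arma::accu(arma::square(p.W[l]));
        double val = arma::accu(arma::square(pred - Yval)) /
                     (Yval.n_rows * Yval.n_cols) + l2 * pen;
        h_train.push_back(ep_loss / nb);
        h_val.push_back(val);
        h_lr.push_back(lr);
        // reduce-on-plateau schedule
        if (val < best_val - 1e-9) { best_val = val; wait = 0; }
        else if (++wait >= plateau_patience) {
            lr = std::max(lr * plateau_factor, min_lr);
            wait = 0;
        }
    }
    List out = params_to_list(p);
    out["history"] = DataFrame::create(
        Named("epoch") = seq_len((int)h_train.size()),
        Named("train_loss") = h_train, Named("val_loss") = h_val,
        Named("learning_rate") = h_lr);
    return out;
}

// [[Rcpp::export(name = ".cpp_mlp_init")]]
List cpp_mlp_init(int n_in, const arma::ivec& hidden, int n_out, bool use_bn) {
    return params_to_list(init_params(n_in, hidden, n_out, use_bn));
}

// loss + analytic gradients with dropout disabled (batchnorm in batch-stats
// mode); used by the finite-difference gradient checks
// [[Rcpp::export(name = ".cpp_mlp_loss_grad")]]
List cpp_mlp_loss_grad(const List& params, const arma::mat& X,
                       const arma::mat& Y, double l2, double bn_eps) {
    Params p = params_from_list(params);
    Cache c;
    double loss = forward_train(p, X, Y, l2, 0.0, bn_eps, 0.99, false, false,
                                nullptr, c);
    Grads g = backward(p, c, Y, l2, bn_eps);
    List gW(g.W.size()), gb(g.b.size());
    for (size_t l = 0; l < g.W.size(); ++l) { gW[l] = g.W[l]; gb[l] = g.b[l]; }
    List out = List::create(Named("loss") = loss, Named("gW") = gW,
                            Named("gb") = gb);
    if (p.use_bn) {
        List gg(g.gamma.size()), gbe(g.beta.size());
        for (size_t l = 0; l < g.gamma.size(); ++l) {
            gg[l] = g.gamma[l]; gbe[l] = g.beta[l];
        }
        out["ggamma"] = gg; out["gbeta"] = gbe;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_mlp_predict")]]
arma::mat cpp_mlp_predict(const List& params, const arma::mat& X,
                          double bn_eps) {
    Params p = params_from_list(params);
    return forward_infer(p, X, bn_eps);
}
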