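// Pruning-algorithm likelihood for k-state continuous-time Markov (Mk)
// characters on a rooted tree, with the kappa branch-length power transform
// applied on the fly.  Called from R once per MCMC iteration, so the hot
// path (k = 2) uses the closed-form transition matrix; k >= 3 uses one
// eigendecomposition of the generator per call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 2-state closed form: P00(t) = (q10 + q01 e^{-(q01+q10)t}) / (q01+q10)
static inline void ptrans2(double q01, double q10, double t, mat &P) {
    double s = q01 + q10;
    if (s <= 0.0 || t <= 0.0) { P.eye(2, 2); return; }
    double e = std::exp(-s * t);
    double pi0 = q10 / s, pi1 = q01 / s;
    P(0, 0) = pi0 + pi1 * e;
    P(0, 1) = 1.0 - P(0, 0);
    P(1, 1) = pi1 + pi0 * e;
    P(1, 0) = 1.0 - P(1, 1);
}

// General k: P(t) = V exp(L t) V^{-1} from one eig_gen of Q; falls back to
// scaling-and-squaring if the eigenvector matrix is ill-conditioned.
struct EigCache {
    bool ok;
    cx_mat V, Vinv;
    cx_vec lambda;
};

static void eig_setup(const mat &Q, EigCache &ec) {
    cx_vec lam;
    cx_mat V;
    ec.ok = false;
    if (eig_gen(lam, V, Q)) {
        double rc = rcond(V);
        if (std::isfinite(rc) && rc > 1e-10) {
            ec.V = V;
            ec.Vinv = inv(V);
            ec.lambda = lam;
            ec.ok = true;
        }
    }
}

static inline void ptrans_general(const mat &Q, const EigCache &ec,
                                  double t, mat &P) {
    const uword k = Q.n_rows;
    if (t <= 0.0) { P.eye(k, k); return; }
    if (ec.ok) {
        cx_mat D = diagmat(exp(ec.lambda * t));
        P = real(ec.V * D * ec.Vinv);
    } else {
        P = expmat(Q * t);
    }
    // numerical clean-up: clip and renormalise rows
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    for (uword i = 0; i < k; ++i) {
        double rs = accu(P.row(i));
        if (rs > 0.0) P.row(i) /= rs;
    }
}

// edge: 2-column integer matrix in *postorder* (ape node numbering:
// tips 1..ntip, root = ntip + 1).  tip_partials: ntip x k (row i = tip i).
// Returns the log-likelihood log sum_s root_prior[s] L_root[s].
// [[Rcpp::export]]
double mk_loglik_cpp(const Rcpp::IntegerMatrix &edge,
                     const Rcpp::NumericVector &edge_length,
                     int ntip,
                     const Rcpp::NumericMatrix &Qr,
                     const Rcpp::NumericMatrix &tip_partials,
                     const Rcpp::NumericVector &root_prior,
                     double kappa) {
    const int k = Qr.nrow();
    const int nedge = edge.nrow();
    const int nnode_total = ntip + (nedge == 0 ? 1 : nedge); // upper bound
    mat Q(Qr.begin(), k, k);

    bool two_state = (k == 2);
    double q01 = 0.0, q10 = 0.0;
    EigCache ec;
    if (two_state) {
        q01 = Q(0, 1);
        q10 = Q(1, 0);
    } else {
        eig_setup(Q, ec);
    }

    // partials indexed by ape node id (1-based -> 0-based)
    mat part(nnode_total + 1, k, fill::ones);
    vec logscale(nnode_total + 1, fill::zeros);
    std::vector<bool> seen(nnode_total + 1, false);
    for (int i = 1; i <= ntip; ++i)
        for (int j = 0; j < k; ++j)
            part(i, j) = tip_partials(i - 1, j);

    mat P(k, k);
    rowvec contrib(k);
    for (int e = 0; e < nedge; ++e) {
        int par = edge(e, 0), chi = edge(e, 1);
        double b = edge_length[e];
        double t = (b == 0.0 && kappa == 0.0) ? 1.0 : std::pow(b, kappa);
        if (two_state) ptrans2(q01, q10, t, P);
        else ptrans_general(Q, ec, t, P);
        for (int s = 0; s < k; ++s) {
            double acc = 0.0;
            for (int sp = 0; sp < k; ++sp) acc += P(s, sp) * part(chi, sp);
            contrib(s) = acc;
        }
        if (!seen[par]) { seen[par] = true; }
        for (int s = 0; s < k; ++s) part(par, s) *= contrib(s);
        logscale(par) += logscale(chi);
        double mx = part.row(par).max();
        if (mx > 0.0 && mx < 1e-100) {
            part.row(par) /= mx;
            logscale(par) += std::log(mx);
        }
        if (!std::isfinite(part(par, 0)))
            Rcpp::stop("non-finite conditional likelihood at node %d", par);
    }

    int root = (nedge > 0) ? edge(nedge - 1, 0) : 1;
    double lik = 0.0;
    for (int s = 0; s < k; ++s) lik += root_prior[s] * part(root, s);
    if (lik <= 0.0) return R_NegInf;
    return std::log(lik) + logscale(root);
}
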