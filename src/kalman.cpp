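#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Kalman filter + RTS smoother for a linear-Gaussian state-space model whose
// dynamics switch over time according to a fixed discrete-state path.
//
//   x_t = A[z_t] x_{t-1} + b[z_t] + B[z_t] u_t + eps,  eps ~ N(0, Q[z_t])
//   y_t = C x_t + d + delta,                           delta ~ N(0, diag(svec))
//
// The observation covariance is diagonal, so the measurement update is done
// in information form: the D x D matrix M = C' S^-1 C is precomputed once and
// the exact marginal log-likelihood uses the matrix determinant lemma.
//
// y    : N x T observations
// C    : N x D, dvec : N, svec : N (diagonal observation variances)
// A    : D x D x K, b : D x K, Q : D x D x K
// B    : D x U x K (U may be 0), u : U x T
// z    : integer vector length T, 1-based state labels
// m0,P0: prior mean/covariance of x_0 (pre-observation anchor)
//
// Returns smoothed means xs (D x T), covariances Vs (D x D x T), lag-one
// smoothed cross-covariances cross (D x D x (T-1)) with slice t-1 holding
// Cov(x_{t+1}, x_t | y_{1:T}), and the exact marginal log-likelihood.
// [[Rcpp::export(name = ".kalman_smoother_tv")]]
Rcpp::List kalman_smoother_tv(const arma::mat& y,
                              const arma::mat& C,
                              const arma::vec& dvec,
                              const arma::vec& svec,
                              const arma::cube& A,
                              const arma::mat& b,
                              const arma::cube& Q,
                              const arma::cube& B,
                              const arma::mat& u,
                              const arma::ivec& z,
                              const arma::vec& m0,
                              const arma::mat& P0) {
    const uword N = y.n_rows, T = y.n_cols, D = C.n_cols;
    const bool has_input = (B.n_cols > 0u) && (u.n_rows > 0u);

    vec sinv = 1.0 / svec;
    mat Ct_Sinv = C.t() * diagmat(sinv);     // D x N
    mat M = Ct_Sinv * C;                     // D x D information increment
    double logdetS = accu(log(svec));
    const double l2pi = std::log(2.0 * M_PI);

    mat mf(D, T), mp(D, T);                  // filtered / predicted means
    cube Pf(D, D, T), Pp(D, D, T);
    double ll = 0.0;

    vec m_prev = m0;
    mat P_prev = P0;
    for (uword t = 0; t < T; ++t) {
        const uword k = (uword)(z(t) - 1);
        vec mpred;
        mat Ppred;
        if (t == 0) {
            // x_1 carries a free prior N(m0, P0); dynamics start at t = 2
            mpred = m0;
            Ppred = P0;
        } else {
            mpred = A.slice(k) * m_prev + b.col(k);
            if (has_input) mpred += B.slice(k) * u.col(t);
            Ppred = A.slice(k) * P_prev * A.slice(k).t() + Q.slice(k);
        }
        Ppred = 0.5 * (Ppred + Ppred.t());

        mp.col(t) = mpred;
        Pp.slice(t) = Ppred;

        vec e = y.col(t) - C * mpred - dvec;
        vec ve = Ct_Sinv * e;

        mat Pinv;
        if (!inv_sympd(Pinv, Ppred)) Pinv = pinv(Ppred);
        mat Jpost = Pinv + M;
        mat Ppost;
        if (!inv_sympd(Ppost, Jpost)) Ppost = pinv(Jpost);
        Ppost = 0.5 * (Ppost + Ppost.t());
        vec mpost = Ppost * (Pinv * mpred + Ct_Sinv * (y.col(t) - dvec));

        // log |C Ppred C' + S| = log|S| + log|Ppred| + log|Pinv + M|
        double ld_pred, sgn1, ld_post, sgn2;
        log_det(ld_pred, sgn1, Ppred);
        log_det(ld_post, sgn2, Jpost);
        double quad = dot(e % sinv, e) - as_scalar(ve.t() * Ppost * ve);
        ll += -0.5 * (N * l2pi + logdetS + ld_pred + ld_post + quad);

        mf.col(t) = mpost;
        Pf.slice(t) = Ppost;
        m_prev = mpost;
        P_prev = Ppost;
    }

    // RTS backward pass
    mat xs(D, T);
    cube Vs(D, D, T), cross(D, D, T > 1 ? T - 1 : 0);
    xs.col(T - 1) = mf.col(T - 1);
    Vs.slice(T - 1) = Pf.slice(T - 1);
    for (uword t = T - 1; t >= 1; --t) {
        const uword k = (uword)(z(t) - 1);
        mat Ppred_inv;
        if (!inv_sympd(Ppred_inv, Pp.slice(t))) Ppred_inv = pinv(Pp.slice(t));
        mat G = Pf.slice(t - 1) * A.slice(k).t() * Ppred_inv;   // gain
        xs.col(t - 1) = mf.col(t - 1) + G * (xs.col(t) - mp.col(t));
        mat V = Pf.slice(t - 1) +
            G * (Vs.slice(t) - Pp.slice(t)) * G.t();
        Vs.slice(t - 1) = 0.5 * (V + V.t());
        cross.slice(t - 1) = Vs.slice(t) * G.t();  // Cov(x_t, x_{t-1})
        if (t == 1) break;
    }

    return Rcpp::List::create(
        Rcpp::Named("xs") = xs,
        Rcpp::Named("Vs") = Vs,
        Rcpp::Named("cross") = cross,
        Rcpp::Named("loglik") = ll);
}
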