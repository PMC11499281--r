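#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Euler integration of the excitatory LIF network with synaptic filtering and
// (optionally) a single graded feedback-inhibition unit:
//
//   tau_m dx_i/dt = -x_i + g (sum_j W_ij p_j - g_inh I_inh) + w_i s(t)
//   tau_s dp_i/dt = -p_i + r_i
//   tau_I dI/dt   = -I + mean_i r_i
//
// Per-step additive Gaussian membrane noise of scale `noiseScale` (drawn from
// the R RNG, so set.seed() gives bit-identical rasters). When x_i crosses the
// threshold, x_i is reset to 0 and r_i is a one-timestep unit impulse.
//
// Spike times are returned as (neuron, step) pairs, capped at `maxSpikes`
// stored events (runaway networks spike at every step; the binned counts are
// always complete). Binned per-neuron spike counts use bins of `binSteps`
// timesteps.
// [[Rcpp::export(name = ".lif_simulate")]]
Rcpp::List lif_simulate(const arma::sp_mat& W, double g, double gInh,
                        double tauM, double tauS, double tauI, double theta,
                        double dt, const arma::vec& s, const arma::vec& w,
                        double noiseScale, int binSteps, int maxSpikes) {
    const uword N = W.n_rows;
    const uword steps = s.n_elem;
    const uword nbins = (steps + binSteps - 1) / binSteps;

    vec x(N, fill::zeros), p(N, fill::zeros), r(N, fill::zeros);
    double Iinh = 0.0;

    mat binned(N, nbins, fill::zeros);
    vec popRate(steps, fill::zeros), IinhTrace(steps, fill::zeros);
    std::vector<int> sp_i, sp_t;
    sp_i.reserve(4096);
    bool truncated = false;

    const double am = dt / tauM, as = dt / tauS, ai = dt / tauI;

    for (uword t = 0; t < steps; ++t) {
        vec rec = W * p;
        if (noiseScale > 0.0) {
            // noise enters the membrane equation like an input current
            Rcpp::NumericVector eta = Rcpp::rnorm(N);
            x += am * (-x + g * (rec - gInh * Iinh) + w * s(t) +
                       noiseScale * vec(eta.begin(), N, false));
        } else {
            x += am * (-x + g * (rec - gInh * Iinh) + w * s(t));
        }
        if (!x.is_finite())
            Rcpp::stop("membrane potential became non-finite at step %d", (int)t);

        r.zeros();
        uvec sp = find(x > theta);
        if (sp.n_elem > 0) {
            x.elem(sp).zeros();
            r.elem(sp).ones();
            const uword bin = t / binSteps;
            for (uword ii = 0; ii < sp.n_elem; ++ii) {
                binned(sp(ii), bin) += 1.0;
                if ((int)sp_i.size() < maxSpikes) {
                    sp_i.push_back((int)sp(ii) + 1);
                    sp_t.push_back((int)t + 1);
                } else truncated = true;
            }
        }
        popRate(t) = (double)sp.n_elem / (double)N;

        p += as * (-p + r);
        Iinh += ai * (-Iinh + mean(r));
        IinhTrace(t) = Iinh;
    }

    Rcpp::IntegerMatrix spikes(sp_i.size(), 2);
    for (size_t i = 0; i < sp_i.size(); ++i) {
        spikes(i, 0) = sp_i[i];
        spikes(i, 1) = sp_t[i];
    }

    return Rcpp::List::create(
        Rcpp::Named("spikes") = spikes,
        Rcpp::Named("binned") = binned,
        Rcpp::Named("popRate") = popRate,
        Rcpp::Named("Iinh") = IinhTrace,
        Rcpp::Named("truncated") = truncated);
}
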