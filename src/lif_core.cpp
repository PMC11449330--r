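#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler stepping of the three-population LIF network.
//
// Populations are ordered WA (0), SA (1), WP (2); neurons are laid out in
// contiguous per-population blocks. `signed_s(src, tgt)` is the synaptic
// strength with the wiring sign already applied by the caller (inhibitory
// entries negative, the absent WP->SA entry zero).
//
// Conventions the R oracle in the test suite replicates exactly:
//  * spike counts recorded at step t drive the update to step t+1
//    (one-step synaptic delay, no same-step recurrence);
//  * the population-level synaptic term s_XY * Sigma_X / N_X is applied
//    uniformly to every target neuron, exactly as the mean-field update
//    is written — a neuron's own previous spike is part of Sigma;
//  * one Poisson(1) draw per neuron per step, taken from R's RNG in
//    population-major, neuron-minor order before any voltage update,
//    so runs are bit-reproducible given set.seed();
//  * threshold crossing resets the voltage to the resting potential in
//    the same step; voltages below rest are never clamped.
// [[Rcpp::export(name = ".lif_simulate_cpp")]]
List lif_simulate_cpp(int n_steps, IntegerVector sizes,
                      NumericVector capacitance, NumericVector tau,
                      NumericVector noise_scale, NumericMatrix signed_s,
                      double rmp, double threshold, double dt,
                      bool store_spikes, bool record_voltages) {
    const int npop = 3;
    if (sizes.size() != npop || capacitance.size() != npop ||
        tau.size() != npop || noise_scale.size() != npop ||
        signed_s.nrow() != npop || signed_s.ncol() != npop)
        stop("expected three populations");
    if (n_steps < 1 || dt <= 0.0)
        stop("n_steps must be >= 1 and dt > 0");

    int ntot = 0;
    int offset[3];
    for (int p = 0; p < npop; ++p) {
        if (sizes[p] < 1) stop("population sizes must be >= 1");
        offset[p] = ntot;
        ntot += sizes[p];
    }

    std::vector<double> v(ntot, rmp);
    std::vector<double> noise(ntot, 0.0);
    double sigma_prev[3] = {0.0, 0.0, 0.0};

    IntegerMatrix counts(n_steps, npop);
    NumericMatrix vtrace = record_voltages ? NumericMatrix(n_steps, npop)
                                           : NumericMatrix(0, 0);
    std::vector<int> ev_step, ev_pop, ev_neuron;
    if (store_spikes) {
        ev_step.reserve(4096);
        ev_pop.reserve(4096);
        ev_neuron.reserve(4096);
    }

    RNGScope scope;
    for (int t = 0; t < n_steps; ++t) {
        // all noise draws first, in the documented fixed order
        for (int p = 0; p < npop; ++p) {
            const double ps = noise_scale[p];
            for (int i = 0; i < sizes[p]; ++i) {
                double x = R::rpois(1.0);
                noise[offset[p] + i] = ps * x;
            }
        }

        // population-level synaptic input per target, from step t-1 counts
        double base[3];
        for (int tgt = 0; tgt < npop; ++tgt) {
            double s = 0.0;
            for (int src = 0; src < npop; ++src)
                s += signed_s(src, tgt) * sigma_prev[src] / sizes[src];
            base[tgt] = s;
        }

        for (int p = 0; p < npop; ++p) {
            const double leak_k = -capacitance[p] / tau[p];
            int nsp = 0;
            for (int i = 0; i < sizes[p]; ++i) {
                const int j = offset[p] + i;
                const double cur = leak_k * (v[j] - rmp) + base[p] + noise[j];
                const double cand = v[j] + dt * cur;
                if (cand >= threshold) {
                    v[j] = rmp;
                    ++nsp;
                    if (store_spikes) {
                        ev_step.push_back(t + 1);
                        ev_pop.push_back(p + 1);
                        ev_neuron.push_back(i + 1);
                    }
                } else {
                    v[j] = cand;
                }
            }
            counts(t, p) = nsp;
            if (record_voltages) vtrace(t, p) = v[offset[p]];
        }

        for (int p = 0; p < npop; ++p) sigma_prev[p] = counts(t, p);
    }

    List out = List::create(_["counts"] = counts);
    if (store_spikes)
        out["events"] = List::create(_["step"] = wrap(ev_step),
                                     _["pop"] = wrap(ev_pop),
                                     _["neuron"] = wrap(ev_neuron));
    if (record_voltages) out["voltages"] = vtrace;
    return out;
}
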