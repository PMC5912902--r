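// Wiener first-passage-time density, forward DDM simulator, closed-loop
// trigger state machine, and the single-site adaptive-Metropolis sweep
// engine for the hierarchical regression models.  All randomness goes
// through R's RNG so set.seed() controls every stream.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Density of the standardized Wiener process (a = 1, v = 0) absorbing at the
// lower boundary, evaluated at normalized time tt = (t - t0) / a^2 for
// relative start point w.  Adaptive choice between the small-time and
// large-time series expansions; the term counts are chosen so the truncation
// error is below eps (Navarro-Fuss-style bounds).
static double fpt_std_lower(const double tt, const double w, const double eps)
{
    if (tt <= 0.0) return 0.0;

    // required number of terms for each expansion
    double ks;
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    double kl;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }

    double f = 0.0;
    if (ks < kl) {                      // small-time expansion
        const int K = (int) std::ceil(ks);
        const int lo = -((K - 1) / 2);
        const int hi = ((K - 1) / 2) + ((K - 1) % 2);
        for (int k = lo; k <= hi; ++k) {
            const double z = w + 2.0 * k;
            f += z * std::exp(-z * z / (2.0 * tt));
        }
        f /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                            // large-time expansion
        const int K = (int) std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            f += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        f *= M_PI;
    }
    return f > 0.0 ? f : 0.0;
}

// full density for one trial; upper = 1 means absorption at the upper bound
static double wfpt_pdf(const double rt, const int upper, const double a,
                       const double v, const double t0, const double w,
                       const double eps)
{
    if (!R_finite(rt) || a <= 0.0 || t0 < 0.0 || w <= 0.0 || w >= 1.0)
        return NA_REAL;
    const double t = rt - t0;
    if (t <= 0.0) return 0.0;
    const double vv = upper ? -v : v;
    const double ww = upper ? 1.0 - w : w;
    const double tt = t / (a * a);
    const double f = fpt_std_lower(tt, ww, eps);
    return (f / (a * a)) * std::exp(-vv * a * ww - vv * vv * t / 2.0);
}

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector rt, IntegerVector upper,
                           NumericVector a, NumericVector v,
                           NumericVector t0, double w, double eps)
{
    const int n = rt.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = wfpt_pdf(rt[i], upper[i], a[i], v[i], t0[i], w, eps);
    return out;
}

// summed log density over a block of trials; -Inf if any trial has zero or
// invalid density (used as the likelihood inside the sampler)
static double loglik_block(const int from, const int to,
                           const NumericVector& rt, const IntegerVector& upper,
                           const double* a, const double* v, const double* t0,
                           const double eps)
{
    double ll = 0.0;
    for (int i = from; i < to; ++i) {
        const double f = wfpt_pdf(rt[i], upper[i], a[i], v[i], t0[i], 0.5, eps);
        if (!R_finite(f) || f <= 0.0) return R_NegInf;
        ll += std::log(f);
    }
    return ll;
}

// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector upper,
                      NumericVector a, NumericVector v, NumericVector t0,
                      double eps)
{
    return loglik_block(0, rt.size(), rt, upper,
                        REAL(a), REAL(v), REAL(t0), eps);
}

// ---------------------------------------------------------------------------
// Forward Euler-Maruyama simulation of the DDM with diffusion scale s = 1.
// Returns decision times (excluding t0) and boundary indicators.
// [[Rcpp::export]]
List ddm_simulate_cpp(NumericVector a, NumericVector v, NumericVector t0,
                      double w, double dt, double t_max)
{
    const int n = a.size();
    NumericVector rt(n);
    IntegerVector upper(n);
    const double sq = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double x = w * a[i];
        double t = 0.0;
        int hit = NA_INTEGER;
        while (t < t_max) {
            x += v[i] * dt + sq * norm_rand();
            t += dt;
            if (x >= a[i]) { hit = 1; break; }
            if (x <= 0.0)  { hit = 0; break; }
        }
        rt[i] = (hit == NA_INTEGER) ? NA_REAL : t0[i] + t;
        upper[i] = hit;
    }
    return List::create(_["rt"] = rt, _["upper"] = upper);
}

// ---------------------------------------------------------------------------
// Closed-loop trigger state machine.  Trigger turns ON when the envelope is
// at or above threshold outside the lockout period, OFF as soon as it falls
// below.  Voltage ramps linearly towards the trigger state over ramp_ms; the
// lockout timer starts at the trigger-off signal and blocks re-triggering.
// [[Rcpp::export]]
List adbs_trigger_cpp(NumericVector env, double fs, double threshold,
                      double ramp_ms, double lockout_ms)
{
    const int n = env.size();
    IntegerVector trig(n);
    NumericVector volt(n);
    const double ramp_samples = std::max(1.0, ramp_ms * fs / 1000.0);
    const double step = 1.0 / ramp_samples;
    const int lockout_samples = (int) std::round(lockout_ms * fs / 1000.0);

    int state = 0;
    double vf = 0.0;
    int lockout_until = -1;         // first sample index allowed to trigger

    for (int i = 0; i < n; ++i) {
        if (state == 1) {
            if (env[i] < threshold) {           // trigger-off signal
                state = 0;
                lockout_until = i + lockout_samples;
            }
        } else {
            if (env[i] >= threshold && i >= lockout_until)
                state = 1;
        }
        // ON: record then ramp up, so full voltage is reached only after a
        // complete ramp (the first ramp_ms of every episode stay below 1);
        // OFF: ramp down then record, so voltage drops at the off sample
        if (state) {
            volt[i] = vf;
            vf += step;
            if (vf > 1.0) vf = 1.0;
        } else {
            vf -= step;
            if (vf < 0.0) vf = 0.0;
            volt[i] = vf;
        }
        trig[i] = state;
    }
    return List::create(_["trigger"] = trig, _["voltage"] = volt);
}

// ---------------------------------------------------------------------------
// Single-site adaptive random-walk Metropolis for the hierarchical DDM
// regression model.  Parameter vector layout:
//   [0] mu_a  [1] mu_v  [2] mu_t  [3] log sig_a  [4] log sig_v  [5] log sig_t
//   [6 .. 6+S)        subject a_s
//   [6+S .. 6+2S)     subject v_s
//   [6+2S .. 6+3S)    subject t_s
//   then pa coefficients on a, pv on v, pt on t.
// Trials must be sorted by subject; subj_start has S+1 entries (0-based,
// half-open block boundaries).  Group-level coefficients enter every
// subject's trials; hyperparameters touch only the subject-level priors.

struct HPrior {
    double mu_a_mean, mu_a_sd, mu_v_mean, mu_v_sd, mu_t_mean, mu_t_sd;
    double sig_a_scale, sig_v_scale, sig_t_scale, beta_sd;
};

static inline double dnorm_log(double x, double m, double s)
{
    const double z = (x - m) / s;
    return -0.5 * z * z - std::log(s) - 0.5 * std::log(2.0 * M_PI);
}

class DDMModel {
public:
    const NumericVector rt;
    const IntegerVector upper;
    const IntegerVector subj_start;   // length S+1
    const NumericMatrix Xa, Xv, Xt;
    const int S, n, pa, pv, pt, npar;
    const double eps;
    HPrior pr;
    std::vector<double> a_k, v_k, t_k;   // per-trial parameter values

    DDMModel(NumericVector rt_, IntegerVector upper_, IntegerVector ss_,
             NumericMatrix Xa_, NumericMatrix Xv_, NumericMatrix Xt_,
             List prior, double eps_)
        : rt(rt_), upper(upper_), subj_start(ss_), Xa(Xa_), Xv(Xv_), Xt(Xt_),
          S(ss_.size() - 1), n(rt_.size()),
          pa(Xa_.ncol()), pv(Xv_.ncol()), pt(Xt_.ncol()),
          npar(6 + 3 * (ss_.size() - 1) + Xa_.ncol() + Xv_.ncol() + Xt_.ncol()),
          eps(eps_)
    {
        pr.mu_a_mean = prior["mu_a_mean"]; pr.mu_a_sd = prior["mu_a_sd"];
        pr.mu_v_mean = prior["mu_v_mean"]; pr.mu_v_sd = prior["mu_v_sd"];
        pr.mu_t_mean = prior["mu_t_mean"]; pr.mu_t_sd = prior["mu_t_sd"];
        pr.sig_a_scale = prior["sig_a_scale"];
        pr.sig_v_scale = prior["sig_v_scale"];
        pr.sig_t_scale = prior["sig_t_scale"];
        pr.beta_sd = prior["beta_sd"];
        a_k.resize(n); v_k.resize(n); t_k.resize(n);
    }

    // refresh per-trial parameters for trials in [from, to)
    void refresh(const std::vector<double>& th, int from, int to) {
        for (int s = 0; s < S; ++s) {
            const int lo = std::max(from, (int) subj_start[s]);
            const int hi = std::min(to, (int) subj_start[s + 1]);
            if (lo >= hi) continue;
            const double as = th[6 + s], vs = th[6 + S + s], ts = th[6 + 2 * S + s];
            for (int i = lo; i < hi; ++i) {
                double a = as, v = vs, t = ts;
                for (int j = 0; j < pa; ++j) a += Xa(i, j) * th[6 + 3 * S + j];
                for (int j = 0; j < pv; ++j) v += Xv(i, j) * th[6 + 3 * S + pa + j];
                for (int j = 0; j < pt; ++j) t += Xt(i, j) * th[6 + 3 * S + pa + pv + j];
                a_k[i] = a; v_k[i] = v; t_k[i] = t;
            }
        }
    }

    double block_ll(int s) const {
        const int from = subj_start[s], to = subj_start[s + 1];
        double ll = 0.0;
        for (int i = from; i < to; ++i) {
            if (a_k[i] <= 0.0 || t_k[i] < 0.0) return R_NegInf;
            const double f = wfpt_pdf(rt[i], upper[i], a_k[i], v_k[i], t_k[i],
                                      0.5, eps);
            if (!R_finite(f) || f <= 0.0) return R_NegInf;
            ll += std::log(f);
        }
        return ll;
    }

    // log prior of hyperparameters plus subject-level prior terms
    double hyper_lp(const std::vector<double>& th) const {
        const double mu_a = th[0], mu_v = th[1], mu_t = th[2];
        const double sig_a = std::exp(th[3]), sig_v = std::exp(th[4]),
                     sig_t = std::exp(th[5]);
        if (mu_a <= 0.0 || mu_t < 0.0) return R_NegInf;
        double lp = dnorm_log(mu_a, pr.mu_a_mean, pr.mu_a_sd) +
                    dnorm_log(mu_v, pr.mu_v_mean, pr.mu_v_sd) +
                    dnorm_log(mu_t, pr.mu_t_mean, pr.mu_t_sd);
        // half-normal on sigma with log-scale Jacobian
        lp += dnorm_log(sig_a, 0.0, pr.sig_a_scale) + th[3];
        lp += dnorm_log(sig_v, 0.0, pr.sig_v_scale) + th[4];
        lp += dnorm_log(sig_t, 0.0, pr.sig_t_scale) + th[5];
        for (int s = 0; s < S; ++s) {
            lp += dnorm_log(th[6 + s], mu_a, sig_a);
            lp += dnorm_log(th[6 + S + s], mu_v, sig_v);
            lp += dnorm_log(th[6 + 2 * S + s], mu_t, sig_t);
        }
        return lp;
    }

    double beta_lp(const std::vector<double>& th) const {
        double lp = 0.0;
        for (int j = 0; j < pa + pv + pt; ++j)
            lp += dnorm_log(th[6 + 3 * S + j], 0.0, pr.beta_sd);
        return lp;
    }
};

// [[Rcpp::export]]
List ddm_mcmc_cpp(NumericVector rt, IntegerVector upper, IntegerVector subj_start,
                  NumericMatrix Xa, NumericMatrix Xv, NumericMatrix Xt,
                  List prior, NumericVector init, NumericVector scale0,
                  int n_iter, int n_burn, int thin, double eps)
{
    DDMModel m(rt, upper, subj_start, Xa, Xv, Xt, prior, eps);
    const int P = m.npar, S = m.S;
    if (init.size() != P) stop("init has wrong length");

    std::vector<double> th(init.begin(), init.end());
    m.refresh(th, 0, m.n);

    std::vector<double> bll(S);            // cached block log-likelihoods
    for (int s = 0; s < S; ++s) bll[s] = m.block_ll(s);
    double hyper = m.hyper_lp(th);
    double betalp = m.beta_lp(th);
    if (!R_finite(hyper))
        stop("non-finite prior density at initialization");
    for (int s = 0; s < S; ++s)
        if (!R_finite(bll[s]))
            stop("non-finite likelihood at initialization");

    std::vector<double> lsc(P);            // log proposal scales
    for (int p = 0; p < P; ++p) lsc[p] = std::log(scale0[p]);
    std::vector<int> acc(P, 0), tries(P, 0);
    int batch = 0, batch_n = 0;

    const int n_keep = (n_iter - n_burn) / thin;
    NumericMatrix draws(n_keep, P);
    NumericVector deviance(n_keep);
    int keep = 0;

    std::vector<double> save_a, save_v, save_t;

    for (int it = 0; it < n_iter; ++it) {
        // --- hyperparameters: prior-only updates -------------------------
        for (int p = 0; p < 6; ++p) {
            const double old = th[p];
            th[p] = old + std::exp(lsc[p]) * norm_rand();
            const double cand = m.hyper_lp(th);
            ++tries[p];
            if (R_finite(cand) && std::log(unif_rand()) < cand - hyper) {
                hyper = cand; ++acc[p];
            } else th[p] = old;
        }
        // --- subject-level parameters ------------------------------------
        for (int s = 0; s < S; ++s) {
            const int from = subj_start[s], to = subj_start[s + 1];
            for (int which = 0; which < 3; ++which) {
                const int p = 6 + which * S + s;
                const double old = th[p];
                th[p] = old + std::exp(lsc[p]) * norm_rand();
                // stash per-trial params for rollback
                save_a.assign(m.a_k.begin() + from, m.a_k.begin() + to);
                save_v.assign(m.v_k.begin() + from, m.v_k.begin() + to);
                save_t.assign(m.t_k.begin() + from, m.t_k.begin() + to);
                m.refresh(th, from, to);
                const double cand_ll = m.block_ll(s);
                const double cand_hyper = m.hyper_lp(th);
                ++tries[p];
                const double num = cand_ll + cand_hyper;
                const double den = bll[s] + hyper;
                if (R_finite(num) && std::log(unif_rand()) < num - den) {
                    bll[s] = cand_ll; hyper = cand_hyper; ++acc[p];
                } else {
                    th[p] = old;
                    std::copy(save_a.begin(), save_a.end(), m.a_k.begin() + from);
                    std::copy(save_v.begin(), save_v.end(), m.v_k.begin() + from);
                    std::copy(save_t.begin(), save_t.end(), m.t_k.begin() + from);
                }
            }
        }
        // --- group-level regression coefficients -------------------------
        for (int j = 0; j < m.pa + m.pv + m.pt; ++j) {
            const int p = 6 + 3 * S + j;
            const double old = th[p];
            th[p] = old + std::exp(lsc[p]) * norm_rand();
            save_a = m.a_k; save_v = m.v_k; save_t = m.t_k;
            m.refresh(th, 0, m.n);
            double cand_total = 0.0;
            std::vector<double> cand_bll(S);
            for (int s = 0; s < S; ++s) {
                cand_bll[s] = m.block_ll(s);
                cand_total += cand_bll[s];
                if (!R_finite(cand_total)) break;
            }
            const double cand_betalp = m.beta_lp(th);
            double cur_total = 0.0;
            for (int s = 0; s < S; ++s) cur_total += bll[s];
            ++tries[p];
            if (R_finite(cand_total) &&
                std::log(unif_rand()) <
                    (cand_total + cand_betalp) - (cur_total + betalp)) {
                bll = cand_bll; betalp = cand_betalp; ++acc[p];
            } else {
                th[p] = old;
                m.a_k = save_a; m.v_k = save_v; m.t_k = save_t;
            }
        }

        // --- scale adaptation (burn-in only), 0.44 target -----------------
        if (++batch_n == 50) {
            ++batch;
            const double delta = std::min(0.1, 1.0 / std::sqrt((double) batch));
            if (it < n_burn) {
                for (int p = 0; p < P; ++p) {
                    const double rate = tries[p] ? (double) acc[p] / tries[p] : 0.0;
                    lsc[p] += (rate > 0.44) ? delta : -delta;
                }
            }
            std::fill(acc.begin(), acc.end(), 0);
            std::fill(tries.begin(), tries.end(), 0);
            batch_n = 0;
        }

        if (it >= n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
            for (int p = 0; p < P; ++p) draws(keep, p) = th[p];
            double tot = 0.0;
            for (int s = 0; s < S; ++s) tot += bll[s];
            deviance[keep] = -2.0 * tot;
            ++keep;
        }
        if (it % 256 == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["draws"] = draws, _["deviance"] = deviance);
}
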