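#include <Rcpp.h>
using namespace Rcpp;

// Single-chain MCMC for the zero-inflated Poisson / ICAR model
//
//   Y_i ~ Poisson(group_i * mu_i),  log mu_i = log E_i + alpha + S_i
//   S   ~ ICAR(tau) identified by sum-to-zero recentring each sweep
//   group_i = occupied_i (deterministic 0/1 mask, not sampled)
//
// Updates: adaptive single-site random-walk Metropolis for each S_i and for
// alpha (target acceptance 0.44, adaptation frozen after burn-in); tau by
// conjugate Gibbs under a Gamma(a, b) precision prior, or sigma = 1/sqrt(tau)
// by log-scale random-walk Metropolis under a bounded-uniform SD prior.
// Uses R's RNG, so draws are reproducible under set.seed().

static inline double pair_ss(const NumericVector& S, const IntegerVector& idx,
                             const IntegerVector& ptr) {
  double ss = 0.0;
  int n = S.size();
  for (int i = 0; i < n; ++i) {
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
      int j = idx[k];
      if (j > i) {
        double d = S[i] - S[j];
        ss += d * d;
      }
    }
  }
  return ss;
}

// [[Rcpp::export(name = ".zip_icar_chain")]]
List zip_icar_chain(IntegerVector Y, NumericVector E, IntegerVector occ,
                    IntegerVector nbr_idx, IntegerVector nbr_ptr, int n_comp,
                    double alpha, NumericVector S_init, double sigma,
                    int burn_in, int iterations, int thin,
                    int prior_kind, double prior_a, double prior_b,
                    bool fix_alpha, bool fix_S, bool fix_sigma,
                    int adapt_interval) {
  int n = Y.size();
  NumericVector S = clone(S_init);
  double tau = 1.0 / (sigma * sigma);
  double rank = n - n_comp;  // ICAR pseudo-rank

  int n_store = iterations / thin;
  NumericVector out_alpha(n_store), out_sigma(n_store), out_lp(n_store);
  NumericMatrix out_S(n_store, n);

  NumericVector ls_S(n, std::log(0.5));   // per-pixel log proposal sd
  double ls_alpha = std::log(0.1), ls_sigma = std::log(0.3);
  NumericVector acc_S(n);
  double acc_alpha = 0.0, acc_sigma = 0.0;
  NumericVector batch_S(n);
  double batch_alpha = 0.0, batch_sigma = 0.0;
  int n_batch = 0;

  double Ytot = 0.0;
  for (int i = 0; i < n; ++i) if (occ[i]) Ytot += Y[i];

  // cached exp(S_i) and the running sum over occupied pixels of E_i exp(S_i)
  NumericVector eS(n);
  double sumEeS = 0.0;
  for (int i = 0; i < n; ++i) {
    eS[i] = std::exp(S[i]);
    if (occ[i]) sumEeS += E[i] * eS[i];
  }

  int total = burn_in + iterations;
  int stored = 0;
  long alpha_tries = 0, sigma_tries = 0;
  NumericVector S_tries(n);

  for (int it = 0; it < total; ++it) {
    bool adapting = (it < burn_in);

    // refresh the exp caches periodically to cancel multiplicative drift
    if (it % 1000 == 0) {
      sumEeS = 0.0;
      for (int i = 0; i < n; ++i) {
        eS[i] = std::exp(S[i]);
        if (occ[i]) sumEeS += E[i] * eS[i];
      }
    }

    // --- spatial field ---
    if (!fix_S) {
      double ea = std::exp(alpha);
      for (int i = 0; i < n; ++i) {
        double sd = std::exp(ls_S[i]);
        double prop = S[i] + norm_rand() * sd;
        double eprop = std::exp(prop);
        double dlog = 0.0;
        if (occ[i]) {
          dlog += Y[i] * (prop - S[i]) - E[i] * ea * (eprop - eS[i]);
        }
        double dprior = 0.0;
        for (int k = nbr_ptr[i]; k < nbr_ptr[i + 1]; ++k) {
          double sj = S[nbr_idx[k]];
          dprior += (prop - sj) * (prop - sj) - (S[i] - sj) * (S[i] - sj);
        }
        dlog -= 0.5 * tau * dprior;
        S_tries[i] += 1;
        if (std::log(unif_rand()) < dlog) {
          if (occ[i]) sumEeS += E[i] * (eprop - eS[i]);
          S[i] = prop;
          eS[i] = eprop;
          acc_S[i] += 1;
          if (adapting) batch_S[i] += 1;
        }
      }
    }

    // --- intercept ---
    if (!fix_alpha) {
      double sd = std::exp(ls_alpha);
      double prop = alpha + norm_rand() * sd;
      double dlog = Ytot * (prop - alpha) -
        sumEeS * (std::exp(prop) - std::exp(alpha));
      alpha_tries++;
      if (std::log(unif_rand()) < dlog) {
        alpha = prop;
        acc_alpha += 1;
        if (adapting) batch_alpha += 1;
      }
    }

    // --- precision / SD ---
    if (!fix_sigma) {
      double ss = pair_ss(S, nbr_idx, nbr_ptr);
      if (prior_kind == 0) {
        // Gamma(a, b) prior on tau: conjugate Gibbs
        tau = R::rgamma(prior_a + 0.5 * rank, 1.0 / (prior_b + 0.5 * ss));
        sigma = 1.0 / std::sqrt(tau);
      } else {
        // Uniform(lo, hi) prior on sigma: random walk on log sigma.
        // target in theta = log sigma: -rank*theta - ss/(2 e^{2 theta}) + theta
        double theta = std::log(sigma);
        double prop = theta + norm_rand() * std::exp(ls_sigma);
        double sp = std::exp(prop);
        sigma_tries++;
        if (sp > prior_a && sp < prior_b) {
          double dlog = (-rank * prop - 0.5 * ss / (sp * sp) + prop) -
            (-rank * theta - 0.5 * ss / (sigma * sigma) + theta);
          if (std::log(unif_rand()) < dlog) {
            sigma = sp;
            acc_sigma += 1;
            if (adapting) batch_sigma += 1;
          }
        }
        tau = 1.0 / (sigma * sigma);
      }
    }

    // --- recentre (sum-to-zero identification) ---
    if (!fix_S) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += S[i];
      m /= n;
      double em = std::exp(-m);
      sumEeS = 0.0;
      for (int i = 0; i < n; ++i) {
        S[i] -= m;
        eS[i] *= em;
        if (occ[i]) sumEeS += E[i] * eS[i];
      }
      if (!fix_alpha) alpha += m;
    }

    // --- proposal adaptation during burn-in ---
    if (adapting && adapt_interval > 0 && (it + 1) % adapt_interval == 0) {
      n_batch++;
      double step = std::min(0.25, 1.0 / std::sqrt((double) n_batch));
      if (!fix_S) {
        for (int i = 0; i < n; ++i) {
          double rate = batch_S[i] / adapt_interval;
          ls_S[i] += (rate > 0.44 ? step : -step);
          if (ls_S[i] < -8) ls_S[i] = -8;
          if (ls_S[i] > 4) ls_S[i] = 4;
          batch_S[i] = 0;
        }
      }
      if (!fix_alpha) {
        double rate = batch_alpha / adapt_interval;
        ls_alpha += (rate > 0.44 ? step : -step);
        batch_alpha = 0;
      }
      if (!fix_sigma && prior_kind == 1) {
        double rate = batch_sigma / adapt_interval;
        ls_sigma += (rate > 0.44 ? step : -step);
        batch_sigma = 0;
      }
    }

    // --- store thinned draw after burn-in ---
    if (it >= burn_in && (it - burn_in + 1) % thin == 0) {
      double lp = 0.0;
      for (int i = 0; i < n; ++i) {
        if (occ[i]) {
          double mu = E[i] * std::exp(alpha + S[i]);
          lp += R::dpois(Y[i], mu, 1);
        }
      }
      double ss = pair_ss(S, nbr_idx, nbr_ptr);
      lp += 0.5 * rank * std::log(tau) - 0.5 * tau * ss;
      if (prior_kind == 0)
        lp += R::dgamma(tau, prior_a, 1.0 / prior_b, 1);
      out_alpha[stored] = alpha;
      out_sigma[stored] = sigma;
      out_lp[stored] = lp;
      for (int i = 0; i < n; ++i) out_S(stored, i) = S[i];
      stored++;
    }
  }

  long swp = total;
  NumericVector acc_rate_S(n);
  for (int i = 0; i < n; ++i)
    acc_rate_S[i] = S_tries[i] > 0 ? acc_S[i] / S_tries[i] : NA_REAL;

  return List::create(
    _["alpha"] = out_alpha, _["sigma"] = out_sigma, _["S"] = out_S,
    _["log_post"] = out_lp,
    _["accept"] = List::create(
      _["S"] = acc_rate_S,
      _["alpha"] = alpha_tries > 0 ? acc_alpha / alpha_tries : NA_REAL,
      _["sigma"] = sigma_tries > 0 ? acc_sigma / sigma_tries : NA_REAL),
    _["scales"] = List::create(_["S"] = exp(ls_S),
                               _["alpha"] = std::exp(ls_alpha),
                               _["sigma"] = std::exp(ls_sigma)),
    _["sweeps"] = (double) swp);
}
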