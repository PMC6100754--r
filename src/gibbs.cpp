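// Metropolis-within-Gibbs sampler for the two-way hierarchical model
//   y_ij ~ N(theta_ij, c_ij^2)          (observed cells only)
//   theta_ij ~ N(alpha_i + gamma_j, sigma^2)
//   alpha ~ MVN(mu_alpha, Ralpha), gamma ~ MVN(mu_gamma, Rgamma)
//   sigma ~ N(sigma_mean, sigma_var) truncated at 0
// Conjugate draws for theta, alpha, gamma; random-walk Metropolis on
// log(sigma). Uses R's RNG throughout so set.seed() governs the chain.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec mvn_draw(const arma::mat& P, const arma::vec& b) {
  // sample from MVN with precision P and mean P^{-1} b
  arma::mat L = arma::chol(P, "lower");
  arma::vec mu = arma::solve(arma::trimatu(L.t()),
                             arma::solve(arma::trimatl(L), b));
  arma::vec z(b.n_elem);
  for (arma::uword k = 0; k < z.n_elem; ++k) z[k] = norm_rand();
  return mu + arma::solve(arma::trimatu(L.t()), z);
}

static double log_sigma_target(double sigma, double mu_s, double var_s,
                               double ss, int ncell) {
  // prior (truncated normal, constant dropped) x theta-level likelihood,
  // plus the log-sigma Jacobian
  return -(sigma - mu_s) * (sigma - mu_s) / (2.0 * var_s)
         - ncell * std::log(sigma) - ss / (2.0 * sigma * sigma)
         + std::log(sigma);
}

// [[Rcpp::export(name = ".gibbs_cpp")]]
List gibbs_cpp(const arma::mat& y, const arma::mat& csd,
               const arma::umat& obs,
               const arma::vec& mu_alpha, const arma::mat& Ralpha,
               const arma::vec& mu_gamma, const arma::mat& Rgamma,
               double sigma_mean, double sigma_var,
               int burn, int draws, int thin,
               double sigma_init, double step_init, double sigma_fix) {
  const int I = y.n_rows, J = y.n_cols, ncell = I * J;
  const bool sample_sigma = sigma_fix <= 0.0;

  arma::mat Ra_inv = arma::inv_sympd(Ralpha);
  arma::mat Rg_inv = arma::inv_sympd(Rgamma);
  arma::vec pa = Ra_inv * mu_alpha;
  arma::vec pg = Rg_inv * mu_gamma;

  // initialization: theta at the data (prior mean structure where missing)
  arma::vec alpha = mu_alpha, gamma = mu_gamma;
  arma::mat theta(I, J);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      theta(i, j) = obs(i, j) ? y(i, j) : alpha[i] + gamma[j];
  double sigma = sample_sigma ? sigma_init : sigma_fix;
  double step = step_init;

  const int nkeep = draws / thin;
  arma::mat theta_out(nkeep, ncell), alpha_out(nkeep, I), gamma_out(nkeep, J);
  arma::vec sigma_out(nkeep), dev_out(nkeep);
  long acc = 0, acc_win = 0, tries_win = 0;
  int kept = 0;

  for (int it = 0; it < burn + draws; ++it) {
    const double s2 = sigma * sigma;
    // theta
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < J; ++j) {
        double m = alpha[i] + gamma[j];
        if (obs(i, j)) {
          double c2 = csd(i, j) * csd(i, j);
          double prec = 1.0 / c2 + 1.0 / s2;
          double mean = (y(i, j) / c2 + m / s2) / prec;
          theta(i, j) = mean + norm_rand() / std::sqrt(prec);
        } else {
          theta(i, j) = m + sigma * norm_rand();
        }
      }
    }
    // alpha | theta, gamma
    {
      arma::mat P = Ra_inv;
      P.diag() += J / s2;
      arma::vec b = pa;
      for (int i = 0; i < I; ++i) {
        double r = 0.0;
        for (int j = 0; j < J; ++j) r += theta(i, j) - gamma[j];
        b[i] += r / s2;
      }
      alpha = mvn_draw(P, b);
    }
    // gamma | theta, alpha
    {
      arma::mat P = Rg_inv;
      P.diag() += I / s2;
      arma::vec b = pg;
      for (int j = 0; j < J; ++j) {
        double r = 0.0;
        for (int i = 0; i < I; ++i) r += theta(i, j) - alpha[i];
        b[j] += r / s2;
      }
      gamma = mvn_draw(P, b);
    }
    // sigma | theta, alpha, gamma (random walk on log sigma)
    if (sample_sigma) {
      double ss = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j) {
          double r = theta(i, j) - alpha[i] - gamma[j];
          ss += r * r;
        }
      double prop = sigma * std::exp(step * norm_rand());
      double la = log_sigma_target(prop, sigma_mean, sigma_var, ss, ncell)
                - log_sigma_target(sigma, sigma_mean, sigma_var, ss, ncell);
      ++tries_win;
      if (std::log(unif_rand()) < la) {
        sigma = prop;
        ++acc_win;
        if (it >= burn) ++acc;
      }
      // tune the proposal scale during burn-in only, then freeze
      if (it < burn && tries_win >= 100) {
        double rate = (double)acc_win / tries_win;
        if (rate > 0.45) step *= 1.2;
        else if (rate < 0.20) step *= 0.8;
        step = std::min(std::max(step, 1e-3), 5.0);
        acc_win = 0; tries_win = 0;
      }
    }
    // record
    if (it >= burn && (it - burn) % thin == thin - 1) {
      double dev = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
          if (obs(i, j)) {
            double c2 = csd(i, j) * csd(i, j);
            double r = y(i, j) - theta(i, j);
            dev += std::log(2.0 * M_PI * c2) + r * r / c2;
          }
      theta_out.row(kept) = arma::vectorise(theta).t();
      alpha_out.row(kept) = alpha.t();
      gamma_out.row(kept) = gamma.t();
      sigma_out[kept] = sigma;
      dev_out[kept] = dev;
      ++kept;
    }
  }

  double acc_rate = sample_sigma && draws > 0 ? (double)acc / draws : NA_REAL;
  return List::create(_["theta"] = theta_out, _["alpha"] = alpha_out,
                      _["gamma"] = gamma_out, _["sigma"] = sigma_out,
                      _["deviance"] = dev_out,
                      _["sigma_acc_rate"] = acc_rate,
                      _["sigma_step"] = step);
}
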