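// Location-scale mixed-model engine shared by the Von Mises (angular error)
// and Gaussian (perceived intensity) branches.
//
// Parameter vector layout (fixed throughout):
//   [ beta_loc (P1) | beta_scale (P2) | u_loc (J) | u_scale (J, optional) |
//     log_sigma_loc | log_sigma_scale (optional) ]
//
// Links: location mu = 2*atan(eta_loc) (Von Mises, radians) or identity
// (Gaussian); scale k = exp(eta_scale) (Von Mises concentration) or
// sd = exp(eta_scale) (Gaussian).  All RNG goes through R's generator so
// set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const int FAM_VONMISES = 0;
static const int FAM_GAUSSIAN = 1;

// log I0(k) via the exponentially-scaled Bessel function: stable for large k.
static inline double log_I0(double k) {
  return std::log(R::bessel_i(k, 0.0, 2.0)) + k;
}

static inline double ll_obs(int family, double y, double eta_loc, double eta_scale) {
  if (family == FAM_VONMISES) {
    double mu = 2.0 * std::atan(eta_loc);
    double k  = std::exp(eta_scale);
    return k * std::cos(y - mu) - M_LN_2PI - log_I0(k);
  }
  double sd = std::exp(eta_scale);
  return R::dnorm(y, eta_loc, sd, 1);
}

// [[Rcpp::export]]
double cpp_vm_logpdf_one(double theta, double mu, double k) {
  if (k < 0) stop("concentration k must be >= 0");
  return k * std::cos(theta - mu) - M_LN_2PI - log_I0(k);
}

struct ModelData {
  NumericVector y;
  int family;
  NumericMatrix Xloc, Xscale;
  IntegerVector pid;          // 0-based participant index, -1 = no grouping
  int J;
  bool re_scale;
  bool noncentered;           // u = sigma * z (MAP mode: interior optimum)
  int N, P1, P2;
  int npar;
  // prior means / sds for fixed effects; half-normal scales for RE sds
  NumericVector bloc_mean, bloc_sd, bscale_mean, bscale_sd;
  double re_sd_loc, re_sd_scale;
};

static ModelData unpack(List md) {
  ModelData d;
  d.y = md["y"];
  d.family = as<int>(md["family"]);
  d.Xloc = as<NumericMatrix>(md["Xloc"]);
  d.Xscale = as<NumericMatrix>(md["Xscale"]);
  d.pid = md["pid"];
  d.J = as<int>(md["J"]);
  d.re_scale = as<bool>(md["re_scale"]);
  d.noncentered = md.containsElementNamed("noncentered") ?
    as<bool>(md["noncentered"]) : false;
  d.N = d.y.size();
  d.P1 = d.Xloc.ncol();
  d.P2 = d.Xscale.ncol();
  d.npar = d.P1 + d.P2;
  if (d.J > 0) {
    d.npar += d.J + 1;                 // u_loc + log_sigma_loc
    if (d.re_scale) d.npar += d.J + 1; // u_scale + log_sigma_scale
  }
  d.bloc_mean = md["bloc_mean"];
  d.bloc_sd = md["bloc_sd"];
  d.bscale_mean = md["bscale_mean"];
  d.bscale_sd = md["bscale_sd"];
  d.re_sd_loc = as<double>(md["re_sd_loc"]);
  d.re_sd_scale = as<double>(md["re_sd_scale"]);
  return d;
}

// linear predictors for one parameter vector
static void linpred(const ModelData& d, const NumericVector& par,
                    std::vector<double>& eta_loc, std::vector<double>& eta_scale) {
  double f_loc = 1.0, f_scale = 1.0;
  if (d.J > 0 && d.noncentered) {
    int ls_loc = d.P1 + d.P2 + d.J + (d.re_scale ? d.J : 0);
    f_loc = std::exp(par[ls_loc]);
    if (d.re_scale) f_scale = std::exp(par[ls_loc + 1]);
  }
  for (int i = 0; i < d.N; ++i) {
    double el = 0.0, es = 0.0;
    for (int j = 0; j < d.P1; ++j) el += d.Xloc(i, j) * par[j];
    for (int j = 0; j < d.P2; ++j) es += d.Xscale(i, j) * par[d.P1 + j];
    if (d.J > 0) {
      int p = d.pid[i];
      el += f_loc * par[d.P1 + d.P2 + p];
      if (d.re_scale) es += f_scale * par[d.P1 + d.P2 + d.J + p];
    }
    eta_loc[i] = el;
    eta_scale[i] = es;
  }
}

// half-normal log density for sigma = exp(lsig) including the log-Jacobian
static inline double lp_halfnormal_lsig(double lsig, double scale) {
  double sigma = std::exp(lsig);
  return M_LN2 + R::dnorm(sigma, 0.0, scale, 1) + lsig;
}

static double log_prior(const ModelData& d, const NumericVector& par) {
  double lp = 0.0;
  for (int j = 0; j < d.P1; ++j)
    lp += R::dnorm(par[j], d.bloc_mean[j], d.bloc_sd[j], 1);
  for (int j = 0; j < d.P2; ++j)
    lp += R::dnorm(par[d.P1 + j], d.bscale_mean[j], d.bscale_sd[j], 1);
  if (d.J > 0) {
    int off = d.P1 + d.P2;
    int ls_loc_idx = off + d.J + (d.re_scale ? d.J : 0);
    // non-centred: the raw effects are standard normal, sigma only enters
    // the likelihood (through linpred) and its own hyperprior
    double sig_loc = d.noncentered ? 1.0 : std::exp(par[ls_loc_idx]);
    for (int j = 0; j < d.J; ++j)
      lp += R::dnorm(par[off + j], 0.0, sig_loc, 1);
    lp += lp_halfnormal_lsig(par[ls_loc_idx], d.re_sd_loc);
    if (d.re_scale) {
      double sig_scale = d.noncentered ? 1.0 : std::exp(par[ls_loc_idx + 1]);
      for (int j = 0; j < d.J; ++j)
        lp += R::dnorm(par[off + d.J + j], 0.0, sig_scale, 1);
      lp += lp_halfnormal_lsig(par[ls_loc_idx + 1], d.re_sd_scale);
    }
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector par, List model_data) {
  ModelData d = unpack(model_data);
  if ((int)par.size() != d.npar) stop("parameter vector has wrong length");
  std::vector<double> el(d.N), es(d.N);
  linpred(d, par, el, es);
  double ll = 0.0;
  for (int i = 0; i < d.N; ++i) ll += ll_obs(d.family, d.y[i], el[i], es[i]);
  double out = ll + log_prior(d, par);
  if (!std::isfinite(out)) return -1e300;
  return out;
}

// Analytic gradient of the log posterior (drives the MAP optimiser).
// [[Rcpp::export]]
NumericVector cpp_log_posterior_grad(NumericVector par, List model_data) {
  ModelData d = unpack(model_data);
  if ((int)par.size() != d.npar) stop("parameter vector has wrong length");
  std::vector<double> el(d.N), es(d.N);
  linpred(d, par, el, es);
  NumericVector g(d.npar);

  // per-observation gradients wrt the two linear predictors
  std::vector<double> gl(d.N), gs(d.N);
  for (int i = 0; i < d.N; ++i) {
    if (d.family == FAM_VONMISES) {
      double mu = 2.0 * std::atan(el[i]);
      double k = std::exp(es[i]);
      double a1 = R::bessel_i(k, 1.0, 2.0) / R::bessel_i(k, 0.0, 2.0);
      gl[i] = k * std::sin(d.y[i] - mu) * 2.0 / (1.0 + el[i] * el[i]);
      gs[i] = (std::cos(d.y[i] - mu) - a1) * k;
    } else {
      double sd = std::exp(es[i]);
      double z = (d.y[i] - el[i]) / sd;
      gl[i] = z / sd;
      gs[i] = z * z - 1.0;
    }
  }
  for (int j = 0; j < d.P1; ++j) {
    double s = 0.0;
    for (int i = 0; i < d.N; ++i) s += d.Xloc(i, j) * gl[i];
    g[j] = s - (par[j] - d.bloc_mean[j]) / (d.bloc_sd[j] * d.bloc_sd[j]);
  }
  for (int j = 0; j < d.P2; ++j) {
    double s = 0.0;
    for (int i = 0; i < d.N; ++i) s += d.Xscale(i, j) * gs[i];
    g[d.P1 + j] = s - (par[d.P1 + j] - d.bscale_mean[j]) /
      (d.bscale_sd[j] * d.bscale_sd[j]);
  }
  if (d.J > 0) {
    int off = d.P1 + d.P2;
    int ls_loc_idx = off + d.J + (d.re_scale ? d.J : 0);
    double sig_loc = std::exp(par[ls_loc_idx]);
    if (d.noncentered) {
      // z_j ~ N(0,1); sigma scales the likelihood route only
      double s_lik = 0.0;
      for (int i = 0; i < d.N; ++i) {
        g[off + d.pid[i]] += sig_loc * gl[i];
        s_lik += gl[i] * sig_loc * par[off + d.pid[i]];
      }
      for (int j = 0; j < d.J; ++j) g[off + j] -= par[off + j];
      g[ls_loc_idx] = s_lik
        - sig_loc * sig_loc / (d.re_sd_loc * d.re_sd_loc) + 1.0;
      if (d.re_scale) {
        int ls_s = ls_loc_idx + 1;
        double sig_s = std::exp(par[ls_s]);
        double s_lik2 = 0.0;
        for (int i = 0; i < d.N; ++i) {
          g[off + d.J + d.pid[i]] += sig_s * gs[i];
          s_lik2 += gs[i] * sig_s * par[off + d.J + d.pid[i]];
        }
        for (int j = 0; j < d.J; ++j) g[off + d.J + j] -= par[off + d.J + j];
        g[ls_s] = s_lik2
          - sig_s * sig_s / (d.re_sd_scale * d.re_sd_scale) + 1.0;
      }
    } else {
      double su2_loc = 0.0;
      for (int i = 0; i < d.N; ++i) g[off + d.pid[i]] += gl[i];
      for (int j = 0; j < d.J; ++j) {
        double u = par[off + j];
        g[off + j] -= u / (sig_loc * sig_loc);
        su2_loc += u * u;
      }
      g[ls_loc_idx] = -d.J + su2_loc / (sig_loc * sig_loc)
        - sig_loc * sig_loc / (d.re_sd_loc * d.re_sd_loc) + 1.0;
      if (d.re_scale) {
        int ls_scale_idx = ls_loc_idx + 1;
        double sig_s = std::exp(par[ls_scale_idx]);
        double su2_s = 0.0;
        for (int i = 0; i < d.N; ++i) g[off + d.J + d.pid[i]] += gs[i];
        for (int j = 0; j < d.J; ++j) {
          double u = par[off + d.J + j];
          g[off + d.J + j] -= u / (sig_s * sig_s);
          su2_s += u * u;
        }
        g[ls_scale_idx] = -d.J + su2_s / (sig_s * sig_s)
          - sig_s * sig_s / (d.re_sd_scale * d.re_sd_scale) + 1.0;
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_pointwise_loglik(NumericMatrix draws, List model_data) {
  ModelData d = unpack(model_data);
  int S = draws.nrow();
  if (draws.ncol() != d.npar) stop("draws matrix has wrong number of columns");
  NumericMatrix out(S, d.N);
  std::vector<double> el(d.N), es(d.N);
  for (int s = 0; s < S; ++s) {
    NumericVector par = draws(s, _);
    linpred(d, par, el, es);
    for (int i = 0; i < d.N; ++i) out(s, i) = ll_obs(d.family, d.y[i], el[i], es[i]);
  }
  return out;
}

// Adaptive Metropolis-within-Gibbs (Roberts & Rosenthal 2009): one
// coordinate at a time, per-coordinate log step sizes adapted in batches of
// 50 during warmup toward a 0.44 acceptance rate.  Linear predictors are
// updated incrementally so a coordinate move costs only the rows it touches.
// [[Rcpp::export]]
List cpp_amwg(List model_data, NumericVector init,
              int n_warmup, int n_save, int thin, bool want_loglik) {
  ModelData d = unpack(model_data);
  if (d.noncentered) stop("the MCMC sampler uses the centred parameterisation");
  if ((int)init.size() != d.npar) stop("init has wrong length");

  // rows touched by each participant
  std::vector< std::vector<int> > rows_of(d.J > 0 ? d.J : 0);
  if (d.J > 0)
    for (int i = 0; i < d.N; ++i) rows_of[d.pid[i]].push_back(i);
  // rows with a non-zero design entry per fixed-effect column
  std::vector< std::vector<int> > rows_loc(d.P1), rows_scale(d.P2);
  for (int j = 0; j < d.P1; ++j)
    for (int i = 0; i < d.N; ++i) if (d.Xloc(i, j) != 0.0) rows_loc[j].push_back(i);
  for (int j = 0; j < d.P2; ++j)
    for (int i = 0; i < d.N; ++i) if (d.Xscale(i, j) != 0.0) rows_scale[j].push_back(i);

  NumericVector par = clone(init);
  std::vector<double> el(d.N), es(d.N), ll(d.N);
  linpred(d, par, el, es);
  for (int i = 0; i < d.N; ++i) ll[i] = ll_obs(d.family, d.y[i], el[i], es[i]);

  int off = d.P1 + d.P2;
  int ls_loc_idx = d.J > 0 ? off + d.J + (d.re_scale ? d.J : 0) : -1;
  int ls_scale_idx = (d.J > 0 && d.re_scale) ? ls_loc_idx + 1 : -1;

  std::vector<double> lstep(d.npar, -1.0);   // log proposal sd
  std::vector<int> acc_batch(d.npar, 0);
  double lstep_blk[2] = {-1.0, -1.0};        // rescaling-move step sizes
  int acc_blk[2] = {0, 0};
  int batch_len = 50, batch_count = 0, in_batch = 0;

  int n_iter = n_warmup + n_save * thin;
  NumericMatrix draws(n_save, d.npar);
  NumericMatrix loglik(want_loglik ? n_save : 0, want_loglik ? d.N : 0);
  std::vector<double> acc_total(d.npar, 0.0);
  int post_warm_sweeps = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < d.npar; ++c) {
      double delta = R::norm_rand() * std::exp(lstep[c]);
      double cur = par[c], prop = cur + delta;
      double dlp = 0.0;
      bool is_beta_loc = c < d.P1;
      bool is_beta_scale = !is_beta_loc && c < off;
      bool is_u_loc = d.J > 0 && c >= off && c < off + d.J;
      bool is_u_scale = d.re_scale && d.J > 0 && c >= off + d.J && c < off + 2 * d.J;

      if (c == ls_loc_idx || c == ls_scale_idx) {
        // hyperparameter: prior terms only
        bool loc = (c == ls_loc_idx);
        double hscale = loc ? d.re_sd_loc : d.re_sd_scale;
        int ubase = loc ? off : off + d.J;
        double cur_sig = std::exp(cur), prop_sig = std::exp(prop);
        double dsum = 0.0;
        for (int j = 0; j < d.J; ++j) {
          double u = par[ubase + j];
          dsum += R::dnorm(u, 0.0, prop_sig, 1) - R::dnorm(u, 0.0, cur_sig, 1);
        }
        dlp = dsum + lp_halfnormal_lsig(prop, hscale) - lp_halfnormal_lsig(cur, hscale);
        if (std::log(R::unif_rand()) < dlp) { par[c] = prop; acc_batch[c]++; acc_total[c]++; }
        continue;
      }

      // prior increment
      if (is_beta_loc)
        dlp += R::dnorm(prop, d.bloc_mean[c], d.bloc_sd[c], 1)
             - R::dnorm(cur, d.bloc_mean[c], d.bloc_sd[c], 1);
      else if (is_beta_scale)
        dlp += R::dnorm(prop, d.bscale_mean[c - d.P1], d.bscale_sd[c - d.P1], 1)
             - R::dnorm(cur, d.bscale_mean[c - d.P1], d.bscale_sd[c - d.P1], 1);
      else {
        double sig = std::exp(par[is_u_loc ? ls_loc_idx : ls_scale_idx]);
        dlp += R::dnorm(prop, 0.0, sig, 1) - R::dnorm(cur, 0.0, sig, 1);
      }

      // likelihood increment over affected rows
      const std::vector<int>* rows;
      bool on_loc;
      if (is_beta_loc) { rows = &rows_loc[c]; on_loc = true; }
      else if (is_beta_scale) { rows = &rows_scale[c - d.P1]; on_loc = false; }
      else if (is_u_loc) { rows = &rows_of[c - off]; on_loc = true; }
      else { rows = &rows_of[c - off - d.J]; on_loc = false; }

      int nr = rows->size();
      std::vector<double> new_ll(nr), new_eta(nr);
      for (int r = 0; r < nr; ++r) {
        int i = (*rows)[r];
        double coef = 1.0;
        if (is_beta_loc) coef = d.Xloc(i, c);
        else if (is_beta_scale) coef = d.Xscale(i, c - d.P1);
        double ne = (on_loc ? el[i] : es[i]) + delta * coef;
        new_eta[r] = ne;
        new_ll[r] = on_loc ? ll_obs(d.family, d.y[i], ne, es[i])
                           : ll_obs(d.family, d.y[i], el[i], ne);
        dlp += new_ll[r] - ll[i];
      }
      if (std::isfinite(dlp) && std::log(R::unif_rand()) < dlp) {
        par[c] = prop;
        for (int r = 0; r < nr; ++r) {
          int i = (*rows)[r];
          if (on_loc) el[i] = new_eta[r]; else es[i] = new_eta[r];
          ll[i] = new_ll[r];
        }
        acc_batch[c]++; acc_total[c]++;
      }
    }

    // Interweaved non-centred rescaling move per random-effect block:
    // propose lsig' = lsig + delta and u' = u * exp(delta) jointly. The
    // random-effect prior and the transformation Jacobian cancel exactly,
    // leaving only the likelihood and the half-normal hyperprior — this
    // breaks the funnel-shaped dependence that stalls coordinate updates.
    if (d.J > 0) {
      for (int blk = 0; blk < (d.re_scale ? 2 : 1); ++blk) {
        bool loc = (blk == 0);
        int lsig_idx = loc ? ls_loc_idx : ls_scale_idx;
        int ubase = loc ? off : off + d.J;
        int sidx = d.npar + blk;  // adaptation slot for this move
        double delta = R::norm_rand() * std::exp(lstep_blk[blk]);
        double fac = std::exp(delta);
        double hscale = loc ? d.re_sd_loc : d.re_sd_scale;
        double dlp = lp_halfnormal_lsig(par[lsig_idx] + delta, hscale)
                   - lp_halfnormal_lsig(par[lsig_idx], hscale);
        std::vector<double> new_ll(d.N), new_eta(d.N);
        for (int i = 0; i < d.N; ++i) {
          double u = par[ubase + d.pid[i]];
          double ne = (loc ? el[i] : es[i]) + u * (fac - 1.0);
          new_eta[i] = ne;
          new_ll[i] = loc ? ll_obs(d.family, d.y[i], ne, es[i])
                          : ll_obs(d.family, d.y[i], el[i], ne);
          dlp += new_ll[i] - ll[i];
        }
        if (std::isfinite(dlp) && std::log(R::unif_rand()) < dlp) {
          par[lsig_idx] += delta;
          for (int j = 0; j < d.J; ++j) par[ubase + j] *= fac;
          for (int i = 0; i < d.N; ++i) {
            if (loc) el[i] = new_eta[i]; else es[i] = new_eta[i];
            ll[i] = new_ll[i];
          }
          acc_blk[blk]++;
        }
        (void)sidx;
      }
    }

    // step-size adaptation during warmup only (keeps the post-warmup chain Markov)
    if (it < n_warmup && ++in_batch == batch_len) {
      batch_count++;
      double adj = std::min(0.05, 1.0 / std::sqrt((double)batch_count));
      for (int c = 0; c < d.npar; ++c) {
        lstep[c] += (acc_batch[c] / (double)batch_len > 0.44) ? adj : -adj;
        acc_batch[c] = 0;
      }
      for (int b = 0; b < 2; ++b) {
        lstep_blk[b] += (acc_blk[b] / (double)batch_len > 0.44) ? adj : -adj;
        acc_blk[b] = 0;
      }
      in_batch = 0;
    }

    if (it >= n_warmup) {
      post_warm_sweeps++;
      int k = it - n_warmup;
      if ((k + 1) % thin == 0) {
        int s = (k + 1) / thin - 1;
        for (int c = 0; c < d.npar; ++c) draws(s, c) = par[c];
        if (want_loglik) for (int i = 0; i < d.N; ++i) loglik(s, i) = ll[i];
      }
    }
  }

  NumericVector acc_rate(d.npar);
  for (int c = 0; c < d.npar; ++c) acc_rate[c] = acc_total[c] / n_iter;

  return List::create(_["draws"] = draws,
                      _["loglik"] = loglik,
                      _["accept_rate"] = acc_rate,
                      _["lstep"] = NumericVector(lstep.begin(), lstep.end()));
}
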