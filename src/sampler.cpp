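// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// four-parameter logistic VAS model with log-quadratic trial variance.
//
// Parameterization (non-centered random intercepts):
//   population: L0, U0, c0, s0, w0, w1, w2
//   subject intercepts: u_m[j] = sd_m * z_m[j], m in {L, U, c, s, theta}
//   item intercepts:    v_m[k] = isd_m * w_m[k], m in {L, U, c, s}
//   mu_n  = 4PL(x_n; L0+uL+vL, U0+uU+vU, c0+uc+vc, s0+us+vs)
//   lv_n  = w0 + u_theta + w1*d_n + w2*d_n^2,  d_n = x_n - mid
//   y_n ~ Normal(mu_n, exp(lv_n))
//
// Besides single-site adaptive random-walk updates, two families of
// likelihood-invariant moves keep the hierarchical geometry mixing:
//   * translation sweeps: (pop, z) -> (pop + delta, z - delta/sd), which move
//     along the population-mean/random-effect ridge at zero likelihood cost;
//   * scale moves: (log sd, z) -> (log sd + t, z * exp(-t)), which traverse
//     the funnel between the intercept scale and the standardized effects.
// Proposal scales adapt toward a 0.44 acceptance rate during warmup only.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

namespace {

struct Adapt {
  double lscale = 0.0;
  long acc = 0, tries = 0;
  double scale() const { return std::exp(lscale); }
  void count(bool accepted) { tries++; if (accepted) acc++; }
  void tune(int batch) {
    if (tries == 0) return;
    double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
    lscale += ((double)acc / (double)tries > 0.44) ? step : -step;
    if (lscale < -12.0) lscale = -12.0;
    if (lscale > 6.0) lscale = 6.0;
    acc = 0; tries = 0;
  }
};

struct Sampler {
  // data
  int N, S, I;
  std::vector<double> y, x, d;
  std::vector<int> subj, item;
  std::vector<std::vector<int>> srows, irows;
  double mid;
  // priors
  std::vector<double> pop_mean, pop_sd, hn_subj, hn_item;
  // state
  double pop[7];
  double lsd_s[5], sd_s[5];
  double lsd_i[4], sd_i[4];
  std::vector<double> zs;  // S x 5, column m at zs[m*S + j]
  std::vector<double> zi;  // I x 4
  std::vector<double> rowll, scratch;
  double total;

  double row_loglik(int n) const {
    const int j = subj[n], k = item[n];
    const double Lv = pop[0] + sd_s[0] * zs[0 * S + j] + sd_i[0] * zi[0 * I + k];
    const double Uv = pop[1] + sd_s[1] * zs[1 * S + j] + sd_i[1] * zi[1 * I + k];
    const double dd = Uv - Lv;
    if (dd < 1e-6) return R_NegInf;
    const double cv = pop[2] + sd_s[2] * zs[2 * S + j] + sd_i[2] * zi[2 * I + k];
    const double sv = pop[3] + sd_s[3] * zs[3 * S + j] + sd_i[3] * zi[3 * I + k];
    const double mu = Lv + dd / (1.0 + std::exp(-(4.0 * sv / dd) * (x[n] - cv)));
    double lv = pop[4] + sd_s[4] * zs[4 * S + j] + pop[5] * d[n] + pop[6] * d[n] * d[n];
    if (lv < -30.0) lv = -30.0; else if (lv > 30.0) lv = 30.0;
    const double r = y[n] - mu;
    return -0.5 * (LOG2PI + lv + r * r * std::exp(-lv));
  }

  double full_sum() { double s = 0; for (int n = 0; n < N; n++) { scratch[n] = row_loglik(n); s += scratch[n]; } return s; }
  void commit_full(double s) { rowll.swap(scratch); total = s; }

  double partial_sum(const std::vector<int>& rows, double& oldsum) {
    double s = 0; oldsum = 0;
    for (size_t q = 0; q < rows.size(); q++) {
      const int n = rows[q];
      scratch[n] = row_loglik(n);
      s += scratch[n];
      oldsum += rowll[n];
    }
    return s;
  }
  void commit_partial(const std::vector<int>& rows, double newsum, double oldsum) {
    for (size_t q = 0; q < rows.size(); q++) rowll[rows[q]] = scratch[rows[q]];
    total += newsum - oldsum;
  }

  double lp_pop(int i, double v) const {
    const double zz = (v - pop_mean[i]) / pop_sd[i];
    return -0.5 * zz * zz;
  }
  // half-normal prior on sd, expressed in lambda = log(sd) (includes Jacobian)
  static double lp_lsd(double lam, double h) {
    const double sd = std::exp(lam);
    return -0.5 * (sd / h) * (sd / h) + lam;
  }
};

bool mh_accept(double logratio) {
  if (!std::isfinite(logratio)) return false;
  return logratio >= 0.0 || unif_rand() < std::exp(logratio);
}

// Running mean/covariance of the population block (Welford) feeding a
// Haario-style adaptive Metropolis proposal: N(0, s^2 * (Sigma + eps I)).
struct PopCov {
  int d, n = 0;
  std::vector<double> mean, cov;   // cov is d x d, row-major
  std::vector<double> chol;        // lower Cholesky of scaled covariance
  bool ready = false;
  explicit PopCov(int dim) : d(dim), mean(dim, 0.0), cov((size_t)dim * dim, 0.0),
                             chol((size_t)dim * dim, 0.0) {}
  void update(const double* v) {
    n++;
    std::vector<double> delta(d);
    for (int i = 0; i < d; i++) { delta[i] = v[i] - mean[i]; mean[i] += delta[i] / n; }
    for (int i = 0; i < d; i++)
      for (int j = 0; j < d; j++)
        cov[(size_t)i * d + j] += delta[i] * (v[j] - mean[j]);
  }
  // factor s^2/(n-1) * cov + jitter; returns false if not enough samples
  bool factor(double s2) {
    if (n < 50) return false;
    std::vector<double> A((size_t)d * d);
    for (int i = 0; i < d; i++)
      for (int j = 0; j < d; j++) {
        A[(size_t)i * d + j] = s2 * cov[(size_t)i * d + j] / (n - 1);
        if (i == j) A[(size_t)i * d + j] += 1e-8 + 1e-4 * s2;
      }
    for (int i = 0; i < d; i++) {
      for (int j = 0; j <= i; j++) {
        double sum = A[(size_t)i * d + j];
        for (int k = 0; k < j; k++)
          sum -= chol[(size_t)i * d + k] * chol[(size_t)j * d + k];
        if (i == j) {
          if (sum <= 0.0) return false;
          chol[(size_t)i * d + j] = std::sqrt(sum);
        } else {
          chol[(size_t)i * d + j] = sum / chol[(size_t)j * d + j];
        }
      }
      for (int j = i + 1; j < d; j++) chol[(size_t)i * d + j] = 0.0;
    }
    ready = true;
    return true;
  }
  void propose(double* step) const {
    std::vector<double> z(d);
    for (int i = 0; i < d; i++) z[i] = norm_rand();
    for (int i = 0; i < d; i++) {
      double s = 0.0;
      for (int k = 0; k <= i; k++) s += chol[(size_t)i * d + k] * z[k];
      step[i] = s;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".vas_sampler")]]
List vas_sampler(NumericVector y, NumericVector x,
                 IntegerVector subj, IntegerVector item,
                 int S, int I, double mid,
                 NumericVector pop_mean, NumericVector pop_sd,
                 NumericVector hn_subj, NumericVector hn_item,
                 int warmup, int iter, int thin,
                 NumericVector pop_init, NumericVector lsd_s_init,
                 NumericVector lsd_i_init, double z_jitter) {
  Sampler m;
  m.N = y.size(); m.S = S; m.I = I; m.mid = mid;
  m.y.assign(y.begin(), y.end());
  m.x.assign(x.begin(), x.end());
  m.subj.assign(subj.begin(), subj.end());
  m.item.assign(item.begin(), item.end());
  m.d.resize(m.N);
  for (int n = 0; n < m.N; n++) m.d[n] = m.x[n] - mid;
  m.srows.resize(S); m.irows.resize(I);
  for (int n = 0; n < m.N; n++) { m.srows[m.subj[n]].push_back(n); m.irows[m.item[n]].push_back(n); }
  m.pop_mean.assign(pop_mean.begin(), pop_mean.end());
  m.pop_sd.assign(pop_sd.begin(), pop_sd.end());
  m.hn_subj.assign(hn_subj.begin(), hn_subj.end());
  m.hn_item.assign(hn_item.begin(), hn_item.end());

  for (int i = 0; i < 7; i++) m.pop[i] = pop_init[i];
  for (int q = 0; q < 5; q++) { m.lsd_s[q] = lsd_s_init[q]; m.sd_s[q] = std::exp(m.lsd_s[q]); }
  for (int q = 0; q < 4; q++) { m.lsd_i[q] = lsd_i_init[q]; m.sd_i[q] = std::exp(m.lsd_i[q]); }
  m.zs.assign((size_t)S * 5, 0.0);
  m.zi.assign((size_t)I * 4, 0.0);
  for (size_t q = 0; q < m.zs.size(); q++) m.zs[q] = z_jitter * norm_rand();
  for (size_t q = 0; q < m.zi.size(); q++) m.zi[q] = z_jitter * norm_rand();
  m.rowll.resize(m.N); m.scratch.resize(m.N);
  m.commit_full(m.full_sum());

  // proposal scale groups
  Adapt a_pop[7], a_sds[5], a_sdi[4], a_zs[5], a_zi[4], a_scl_s[5], a_scl_i[4];
  double base[7] = {2.0, 2.0, 0.2, 1.0, 0.2, 0.05, 0.02};
  for (int i = 0; i < 7; i++) a_pop[i].lscale = std::log(base[i]);
  for (int q = 0; q < 5; q++) { a_sds[q].lscale = std::log(0.3); a_zs[q].lscale = std::log(0.5); a_scl_s[q].lscale = std::log(0.3); }
  for (int q = 0; q < 4; q++) { a_sdi[q].lscale = std::log(0.3); a_zi[q].lscale = std::log(0.5); a_scl_i[q].lscale = std::log(0.3); }

  PopCov popcov(7);
  double lscale_blk = 0.0;
  long blk_acc = 0, blk_tries = 0;

  const int n_keep = iter / thin;
  const int P = 16 + 5 * S + 4 * I;
  NumericMatrix draws(n_keep, P);
  int kept = 0, batch = 0;
  const int total_iters = warmup + iter;

  for (int it = 1; it <= total_iters; it++) {
    const bool adapting = it <= warmup;

    // 1) population parameters, single-site
    for (int i = 0; i < 7; i++) {
      const double old = m.pop[i];
      m.pop[i] = old + a_pop[i].scale() * norm_rand();
      const double news = m.full_sum();
      const double lr = news - m.total + m.lp_pop(i, m.pop[i]) - m.lp_pop(i, old);
      if (mh_accept(lr)) m.commit_full(news); else m.pop[i] = old;
      if (adapting) a_pop[i].count(m.pop[i] != old);
    }

    // 2) random-effect scales (log sd random walks)
    for (int q = 0; q < 5; q++) {
      const double old = m.lsd_s[q];
      m.lsd_s[q] = old + a_sds[q].scale() * norm_rand();
      m.sd_s[q] = std::exp(m.lsd_s[q]);
      const double news = m.full_sum();
      const double lr = news - m.total +
        Sampler::lp_lsd(m.lsd_s[q], m.hn_subj[q]) - Sampler::lp_lsd(old, m.hn_subj[q]);
      if (mh_accept(lr)) m.commit_full(news);
      else { m.lsd_s[q] = old; m.sd_s[q] = std::exp(old); }
      if (adapting) a_sds[q].count(m.lsd_s[q] != old);
    }
    for (int q = 0; q < 4; q++) {
      const double old = m.lsd_i[q];
      m.lsd_i[q] = old + a_sdi[q].scale() * norm_rand();
      m.sd_i[q] = std::exp(m.lsd_i[q]);
      const double news = m.full_sum();
      const double lr = news - m.total +
        Sampler::lp_lsd(m.lsd_i[q], m.hn_item[q]) - Sampler::lp_lsd(old, m.hn_item[q]);
      if (mh_accept(lr)) m.commit_full(news);
      else { m.lsd_i[q] = old; m.sd_i[q] = std::exp(old); }
      if (adapting) a_sdi[q].count(m.lsd_i[q] != old);
    }

    // 3) standardized subject effects (local likelihood)
    for (int q = 0; q < 5; q++) {
      for (int j = 0; j < S; j++) {
        double& z = m.zs[(size_t)q * S + j];
        const double old = z;
        z = old + a_zs[q].scale() * norm_rand();
        double oldsum;
        const double news = m.partial_sum(m.srows[j], oldsum);
        const double lr = news - oldsum - 0.5 * (z * z - old * old);
        if (mh_accept(lr)) m.commit_partial(m.srows[j], news, oldsum); else z = old;
        if (adapting) a_zs[q].count(z != old);
      }
    }
    // 4) standardized item effects
    for (int q = 0; q < 4; q++) {
      for (int k = 0; k < I; k++) {
        double& z = m.zi[(size_t)q * I + k];
        const double old = z;
        z = old + a_zi[q].scale() * norm_rand();
        double oldsum;
        const double news = m.partial_sum(m.irows[k], oldsum);
        const double lr = news - oldsum - 0.5 * (z * z - old * old);
        if (mh_accept(lr)) m.commit_partial(m.irows[k], news, oldsum); else z = old;
        if (adapting) a_zi[q].count(z != old);
      }
    }

    // 5) translation sweeps along the likelihood-invariant ridge
    // (pop, z) -> (pop + delta, z - delta/sd). The conditional density of
    // delta is Gaussian (pop prior x standard-normal z priors), so this is an
    // exact Gibbs draw: delta ~ N(t*, v) with
    //   v  = 1 / (1/s0^2 + n/sd^2),
    //   t* = v * ( -(pop - m0)/s0^2 + sum(z)/sd ).
    for (int q = 0; q < 5; q++) {
      const double sd = m.sd_s[q];
      const double s0sq = m.pop_sd[q] * m.pop_sd[q];
      double zsum = 0.0;
      for (int j = 0; j < S; j++) zsum += m.zs[(size_t)q * S + j];
      const double v = 1.0 / (1.0 / s0sq + S / (sd * sd));
      const double tstar = v * (-(m.pop[q] - m.pop_mean[q]) / s0sq + zsum / sd);
      const double delta = tstar + std::sqrt(v) * norm_rand();
      m.pop[q] += delta;
      const double shift = delta / sd;
      for (int j = 0; j < S; j++) m.zs[(size_t)q * S + j] -= shift;
    }
    for (int q = 0; q < 4; q++) {
      const double sd = m.sd_i[q];
      const double s0sq = m.pop_sd[q] * m.pop_sd[q];
      double zsum = 0.0;
      for (int k = 0; k < I; k++) zsum += m.zi[(size_t)q * I + k];
      const double v = 1.0 / (1.0 / s0sq + I / (sd * sd));
      const double tstar = v * (-(m.pop[q] - m.pop_mean[q]) / s0sq + zsum / sd);
      const double delta = tstar + std::sqrt(v) * norm_rand();
      m.pop[q] += delta;
      const double shift = delta / sd;
      for (int k = 0; k < I; k++) m.zi[(size_t)q * I + k] -= shift;
    }

    // 6) scale moves (likelihood invariant funnel traversal); repeated, they
    // cost O(S) each
    for (int srep = 0; srep < 3; srep++) {
    for (int q = 0; q < 5; q++) {
      const double t = a_scl_s[q].scale() * norm_rand();
      const double a = std::exp(t);
      double lr = Sampler::lp_lsd(m.lsd_s[q] + t, m.hn_subj[q]) -
                  Sampler::lp_lsd(m.lsd_s[q], m.hn_subj[q]) - S * t;
      for (int j = 0; j < S; j++) {
        const double z = m.zs[(size_t)q * S + j], zn = z / a;
        lr += -0.5 * (zn * zn - z * z);
      }
      const bool ok = mh_accept(lr);
      if (ok) {
        m.lsd_s[q] += t; m.sd_s[q] = std::exp(m.lsd_s[q]);
        for (int j = 0; j < S; j++) m.zs[(size_t)q * S + j] /= a;
      }
      if (adapting) a_scl_s[q].count(ok);
    }
    for (int q = 0; q < 4; q++) {
      const double t = a_scl_i[q].scale() * norm_rand();
      const double a = std::exp(t);
      double lr = Sampler::lp_lsd(m.lsd_i[q] + t, m.hn_item[q]) -
                  Sampler::lp_lsd(m.lsd_i[q], m.hn_item[q]) - I * t;
      for (int k = 0; k < I; k++) {
        const double z = m.zi[(size_t)q * I + k], zn = z / a;
        lr += -0.5 * (zn * zn - z * z);
      }
      const bool ok = mh_accept(lr);
      if (ok) {
        m.lsd_i[q] += t; m.sd_i[q] = std::exp(m.lsd_i[q]);
        for (int k = 0; k < I; k++) m.zi[(size_t)q * I + k] /= a;
      }
      if (adapting) a_scl_i[q].count(ok);
    }
    }  // srep

    // 7) joint population block (adaptive-covariance Metropolis), twice per
    // iteration: handles the strong cross-correlations among the 4PL and
    // variance-profile population parameters that single-site moves miss.
    if (adapting) popcov.update(m.pop);
    if (adapting && it % 50 == 0 && it >= 100)
      popcov.factor(std::exp(2.0 * lscale_blk) * 2.38 * 2.38 / 7.0);
    if (popcov.ready) {
      for (int rep = 0; rep < 2; rep++) {
        double step[7], old[7];
        popcov.propose(step);
        double lr = 0.0;
        for (int i = 0; i < 7; i++) {
          old[i] = m.pop[i];
          m.pop[i] = old[i] + step[i];
          lr += m.lp_pop(i, m.pop[i]) - m.lp_pop(i, old[i]);
        }
        const double news = m.full_sum();
        lr += news - m.total;
        const bool ok = mh_accept(lr);
        if (ok) m.commit_full(news);
        else for (int i = 0; i < 7; i++) m.pop[i] = old[i];
        if (adapting) { blk_tries++; if (ok) blk_acc++; }
      }
    }

    if (adapting && it % 50 == 0) {
      if (blk_tries > 0) {
        double step = std::min(0.05, 1.0 / std::sqrt((double)(batch + 1)));
        lscale_blk += ((double)blk_acc / blk_tries > 0.25) ? step : -step;
        blk_acc = blk_tries = 0;
      }
      batch++;
      for (int i = 0; i < 7; i++) a_pop[i].tune(batch);
      for (int q = 0; q < 5; q++) { a_sds[q].tune(batch); a_zs[q].tune(batch); a_scl_s[q].tune(batch); }
      for (int q = 0; q < 4; q++) { a_sdi[q].tune(batch); a_zi[q].tune(batch); a_scl_i[q].tune(batch); }
    }
    if (it % 250 == 0) m.commit_full(m.full_sum());  // guard against FP drift

    if (!adapting && ((it - warmup) % thin == 0) && kept < n_keep) {
      int col = 0;
      for (int i = 0; i < 7; i++) draws(kept, col++) = m.pop[i];
      for (int q = 0; q < 5; q++) draws(kept, col++) = m.sd_s[q];
      for (int q = 0; q < 4; q++) draws(kept, col++) = m.sd_i[q];
      for (int q = 0; q < 5; q++)
        for (int j = 0; j < S; j++) draws(kept, col++) = m.sd_s[q] * m.zs[(size_t)q * S + j];
      for (int q = 0; q < 4; q++)
        for (int k = 0; k < I; k++) draws(kept, col++) = m.sd_i[q] * m.zi[(size_t)q * I + k];
      kept++;
    }
  }

  NumericVector acc_pop(7);
  for (int i = 0; i < 7; i++) acc_pop[i] = a_pop[i].scale();
  return List::create(_["draws"] = draws,
                      _["final_loglik"] = m.total,
                      _["pop_scales"] = acc_pop);
}
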