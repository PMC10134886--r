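// Next-reaction stochastic simulation of a reaction network embedded in
// a dividing cell: putative-time queue with Gibson-Bruck rescaling on
// dependency updates, explicit gene-replication events (copy number 1 -> 2
// at p * tau_c after birth), per-cycle growth-rate and Spo0A~P resampling,
// and binomial partitioning of every species at division.
//
// All randomness flows through R's RNG (RNGScope), so set.seed() on the
// R side makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <climits>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Engine {
  int ns, nr, ng;
  IntegerMatrix stoich;
  IntegerVector re1, re2;
  NumericVector rate;
  IntegerVector mtype, mspec;
  NumericVector mK, mn;
  IntegerVector gene;
  std::vector<long long> x;
  std::vector<int> gcopy;
  std::vector<std::vector<int>> dep;   // reaction -> dependent reactions
  std::vector<double> a;               // propensities
  std::vector<double> tput;            // putative absolute firing times
  double spo0a;                        // current input (uM)
  long long nevents = 0;

  Engine(List cmp, IntegerVector x0)
    : stoich(as<IntegerMatrix>(cmp["stoich"])),
      re1(as<IntegerVector>(cmp["re1"])), re2(as<IntegerVector>(cmp["re2"])),
      rate(as<NumericVector>(cmp["rate"])),
      mtype(as<IntegerVector>(cmp["mtype"])),
      mspec(as<IntegerVector>(cmp["mspec"])),
      mK(as<NumericVector>(cmp["mK"])), mn(as<NumericVector>(cmp["mn"])),
      gene(as<IntegerVector>(cmp["gene"])) {
    ns = stoich.nrow(); nr = stoich.ncol();
    ng = as<NumericVector>(cmp["gene_p"]).size();
    x.assign(x0.begin(), x0.end());
    gcopy.assign(std::max(ng, 1), 1);
    a.assign(nr, 0.0); tput.assign(nr, INF);
    // dependency graph: j affects k if j changes a species k reads
    std::vector<std::vector<bool>> reads(nr, std::vector<bool>(ns, false));
    for (int k = 0; k < nr; ++k) {
      if (re1[k] >= 0) reads[k][re1[k]] = true;
      if (re2[k] >= 0) reads[k][re2[k]] = true;
      if (mtype[k] == 2 && mspec[k] >= 0) reads[k][mspec[k]] = true;
    }
    dep.assign(nr, {});
    for (int j = 0; j < nr; ++j)
      for (int k = 0; k < nr; ++k) {
        bool hit = false;
        for (int s = 0; s < ns && !hit; ++s)
          if (stoich(s, j) != 0 && reads[k][s]) hit = true;
        if (hit) dep[j].push_back(k);
      }
  }

  double prop(int j) const {
    double v = rate[j];
    if (re1[j] >= 0) {
      if (re2[j] == re1[j]) v *= (double)x[re1[j]] * (double)(x[re1[j]] - 1);
      else {
        v *= (double)x[re1[j]];
        if (re2[j] >= 0) v *= (double)x[re2[j]];
      }
    }
    if (mtype[j] == 1) {
      double sn = std::pow(spo0a, mn[j]);
      v *= sn / (sn + std::pow(mK[j], mn[j]));
    } else if (mtype[j] == 2) {
      double kn = std::pow(mK[j], mn[j]);
      v *= kn / (kn + std::pow((double)x[mspec[j]], mn[j]));
    }
    if (gene[j] >= 0) v *= gcopy[gene[j]];
    return v;
  }

  void refresh_all(double t) {
    for (int j = 0; j < nr; ++j) {
      a[j] = prop(j);
      tput[j] = a[j] > 0 ? t + R::rexp(1.0) / a[j] : INF;
    }
  }

  void update_after(int fired, double t) {
    // the fired reaction is always redrawn, even when it reads none of
    // the species it changes (zero-order production)
    a[fired] = prop(fired);
    tput[fired] = a[fired] > 0 ? t + R::rexp(1.0) / a[fired] : INF;
    for (int k : dep[fired]) {
      if (k == fired) continue;
      double anew = prop(k);
      if (anew > 0) {
        tput[k] = (a[k] > 0 && std::isfinite(tput[k]))
          ? t + (a[k] / anew) * (tput[k] - t)
          : t + R::rexp(1.0) / anew;
      } else tput[k] = INF;
      a[k] = anew;
    }
  }

  // advance the chemistry to t_stop; record any samples passed
  void run_until(double t_stop, double &t,
                 const NumericVector &sample_times, int &sk,
                 std::vector<long long> &rec, double mu_now,
                 std::vector<double> &rec_mu, std::vector<double> &rec_s) {
    while (true) {
      int jmin = -1; double tmin = INF;
      for (int j = 0; j < nr; ++j)
        if (tput[j] < tmin) { tmin = tput[j]; jmin = j; }
      double tnext = std::min(tmin, t_stop);
      while (sk < sample_times.size() && sample_times[sk] <= tnext) {
        for (int s = 0; s < ns; ++s) rec.push_back(x[s]);
        rec_mu.push_back(mu_now); rec_s.push_back(spo0a);
        ++sk;
      }
      if (tmin > t_stop) { t = t_stop; return; }
      t = tmin;
      for (int s = 0; s < ns; ++s) {
        x[s] += stoich(s, jmin);
        if (x[s] < 0) stop("negative count for species %d at t=%f", s + 1, t);
      }
      ++nevents;
      update_after(jmin, t);
      if (nevents % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
  }
};

static double interp(const NumericVector &xs, const NumericVector &ys,
                     double x) {
  int n = xs.size();
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid; }
  double w = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] * (1 - w) + ys[hi] * w;
}

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(List cmp, IntegerVector x0, double t_end,
             NumericVector sample_times,
             int mu_mode, double mu_fixed,
             NumericVector traj_t, NumericVector traj_mu,
             int s_mode, double s_fixed,
             NumericVector smap_mu, NumericVector smap_s,
             double epsilon, double cv, double min_gen, int max_retry,
             bool divisions) {
  RNGScope scope;
  Engine eng(cmp, x0);
  NumericVector gene_p = as<NumericVector>(cmp["gene_p"]);
  int ng = gene_p.size();

  std::vector<long long> rec;
  std::vector<double> rec_mu, rec_s;
  std::vector<double> div_times, repl_times;
  std::vector<int> repl_gene;
  int sk = 0;
  double t = 0.0;

  if (!divisions) {
    // plain well-mixed SSA, constant conditions, no cell cycle
    eng.spo0a = s_fixed;
    eng.refresh_all(t);
    eng.run_until(t_end, t, sample_times, sk, rec, mu_fixed, rec_mu, rec_s);
  } else {
    while (t < t_end) {
      double cycle_start = t;
      // mean generation time (time-shift corrected in trajectory mode)
      double mean_tau;
      if (mu_mode == 0) {
        mean_tau = M_LN2 / mu_fixed;
      } else {
        double mu0 = interp(traj_t, traj_mu, cycle_start);
        if (mu0 <= 0) stop("degenerate growth: mu(t)=0 at t=%f", cycle_start);
        double dt = epsilon * M_LN2 / mu0;
        double mu1 = interp(traj_t, traj_mu, cycle_start + dt);
        if (mu1 <= 0) stop("degenerate growth: mu(t+dt)=0 at t=%f", cycle_start);
        mean_tau = M_LN2 / mu1;
      }
      // truncated-normal generation time (rejection below min_gen)
      double tau = mean_tau;
      if (cv > 0) {
        int tries = 0;
        do {
          tau = R::rnorm(mean_tau, cv * mean_tau);
          if (++tries > max_retry)
            stop("generation-time rejection cap exceeded at t=%f", t);
        } while (tau < min_gen);
      } else if (tau < min_gen) tau = min_gen;

      double mu_cycle = M_LN2 / tau;
      eng.spo0a = (s_mode == 0) ? s_fixed : interp(smap_mu, smap_s, mu_cycle);

      // replication events within this cycle
      double tau_c = 0.78 + 0.15 / mu_cycle;
      std::vector<std::pair<double, int>> events;  // (time, gene)
      for (int g = 0; g < ng; ++g) {
        eng.gcopy[g] = 1;
        double rt = gene_p[g] * tau_c;
        if (rt <= tau) events.push_back({cycle_start + rt, g});
      }
      std::sort(events.begin(), events.end());
      double division_time = cycle_start + tau;

      eng.refresh_all(t);
      for (auto &ev : events) {
        double stopt = std::min(ev.first, std::min(division_time, t_end));
        eng.run_until(stopt, t, sample_times, sk, rec, mu_cycle,
                      rec_mu, rec_s);
        if (t >= t_end || stopt >= division_time) break;
        eng.gcopy[ev.second] = 2;
        repl_times.push_back(t); repl_gene.push_back(ev.second + 1);
        eng.refresh_all(t);
      }
      if (t < std::min(division_time, t_end))
        eng.run_until(std::min(division_time, t_end), t, sample_times, sk,
                      rec, mu_cycle, rec_mu, rec_s);
      if (t >= t_end) break;
      // division: binomial partition, keep one daughter
      for (int s = 0; s < eng.ns; ++s)
        eng.x[s] = (long long)R::rbinom((double)eng.x[s], 0.5);
      div_times.push_back(t);
    }
  }
  // flush samples at exactly t_end
  while (sk < sample_times.size() && sample_times[sk] <= t_end + 1e-12) {
    for (int s = 0; s < eng.ns; ++s) rec.push_back(eng.x[s]);
    rec_mu.push_back(mu_mode == 0 ? mu_fixed :
                     (rec_mu.empty() ? mu_fixed : rec_mu.back()));
    rec_s.push_back(eng.spo0a);
    ++sk;
  }

  int nsamp = rec.size() / eng.ns;
  IntegerMatrix counts(nsamp, eng.ns);
  for (int i = 0; i < nsamp; ++i)
    for (int s = 0; s < eng.ns; ++s) {
      long long v = rec[(size_t)i * eng.ns + s];
      counts(i, s) = (v > INT_MAX) ? NA_INTEGER : (int)v;
    }
  return List::create(
    _["counts"] = counts,
    _["mu_at"] = NumericVector(rec_mu.begin(), rec_mu.end()),
    _["spo0a_at"] = NumericVector(rec_s.begin(), rec_s.end()),
    _["division_times"] = NumericVector(div_times.begin(), div_times.end()),
    _["replication_times"] = NumericVector(repl_times.begin(), repl_times.end()),
    _["replication_gene"] = IntegerVector(repl_gene.begin(), repl_gene.end()),
    _["n_events"] = (double)eng.nevents
  );
}
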