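#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Direct-method stochastic simulation of the five-rate exclusion process
// (TASEP with Langmuir kinetics) on a 1-D lattice, minus-end entry at site 1,
// plus-end exit at site n, optional finite cytoplasmic motor pool.
//
// Event codes in the log: 1 = enter (site 1), 2 = land, 3 = hop,
// 4 = detach (lattice), 5 = exit (plus-end).
//
// Occupancy is strictly exclusive: every event target is checked before the
// move and the invariant is asserted per event.

static inline double free_conc(double total, long n_bound, double vol_fl,
                               double n_mt, bool finite_pool) {
  if (!finite_pool) return total;
  // 1 nM in 1 fL corresponds to N_A * 1e-9 * 1e-15 = 0.602214076 molecules
  double c = total - (double)n_bound * n_mt / (0.602214076 * vol_fl);
  return c > 0.0 ? c : 0.0;
}

// [[Rcpp::export(name = ".gillespie_core")]]
List gillespie_core(int n_sites,
                    double k_in, double k_on, double k_off, double k_step,
                    double k_out,
                    double kip2_total, double volume_fl, double n_mt,
                    bool finite_pool, bool terminal_additive,
                    NumericVector record_times,
                    double t_end, double avg_start,
                    int seed, bool log_events,
                    IntegerVector init_occupancy) {
  if (n_sites < 1) stop("n_sites must be >= 1");
  std::vector<int> occ(n_sites, 0);
  long n_bound = 0;
  if (init_occupancy.size() == n_sites) {
    for (int i = 0; i < n_sites; ++i) {
      occ[i] = init_occupancy[i] ? 1 : 0;
      n_bound += occ[i];
    }
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int n_rec = record_times.size();
  IntegerMatrix snapshots(n_rec, n_sites);
  int rec_idx = 0;

  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_site;

  std::vector<double> occ_time(n_sites, 0.0); // residency time after avg_start
  long exit_count = 0;       // exits after avg_start
  long n_events = 0;

  double t = 0.0;
  double c = free_conc(kip2_total, n_bound, volume_fl, n_mt, finite_pool);

  std::vector<int> empty_sites, hop_sites, occ_offable;
  empty_sites.reserve(n_sites);
  hop_sites.reserve(n_sites);
  occ_offable.reserve(n_sites);

  auto snapshot_upto = [&](double tnew) {
    while (rec_idx < n_rec && record_times[rec_idx] <= tnew) {
      for (int i = 0; i < n_sites; ++i) snapshots(rec_idx, i) = occ[i];
      ++rec_idx;
    }
  };
  auto accumulate = [&](double t0, double t1) {
    double lo = t0 > avg_start ? t0 : avg_start;
    if (t1 <= lo) return;
    double dt = t1 - lo;
    for (int i = 0; i < n_sites; ++i)
      if (occ[i]) occ_time[i] += dt;
  };

  while (t < t_end) {
    // enumerate propensity classes
    empty_sites.clear(); hop_sites.clear(); occ_offable.clear();
    for (int i = 0; i < n_sites; ++i) {
      if (!occ[i]) {
        empty_sites.push_back(i);
      } else {
        if (i < n_sites - 1) {
          if (!occ[i + 1]) hop_sites.push_back(i);
          occ_offable.push_back(i);
        } else if (terminal_additive) {
          occ_offable.push_back(i); // terminal keeps k_off in additive mode
        }
      }
    }
    double a_enter = (!occ[0]) ? k_in * c : 0.0;
    double a_land  = k_on * c * (double)empty_sites.size();
    double a_hop   = k_step * (double)hop_sites.size();
    double a_off   = k_off * (double)occ_offable.size();
    double a_exit  = occ[n_sites - 1] ? k_out : 0.0;
    double a_tot = a_enter + a_land + a_hop + a_off + a_exit;

    if (a_tot <= 0.0) { // frozen configuration (e.g. empty, no entry paths)
      accumulate(t, t_end);
      snapshot_upto(t_end);
      t = t_end;
      break;
    }

    double tau = -std::log(unif(rng)) / a_tot;
    double t_new = t + tau;
    if (t_new > t_end) {
      accumulate(t, t_end);
      snapshot_upto(t_end);
      t = t_end;
      break;
    }
    snapshot_upto(t_new);
    accumulate(t, t_new);
    t = t_new;

    double u = unif(rng) * a_tot;
    int type = 0, site = -1;
    if (u < a_enter) {
      type = 1; site = 0;
      if (occ[0]) stop("exclusion violated (enter)");
      occ[0] = 1; ++n_bound;
    } else if (u < a_enter + a_land) {
      type = 2;
      int k = (int)(unif(rng) * empty_sites.size());
      if (k >= (int)empty_sites.size()) k = empty_sites.size() - 1;
      site = empty_sites[k];
      if (occ[site]) stop("exclusion violated (land)");
      occ[site] = 1; ++n_bound;
    } else if (u < a_enter + a_land + a_hop) {
      type = 3;
      int k = (int)(unif(rng) * hop_sites.size());
      if (k >= (int)hop_sites.size()) k = hop_sites.size() - 1;
      site = hop_sites[k];
      if (!occ[site] || occ[site + 1]) stop("exclusion violated (hop)");
      occ[site] = 0; occ[site + 1] = 1;
    } else if (u < a_enter + a_land + a_hop + a_off) {
      type = 4;
      int k = (int)(unif(rng) * occ_offable.size());
      if (k >= (int)occ_offable.size()) k = occ_offable.size() - 1;
      site = occ_offable[k];
      occ[site] = 0; --n_bound;
    } else {
      type = 5; site = n_sites - 1;
      occ[site] = 0; --n_bound;
      if (t >= avg_start) ++exit_count;
    }
    ++n_events;
    c = free_conc(kip2_total, n_bound, volume_fl, n_mt, finite_pool);
    if (log_events) {
      ev_time.push_back(t);
      ev_type.push_back(type);
      ev_site.push_back(site + 1); // 1-based for R
    }
  }
  snapshot_upto(t_end + 1.0); // flush any trailing record times == t_end

  double denom = t_end - avg_start;
  NumericVector mean_occ(n_sites);
  for (int i = 0; i < n_sites; ++i)
    mean_occ[i] = denom > 0 ? occ_time[i] / denom : NA_REAL;

  IntegerVector final_occ(n_sites);
  for (int i = 0; i < n_sites; ++i) final_occ[i] = occ[i];

  List out = List::create(
    _["snapshots"] = snapshots,
    _["record_times"] = record_times,
    _["mean_occupancy"] = mean_occ,
    _["avg_window"] = NumericVector::create(avg_start, t_end),
    _["exit_count"] = (double)exit_count,
    _["n_events"] = (double)n_events,
    _["final_occupancy"] = final_occ,
    _["n_bound"] = (double)n_bound,
    _["c_free"] = c);
  if (log_events) {
    out["events"] = DataFrame::create(
      _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["type"] = IntegerVector(ev_type.begin(), ev_type.end()),
      _["site"] = IntegerVector(ev_site.begin(), ev_site.end()));
  }
  return out;
}
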