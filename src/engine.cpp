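#include <Rcpp.h>
using namespace Rcpp;

// Occupant codes: -1 = tSC, 0 = vacancy, k >= 1 = axon identity k.
// Variants: 0 = vacancy-mediated, 1 = random rows, 2 = equal rows.
//
// RNG contract (shared draw-for-draw with the reference R step functions):
//   site selection: one uniform (index = floor(u * n) when unweighted,
//   otherwise threshold scan of u * total over sequentially accumulated
//   weights); then one uniform for the transition draw; then, where an
//   axon identity is needed, one uniform over the cumulative integer
//   weights (vacancy-mediated) or the donor list (neighbour adoption).
//   Random rows draw three exponentials (-log u) in target order S, V, A.

static inline int kind_of(int occ) { return occ >= 1 ? 2 : (occ == -1 ? 0 : 1); } // 0=S,1=V,2=A

// [[Rcpp::export]]
List engine_run(IntegerVector occ0, List adj, int n_axons, int variant,
                double p_av, double p_sv, double p_vs,
                LogicalVector active, double divisor,
                int max_iter, bool terminate,
                int series_stride, bool record_events, int max_events,
                bool donor_adjacent) {
  const int n = occ0.size();
  std::vector<int> occ(occ0.begin(), occ0.end());

  // adjacency as flat arrays (1-based R indices -> 0-based)
  std::vector<int> adj_start(n + 1, 0), adj_flat;
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    adj_start[i + 1] = adj_start[i] + nb.size();
    for (int j = 0; j < nb.size(); ++j) adj_flat.push_back(nb[j] - 1);
  }

  std::vector<int> axon_cnt(n_axons + 1, 0);
  int n_tsc = 0, n_vac = 0;
  for (int i = 0; i < n; ++i) {
    if (occ[i] >= 1) axon_cnt[occ[i]]++;
    else if (occ[i] == -1) n_tsc++;
    else n_vac++;
  }
  int alive = 0, n_axon_sites = n - n_tsc - n_vac;
  for (int k = 1; k <= n_axons; ++k) if (axon_cnt[k] > 0) alive++;

  bool has_activity = false;
  for (int k = 0; k < active.size(); ++k) if (active[k]) has_activity = true;

  // completion test; winner: k>=1 axon, -1 all-tSC, -2 all-vacant, 0 none
  auto completion = [&](int &winner) -> bool {
    if (variant == 0) {
      if (alive == 1) {
        for (int k = 1; k <= n_axons; ++k)
          if (axon_cnt[k] > 0) { winner = k; return true; }
      }
      return false;
    }
    if (n_tsc == n) { winner = -1; return true; }
    if (n_vac == n) { winner = -2; return true; }
    for (int k = 1; k <= n_axons; ++k)
      if (axon_cnt[k] == n) { winner = k; return true; }
    return false;
  };

  int n_series = 0;
  NumericMatrix series;
  if (series_stride > 0) {
    series = NumericMatrix(max_iter / series_stride + 3, 5);
  }
  auto push_series = [&](int iter) {
    if (series_stride <= 0 || n_series >= series.nrow()) return;
    series(n_series, 0) = iter;
    series(n_series, 1) = (double)n_tsc / n;
    series(n_series, 2) = (double)n_vac / n;
    series(n_series, 3) = (double)n_axon_sites / n;
    series(n_series, 4) = alive;
    n_series++;
  };

  IntegerMatrix events;
  int n_ev = 0;
  bool ev_truncated = false;
  if (record_events) events = IntegerMatrix(max_events, 4);
  auto push_event = [&](int iter, int site, int oldo, int newo) {
    if (!record_events) return;
    if (n_ev >= max_events) { ev_truncated = true; return; }
    events(n_ev, 0) = iter; events(n_ev, 1) = site + 1;
    events(n_ev, 2) = oldo; events(n_ev, 3) = newo;
    n_ev++;
  };

  auto set_occ = [&](int iter, int i, int newo) {
    int oldo = occ[i];
    if (oldo == newo) return;
    if (oldo >= 1) { axon_cnt[oldo]--; n_axon_sites--; if (axon_cnt[oldo] == 0) alive--; }
    else if (oldo == -1) n_tsc--;
    else n_vac--;
    if (newo >= 1) { if (axon_cnt[newo] == 0) alive++; axon_cnt[newo]++; n_axon_sites++; }
    else if (newo == -1) n_tsc++;
    else n_vac++;
    occ[i] = newo;
    push_event(iter, i, oldo, newo);
  };

  int winner = 0, completed_iter = -1;
  double sum_s = 0, sum_v = 0, sum_a = 0;

  {
    int w;
    if (completion(w)) { completed_iter = 0; winner = w; }
  }
  push_series(0);

  int iter = 0;
  if (!(terminate && completed_iter >= 0)) {
    for (iter = 1; iter <= max_iter; ++iter) {
      // --- site selection ---
      int i;
      double u = unif_rand();
      if (has_activity) {
        double total = 0.0;
        for (int j = 0; j < n; ++j)
          total += (occ[j] >= 1 && active[occ[j] - 1]) ? 1.0 / divisor : 1.0;
        double thr = u * total, acc = 0.0;
        i = n - 1;
        for (int j = 0; j < n; ++j) {
          acc += (occ[j] >= 1 && active[occ[j] - 1]) ? 1.0 / divisor : 1.0;
          if (thr <= acc) { i = j; break; }
        }
      } else {
        i = (int)(u * n);
        if (i >= n) i = n - 1;
      }

      // --- transition ---
      if (variant == 0) {
        if (occ[i] >= 1) {
          if (unif_rand() < p_av) set_occ(iter, i, 0);
        } else if (occ[i] == -1) {
          if (unif_rand() < p_sv) set_occ(iter, i, 0);
        } else {
          if (unif_rand() < p_vs) {
            set_occ(iter, i, -1);
          } else {
            // axon reclaim weighted by adjacent site counts, falling back
            // to global site counts; extinct axons have weight zero
            std::vector<int> w(n_axons + 1, 0);
            int tot = 0;
            for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
              int o = occ[adj_flat[a]];
              if (o >= 1) { w[o]++; tot++; }
            }
            if (tot == 0) {
              for (int k = 1; k <= n_axons; ++k) { w[k] = axon_cnt[k]; tot += w[k]; }
            }
            if (tot > 0) {
              double thr = unif_rand() * tot, acc = 0.0;
              int chosen = n_axons;
              for (int k = 1; k <= n_axons; ++k) {
                acc += w[k];
                if (thr <= acc) { chosen = k; break; }
              }
              set_occ(iter, i, chosen);
            }
            // no axon sites anywhere: the vacancy stays vacant
          }
        }
      } else if (donor_adjacent) {
        // neighbour-copy reading: the chosen site transitions into a site
        // adjacent to it — a uniformly chosen neighbour is adopted with
        // the probability the row assigns to that neighbour's kind
        int deg = adj_start[i + 1] - adj_start[i];
        if (deg > 0) {
          int pick = (int)(unif_rand() * deg);
          if (pick >= deg) pick = deg - 1;
          int j = adj_flat[adj_start[i] + pick];
          double p;
          if (variant == 1) {
            double e1 = -log(unif_rand()), e2 = -log(unif_rand()),
                   e3 = -log(unif_rand());
            double s = (e1 + e2) + e3;
            int kj = kind_of(occ[j]);
            p = (kj == 0 ? e1 : kj == 1 ? e2 : e3) / s;
          } else {
            p = 1.0 / 3.0;
          }
          if (unif_rand() < p) set_occ(iter, i, occ[j]);
        }
      } else {
        // row-outcome reading: one probability row for the current kind,
        // targets in order (S, V, A); only axon outcomes need a donor
        double pS, pV;
        if (variant == 1) {
          double e1 = -log(unif_rand()), e2 = -log(unif_rand()), e3 = -log(unif_rand());
          double s = (e1 + e2) + e3;
          pS = e1 / s; pV = e2 / s;
        } else {
          pS = 1.0 / 3.0; pV = 1.0 / 3.0;
        }
        double uo = unif_rand();
        int target = uo < pS ? 0 : (uo < pS + pV ? 1 : 2); // 0=S,1=V,2=A
        int cur = kind_of(occ[i]);
        if (target != cur) {
          if (target == 0) set_occ(iter, i, -1);
          else if (target == 1) set_occ(iter, i, 0);
          else {
            // adopt identity from a uniformly chosen adjacent axon site
            int m = 0;
            for (int a = adj_start[i]; a < adj_start[i + 1]; ++a)
              if (occ[adj_flat[a]] >= 1) m++;
            if (m > 0) {
              int pick = (int)(unif_rand() * m);
              if (pick >= m) pick = m - 1;
              int c = 0;
              for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
                if (occ[adj_flat[a]] >= 1 && c++ == pick) {
                  set_occ(iter, i, occ[adj_flat[a]]);
                  break;
                }
              }
            }
          }
        }
      }

      sum_s += (double)n_tsc / n; sum_v += (double)n_vac / n;
      sum_a += (double)n_axon_sites / n;
      if (series_stride > 0 && iter % series_stride == 0) push_series(iter);

      if (completed_iter < 0) {
        int w;
        if (completion(w)) {
          completed_iter = iter; winner = w;
          if (terminate) break;
        }
      }
    }
    if (iter > max_iter) iter = max_iter;
  }

  int iters_run = iter;
  if (series_stride > 0 && iters_run > 0 &&
      (n_series == 0 || series(n_series - 1, 0) != iters_run)) {
    push_series(iters_run);
  }

  NumericVector mean_comp = NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  if (iters_run > 0) {
    mean_comp[0] = sum_s / iters_run;
    mean_comp[1] = sum_v / iters_run;
    mean_comp[2] = sum_a / iters_run;
  }

  SEXP series_out = R_NilValue, events_out = R_NilValue;
  if (series_stride > 0) {
    NumericMatrix s(std::max(n_series, 1), 5);
    for (int r = 0; r < s.nrow(); ++r)
      for (int c = 0; c < 5; ++c) s(r, c) = series(r, c);
    series_out = s;
  }
  if (record_events) {
    IntegerMatrix e(n_ev, 4);
    for (int r = 0; r < n_ev; ++r)
      for (int c = 0; c < 4; ++c) e(r, c) = events(r, c);
    events_out = e;
  }

  return List::create(
    _["completed"] = completed_iter >= 0,
    _["iterations"] = completed_iter >= 0 ? completed_iter : iters_run,
    _["iters_run"] = iters_run,
    _["winner"] = winner,
    _["occ"] = IntegerVector(occ.begin(), occ.end()),
    _["series"] = series_out,
    _["events"] = events_out,
    _["events_truncated"] = ev_truncated,
    _["mean_composition"] = mean_comp);
}
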