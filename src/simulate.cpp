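// Core of the contact simulation: exact sampling of a node's next cognate
// set from P(v) proportional to exp(sum_{c in v} wscore(c) - d * |v|^2) over
// all non-empty subsets v of the candidate set, plus the per-concept run loop.
//
// The sampler never enumerates the power set.  It factorizes the target as
// P(v) = f(|v|) * prod_{c in v} x_c with x_c = exp(wscore(c)):
//   1. draw k = |v| with weight e_k(x_1..x_n) * exp(-d k^2),
//      e_k the elementary symmetric polynomial;
//   2. draw a k-subset with probability proportional to prod x_c using the
//      standard sequential scheme on suffix elementary symmetric polynomials.
// Scores are max-shifted before exponentiation so only log-weights matter.

#include <Rcpp.h>
#include <random>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::mt19937_64 rng_t;

static inline double runif01(rng_t &rng) {
  return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
}

// Suffix table of elementary symmetric polynomials:
// E[i][k] = e_k(x_i, ..., x_{n-1}), E[n][0] = 1.
static void esp_suffix(const std::vector<double> &x,
                       std::vector< std::vector<double> > &E) {
  const int n = (int) x.size();
  E.assign(n + 1, std::vector<double>());
  E[n].assign(1, 1.0);
  for (int i = n - 1; i >= 0; --i) {
    const int kmax = n - i;
    E[i].assign(kmax + 1, 0.0);
    E[i][0] = 1.0;
    for (int k = 1; k <= kmax; ++k) {
      double carry = (k <= (int) E[i + 1].size() - 1) ? E[i + 1][k] : 0.0;
      E[i][k] = carry + x[i] * E[i + 1][k - 1];
    }
  }
}

// One draw from the subset distribution; returns 0-based candidate indices.
static std::vector<int> sample_subset_core(const std::vector<double> &ws,
                                           double dcost, rng_t &rng) {
  const int n = (int) ws.size();
  std::vector<int> out;
  if (n == 0) stop("no candidates to sample from");
  if (n == 1) { out.push_back(0); return out; }

  double m = ws[0];
  for (int i = 1; i < n; ++i) if (ws[i] > m) m = ws[i];
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = std::exp(ws[i] - m);

  std::vector< std::vector<double> > E;
  esp_suffix(x, E);

  // log-weights over sizes k = 1..n
  std::vector<double> logw(n + 1, -HUGE_VAL);
  double lmax = -HUGE_VAL;
  for (int k = 1; k <= n; ++k) {
    double ek = E[0][k];
    if (ek <= 0.0) continue;
    logw[k] = std::log(ek) + k * m - dcost * (double) k * (double) k;
    if (logw[k] > lmax) lmax = logw[k];
  }
  double tot = 0.0;
  std::vector<double> wk(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) {
    if (std::isfinite(logw[k])) { wk[k] = std::exp(logw[k] - lmax); tot += wk[k]; }
  }
  double u = runif01(rng) * tot;
  int ksel = n;
  for (int k = 1; k <= n; ++k) {
    u -= wk[k];
    if (u <= 0.0) { ksel = k; break; }
  }

  // sequential k-subset draw: include i with prob x_i e_{r-1}(suffix)/e_r(suffix)
  int r = ksel;
  for (int i = 0; i < n && r > 0; ++i) {
    double denom = E[i][r];
    double num = x[i] * E[i + 1][r - 1];
    double p = (denom > 0.0) ? num / denom : 1.0;
    if (runif01(rng) < p) { out.push_back(i); --r; }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sample_subset_cpp")]]
List sample_subset_cpp(NumericVector wscores, double dcost, int ndraws, int seed) {
  rng_t rng((uint64_t) seed);
  std::vector<double> ws(wscores.begin(), wscores.end());
  List res(ndraws);
  for (int i = 0; i < ndraws; ++i) {
    std::vector<int> s = sample_subset_core(ws, dcost, rng);
    IntegerVector iv(s.size());
    for (size_t j = 0; j < s.size(); ++j) iv[j] = s[j] + 1;  // 1-based for R
    res[i] = iv;
  }
  return res;
}

// Runs one concept for T steps on a (possibly growing) network.
//
// w           full influence matrix incl. self weights w[i][i] = s * p_i and
//             all event-node rows/columns
// pop         node populations
// active_from 0 for founding nodes; t0 > 0 for a node created by a copy event
//             at the end of step t0 (first own update at t0 + 1)
// copy_src    0-based index of the copy source, -1 for founding nodes
//
// Cognate ids are 0-based internally; id 0 is the shared initial cognate.
//' @noRd
// [[Rcpp::export(name = ".run_concept_cpp")]]
List run_concept_cpp(NumericMatrix w, NumericVector pop, IntegerVector active_from,
                     IntegerVector copy_src, double b, double dcost, int T,
                     int seed, bool keep_history) {
  const int n = w.nrow();
  rng_t rng((uint64_t) seed);

  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0.0) nb[i].push_back(j);

  std::vector< std::vector<int> > V(n);
  for (int i = 0; i < n; ++i)
    if (active_from[i] == 0) V[i].push_back(0);

  std::vector<int> birth_node(1, -1), birth_time(1, 0), death_time(1, -1);
  std::vector<int> alive(1, 0);
  List history;
  if (keep_history) history = List(T);

  for (int t = 1; t <= T; ++t) {
    std::vector< std::vector<int> > newV(n);
    for (int i = 0; i < n; ++i) {
      bool active = (active_from[i] == 0) || (active_from[i] < t);
      if (!active) continue;

      // wscore over existing candidates (ascending id => deterministic order)
      std::map<int, double> score;
      for (int c : V[i]) score[c] += w(i, i) / (double) V[i].size();
      for (int j : nb[i]) {
        if (V[j].empty()) continue;  // not yet active
        double inc = w(i, j) / (double) V[j].size();
        for (int c : V[j]) score[c] += inc;
      }

      std::vector<int> cand;
      std::vector<double> ws;
      for (std::map<int, double>::iterator it = score.begin(); it != score.end(); ++it) {
        cand.push_back(it->first);
        ws.push_back(it->second);
      }
      // fresh new-word token, materialized only if kept; b = 0 disables
      // innovation entirely rather than offering a zero-score novelty
      if (b * pop[i] > 0.0) {
        cand.push_back(-1);
        ws.push_back(b * pop[i]);
      }

      std::vector<int> pick = sample_subset_core(ws, dcost, rng);
      std::vector<int> &vi = newV[i];
      for (int idx : pick) {
        int c = cand[idx];
        if (c == -1) {
          c = (int) birth_node.size();
          birth_node.push_back(i);
          birth_time.push_back(t);
          death_time.push_back(-1);
          alive.push_back(c);
        }
        vi.push_back(c);
      }
    }

    // copy events scheduled at the end of this step
    for (int i = 0; i < n; ++i)
      if (active_from[i] == t) newV[i] = newV[copy_src[i]];

    V.swap(newV);

    // deaths: first step at which a cognate is held by no node
    std::vector<char> present(birth_node.size(), 0);
    for (int i = 0; i < n; ++i)
      for (int c : V[i]) present[c] = 1;
    std::vector<int> still;
    still.reserve(alive.size());
    for (int c : alive) {
      if (present[c]) still.push_back(c);
      else death_time[c] = t;
    }
    alive.swap(still);

    if (keep_history) {
      List snap(n);
      for (int i = 0; i < n; ++i) {
        IntegerVector iv(V[i].size());
        for (size_t k = 0; k < V[i].size(); ++k) iv[k] = V[i][k] + 1;
        snap[i] = iv;
      }
      history[t - 1] = snap;
    }
  }

  List fin(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector iv(V[i].size());
    for (size_t k = 0; k < V[i].size(); ++k) iv[k] = V[i][k] + 1;
    fin[i] = iv;
  }
  const int ncog = (int) birth_node.size();
  IntegerVector rid(ncog), rbn(ncog), rbt(ncog), rdt(ncog);
  for (int c = 0; c < ncog; ++c) {
    rid[c] = c + 1;
    rbn[c] = (birth_node[c] < 0) ? NA_INTEGER : birth_node[c] + 1;
    rbt[c] = birth_time[c];
    rdt[c] = (death_time[c] < 0) ? NA_INTEGER : death_time[c];
  }
  List out = List::create(
    _["final"] = fin,
    _["cognate_id"] = rid,
    _["birth_node"] = rbn,
    _["birth_time"] = rbt,
    _["death_time"] = rdt);
  if (keep_history) out["history"] = history;
  return out;
}
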