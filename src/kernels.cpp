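#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Multinomial log-likelihood of one node given a parent configuration,
// reading columns of the encoded data matrix in place.
// X: n x p matrix of 1-based integer codes (no NAs); xcol: 1-based column of
// the node; r: declared level count of the node; pcols: 1-based parent
// columns; plv: declared level counts of the parents; rows: optional 1-based
// row subset (length 0 = all rows), used for bootstrap resamples without
// materializing the resampled matrix.
// Returns loglik = sum_jk N_jk log(N_jk / N_j) with 0 log 0 = 0, and the
// declared number of parent configurations q = prod(plv) (q = 1 when k = 0).
// [[Rcpp::export]]
List cpp_local_loglik(IntegerMatrix X, int xcol, int r, IntegerVector pcols,
                      IntegerVector plv, IntegerVector rows) {
  const int ntot = X.nrow();
  const int k = pcols.size();
  const bool sub = rows.size() > 0;
  const int n = sub ? rows.size() : ntot;
  const int *rw = rows.begin();
  double q = 1.0;
  for (int j = 0; j < k; ++j) q *= (double) plv[j];
  if (q * r > 2e7) stop("parent configuration space too large (%g cells)", q * r);
  const int64_t qi = (int64_t) q;

  // mixed-radix parent configuration per observation, FIRST parent fastest
  std::vector<int64_t> cfg((size_t) n, 0);
  int64_t mult = 1;
  for (int j = 0; j < k; ++j) {
    const int *pj = X.begin() + (int64_t)(pcols[j] - 1) * ntot;
    if (sub) {
      for (int i = 0; i < n; ++i) cfg[i] += (int64_t)(pj[rw[i] - 1] - 1) * mult;
    } else {
      for (int i = 0; i < n; ++i) cfg[i] += (int64_t)(pj[i] - 1) * mult;
    }
    mult *= plv[j];
  }
  const int *xv = X.begin() + (int64_t)(xcol - 1) * ntot;
  std::vector<double> njk((size_t)(qi * r), 0.0);
  std::vector<double> nj((size_t) qi, 0.0);
  if (sub) {
    for (int i = 0; i < n; ++i) {
      njk[(size_t)(cfg[i] * r + (xv[rw[i] - 1] - 1))] += 1.0;
      nj[(size_t) cfg[i]] += 1.0;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      njk[(size_t)(cfg[i] * r + (xv[i] - 1))] += 1.0;
      nj[(size_t) cfg[i]] += 1.0;
    }
  }
  double ll = 0.0;
  for (int64_t c = 0; c < qi; ++c) {
    if (nj[(size_t) c] == 0.0) continue;
    const double lnj = std::log(nj[(size_t) c]);
    for (int s = 0; s < r; ++s) {
      double cnt = njk[(size_t)(c * r + s)];
      if (cnt > 0.0) ll += cnt * (std::log(cnt) - lnj);
    }
  }
  return List::create(_["loglik"] = ll, _["q"] = q);
}

// Counts N_jk for CPT fitting: returns q x r matrix (rows = parent configs in
// mixed-radix order with the FIRST parent varying fastest, cols = node levels).
// [[Rcpp::export]]
NumericMatrix cpp_cpt_counts(IntegerVector x, int r, IntegerMatrix P, IntegerVector plv) {
  const int n = x.size();
  const int k = P.ncol();
  double qd = 1.0;
  for (int j = 0; j < k; ++j) qd *= (double) plv[j];
  if (qd > 2e7) stop("parent configuration space too large");
  const int qi = (int) qd;
  NumericMatrix out(qi, r);
  for (int i = 0; i < n; ++i) {
    int64_t cfg = 0, mult = 1;
    for (int j = 0; j < k; ++j) {
      cfg += (int64_t)(P(i, j) - 1) * mult;
      mult *= plv[j];
    }
    out((int) cfg, x[i] - 1) += 1.0;
  }
  return out;
}

static inline bool mask_acyclic(const int p, const uint32_t *par) {
  // Kahn's algorithm on bitmask parent sets.
  uint32_t removed = 0;
  const uint32_t all = (p == 32) ? 0xffffffffu : ((1u << p) - 1u);
  for (int step = 0; step < p; ++step) {
    bool found = false;
    for (int i = 0; i < p; ++i) {
      if (removed & (1u << i)) continue;
      if ((par[i] & ~removed) == 0u) { removed |= (1u << i); found = true; break; }
    }
    if (!found) return false;
  }
  return removed == all;
}

// Exhaustive DAG search for p <= 5 nodes.
// scoretab: p x 2^p matrix; scoretab(i, m) = local score of node i with parent
// set given by bitmask m (entries with m containing i are ignored).
// Arc bit order: ordered pairs (i -> j), i != j, enumerated j-major then i
// (bit index = position in the list built as for(i) for(j)).
// Returns best score, number of DAGs enumerated, and all arc-masks attaining
// the best score (for tie-breaking in R).
// [[Rcpp::export]]
List cpp_exhaustive(NumericMatrix scoretab, int p) {
  if (p < 1 || p > 5) stop("exhaustive search supports 1..5 nodes");
  const int narcs = p * (p - 1);
  // arc index -> (from, to)
  std::vector<int> from(narcs), to(narcs);
  int a = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { from[a] = i; to[a] = j; ++a; }

  const uint64_t total = 1ull << narcs;
  double best = R_NegInf;
  double ndags = 0.0;
  std::vector<double> bestMasks;
  uint32_t par[5];
  for (uint64_t m = 0; m < total; ++m) {
    for (int i = 0; i < p; ++i) par[i] = 0u;
    for (int b = 0; b < narcs; ++b)
      if (m & (1ull << b)) par[to[b]] |= (1u << from[b]);
    if (!mask_acyclic(p, par)) continue;
    ndags += 1.0;
    double s = 0.0;
    for (int i = 0; i < p; ++i) s += scoretab(i, (int) par[i]);
    if (s > best + 1e-12) {
      best = s;
      bestMasks.clear();
      bestMasks.push_back((double) m);
    } else if (s >= best - 1e-12) {
      if (bestMasks.size() < 64) bestMasks.push_back((double) m);
    }
  }
  return List::create(_["best_score"] = best, _["n_dags"] = ndags,
                      _["best_masks"] = wrap(bestMasks));
}
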