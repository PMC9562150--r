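#include <Rcpp.h>
using namespace Rcpp;

// Mahalanobis quadratic form between the trait rows held at slots a and b.
static inline double quad_form(const NumericMatrix& X, const NumericMatrix& Sinv,
                               int a, int b) {
  const int d = X.ncol();
  double out = 0.0;
  for (int u = 0; u < d; ++u) {
    const double du = X(a, u) - X(b, u);
    for (int v = 0; v < d; ++v) {
      out += du * Sinv(u, v) * (X(a, v) - X(b, v));
    }
  }
  return out;
}

// Greedy swap annealer for the social-selection level beta = 1 - mu/mu_random.
// Nodes carry full (trait vector, hesitancy) tuples via the permutation perm:
// perm[i] is the tuple slot currently sitting at node i. A proposal exchanges
// the tuples of two uniformly chosen nodes and is kept only if it moves beta
// strictly closer to beta_target. Edge list is 0-based here; the R wrapper
// converts. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List anneal_swaps_cpp(IntegerMatrix edges, NumericMatrix X, NumericMatrix Sinv,
                      double mu_random, double beta_target, double tol,
                      int max_swaps) {
  const int n = X.nrow();
  const int m = edges.nrow();

  // incidence lists
  std::vector<std::vector<int>> inc(n);
  for (int e = 0; e < m; ++e) {
    inc[edges(e, 0)].push_back(e);
    inc[edges(e, 1)].push_back(e);
  }

  IntegerVector perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  double mu_sum = 0.0;
  for (int e = 0; e < m; ++e) mu_sum += quad_form(X, Sinv, edges(e, 0), edges(e, 1));

  double beta = 1.0 - (mu_sum / m) / mu_random;
  int accepted = 0, proposed = 0;
  bool converged = std::abs(beta - beta_target) <= tol;

  std::vector<int> touched;
  touched.reserve(32);

  while (!converged && proposed < max_swaps) {
    ++proposed;
    int i = (int)std::floor(unif_rand() * n);
    int j = (int)std::floor(unif_rand() * n);
    if (i >= n) i = n - 1;
    if (j >= n) j = n - 1;
    if (i == j) continue;

    touched.clear();
    for (int e : inc[i]) touched.push_back(e);
    for (int e : inc[j]) {
      bool dup = false;
      for (int f : inc[i]) if (f == e) { dup = true; break; }
      if (!dup) touched.push_back(e);
    }

    double before = 0.0;
    for (int e : touched) before += quad_form(X, Sinv, perm[edges(e, 0)], perm[edges(e, 1)]);

    std::swap(perm[i], perm[j]);
    double after = 0.0;
    for (int e : touched) after += quad_form(X, Sinv, perm[edges(e, 0)], perm[edges(e, 1)]);

    const double mu_new = mu_sum + (after - before);
    const double beta_new = 1.0 - (mu_new / m) / mu_random;

    if (std::abs(beta_new - beta_target) < std::abs(beta - beta_target)) {
      mu_sum = mu_new;
      beta = beta_new;
      ++accepted;
      converged = std::abs(beta - beta_target) <= tol;
    } else {
      std::swap(perm[i], perm[j]); // revert
    }
  }

  return List::create(_["perm"] = perm, _["beta"] = beta, _["mu"] = mu_sum / m,
                      _["swap_count"] = accepted, _["proposals"] = proposed,
                      _["converged"] = converged);
}
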