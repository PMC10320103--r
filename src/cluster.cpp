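// Stochastic sampler maximizing the clustering objective
//   sum_k sum_{u in U} max( sum_{r in R_k} Pu[r, u], 0 )
// by random single-read moves; improvements are always accepted and
// worsenings with probability exp(delta).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

double full_objective(const NumericMatrix& Pu, const std::vector<int>& asg, int K) {
  const int N = Pu.nrow(), U = Pu.ncol();
  std::vector<double> S((size_t)K * U, 0.0);
  for (int r = 0; r < N; ++r)
    for (int u = 0; u < U; ++u) S[(size_t)asg[r] * U + u] += Pu(r, u);
  double obj = 0.0;
  for (double v : S)
    if (v > 0) obj += v;
  return obj;
}

}  // namespace

// [[Rcpp::export(name = ".ca_cluster_cpp")]]
List ca_cluster_cpp(NumericMatrix Pu, int K, double T, int restarts, int seed) {
  const int N = Pu.nrow(), U = Pu.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("more clusters than reads");
  std::vector<int> best_asg(N, 0);
  double best_obj = -1.0;
  long Tl = (long)T;
  for (int rs = 0; rs < restarts; ++rs) {
    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 97ULL * rs + 1ULL);
    std::uniform_int_distribution<int> pick_cluster(0, K - 1);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::vector<int> asg(N);
    std::vector<std::vector<int>> members(K);
    for (int r = 0; r < N; ++r) {
      asg[r] = pick_cluster(rng);
      members[asg[r]].push_back(r);
    }
    std::vector<double> S((size_t)K * U, 0.0);
    for (int r = 0; r < N; ++r)
      for (int u = 0; u < U; ++u) S[(size_t)asg[r] * U + u] += Pu(r, u);
    double obj = 0.0;
    for (double v : S)
      if (v > 0) obj += v;
    std::vector<int> loc_best = asg;
    double loc_best_obj = obj;
    for (long t = 0; t < Tl; ++t) {
      int a = pick_cluster(rng), b = pick_cluster(rng);
      if (a == b || members[a].empty()) continue;
      std::uniform_int_distribution<int> pick_member(0, (int)members[a].size() - 1);
      int mi = pick_member(rng);
      int r = members[a][mi];
      double delta = 0.0;
      for (int u = 0; u < U; ++u) {
        double p = Pu(r, u);
        double sa = S[(size_t)a * U + u], sb = S[(size_t)b * U + u];
        delta += std::max(sa - p, 0.0) - std::max(sa, 0.0) +
                 std::max(sb + p, 0.0) - std::max(sb, 0.0);
      }
      bool accept = delta > 0 || unif(rng) < std::exp(delta);
      if (!accept) continue;
      for (int u = 0; u < U; ++u) {
        double p = Pu(r, u);
        S[(size_t)a * U + u] -= p;
        S[(size_t)b * U + u] += p;
      }
      members[a][mi] = members[a].back();
      members[a].pop_back();
      members[b].push_back(r);
      asg[r] = b;
      obj += delta;
      if (obj > loc_best_obj + 1e-12) {
        loc_best_obj = obj;
        loc_best = asg;
      }
    }
    double exact = full_objective(Pu, loc_best, K);
    if (exact > best_obj + 1e-12 || rs == 0) {
      if (exact > best_obj) {
        best_obj = exact;
        best_asg = loc_best;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["assignment"] = wrap(best_asg), _["objective"] = best_obj);
}
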