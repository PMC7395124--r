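// Stochastic frontier percolation on the residue network.
//
// One round: sources start perturbed (V=1, W=1) and enqueued. Popping node n
// (FIFO), its neighbours m are visited in ascending index; a neighbour not yet
// tested (W_m == 0) receives one uniform draw r in [0,1): W_m <- 1 always, and
// if r < P_nm the perturbation transmits (V_m <- 1, parent[m] <- n, enqueue m).
// Only perturbed nodes propagate; the round ends when the frontier empties.
// Uses R's RNG so results are reproducible through set.seed().

#include <Rcpp.h>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<std::vector<int> > nbr;   // 0-based, ascending
  std::vector<std::vector<double> > prob;
};

Net build_net(const List& neighbors, const List& probs) {
  Net net;
  net.n = neighbors.size();
  net.nbr.resize(net.n);
  net.prob.resize(net.n);
  for (int i = 0; i < net.n; ++i) {
    IntegerVector nb = neighbors[i];
    NumericVector pr = probs[i];
    if (nb.size() != pr.size()) stop("neighbor/probability length mismatch");
    net.nbr[i].assign(nb.begin(), nb.end());
    for (size_t k = 0; k < net.nbr[i].size(); ++k) net.nbr[i][k] -= 1;
    net.prob[i].assign(pr.begin(), pr.end());
  }
  return net;
}

// one percolation round; V/W/parent are reset inside. Returns perturbed nodes
// in order of perturbation (sources first, in given order).
void one_round(const Net& net, const std::vector<int>& src,
               std::vector<signed char>& V, std::vector<signed char>& W,
               std::vector<int>& parent, std::vector<int>& order) {
  std::fill(V.begin(), V.end(), 0);
  std::fill(W.begin(), W.end(), 0);
  std::fill(parent.begin(), parent.end(), -1);
  order.clear();
  std::queue<int> q;
  for (size_t k = 0; k < src.size(); ++k) {
    int s = src[k];
    if (!V[s]) { V[s] = 1; W[s] = 1; q.push(s); order.push_back(s); }
  }
  while (!q.empty()) {
    int n0 = q.front(); q.pop();
    const std::vector<int>& nb = net.nbr[n0];
    const std::vector<double>& pr = net.prob[n0];
    for (size_t k = 0; k < nb.size(); ++k) {
      int m = nb[k];
      if (W[m]) continue;
      W[m] = 1;
      double r = unif_rand();
      if (r < pr[k]) {
        V[m] = 1;
        parent[m] = n0;
        q.push(m);
        order.push_back(m);
      }
    }
  }
}

std::vector<int> as_src(const IntegerVector& source, int n) {
  std::vector<int> src;
  for (int k = 0; k < source.size(); ++k) {
    int s = source[k] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    src.push_back(s);
  }
  if (src.empty()) stop("source must be non-empty");
  return src;
}

}  // namespace

// [[Rcpp::export]]
List cpp_propagate_once(List neighbors, List probs, IntegerVector source) {
  Net net = build_net(neighbors, probs);
  std::vector<int> src = as_src(source, net.n);
  std::vector<signed char> V(net.n), W(net.n);
  std::vector<int> parent(net.n), order;
  one_round(net, src, V, W, parent, order);
  IntegerVector pert(order.size()), par(net.n);
  for (size_t k = 0; k < order.size(); ++k) pert[k] = order[k] + 1;
  for (int i = 0; i < net.n; ++i) par[i] = parent[i] + 1;  // 0 = none
  return List::create(_["perturbed"] = pert, _["parent"] = par);
}

// [[Rcpp::export]]
NumericVector cpp_aci_counts(List neighbors, List probs, IntegerVector source,
                             int n_rounds) {
  Net net = build_net(neighbors, probs);
  std::vector<int> src = as_src(source, net.n);
  std::vector<signed char> V(net.n), W(net.n);
  std::vector<int> parent(net.n), order;
  std::vector<double> counts(net.n, 0.0);
  for (int r = 0; r < n_rounds; ++r) {
    one_round(net, src, V, W, parent, order);
    for (int i = 0; i < net.n; ++i)
      if (V[i]) counts[i] += 1.0;
  }
  return NumericVector(counts.begin(), counts.end());
}

// [[Rcpp::export]]
List cpp_sample_pathways(List neighbors, List probs, IntegerVector source,
                         IntegerVector target, int n_rounds) {
  Net net = build_net(neighbors, probs);
  std::vector<int> src = as_src(source, net.n);
  std::vector<signed char> is_target(net.n, 0);
  for (int k = 0; k < target.size(); ++k) {
    int t = target[k] - 1;
    if (t < 0 || t >= net.n) stop("target index out of range");
    is_target[t] = 1;
  }
  std::vector<signed char> V(net.n), W(net.n);
  std::vector<int> parent(net.n), order;
  std::map<std::vector<int>, int> tally;
  int reached = 0;
  for (int r = 0; r < n_rounds; ++r) {
    one_round(net, src, V, W, parent, order);
    // earliest-perturbed target node this round
    int hit = -1;
    for (size_t k = 0; k < order.size(); ++k)
      if (is_target[order[k]]) { hit = order[k]; break; }
    if (hit < 0) continue;
    ++reached;
    std::vector<int> path;
    for (int v = hit; v >= 0; v = parent[v]) path.push_back(v);
    std::reverse(path.begin(), path.end());   // source ... target
    tally[path] += 1;
  }
  List paths(tally.size());
  IntegerVector counts(tally.size());
  int k = 0;
  for (std::map<std::vector<int>, int>::const_iterator it = tally.begin();
       it != tally.end(); ++it, ++k) {
    IntegerVector p(it->first.size());
    for (size_t j = 0; j < it->first.size(); ++j) p[j] = it->first[j] + 1;
    paths[k] = p;
    counts[k] = it->second;
  }
  return List::create(_["paths"] = paths, _["counts"] = counts,
                      _["reached"] = reached);
}
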