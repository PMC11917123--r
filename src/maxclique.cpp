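// Branch-and-bound maximum clique with a greedy-colouring bound and a
// node-expansion budget. Used for maximum-common-substructure search on
// modular product graphs: vertices are atom pairs, a maximum clique is a
// maximum common (connected or disconnected) substructure.
//
// Deterministic: vertices are explored in their input order and the first
// maximum-sized clique found is kept, so results are reproducible across
// runs for a fixed input ordering.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Search {
  int n;
  std::vector<std::vector<char> > adj;
  std::vector<int> best;
  std::vector<int> cur;
  long budget;
  long expansions;
  bool timed_out;

  // greedy colouring of P; returns vertices reordered by colour class with
  // parallel colour numbers (1-based), used as the bound
  void colour(const std::vector<int>& P, std::vector<int>& ordered,
              std::vector<int>& colours) const {
    std::vector<std::vector<int> > classes;
    for (size_t i = 0; i < P.size(); ++i) {
      int v = P[i];
      size_t k = 0;
      for (; k < classes.size(); ++k) {
        bool ok = true;
        for (size_t j = 0; j < classes[k].size(); ++j) {
          if (adj[v][classes[k][j]]) { ok = false; break; }
        }
        if (ok) break;
      }
      if (k == classes.size()) classes.push_back(std::vector<int>());
      classes[k].push_back(v);
    }
    ordered.clear(); colours.clear();
    for (size_t k = 0; k < classes.size(); ++k) {
      for (size_t j = 0; j < classes[k].size(); ++j) {
        ordered.push_back(classes[k][j]);
        colours.push_back((int)k + 1);
      }
    }
  }

  void expand(const std::vector<int>& P) {
    if (timed_out) return;
    if (++expansions > budget) { timed_out = true; return; }
    std::vector<int> ordered, colours;
    colour(P, ordered, colours);
    for (int i = (int)ordered.size() - 1; i >= 0; --i) {
      if ((int)cur.size() + colours[i] <= (int)best.size()) return;
      int v = ordered[i];
      cur.push_back(v);
      std::vector<int> P2;
      for (int j = 0; j < i; ++j) {
        if (adj[v][ordered[j]]) P2.push_back(ordered[j]);
      }
      if (P2.empty()) {
        if (cur.size() > best.size()) best = cur;
      } else {
        expand(P2);
      }
      cur.pop_back();
      if (timed_out) return;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".lk_max_clique")]]
List lk_max_clique(LogicalMatrix adjacency, double budget) {
  int n = adjacency.nrow();
  Search s;
  s.n = n;
  s.adj.assign(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      s.adj[i][j] = adjacency(i, j) ? 1 : 0;
  s.budget = (long)budget;
  s.expansions = 0;
  s.timed_out = false;
  std::vector<int> P(n);
  for (int i = 0; i < n; ++i) P[i] = i;
  if (n > 0) s.expand(P);
  IntegerVector clique(s.best.size());
  for (size_t i = 0; i < s.best.size(); ++i) clique[i] = s.best[i] + 1;
  return List::create(_["clique"] = clique,
                      _["expansions"] = (double)s.expansions,
                      _["timed_out"] = s.timed_out);
}
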