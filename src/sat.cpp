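// Iterative DPLL SAT solver with two-watched-literal propagation,
// randomized decision order/polarity (xorshift, seeded) and model
// enumeration via blocking clauses over a designated variable subset.
// Instances here are small (hundreds of variables): no clause learning.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cstdlib>

namespace {

struct Solver {
  int nv;
  std::vector<std::vector<int>> clauses;   // size >= 2 each
  std::vector<int> units;                  // unit literals from input
  std::vector<std::vector<int>> watchers;  // literal index -> clause ids
  std::vector<signed char> assign;         // 1..nv: 0 free, +1 true, -1 false
  std::vector<int> trail;
  std::vector<int> lim;                    // trail positions of decisions
  std::vector<char> tried;                 // second branch taken?
  uint64_t rng;

  explicit Solver(int nvars, uint64_t seed) : nv(nvars), rng(seed * 2654435769ULL + 1ULL) {
    assign.assign(nv + 1, 0);
    watchers.assign(2 * nv, {});
  }

  uint32_t rnd() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return (uint32_t)(rng >> 32);
  }

  static int lidx(int l) { return l > 0 ? ((l - 1) << 1) : (((-l - 1) << 1) | 1); }

  int lval(int l) const {
    int v = l > 0 ? l : -l;
    int a = assign[v];
    if (a == 0) return 0;
    return ((l > 0) == (a > 0)) ? 1 : -1;
  }

  void add_clause(const std::vector<int>& c) {
    if (c.size() == 1) { units.push_back(c[0]); return; }
    int ci = (int)clauses.size();
    clauses.push_back(c);
    watchers[lidx(c[0])].push_back(ci);
    watchers[lidx(c[1])].push_back(ci);
  }

  bool enqueue(int l) {
    int v = l > 0 ? l : -l;
    int want = l > 0 ? 1 : -1;
    if (assign[v] != 0) return assign[v] == want;
    assign[v] = (signed char)want;
    trail.push_back(l);
    return true;
  }

  bool propagate(size_t& qhead) {
    while (qhead < trail.size()) {
      int l = trail[qhead++];
      int fl = -l;                       // literal that just became false
      std::vector<int>& ws = watchers[lidx(fl)];
      size_t i = 0;
      while (i < ws.size()) {
        int ci = ws[i];
        std::vector<int>& c = clauses[ci];
        if (c[0] == fl) std::swap(c[0], c[1]);
        // c[1] == fl
        if (lval(c[0]) == 1) { ++i; continue; }
        bool moved = false;
        for (size_t k = 2; k < c.size(); ++k) {
          if (lval(c[k]) != -1) {
            std::swap(c[1], c[k]);
            watchers[lidx(c[1])].push_back(ci);
            ws[i] = ws.back(); ws.pop_back();
            moved = true;
            break;
          }
        }
        if (moved) continue;
        if (lval(c[0]) == -1) return false;   // conflict
        if (!enqueue(c[0])) return false;     // unit
        ++i;
      }
    }
    return true;
  }

  // 1 = SAT (assign holds a model), 0 = UNSAT, -1 = conflict budget exceeded
  int solve(const std::vector<int>& assumptions, long max_conflicts) {
    size_t qhead = 0;
    long conflicts = 0;
    for (int u : units) if (!enqueue(u)) return 0;
    for (int a : assumptions) if (!enqueue(a)) return 0;
    std::vector<int> free_vars;
    free_vars.reserve(nv);
    for (;;) {
      if (!propagate(qhead)) {
        if (max_conflicts > 0 && ++conflicts > max_conflicts) return -1;
        // backtrack chronologically
        for (;;) {
          if (lim.empty()) return 0;
          int dpos = lim.back();
          int dlit = trail[dpos];
          char was = tried.back();
          for (int t = (int)trail.size() - 1; t >= dpos; --t)
            assign[std::abs(trail[t])] = 0;
          trail.resize(dpos);
          qhead = trail.size();
          lim.pop_back(); tried.pop_back();
          if (!was) {
            lim.push_back((int)trail.size());
            tried.push_back(1);
            enqueue(-dlit);
            break;
          }
        }
        continue;
      }
      free_vars.clear();
      for (int v = 1; v <= nv; ++v) if (assign[v] == 0) free_vars.push_back(v);
      if (free_vars.empty()) return 1;
      int v = free_vars[rnd() % free_vars.size()];
      int pol = (rnd() & 1u) ? 1 : -1;
      lim.push_back((int)trail.size());
      tried.push_back(0);
      enqueue(pol * v);
    }
  }
};

std::vector<std::vector<int>> unpack(const Rcpp::IntegerVector& lits,
                                     const Rcpp::IntegerVector& lens) {
  std::vector<std::vector<int>> out;
  out.reserve(lens.size());
  int p = 0;
  for (int i = 0; i < lens.size(); ++i) {
    int n = lens[i];
    if (n <= 0) Rcpp::stop("empty clause in input");
    std::vector<int> c(n);
    for (int k = 0; k < n; ++k) c[k] = lits[p + k];
    p += n;
    out.push_back(std::move(c));
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_sat_solve(int nvars, Rcpp::IntegerVector lits, Rcpp::IntegerVector lens,
                         int seed, Rcpp::IntegerVector assumptions,
                         double max_conflicts = 0) {
  std::vector<std::vector<int>> cs = unpack(lits, lens);
  Solver s(nvars, (uint64_t)(uint32_t)seed);
  for (auto& c : cs) s.add_clause(c);
  std::vector<int> as(assumptions.begin(), assumptions.end());
  int st = s.solve(as, (long)max_conflicts);
  Rcpp::IntegerVector model(nvars, NA_INTEGER);
  if (st == 1)
    for (int v = 1; v <= nvars; ++v) model[v - 1] = s.assign[v] > 0 ? 1 : 0;
  std::string status = st == 1 ? "sat" : (st == 0 ? "unsat" : "unknown");
  return Rcpp::List::create(Rcpp::Named("satisfiable") = (st == 1),
                            Rcpp::Named("status") = status,
                            Rcpp::Named("model") = model);
}

// Enumerate up to max_models distinct models, where distinctness is over the
// projection onto block_vars: after each model, a clause requiring at least
// one block_var currently true to become false is added.
// [[Rcpp::export]]
Rcpp::List cpp_sat_enumerate(int nvars, Rcpp::IntegerVector lits, Rcpp::IntegerVector lens,
                             int seed, int max_models, Rcpp::IntegerVector block_vars,
                             Rcpp::IntegerVector assumptions) {
  std::vector<std::vector<int>> cs = unpack(lits, lens);
  std::vector<int> as(assumptions.begin(), assumptions.end());
  std::vector<int> bv(block_vars.begin(), block_vars.end());
  Rcpp::List models;
  bool complete = false;
  uint64_t sseed = (uint64_t)(uint32_t)seed;
  for (int m = 0; m < max_models; ++m) {
    Solver s(nvars, sseed + (uint64_t)m * 0x9E3779B97F4A7C15ULL);
    for (auto& c : cs) s.add_clause(c);
    if (s.solve(as, 0) != 1) { complete = true; break; }
    Rcpp::IntegerVector model(nvars);
    for (int v = 1; v <= nvars; ++v) model[v - 1] = s.assign[v] > 0 ? 1 : 0;
    models.push_back(model);
    std::vector<int> block;
    for (int v : bv) if (s.assign[v] > 0) block.push_back(-v);
    if (block.empty()) { complete = true; break; }  // unique projection
    cs.push_back(block);
  }
  return Rcpp::List::create(Rcpp::Named("models") = models,
                            Rcpp::Named("complete") = complete);
}
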