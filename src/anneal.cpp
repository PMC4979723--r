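#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Deterministic RNG helpers built on the standardized mt19937 core so that
// results are identical across platforms (the std distributions are
// implementation-defined, so we draw uniforms ourselves).
namespace {

struct Rng {
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  double unif() {  // in [0, 1)
    uint64_t a = eng(), b = eng();
    return ((a >> 5) * 67108864.0 + (b >> 6)) / 9007199254740992.0;
  }
  int unif_int(int n) {  // in [0, n)
    return static_cast<int>(unif() * n) % n;
  }
};

struct Problem {
  int n_pu;
  std::vector<double> cost;
  std::vector<int> status;            // 0 available, 1 locked_in, 2 locked_out
  std::vector<int> pu_ptr;            // CSC over PUs into feat/amt
  std::vector<int> feat;
  std::vector<double> amt;
  std::vector<double> target;
  std::vector<double> spf;
  double cost_scale;
  double blm;
  std::vector<int> adj_ptr;           // per-PU neighbour lists
  std::vector<int> adj_to;
  std::vector<double> adj_len;
};

struct State {
  std::vector<int> sel;               // 0/1 per PU
  std::vector<double> achieved;       // per feature
  double cost_sum, penalty, boundary;
};

double penalty_term(const Problem& p, int f, double achieved) {
  if (p.target[f] <= 0) return 0.0;
  double shortfall = p.target[f] - achieved;
  if (shortfall <= 0) return 0.0;
  return p.spf[f] * p.cost_scale * shortfall / p.target[f];
}

// objective change from flipping PU i (add if sel[i]==0, drop otherwise)
double flip_delta(const Problem& p, const State& s, int i) {
  double sign = s.sel[i] ? -1.0 : 1.0;
  double d = sign * p.cost[i];
  for (int k = p.pu_ptr[i]; k < p.pu_ptr[i + 1]; ++k) {
    int f = p.feat[k];
    double before = penalty_term(p, f, s.achieved[f]);
    double after = penalty_term(p, f, s.achieved[f] + sign * p.amt[k]);
    d += after - before;
  }
  if (p.blm != 0) {
    double db = 0.0;
    for (int k = p.adj_ptr[i]; k < p.adj_ptr[i + 1]; ++k) {
      // an edge to a selected neighbour flips between exterior and interior
      db += (s.sel[p.adj_to[k]] ? -1.0 : 1.0) * p.adj_len[k];
    }
    d += p.blm * sign * db;
  }
  return d;
}

void apply_flip(const Problem& p, State& s, int i) {
  double sign = s.sel[i] ? -1.0 : 1.0;
  s.cost_sum += sign * p.cost[i];
  for (int k = p.pu_ptr[i]; k < p.pu_ptr[i + 1]; ++k) {
    int f = p.feat[k];
    s.penalty -= penalty_term(p, f, s.achieved[f]);
    s.achieved[f] += sign * p.amt[k];
    s.penalty += penalty_term(p, f, s.achieved[f]);
  }
  if (p.blm != 0) {
    double db = 0.0;
    for (int k = p.adj_ptr[i]; k < p.adj_ptr[i + 1]; ++k)
      db += (s.sel[p.adj_to[k]] ? -1.0 : 1.0) * p.adj_len[k];
    s.boundary += sign * db;
  }
  s.sel[i] = 1 - s.sel[i];
}

State init_state(const Problem& p, Rng& rng, double init_prob) {
  State s;
  s.sel.assign(p.n_pu, 0);
  s.achieved.assign(p.target.size(), 0.0);
  s.cost_sum = 0.0;
  s.boundary = 0.0;
  for (int i = 0; i < p.n_pu; ++i) {
    bool take = (p.status[i] == 1) ||
                (p.status[i] == 0 && rng.unif() < init_prob);
    if (take) {
      s.sel[i] = 1;
      s.cost_sum += p.cost[i];
      for (int k = p.pu_ptr[i]; k < p.pu_ptr[i + 1]; ++k)
        s.achieved[p.feat[k]] += p.amt[k];
    }
  }
  s.penalty = 0.0;
  for (size_t f = 0; f < p.target.size(); ++f)
    s.penalty += penalty_term(p, (int)f, s.achieved[f]);
  if (p.blm != 0) {
    for (int i = 0; i < p.n_pu; ++i)
      for (int k = p.adj_ptr[i]; k < p.adj_ptr[i + 1]; ++k)
        if (p.adj_to[k] > i && (s.sel[i] != s.sel[p.adj_to[k]]))
          s.boundary += p.adj_len[k];
  }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericVector cost, IntegerVector status,
                IntegerVector pu_ptr, IntegerVector feat, NumericVector amt,
                NumericVector target, NumericVector spf, double cost_scale,
                double blm, IntegerVector adj_ptr, IntegerVector adj_to,
                NumericVector adj_len, int n_iter, int seed,
                double init_prob) {
  Problem p;
  p.n_pu = cost.size();
  p.cost = as<std::vector<double>>(cost);
  p.status = as<std::vector<int>>(status);
  p.pu_ptr = as<std::vector<int>>(pu_ptr);
  p.feat = as<std::vector<int>>(feat);
  p.amt = as<std::vector<double>>(amt);
  p.target = as<std::vector<double>>(target);
  p.spf = as<std::vector<double>>(spf);
  p.cost_scale = cost_scale;
  p.blm = blm;
  p.adj_ptr = as<std::vector<int>>(adj_ptr);
  p.adj_to = as<std::vector<int>>(adj_to);
  p.adj_len = as<std::vector<double>>(adj_len);

  std::vector<int> avail;
  for (int i = 0; i < p.n_pu; ++i) if (p.status[i] == 0) avail.push_back(i);

  Rng rng(static_cast<uint32_t>(seed));
  State s = init_state(p, rng, init_prob);

  if (!avail.empty()) {
    // initial temperature from the spread of proposal deltas
    int n_probe = std::min<int>(1000, 20 * (int)avail.size());
    double acc = 0.0;
    for (int t = 0; t < n_probe; ++t)
      acc += std::abs(flip_delta(p, s, avail[rng.unif_int((int)avail.size())]));
    double t0 = n_probe > 0 ? acc / n_probe : 1.0;
    if (t0 <= 0) t0 = 1.0;
    double alpha = std::pow(1e-6, 1.0 / std::max(1, n_iter));
    double temp = t0;
    // proposals mix single flips with selected<->unselected swaps; swaps let
    // the chain cross the penalty barriers separating near-feasible sets at
    // low temperature, where a remove-then-add path is effectively frozen
    for (int it = 0; it < n_iter; ++it) {
      int i = avail[rng.unif_int((int)avail.size())];
      if (rng.unif() < 0.3) {
        int j = avail[rng.unif_int((int)avail.size())];
        if (s.sel[i] == s.sel[j]) {
          double d = flip_delta(p, s, i);
          if (d <= 0 || rng.unif() < std::exp(-d / temp)) apply_flip(p, s, i);
        } else {
          double d1 = flip_delta(p, s, i);
          apply_flip(p, s, i);
          double d2 = flip_delta(p, s, j);
          double d = d1 + d2;
          if (d <= 0 || rng.unif() < std::exp(-d / temp)) {
            apply_flip(p, s, j);
          } else {
            apply_flip(p, s, i);  // revert
          }
        }
      } else {
        double d = flip_delta(p, s, i);
        if (d <= 0 || rng.unif() < std::exp(-d / temp)) apply_flip(p, s, i);
      }
      temp *= alpha;
    }
    // greedy clean-up: single flips (removals first), then improving
    // one-for-one exchanges, until no move lowers the objective
    bool improved = true;
    while (improved) {
      improved = false;
      for (int i : avail) {
        if (s.sel[i] && flip_delta(p, s, i) < 0) {
          apply_flip(p, s, i);
          improved = true;
        }
      }
      for (int i : avail) {
        if (!s.sel[i] && flip_delta(p, s, i) < 0) {
          apply_flip(p, s, i);
          improved = true;
        }
      }
      for (int i : avail) {
        if (!s.sel[i]) continue;
        double d1 = flip_delta(p, s, i);
        apply_flip(p, s, i);
        int best_j = -1;
        double best_d2 = -d1;  // need d1 + d2 < 0
        for (int j : avail) {
          if (s.sel[j]) continue;
          double d2 = flip_delta(p, s, j);
          if (d2 < best_d2 - 1e-12) {
            best_d2 = d2;
            best_j = j;
          }
        }
        if (best_j >= 0) {
          apply_flip(p, s, best_j);
          improved = true;
        } else {
          apply_flip(p, s, i);  // revert removal
        }
      }
    }
  }

  double objective = s.cost_sum + s.penalty + p.blm * s.boundary;
  LogicalVector selected(p.n_pu);
  for (int i = 0; i < p.n_pu; ++i) selected[i] = s.sel[i] == 1;
  return List::create(_["selected"] = selected, _["objective"] = objective,
                      _["achieved"] = NumericVector(s.achieved.begin(),
                                                    s.achieved.end()));
}
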