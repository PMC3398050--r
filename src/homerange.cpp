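// Core combinatorics of home-range establishment on a toroidal grid.
//
// Cells are addressed 0-based, row-major (idx = row * ncol + col).
// Adjacency is rook (4-neighbour) with wrap-around on both axes.
// A coverage vector `cov` counts, for every cell, the number of home
// ranges (including the focal one, where it exists) that contain it,
// so the overlap discount 1/(1 + N_c) for a cell inside the focal
// range is 1/cov[c], and for a cell being considered for addition it
// is 1/(1 + cov[c]).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Torus {
  int nr, nc, n;
  std::vector<int> nb;  // 4 * n neighbour indices (up, down, left, right)
  Torus(int nr_, int nc_) : nr(nr_), nc(nc_), n(nr_ * nc_), nb(4 * n) {
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int i = r * nc + c;
        nb[4 * i + 0] = ((r + nr - 1) % nr) * nc + c;
        nb[4 * i + 1] = ((r + 1) % nr) * nc + c;
        nb[4 * i + 2] = r * nc + (c + nc - 1) % nc;
        nb[4 * i + 3] = r * nc + (c + 1) % nc;
      }
    }
  }
};

// Deterministic, platform-independent RNG (Mersenne Twister output is
// standardized; we avoid std::uniform_int_distribution, which is not).
struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  int uniform_int(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
};

inline double benefit_of(double S, double p1, double p2, int form) {
  if (S <= 0.0) return 0.0;
  if (form == 0) return p1 * (1.0 - std::exp(-p2 * S));  // exponential saturation
  return p1 * S / (p2 + S);                              // hyperbolic alternative
}

inline double net_value_of(double S, int area, double p1, double p2, double p3,
                           int form) {
  return benefit_of(S, p1, p2, form) - p3 - std::sqrt(static_cast<double>(area));
}

struct HRSet {
  std::vector<int> cells;        // sorted ascending
  std::vector<char> memb;        // length n membership mask
  explicit HRSet(int n) : memb(n, 0) {}
  void add(int c) {
    cells.insert(std::lower_bound(cells.begin(), cells.end(), c), c);
    memb[c] = 1;
  }
  void remove(int c) {
    cells.erase(std::lower_bound(cells.begin(), cells.end(), c));
    memb[c] = 0;
  }
};


// scratch buffers reused across greedy steps (stamped marking avoids
// clearing arrays between uses)
struct Workspace {
  std::vector<int> seen, infro;
  int stamp_seen = 0, stamp_infro = 0;
  std::vector<int> frontier, stack;
  explicit Workspace(int n) : seen(n, 0), infro(n, 0) {
    frontier.reserve(n);
    stack.reserve(n);
  }
};

// S with the focal range already counted in cov.
double range_S(const HRSet& rg, const std::vector<double>& V,
               const std::vector<int>& cov) {
  double S = 0.0;
  for (int c : rg.cells) S += V[c] / static_cast<double>(cov[c]);
  return S;
}

// Is the focal range still rook-connected when `skip1`/`skip2` are removed
// and the non-member cell `extra` (if >= 0) is added?
bool connected_without(const HRSet& rg, const Torus& T, int skip1, int skip2,
                       Workspace& ws, int extra = -1) {
  int m = static_cast<int>(rg.cells.size()) - (skip1 >= 0) - (skip2 >= 0) +
          (extra >= 0);
  if (m <= 0) return false;
  int start = extra;
  if (start < 0)
    for (int c : rg.cells)
      if (c != skip1 && c != skip2) { start = c; break; }
  ++ws.stamp_seen;
  ws.stack.clear();
  ws.stack.push_back(start);
  ws.seen[start] = ws.stamp_seen;
  int reached = 0;
  while (!ws.stack.empty()) {
    int c = ws.stack.back();
    ws.stack.pop_back();
    ++reached;
    for (int k = 0; k < 4; ++k) {
      int u = T.nb[4 * c + k];
      if ((rg.memb[u] || u == extra) && ws.seen[u] != ws.stamp_seen &&
          u != skip1 && u != skip2) {
        ws.seen[u] = ws.stamp_seen;
        ws.stack.push_back(u);
      }
    }
  }
  return reached == m;
}

struct Move {
  int kind;        // 0 none, 1 add1, 2 add2, 3 rem1, 4 rem2, 5 swap
  int a, b;        // affected cells (for swap: a added, b removed)
  double nv;
};


// One greedy step: enumerate all legal moves (single/pair add, single/pair
// remove), apply the one with maximal resulting net value if it strictly
// improves on the current value. Enumeration order is fixed (adds before
// removes, cells ascending), so ties resolve deterministically to the
// lexicographically first affected cell(s). Returns true if a move was made.
bool improve_once(HRSet& rg, std::vector<int>& cov, const std::vector<double>& V,
                  const Torus& T, double p1, double p2, double p3, int form,
                  int min_cells, Workspace& ws) {
  const double eps = 1e-12;
  int A = static_cast<int>(rg.cells.size());
  double S = range_S(rg, V, cov);
  double cur = net_value_of(S, A, p1, p2, p3, form);

  // frontier: non-member cells adjacent to the range (cells ascending, so
  // enumeration order is lexicographic in (row, col))
  ws.frontier.clear();
  ++ws.stamp_infro;
  for (int c : rg.cells) {
    for (int k = 0; k < 4; ++k) {
      int u = T.nb[4 * c + k];
      if (!rg.memb[u] && ws.infro[u] != ws.stamp_infro) {
        ws.infro[u] = ws.stamp_infro;
        ws.frontier.push_back(u);
      }
    }
  }
  std::sort(ws.frontier.begin(), ws.frontier.end());

  Move best{0, -1, -1, cur};
  auto consider = [&](int kind, int a, int b, double nv) {
    if (nv > best.nv + eps) best = Move{kind, a, b, nv};
  };

  // single additions
  for (int f : ws.frontier) {
    double S1 = S + V[f] / (1.0 + cov[f]);
    consider(1, f, -1, net_value_of(S1, A + 1, p1, p2, p3, form));
  }
  // ordered pairs of additions: the second cell must touch the augmented
  // range, i.e. be in the frontier or adjacent to the first added cell
  for (int f1 : ws.frontier) {
    double S1 = S + V[f1] / (1.0 + cov[f1]);
    auto try_second = [&](int f2) {
      double S2 = S1 + V[f2] / (1.0 + cov[f2]);
      consider(2, f1, f2, net_value_of(S2, A + 2, p1, p2, p3, form));
    };
    for (int f2 : ws.frontier)
      if (f2 != f1) try_second(f2);
    for (int k = 0; k < 4; ++k) {
      int u = T.nb[4 * f1 + k];
      if (!rg.memb[u] && ws.infro[u] != ws.stamp_infro && u != f1) try_second(u);
    }
  }
  // swaps (one cell added, one removed; two single-cell moves applied
  // jointly, area unchanged): the resulting range must stay connected.
  // Net value is computed first and the (costlier) connectivity check run
  // only for would-be improvements; the accepted move is identical to
  // eager checking because invalid candidates can never become `best`.
  for (int f : ws.frontier) {
    double S1 = S + V[f] / (1.0 + cov[f]);
    for (int c : rg.cells) {
      double S2 = S1 - V[c] / cov[c];
      double nv = net_value_of(S2, A, p1, p2, p3, form);
      if (nv > best.nv + eps && connected_without(rg, T, c, -1, ws, f))
        best = Move{5, f, c, nv};
    }
  }
  // single removals (connectivity and minimum size preserved)
  if (A - 1 >= min_cells) {
    for (int c : rg.cells) {
      if (!connected_without(rg, T, c, -1, ws)) continue;
      double S1 = S - V[c] / cov[c];
      consider(3, c, -1, net_value_of(S1, A - 1, p1, p2, p3, form));
    }
  }
  // pairs of removals: only the resulting range must be legal (connected,
  // >= min_cells) -- removing an articulation cell together with the cell
  // it would strand is a valid two-cell contraction
  if (A - 2 >= min_cells) {
    for (int c1 : rg.cells) {
      double S1 = S - V[c1] / cov[c1];
      for (int c2 : rg.cells) {
        if (c2 <= c1) continue;  // unordered: outcome symmetric in (c1, c2)
        double S2 = S1 - V[c2] / cov[c2];
        double nv = net_value_of(S2, A - 2, p1, p2, p3, form);
        if (nv > best.nv + eps && connected_without(rg, T, c1, c2, ws))
          best = Move{4, c1, c2, nv};
      }
    }
  }

  switch (best.kind) {
    case 1: rg.add(best.a); ++cov[best.a]; return true;
    case 2: rg.add(best.a); ++cov[best.a]; rg.add(best.b); ++cov[best.b]; return true;
    case 3: rg.remove(best.a); --cov[best.a]; return true;
    case 4: rg.remove(best.a); --cov[best.a]; rg.remove(best.b); --cov[best.b]; return true;
    case 5: rg.add(best.a); ++cov[best.a]; rg.remove(best.b); --cov[best.b]; return true;
    default: return false;
  }
}

std::vector<int> block_cells(int anchor, const Torus& T) {
  // 2x2 block anchored at its top-left cell, with toroidal wrap
  int r = anchor / T.nc, c = anchor % T.nc;
  int r2 = (r + 1) % T.nr, c2 = (c + 1) % T.nc;
  std::vector<int> out{r * T.nc + c, r * T.nc + c2, r2 * T.nc + c, r2 * T.nc + c2};
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());  // degenerate 1-wide grids
  return out;
}

// Best 2x2 anchor position by exhaustive scan given existing coverage.
int best_anchor(const std::vector<double>& V, const std::vector<int>& cov,
                const Torus& T, double p1, double p2, double p3, int form) {
  int best = 0;
  double best_nv = -std::numeric_limits<double>::infinity();
  for (int a = 0; a < T.n; ++a) {
    std::vector<int> cells = block_cells(a, T);
    double S = 0.0;
    for (int c : cells) S += V[c] / (1.0 + cov[c]);
    double nv = net_value_of(S, static_cast<int>(cells.size()), p1, p2, p3, form);
    if (nv > best_nv + 1e-12) { best_nv = nv; best = a; }
  }
  return best;
}

void place_block(HRSet& rg, std::vector<int>& cov, int anchor, const Torus& T) {
  for (int c : block_cells(anchor, T)) { rg.add(c); ++cov[c]; }
}

void unplace_all(std::vector<HRSet>& ranges, std::vector<int>& cov) {
  std::fill(cov.begin(), cov.end(), 0);
  for (auto& rg : ranges) {
    rg.cells.clear();
    std::fill(rg.memb.begin(), rg.memb.end(), 0);
  }
}

// Round-robin improvement: one best move per range per pass, in order of
// establishment, until a full pass makes no change.
void round_robin(std::vector<HRSet>& ranges, std::vector<int>& cov,
                 const std::vector<double>& V, const Torus& T, double p1,
                 double p2, double p3, int form, int min_cells, Workspace& ws) {
  // With two or more ranges these best-response dynamics need not settle
  // (one range's improving move can undo another's), so the iteration is
  // capped; convergent configurations settle in well under 50 passes.
  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= 250) {
    changed = false;
    for (auto& rg : ranges)
      if (improve_once(rg, cov, V, T, p1, p2, p3, form, min_cells, ws))
        changed = true;
  }
}

double range_nv(const HRSet& rg, const std::vector<int>& cov,
                const std::vector<double>& V, const Torus& T, double p1,
                double p2, double p3, int form) {
  return net_value_of(range_S(rg, V, cov), static_cast<int>(rg.cells.size()),
                      p1, p2, p3, form);
}

}  // namespace

// [[Rcpp::export]]
List cpp_optimize_range(NumericVector v_rowmajor, int nr, int nc,
                        IntegerVector cells0, IntegerVector cov_other,
                        double p1, double p2, double p3, int form,
                        int min_cells) {
  Torus T(nr, nc);
  std::vector<double> V(v_rowmajor.begin(), v_rowmajor.end());
  std::vector<int> cov(cov_other.begin(), cov_other.end());
  HRSet rg(T.n);
  Workspace ws(T.n);
  for (int c : cells0) { rg.add(c); ++cov[c]; }
  int steps = 0;
  while (improve_once(rg, cov, V, T, p1, p2, p3, form, min_cells, ws)) ++steps;
  double S = range_S(rg, V, cov);
  return List::create(_["cells"] = IntegerVector(rg.cells.begin(), rg.cells.end()),
                      _["S"] = S,
                      _["net_value"] = net_value_of(S, rg.cells.size(), p1, p2, p3, form),
                      _["steps"] = steps);
}

// [[Rcpp::export]]
List cpp_establish(NumericVector v_rowmajor, int nr, int nc, double p1,
                   double p2, double p3, int form, int restarts, int seed,
                   int min_cells, int max_ranges) {
  Torus T(nr, nc);
  std::vector<double> V(v_rowmajor.begin(), v_rowmajor.end());
  Rng rng(static_cast<uint32_t>(seed));
  Workspace ws(T.n);

  std::vector<HRSet> ranges;
  std::vector<int> cov(T.n, 0);

  // best jointly-viable configuration seen so far
  std::vector<std::vector<int>> snap_cells;
  std::vector<int> snap_cov(T.n, 0);
  int total_restarts = 0;

  if (max_ranges <= 0) max_ranges = T.n;

  while (static_cast<int>(ranges.size()) < max_ranges) {
    ranges.emplace_back(T.n);
    place_block(ranges.back(), cov,
                best_anchor(V, cov, T, p1, p2, p3, form), T);
    int attempts = 0;
    bool viable;
    for (;;) {
      round_robin(ranges, cov, V, T, p1, p2, p3, form, min_cells, ws);
      viable = true;
      for (auto& rg : ranges)
        if (range_nv(rg, cov, V, T, p1, p2, p3, form) <= 0.0) { viable = false; break; }
      if (viable) break;
      if (++attempts > restarts) break;
      ++total_restarts;
      // re-establish all current ranges from fresh random initial positions
      unplace_all(ranges, cov);
      for (auto& rg : ranges) place_block(rg, cov, rng.uniform_int(T.n), T);
    }
    if (!viable) break;
    snap_cells.clear();
    for (auto& rg : ranges) snap_cells.push_back(rg.cells);
    std::copy(cov.begin(), cov.end(), snap_cov.begin());
  }

  List out_ranges(snap_cells.size());
  for (size_t i = 0; i < snap_cells.size(); ++i)
    out_ranges[i] = IntegerVector(snap_cells[i].begin(), snap_cells[i].end());
  return List::create(_["ranges"] = out_ranges,
                      _["cover"] = IntegerVector(snap_cov.begin(), snap_cov.end()),
                      _["abundance"] = static_cast<int>(snap_cells.size()),
                      _["restarts_used"] = total_restarts);
}

namespace {

// Redelmeier-style enumeration of all rook-connected cell sets (with
// toroidal wrap) of size min_area..max_area, each generated exactly once
// (rooted at its minimum cell index). Callback evaluates net value.
struct Enumerator {
  const Torus& T;
  const std::vector<double>& V;
  const std::vector<int>& cov_other;  // other-range cover: discount 1/(1+cov)
  double p1, p2, p3;
  int form, min_area, max_area;
  long long count = 0;
  double best_nv = -std::numeric_limits<double>::infinity();
  std::vector<int> best_cells;
  std::vector<int> sub;
  std::vector<char> reached;
  double S = 0.0;
  int root = 0;

  Enumerator(const Torus& T_, const std::vector<double>& V_,
             const std::vector<int>& cov_, double p1_, double p2_, double p3_,
             int form_, int min_a, int max_a)
      : T(T_), V(V_), cov_other(cov_), p1(p1_), p2(p2_), p3(p3_),
        form(form_), min_area(min_a), max_area(max_a), reached(T_.n, 0) {}

  void evaluate() {
    ++count;
    double nv = net_value_of(S, static_cast<int>(sub.size()), p1, p2, p3, form);
    if (nv > best_nv + 1e-12) { best_nv = nv; best_cells = sub; }
  }

  void rec(std::vector<int> untried) {
    while (!untried.empty()) {
      int w = untried.back();
      untried.pop_back();  // w stays "reached" for the rest of this frame
      sub.push_back(w);
      S += V[w] / (1.0 + cov_other[w]);
      if (static_cast<int>(sub.size()) >= min_area) evaluate();
      if (static_cast<int>(sub.size()) < max_area) {
        std::vector<int> next(untried);
        std::vector<int> marked;
        for (int k = 0; k < 4; ++k) {
          int u = T.nb[4 * w + k];
          if (u > root && !reached[u]) {
            reached[u] = 1;
            marked.push_back(u);
            next.push_back(u);
          }
        }
        rec(std::move(next));
        for (int u : marked) reached[u] = 0;
      }
      S -= V[w] / (1.0 + cov_other[w]);
      sub.pop_back();
    }
  }

  void run() {
    for (root = 0; root < T.n; ++root) {
      std::fill(reached.begin(), reached.end(), 0);
      reached[root] = 1;
      rec(std::vector<int>{root});
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_best_connected_set(NumericVector v_rowmajor, int nr, int nc,
                            IntegerVector cov_other, double p1, double p2,
                            double p3, int form, int min_area, int max_area) {
  Torus T(nr, nc);
  std::vector<double> V(v_rowmajor.begin(), v_rowmajor.end());
  std::vector<int> cov(cov_other.begin(), cov_other.end());
  Enumerator en(T, V, cov, p1, p2, p3, form, min_area, max_area);
  en.run();
  return List::create(_["cells"] = IntegerVector(en.best_cells.begin(), en.best_cells.end()),
                      _["net_value"] = en.best_nv,
                      _["n_sets"] = static_cast<double>(en.count));
}

// [[Rcpp::export]]
bool cpp_is_connected(IntegerVector cells0, int nr, int nc) {
  if (cells0.size() == 0) return false;
  Torus T(nr, nc);
  HRSet rg(T.n);
  Workspace ws(T.n);
  for (int c : cells0) { if (rg.memb[c]) continue; rg.add(c); }
  return connected_without(rg, T, -1, -1, ws);
}
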