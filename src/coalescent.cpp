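// Hudson-style coalescent with recombination restricted to fragment
// boundaries.  Time is measured in units of 2*Ne generations, so a pair of
// lineages coalesces at rate 1, a lineage recombines at rate rho_b/2 per
// boundary spanned by its ancestral material (rho_b = 4*Ne*c, with c the
// per-meiosis crossover probability between adjacent fragments), and a
// fragment of length L accumulates mutations at rate theta_f/2 per lineage
// (theta_f = 4*Ne*mu*L).  Within a fragment there is no recombination, so
// the infinite-sites / four-gamete property holds per fragment exactly.
//
// Marginal genealogies are recorded as an edge table (parent, child,
// fragment interval) in the manner of succinct tree sequences; mutations are
// Poisson-dropped per fragment on the marginal branch lengths and carriers
// are recovered by descent traversal.  All randomness goes through R's RNG
// so set.seed() in R gives bit-for-bit reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {        // run of fragments [lo, hi) mapped to one marginal node
  int lo, hi, node;
};

typedef std::vector<Seg> Lineage;

// Fenwick tree over lineage slots, holding each lineage's recombination
// weight (number of fragment boundaries inside its ancestral span).
struct Fenwick {
  std::vector<double> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0.0), n(n_) {}
  void grow(int n_) {
    std::vector<double> vals(n, 0.0);
    for (int i = 1; i <= n; ++i) vals[i - 1] = value(i - 1);
    t.assign(n_ + 1, 0.0); int old = n; n = n_;
    for (int i = 0; i < old; ++i) if (vals[i] != 0.0) add(i, vals[i]);
  }
  void add(int i, double d) { for (++i; i <= n; i += i & (-i)) t[i] += d; }
  double prefix(int i) const {  // sum of [0, i]
    double s = 0; for (++i; i > 0; i -= i & (-i)) s += t[i]; return s;
  }
  double value(int i) const { return prefix(i) - (i ? prefix(i - 1) : 0.0); }
  double total() const { return prefix(n - 1); }
  int find(double x) const {  // smallest i with prefix(i) >= x
    int pos = 0, logn = 1; while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] < x) { pos += pw; x -= t[pos]; }
    }
    return pos;  // 0-based slot
  }
};

inline int span_boundaries(const Lineage &L) {
  if (L.empty()) return 0;
  return L.back().hi - L.front().lo - 1;
}

struct Graph {
  int n_samples, n_frag;
  std::vector<double> node_time;
  std::vector<int> e_par, e_child, e_lo, e_hi;
  long n_rec, n_coal;
  int new_node(double t) { node_time.push_back(t); return (int)node_time.size() - 1; }
  void add_edge(int p, int c, int lo, int hi) {
    e_par.push_back(p); e_child.push_back(c); e_lo.push_back(lo); e_hi.push_back(hi);
  }
};

// Simulate the ARG down to the marginal MRCA of every fragment.
void simulate_arg(int n, int n_frag, double rho_b, Graph &arg) {
  arg.n_samples = n; arg.n_frag = n_frag; arg.n_rec = 0; arg.n_coal = 0;
  arg.node_time.assign(n, 0.0);

  std::vector<Lineage> slots;            // lineage storage by slot
  std::vector<int> active;               // slot ids of live lineages
  std::vector<int> slot_pos;             // slot -> index in `active` (-1 dead)
  std::vector<int> free_slots;
  std::vector<int> frag_cnt(n_frag, n);  // live lineages ancestral to fragment
  std::vector<char> frag_done(n_frag, 0);
  int frag_left = n_frag;

  int cap = 2 * n + 64;
  Fenwick fen(cap);
  slots.reserve(cap); slot_pos.reserve(cap);
  for (int i = 0; i < n; ++i) {
    Lineage L(1); L[0].lo = 0; L[0].hi = n_frag; L[0].node = i;
    slots.push_back(L); slot_pos.push_back((int)active.size()); active.push_back(i);
    if (rho_b > 0) fen.add(i, span_boundaries(L));
  }
  for (int i = n; i < cap; ++i) { slots.push_back(Lineage()); slot_pos.push_back(-1); free_slots.push_back(i); }

  double t = 0.0;

  auto alloc_slot = [&]() -> int {
    if (free_slots.empty()) {
      int old = (int)slots.size(), ncap = 2 * old;
      for (int i = old; i < ncap; ++i) { slots.push_back(Lineage()); slot_pos.push_back(-1); free_slots.push_back(i); }
      fen.grow(ncap);
    }
    int s = free_slots.back(); free_slots.pop_back(); return s;
  };
  auto activate = [&](int slot) {
    slot_pos[slot] = (int)active.size(); active.push_back(slot);
    if (rho_b > 0) fen.add(slot, span_boundaries(slots[slot]) - fen.value(slot));
  };
  auto deactivate = [&](int slot) {
    int pos = slot_pos[slot], last = active.back();
    active[pos] = last; slot_pos[last] = pos; active.pop_back(); slot_pos[slot] = -1;
    if (rho_b > 0) fen.add(slot, -fen.value(slot));
    slots[slot].clear(); free_slots.push_back(slot);
  };

  long guard = 0;
  while (frag_left > 0) {
    if (++guard > 200000000L) stop("coalescent did not terminate (event guard hit)");
    int k = (int)active.size();
    if (k <= 1) break;  // should coincide with frag_left == 0
    double coal = 0.5 * (double)k * (k - 1);
    double rec = (rho_b > 0) ? 0.5 * rho_b * fen.total() : 0.0;
    double tot = coal + rec;
    t += R::exp_rand() / tot;

    if (R::unif_rand() * tot < rec) {
      // ---- recombination: split one lineage at a boundary in its span ----
      ++arg.n_rec;
      double x = R::unif_rand() * fen.total();
      int slot = fen.find(x);
      Lineage &L = slots[slot];
      int lo = L.front().lo, nb = span_boundaries(L);
      int b = lo + 1 + (int)(R::unif_rand() * nb);
      if (b > lo + nb) b = lo + nb;
      Lineage left, right;
      for (size_t s = 0; s < L.size(); ++s) {
        if (L[s].hi <= b) left.push_back(L[s]);
        else if (L[s].lo >= b) right.push_back(L[s]);
        else {
          Seg a = L[s]; a.hi = b; left.push_back(a);
          Seg c = L[s]; c.lo = b; right.push_back(c);
        }
      }
      int rslot = alloc_slot();
      slots[slot].swap(left);
      if (rho_b > 0) fen.add(slot, span_boundaries(slots[slot]) - fen.value(slot));
      slots[rslot].swap(right);
      activate(rslot);
    } else {
      // ---- coalescence of a uniform pair ----
      ++arg.n_coal;
      int k2 = (int)active.size();
      int ia = (int)(R::unif_rand() * k2); if (ia == k2) --ia;
      int ib = (int)(R::unif_rand() * (k2 - 1)); if (ib == k2 - 1) --ib;
      if (ib >= ia) ++ib;
      int sa = active[ia], sb = active[ib];
      const Lineage A = slots[sa], B = slots[sb];
      Lineage P;
      size_t i = 0, j = 0;
      Seg a, b2; bool have_a = i < A.size(), have_b = j < B.size();
      if (have_a) a = A[i]; if (have_b) b2 = B[j];
      while (have_a && have_b) {
        if (a.hi <= b2.lo) { P.push_back(a); if (++i < A.size()) a = A[i]; else have_a = false; continue; }
        if (b2.hi <= a.lo) { P.push_back(b2); if (++j < B.size()) b2 = B[j]; else have_b = false; continue; }
        int lo = std::max(a.lo, b2.lo), hi = std::min(a.hi, b2.hi);
        if (a.lo < lo) { Seg s = a; s.hi = lo; P.push_back(s); }
        if (b2.lo < lo) { Seg s = b2; s.hi = lo; P.push_back(s); }
        int u = arg.new_node(t);
        arg.add_edge(u, a.node, lo, hi);
        arg.add_edge(u, b2.node, lo, hi);
        bool finished_any = false;
        for (int f = lo; f < hi; ++f) {
          if (--frag_cnt[f] == 1) { frag_done[f] = 1; --frag_left; finished_any = true; }
        }
        // carry the un-finished part of [lo, hi)
        if (!finished_any) {
          Seg s; s.lo = lo; s.hi = hi; s.node = u; P.push_back(s);
        } else {
          int f = lo;
          while (f < hi) {
            while (f < hi && frag_done[f]) ++f;
            int l2 = f;
            while (f < hi && !frag_done[f]) ++f;
            if (f > l2) { Seg s; s.lo = l2; s.hi = f; s.node = u; P.push_back(s); }
          }
        }
        a.lo = hi; b2.lo = hi;
        if (a.lo >= a.hi) { if (++i < A.size()) a = A[i]; else have_a = false; }
        if (b2.lo >= b2.hi) { if (++j < B.size()) b2 = B[j]; else have_b = false; }
      }
      while (have_a) { P.push_back(a); if (++i < A.size()) a = A[i]; else have_a = false; }
      while (have_b) { P.push_back(b2); if (++j < B.size()) b2 = B[j]; else have_b = false; }
      // fragments can only finish inside overlap intervals, and those are
      // excluded from P at push time, so P never mentions a finished fragment
      deactivate(sa); deactivate(sb);
      if (!P.empty()) {
        int sp = alloc_slot();
        slots[sp].swap(P);
        activate(sp);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_fragment_panel")]]
List sim_fragment_panel(int n_haplotypes, int n_fragments, double fragment_length,
                        double theta_frag, double rho_boundary) {
  if (n_haplotypes < 2) stop("need at least 2 haplotypes");
  if (n_fragments < 1) stop("need at least 1 fragment");
  Graph arg;
  simulate_arg(n_haplotypes, n_fragments, rho_boundary, arg);

  const int nE = (int)arg.e_par.size();
  // sweep fragments left to right keeping the set of edges covering each
  std::vector<std::vector<int> > starts(n_fragments), ends(n_fragments);
  for (int e = 0; e < nE; ++e) { starts[arg.e_lo[e]].push_back(e); ends[arg.e_hi[e] - 1].push_back(e); }

  std::vector<int> act;               // active edge ids
  std::vector<int> act_pos(nE, -1);   // edge -> position in act
  const int nN = (int)arg.node_time.size();
  std::vector<int> head(nN, -1), nxt(nE, -1);

  std::vector<int> mut_frag, mut_edge;
  std::vector<double> mut_pos;
  std::vector<std::vector<int> > carriers;

  std::vector<int> stack_;
  std::vector<double> cum;
  for (int f = 0; f < n_fragments; ++f) {
    for (size_t s = 0; s < starts[f].size(); ++s) {
      int e = starts[f][s]; act_pos[e] = (int)act.size(); act.push_back(e);
    }
    double total_len = 0.0;
    for (size_t s = 0; s < act.size(); ++s) {
      int e = act[s];
      total_len += arg.node_time[arg.e_par[e]] - arg.node_time[arg.e_child[e]];
    }
    int nm = (total_len > 0) ? (int)R::rpois(0.5 * theta_frag * total_len) : 0;
    if (nm > 0) {
      // adjacency restricted to this fragment, plus cumulative branch lengths
      cum.resize(act.size());
      double acc = 0.0;
      for (size_t s = 0; s < act.size(); ++s) {
        int e = act[s]; nxt[e] = head[arg.e_par[e]]; head[arg.e_par[e]] = e;
        acc += arg.node_time[arg.e_par[e]] - arg.node_time[arg.e_child[e]];
        cum[s] = acc;
      }
      for (int m = 0; m < nm; ++m) {
        double x = R::unif_rand() * total_len;
        size_t s = std::lower_bound(cum.begin(), cum.end(), x) - cum.begin();
        if (s >= act.size()) s = act.size() - 1;
        int hit = act[s];
        // carriers: leaves below the child of `hit` in this fragment's tree
        std::vector<int> carr;
        stack_.clear(); stack_.push_back(arg.e_child[hit]);
        while (!stack_.empty()) {
          int v = stack_.back(); stack_.pop_back();
          if (v < n_haplotypes) { carr.push_back(v); continue; }
          for (int e = head[v]; e != -1; e = nxt[e]) stack_.push_back(arg.e_child[e]);
        }
        if (carr.empty() || (int)carr.size() >= n_haplotypes) continue;  // non-segregating
        std::sort(carr.begin(), carr.end());
        mut_frag.push_back(f);
        mut_edge.push_back(hit);
        mut_pos.push_back(f * fragment_length + R::unif_rand() * fragment_length);
        carriers.push_back(carr);
      }
      for (size_t s = 0; s < act.size(); ++s) head[arg.e_par[act[s]]] = -1;
    }
    for (size_t s = 0; s < ends[f].size(); ++s) {
      int e = ends[f][s], pos = act_pos[e], last = act.back();
      act[pos] = last; act_pos[last] = pos; act.pop_back(); act_pos[e] = -1;
    }
  }

  // order sites by physical position
  const int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });

  NumericVector pos_out(S);
  IntegerVector frag_out(S), count_out(S);
  List carr_out(S);
  for (int i = 0; i < S; ++i) {
    int m = ord[i];
    pos_out[i] = mut_pos[m];
    frag_out[i] = mut_frag[m];
    count_out[i] = (int)carriers[m].size();
    carr_out[i] = wrap(carriers[m]);  // 0-based; R wrapper shifts
  }
  return List::create(_["positions"] = pos_out, _["fragment"] = frag_out,
                      _["count"] = count_out, _["carriers"] = carr_out,
                      _["n_rec_events"] = (double)arg.n_rec,
                      _["n_coal_events"] = (double)arg.n_coal);
}
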