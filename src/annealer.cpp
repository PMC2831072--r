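// Simulated-annealing structure search over DAGs with BDe (Cooper-Herskovits)
// scoring.  Parent sets are 64-bit masks, so the compiled path handles up to
// 62 nodes; compendium-scale gene subsets (tens of nodes) fit comfortably.
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every run bit-reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Move { int type; int i; int j; };  // 0 add, 1 delete, 2 reverse

class Annealer {
public:
  Annealer(const IntegerMatrix& data, const IntegerVector& arity,
           int max_parents, double ess, bool bdeu)
    : data_(data), arity_(arity), n_(data.nrow()), m_(data.ncol()),
      max_parents_(max_parents), ess_(ess), bdeu_(bdeu),
      pmask_(n_, 0), chmask_(n_, 0), fam_(n_, 0.0), cache_(n_) {
    int rmax = 2;
    for (int i = 0; i < n_; ++i) rmax = std::max(rmax, arity_[i]);
    lg_.resize(m_ + rmax + 2);
    for (size_t k = 0; k < lg_.size(); ++k)
      lg_[k] = R::lgammafn(static_cast<double>(k));
  }

  int n() const { return n_; }

  // log BDe family score of `child` given parent mask
  double family_score(int child, uint64_t pmask) {
    auto& memo = cache_[child];
    auto it = memo.find(pmask);
    if (it != memo.end()) return it->second;

    std::vector<int> ps;
    for (int i = 0; i < n_; ++i) if ((pmask >> i) & 1ULL) ps.push_back(i);
    const int r = arity_[child];
    long long q = 1;
    for (int p : ps) q *= arity_[p];
    std::vector<long long> radix(ps.size());
    long long w = q;
    for (size_t t = 0; t < ps.size(); ++t) { w /= arity_[ps[t]]; radix[t] = w; }
    std::vector<int> counts(static_cast<size_t>(q) * r, 0);
    for (int s = 0; s < m_; ++s) {
      long long j = 0;
      for (size_t t = 0; t < ps.size(); ++t) j += radix[t] * data_(ps[t], s);
      counts[static_cast<size_t>(j) * r + data_(child, s)]++;
    }
    double sc = 0.0;
    if (!bdeu_) {
      // all-ones prior: every lgamma argument is an integer, and a parent
      // configuration with no observations contributes exactly zero
      const double lg_r = lg_[r];
      for (long long j = 0; j < q; ++j) {
        const int* row = counts.data() + static_cast<size_t>(j) * r;
        int Nij = 0;
        for (int k = 0; k < r; ++k) Nij += row[k];
        if (Nij == 0) continue;
        sc += lg_r - lg_[Nij + r];
        for (int k = 0; k < r; ++k) sc += lg_[row[k] + 1];
      }
    } else {
      const double a_ij = ess_ / static_cast<double>(q);
      const double a_ijk = a_ij / r;
      const double base = R::lgammafn(a_ij) - r * R::lgammafn(a_ijk);
      for (long long j = 0; j < q; ++j) {
        int Nij = 0;
        for (int k = 0; k < r; ++k) Nij += counts[static_cast<size_t>(j) * r + k];
        sc += base - R::lgammafn(Nij + a_ij);
        for (int k = 0; k < r; ++k)
          sc += R::lgammafn(counts[static_cast<size_t>(j) * r + k] + a_ijk);
      }
    }
    memo.emplace(pmask, sc);
    return sc;
  }

  void set_structure(const LogicalMatrix& adj) {
    std::fill(pmask_.begin(), pmask_.end(), 0ULL);
    std::fill(chmask_.begin(), chmask_.end(), 0ULL);
    for (int i = 0; i < n_; ++i)
      for (int j = 0; j < n_; ++j)
        if (adj(i, j)) { pmask_[j] |= 1ULL << i; chmask_[i] |= 1ULL << j; }
    for (int j = 0; j < n_; ++j) fam_[j] = family_score(j, pmask_[j]);
  }

  double total() const {
    double s = 0.0;
    for (double f : fam_) s += f;
    return s;
  }

  // DFS: does a path src ~> dst exist?  Optionally ignore edge skip_from->skip_to.
  bool reaches(int src, int dst, int skip_from = -1, int skip_to = -1) const {
    uint64_t seen = 1ULL << src;
    std::vector<int> stack{src};
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      uint64_t ch = chmask_[u];
      if (u == skip_from && skip_to >= 0) ch &= ~(1ULL << skip_to);
      while (ch) {
        int v = __builtin_ctzll(ch);
        ch &= ch - 1;
        if (v == dst) return true;
        if (!((seen >> v) & 1ULL)) { seen |= 1ULL << v; stack.push_back(v); }
      }
    }
    return false;
  }

  // descendant masks for all nodes (desc[u] excludes u unless on a cycle,
  // which cannot happen here)
  void descendants(std::vector<uint64_t>& desc) const {
    desc.assign(n_, 0ULL);
    // reverse topological order via Kahn on out-degree
    std::vector<int> outdeg(n_), order;
    order.reserve(n_);
    for (int i = 0; i < n_; ++i)
      outdeg[i] = __builtin_popcountll(chmask_[i]);
    std::vector<int> stack;
    for (int i = 0; i < n_; ++i) if (outdeg[i] == 0) stack.push_back(i);
    std::vector<int> od = outdeg;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      order.push_back(u);
      uint64_t pa = pmask_[u];
      while (pa) {
        int p = __builtin_ctzll(pa); pa &= pa - 1;
        if (--od[p] == 0) stack.push_back(p);
      }
    }
    for (int u : order) {
      uint64_t ch = chmask_[u], d = ch;
      while (ch) { int v = __builtin_ctzll(ch); ch &= ch - 1; d |= desc[v]; }
      desc[u] = d;
    }
  }

  void legal_moves(std::vector<Move>& out) const {
    out.clear();
    std::vector<uint64_t> desc;
    descendants(desc);
    for (int j = 0; j < n_; ++j) {
      if (__builtin_popcountll(pmask_[j]) >= max_parents_) continue;
      for (int i = 0; i < n_; ++i) {
        if (i == j) continue;
        if ((chmask_[i] >> j) & 1ULL) continue;   // edge exists
        if ((desc[j] >> i) & 1ULL) continue;      // would close a cycle
        if ((chmask_[j] >> i) & 1ULL) continue;   // j->i present (2-cycle)
        out.push_back({0, i, j});
      }
    }
    for (int i = 0; i < n_; ++i) {
      uint64_t ch = chmask_[i];
      while (ch) {
        int j = __builtin_ctzll(ch); ch &= ch - 1;
        out.push_back({1, i, j});
        if (__builtin_popcountll(pmask_[i]) < max_parents_ &&
            !reaches(i, j, i, j)) {
          out.push_back({2, i, j});
        }
      }
    }
  }

  void apply(const Move& mv, double fj, double fi) {
    const int i = mv.i, j = mv.j;
    if (mv.type == 0) {
      pmask_[j] |= 1ULL << i; chmask_[i] |= 1ULL << j;
      fam_[j] = fj;
    } else if (mv.type == 1) {
      pmask_[j] &= ~(1ULL << i); chmask_[i] &= ~(1ULL << j);
      fam_[j] = fj;
    } else {
      pmask_[j] &= ~(1ULL << i); chmask_[i] &= ~(1ULL << j);
      pmask_[i] |= 1ULL << j;  chmask_[j] |= 1ULL << i;
      fam_[j] = fj; fam_[i] = fi;
    }
  }

  const std::vector<uint64_t>& pmask() const { return pmask_; }
  double fam(int j) const { return fam_[j]; }

private:
  IntegerMatrix data_;
  IntegerVector arity_;
  int n_, m_, max_parents_;
  double ess_;
  bool bdeu_;
  std::vector<uint64_t> pmask_, chmask_;
  std::vector<double> fam_, lg_;
  std::vector<std::unordered_map<uint64_t, double>> cache_;
};

struct TopEntry { std::vector<uint64_t> pmask; double score; };

class TopK {
public:
  explicit TopK(int k) : k_(k) {}
  void consider(const std::vector<uint64_t>& pm, double score) {
    if (static_cast<int>(entries_.size()) == k_ &&
        score <= entries_.back().score) {
      // can't beat the worst kept entry unless it's a duplicate anyway
      return;
    }
    for (const auto& e : entries_) if (e.pmask == pm) return;
    TopEntry ent{pm, score};
    auto it = entries_.begin();
    while (it != entries_.end() && it->score >= score) ++it;
    entries_.insert(it, ent);
    if (static_cast<int>(entries_.size()) > k_) entries_.pop_back();
  }
  const std::vector<TopEntry>& entries() const { return entries_; }
private:
  int k_;
  std::vector<TopEntry> entries_;
};

}  // namespace

// [[Rcpp::export]]
double cpp_family_score(IntegerMatrix data, IntegerVector arity, int child0,
                        IntegerVector parents0, double ess = 1.0,
                        bool bdeu = false) {
  Annealer a(data, arity, data.nrow(), ess, bdeu);
  uint64_t pm = 0;
  for (int p : parents0) pm |= 1ULL << p;
  return a.family_score(child0, pm);
}

// [[Rcpp::export]]
List cpp_anneal(IntegerMatrix data, IntegerVector arity,
                LogicalMatrix start_adj, int n_proposals, int keep_top,
                int max_parents, double t0, double cooling, int reheat_after,
                double ess = 1.0, bool bdeu = false) {
  const int n = data.nrow();
  if (n > 62) stop("compiled search supports at most 62 nodes");
  Annealer ann(data, arity, max_parents, ess, bdeu);
  ann.set_structure(start_adj);
  double cur = ann.total();

  TopK top(keep_top);
  top.consider(ann.pmask(), cur);

  double T = t0;
  int rejections = 0;
  std::vector<Move> moves;
  std::vector<uint64_t> cand;
  const int traj_every = std::max(1, n_proposals / 100);
  std::vector<double> traj;
  double best = cur;

  for (int t = 0; t < n_proposals; ++t) {
    ann.legal_moves(moves);
    if (!moves.empty()) {
      int idx = static_cast<int>(unif_rand() * moves.size());
      if (idx >= static_cast<int>(moves.size()))
        idx = static_cast<int>(moves.size()) - 1;
      const Move& mv = moves[idx];

      double fj_new = 0.0, fi_new = 0.0, delta = 0.0;
      cand = ann.pmask();
      if (mv.type == 0) {
        uint64_t pm = cand[mv.j] | (1ULL << mv.i);
        fj_new = ann.family_score(mv.j, pm);
        delta = fj_new - ann.fam(mv.j);
        cand[mv.j] = pm;
      } else if (mv.type == 1) {
        uint64_t pm = cand[mv.j] & ~(1ULL << mv.i);
        fj_new = ann.family_score(mv.j, pm);
        delta = fj_new - ann.fam(mv.j);
        cand[mv.j] = pm;
      } else {
        uint64_t pmj = cand[mv.j] & ~(1ULL << mv.i);
        uint64_t pmi = cand[mv.i] | (1ULL << mv.j);
        fj_new = ann.family_score(mv.j, pmj);
        fi_new = ann.family_score(mv.i, pmi);
        delta = (fj_new - ann.fam(mv.j)) + (fi_new - ann.fam(mv.i));
        cand[mv.j] = pmj; cand[mv.i] = pmi;
      }
      double cand_score = cur + delta;
      top.consider(cand, cand_score);
      if (cand_score > best) best = cand_score;

      bool accept = delta > 0 || unif_rand() < std::exp(delta / T);
      if (accept) {
        ann.apply(mv, fj_new, fi_new);
        cur = cand_score;
        rejections = 0;
      } else {
        ++rejections;
      }
    }
    T *= cooling;
    if (reheat_after > 0 && rejections >= reheat_after) {
      T = t0;
      rejections = 0;
    }
    if ((t + 1) % traj_every == 0) traj.push_back(best);
  }

  // Recompute returned scores fresh (family sums in node order) so totals
  // are exact sums of the reported per-family terms, not drifted running sums.
  List nets;
  for (const auto& e : top.entries()) {
    LogicalMatrix adj(n, n);
    NumericVector fam(n);
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      uint64_t pm = e.pmask[j];
      for (int i = 0; i < n; ++i) adj(i, j) = (pm >> i) & 1ULL;
      fam[j] = ann.family_score(j, pm);
      tot += fam[j];
    }
    nets.push_back(List::create(_["adj"] = adj, _["log_score"] = tot,
                                _["per_family"] = fam));
  }
  return List::create(_["networks"] = nets,
                      _["trajectory"] = NumericVector(traj.begin(), traj.end()));
}
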