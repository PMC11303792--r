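// Compiled mining core: FP-growth over an FP-tree, exhaustive
// antecedent/consequent split enumeration with memoized subset counts,
// and the rare-vs-frequent antecedent Jaccard scan. Itemsets cross the
// R boundary either as 1-based index vectors (patterns) or as bitmasks
// stored in doubles (rules/pairs; exact for < 2^52).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

namespace {

struct FPNode {
  int item;   // rank-space item id, -1 at root
  int count;
  int parent;
  std::unordered_map<int, int> children;
};

struct FPTree {
  std::vector<FPNode> nodes;
  std::vector<std::vector<int>> header;  // per rank item: node ids
  explicit FPTree(int n_items) : header(n_items) {
    nodes.push_back(FPNode{-1, 0, -1, {}});
  }
  // items must arrive sorted by ascending rank (most frequent first)
  void insert(const std::vector<int>& items, int count) {
    int cur = 0;
    for (int it : items) {
      auto f = nodes[cur].children.find(it);
      if (f == nodes[cur].children.end()) {
        int idx = static_cast<int>(nodes.size());
        nodes.push_back(FPNode{it, count, cur, {}});  // may reallocate
        nodes[cur].children.emplace(it, idx);
        header[it].push_back(idx);
        cur = idx;
      } else {
        int nxt = f->second;
        nodes[nxt].count += count;
        cur = nxt;
      }
    }
  }
};

void mine_tree(const FPTree& tree, int n_items, int min_count,
               std::vector<int>& suffix,
               std::vector<std::vector<int>>& out_items,
               std::vector<int>& out_counts) {
  // iterate least-frequent-first so conditional trees only contain
  // items of lower rank
  for (int it = n_items - 1; it >= 0; --it) {
    const auto& links = tree.header[it];
    if (links.empty()) continue;
    int total = 0;
    for (int nid : links) total += tree.nodes[nid].count;
    if (total < min_count) continue;

    suffix.push_back(it);
    out_items.push_back(suffix);
    out_counts.push_back(total);

    // conditional pattern base: prefix path of every node holding `it`
    std::vector<std::pair<std::vector<int>, int>> base;
    std::vector<int> cond_count(n_items, 0);
    for (int nid : links) {
      int cnt = tree.nodes[nid].count;
      std::vector<int> path;
      for (int p = tree.nodes[nid].parent; p > 0; p = tree.nodes[p].parent)
        path.push_back(tree.nodes[p].item);
      if (!path.empty()) {
        std::reverse(path.begin(), path.end());  // ascending rank
        for (int pi : path) cond_count[pi] += cnt;
        base.emplace_back(std::move(path), cnt);
      }
    }

    bool any = false;
    for (int i = 0; i < n_items && !any; ++i)
      any = cond_count[i] >= min_count;
    if (any) {
      FPTree cond(n_items);
      std::vector<int> filtered;
      for (auto& pc : base) {
        filtered.clear();
        for (int pi : pc.first)
          if (cond_count[pi] >= min_count) filtered.push_back(pi);
        if (!filtered.empty()) cond.insert(filtered, pc.second);
      }
      mine_tree(cond, n_items, min_count, suffix, out_items, out_counts);
    }
    suffix.pop_back();
  }
}

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

}  // namespace

// [[Rcpp::export]]
List cpp_fpgrowth(LogicalMatrix mat, IntegerVector item_order, int min_count) {
  const int m = mat.nrow();
  const int n = mat.ncol();
  const int k = item_order.size();  // frequent single items, ordered

  std::vector<int> rank(n, -1);     // original col -> rank id
  for (int r = 0; r < k; ++r) rank[item_order[r]] = r;

  FPTree tree(k);
  std::vector<int> txn;
  for (int i = 0; i < m; ++i) {
    txn.clear();
    for (int j = 0; j < n; ++j)
      if (mat(i, j) && rank[j] >= 0) txn.push_back(rank[j]);
    if (txn.empty()) continue;
    std::sort(txn.begin(), txn.end());
    tree.insert(txn, 1);
  }

  std::vector<std::vector<int>> out_items;
  std::vector<int> out_counts;
  std::vector<int> suffix;
  mine_tree(tree, k, min_count, suffix, out_items, out_counts);

  List items(out_items.size());
  for (size_t i = 0; i < out_items.size(); ++i) {
    IntegerVector v(out_items[i].size());
    for (size_t j = 0; j < out_items[i].size(); ++j)
      v[j] = item_order[out_items[i][j]] + 1;  // back to 1-based orig cols
    items[i] = v;
  }
  return List::create(_["items"] = items,
                      _["count"] = IntegerVector(out_counts.begin(),
                                                 out_counts.end()));
}

// Exhaustive ordered splits X -> Y (all non-empty X, Y = P \ X) of every
// pattern with >= 2 items. Subset counts are looked up in a hash of the
// supplied patterns and recomputed from the matrix (then memoized) when a
// subset lies outside the mined band.
// [[Rcpp::export]]
List cpp_generate_rules(NumericVector pattern_masks, IntegerVector counts,
                        LogicalMatrix mat,
                        int class_no, int class_yes,  // 1-based cols, 0 = none
                        bool class_only) {
  const int m = mat.nrow();
  const int n = mat.ncol();
  if (n > 52) stop("rule generation supports at most 52 items");
  const int np = pattern_masks.size();

  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve(np * 2);
  std::vector<uint64_t> masks(np);
  for (int p = 0; p < np; ++p) {
    masks[p] = static_cast<uint64_t>(pattern_masks[p]);
    cnt[masks[p]] = counts[p];
  }

  auto get_count = [&](uint64_t msk) -> int {
    auto f = cnt.find(msk);
    if (f != cnt.end()) return f->second;
    int c = 0;
    for (int i = 0; i < m; ++i) {
      bool all = true;
      uint64_t rest = msk;
      while (rest) {
        int j = __builtin_ctzll(rest);
        rest &= rest - 1;
        if (!mat(i, j)) { all = false; break; }
      }
      if (all) ++c;
    }
    cnt.emplace(msk, c);
    return c;
  };

  const uint64_t no_bit = class_no > 0 ? (uint64_t(1) << (class_no - 1)) : 0;
  const uint64_t yes_bit = class_yes > 0 ? (uint64_t(1) << (class_yes - 1)) : 0;

  std::vector<double> ant, cons;
  std::vector<int> cxy, cx, cy;
  for (int p = 0; p < np; ++p) {
    uint64_t full = masks[p];
    if (popcount64(full) < 2) continue;
    int count_full = counts[p];
    if (class_only) {
      for (uint64_t ybit : {no_bit, yes_bit}) {
        if (ybit == 0 || !(full & ybit)) continue;
        uint64_t x = full ^ ybit;
        ant.push_back(static_cast<double>(x));
        cons.push_back(static_cast<double>(ybit));
        cxy.push_back(count_full);
        cx.push_back(get_count(x));
        cy.push_back(get_count(ybit));
      }
    } else {
      // enumerate proper non-empty submasks as antecedents
      for (uint64_t x = (full - 1) & full; x; x = (x - 1) & full) {
        uint64_t y = full ^ x;
        ant.push_back(static_cast<double>(x));
        cons.push_back(static_cast<double>(y));
        cxy.push_back(count_full);
        cx.push_back(get_count(x));
        cy.push_back(get_count(y));
      }
    }
  }

  return List::create(
      _["antMask"] = NumericVector(ant.begin(), ant.end()),
      _["consMask"] = NumericVector(cons.begin(), cons.end()),
      _["countXY"] = IntegerVector(cxy.begin(), cxy.end()),
      _["countX"] = IntegerVector(cx.begin(), cx.end()),
      _["countY"] = IntegerVector(cy.begin(), cy.end()));
}

// All-pairs antecedent Jaccard scan between rare and frequent rules.
// [[Rcpp::export]]
List cpp_pair_scan(NumericVector rare_masks, NumericVector freq_masks,
                   double sim_t, bool strict) {
  const int nr = rare_masks.size();
  const int nf = freq_masks.size();
  std::vector<uint64_t> rm(nr), fm(nf);
  for (int i = 0; i < nr; ++i) rm[i] = static_cast<uint64_t>(rare_masks[i]);
  for (int j = 0; j < nf; ++j) fm[j] = static_cast<uint64_t>(freq_masks[j]);

  std::vector<int> ri, fi;
  std::vector<double> sim;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nf; ++j) {
      int inter = popcount64(rm[i] & fm[j]);
      if (inter == 0) continue;
      int uni = popcount64(rm[i] | fm[j]);
      double s = static_cast<double>(inter) / uni;
      bool keep = strict ? (s > sim_t) : (s >= sim_t);
      if (keep) {
        ri.push_back(i + 1);
        fi.push_back(j + 1);
        sim.push_back(s);
      }
    }
  }
  return List::create(_["rareIdx"] = IntegerVector(ri.begin(), ri.end()),
                      _["freqIdx"] = IntegerVector(fi.begin(), fi.end()),
                      _["similarity"] = NumericVector(sim.begin(), sim.end()));
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(NumericVector masks) {
  IntegerVector out(masks.size());
  for (int i = 0; i < masks.size(); ++i)
    out[i] = popcount64(static_cast<uint64_t>(masks[i]));
  return out;
}

// Decode masks to "a;b;c" strings with items in lexicographic order.
// lex_order gives 0-based column indices sorted by item name.
// [[Rcpp::export]]
CharacterVector cpp_masks_to_strings(NumericVector masks,
                                     CharacterVector item_names,
                                     IntegerVector lex_order,
                                     std::string sep) {
  const int n = item_names.size();
  std::vector<std::string> names(n);
  for (int j = 0; j < n; ++j) names[j] = as<std::string>(item_names[j]);
  CharacterVector out(masks.size());
  std::string buf;
  for (int i = 0; i < masks.size(); ++i) {
    uint64_t msk = static_cast<uint64_t>(masks[i]);
    buf.clear();
    for (int r = 0; r < n; ++r) {
      int j = lex_order[r];
      if (msk & (uint64_t(1) << j)) {
        if (!buf.empty()) buf += sep;
        buf += names[j];
      }
    }
    out[i] = buf;
  }
  return out;
}
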