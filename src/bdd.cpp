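// Reduced ordered binary decision diagrams over a fixed variable order.
//
// This is the symbolic kernel behind coloured state sets and candidate
// sets: Boolean functions over (state bits, bound-state-copy bits,
// parameter bits).  Nodes are hash-consed, so two handles denote the same
// function iff they are equal integers; all set algebra reduces to ite().
// Nodes are never garbage collected: managers are per-analysis and the
// node cap below bounds memory instead.

#include <Rcpp.h>

#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// Handles must fit in 21 bits so (v, lo, hi) packs into one 64-bit key.
constexpr int kMaxNodes = (1 << 21) - 2;

struct Mgr {
  // var_[0..1] hold the terminals; their level sits below every decision
  // variable so min() over levels never selects them.
  std::vector<int32_t> var_, lo_, hi_;
  std::unordered_map<uint64_t, int32_t> unique_;
  std::unordered_map<uint64_t, int32_t> ite_;
  int nvars_;

  explicit Mgr(int nvars) : nvars_(nvars) {
    var_ = {nvars, nvars};
    lo_ = {0, 1};
    hi_ = {0, 1};
  }

  static uint64_t pack(int a, int b, int c) {
    return (uint64_t)a << 42 | (uint64_t)b << 21 | (uint64_t)c;
  }

  int mk(int v, int l, int h) {
    if (l == h) return l;
    uint64_t key = pack(v, l, h);
    auto it = unique_.find(key);
    if (it != unique_.end()) return it->second;
    if ((int)var_.size() > kMaxNodes)
      stop("BDD node limit exceeded; the instance is too large for the symbolic engine");
    int id = (int)var_.size();
    var_.push_back(v);
    lo_.push_back(l);
    hi_.push_back(h);
    unique_.emplace(key, id);
    return id;
  }

  int ite(int f, int g, int h) {
    if (f == 1) return g;
    if (f == 0) return h;
    if (g == h) return g;
    if (g == 1 && h == 0) return f;
    uint64_t key = pack(f, g, h);
    auto it = ite_.find(key);
    if (it != ite_.end()) return it->second;
    int v = std::min(var_[f], std::min(var_[g], var_[h]));
    int f0 = var_[f] == v ? lo_[f] : f, f1 = var_[f] == v ? hi_[f] : f;
    int g0 = var_[g] == v ? lo_[g] : g, g1 = var_[g] == v ? hi_[g] : g;
    int h0 = var_[h] == v ? lo_[h] : h, h1 = var_[h] == v ? hi_[h] : h;
    int r = mk(v, ite(f0, g0, h0), ite(f1, g1, h1));
    ite_.emplace(key, r);
    return r;
  }

  int bnot(int f) { return ite(f, 0, 1); }

  int quant_rec(int f, const std::vector<char>& mask, int maxq, bool exist,
                std::unordered_map<int, int>& memo) {
    if (f < 2 || var_[f] > maxq) return f;
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int l = quant_rec(lo_[f], mask, maxq, exist, memo);
    int h = quant_rec(hi_[f], mask, maxq, exist, memo);
    int r;
    if (mask[var_[f]])
      r = exist ? ite(l, 1, h) : ite(l, h, 0);
    else
      r = mk(var_[f], l, h);
    memo.emplace(f, r);
    return r;
  }

  // Rename variables via an order-preserving map (callers guarantee that
  // relative variable order is unchanged, so the result stays canonical).
  int rename_rec(int f, const std::vector<int>& map,
                 std::unordered_map<int, int>& memo) {
    if (f < 2) return f;
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int v = map[var_[f]] >= 0 ? map[var_[f]] : var_[f];
    int r = mk(v, rename_rec(lo_[f], map, memo),
               rename_rec(hi_[f], map, memo));
    memo.emplace(f, r);
    return r;
  }

  int restrict_rec(int f, int v, int val, std::unordered_map<int, int>& memo) {
    if (f < 2 || var_[f] > v) return f;
    if (var_[f] == v) return val ? hi_[f] : lo_[f];
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int r = mk(var_[f], restrict_rec(lo_[f], v, val, memo),
               restrict_rec(hi_[f], v, val, memo));
    memo.emplace(f, r);
    return r;
  }

  // Substitute variable v by its negation (swap the two cofactors at v).
  int flip_rec(int f, int v, std::unordered_map<int, int>& memo) {
    if (f < 2 || var_[f] > v) return f;
    if (var_[f] == v) return mk(v, hi_[f], lo_[f]);
    auto it = memo.find(f);
    if (it != memo.end()) return it->second;
    int r = mk(var_[f], flip_rec(lo_[f], v, memo), flip_rec(hi_[f], v, memo));
    memo.emplace(f, r);
    return r;
  }
};

Mgr* get(SEXP m) {
  XPtr<Mgr> p(m);
  return p.get();
}

void check_handle(Mgr* p, int f) {
  if (f < 0 || f >= (int)p->var_.size()) stop("invalid BDD handle");
}

}  // namespace

// [[Rcpp::export]]
SEXP bdd_mgr_new(int nvars) {
  if (nvars < 0 || nvars >= (1 << 21)) stop("invalid variable count");
  return XPtr<Mgr>(new Mgr(nvars));
}

// [[Rcpp::export]]
int bdd_mgr_nvars(SEXP m) { return get(m)->nvars_; }

// [[Rcpp::export]]
int bdd_mgr_size(SEXP m) { return (int)get(m)->var_.size(); }

// [[Rcpp::export]]
int bdd_v(SEXP m, int i) {
  Mgr* p = get(m);
  if (i < 0 || i >= p->nvars_) stop("BDD variable index out of range");
  return p->mk(i, 0, 1);
}

// [[Rcpp::export]]
int bdd_not(SEXP m, int f) {
  Mgr* p = get(m);
  check_handle(p, f);
  return p->bnot(f);
}

// [[Rcpp::export]]
int bdd_ite(SEXP m, int f, int g, int h) {
  Mgr* p = get(m);
  check_handle(p, f);
  check_handle(p, g);
  check_handle(p, h);
  return p->ite(f, g, h);
}

// [[Rcpp::export]]
int bdd_apply(SEXP m, std::string op, int f, int g) {
  Mgr* p = get(m);
  check_handle(p, f);
  check_handle(p, g);
  if (op == "and") return p->ite(f, g, 0);
  if (op == "or") return p->ite(f, 1, g);
  if (op == "xor") return p->ite(f, p->bnot(g), g);
  if (op == "imp") return p->ite(f, g, 1);
  if (op == "iff") return p->ite(f, g, p->bnot(g));
  stop("unknown BDD operator '%s'", op.c_str());
}

// [[Rcpp::export]]
int bdd_quantify(SEXP m, int f, IntegerVector vars, bool exist) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (vars.size() == 0) return f;
  std::vector<char> mask(p->nvars_, 0);
  int maxq = -1;
  for (int v : vars) {
    if (v < 0 || v >= p->nvars_) stop("BDD variable index out of range");
    mask[v] = 1;
    maxq = std::max(maxq, v);
  }
  std::unordered_map<int, int> memo;
  return p->quant_rec(f, mask, maxq, exist, memo);
}

// [[Rcpp::export]]
int bdd_rename(SEXP m, int f, IntegerVector from, IntegerVector to) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (from.size() != to.size()) stop("rename maps must have equal length");
  std::vector<int> map(p->nvars_, -1);
  for (int i = 0; i < from.size(); ++i) {
    if (from[i] < 0 || from[i] >= p->nvars_ || to[i] < 0 || to[i] >= p->nvars_)
      stop("BDD variable index out of range");
    map[from[i]] = to[i];
  }
  // order preservation check: the map restricted to mentioned vars must be
  // strictly increasing when sources are sorted
  {
    std::vector<std::pair<int, int>> pairs;
    for (int i = 0; i < from.size(); ++i) pairs.emplace_back(from[i], to[i]);
    std::sort(pairs.begin(), pairs.end());
    for (size_t i = 1; i < pairs.size(); ++i)
      if (pairs[i].second <= pairs[i - 1].second)
        stop("BDD rename map must preserve variable order");
  }
  std::unordered_map<int, int> memo;
  return p->rename_rec(f, map, memo);
}

// [[Rcpp::export]]
int bdd_restrict(SEXP m, int f, int v, int val) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (v < 0 || v >= p->nvars_) stop("BDD variable index out of range");
  std::unordered_map<int, int> memo;
  return p->restrict_rec(f, v, val ? 1 : 0, memo);
}

// [[Rcpp::export]]
int bdd_flip(SEXP m, int f, int v) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (v < 0 || v >= p->nvars_) stop("BDD variable index out of range");
  std::unordered_map<int, int> memo;
  return p->flip_rec(f, v, memo);
}

// [[Rcpp::export]]
IntegerVector bdd_support(SEXP m, int f) {
  Mgr* p = get(m);
  check_handle(p, f);
  std::vector<char> invars(p->nvars_, 0), seen(p->var_.size(), 0);
  std::vector<int> stack = {f};
  while (!stack.empty()) {
    int n = stack.back();
    stack.pop_back();
    if (n < 2 || seen[n]) continue;
    seen[n] = 1;
    invars[p->var_[n]] = 1;
    stack.push_back(p->lo_[n]);
    stack.push_back(p->hi_[n]);
  }
  IntegerVector out;
  for (int v = 0; v < p->nvars_; ++v)
    if (invars[v]) out.push_back(v);
  return out;
}

// Reachable node table: one row per internal node (id >= 2), columns
// id, var, lo, hi.  Terminals keep ids 0/1 and are not listed.
// [[Rcpp::export]]
IntegerMatrix bdd_nodes(SEXP m, int f) {
  Mgr* p = get(m);
  check_handle(p, f);
  std::vector<char> seen(p->var_.size(), 0);
  std::vector<int> order, stack = {f};
  while (!stack.empty()) {
    int n = stack.back();
    stack.pop_back();
    if (n < 2 || seen[n]) continue;
    seen[n] = 1;
    order.push_back(n);
    stack.push_back(p->lo_[n]);
    stack.push_back(p->hi_[n]);
  }
  std::sort(order.begin(), order.end());
  IntegerMatrix out(order.size(), 4);
  for (size_t i = 0; i < order.size(); ++i) {
    int n = order[i];
    out(i, 0) = n;
    out(i, 1) = p->var_[n];
    out(i, 2) = p->lo_[n];
    out(i, 3) = p->hi_[n];
  }
  colnames(out) = CharacterVector::create("id", "var", "lo", "hi");
  return out;
}

// [[Rcpp::export]]
int bdd_node_var(SEXP m, int f) {
  Mgr* p = get(m);
  check_handle(p, f);
  return p->var_[f];
}

// [[Rcpp::export]]
int bdd_node_child(SEXP m, int f, bool high) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (f < 2) stop("terminal nodes have no children");
  return high ? p->hi_[f] : p->lo_[f];
}

// [[Rcpp::export]]
bool bdd_eval(SEXP m, int f, IntegerVector assign) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (assign.size() != p->nvars_) stop("assignment length must equal nvars");
  int n = f;
  while (n >= 2) n = assign[p->var_[n]] ? p->hi_[n] : p->lo_[n];
  return n == 1;
}

// Row-wise evaluation; columns of `assign` are BDD variables 0..nvars-1.
// [[Rcpp::export]]
LogicalVector bdd_eval_many(SEXP m, int f, IntegerMatrix assign) {
  Mgr* p = get(m);
  check_handle(p, f);
  if (assign.ncol() != p->nvars_) stop("assignment width must equal nvars");
  LogicalVector out(assign.nrow());
  for (int r = 0; r < assign.nrow(); ++r) {
    int n = f;
    while (n >= 2) n = assign(r, p->var_[n]) ? p->hi_[n] : p->lo_[n];
    out[r] = (n == 1);
  }
  return out;
}
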