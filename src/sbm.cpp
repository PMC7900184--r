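// Degree-corrected microcanonical stochastic block model:
// exact description length and a greedy agglomerative fit with
// node-level refinement sweeps.
//
// Description length (nats), flat (non-nested) model, simple undirected
// graphs.  With B blocks, block sizes n_r, block degree sums e_r,
// inter-block edge counts e_rs (r != s) and e_rr = twice the number of
// within-block edges, node degrees k_i, N nodes and E edges:
//
//   DL = -sum_{r<s} ln e_rs! - sum_r ln e_rr!! - sum_i ln k_i!
//        + sum_r ln e_r!                                   [edges | k,e,b]
//        + sum_r ln multiset(n_r, e_r)                     [degrees | e,b]
//        + ln multiset(B(B+1)/2, E)                        [e | b]
//        + ln C(N-1, B-1) + ln N! - sum_r ln n_r! + ln N   [b]
//
// where multiset(n, m) = C(n + m - 1, m) and x!! is the double factorial
// of an even x.  Lower is better.  The formula is exact (no Stirling
// approximations), so an exhaustive search over partitions with the same
// function is a valid optimality oracle on small graphs.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

typedef long long ll;

struct Lgf {
  // lgf[x] = lgamma(x + 1) = ln(x!)
  std::vector<double> tab;
  explicit Lgf(size_t maxv) {
    tab.resize(maxv + 2);
    for (size_t x = 0; x < tab.size(); ++x) tab[x] = lgamma((double)x + 1.0);
  }
  inline double operator()(ll x) const { return tab[(size_t)x]; }
};

// ln x!! for even x >= 0
inline double ldfact2(ll x, const Lgf& lgf) {
  return lgf(x) - 0.5 * (double)x * M_LN2 - lgf(x / 2);
}

// ln multiset(n, m) = ln C(n + m - 1, m)
inline double lms(ll n, ll m, const Lgf& lgf) {
  if (n == 0) return 0.0;  // only reachable with m == 0
  return lgf(n + m - 1) - lgf(m) - lgf(n - 1);
}

inline double lbinom(ll n, ll k, const Lgf& lgf) {
  return lgf(n) - lgf(k) - lgf(n - k);
}

struct Rng {
  // xorshift-free: explicit mt19937 kept deterministic across platforms by
  // avoiding std::shuffle / std::uniform_int_distribution.
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  inline uint32_t next(uint32_t k) { return eng() % k; }  // k >= 1
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = (int)next((uint32_t)(i + 1));
      std::swap(v[i], v[j]);
    }
  }
};

struct State {
  int n;        // nodes
  ll  E;        // edges
  int B;        // alive blocks
  std::vector<int> memb;                // node -> block slot
  std::vector<char> alive;              // block slot alive?
  std::vector<ll> nr, er;               // block sizes, block degree sums
  std::vector<ll> m;                    // flat n x n block edge-count matrix
  std::vector<std::vector<int>> adj;    // adjacency lists
  std::vector<ll> deg;
  double Ck;                            // sum_i ln k_i!
  const Lgf* lgf;

  inline ll& M(int r, int s) { return m[(size_t)r * n + s]; }
  inline ll Mv(int r, int s) const { return m[(size_t)r * n + s]; }

  void init(int n_, const IntegerMatrix& edges, const Lgf* lgf_) {
    n = n_; lgf = lgf_;
    E = edges.nrow();
    adj.assign(n, {});
    deg.assign(n, 0);
    for (int e = 0; e < (int)E; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      adj[a].push_back(b);
      adj[b].push_back(a);
      deg[a]++; deg[b]++;
    }
    Ck = 0.0;
    for (int i = 0; i < n; ++i) Ck += (*lgf)(deg[i]);
  }

  void set_membership(const std::vector<int>& mm) {
    memb = mm;
    alive.assign(n, 0);
    nr.assign(n, 0);
    er.assign(n, 0);
    m.assign((size_t)n * n, 0);
    B = 0;
    for (int i = 0; i < n; ++i) {
      int r = memb[i];
      if (!alive[r]) { alive[r] = 1; B++; }
      nr[r]++;
      er[r] += deg[i];
    }
    for (int i = 0; i < n; ++i)
      for (int j : adj[i]) {
        if (j < i) continue;
        int r = memb[i], s = memb[j];
        if (r == s) M(r, r) += 2;
        else { M(r, s) += 1; M(s, r) += 1; }
      }
  }

  double full_dl() const {
    const Lgf& lg = *lgf;
    double S = -Ck;
    for (int r = 0; r < n; ++r) {
      if (!alive[r]) continue;
      S -= ldfact2(Mv(r, r), lg);
      S += lg(er[r]);
      S += lms(nr[r], er[r], lg);
      S -= lg(nr[r]);
      for (int s = r + 1; s < n; ++s) {
        if (!alive[s]) continue;
        S -= lg(Mv(r, s));
      }
    }
    S += lms((ll)B * (B + 1) / 2, E, lg);
    S += lbinom(n - 1, B - 1, lg);
    S += lg(n);
    S += std::log((double)n);
    return S;
  }

  // DL change from merging block s into block r (B decreases by one).
  double delta_merge(int r, int s) const {
    const Lgf& lg = *lgf;
    double d = 0.0;
    for (int t = 0; t < n; ++t) {
      if (!alive[t] || t == r || t == s) continue;
      d += -lg(Mv(r, t) + Mv(s, t)) + lg(Mv(r, t)) + lg(Mv(s, t));
    }
    d += -ldfact2(Mv(r, r) + Mv(s, s) + 2 * Mv(r, s), lg)
         + ldfact2(Mv(r, r), lg) + ldfact2(Mv(s, s), lg) + lg(Mv(r, s));
    d += lg(er[r] + er[s]) - lg(er[r]) - lg(er[s]);
    d += lms(nr[r] + nr[s], er[r] + er[s], lg)
         - lms(nr[r], er[r], lg) - lms(nr[s], er[s], lg);
    d += -lg(nr[r] + nr[s]) + lg(nr[r]) + lg(nr[s]);
    d += lms((ll)(B - 1) * B / 2, E, lg) - lms((ll)B * (B + 1) / 2, E, lg);
    d += lbinom(n - 1, B - 2, lg) - lbinom(n - 1, B - 1, lg);
    return d;
  }

  void apply_merge(int r, int s) {
    for (int t = 0; t < n; ++t) {
      if (!alive[t] || t == r || t == s) continue;
      M(r, t) += M(s, t);
      M(t, r) = M(r, t);
      M(s, t) = 0; M(t, s) = 0;
    }
    M(r, r) += M(s, s) + 2 * M(r, s);
    M(r, s) = 0; M(s, r) = 0; M(s, s) = 0;
    er[r] += er[s]; er[s] = 0;
    nr[r] += nr[s]; nr[s] = 0;
    alive[s] = 0;
    B--;
    for (int i = 0; i < n; ++i) if (memb[i] == s) memb[i] = r;
  }

  // DL change from moving node i (block r, degree k, block-neighbour
  // counts c[]) to block s.  B is unchanged (caller forbids emptying r).
  double delta_move(int i, int r, int s, const std::vector<ll>& c,
                    const std::vector<int>& touched) const {
    const Lgf& lg = *lgf;
    ll k = deg[i];
    double d = 0.0;
    ll mrr = Mv(r, r), mss = Mv(s, s), mrs = Mv(r, s);
    d += -ldfact2(mrr - 2 * c[r], lg) + ldfact2(mrr, lg);
    d += -ldfact2(mss + 2 * c[s], lg) + ldfact2(mss, lg);
    d += -lg(mrs + c[r] - c[s]) + lg(mrs);
    for (int t : touched) {
      if (t == r || t == s) continue;
      d += -lg(Mv(r, t) - c[t]) + lg(Mv(r, t));
      d += -lg(Mv(s, t) + c[t]) + lg(Mv(s, t));
    }
    d += lg(er[r] - k) - lg(er[r]);
    d += lg(er[s] + k) - lg(er[s]);
    d += lms(nr[r] - 1, er[r] - k, lg) - lms(nr[r], er[r], lg);
    d += lms(nr[s] + 1, er[s] + k, lg) - lms(nr[s], er[s], lg);
    d += -lg(nr[r] - 1) + lg(nr[r]);
    d += -lg(nr[s] + 1) + lg(nr[s]);
    return d;
  }

  void apply_move(int i, int r, int s, const std::vector<ll>& c,
                  const std::vector<int>& touched) {
    for (int t : touched) {
      if (t == r || t == s) continue;
      M(r, t) -= c[t]; M(t, r) = M(r, t);
      M(s, t) += c[t]; M(t, s) = M(s, t);
    }
    M(r, r) -= 2 * c[r];
    M(s, s) += 2 * c[s];
    M(r, s) += c[r] - c[s];
    M(s, r) = M(r, s);
    er[r] -= deg[i]; er[s] += deg[i];
    nr[r] -= 1; nr[s] += 1;
    memb[i] = s;
  }
};

// Local refinement: sweep nodes in random order, accept strictly improving
// moves, stop after a sweep with no move.  Moves that would empty a block
// are skipped so B stays fixed.
void refine_sweeps(State& st, Rng& rng) {
  std::vector<int> order(st.n);
  for (int i = 0; i < st.n; ++i) order[i] = i;
  std::vector<ll> c(st.n, 0);
  std::vector<int> touched;
  bool improved = true;
  int guard = 0;
  while (improved && guard++ < 200) {
    improved = false;
    rng.shuffle(order);
    for (int idx = 0; idx < st.n; ++idx) {
      int i = order[idx];
      int r = st.memb[i];
      if (st.nr[r] <= 1) continue;
      touched.clear();
      for (int j : st.adj[i]) {
        int t = st.memb[j];
        if (c[t] == 0) touched.push_back(t);
        c[t]++;
      }
      double best_d = -1e-10;
      int best_s = -1;
      for (int s = 0; s < st.n; ++s) {
        if (!st.alive[s] || s == r) continue;
        double d = st.delta_move(i, r, s, c, touched);
        if (d < best_d - 1e-12) { best_d = d; best_s = s; }
      }
      if (best_s >= 0) {
        st.apply_move(i, r, best_s, c, touched);
        improved = true;
      }
      for (int t : touched) c[t] = 0;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sbm_dl_cpp")]]
double sbm_dl_cpp(int n, IntegerMatrix edges, IntegerVector membership) {
  ll E = edges.nrow();
  size_t maxv = (size_t)n * (n + 1) / 2 + 2 * (size_t)E + n + 10;
  Lgf lgf(maxv);
  State st;
  st.init(n, edges, &lgf);
  std::vector<int> mm(membership.begin(), membership.end());
  st.set_membership(mm);
  return st.full_dl();
}

// [[Rcpp::export(name = ".sbm_fit_cpp")]]
List sbm_fit_cpp(int n, IntegerMatrix edges, int seed) {
  ll E = edges.nrow();
  size_t maxv = (size_t)n * (n + 1) / 2 + 2 * (size_t)E + n + 10;
  Lgf lgf(maxv);
  Rng rng((uint32_t)seed);

  State st;
  st.init(n, edges, &lgf);
  std::vector<int> ident(n);
  for (int i = 0; i < n; ++i) ident[i] = i;
  st.set_membership(ident);

  // Greedy agglomeration from singletons down to one block, tracking the
  // DL along the way.  For large B only connected block pairs are
  // candidates (cheaper, rarely worse); for small B all pairs are.
  std::vector<std::pair<int, int>> merges;
  std::vector<double> dl_at(n + 1, R_PosInf);
  double dl = st.full_dl();
  dl_at[st.B] = dl;
  std::vector<int> cand_r, cand_s;
  std::vector<double> cand_d;
  while (st.B > 1) {
    cand_r.clear(); cand_s.clear(); cand_d.clear();
    bool adjacent_only = st.B > 40;
    for (int pass = 0; pass < 2; ++pass) {
      for (int r = 0; r < n; ++r) {
        if (!st.alive[r]) continue;
        for (int s = r + 1; s < n; ++s) {
          if (!st.alive[s]) continue;
          if (adjacent_only && st.Mv(r, s) == 0) continue;
          cand_r.push_back(r);
          cand_s.push_back(s);
        }
      }
      if (!cand_r.empty() || !adjacent_only) break;
      adjacent_only = false;  // disconnected at coarse level: widen
    }
    double best = R_PosInf;
    for (size_t q = 0; q < cand_r.size(); ++q) {
      double d = st.delta_merge(cand_r[q], cand_s[q]);
      cand_d.push_back(d);
      if (d < best) best = d;
    }
    std::vector<size_t> ties;
    for (size_t q = 0; q < cand_d.size(); ++q)
      if (cand_d[q] <= best + 1e-10) ties.push_back(q);
    size_t pick = ties[rng.next((uint32_t)ties.size())];
    int r = cand_r[pick], s = cand_s[pick];
    merges.push_back({r, s});
    st.apply_merge(r, s);
    dl += cand_d[pick];
    dl_at[st.B] = dl;
  }

  int Bstar = 1;
  for (int b = 1; b <= n; ++b)
    if (dl_at[b] < dl_at[Bstar]) Bstar = b;

  // Refine around the best merge level and keep the overall minimum.
  double best_dl = R_PosInf;
  std::vector<int> best_memb;
  for (int Bc = std::max(1, Bstar - 1); Bc <= std::min(n, Bstar + 1); ++Bc) {
    if (!R_finite(dl_at[Bc])) continue;
    std::vector<int> mm = ident;
    int nmerge = n - Bc;
    for (int q = 0; q < nmerge; ++q) {
      int r = merges[q].first, s = merges[q].second;
      for (int i = 0; i < n; ++i) if (mm[i] == s) mm[i] = r;
    }
    st.set_membership(mm);
    refine_sweeps(st, rng);
    double d = st.full_dl();
    if (d < best_dl) { best_dl = d; best_memb = st.memb; }
  }

  return List::create(_["membership"] = IntegerVector(best_memb.begin(),
                                                      best_memb.end()),
                      _["description_length"] = best_dl);
}
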