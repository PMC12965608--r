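// Score-based and constraint-based structure learning cores.
//
// Scores are decomposable BIC families (multinomial for discretized views,
// linear-Gaussian for rank-transformed views); per-node local scores are
// cached on parent-set bitmasks (p <= 31). Hill climbing and tabu search
// share one move enumerator with lexicographic (from, to) tie-breaking so
// runs are exactly reproducible.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <deque>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double MOVE_TOL = 1e-8;

struct ScoreCtx {
  int type;  // 0 = gaussian, 1 = discrete
  int n, p;
  double logn;
  arma::mat S;    // gaussian: MLE covariance (divisor n)
  arma::imat X;   // discrete: 0-based codes
  arma::ivec nlev;
  std::vector<std::unordered_map<uint32_t, double> > cache;

  ScoreCtx(const NumericMatrix& data, int type_, const IntegerVector& nlev_)
      : type(type_) {
    n = data.nrow();
    p = data.ncol();
    if (p > 31) stop("at most 31 variables are supported");
    logn = std::log((double)n);
    cache.resize(p);
    if (type == 0) {
      arma::mat M(data.begin(), n, p);
      arma::rowvec mu = arma::mean(M, 0);
      M.each_row() -= mu;
      S = (M.t() * M) / (double)n;
    } else {
      X.set_size(n, p);
      nlev.set_size(p);
      for (int j = 0; j < p; ++j) nlev(j) = nlev_[j];
      for (int j = 0; j < p; ++j)
        for (int i = 0; i < n; ++i) {
          int c = (int)data(i, j) - 1;
          if (c < 0 || c >= nlev(j)) stop("discrete code out of range");
          X(i, j) = c;
        }
    }
  }

  double local_raw(int v, uint32_t mask) {
    std::vector<int> ps;
    for (int j = 0; j < p; ++j)
      if (mask >> j & 1u) ps.push_back(j);
    if (type == 0) {
      double sigma2;
      if (ps.empty()) {
        sigma2 = S(v, v);
      } else {
        arma::uvec idx(ps.size());
        for (size_t k = 0; k < ps.size(); ++k) idx(k) = ps[k];
        arma::mat SPP = S.submat(idx, idx);
        arma::vec sPv(ps.size());
        for (size_t k = 0; k < ps.size(); ++k) sPv(k) = S(ps[k], v);
        arma::vec b;
        bool ok = arma::solve(b, SPP, sPv, arma::solve_opts::likely_sympd);
        if (!ok) return NEG_INF;
        sigma2 = S(v, v) - arma::dot(sPv, b);
      }
      sigma2 = std::max(sigma2, 1e-10);
      double ll = -0.5 * n * (std::log(2.0 * M_PI * sigma2) + 1.0);
      return ll - 0.5 * logn * (double)(ps.size() + 2);
    }
    // discrete multinomial BIC
    long long q = 1;
    for (size_t k = 0; k < ps.size(); ++k) {
      q *= nlev(ps[k]);
      if (q > 200000) return NEG_INF;  // parameter blow-up guard
    }
    int r = nlev(v);
    std::vector<int> njk((size_t)q * r, 0), nj((size_t)q, 0);
    for (int i = 0; i < n; ++i) {
      long long idx = 0;
      for (size_t k = 0; k < ps.size(); ++k) idx = idx * nlev(ps[k]) + X(i, ps[k]);
      njk[(size_t)idx * r + X(i, v)]++;
      nj[(size_t)idx]++;
    }
    double ll = 0.0;
    for (long long j = 0; j < q; ++j) {
      if (nj[(size_t)j] == 0) continue;
      for (int k = 0; k < r; ++k) {
        int c = njk[(size_t)j * r + k];
        if (c > 0) ll += c * std::log((double)c / nj[(size_t)j]);
      }
    }
    return ll - 0.5 * logn * (double)(r - 1) * (double)q;
  }

  double local(int v, uint32_t mask) {
    std::unordered_map<uint32_t, double>& cv = cache[v];
    std::unordered_map<uint32_t, double>::iterator it = cv.find(mask);
    if (it != cv.end()) return it->second;
    double s = local_raw(v, mask);
    cv[mask] = s;
    return s;
  }
};

static bool has_path(int from, int to, const std::vector<uint32_t>& pa, int p) {
  if (from == to) return true;
  std::vector<char> vis(p, 0);
  std::vector<int> stk;
  stk.push_back(from);
  vis[from] = 1;
  while (!stk.empty()) {
    int u = stk.back();
    stk.pop_back();
    for (int k = 0; k < p; ++k) {
      if (!vis[k] && (pa[k] >> u & 1u)) {
        if (k == to) return true;
        vis[k] = 1;
        stk.push_back(k);
      }
    }
  }
  return false;
}

static uint64_t hash_pa(const std::vector<uint32_t>& pa) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < pa.size(); ++i) {
    uint32_t m = pa[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (m >> (8 * b)) & 0xFFu;
      h *= 1099511628211ULL;
    }
  }
  return h;
}

struct Move {
  int op;  // 0 none, 1 add, 2 delete, 3 reverse
  int from, to;
  double delta;
};

// Enumerate admissible moves in lexicographic (from, to, add<delete<reverse)
// order; first strict improvement over the running best wins ties.
static Move best_move(ScoreCtx& ctx, std::vector<uint32_t>& pa,
                      const LogicalMatrix& bl, const Nullable<LogicalMatrix>& rs_,
                      bool use_tabu, const std::deque<uint64_t>& tabu) {
  const int p = ctx.p;
  LogicalMatrix rs;
  bool restricted = rs_.isNotNull();
  if (restricted) rs = rs_.get();
  Move bm;
  bm.op = 0;
  bm.delta = NEG_INF;

  std::vector<uint64_t> tb(tabu.begin(), tabu.end());
  for (int from = 0; from < p; ++from) {
    for (int to = 0; to < p; ++to) {
      if (from == to) continue;
      bool present = (pa[to] >> from) & 1u;
      if (!present) {
        if (bl(from, to)) continue;
        if (restricted && !rs(from, to)) continue;
        if (has_path(to, from, pa, p)) continue;
        double d = ctx.local(to, pa[to] | (1u << from)) - ctx.local(to, pa[to]);
        if (d > bm.delta) {
          if (use_tabu) {
            pa[to] |= (1u << from);
            uint64_t h = hash_pa(pa);
            pa[to] &= ~(1u << from);
            if (std::find(tb.begin(), tb.end(), h) != tb.end()) continue;
          }
          bm.op = 1; bm.from = from; bm.to = to; bm.delta = d;
        }
      } else {
        // delete
        double d = ctx.local(to, pa[to] & ~(1u << from)) - ctx.local(to, pa[to]);
        if (d > bm.delta) {
          bool ok = true;
          if (use_tabu) {
            pa[to] &= ~(1u << from);
            uint64_t h = hash_pa(pa);
            pa[to] |= (1u << from);
            ok = std::find(tb.begin(), tb.end(), h) == tb.end();
          }
          if (ok) { bm.op = 2; bm.from = from; bm.to = to; bm.delta = d; }
        }
        // reverse from->to into to->from
        if (!bl(to, from)) {
          pa[to] &= ~(1u << from);
          bool cyc = has_path(from, to, pa, p);
          pa[to] |= (1u << from);
          if (!cyc) {
            double d2 = (ctx.local(to, pa[to] & ~(1u << from)) - ctx.local(to, pa[to])) +
                        (ctx.local(from, pa[from] | (1u << to)) - ctx.local(from, pa[from]));
            if (d2 > bm.delta) {
              bool ok = true;
              if (use_tabu) {
                pa[to] &= ~(1u << from);
                pa[from] |= (1u << to);
                uint64_t h = hash_pa(pa);
                pa[from] &= ~(1u << to);
                pa[to] |= (1u << from);
                ok = std::find(tb.begin(), tb.end(), h) == tb.end();
              }
              if (ok) { bm.op = 3; bm.from = from; bm.to = to; bm.delta = d2; }
            }
          }
        }
      }
    }
  }
  return bm;
}

static void apply_move(std::vector<uint32_t>& pa, const Move& m) {
  if (m.op == 1) pa[m.to] |= (1u << m.from);
  else if (m.op == 2) pa[m.to] &= ~(1u << m.from);
  else if (m.op == 3) {
    pa[m.to] &= ~(1u << m.from);
    pa[m.from] |= (1u << m.to);
  }
}

static List pack_result(const std::vector<uint32_t>& pa, int p, double score,
                        bool truncated) {
  int na = 0;
  for (int j = 0; j < p; ++j) na += __builtin_popcount(pa[j]);
  IntegerMatrix arcs(na, 2);
  int k = 0;
  for (int from = 0; from < p; ++from)
    for (int to = 0; to < p; ++to)
      if ((pa[to] >> from) & 1u) {
        arcs(k, 0) = from + 1;
        arcs(k, 1) = to + 1;
        ++k;
      }
  return List::create(_["arcs"] = arcs, _["score"] = score,
                      _["truncated"] = truncated);
}

// algo: 0 = hill climbing, 1 = tabu search
// [[Rcpp::export]]
List cc_search(const NumericMatrix& data, int type, const IntegerVector& nlev,
               const LogicalMatrix& bl, const Nullable<LogicalMatrix>& restrict_,
               int algo, int tabu_length, int max_worsening, int max_iter) {
  ScoreCtx ctx(data, type, nlev);
  const int p = ctx.p;
  std::vector<uint32_t> pa(p, 0u);
  double cur = 0.0;
  for (int v = 0; v < p; ++v) cur += ctx.local(v, 0u);

  std::deque<uint64_t> tabu;
  bool use_tabu = (algo == 1);
  if (use_tabu) tabu.push_back(hash_pa(pa));
  std::vector<uint32_t> best_pa = pa;
  double best = cur;
  int worsening = 0;
  bool truncated = true;

  for (int it = 0; it < max_iter; ++it) {
    Move m = best_move(ctx, pa, bl, restrict_, use_tabu, tabu);
    if (m.op == 0) { truncated = false; break; }
    if (!use_tabu) {
      if (m.delta <= MOVE_TOL) { truncated = false; break; }
      apply_move(pa, m);
      cur += m.delta;
      best_pa = pa;
      best = cur;
    } else {
      if (m.delta <= MOVE_TOL && worsening >= max_worsening) {
        truncated = false;
        break;
      }
      apply_move(pa, m);
      cur += m.delta;
      tabu.push_back(hash_pa(pa));
      while ((int)tabu.size() > tabu_length + 1) tabu.pop_front();
      if (cur > best + MOVE_TOL) {
        best = cur;
        best_pa = pa;
        worsening = 0;
      } else {
        ++worsening;
      }
    }
  }
  return pack_result(best_pa, p, best, truncated);
}

// [[Rcpp::export]]
double cc_local_score(const NumericMatrix& data, int type, const IntegerVector& nlev,
                      int v, const IntegerVector& parents) {
  ScoreCtx ctx(data, type, nlev);
  uint32_t mask = 0;
  for (int k = 0; k < parents.size(); ++k) mask |= (1u << (parents[k] - 1));
  return ctx.local(v - 1, mask);
}

// ---------------------------------------------------------------------------
// Conditional independence tests
// ---------------------------------------------------------------------------

static double ci_gauss(const ScoreCtx& ctx, int x, int y, const std::vector<int>& Z) {
  int d = Z.size();
  if (ctx.n - d - 3 <= 0) return 1.0;
  arma::uvec idx(d + 2);
  idx(0) = x;
  idx(1) = y;
  for (int k = 0; k < d; ++k) idx(k + 2) = Z[k];
  arma::mat M = ctx.S.submat(idx, idx);
  arma::mat P;
  if (!arma::inv_sympd(P, M)) {
    arma::mat Mj = M;
    Mj.diag() += 1e-8;
    P = arma::pinv(Mj);
  }
  double r = -P(0, 1) / std::sqrt(std::max(P(0, 0) * P(1, 1), 1e-300));
  r = std::max(std::min(r, 1.0 - 1e-12), -1.0 + 1e-12);
  double z = 0.5 * std::log((1.0 + r) / (1.0 - r)) * std::sqrt((double)(ctx.n - d - 3));
  return 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

static double ci_disc(const ScoreCtx& ctx, int x, int y, const std::vector<int>& Z) {
  int rx = ctx.nlev(x), ry = ctx.nlev(y);
  std::unordered_map<uint64_t, std::vector<int> > tabs;  // z-config -> rx*ry counts
  for (int i = 0; i < ctx.n; ++i) {
    uint64_t zi = 0;
    for (size_t k = 0; k < Z.size(); ++k) zi = zi * ctx.nlev(Z[k]) + ctx.X(i, Z[k]);
    std::vector<int>& t = tabs[zi];
    if (t.empty()) t.assign((size_t)rx * ry, 0);
    t[(size_t)ctx.X(i, x) * ry + ctx.X(i, y)]++;
  }
  double g2 = 0.0;
  int nzcfg = 0;
  for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = tabs.begin();
       it != tabs.end(); ++it) {
    const std::vector<int>& t = it->second;
    std::vector<int> rx_m(rx, 0), ry_m(ry, 0);
    int nz = 0;
    for (int a = 0; a < rx; ++a)
      for (int b = 0; b < ry; ++b) {
        int c = t[(size_t)a * ry + b];
        rx_m[a] += c;
        ry_m[b] += c;
        nz += c;
      }
    if (nz == 0) continue;
    ++nzcfg;
    for (int a = 0; a < rx; ++a)
      for (int b = 0; b < ry; ++b) {
        int c = t[(size_t)a * ry + b];
        if (c > 0)
          g2 += 2.0 * c * std::log((double)c * nz / ((double)rx_m[a] * ry_m[b]));
      }
  }
  double df = std::max(1.0, (double)nzcfg * (rx - 1) * (ry - 1));
  return R::pchisq(g2, df, 0, 0);
}

static double ci_test(const ScoreCtx& ctx, int x, int y, const std::vector<int>& Z) {
  return ctx.type == 0 ? ci_gauss(ctx, x, y, Z) : ci_disc(ctx, x, y, Z);
}

// [[Rcpp::export]]
double cc_citest(const NumericMatrix& data, int type, const IntegerVector& nlev,
                 int x, int y, const IntegerVector& Z) {
  ScoreCtx ctx(data, type, nlev);
  std::vector<int> zz;
  for (int k = 0; k < Z.size(); ++k) zz.push_back(Z[k] - 1);
  return ci_test(ctx, x - 1, y - 1, zz);
}

// ---------------------------------------------------------------------------
// MMPC-style parents-and-children discovery (max-min heuristic; candidates
// whose running max p-value over conditioning subsets exceeds alpha are
// permanently excluded).
// ---------------------------------------------------------------------------

static const int MAX_SUBSET = 8;   // conditioning-set size cap
static const int MAX_CPC = 12;

static void subsets_of(const std::vector<int>& pool, int cap,
                       std::vector<std::vector<int> >& out) {
  int m = pool.size();
  int lim = 1 << m;
  for (int msk = 0; msk < lim; ++msk) {
    if (__builtin_popcount((unsigned)msk) > cap) continue;
    std::vector<int> s;
    for (int k = 0; k < m; ++k)
      if (msk >> k & 1) s.push_back(pool[k]);
    out.push_back(s);
  }
}

static std::vector<int> pc_search(ScoreCtx& ctx, int T, double alpha,
                                  const std::vector<int>& candidates,
                                  const std::vector<double>& marg_p) {
  std::vector<int> cand;
  std::vector<double> maxp;
  for (size_t k = 0; k < candidates.size(); ++k) {
    if (marg_p[k] <= alpha) {
      cand.push_back(candidates[k]);
      maxp.push_back(marg_p[k]);
    }
  }
  std::vector<int> cpc;
  while (!cand.empty() && (int)cpc.size() < MAX_CPC) {
    // pick max-min candidate: smallest running max p-value
    size_t bi = 0;
    for (size_t k = 1; k < cand.size(); ++k)
      if (maxp[k] < maxp[bi]) bi = k;
    int Xn = cand[bi];
    cpc.push_back(Xn);
    cand.erase(cand.begin() + bi);
    maxp.erase(maxp.begin() + bi);
    if (cand.empty()) break;
    // refresh remaining candidates on subsets that include the new member
    std::vector<int> rest(cpc.begin(), cpc.end() - 1);
    std::vector<std::vector<int> > subs;
    subsets_of(rest, MAX_SUBSET - 1, subs);
    for (size_t si = 0; si < subs.size(); ++si) subs[si].push_back(Xn);
    for (int k = (int)cand.size() - 1; k >= 0; --k) {
      for (size_t si = 0; si < subs.size(); ++si) {
        double pv = ci_test(ctx, cand[k], T, subs[si]);
        if (pv > maxp[k]) maxp[k] = pv;
        if (maxp[k] > alpha) break;
      }
      if (maxp[k] > alpha) {
        cand.erase(cand.begin() + k);
        maxp.erase(maxp.begin() + k);
      }
    }
  }
  // backward: drop members independent of T given some subset of the rest
  for (int k = (int)cpc.size() - 1; k >= 0; --k) {
    std::vector<int> rest;
    for (size_t m = 0; m < cpc.size(); ++m)
      if ((int)m != k) rest.push_back(cpc[m]);
    std::vector<std::vector<int> > subs;
    subsets_of(rest, MAX_SUBSET, subs);
    for (size_t si = 0; si < subs.size(); ++si) {
      if (ci_test(ctx, cpc[k], T, subs[si]) > alpha) {
        cpc.erase(cpc.begin() + k);
        break;
      }
    }
  }
  return cpc;
}

// method: 0 = mmpc, 1 = hpc (parents-and-children-superset pool expanded by
// one neighborhood, then the same subset-filtered PC search)
// [[Rcpp::export]]
LogicalMatrix cc_skeleton(const NumericMatrix& data, int type, const IntegerVector& nlev,
                          int method, double alpha) {
  ScoreCtx ctx(data, type, nlev);
  const int p = ctx.p;
  std::vector<int> empty;
  // marginal p-value matrix
  arma::mat pm(p, p, arma::fill::ones);
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double pv = ci_test(ctx, i, j, empty);
      pm(i, j) = pm(j, i) = pv;
    }

  std::vector<std::vector<int> > pcs(p);
  if (method == 1) {
    // PCS: marginally dependent, pruned by single-variable conditioning
    for (int T = 0; T < p; ++T) {
      std::vector<int> s0;
      for (int X = 0; X < p; ++X)
        if (X != T && pm(X, T) <= alpha) s0.push_back(X);
      for (size_t k = 0; k < s0.size(); ++k) {
        bool keep = true;
        for (size_t m = 0; m < s0.size() && keep; ++m) {
          if (m == k) continue;
          std::vector<int> Z(1, s0[m]);
          if (ci_test(ctx, s0[k], T, Z) > alpha) keep = false;
        }
        if (keep) pcs[T].push_back(s0[k]);
      }
    }
  }

  std::vector<std::vector<int> > pc(p);
  for (int T = 0; T < p; ++T) {
    std::vector<int> candidates;
    if (method == 0) {
      for (int X = 0; X < p; ++X)
        if (X != T) candidates.push_back(X);
    } else {
      std::vector<char> in(p, 0);
      for (size_t k = 0; k < pcs[T].size(); ++k) {
        in[pcs[T][k]] = 1;
        const std::vector<int>& nb = pcs[pcs[T][k]];
        for (size_t m = 0; m < nb.size(); ++m)
          if (nb[m] != T) in[nb[m]] = 1;
      }
      for (int X = 0; X < p; ++X)
        if (X != T && in[X]) candidates.push_back(X);
    }
    std::vector<double> marg(candidates.size());
    for (size_t k = 0; k < candidates.size(); ++k) marg[k] = pm(candidates[k], T);
    pc[T] = pc_search(ctx, T, alpha, candidates, marg);
  }

  // AND-symmetrization
  LogicalMatrix adj(p, p);
  for (int i = 0; i < p; ++i)
    for (size_t k = 0; k < pc[i].size(); ++k) {
      int j = pc[i][k];
      const std::vector<int>& pj = pc[j];
      if (std::find(pj.begin(), pj.end(), i) != pj.end()) adj(i, j) = true;
    }
  return adj;
}
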