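// Multivariate polynomials over Q with lexicographic order (variable 0 ranks
// highest), multivariate division, S-polynomials and Buchberger's algorithm.
// Buchberger runs fraction-free on content-stripped integer polynomials; the
// reduced basis is returned monic over Q.
#ifndef SWITCHSCAN_POLY_H
#define SWITCHSCAN_POLY_H

#include "bigrat.h"
#include <map>
#include <set>
#include <utility>

namespace swsc {

typedef std::vector<int> Expo;

inline int lexCmpExpo(const Expo &a, const Expo &b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

inline bool expoDivides(const Expo &div, const Expo &e) { // div | e
  for (size_t i = 0; i < div.size(); ++i) if (div[i] > e[i]) return false;
  return true;
}

inline Expo expoSub(const Expo &a, const Expo &b) {
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] - b[i];
  return r;
}

inline Expo expoAdd(const Expo &a, const Expo &b) {
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] + b[i];
  return r;
}

inline Expo expoMax(const Expo &a, const Expo &b) {
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = std::max(a[i], b[i]);
  return r;
}

inline int expoTotal(const Expo &a) { int s = 0; for (size_t i = 0; i < a.size(); ++i) s += a[i]; return s; }

// ---- rational-coefficient polynomial ---------------------------------------

struct QTerm { Expo e; Rat c; };

// terms sorted descending lex, no zero coefficients
struct QPoly {
  int nv;
  std::vector<QTerm> t;
  explicit QPoly(int n = 0) : nv(n) {}
  bool isZero() const { return t.empty(); }
};

inline void qNormalize(QPoly &p) {
  std::sort(p.t.begin(), p.t.end(),
            [](const QTerm &a, const QTerm &b) { return lexCmpExpo(a.e, b.e) > 0; });
  std::vector<QTerm> out;
  for (size_t i = 0; i < p.t.size(); ++i) {
    if (!out.empty() && lexCmpExpo(out.back().e, p.t[i].e) == 0) {
      out.back().c = radd(out.back().c, p.t[i].c);
      if (out.back().c.isZero()) out.pop_back();
    } else if (!p.t[i].c.isZero()) {
      out.push_back(p.t[i]);
    }
  }
  p.t.swap(out);
}

inline QPoly qAdd(const QPoly &a, const QPoly &b) {
  QPoly r(a.nv);
  size_t i = 0, j = 0;
  while (i < a.t.size() || j < b.t.size()) {
    if (j >= b.t.size()) { r.t.push_back(a.t[i++]); continue; }
    if (i >= a.t.size()) { r.t.push_back(b.t[j++]); continue; }
    int c = lexCmpExpo(a.t[i].e, b.t[j].e);
    if (c > 0) r.t.push_back(a.t[i++]);
    else if (c < 0) r.t.push_back(b.t[j++]);
    else {
      Rat s = radd(a.t[i].c, b.t[j].c);
      if (!s.isZero()) { QTerm tt; tt.e = a.t[i].e; tt.c = s; r.t.push_back(tt); }
      ++i; ++j;
    }
  }
  return r;
}

inline QPoly qScale(const QPoly &a, const Rat &s) {
  QPoly r(a.nv);
  if (s.isZero()) return r;
  r.t = a.t;
  for (size_t i = 0; i < r.t.size(); ++i) r.t[i].c = rmul(r.t[i].c, s);
  return r;
}

inline QPoly qNeg(const QPoly &a) { return qScale(a, Rat(-1)); }
inline QPoly qSub(const QPoly &a, const QPoly &b) { return qAdd(a, qNeg(b)); }

inline QPoly qMul(const QPoly &a, const QPoly &b) {
  QPoly r(a.nv);
  if (a.isZero() || b.isZero()) return r;
  // accumulate via map keyed by exponent
  std::map<Expo, Rat, bool (*)(const Expo &, const Expo &)> acc(
      [](const Expo &x, const Expo &y) { return lexCmpExpo(x, y) > 0; });
  for (size_t i = 0; i < a.t.size(); ++i) {
    for (size_t j = 0; j < b.t.size(); ++j) {
      Expo e = expoAdd(a.t[i].e, b.t[j].e);
      Rat c = rmul(a.t[i].c, b.t[j].c);
      auto it = acc.find(e);
      if (it == acc.end()) acc.emplace(e, c);
      else it->second = radd(it->second, c);
    }
  }
  for (auto &kv : acc) {
    if (!kv.second.isZero()) { QTerm tt; tt.e = kv.first; tt.c = kv.second; r.t.push_back(tt); }
  }
  return r;
}

// multiply by monomial coef*x^shift
inline QPoly qMulMono(const QPoly &a, const Rat &c, const Expo &shift) {
  QPoly r(a.nv);
  if (a.isZero() || c.isZero()) return r;
  r.t = a.t;
  for (size_t i = 0; i < r.t.size(); ++i) {
    r.t[i].e = expoAdd(r.t[i].e, shift);
    r.t[i].c = rmul(r.t[i].c, c);
  }
  return r;
}

inline QPoly qPow(const QPoly &a, int k) {
  QPoly r(a.nv);
  QTerm one; one.e.assign(a.nv, 0); one.c = Rat(1);
  r.t.push_back(one);
  QPoly base = a;
  while (k > 0) {
    if (k & 1) r = qMul(r, base);
    k >>= 1;
    if (k) base = qMul(base, base);
  }
  return r;
}

inline QPoly qDeriv(const QPoly &a, int var) {
  QPoly r(a.nv);
  for (size_t i = 0; i < a.t.size(); ++i) {
    if (a.t[i].e[var] > 0) {
      QTerm tt;
      tt.e = a.t[i].e;
      tt.c = rmul(a.t[i].c, Rat(tt.e[var]));
      tt.e[var] -= 1;
      r.t.push_back(tt);
    }
  }
  return r;
}

// Full multivariate division: remainder has no term divisible by any leading term.
inline QPoly qReduce(const QPoly &p, const std::vector<QPoly> &G) {
  QPoly r = p;
  size_t i = 0;
  while (i < r.t.size()) {
    bool reduced = false;
    for (size_t k = 0; k < G.size(); ++k) {
      if (G[k].isZero()) continue;
      const QTerm &lt = G[k].t[0];
      if (expoDivides(lt.e, r.t[i].e)) {
        Rat factor = rdiv(r.t[i].c, lt.c);
        r = qSub(r, qMulMono(G[k], factor, expoSub(r.t[i].e, lt.e)));
        reduced = true;
        break;
      }
    }
    if (!reduced) ++i;
    // after a reduction the first i terms are unchanged monomials (still
    // irreducible); term i was cancelled, so re-testing index i is correct.
  }
  return r;
}

inline QPoly qSPoly(const QPoly &f, const QPoly &g) {
  if (f.isZero() || g.isZero()) throw std::runtime_error("S-polynomial of zero polynomial");
  Expo gamma = expoMax(f.t[0].e, g.t[0].e);
  QPoly a = qMulMono(f, rdiv(Rat(1), f.t[0].c), expoSub(gamma, f.t[0].e));
  QPoly b = qMulMono(g, rdiv(Rat(1), g.t[0].c), expoSub(gamma, g.t[0].e));
  return qSub(a, b);
}

// Exact multivariate division p / q; returns false if not divisible.
inline bool qExactDiv(const QPoly &p, const QPoly &q, QPoly &out) {
  if (q.isZero()) throw std::runtime_error("division by zero polynomial");
  QPoly r = p;
  out = QPoly(p.nv);
  while (!r.isZero()) {
    const QTerm &lr = r.t[0];
    const QTerm &lq = q.t[0];
    if (!expoDivides(lq.e, lr.e)) return false;
    QTerm h;
    h.e = expoSub(lr.e, lq.e);
    h.c = rdiv(lr.c, lq.c);
    out.t.push_back(h);
    r = qSub(r, qMulMono(q, h.c, h.e));
  }
  qNormalize(out);
  return true;
}

// ---- integer (fraction-free) polynomials for Buchberger ---------------------

struct ITerm { Expo e; BigInt c; };
struct IPoly {
  int nv;
  std::vector<ITerm> t; // sorted descending lex
  explicit IPoly(int n = 0) : nv(n) {}
  bool isZero() const { return t.empty(); }
};

inline void iPrimitivize(IPoly &p) {
  if (p.isZero()) return;
  BigInt g = absB(p.t[0].c);
  for (size_t i = 1; i < p.t.size() && !(g.d.size() == 1 && g.d[0] == 1); ++i)
    g = gcdB(g, p.t[i].c);
  bool flip = p.t[0].c.sign < 0;
  if (flip) g.sign = -1;
  if (!(g.d.size() == 1 && g.d[0] == 1 && g.sign == 1)) {
    for (size_t i = 0; i < p.t.size(); ++i) p.t[i].c = divExact(p.t[i].c, g);
  }
}

inline IPoly iFromQ(const QPoly &q) {
  IPoly r(q.nv);
  if (q.isZero()) return r;
  BigInt l(1);
  for (size_t i = 0; i < q.t.size(); ++i) {
    BigInt g = gcdB(l, q.t[i].c.d);
    l = mul(divExact(l, g), q.t[i].c.d);
  }
  for (size_t i = 0; i < q.t.size(); ++i) {
    ITerm tt;
    tt.e = q.t[i].e;
    tt.c = mul(q.t[i].c.n, divExact(l, q.t[i].c.d));
    r.t.push_back(tt);
  }
  iPrimitivize(r);
  return r;
}

inline QPoly qFromIMonic(const IPoly &p) {
  QPoly r(p.nv);
  if (p.isZero()) return r;
  const BigInt &lc = p.t[0].c;
  for (size_t i = 0; i < p.t.size(); ++i) {
    QTerm tt;
    tt.e = p.t[i].e;
    tt.c = Rat(p.t[i].c, lc);
    r.t.push_back(tt);
  }
  return r;
}

// r <- a*r - b * x^shift * g   (merge; a,b integers, a from lc(g))
inline IPoly iCombine(const IPoly &r, const BigInt &a, const BigInt &b,
                      const Expo &shift, const IPoly &g) {
  IPoly out(r.nv);
  size_t i = 0, j = 0;
  BigInt nb = neg(b);
  while (i < r.t.size() || j < g.t.size()) {
    if (j >= g.t.size()) {
      ITerm tt; tt.e = r.t[i].e; tt.c = mul(r.t[i].c, a);
      if (!tt.c.isZero()) out.t.push_back(tt);
      ++i; continue;
    }
    Expo ge = expoAdd(g.t[j].e, shift);
    if (i >= r.t.size()) {
      ITerm tt; tt.e = ge; tt.c = mul(g.t[j].c, nb);
      if (!tt.c.isZero()) out.t.push_back(tt);
      ++j; continue;
    }
    int c = lexCmpExpo(r.t[i].e, ge);
    if (c > 0) {
      ITerm tt; tt.e = r.t[i].e; tt.c = mul(r.t[i].c, a);
      if (!tt.c.isZero()) out.t.push_back(tt);
      ++i;
    } else if (c < 0) {
      ITerm tt; tt.e = ge; tt.c = mul(g.t[j].c, nb);
      if (!tt.c.isZero()) out.t.push_back(tt);
      ++j;
    } else {
      ITerm tt; tt.e = ge;
      tt.c = add(mul(r.t[i].c, a), mul(g.t[j].c, nb));
      if (!tt.c.isZero()) out.t.push_back(tt);
      ++i; ++j;
    }
  }
  return out;
}

// fraction-free full normal form (remainder scaled by a positive rational)
inline IPoly iNormalForm(const IPoly &p, const std::vector<IPoly> &G) {
  IPoly r = p;
  size_t i = 0;
  while (i < r.t.size()) {
    bool reduced = false;
    for (size_t k = 0; k < G.size(); ++k) {
      if (G[k].isZero()) continue;
      const ITerm &lt = G[k].t[0];
      if (expoDivides(lt.e, r.t[i].e)) {
        BigInt d = gcdB(lt.c, r.t[i].c);
        BigInt a = divExact(lt.c, d);
        BigInt b = divExact(r.t[i].c, d);
        // keep the multiplier on r positive so orientation is stable
        if (a.sign < 0) { a.sign = 1; b.sign = -b.sign; }
        r = iCombine(r, a, b, expoSub(r.t[i].e, lt.e), G[k]);
        iPrimitivize(r);
        reduced = true;
        break;
      }
    }
    if (!reduced) ++i;
  }
  return r;
}

inline IPoly iSPoly(const IPoly &f, const IPoly &g) {
  Expo gamma = expoMax(f.t[0].e, g.t[0].e);
  BigInt d = gcdB(f.t[0].c, g.t[0].c);
  BigInt a = divExact(g.t[0].c, d); // multiplies f
  BigInt b = divExact(f.t[0].c, d); // multiplies g
  // S = a * x^(gamma-ltf) * f - b * x^(gamma-ltg) * g
  IPoly fa = f;
  Expo sf = expoSub(gamma, f.t[0].e);
  for (size_t i = 0; i < fa.t.size(); ++i) {
    fa.t[i].e = expoAdd(fa.t[i].e, sf);
    fa.t[i].c = mul(fa.t[i].c, a);
  }
  IPoly out = iCombine(fa, BigInt(1), b, expoSub(gamma, g.t[0].e), g);
  iPrimitivize(out);
  return out;
}

struct GBError : std::runtime_error {
  explicit GBError(const std::string &m) : std::runtime_error(m) {}
};

// Buchberger with product + chain criteria, normal selection strategy.
inline std::vector<IPoly> buchberger(std::vector<IPoly> F, long pairCap, long *pairsUsed) {
  std::vector<IPoly> G;
  for (size_t i = 0; i < F.size(); ++i) {
    if (!F[i].isZero()) { iPrimitivize(F[i]); G.push_back(F[i]); }
  }
  if (G.empty()) return G;
  int nv = G[0].nv;
  (void)nv;
  std::set<std::pair<size_t, size_t>> done;
  std::vector<std::pair<size_t, size_t>> queue;
  for (size_t i = 0; i < G.size(); ++i)
    for (size_t j = i + 1; j < G.size(); ++j) queue.push_back(std::make_pair(i, j));
  long processed = 0;
  while (!queue.empty()) {
    // normal strategy: minimal total degree of lcm, then lex-smallest lcm
    size_t best = 0;
    Expo bestL = expoMax(G[queue[0].first].t[0].e, G[queue[0].second].t[0].e);
    int bestD = expoTotal(bestL);
    for (size_t q = 1; q < queue.size(); ++q) {
      Expo L = expoMax(G[queue[q].first].t[0].e, G[queue[q].second].t[0].e);
      int D = expoTotal(L);
      if (D < bestD || (D == bestD && lexCmpExpo(L, bestL) < 0)) {
        best = q; bestL = L; bestD = D;
      }
    }
    std::pair<size_t, size_t> pr = queue[best];
    queue.erase(queue.begin() + best);
    done.insert(pr);
    if (++processed > pairCap) throw GBError("S-pair limit exceeded (raise pairCap)");
    const IPoly &f = G[pr.first], &g = G[pr.second];
    // product criterion: coprime leading monomials
    bool coprime = true;
    for (size_t v = 0; v < f.t[0].e.size(); ++v)
      if (f.t[0].e[v] > 0 && g.t[0].e[v] > 0) { coprime = false; break; }
    if (coprime) continue;
    // chain criterion
    bool skip = false;
    Expo L = expoMax(f.t[0].e, g.t[0].e);
    for (size_t k = 0; k < G.size() && !skip; ++k) {
      if (k == pr.first || k == pr.second) continue;
      if (!expoDivides(G[k].t[0].e, L)) continue;
      std::pair<size_t, size_t> p1(std::min(k, pr.first), std::max(k, pr.first));
      std::pair<size_t, size_t> p2(std::min(k, pr.second), std::max(k, pr.second));
      if (done.count(p1) && done.count(p2)) skip = true;
    }
    if (skip) continue;
    IPoly h = iNormalForm(iSPoly(f, g), G);
    if (!h.isZero()) {
      G.push_back(h);
      size_t newIdx = G.size() - 1;
      for (size_t i = 0; i < newIdx; ++i) queue.push_back(std::make_pair(i, newIdx));
    }
  }
  if (pairsUsed) *pairsUsed = processed;
  // minimalize: drop elements whose leading term is divisible by another's
  std::vector<bool> keep(G.size(), true);
  for (size_t i = 0; i < G.size(); ++i) {
    if (!keep[i]) continue;
    for (size_t j = 0; j < G.size(); ++j) {
      if (i == j || !keep[j]) continue;
      if (expoDivides(G[j].t[0].e, G[i].t[0].e)) {
        // drop i unless same lt and j>i (keep the first of identical lts)
        if (lexCmpExpo(G[j].t[0].e, G[i].t[0].e) == 0 && j > i) continue;
        keep[i] = false;
        break;
      }
    }
  }
  std::vector<IPoly> M;
  for (size_t i = 0; i < G.size(); ++i) if (keep[i]) M.push_back(G[i]);
  // tail-reduce each element against the others
  std::vector<IPoly> R;
  for (size_t i = 0; i < M.size(); ++i) {
    std::vector<IPoly> others;
    for (size_t j = 0; j < M.size(); ++j) if (j != i) others.push_back(M[j]);
    IPoly h = iNormalForm(M[i], others);
    if (!h.isZero()) R.push_back(h);
  }
  std::sort(R.begin(), R.end(),
            [](const IPoly &a, const IPoly &b) { return lexCmpExpo(a.t[0].e, b.t[0].e) < 0; });
  return R;
}

} // namespace swsc

#endif
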