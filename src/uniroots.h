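// Exact real-root isolation for univariate polynomials over Q:
// Yun squarefree decomposition, Sturm-sequence counting, dyadic bisection.
#ifndef SWITCHSCAN_UNIROOTS_H
#define SWITCHSCAN_UNIROOTS_H

#include "bigrat.h"

namespace swsc {

typedef std::vector<Rat> UPoly; // ascending coefficients c0 + c1 x + ...

inline void uTrim(UPoly &p) { while (!p.empty() && p.back().isZero()) p.pop_back(); }
inline int uDeg(const UPoly &p) { return (int)p.size() - 1; }

inline UPoly uDeriv(const UPoly &p) {
  UPoly r;
  for (size_t i = 1; i < p.size(); ++i) r.push_back(rmul(p[i], Rat((long long)i)));
  return r;
}

inline UPoly uSub(const UPoly &a, const UPoly &b) {
  UPoly r(std::max(a.size(), b.size()), Rat(0));
  for (size_t i = 0; i < a.size(); ++i) r[i] = a[i];
  for (size_t i = 0; i < b.size(); ++i) r[i] = rsub(r[i], b[i]);
  uTrim(r);
  return r;
}

inline UPoly uMonic(UPoly p) {
  uTrim(p);
  if (p.empty()) return p;
  Rat lc = p.back();
  for (size_t i = 0; i < p.size(); ++i) p[i] = rdiv(p[i], lc);
  return p;
}

// division with remainder; both returned
inline void uDivMod(const UPoly &a, const UPoly &b, UPoly &q, UPoly &r) {
  r = a; uTrim(r);
  q.clear();
  UPoly bb = b; uTrim(bb);
  if (bb.empty()) throw std::runtime_error("polynomial division by zero");
  int db = uDeg(bb);
  q.assign(std::max(0, uDeg(r) - db + 1), Rat(0));
  while (uDeg(r) >= db) {
    int k = uDeg(r) - db;
    Rat f = rdiv(r.back(), bb.back());
    q[k] = radd(q[k], f);
    for (int i = 0; i <= db; ++i) r[k + i] = rsub(r[k + i], rmul(f, bb[i]));
    uTrim(r);
  }
}

inline UPoly uGcd(UPoly a, UPoly b) {
  uTrim(a); uTrim(b);
  while (!b.empty()) {
    UPoly q, r;
    uDivMod(a, b, q, r);
    a = b; b = uMonic(r); // monic to keep coefficient growth down
  }
  return uMonic(a);
}

inline UPoly uDivExact(const UPoly &a, const UPoly &b) {
  UPoly q, r;
  uDivMod(a, b, q, r);
  if (!r.empty()) throw std::runtime_error("inexact polynomial division");
  return q;
}

inline Rat uEval(const UPoly &p, const Rat &x) {
  Rat acc(0);
  for (size_t i = p.size(); i-- > 0;) acc = radd(rmul(acc, x), p[i]);
  return acc;
}

// Yun's algorithm: squarefree factors with multiplicities (f assumed nonzero).
inline std::vector<std::pair<UPoly, int>> squarefreeDecomp(UPoly f) {
  std::vector<std::pair<UPoly, int>> out;
  f = uMonic(f);
  if (uDeg(f) <= 0) return out;
  UPoly fp = uDeriv(f);
  UPoly g = uGcd(f, fp);
  if (uDeg(g) == 0) { out.push_back(std::make_pair(f, 1)); return out; }
  UPoly w = uDivExact(f, g);
  UPoly y = uDivExact(fp, g);
  UPoly z = uSub(y, uDeriv(w));
  int i = 1;
  while (uDeg(w) > 0) {
    UPoly a = uGcd(w, z);
    if (uDeg(a) > 0) out.push_back(std::make_pair(a, i));
    w = uDivExact(w, a);
    y = uDivExact(z, a);
    z = uSub(y, uDeriv(w));
    ++i;
  }
  return out;
}

// Sturm chain of a squarefree polynomial
inline std::vector<UPoly> sturmChain(const UPoly &f) {
  std::vector<UPoly> ch;
  ch.push_back(f);
  UPoly fp = uDeriv(f);
  uTrim(fp);
  if (!fp.empty()) ch.push_back(fp);
  while (ch.size() >= 2) {
    UPoly q, r;
    uDivMod(ch[ch.size() - 2], ch.back(), q, r);
    uTrim(r);
    if (r.empty()) break;
    for (size_t i = 0; i < r.size(); ++i) r[i] = rneg(r[i]);
    // rescale by |lc| to keep numbers small: only a POSITIVE factor
    // preserves the Sturm sign sequence
    Rat lc = r.back();
    if (lc.sign() < 0) lc = rneg(lc);
    for (size_t i = 0; i < r.size(); ++i) r[i] = rdiv(r[i], lc);
    ch.push_back(r);
    if (uDeg(ch.back()) == 0) break;
  }
  return ch;
}

inline int sturmVar(const std::vector<UPoly> &ch, const Rat &x) {
  int v = 0, prev = 0;
  for (size_t i = 0; i < ch.size(); ++i) {
    int s = uEval(ch[i], x).sign();
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++v;
    prev = s;
  }
  return v;
}

struct RootRec {
  double value;
  int multiplicity;
  std::string exact; // "" when not exactly rational
  Rat lo, hi;        // final isolating interval (lo==hi for exact roots)
};

// dyadic rational helper: k / 2^s
inline Rat dyadic(const BigInt &k, int s) {
  BigInt den(1);
  BigInt two(2);
  for (int i = 0; i < s; ++i) den = mul(den, two);
  return Rat(k, den);
}

// attempt small-denominator rational reconstruction of a double
inline bool ratReconstruct(double x, Rat &out) {
  double a = x;
  long long p0 = 0, q0 = 1, p1 = 1, q1 = 0;
  for (int it = 0; it < 40; ++it) {
    double fl = std::floor(a);
    if (fl > 9e15 || fl < -9e15) return false;
    long long ai = (long long)fl;
    long long p2 = ai * p1 + p0, q2 = ai * q1 + q0;
    if (q2 > 1000000000LL || q2 < 0) return false;
    p0 = p1; q0 = q1; p1 = p2; q1 = q2;
    double approx = (double)p1 / (double)q1;
    if (std::fabs(approx - x) <= 1e-12 * std::max(1.0, std::fabs(x))) {
      out = Rat(BigInt(p1), BigInt(q1));
      return true;
    }
    double rem = a - fl;
    if (rem < 1e-15) return false;
    a = 1.0 / rem;
  }
  return false;
}

// Isolate and refine all real roots of squarefree f within [-M, M].
inline void isolateSquarefree(const UPoly &f, int mult, double reltol,
                              std::vector<RootRec> &out) {
  if (uDeg(f) <= 0) return;
  if (uDeg(f) == 1) {
    Rat root = rneg(rdiv(f[0], f[1]));
    RootRec rr;
    rr.value = rToDouble(root);
    rr.multiplicity = mult;
    rr.exact = ratToString(root);
    rr.lo = rr.hi = root;
    out.push_back(rr);
    return;
  }
  // Cauchy bound: 1 + max |ci|/|cn|
  double mx = 0;
  for (int i = 0; i < uDeg(f); ++i) {
    double v = std::fabs(rToDouble(f[i]) / rToDouble(f.back()));
    if (v > mx) mx = v;
  }
  long long Mi = (long long)std::ceil(1.0 + mx) + 1;
  std::vector<UPoly> chain = sturmChain(f);
  // work queue of dyadic intervals (klo, khi, scale): interval (klo/2^s, khi/2^s]
  struct Iv { BigInt klo, khi; int s; int vlo, vhi; };
  std::vector<Iv> stack;
  {
    Iv root;
    root.klo = BigInt(-Mi); root.khi = BigInt(Mi); root.s = 0;
    // ensure endpoints are not roots (bound is strict, so f(+-M) != 0)
    root.vlo = sturmVar(chain, dyadic(root.klo, 0));
    root.vhi = sturmVar(chain, dyadic(root.khi, 0));
    stack.push_back(root);
  }
  while (!stack.empty()) {
    Iv iv = stack.back();
    stack.pop_back();
    int count = iv.vlo - iv.vhi;
    if (count <= 0) continue;
    Rat lo = dyadic(iv.klo, iv.s), hi = dyadic(iv.khi, iv.s);
    if (count == 1) {
      // refine by sign bisection (simple root of squarefree poly)
      Rat flo = uEval(f, lo);
      Rat fhi = uEval(f, hi);
      int slo = flo.sign();
      // interval is (lo, hi]; if f(hi)==0 the root is hi exactly
      if (fhi.isZero()) {
        RootRec rr;
        rr.value = rToDouble(hi);
        rr.multiplicity = mult;
        rr.exact = ratToString(hi);
        rr.lo = rr.hi = hi;
        out.push_back(rr);
        continue;
      }
      // f(lo) may be 0 when lo is a root belonging to the neighbouring
      // interval; nudge lo upward (checking the Sturm count stays 1) until
      // f(lo) != 0.
      if (slo == 0) {
        BigInt klo2 = iv.klo; int s2 = iv.s;
        int extra = 2;
        while (true) {
          BigInt kc = klo2;
          for (int t = 0; t < extra; ++t) kc = mul(kc, BigInt(2));
          kc = add(kc, BigInt(1));
          Rat cand = dyadic(kc, s2 + extra);
          if (uEval(f, cand).sign() != 0 &&
              sturmVar(chain, cand) - iv.vhi == 1) {
            lo = cand;
            slo = uEval(f, lo).sign();
            break;
          }
          extra += 2; // smaller nudge
          if (extra > 400) throw std::runtime_error("root isolation failed to separate");
        }
      }
      double target = reltol;
      while (true) {
        double dlo = rToDouble(lo), dhi = rToDouble(hi);
        if (std::fabs(dhi - dlo) <= target * std::max(1.0, std::fabs(dlo)))
          break;
        Rat mid = rmul(radd(lo, hi), Rat(BigInt(1), BigInt(2)));
        Rat fm = uEval(f, mid);
        if (fm.isZero()) {
          RootRec rr;
          rr.value = rToDouble(mid);
          rr.multiplicity = mult;
          rr.exact = ratToString(mid);
          rr.lo = rr.hi = mid;
          out.push_back(rr);
          goto nextInterval;
        }
        if (fm.sign() == slo) lo = mid; else hi = mid;
      }
      {
        double mid = 0.5 * (rToDouble(lo) + rToDouble(hi));
        RootRec rr;
        rr.value = mid;
        rr.multiplicity = mult;
        rr.exact = "";
        rr.lo = lo; rr.hi = hi;
        // try exact small-rational reconstruction
        Rat cand;
        if (ratReconstruct(mid, cand)) {
          if (uEval(f, cand).isZero()) {
            rr.exact = ratToString(cand);
            rr.value = rToDouble(cand);
            rr.lo = rr.hi = cand;
          }
        }
        out.push_back(rr);
      }
    nextInterval:;
      continue;
    }
    // count > 1: bisect
    BigInt klo2 = mul(iv.klo, BigInt(2));
    BigInt khi2 = mul(iv.khi, BigInt(2));
    BigInt kmid = add(klo2, khi2);
    // kmid/2 might not be integer when klo+khi odd; use scale+1 uniformly
    int s2 = iv.s + 1;
    kmid = add(iv.klo, iv.khi); // (klo+khi) / 2^(s+1)
    Rat mid = dyadic(kmid, s2);
    int vm = sturmVar(chain, mid);
    Iv left;  left.klo = klo2; left.khi = kmid; left.s = s2; left.vlo = iv.vlo; left.vhi = vm;
    Iv right; right.klo = kmid; right.khi = khi2; right.s = s2; right.vlo = vm; right.vhi = iv.vhi;
    // If mid is itself a root, Sturm variation at the root still yields a
    // consistent (a,b] split because f(mid)=0 contributes no sign.
    if (uEval(f, mid).isZero()) {
      RootRec rr;
      rr.value = rToDouble(mid);
      rr.multiplicity = mult;
      rr.exact = ratToString(mid);
      rr.lo = rr.hi = mid;
      out.push_back(rr);
      // roots strictly left / right of mid: shrink both sides slightly
      // left interval (lo, mid-eps], right (mid+eps, hi]
      BigInt kml = sub(mul(kmid, BigInt(1024)), BigInt(1));
      BigInt kmr = add(mul(kmid, BigInt(1024)), BigInt(1));
      int s3 = s2 + 10;
      Iv l2; l2.klo = mul(klo2, BigInt(1024)); l2.khi = kml; l2.s = s3;
      l2.vlo = iv.vlo; l2.vhi = sturmVar(chain, dyadic(kml, s3));
      Iv r2; r2.klo = kmr; r2.khi = mul(khi2, BigInt(1024)); r2.s = s3;
      r2.vlo = sturmVar(chain, dyadic(kmr, s3)); r2.vhi = iv.vhi;
      stack.push_back(l2);
      stack.push_back(r2);
    } else {
      stack.push_back(left);
      stack.push_back(right);
    }
  }
}

inline std::vector<RootRec> realRootsExact(const UPoly &fIn, double reltol) {
  UPoly f = fIn;
  uTrim(f);
  if (f.empty()) throw std::runtime_error("zero polynomial has no well-defined roots");
  std::vector<RootRec> out;
  std::vector<std::pair<UPoly, int>> sq = squarefreeDecomp(f);
  for (size_t i = 0; i < sq.size(); ++i)
    isolateSquarefree(sq[i].first, sq[i].second, reltol, out);
  std::sort(out.begin(), out.end(),
            [](const RootRec &a, const RootRec &b) { return a.value < b.value; });
  return out;
}

} // namespace swsc

#endif
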