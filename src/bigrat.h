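// Exact arbitrary-precision integer and rational arithmetic.
// Base-1e9 limbs; schoolbook multiplication and Knuth division are ample for
// the coefficient sizes that lex Groebner bases of small reaction networks
// produce (up to a few thousand digits).
#ifndef SWITCHSCAN_BIGRAT_H
#define SWITCHSCAN_BIGRAT_H

#include <vector>
#include <string>
#include <cstdint>
#include <cstdlib>
#include <cmath>
#include <stdexcept>
#include <algorithm>

namespace swsc {

typedef uint32_t limb_t;
const uint64_t LIMB_BASE = 1000000000u; // 1e9
const int LIMB_DIGITS = 9;

struct BigInt {
  int sign;                  // -1, 0, +1
  std::vector<limb_t> d;     // little-endian base-1e9; empty iff sign==0

  BigInt() : sign(0) {}
  explicit BigInt(long long v) : sign(0) {
    if (v < 0) { sign = -1; v = -v; }
    else if (v > 0) sign = 1;
    while (v) { d.push_back((limb_t)(v % (long long)LIMB_BASE)); v /= (long long)LIMB_BASE; }
  }
  bool isZero() const { return sign == 0; }
  void trim() {
    while (!d.empty() && d.back() == 0) d.pop_back();
    if (d.empty()) sign = 0;
  }
};

// ---- low-level magnitude helpers -------------------------------------------

inline int cmpAbs(const BigInt &a, const BigInt &b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;) {
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  }
  return 0;
}

inline std::vector<limb_t> addAbs(const std::vector<limb_t> &a, const std::vector<limb_t> &b) {
  const std::vector<limb_t> *x = &a, *y = &b;
  if (x->size() < y->size()) std::swap(x, y);
  std::vector<limb_t> r(x->size() + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < x->size(); ++i) {
    uint64_t s = carry + (*x)[i] + (i < y->size() ? (*y)[i] : 0);
    r[i] = (limb_t)(s % LIMB_BASE);
    carry = s / LIMB_BASE;
  }
  r[x->size()] = (limb_t)carry;
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

// requires |a| >= |b|
inline std::vector<limb_t> subAbs(const std::vector<limb_t> &a, const std::vector<limb_t> &b) {
  std::vector<limb_t> r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += (int64_t)LIMB_BASE; borrow = 1; } else borrow = 0;
    r[i] = (limb_t)s;
  }
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

inline std::vector<limb_t> mulAbs(const std::vector<limb_t> &a, const std::vector<limb_t> &b) {
  if (a.empty() || b.empty()) return std::vector<limb_t>();
  std::vector<uint64_t> acc(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t ai = a[i], carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t cur = acc[i + j] + ai * (uint64_t)b[j] + carry;
      acc[i + j] = cur % LIMB_BASE;
      carry = cur / LIMB_BASE;
    }
    size_t k = i + b.size();
    while (carry) { uint64_t cur = acc[k] + carry; acc[k] = cur % LIMB_BASE; carry = cur / LIMB_BASE; ++k; }
  }
  std::vector<limb_t> r(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) r[i] = (limb_t)acc[i];
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

// ---- arithmetic -------------------------------------------------------------

inline BigInt neg(const BigInt &a) { BigInt r = a; r.sign = -r.sign; return r; }

inline BigInt add(const BigInt &a, const BigInt &b) {
  if (a.isZero()) return b;
  if (b.isZero()) return a;
  BigInt r;
  if (a.sign == b.sign) { r.d = addAbs(a.d, b.d); r.sign = a.sign; }
  else {
    int c = cmpAbs(a, b);
    if (c == 0) return BigInt();
    if (c > 0) { r.d = subAbs(a.d, b.d); r.sign = a.sign; }
    else       { r.d = subAbs(b.d, a.d); r.sign = b.sign; }
  }
  r.trim();
  return r;
}

inline BigInt sub(const BigInt &a, const BigInt &b) { return add(a, neg(b)); }

inline BigInt mul(const BigInt &a, const BigInt &b) {
  BigInt r;
  if (a.isZero() || b.isZero()) return r;
  r.d = mulAbs(a.d, b.d);
  r.sign = a.sign * b.sign;
  r.trim();
  return r;
}

inline int cmp(const BigInt &a, const BigInt &b) {
  if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
  int c = cmpAbs(a, b);
  return a.sign >= 0 ? c : -c;
}

// Knuth algorithm D, base 1e9.  q = floor(|u|/|v|), r = |u| - q*|v| (magnitudes).
inline void divmodAbs(const std::vector<limb_t> &uIn, const std::vector<limb_t> &vIn,
                      std::vector<limb_t> &q, std::vector<limb_t> &r) {
  q.clear(); r.clear();
  if (vIn.empty()) throw std::runtime_error("division by zero");
  // compare
  {
    BigInt U, V; U.d = uIn; U.sign = uIn.empty() ? 0 : 1; V.d = vIn; V.sign = 1;
    if (uIn.empty() || cmpAbs(U, V) < 0) { r = uIn; return; }
  }
  if (vIn.size() == 1) {
    uint64_t v0 = vIn[0], rem = 0;
    q.assign(uIn.size(), 0);
    for (size_t i = uIn.size(); i-- > 0;) {
      uint64_t cur = rem * LIMB_BASE + uIn[i];
      q[i] = (limb_t)(cur / v0);
      rem = cur % v0;
    }
    while (!q.empty() && q.back() == 0) q.pop_back();
    if (rem) r.push_back((limb_t)rem);
    return;
  }
  size_t n = vIn.size(), m = uIn.size() - n;
  uint64_t dnorm = LIMB_BASE / ((uint64_t)vIn.back() + 1);
  // normalized copies
  std::vector<limb_t> u(uIn.size() + 1, 0), v(vIn.size(), 0);
  {
    uint64_t carry = 0;
    for (size_t i = 0; i < uIn.size(); ++i) {
      uint64_t cur = (uint64_t)uIn[i] * dnorm + carry;
      u[i] = (limb_t)(cur % LIMB_BASE); carry = cur / LIMB_BASE;
    }
    u[uIn.size()] = (limb_t)carry;
    carry = 0;
    for (size_t i = 0; i < vIn.size(); ++i) {
      uint64_t cur = (uint64_t)vIn[i] * dnorm + carry;
      v[i] = (limb_t)(cur % LIMB_BASE); carry = cur / LIMB_BASE;
    }
  }
  q.assign(m + 1, 0);
  for (size_t j = m + 1; j-- > 0;) {
    uint64_t num = (uint64_t)u[j + n] * LIMB_BASE + u[j + n - 1];
    uint64_t qhat = num / v[n - 1];
    uint64_t rhat = num % v[n - 1];
    while (qhat >= LIMB_BASE ||
           (n >= 2 && qhat * (uint64_t)v[n - 2] > rhat * LIMB_BASE + u[j + n - 2])) {
      --qhat; rhat += v[n - 1];
      if (rhat >= LIMB_BASE) break;
    }
    // multiply and subtract
    int64_t borrow = 0; uint64_t carry = 0;
    for (size_t i = 0; i < n; ++i) {
      uint64_t p = qhat * (uint64_t)v[i] + carry;
      carry = p / LIMB_BASE;
      int64_t t = (int64_t)u[i + j] - (int64_t)(p % LIMB_BASE) - borrow;
      if (t < 0) { t += (int64_t)LIMB_BASE; borrow = 1; } else borrow = 0;
      u[i + j] = (limb_t)t;
    }
    int64_t t = (int64_t)u[j + n] - (int64_t)carry - borrow;
    if (t < 0) { // qhat was one too large: add back
      t += (int64_t)LIMB_BASE;
      u[j + n] = (limb_t)t;
      --qhat;
      uint64_t c2 = 0;
      for (size_t i = 0; i < n; ++i) {
        uint64_t s = (uint64_t)u[i + j] + v[i] + c2;
        u[i + j] = (limb_t)(s % LIMB_BASE); c2 = s / LIMB_BASE;
      }
      u[j + n] = (limb_t)(((uint64_t)u[j + n] + c2) % LIMB_BASE);
    } else {
      u[j + n] = (limb_t)t;
    }
    q[j] = (limb_t)qhat;
  }
  while (!q.empty() && q.back() == 0) q.pop_back();
  // denormalize remainder
  r.assign(u.begin(), u.begin() + n);
  while (!r.empty() && r.back() == 0) r.pop_back();
  if (dnorm > 1 && !r.empty()) {
    uint64_t rem = 0;
    for (size_t i = r.size(); i-- > 0;) {
      uint64_t cur = rem * LIMB_BASE + r[i];
      r[i] = (limb_t)(cur / dnorm);
      rem = cur % dnorm;
    }
    while (!r.empty() && r.back() == 0) r.pop_back();
  }
}

inline void divmod(const BigInt &a, const BigInt &b, BigInt &q, BigInt &r) {
  std::vector<limb_t> qq, rr;
  divmodAbs(a.d, b.d, qq, rr);
  q.d = qq; q.sign = qq.empty() ? 0 : a.sign * b.sign; q.trim();
  r.d = rr; r.sign = rr.empty() ? 0 : a.sign; r.trim();
}

inline BigInt divExact(const BigInt &a, const BigInt &b) {
  BigInt q, r;
  divmod(a, b, q, r);
  if (!r.isZero()) throw std::runtime_error("inexact integer division");
  return q;
}

inline BigInt absB(const BigInt &a) { BigInt r = a; if (r.sign < 0) r.sign = 1; return r; }

inline BigInt gcdB(BigInt a, BigInt b) {
  a = absB(a); b = absB(b);
  while (!b.isZero()) {
    BigInt q, r;
    divmod(a, b, q, r);
    a = b; b = r;
  }
  if (a.isZero()) a = BigInt(0);
  return a;
}

// ---- string / double conversion ---------------------------------------------

inline BigInt bigFromDigits(const std::string &s) { // nonempty decimal digits
  BigInt r;
  size_t n = s.size();
  for (size_t pos = n; pos > 0;) {
    size_t start = pos >= (size_t)LIMB_DIGITS ? pos - LIMB_DIGITS : 0;
    limb_t v = 0;
    for (size_t i = start; i < pos; ++i) {
      if (s[i] < '0' || s[i] > '9') throw std::runtime_error("bad digit in integer literal");
      v = v * 10 + (limb_t)(s[i] - '0');
    }
    r.d.push_back(v);
    pos = start;
  }
  r.sign = 1;
  r.trim();
  return r;
}

inline std::string toString(const BigInt &a) {
  if (a.isZero()) return "0";
  std::string s = a.sign < 0 ? "-" : "";
  char buf[16];
  snprintf(buf, sizeof(buf), "%u", (unsigned)a.d.back());
  s += buf;
  for (size_t i = a.d.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09u", (unsigned)a.d[i]);
    s += buf;
  }
  return s;
}

// mantissa in [1,1e9) times 10^(9*exp9), approximately
inline void toMantExp(const BigInt &a, double &mant, long &exp9) {
  if (a.isZero()) { mant = 0; exp9 = 0; return; }
  size_t n = a.d.size();
  mant = 0;
  size_t take = n >= 3 ? 3 : n;
  for (size_t i = 0; i < take; ++i) mant = mant * 1e9 + (double)a.d[n - 1 - i];
  exp9 = (long)(n - take);
  if (a.sign < 0) mant = -mant;
}

inline double toDouble(const BigInt &a) {
  double mant; long e9;
  toMantExp(a, mant, e9);
  return mant * std::pow(1e9, (double)e9);
}

inline BigInt pow10Big(long k) {
  BigInt r(1);
  BigInt ten(10);
  for (long i = 0; i < k; ++i) r = mul(r, ten);
  return r;
}

// ---- rationals --------------------------------------------------------------

struct Rat {
  BigInt n, d; // d > 0, gcd(n,d)=1; zero is 0/1
  Rat() : n(0), d(1) {}
  Rat(const BigInt &nn, const BigInt &dd) : n(nn), d(dd) { normalize(); }
  explicit Rat(long long v) : n(v), d(1) {}
  void normalize() {
    if (d.isZero()) throw std::runtime_error("rational with zero denominator");
    if (n.isZero()) { d = BigInt(1); return; }
    if (d.sign < 0) { n.sign = -n.sign; d.sign = 1; }
    BigInt g = gcdB(n, d);
    if (!(g.d.size() == 1 && g.d[0] == 1)) { n = divExact(n, g); d = divExact(d, g); }
  }
  bool isZero() const { return n.isZero(); }
  int sign() const { return n.sign; }
};

inline Rat radd(const Rat &a, const Rat &b) { return Rat(add(mul(a.n, b.d), mul(b.n, a.d)), mul(a.d, b.d)); }
inline Rat rsub(const Rat &a, const Rat &b) { return Rat(sub(mul(a.n, b.d), mul(b.n, a.d)), mul(a.d, b.d)); }
inline Rat rmul(const Rat &a, const Rat &b) { return Rat(mul(a.n, b.n), mul(a.d, b.d)); }
inline Rat rdiv(const Rat &a, const Rat &b) {
  if (b.isZero()) throw std::runtime_error("rational division by zero");
  return Rat(mul(a.n, b.d), mul(a.d, b.n));
}
inline Rat rneg(const Rat &a) { Rat r = a; r.n.sign = -r.n.sign; return r; }
inline int rcmp(const Rat &a, const Rat &b) { return cmp(mul(a.n, b.d), mul(b.n, a.d)); }

inline double rToDouble(const Rat &a) {
  double mn, md; long en, ed;
  toMantExp(a.n, mn, en);
  toMantExp(a.d, md, ed);
  if (mn == 0) return 0.0;
  return (mn / md) * std::pow(1e9, (double)(en - ed));
}

// Parses "-3", "3/4", "1.5", "1.0625e-4", ".5", "2E3"; exact decimal semantics.
inline Rat parseRat(const std::string &sIn) {
  std::string s;
  for (size_t i = 0; i < sIn.size(); ++i) if (!isspace((unsigned char)sIn[i])) s += sIn[i];
  if (s.empty()) throw std::runtime_error("empty rational literal");
  size_t slash = s.find('/');
  if (slash != std::string::npos) {
    Rat a = parseRat(s.substr(0, slash));
    Rat b = parseRat(s.substr(slash + 1));
    return rdiv(a, b);
  }
  int sign = 1; size_t pos = 0;
  if (s[pos] == '+') ++pos;
  else if (s[pos] == '-') { sign = -1; ++pos; }
  std::string digits; long fracLen = 0, expo = 0;
  bool seenDot = false, any = false;
  while (pos < s.size() && (isdigit((unsigned char)s[pos]) || s[pos] == '.')) {
    if (s[pos] == '.') {
      if (seenDot) throw std::runtime_error("bad numeric literal: " + sIn);
      seenDot = true;
    } else {
      digits += s[pos];
      if (seenDot) ++fracLen;
      any = true;
    }
    ++pos;
  }
  if (!any) throw std::runtime_error("bad numeric literal: " + sIn);
  if (pos < s.size() && (s[pos] == 'e' || s[pos] == 'E')) {
    ++pos;
    long esign = 1;
    if (pos < s.size() && (s[pos] == '+' || s[pos] == '-')) { if (s[pos] == '-') esign = -1; ++pos; }
    if (pos >= s.size()) throw std::runtime_error("bad exponent: " + sIn);
    long e = 0;
    while (pos < s.size() && isdigit((unsigned char)s[pos])) { e = e * 10 + (s[pos] - '0'); ++pos; }
    expo = esign * e;
  }
  if (pos != s.size()) throw std::runtime_error("bad numeric literal: " + sIn);
  BigInt num = bigFromDigits(digits.empty() ? "0" : digits);
  num.sign = num.isZero() ? 0 : sign;
  long shift = expo - fracLen;
  BigInt den(1);
  if (shift > 0) num = mul(num, pow10Big(shift));
  else if (shift < 0) den = pow10Big(-shift);
  return Rat(num, den);
}

inline std::string ratToString(const Rat &a) {
  if (a.d.d.size() == 1 && a.d.d[0] == 1) return toString(a.n);
  return toString(a.n) + "/" + toString(a.d);
}

} // namespace swsc

#endif
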