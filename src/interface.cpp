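// Rcpp bridge.  Polynomials cross the boundary as
//   list(exps = integer matrix [terms x nvars], coefs = character vector)
// with terms in descending lexicographic order (variable/column 1 ranks
// highest) and coefficients as exact rational strings "n" or "n/d".
#include <Rcpp.h>
#include "bigrat.h"
#include "poly.h"
#include "uniroots.h"

using namespace Rcpp;
using namespace swsc;

static QPoly polyFromR(const List &p) {
  IntegerMatrix exps = p["exps"];
  CharacterVector coefs = p["coefs"];
  if (exps.nrow() != coefs.size())
    stop("polynomial exps/coefs length mismatch");
  QPoly q(exps.ncol());
  for (int i = 0; i < exps.nrow(); ++i) {
    QTerm t;
    t.e.resize(exps.ncol());
    for (int j = 0; j < exps.ncol(); ++j) {
      if (exps(i, j) < 0) stop("negative exponent in polynomial");
      t.e[j] = exps(i, j);
    }
    t.c = parseRat(as<std::string>(coefs[i]));
    q.t.push_back(t);
  }
  qNormalize(q);
  return q;
}

static List polyToR(const QPoly &q) {
  IntegerMatrix exps(q.t.size(), q.nv);
  CharacterVector coefs(q.t.size());
  for (size_t i = 0; i < q.t.size(); ++i) {
    for (int j = 0; j < q.nv; ++j) exps(i, j) = q.t[i].e[j];
    coefs[i] = ratToString(q.t[i].c);
  }
  return List::create(_["exps"] = exps, _["coefs"] = coefs);
}

// [[Rcpp::export]]
std::string cpp_rat_norm(std::string s) { return ratToString(parseRat(s)); }

// [[Rcpp::export]]
std::string cpp_rat_arith(std::string op, std::string a, std::string b) {
  Rat x = parseRat(a), y = parseRat(b);
  if (op == "add") return ratToString(radd(x, y));
  if (op == "sub") return ratToString(rsub(x, y));
  if (op == "mul") return ratToString(rmul(x, y));
  if (op == "div") return ratToString(rdiv(x, y));
  stop("unknown rational op");
}

// [[Rcpp::export]]
int cpp_rat_cmp(std::string a, std::string b) { return rcmp(parseRat(a), parseRat(b)); }

// [[Rcpp::export]]
NumericVector cpp_rat_to_double(CharacterVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = rToDouble(parseRat(as<std::string>(x[i])));
  return out;
}

// [[Rcpp::export]]
int cpp_lex_compare(IntegerVector m1, IntegerVector m2) {
  if (m1.size() != m2.size()) stop("exponent vectors differ in length");
  Expo a(m1.begin(), m1.end()), b(m2.begin(), m2.end());
  return lexCmpExpo(a, b);
}

// [[Rcpp::export]]
List cpp_poly_arith(std::string op, List pa, List pb) {
  QPoly a = polyFromR(pa), b = polyFromR(pb);
  if (a.nv != b.nv) stop("polynomials over different variable counts");
  if (op == "add") return polyToR(qAdd(a, b));
  if (op == "sub") return polyToR(qSub(a, b));
  if (op == "mul") return polyToR(qMul(a, b));
  stop("unknown polynomial op");
}

// [[Rcpp::export]]
List cpp_poly_scale(List p, std::string s) {
  return polyToR(qScale(polyFromR(p), parseRat(s)));
}

// [[Rcpp::export]]
List cpp_poly_pow(List p, int k) {
  if (k < 0) stop("negative polynomial power");
  return polyToR(qPow(polyFromR(p), k));
}

// [[Rcpp::export]]
List cpp_poly_deriv(List p, int var) {
  QPoly a = polyFromR(p);
  if (var < 0 || var >= a.nv) stop("variable index out of range");
  return polyToR(qDeriv(a, var));
}

// [[Rcpp::export]]
std::string cpp_poly_eval_rat(List p, CharacterVector point) {
  QPoly a = polyFromR(p);
  if ((int)point.size() != a.nv) stop("evaluation point has wrong length");
  std::vector<Rat> x(a.nv);
  for (int i = 0; i < a.nv; ++i) x[i] = parseRat(as<std::string>(point[i]));
  Rat acc(0);
  for (size_t i = 0; i < a.t.size(); ++i) {
    Rat term = a.t[i].c;
    for (int j = 0; j < a.nv; ++j) {
      for (int k = 0; k < a.t[i].e[j]; ++k) term = rmul(term, x[j]);
    }
    acc = radd(acc, term);
  }
  return ratToString(acc);
}

// partial evaluation: substitute an exact rational for one variable
// [[Rcpp::export]]
List cpp_poly_subst_rat(List p, int var, std::string val) {
  QPoly a = polyFromR(p);
  if (var < 0 || var >= a.nv) stop("variable index out of range");
  Rat v = parseRat(val);
  QPoly r(a.nv);
  for (size_t i = 0; i < a.t.size(); ++i) {
    QTerm t = a.t[i];
    for (int k = 0; k < a.t[i].e[var]; ++k) t.c = rmul(t.c, v);
    t.e[var] = 0;
    r.t.push_back(t);
  }
  qNormalize(r);
  return polyToR(r);
}

// substitute polynomial q for variable var of p (Horner in var)
// [[Rcpp::export]]
List cpp_poly_subst_poly(List p, int var, List q) {
  QPoly a = polyFromR(p), b = polyFromR(q);
  if (a.nv != b.nv) stop("polynomials over different variable counts");
  if (var < 0 || var >= a.nv) stop("variable index out of range");
  int dmax = 0;
  for (size_t i = 0; i < a.t.size(); ++i) dmax = std::max(dmax, a.t[i].e[var]);
  // split a by power of var
  std::vector<QPoly> byPow((size_t)dmax + 1, QPoly(a.nv));
  for (size_t i = 0; i < a.t.size(); ++i) {
    QTerm t = a.t[i];
    int d = t.e[var];
    t.e[var] = 0;
    byPow[d].t.push_back(t);
  }
  for (size_t d = 0; d < byPow.size(); ++d) qNormalize(byPow[d]);
  QPoly acc = byPow[dmax];
  for (int d = dmax - 1; d >= 0; --d) acc = qAdd(qMul(acc, b), byPow[d]);
  return polyToR(acc);
}

// [[Rcpp::export]]
List cpp_poly_reduce(List p, List basis) {
  QPoly a = polyFromR(p);
  std::vector<QPoly> G;
  for (int i = 0; i < basis.size(); ++i) {
    QPoly g = polyFromR(basis[i]);
    if (g.isZero()) stop("zero polynomial in reduction basis");
    G.push_back(g);
  }
  return polyToR(qReduce(a, G));
}

// [[Rcpp::export]]
List cpp_spoly(List p, List q) {
  QPoly a = polyFromR(p), b = polyFromR(q);
  if (a.isZero() || b.isZero()) stop("S-polynomial of a zero polynomial");
  return polyToR(qSPoly(a, b));
}

// [[Rcpp::export]]
SEXP cpp_exact_div(List p, List q) {
  QPoly a = polyFromR(p), b = polyFromR(q);
  QPoly h(a.nv);
  if (!qExactDiv(a, b, h)) return R_NilValue;
  return polyToR(h);
}

// [[Rcpp::export]]
List cpp_buchberger(List Fin, double pairCap) {
  std::vector<IPoly> F;
  int nv = -1;
  for (int i = 0; i < Fin.size(); ++i) {
    QPoly q = polyFromR(Fin[i]);
    if (nv < 0) nv = q.nv;
    if (q.nv != nv) stop("input polynomials over different variable counts");
    if (!q.isZero()) F.push_back(iFromQ(q));
  }
  if (F.empty()) stop("Buchberger needs at least one nonzero polynomial");
  long used = 0;
  std::vector<IPoly> G;
  try {
    G = buchberger(F, (long)pairCap, &used);
  } catch (GBError &e) {
    stop(std::string(e.what()));
  }
  List out(G.size());
  for (size_t i = 0; i < G.size(); ++i) out[i] = polyToR(qFromIMonic(G[i]));
  out.attr("pairsProcessed") = (double)used;
  return out;
}

// [[Rcpp::export]]
List cpp_uni_roots(CharacterVector coefsAsc, double reltol) {
  UPoly f;
  for (int i = 0; i < coefsAsc.size(); ++i) f.push_back(parseRat(as<std::string>(coefsAsc[i])));
  uTrim(f);
  if (f.empty()) stop("zero polynomial");
  std::vector<RootRec> roots = realRootsExact(f, reltol);
  NumericVector val(roots.size());
  IntegerVector mult(roots.size());
  CharacterVector exact(roots.size());
  for (size_t i = 0; i < roots.size(); ++i) {
    val[i] = roots[i].value;
    mult[i] = roots[i].multiplicity;
    exact[i] = roots[i].exact;
  }
  return List::create(_["value"] = val, _["multiplicity"] = mult, _["exact"] = exact);
}
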